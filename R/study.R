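#' Study template set
#'
#' Bundles one study's montage, its ordered microstate template maps, the
#' number of included subjects (the weight used by the meta-clustering),
#' free-form metadata, and the study's empirical findings.  Maps are
#' canonicalized on construction (average reference, unit norm); whether
#' each input map already was canonical is recorded in
#' \code{input_was_canonical}.
#'
#' @param study_id unique study identifier, e.g. \code{"Diezig 2022"}.
#' @param montage an [ms_montage()].
#' @param maps channels x classes numeric matrix; column names are the
#'   class labels (e.g. \code{"A"}..\code{"D"} or \code{"1"}..\code{"4"}).
#'   Map order is preserved exactly as authored.
#' @param n_subjects positive integer; the study weight.
#' @param metadata named list of free-form text (publication, analysis
#'   parameters, groups/conditions).
#' @param findings data frame with columns \code{map_label},
#'   \code{contrast}, \code{effect} (see [validate_finding()]), or an
#'   already-normalized \code{ms_findings} table.
#' @return an object of class \code{ms_study}.
#' @export
ms_study <- function(study_id, montage, maps, n_subjects,
                     metadata = list(), findings = NULL) {
  stopifnot(inherits(montage, "ms_montage"))
  study_id <- as.character(study_id)
  if (length(study_id) != 1L || !nzchar(study_id))
    stop_ms("study_id must be a non-empty string")
  if (!is_count(n_subjects))
    stop_ms("missing or invalid n_subjects for study '", study_id,
            "' (need a positive integer)")
  maps <- as.matrix(maps)
  if (is.null(colnames(maps)))
    colnames(maps) <- as.character(seq_len(ncol(maps)))
  if (ncol(maps) < 1L)
    stop_ms("study '", study_id, "' must have at least one map")
  if (nrow(maps) != montage$n_channels)
    stop_ms("channel-count mismatch in study '", study_id, "': maps have ",
            nrow(maps), " channels, montage has ", montage$n_channels)
  if (anyDuplicated(colnames(maps)))
    stop_ms("duplicate map labels in study '", study_id, "': ",
            paste(unique(colnames(maps)[duplicated(colnames(maps))]),
                  collapse = ", "))
  maps <- canonicalize_columns(maps, context = paste0("study '", study_id, "'"))
  flags <- attr(maps, "input_was_canonical")
  attr(maps, "input_was_canonical") <- NULL
  rownames(maps) <- montage$labels
  if (inherits(findings, "ms_findings")) {
    fnd <- findings
    fnd$study_id <- study_id
    unknown <- setdiff(fnd$map_label, colnames(maps))
    if (length(unknown))
      stop_ms("finding(s) reference unknown map label(s): ",
              paste(unknown, collapse = ", "))
  } else {
    fnd <- validate_findings_table(findings, study_id = study_id,
                                   map_labels = colnames(maps))
  }
  metadata <- lapply(metadata %||% list(), as.character)
  structure(list(study_id = study_id, montage = montage, maps = maps,
                 n_subjects = as.integer(round(n_subjects)),
                 metadata = metadata, findings = fnd,
                 input_was_canonical = stats::setNames(flags, colnames(maps))),
            class = "ms_study")
}

#' @export
print.ms_study <- function(x, ...) {
  cat("Microstate study '", x$study_id, "': ", ncol(x$maps), " map(s) [",
      paste(colnames(x$maps), collapse = ", "), "] on ",
      x$montage$n_channels, " channels, n = ", x$n_subjects,
      " subjects, ", nrow(x$findings), " finding(s)\n", sep = "")
  invisible(x)
}

#' Atlas: a collection of studies
#'
#' @param studies list of [ms_study()] objects with unique study ids and
#'   at least one map in total.
#' @return an object of class \code{ms_atlas}.
#' @export
ms_atlas <- function(studies) {
  if (inherits(studies, "ms_study")) studies <- list(studies)
  stopifnot(length(studies) >= 1L,
            all(vapply(studies, inherits, TRUE, "ms_study")))
  ids <- vapply(studies, `[[`, "", "study_id")
  if (anyDuplicated(ids))
    stop_ms("duplicate study ids: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (sum(vapply(studies, function(s) ncol(s$maps), 1L)) < 1L)
    stop_ms("atlas must contain at least one map")
  structure(list(studies = stats::setNames(studies, ids)),
            class = "ms_atlas")
}

#' @export
print.ms_atlas <- function(x, ...) {
  nmaps <- sum(vapply(x$studies, function(s) ncol(s$maps), 1L))
  cat("Microstate atlas:", length(x$studies), "studies,", nmaps, "maps\n")
  invisible(x)
}

## Index of every map in an atlas, in atlas order.
atlas_map_index <- function(atlas) {
  rows <- lapply(atlas$studies, function(s) {
    data.frame(study_id = s$study_id, map_label = colnames(s$maps),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---- JSON study files -------------------------------------------------

study_to_doc <- function(study) {
  ub <- jsonlite::unbox
  fnd <- study$findings
  list(
    study_id = ub(study$study_id),
    n_subjects = ub(study$n_subjects),
    metadata = lapply(study$metadata, ub),
    montage = list(labels = study$montage$labels,
                   positions = unname(study$montage$positions)),
    maps = lapply(colnames(study$maps), function(l) {
      list(label = ub(l), values = unname(study$maps[, l]))
    }),
    findings = lapply(seq_len(nrow(fnd)), function(i) {
      list(map_label = ub(fnd$map_label[i]),
           contrast = ub(fnd$contrast[i]),
           effect = ub(effect_string(fnd$direction[i], fnd$parameter[i],
                                     fnd$parameter_detail[i])))
    }),
    input_was_canonical = unname(study$input_was_canonical)
  )
}

study_from_doc <- function(doc, source = "study document") {
  need <- c("study_id", "montage", "maps")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop_ms(source, ": missing field(s) ", paste(miss, collapse = ", "))
  if (is.null(doc$n_subjects))
    stop_ms(source, ": missing n_subjects")
  mon <- ms_montage(unlist(doc$montage$labels),
                    do.call(rbind, lapply(doc$montage$positions, unlist)))
  labels <- vapply(doc$maps, function(m) as.character(m$label), "")
  vals <- lapply(doc$maps, function(m) as.numeric(unlist(m$values)))
  nv <- unique(vapply(vals, length, 1L))
  if (length(nv) != 1L || nv != mon$n_channels)
    stop_ms(source, ": channel-count mismatch between montage (",
            mon$n_channels, ") and map values (",
            paste(unique(vapply(vals, length, 1L)), collapse = ","), ")")
  maps <- do.call(cbind, vals)
  colnames(maps) <- labels
  fnd <- NULL
  if (length(doc$findings)) {
    fnd <- data.frame(
      map_label = vapply(doc$findings, function(f) as.character(f$map_label), ""),
      contrast = vapply(doc$findings, function(f) as.character(f$contrast %||% ""), ""),
      effect = vapply(doc$findings, function(f) as.character(f$effect), ""),
      stringsAsFactors = FALSE)
  }
  ms_study(doc$study_id, mon, maps, doc$n_subjects,
           metadata = doc$metadata %||% list(), findings = fnd)
}

#' Read / write study files
#'
#' Studies are stored as JSON documents
#' \code{\{study_id, n_subjects, metadata, montage\{labels, positions\},
#' maps[\{label, values\}], findings[\{map_label, contrast, effect\}]\}}.
#' Maps are canonicalized on load and a flag records whether the stored
#' values already were canonical.  \code{write_study} followed by
#' \code{read_study} reproduces text fields exactly and numeric fields to
#' within 1e-12.
#'
#' @param path file path.
#' @param study an [ms_study()].
#' @return \code{read_study} returns an \code{ms_study};
#'   \code{write_study} returns \code{path} invisibly.
#' @export
read_study <- function(path) {
  if (!file.exists(path)) stop_ms("study file not found: ", path)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop_ms("cannot parse study file ", path, ": ",
                                conditionMessage(e)))
  study_from_doc(doc, source = path)
}

#' @rdname read_study
#' @export
write_study <- function(study, path) {
  stopifnot(inherits(study, "ms_study"))
  jsonlite::write_json(study_to_doc(study), path, digits = NA,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Read / write an atlas
#'
#' An atlas on disk is either a directory of per-study \code{.json} files
#' or a single JSON array of study documents.
#'
#' @param path directory or JSON file (\code{read_atlas}); output
#'   directory (\code{write_atlas}).
#' @param atlas an [ms_atlas()].
#' @return \code{read_atlas} returns an \code{ms_atlas};
#'   \code{write_atlas} returns \code{path} invisibly.
#' @export
read_atlas <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
    if (!length(files)) stop_ms("no study .json files in ", path)
    return(ms_atlas(lapply(files, read_study)))
  }
  if (!file.exists(path)) stop_ms("atlas path not found: ", path)
  docs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ms_atlas(lapply(seq_along(docs), function(i) {
    study_from_doc(docs[[i]], source = paste0(path, "[", i, "]"))
  }))
}

#' @rdname read_atlas
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "ms_atlas"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (s in atlas$studies) {
    fn <- gsub("[^A-Za-z0-9._-]+", "_", s$study_id)
    write_study(s, file.path(path, paste0(fn, ".json")))
  }
  invisible(path)
}
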