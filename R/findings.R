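## Findings database: validated empirical findings attached to template
## maps, queryable by explicit map selection or by meta-class membership.

.ms_parameters <- c("Duration", "Occurrence", "Contribution", "GEV",
                    "CurrentDensity")

.findings_cols <- c("study_id", "map_label", "contrast", "direction",
                    "parameter", "parameter_detail")

#' Validate and normalize one findings record
#'
#' A finding attaches an empirical effect to one template map: a contrast
#' (the compared groups/conditions, free text) and an effect made of a
#' direction (\code{More}/\code{Less}) and a microstate parameter
#' (\code{Duration}, \code{Occurrence}, \code{Contribution}, \code{GEV},
#' \code{CurrentDensity}, or \code{Other} with the verbatim text kept in
#' \code{parameter_detail}).  Maps without findings carry a single
#' \code{NoFinding} record with empty contrast and parameter.
#'
#' @param map_label label of the map within its study.
#' @param contrast free-text contrast; must be empty for "No findings" and
#'   non-empty otherwise.
#' @param effect effect string, e.g. \code{"More Duration"},
#'   \code{"Less Occurrence"}, \code{"More current density"},
#'   \code{"No findings"}.
#' @param study_id optional study id recorded in the returned row.
#' @return a one-row data frame with columns study_id, map_label, contrast,
#'   direction, parameter, parameter_detail.
#' @export
#' @examples
#' validate_finding("4", "Hypnagogic state vs. wake", "More Duration")
#' validate_finding("C", "", "No findings")
validate_finding <- function(map_label, contrast, effect, study_id = NA_character_) {
  map_label <- trimws(as.character(map_label))
  contrast <- trimws(as.character(contrast %||% ""))
  effect <- trimws(as.character(effect %||% ""))
  if (is.na(contrast)) contrast <- ""
  row <- function(direction, parameter, detail = "") {
    df <- data.frame(study_id = study_id, map_label = map_label,
                     contrast = contrast, direction = direction,
                     parameter = parameter, parameter_detail = detail,
                     stringsAsFactors = FALSE)
    class(df) <- c("ms_findings", "data.frame")
    df
  }
  if (grepl("^no finding(s)?$", effect, ignore.case = TRUE) ||
      toupper(effect) == "NOFINDING") {
    if (nzchar(contrast))
      stop_ms("a 'No findings' record must have an empty contrast (map '",
              map_label, "')")
    return(row("NoFinding", ""))
  }
  m <- regmatches(effect, regexec("^(\\S+)\\s+(.+)$", effect))[[1L]]
  if (length(m) != 3L)
    stop_ms("cannot parse effect '", effect, "' (map '", map_label,
            "'): expected '<More|Less> <parameter>' or 'No findings'")
  direction <- c(more = "More", less = "Less")[tolower(m[2L])]
  if (is.na(direction))
    stop_ms("unknown direction token '", m[2L], "' in effect '", effect, "'")
  if (!nzchar(contrast))
    stop_ms("missing contrast for finding '", effect, "' (map '",
            map_label, "')")
  ptext <- trimws(m[3L])
  pkey <- gsub("[^a-z]", "", tolower(ptext))
  parameter <- switch(pkey,
                      duration = "Duration",
                      occurrence = "Occurrence",
                      contribution = "Contribution",
                      gev = "GEV",
                      currentdensity = "CurrentDensity",
                      "Other")
  row(unname(direction), parameter,
      if (parameter == "Other") ptext else "")
}

## Recombine the normalized fields into the display/export effect string.
effect_string <- function(direction, parameter, detail = "") {
  ifelse(direction == "NoFinding", "No findings",
         paste(direction,
               ifelse(parameter == "CurrentDensity", "current density",
                      ifelse(parameter == "Other", detail, parameter))))
}

## Normalize a raw findings data frame (map_label, contrast, effect).
validate_findings_table <- function(raw, study_id = NA_character_,
                                    map_labels = NULL) {
  if (is.null(raw) || !NROW(raw)) return(empty_findings())
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    validate_finding(raw$map_label[i], raw$contrast[i], raw$effect[i],
                     study_id = study_id)
  })
  out <- do.call(rbind, rows)
  if (!is.null(map_labels)) {
    unknown <- setdiff(out$map_label, map_labels)
    if (length(unknown))
      stop_ms("finding(s) reference unknown map label(s): ",
              paste(unknown, collapse = ", "))
  }
  out
}

empty_findings <- function(provenance = NULL) {
  df <- data.frame(study_id = character(), map_label = character(),
                   contrast = character(), direction = character(),
                   parameter = character(), parameter_detail = character(),
                   stringsAsFactors = FALSE)
  class(df) <- c("ms_findings", "data.frame")
  if (!is.null(provenance)) attr(df, "provenance") <- provenance
  df
}

## Deterministic row order: study, then map label, then parameter.
sort_findings <- function(df) {
  o <- order(df$study_id, df$map_label, df$parameter, df$direction,
             df$contrast, method = "radix")
  out <- df[o, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ms_findings", "data.frame")
  out
}

#' Query findings for an explicit selection of maps
#'
#' Returns all findings attached to exactly the selected
#' (study, map label) pairs, in a deterministic order.  A selected map
#' that carries no findings contributes a single \code{NoFinding} row, so
#' every selected map is visible in the result.
#'
#' @param atlas an [ms_atlas()].
#' @param selection data frame (or 2-column matrix) with columns
#'   \code{study_id} and \code{map_label}.
#' @return an \code{ms_findings} data frame with a \code{provenance}
#'   attribute describing the selection.
#' @seealso [query_metaclass_findings()], [export_findings()]
#' @export
query_findings <- function(atlas, selection) {
  stopifnot(inherits(atlas, "ms_atlas"))
  selection <- as.data.frame(selection, stringsAsFactors = FALSE)
  if (ncol(selection) == 2L && !all(c("study_id", "map_label") %in% names(selection)))
    names(selection) <- c("study_id", "map_label")
  if (!nrow(selection)) stop_ms("empty selection")
  ids <- vapply(atlas$studies, `[[`, "", "study_id")
  offenders <- character()
  rows <- vector("list", nrow(selection))
  for (i in seq_len(nrow(selection))) {
    sid <- as.character(selection$study_id[i])
    lab <- as.character(selection$map_label[i])
    si <- match(sid, ids)
    if (is.na(si) || !(lab %in% colnames(atlas$studies[[si]]$maps))) {
      offenders <- c(offenders, paste0(sid, "_", lab))
      next
    }
    f <- atlas$studies[[si]]$findings
    f <- f[f$map_label == lab, , drop = FALSE]
    if (!nrow(f)) {
      f <- validate_finding(lab, "", "No findings", study_id = sid)
    } else {
      f$study_id <- sid
    }
    rows[[i]] <- f
  }
  if (length(offenders))
    stop_ms("selection refers to unknown map(s): ",
            paste(unique(offenders), collapse = ", "))
  out <- sort_findings(unique(do.call(rbind, rows)))
  attr(out, "provenance") <- paste0("selection of ", nrow(selection),
                                    " map(s)")
  out
}

#' Query findings for one meta-microstate class
#'
#' Backfits the atlas's template maps to the meta-map solution and returns
#' the findings of all maps assigned to class \code{k}.  Over all classes
#' these tables partition the atlas's maps.
#'
#' @param atlas an [ms_atlas()].
#' @param solution an \code{ms_metasolution} (see [modified_kmeans()],
#'   [as_metasolution()]).
#' @param k class index in \code{1..K}.
#' @param config spline configuration used when resampling study maps to
#'   the solution's montage.
#' @return an \code{ms_findings} data frame (possibly empty) with a
#'   \code{provenance} attribute.
#' @export
query_metaclass_findings <- function(atlas, solution, k,
                                     config = spline_config()) {
  stopifnot(inherits(solution, "ms_metasolution"))
  if (!is_count(k) || k > solution$K)
    stop_ms("class index k must be in 1..", solution$K)
  bf <- backfit_maps(solution, atlas, config = config)
  sel <- bf[bf$class == k, c("study_id", "map_label"), drop = FALSE]
  prov <- paste0("meta-class ", k, " of the ", solution$K, "-class solution")
  if (!nrow(sel)) {
    return(empty_findings(provenance = paste0(prov, " (no assigned maps)")))
  }
  out <- query_findings(atlas, sel)
  attr(out, "provenance") <- paste0(prov, ": ", nrow(sel), " map(s)")
  out
}

#' Export a findings table to CSV
#'
#' Writes the stable tabular form (study_id, map_label, label, contrast,
#' effect) used for interchange; [read_findings()] round-trips it.
#'
#' @param table an \code{ms_findings} data frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
export_findings <- function(table, path) {
  stopifnot(inherits(table, "ms_findings"))
  if (!nrow(table)) {
    out <- data.frame(study_id = character(), map_label = character(),
                      label = character(), contrast = character(),
                      effect = character(), stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(path))
  }
  out <- data.frame(
    study_id = table$study_id,
    map_label = table$map_label,
    label = paste0(table$study_id, "_", table$map_label),
    contrast = table$contrast,
    effect = effect_string(table$direction, table$parameter,
                           table$parameter_detail),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a findings CSV written by [export_findings()]
#'
#' @param path CSV path.
#' @return an \code{ms_findings} data frame.
#' @export
read_findings <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  if (!nrow(d)) return(empty_findings())
  rows <- lapply(seq_len(nrow(d)), function(i) {
    validate_finding(d$map_label[i], d$contrast[i], d$effect[i],
                     study_id = d$study_id[i])
  })
  sort_findings(do.call(rbind, rows))
}

#' @export
print.ms_findings <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("Findings table:", nrow(x), "row(s)",
      if (!is.null(prov)) paste0("(", prov, ")"), "\n")
  if (nrow(x)) {
    show <- data.frame(label = paste0(x$study_id, "_", x$map_label),
                       contrast = x$contrast,
                       effect = effect_string(x$direction, x$parameter,
                                              x$parameter_detail))
    print.data.frame(utils::head(show, 20L))
    if (nrow(x) > 20L) cat("...\n")
  }
  invisible(x)
}
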