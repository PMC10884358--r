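#' Electrode montage
#'
#' An electrode montage is the set of channel labels and 3-D head-centered
#' Cartesian electrode positions of a recording setup.  Positions may be in
#' arbitrary length units; all scalp-map operations that need a sphere
#' project each electrode onto the unit sphere by dividing by its own norm.
#'
#' Invariants enforced here: at least 8 channels, labels unique
#' (case-insensitively), every position of nonzero length, and no two
#' electrodes whose unit-sphere projections coincide within an angular
#' tolerance of 1e-6 rad.
#'
#' @param labels character vector of channel names.
#' @param positions numeric matrix with one row per channel and columns
#'   x, y, z (head-centered Cartesian).
#' @return an object of class \code{ms_montage} with fields \code{labels},
#'   \code{positions} and \code{n_channels}.
#' @seealso [read_montage()], [montage_1020()]
#' @export
#' @examples
#' m <- montage_1020()
#' m$n_channels
ms_montage <- function(labels, positions) {
  labels <- as.character(labels)
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  n <- length(labels)
  if (n < 8L)
    stop_ms("montage must have at least 8 channels, got ", n)
  if (ncol(positions) != 3L || nrow(positions) != n)
    stop_ms("positions must be a ", n, " x 3 matrix")
  if (!all(is.finite(positions)))
    stop_ms("montage positions must be finite")
  if (anyDuplicated(tolower(labels)))
    stop_ms("duplicate channel labels (case-insensitive): ",
            paste(unique(labels[duplicated(tolower(labels))]), collapse = ", "))
  nrm <- sqrt(rowSums(positions^2))
  if (any(nrm <= 0))
    stop_ms("electrode position(s) with zero length: ",
            paste(labels[nrm <= 0], collapse = ", "))
  ## coincident projections would make the spherical-spline system singular
  p <- positions / nrm
  cosang <- tcrossprod(p)
  cosang <- clamp1(cosang)
  ang <- acos(cosang)
  diag(ang) <- Inf
  if (any(ang < 1e-6)) {
    bad <- which(ang < 1e-6, arr.ind = TRUE)[1L, ]
    stop_ms("coincident electrode projections: ",
            labels[bad[1L]], " and ", labels[bad[2L]])
  }
  rownames(positions) <- labels
  colnames(positions) <- c("x", "y", "z")
  structure(list(labels = labels, positions = positions, n_channels = n),
            class = "ms_montage")
}

#' @export
print.ms_montage <- function(x, ...) {
  cat("EEG montage:", x$n_channels, "channels\n")
  cat("  ", paste(utils::head(x$labels, 10L), collapse = " "),
      if (x$n_channels > 10L) "..." else "", "\n")
  invisible(x)
}

## Unit-sphere projection of the electrode positions.
projected_positions <- function(montage) {
  p <- montage$positions
  p / sqrt(rowSums(p^2))
}

#' Test whether two montages are the same electrode set
#'
#' Montages are considered equal when they have the same labels (in order,
#' case-insensitively) and positions agreeing within \code{tol}.
#'
#' @param a,b \code{ms_montage} objects.
#' @param tol numeric tolerance on positions.
#' @return logical.
#' @export
montage_equal <- function(a, b, tol = 1e-9) {
  a$n_channels == b$n_channels &&
    all(tolower(a$labels) == tolower(b$labels)) &&
    max(abs(a$positions - b$positions)) <= tol
}

## Stable cache key for a montage (used to memoise spline operators).
montage_key <- function(montage) {
  paste(c(tolower(montage$labels), signif(as.vector(montage$positions), 12)),
        collapse = "|")
}

#' Read an electrode montage file
#'
#' Supports the whitespace-delimited \code{.sfp} dialect (one electrode per
#' line, \code{label x y z}, comment lines starting with \code{#}) and a
#' headered CSV with columns \code{label,x,y,z}.  Coordinates are retained
#' unscaled; projection to the unit sphere happens inside the spline code.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"sfp"} or \code{"csv"}.
#' @return an [ms_montage()].
#' @export
read_montage <- function(path, format = c("auto", "sfp", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "sfp"
  }
  if (format == "csv") {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("label", "x", "y", "z")
    if (!all(need %in% names(d)))
      stop_ms("montage CSV must have columns label,x,y,z: ", path)
    return(ms_montage(d$label, as.matrix(d[, c("x", "y", "z")])))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop_ms("empty montage file: ", path)
  parts <- strsplit(lines, "[[:space:],]+")
  bad <- vapply(parts, length, 1L) != 4L
  if (any(bad))
    stop_ms("unparsable montage row(s) in ", path, ": ",
            paste(utils::head(lines[bad], 3L), collapse = " | "))
  labels <- vapply(parts, `[[`, "", 1L)
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3L)))
  if (!all(is.finite(xyz)))
    stop_ms("non-numeric coordinates in montage file: ", path)
  ms_montage(labels, xyz)
}

#' Write a montage to an .sfp or CSV file
#'
#' @param montage an [ms_montage()].
#' @param path output path; extension \code{.csv} selects the CSV dialect.
#' @return \code{path}, invisibly.
#' @export
write_montage <- function(montage, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    d <- data.frame(label = montage$labels,
                    x = montage$positions[, 1L],
                    y = montage$positions[, 2L],
                    z = montage$positions[, 3L])
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  } else {
    writeLines(sprintf("%s\t%.12g\t%.12g\t%.12g", montage$labels,
                       montage$positions[, 1L], montage$positions[, 2L],
                       montage$positions[, 3L]), path)
  }
  invisible(path)
}
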