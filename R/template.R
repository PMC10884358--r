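#' Canonicalize a scalp map
#'
#' Brings a per-channel potential vector into the canonical form used for
#' all topographic comparisons: average reference (subtract the mean over
#' all channels) followed by scaling to unit L2 norm.  Since GFP and vector
#' norm differ only by a fixed factor of \eqn{\sqrt{n}} per montage, unit
#' norm is equivalent to a montage-wide common GFP; every similarity
#' measure in this package is invariant to that choice.
#'
#' Canonicalization is idempotent and invariant to positive rescaling;
#' negating the input negates the output (polarity is preserved here and
#' handled by the polarity-invariant similarity measures instead).
#'
#' @param values numeric vector of per-channel potentials (length >= 8).
#' @return a numeric vector with zero mean and unit L2 norm.
#' @export
#' @examples
#' v <- canonicalize_map(c(2, 0, 0, -2, 0, 0, 0, 0))
#' c(mean(v), sqrt(sum(v^2)))
canonicalize_map <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 8L)
    stop_ms("a scalp map needs at least 8 channels, got ", length(values))
  if (!all(is.finite(values)))
    stop_ms("scalp map contains non-finite values")
  v <- values - mean(values)
  nrm <- sqrt(sum(v^2))
  if (nrm <= 1e-12 * max(1, max(abs(values))))
    stop_ms("degenerate map: constant across channels (zero after average reference)")
  v / nrm
}

## TRUE when v is already average-referenced and unit-norm within tol.
is_canonical_map <- function(v, tol = 1e-8) {
  v <- as.numeric(v)
  all(is.finite(v)) &&
    abs(mean(v)) <= tol &&
    abs(sqrt(sum(v^2)) - 1) <= tol
}

## Canonicalize the columns of a channels x maps matrix, with map labels in
## error messages.  Returns the matrix; attribute "input_was_canonical"
## records per column whether the input already was in canonical form.
canonicalize_columns <- function(m, labels = colnames(m), context = NULL) {
  m <- as.matrix(m)
  flags <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    flags[j] <- is_canonical_map(m[, j])
    m[, j] <- tryCatch(canonicalize_map(m[, j]), error = function(e) {
      stop_ms(if (!is.null(context)) paste0(context, ", ") else "",
              "map '", labels[j] %||% j, "': ", conditionMessage(e))
    })
  }
  attr(m, "input_was_canonical") <- flags
  m
}
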