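## Backfitting meta-maps to study template maps and to continuous EEG,
## and commonality-of-assignment matrices across cluster numbers.

#' Continuous EEG recording
#'
#' @param data channels x samples numeric matrix of potentials (uV).
#' @param montage an [ms_montage()] matching the rows of \code{data}.
#' @param sampling_rate sampling rate in Hz.
#' @return an object of class \code{ms_eeg}.  Data are average-referenced
#'   per sample on construction; whether re-referencing actually changed
#'   the data is recorded in the \code{rereferenced} field.
#' @export
ms_eeg <- function(data, montage, sampling_rate) {
  stopifnot(inherits(montage, "ms_montage"))
  data <- as.matrix(data)
  if (nrow(data) != montage$n_channels)
    stop_ms("EEG has ", nrow(data), " channels but montage has ",
            montage$n_channels)
  if (ncol(data) < 1L) stop_ms("EEG must have at least one sample")
  if (!all(is.finite(data))) stop_ms("EEG contains non-finite values")
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop_ms("sampling_rate must be positive")
  mu <- colMeans(data)
  rereferenced <- max(abs(mu)) > 1e-12 * max(1, max(abs(data)))
  data <- sweep(data, 2L, mu)
  dimnames(data) <- list(montage$labels, NULL)
  structure(list(data = data, montage = montage,
                 sampling_rate = sampling_rate,
                 rereferenced = rereferenced),
            class = "ms_eeg")
}

#' @export
print.ms_eeg <- function(x, ...) {
  cat("EEG recording:", nrow(x$data), "channels x", ncol(x$data),
      "samples @", x$sampling_rate, "Hz",
      if (x$rereferenced) "(average-referenced on load)" else "", "\n")
  invisible(x)
}

#' Read / write continuous EEG as CSV
#'
#' The CSV layout is rows = samples, columns = channels with a header of
#' channel labels.  On read, columns are matched (case-insensitively) and
#' reordered to the montage.
#'
#' @param path CSV path.
#' @param montage an [ms_montage()].
#' @param sampling_rate sampling rate in Hz.
#' @param eeg an [ms_eeg()].
#' @return \code{read_eeg} returns an \code{ms_eeg}; \code{write_eeg}
#'   returns \code{path} invisibly.
#' @export
read_eeg <- function(path, montage, sampling_rate) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  hit <- match(tolower(montage$labels), tolower(names(d)))
  if (anyNA(hit))
    stop_ms("EEG file ", path, " is missing channel(s): ",
            paste(montage$labels[is.na(hit)], collapse = ", "))
  ms_eeg(t(as.matrix(d[, hit, drop = FALSE])), montage, sampling_rate)
}

#' @rdname read_eeg
#' @export
write_eeg <- function(eeg, path) {
  stopifnot(inherits(eeg, "ms_eeg"))
  d <- as.data.frame(t(eeg$data))
  names(d) <- eeg$montage$labels
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Backfit meta-maps to study template maps
#'
#' Resamples every study map onto the solution's common montage and
#' assigns it to the meta-map with the largest shared variance (ties to
#' the lowest class index).  Assignment is polarity-invariant.
#'
#' @param solution an \code{ms_metasolution}.
#' @param atlas an [ms_atlas()].
#' @param config a [spline_config()].
#' @return a data frame with columns \code{study_id}, \code{map_label},
#'   \code{class} (winning meta-class) and \code{sv} (shared variance to
#'   the winning meta-map, percent).
#' @export
backfit_maps <- function(solution, atlas, config = spline_config()) {
  stopifnot(inherits(solution, "ms_metasolution"),
            inherits(atlas, "ms_atlas"))
  prep <- prepare_items(atlas, solution$montage, config)
  sv <- 100 * crossprod(prep$items, solution$maps)^2  # n x K
  cls <- max.col(sv, ties.method = "first")
  data.frame(study_id = prep$index$study_id,
             map_label = prep$index$map_label,
             class = cls,
             sv = sv[cbind(seq_len(nrow(sv)), cls)],
             stringsAsFactors = FALSE)
}

#' Backfit meta-maps to continuous EEG
#'
#' Assigns every sample t the class
#' \eqn{a_t = \arg\max_k (\hat x_t^T t_k)^2} where \eqn{\hat x_t} is the
#' canonicalized (average-referenced, unit-norm) sample — i.e. the
#' polarity-invariant best-correlating meta-map, ties to the lowest class.
#' All samples are labeled; there is no temporal smoothing or GFP-peak
#' restriction by default.  Optional flags add a minimum-GFP exclusion
#' (excluded samples inherit the previous label) and a majority-vote
#' smoothing of the label series, both off by default.  A zero-variance
#' sample is assigned the previous sample's label (class 1 if first) and
#' counted in the degenerate-sample tally.
#'
#' @param solution an \code{ms_metasolution}.
#' @param eeg an [ms_eeg()] on the solution's montage, or any montage if
#'   \code{operator} is supplied.
#' @param operator optional [spline_operator()] from the EEG montage to
#'   the solution montage.
#' @param min_gfp optional minimum GFP (uV); samples below it are treated
#'   like degenerate samples.  Default \code{0} (all samples assigned).
#' @param smooth_window optional odd window length for majority-vote label
#'   smoothing; default \code{0} (off).
#' @return an object of class \code{ms_assignments}: \code{K},
#'   \code{labels} (per-sample class), \code{n_samples},
#'   \code{degenerate_samples}, \code{sampling_rate}.
#' @export
backfit_eeg <- function(solution, eeg, operator = NULL, min_gfp = 0,
                        smooth_window = 0L) {
  stopifnot(inherits(solution, "ms_metasolution"), inherits(eeg, "ms_eeg"))
  X <- eeg$data
  if (!montage_equal(eeg$montage, solution$montage)) {
    if (is.null(operator))
      stop_ms("EEG montage differs from the solution's montage; ",
              "supply a spline operator")
    if (!montage_equal(operator$source, eeg$montage) ||
        !montage_equal(operator$target, solution$montage))
      stop_ms("operator does not map the EEG montage onto the solution montage")
    X <- operator$transfer %*% X
  }
  n <- nrow(X)
  T_ <- ncol(X)
  X <- sweep(X, 2L, colMeans(X))
  nrm <- sqrt(colSums(X^2))
  sample_gfp <- nrm / sqrt(n)
  scale_ref <- max(1, max(abs(X)))
  bad <- nrm <= 1e-12 * scale_ref | sample_gfp < min_gfp
  ok <- !bad
  labels <- integer(T_)
  if (any(ok)) {
    A2 <- crossprod(solution$maps, sweep(X[, ok, drop = FALSE], 2L,
                                         nrm[ok], "/"))^2  # K x T_ok
    labels[ok] <- max.col(t(A2), ties.method = "first")
  }
  if (any(bad)) {
    for (t in which(bad)) labels[t] <- if (t == 1L) 1L else labels[t - 1L]
    ## a leading run of bad samples stays class 1; propagate forward once
    for (t in seq_len(T_)[-1L]) if (bad[t]) labels[t] <- labels[t - 1L]
  }
  if (smooth_window >= 3L) {
    if (smooth_window %% 2L == 0L) stop_ms("smooth_window must be odd")
    half <- smooth_window %/% 2L
    sm <- labels
    for (t in seq_len(T_)) {
      lo <- max(1L, t - half)
      hi <- min(T_, t + half)
      tab <- tabulate(labels[lo:hi], solution$K)
      sm[t] <- which.max(tab)
    }
    labels <- sm
  }
  structure(list(K = solution$K, labels = labels, n_samples = T_,
                 degenerate_samples = sum(nrm <= 1e-12 * scale_ref),
                 sampling_rate = eeg$sampling_rate),
            class = "ms_assignments")
}

#' @export
print.ms_assignments <- function(x, ...) {
  cat("Microstate assignment series: ", x$n_samples, " samples, K = ",
      x$K, "; class coverage (%): ",
      paste(round(100 * tabulate(x$labels, x$K) / x$n_samples, 1),
            collapse = " "), "\n", sep = "")
  if (x$degenerate_samples > 0)
    cat("  degenerate (zero-variance) samples:", x$degenerate_samples, "\n")
  invisible(x)
}

#' Read / write an assignment series as CSV
#'
#' Columns: \code{sample}, \code{class}, \code{k} (number of classes,
#' repeated), \code{sampling_rate} (repeated).
#'
#' @param a an \code{ms_assignments}.
#' @param path CSV path.
#' @return \code{read_assignments} returns an \code{ms_assignments};
#'   \code{write_assignments} returns \code{path} invisibly.
#' @export
write_assignments <- function(a, path) {
  stopifnot(inherits(a, "ms_assignments"))
  utils::write.csv(data.frame(sample = seq_len(a$n_samples),
                              class = a$labels, k = a$K,
                              sampling_rate = a$sampling_rate),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  d <- utils::read.csv(path)
  structure(list(K = as.integer(d$k[1L]), labels = as.integer(d$class),
                 n_samples = nrow(d), degenerate_samples = 0L,
                 sampling_rate = as.numeric(d$sampling_rate[1L])),
            class = "ms_assignments")
}

#' Commonality of assignment between two cluster numbers
#'
#' Cross-tabulates two per-sample assignment series of the same recording
#' and column-normalizes within the first (from) solution's classes:
#' \deqn{C[j, k] = 100 \cdot \#\{t: a_t = k \wedge b_t = j\} /
#'   \#\{t: a_t = k\}} so that every column over a non-empty source class
#' sums to exactly 100 percent.  Columns over empty source classes are
#' zero and flagged.
#'
#' @param a assignment series of the "from" solution (columns).
#' @param b assignment series of the "to" solution (rows).
#' @return an object of class \code{ms_commonality}: \code{K_from},
#'   \code{K_to}, \code{values} (K_to x K_from percent matrix),
#'   \code{empty_from_classes}.
#' @export
commonality <- function(a, b) {
  stopifnot(inherits(a, "ms_assignments"), inherits(b, "ms_assignments"))
  if (a$n_samples != b$n_samples)
    stop_ms("assignment series have different lengths (", a$n_samples,
            " vs ", b$n_samples, ")")
  counts <- table(factor(b$labels, levels = seq_len(b$K)),
                  factor(a$labels, levels = seq_len(a$K)))
  counts <- matrix(as.numeric(counts), b$K, a$K)
  colsum <- colSums(counts)
  empty <- which(colsum == 0)
  C <- counts
  nz <- colsum > 0
  C[, nz] <- 100 * sweep(counts[, nz, drop = FALSE], 2L, colsum[nz], "/")
  C[, !nz] <- 0
  dimnames(C) <- list(paste0("to", seq_len(b$K)),
                      paste0("from", seq_len(a$K)))
  structure(list(K_from = a$K, K_to = b$K, values = C,
                 empty_from_classes = empty),
            class = "ms_commonality")
}

#' @export
print.ms_commonality <- function(x, ...) {
  cat("Commonality of assignment: K =", x$K_from, "->", x$K_to,
      "(percent per source-class column)\n")
  print(round(x$values, 1))
  if (length(x$empty_from_classes))
    cat("  empty source class(es):",
        paste(x$empty_from_classes, collapse = ", "), "\n")
  invisible(x)
}
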