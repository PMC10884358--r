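## Polarity-invariant topographic similarity across studies, global map
## dissimilarity, and classical multidimensional scaling.

#' Spatial correlation and shared variance between two maps
#'
#' For canonical maps (average-referenced, unit norm) the spatial
#' correlation is simply the dot product over channels, identical to the
#' Pearson correlation of the two maps.  Shared variance is
#' \eqn{100 r^2} percent, which is invariant to map polarity and scaling
#' and is the similarity measure used throughout.
#'
#' Both maps must live on the same montage; cross-montage comparisons must
#' resample first (see [similarity_matrix()], which always resamples the
#' map from the larger montage onto the smaller one).
#'
#' @param u,v numeric per-channel vectors of equal length (canonicalized
#'   internally if needed).
#' @return \code{spatial_correlation}: r in [-1, 1];
#'   \code{shared_variance}: percent in [0, 100].
#' @export
#' @examples
#' u <- canonicalize_map(c(1, -1, 1, -1, 0, 0, 0, 0))
#' shared_variance(u, -u)
spatial_correlation <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v))
    stop_ms("montage mismatch: maps have ", length(u), " and ", length(v),
            " channels")
  r <- sum(canonicalize_map(u) * canonicalize_map(v))
  min(1, max(-1, r))
}

#' @rdname spatial_correlation
#' @export
shared_variance <- function(u, v) 100 * spatial_correlation(u, v)^2

#' Global map dissimilarity
#'
#' The polarity-invariant global map dissimilarity
#' \eqn{d = \sqrt{2 (1 - |r|)}}: the L2 distance between the two canonical
#' maps after choosing the polarity that minimizes it, i.e.
#' \eqn{\min(\|u - v\|_2, \|u + v\|_2)}.  It is monotone decreasing in
#' shared variance via \eqn{d = \sqrt{2 (1 - \sqrt{SV/100})}}.  The signed
#' variant \eqn{\sqrt{2 (1 - r)}} is available for workflows where map
#' polarity is meaningful.
#'
#' @inheritParams spatial_correlation
#' @param polarity \code{"invariant"} (default) uses |r|; \code{"signed"}
#'   uses r.
#' @return a non-negative distance (0 for identical maps, \eqn{\sqrt 2}
#'   for orthogonal ones, 2 for signed opposite maps).
#' @export
map_dissimilarity <- function(u, v, polarity = c("invariant", "signed")) {
  polarity <- match.arg(polarity)
  r <- spatial_correlation(u, v)
  if (polarity == "invariant") r <- abs(r)
  sqrt(max(0, 2 * (1 - r)))
}

#' Pairwise shared-variance matrix over all maps of selected studies
#'
#' Computes the shared variance (percent) between every pair of template
#' maps across all studies.  For a pair of studies with different
#' montages, the maps from the montage with more electrodes are
#' spline-resampled onto the montage with fewer electrodes before
#' comparison; when the counts are equal but the electrode sets differ,
#' the second study's maps are resampled onto the first study's montage.
#' Spline operators and resampled map sets are cached per montage pair.
#'
#' @param atlas an [ms_atlas()] (or list of [ms_study()]).
#' @param config a [spline_config()].
#' @return an object of class \code{ms_similarity} with fields
#'   \code{map_index} (data frame study_id, map_label) and \code{values}
#'   (symmetric matrix of percent, diagonal 100).
#' @export
similarity_matrix <- function(atlas, config = spline_config()) {
  if (!inherits(atlas, "ms_atlas")) atlas <- ms_atlas(atlas)
  studies <- atlas$studies
  ns <- length(studies)
  idx <- atlas_map_index(atlas)
  if (nrow(idx) < 2L)
    stop_ms("need at least 2 maps to build a similarity matrix")
  counts <- vapply(studies, function(s) ncol(s$maps), 1L)
  offset <- cumsum(c(0L, counts))
  S <- matrix(NA_real_, nrow(idx), nrow(idx))
  op_cache <- new.env(parent = emptyenv())
  maps_cache <- new.env(parent = emptyenv())

  resampled_maps <- function(si, target) {
    s <- studies[[si]]
    key <- paste0(si, "=>", montage_key(target))
    if (!is.null(maps_cache[[key]])) return(maps_cache[[key]])
    opkey <- paste0(montage_key(s$montage), "=>", montage_key(target))
    op <- op_cache[[opkey]]
    if (is.null(op)) {
      op <- spline_operator(s$montage, target, config)
      op_cache[[opkey]] <- op
    }
    m <- matrix(NA_real_, target$n_channels, ncol(s$maps))
    for (j in seq_len(ncol(s$maps))) {
      m[, j] <- tryCatch(resample_map(s$maps[, j], op), error = function(e) {
        stop_ms("degenerate map after resampling: study '", s$study_id,
                "', map '", colnames(s$maps)[j], "': ", conditionMessage(e))
      })
    }
    maps_cache[[key]] <- m
    m
  }

  for (i in seq_len(ns)) {
    for (j in i:ns) {
      mi <- studies[[i]]$montage
      mj <- studies[[j]]$montage
      if (montage_equal(mi, mj)) {
        A <- studies[[i]]$maps
        B <- studies[[j]]$maps
      } else if (mj$n_channels < mi$n_channels) {
        A <- resampled_maps(i, mj)
        B <- studies[[j]]$maps
      } else {
        ## fewer (or equal) channels in study i: resample j onto i
        A <- studies[[i]]$maps
        B <- resampled_maps(j, mi)
      }
      block <- 100 * crossprod(A, B)^2
      rows <- offset[i] + seq_len(counts[i])
      cols <- offset[j] + seq_len(counts[j])
      S[rows, cols] <- block
      S[cols, rows] <- t(block)
    }
  }
  S[] <- pmin(100, pmax(0, S))
  S <- (S + t(S)) / 2
  diag(S) <- 100
  dimnames(S) <- rep(list(paste0(idx$study_id, "_", idx$map_label)), 2L)
  structure(list(map_index = idx, values = S), class = "ms_similarity")
}

#' @export
print.ms_similarity <- function(x, ...) {
  cat("Shared-variance matrix:", nrow(x$values), "maps from",
      length(unique(x$map_index$study_id)), "studies\n")
  cat("  off-diagonal range: ",
      paste(round(range(x$values[upper.tri(x$values)]), 1), collapse = " - "),
      " %\n", sep = "")
  invisible(x)
}

#' Convert a shared-variance matrix to global map dissimilarities
#'
#' Applies \eqn{d = \sqrt{2 (1 - \sqrt{SV/100})}} elementwise (the
#' polarity-invariant global map dissimilarity), giving a symmetric
#' zero-diagonal distance matrix suitable for [mds_embed()].
#'
#' @param sim an \code{ms_similarity} (or plain percent matrix).
#' @return a distance matrix with the map index carried in
#'   attribute \code{map_index}.
#' @export
dissimilarity_matrix <- function(sim) {
  S <- if (inherits(sim, "ms_similarity")) sim$values else as.matrix(sim)
  D <- S
  D[] <- sqrt(pmax(0, 2 * (1 - sqrt(pmin(100, pmax(0, S)) / 100))))
  diag(D) <- 0
  if (inherits(sim, "ms_similarity"))
    attr(D, "map_index") <- sim$map_index
  D
}

#' Classical multidimensional scaling of a map dissimilarity matrix
#'
#' Torgerson scaling: square the distances, double-center
#' \eqn{B = -\tfrac12 C D^{(2)} C}, eigendecompose, and take the top
#' \code{dims} eigenvectors scaled by the square roots of their
#' eigenvalues.  Axes are ordered by eigenvalue and the sign of each axis
#' is fixed so that its largest-magnitude coordinate is positive, making
#' the embedding deterministic.  If fewer than \code{dims} eigenvalues are
#' positive the remaining axes are zero-padded with a warning.
#'
#' @param D symmetric, zero-diagonal dissimilarity matrix (e.g. from
#'   [dissimilarity_matrix()]).
#' @param dims 2 or 3.
#' @return an object of class \code{ms_mds} with fields
#'   \code{coordinates} (n x dims), \code{eigenvalues} (full spectrum of
#'   the double-centered matrix) and \code{map_index} (if present on D).
#' @export
mds_embed <- function(D, dims = 2L) {
  D <- as.matrix(D)
  if (!dims %in% c(2L, 3L)) stop_ms("dims must be 2 or 3")
  n <- nrow(D)
  if (n != ncol(D) || max(abs(D - t(D))) > 1e-8 || max(abs(diag(D))) > 1e-8)
    stop_ms("D must be a symmetric matrix with zero diagonal")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  npos <- sum(e$values > max(1e-12, 1e-9 * max(abs(e$values), 1)))
  if (npos < dims)
    warning("only ", npos, " positive eigenvalue(s); padding ",
            dims - npos, " axis/axes with zeros", call. = FALSE)
  X <- matrix(0, n, dims)
  for (k in seq_len(min(dims, npos))) {
    ax <- e$vectors[, k] * sqrt(e$values[k])
    i0 <- which.max(abs(ax))
    if (ax[i0] < 0) ax <- -ax
    X[, k] <- ax
  }
  colnames(X) <- paste0("dim", seq_len(dims))
  structure(list(coordinates = X, eigenvalues = e$values,
                 map_index = attr(D, "map_index")),
            class = "ms_mds")
}

#' @export
print.ms_mds <- function(x, ...) {
  cat("MDS embedding:", nrow(x$coordinates), "maps in",
      ncol(x$coordinates), "dimensions\n")
  ev <- x$eigenvalues
  cat("  leading eigenvalues:",
      paste(signif(utils::head(ev, 4L), 4), collapse = ", "), "\n")
  invisible(x)
}
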