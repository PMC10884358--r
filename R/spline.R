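## Spherical-spline interpolation of scalp maps between electrode
## montages (Perrin-style splines on the unit sphere).  Any cross-montage
## map comparison or clustering in this package goes through these
## operators.

#' Spherical-spline configuration
#'
#' @param m spline order (integer >= 2; 4 is the customary choice for
#'   scalp potentials).
#' @param n_terms truncation point N of the Legendre series; at m = 4 the
#'   tail beyond N = 50 contributes less than 1e-10.
#' @param ridge non-negative diagonal regularization added to the spline
#'   system; a tiny ridge guards against near-coincident electrodes.
#' @return an object of class \code{ms_spline_config}.
#' @export
spline_config <- function(m = 4L, n_terms = 50L, ridge = 1e-8) {
  if (!is_count(m, min = 2L)) stop_ms("spline order m must be an integer >= 2")
  if (!is_count(n_terms, min = 1L)) stop_ms("n_terms must be a positive integer")
  if (!is.finite(ridge) || ridge < 0) stop_ms("ridge must be non-negative")
  structure(list(m = as.integer(m), n_terms = as.integer(n_terms),
                 ridge = ridge),
            class = "ms_spline_config")
}

#' Spherical-spline kernel g
#'
#' Evaluates \deqn{g(x) = \frac{1}{4\pi} \sum_{n=1}^{N}
#'   \frac{2n+1}{n^m (n+1)^m} P_n(x)} with \eqn{P_n} the Legendre
#' polynomials, computed by the stable three-term recurrence.  \code{x} is
#' the cosine of the angle between two points on the unit sphere.
#'
#' @param cos_angle numeric vector/matrix with values in [-1, 1] (values
#'   within 1e-12 beyond that range are clamped).
#' @param config a [spline_config()].
#' @return kernel values with the shape of \code{cos_angle}.
#' @export
g_kernel <- function(cos_angle, config = spline_config()) {
  x <- cos_angle
  if (any(!is.finite(x)) || any(abs(x) > 1 + 1e-12))
    stop_ms("cos_angle must lie in [-1, 1]")
  dm <- dim(x)
  x <- pmin(1, pmax(-1, as.numeric(x)))
  N <- config$n_terms
  m <- config$m
  n <- seq_len(N)
  coef <- (2 * n + 1) / (n^m * (n + 1)^m)
  p_prev <- rep(1, length(x))   # P_0
  p_cur <- x                    # P_1
  acc <- coef[1L] * p_cur
  if (N >= 2L) {
    for (k in 2:N) {
      p_next <- ((2 * k - 1) * x * p_cur - (k - 1) * p_prev) / k
      acc <- acc + coef[k] * p_next
      p_prev <- p_cur
      p_cur <- p_next
    }
  }
  out <- acc / (4 * pi)
  dim(out) <- dm
  out
}

#' Build a spherical-spline interpolation operator between montages
#'
#' Fits, for source values \eqn{v}, the bordered spline system
#' \deqn{[G + \lambda I, 1; 1^T, 0] [c; c_0] = [v; 0]} on the unit-sphere
#' projections of the source electrodes and evaluates
#' \eqn{c_0 + \sum_i c_i g(\cos\angle(x, x_i))} at each target electrode.
#' Because both steps are linear in \eqn{v}, the whole interpolation is
#' precomposed into one target x source transfer matrix.  The operator
#' maps a constant source map to the same constant on the target montage.
#'
#' @param source,target [ms_montage()] objects.
#' @param config a [spline_config()].
#' @return an object of class \code{ms_spline_operator} with fields
#'   \code{source}, \code{target}, \code{config}, \code{transfer}.
#' @seealso [resample_map()], [resample_study()]
#' @export
spline_operator <- function(source, target, config = spline_config()) {
  stopifnot(inherits(source, "ms_montage"), inherits(target, "ms_montage"))
  ps <- projected_positions(source)
  pt <- projected_positions(target)
  ns <- nrow(ps)
  G <- g_kernel(clamp1(tcrossprod(ps)), config)
  A <- rbind(cbind(G + diag(config$ridge, ns), rep(1, ns)),
             c(rep(1, ns), 0))
  sol <- tryCatch(solve(A), error = function(e) {
    stop_ms("singular spherical-spline system (coincident source ",
            "electrodes?): ", conditionMessage(e))
  })
  Gt <- g_kernel(clamp1(tcrossprod(pt, ps)), config)
  transfer <- cbind(Gt, rep(1, nrow(pt))) %*% sol[, seq_len(ns), drop = FALSE]
  dimnames(transfer) <- list(target$labels, source$labels)
  structure(list(source = source, target = target, config = config,
                 transfer = transfer),
            class = "ms_spline_operator")
}

#' @export
print.ms_spline_operator <- function(x, ...) {
  cat("Spherical-spline operator:", x$source$n_channels, "->",
      x$target$n_channels, "channels (m =", x$config$m, ", N =",
      x$config$n_terms, ")\n")
  invisible(x)
}

#' Resample a scalp map onto another montage
#'
#' Applies a precomputed spline operator to a per-channel map.  By default
#' the interpolated map is canonicalized (average reference, unit norm),
#' which is what every cross-montage comparison in this package consumes;
#' \code{canonical = FALSE} returns the raw interpolated potentials (the
#' raw operation is exactly linear in the input).
#'
#' @param values numeric vector on the operator's source montage.
#' @param operator an [spline_operator()].
#' @param canonical canonicalize the result (default TRUE).
#' @return numeric vector on the target montage.
#' @export
resample_map <- function(values, operator, canonical = TRUE) {
  stopifnot(inherits(operator, "ms_spline_operator"))
  values <- as.numeric(values)
  if (length(values) != operator$source$n_channels)
    stop_ms("map has ", length(values), " channels but operator expects ",
            operator$source$n_channels)
  out <- as.numeric(operator$transfer %*% values)
  if (canonical) out <- canonicalize_map(out) else names(out) <- operator$target$labels
  out
}

#' Resample a whole study onto a target montage
#'
#' @param study an [ms_study()].
#' @param target target [ms_montage()].
#' @param config a [spline_config()].
#' @return an \code{ms_study} on \code{target} with all maps resampled and
#'   canonicalized; metadata, weight and findings carried over.
#' @export
resample_study <- function(study, target, config = spline_config()) {
  stopifnot(inherits(study, "ms_study"))
  if (montage_equal(study$montage, target)) return(study)
  op <- spline_operator(study$montage, target, config)
  maps <- apply(study$maps, 2L, resample_map, operator = op)
  colnames(maps) <- colnames(study$maps)
  ms_study(study$study_id, target, maps, study$n_subjects,
           metadata = study$metadata, findings = study$findings)
}
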