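## Seeded generators for montages, prototype topographies, noisy
## multi-study atlases and microstate-structured EEG.  These emulate the
## structure of a multi-study template-map collection and of resting-state
## EEG, giving every other module a download-free test surface.

#' Built-in 19-channel 10-20 montage
#'
#' An idealized spherical 10-20 layout on the unit sphere (x right,
#' y anterior, z superior): midline and circumferential electrodes are
#' placed at the standard 10/20 percent arc positions, and F3/F4, P3/P4 at
#' the geodesic midpoints of their neighboring standard positions.
#'
#' @return an [ms_montage()] with the 19 standard labels Fp1..O2.
#' @export
montage_1020 <- function() {
  pos <- function(incl_deg, az_deg) {
    a <- incl_deg * pi / 180
    b <- az_deg * pi / 180   # positive azimuth = toward the left ear
    c(-sin(a) * sin(b), sin(a) * cos(b), cos(a))
  }
  mid <- function(p, q) {
    s <- p + q
    s / sqrt(sum(s^2))
  }
  p <- list(
    Fp1 = pos(72, 18), Fp2 = pos(72, -18),
    F7 = pos(72, 54), F8 = pos(72, -54),
    T7 = pos(72, 90), T8 = pos(72, -90),
    P7 = pos(72, 126), P8 = pos(72, -126),
    O1 = pos(72, 162), O2 = pos(72, -162),
    Fz = pos(36, 0), Cz = pos(0, 0), Pz = pos(-36, 0),
    C3 = pos(36, 90), C4 = pos(36, -90))
  p$F3 <- mid(p$Fz, p$F7); p$F4 <- mid(p$Fz, p$F8)
  p$P3 <- mid(p$Pz, p$P7); p$P4 <- mid(p$Pz, p$P8)
  ord <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz",
           "C4", "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2")
  ms_montage(ord, do.call(rbind, p[ord]))
}

#' Simulate an electrode montage
#'
#' \code{n_channels = 19} returns the built-in 10-20 layout; any other
#' count places near-uniform points on the upper hemisphere of the unit
#' sphere (a Fibonacci lattice with a small seeded jitter) and verifies a
#' minimum pairwise angular separation of 5 degrees.
#'
#' @param n_channels number of electrodes (>= 8).
#' @param seed optional integer seed; \code{NULL} draws from the current
#'   RNG stream.
#' @return an [ms_montage()].
#' @export
sim_montage <- function(n_channels, seed = NULL) {
  if (!is_count(n_channels, min = 8L))
    stop_ms("n_channels must be an integer >= 8")
  if (n_channels == 19L) return(montage_1020())
  gen <- function() {
    i <- seq_len(n_channels)
    z <- (i - 0.5) / n_channels          # uniform in (0, 1): upper hemisphere
    r <- sqrt(pmax(0, 1 - z^2))
    phi <- i * (pi * (3 - sqrt(5)))      # golden angle
    p <- cbind(r * cos(phi), r * sin(phi), z)
    p <- p + matrix(stats::rnorm(3 * n_channels, sd = 0.01), ncol = 3L)
    p[, 3L] <- pmax(p[, 3L], 0.02)
    p <- p / sqrt(rowSums(p^2))
    m <- ms_montage(sprintf("E%02d", i), p)
    cosang <- clamp1(tcrossprod(p))
    ang <- acos(cosang)
    diag(ang) <- Inf
    if (min(ang) <= 5 * pi / 180)
      stop_ms("generated montage violates the 5-degree separation target")
    m
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

## Smooth basis fields on the unit sphere: low-order polynomial surrogates
## of real spherical harmonics, order 1..3.
.basis_fields <- list(
  list(order = 1, f = function(p) p[, 1L]),
  list(order = 1, f = function(p) p[, 2L]),
  list(order = 1, f = function(p) p[, 3L]),
  list(order = 2, f = function(p) p[, 1L] * p[, 2L]),
  list(order = 2, f = function(p) p[, 1L] * p[, 3L]),
  list(order = 2, f = function(p) p[, 2L] * p[, 3L]),
  list(order = 2, f = function(p) p[, 1L]^2 - p[, 2L]^2),
  list(order = 2, f = function(p) 3 * p[, 3L]^2 - 1),
  list(order = 3, f = function(p) p[, 1L] * p[, 2L] * p[, 3L]),
  list(order = 3, f = function(p) p[, 3L] * (p[, 1L]^2 - p[, 2L]^2)),
  list(order = 3, f = function(p) p[, 1L] * (4 * p[, 3L]^2 - p[, 1L]^2 - p[, 2L]^2)),
  list(order = 3, f = function(p) p[, 2L] * (4 * p[, 3L]^2 - p[, 1L]^2 - p[, 2L]^2)),
  list(order = 3, f = function(p) p[, 3L] * (2 * p[, 3L]^2 - 3 * p[, 1L]^2 - 3 * p[, 2L]^2))
)

## Evaluate one analytic field (coefficient vector) on a montage.
eval_field <- function(coef, montage) {
  p <- projected_positions(montage)
  vals <- vapply(seq_along(coef), function(i) {
    coef[i] * .basis_fields[[i]]$f(p)
  }, numeric(nrow(p)))
  canonicalize_map(rowSums(vals))
}

#' Simulate prototype topographies
#'
#' Draws K smooth scalp fields as random combinations of low-order
#' polynomial basis fields on the sphere (order limited by
#' \code{smoothness}), canonicalizes them on \code{montage}, and accepts
#' candidates sequentially so that all pairwise shared variances stay
#' below 25 percent.  Because acceptance is sequential, calling with the
#' same seed and a larger K extends the set: the first K prototypes of a
#' (K+1)-prototype call equal the K-prototype call's (the nested
#' construction used in the commonality experiments).
#'
#' @param K number of prototypes (>= 1).
#' @param montage [ms_montage()] on which decorrelation is measured.
#' @param smoothness highest basis order used (1..3; default 2).
#' @param seed optional integer seed.
#' @param max_draws candidate budget before giving up (default 1000).
#' @return an object of class \code{ms_prototypes}: \code{maps}
#'   (channels x K canonical matrix), \code{fields} (list of coefficient
#'   vectors, evaluable on any montage via [prototype_maps()]),
#'   \code{montage}, \code{seed}.
#' @export
sim_prototypes <- function(K, montage = montage_1020(), smoothness = 2L,
                           seed = NULL, max_draws = 1000L) {
  if (!is_count(K)) stop_ms("K must be a positive integer")
  if (!smoothness %in% 1:3) stop_ms("smoothness must be 1, 2 or 3")
  nb <- sum(vapply(.basis_fields, `[[`, 0, "order") <= smoothness)
  orders <- vapply(.basis_fields[seq_len(nb)], `[[`, 0, "order")
  gen <- function() {
    fields <- list()
    maps <- matrix(NA_real_, montage$n_channels, 0L)
    draws <- 0L
    while (length(fields) < K) {
      draws <- draws + 1L
      if (draws > max_draws)
        stop_ms("could not decorrelate ", K, " prototypes below 25% ",
                "shared variance in ", max_draws, " draws")
      coef <- stats::rnorm(nb) / orders
      v <- eval_field(coef, montage)
      if (ncol(maps) == 0L || max(100 * as.numeric(crossprod(maps, v))^2) < 25) {
        fields[[length(fields) + 1L]] <- coef
        maps <- cbind(maps, v)
      }
    }
    colnames(maps) <- paste0("P", seq_len(K))
    rownames(maps) <- montage$labels
    list(maps = maps, fields = fields)
  }
  out <- if (is.null(seed)) gen() else with_seed(seed, gen())
  structure(list(maps = out$maps, fields = out$fields, montage = montage,
                 seed = seed),
            class = "ms_prototypes")
}

#' Evaluate prototype fields on a montage
#'
#' @param prototypes an \code{ms_prototypes} from [sim_prototypes()].
#' @param montage target [ms_montage()].
#' @return channels x K matrix of canonical maps.
#' @export
prototype_maps <- function(prototypes, montage) {
  stopifnot(inherits(prototypes, "ms_prototypes"))
  maps <- vapply(prototypes$fields, eval_field,
                 numeric(montage$n_channels), montage = montage)
  colnames(maps) <- paste0("P", seq_along(prototypes$fields))
  rownames(maps) <- montage$labels
  maps
}

## Rotate a canonical map by angle theta toward a random direction that is
## orthogonal to it within the zero-mean subspace.
perturb_map <- function(v, theta) {
  if (theta == 0) return(v)
  g <- stats::rnorm(length(v))
  g <- g - mean(g)
  g <- g - sum(g * v) * v
  g <- g / sqrt(sum(g^2))
  canonicalize_map(cos(theta) * v + sin(theta) * g)
}

#' Simulate a multi-study atlas with ground truth
#'
#' Emulates a collection of study template sets: K prototypes are drawn
#' once as smooth analytic fields, evaluated on each study's montage, and
#' perturbed on the map hypersphere by a rotation of
#' \code{angular_noise_sd} radians toward a random orthogonal direction
#' (so the expected shared variance to the prototype is
#' \eqn{100\cos^2(\theta)}).  Study montages cycle through
#' \code{channels}; subject counts are drawn uniformly from
#' \code{subjects_range}.  The true class of every map is stored in the
#' study metadata (key \code{ground_truth_class}) and returned as the
#' \code{truth} attribute; the generating prototypes are returned as the
#' \code{prototypes} attribute.
#'
#' @param n_studies number of studies (default 20).
#' @param n_prototypes number of prototype classes K (default 5).
#' @param channels channel counts cycled over the studies
#'   (default \code{c(19, 32, 64)}).
#' @param angular_noise_sd per-map rotation angle in radians (default 0.3).
#' @param subjects_range inclusive range for n_subjects (default 10..50).
#' @param smoothness prototype smoothness order (default 2).
#' @param findings also attach simple synthetic findings (default TRUE).
#' @param seed optional integer seed.
#' @return an [ms_atlas()] with attributes \code{truth} (data frame
#'   study_id, map_label, class) and \code{prototypes}
#'   (\code{ms_prototypes}).
#' @export
sim_atlas <- function(n_studies = 20L, n_prototypes = 5L,
                      channels = c(19L, 32L, 64L), angular_noise_sd = 0.3,
                      subjects_range = c(10L, 50L), smoothness = 2L,
                      findings = TRUE, seed = NULL) {
  if (!is_count(n_studies)) stop_ms("n_studies must be >= 1")
  if (angular_noise_sd < 0) stop_ms("angular_noise_sd must be >= 0")
  gen <- function() {
    protos <- sim_prototypes(n_prototypes, montage_1020(),
                             smoothness = smoothness, seed = NULL)
    ch <- rep_len(as.integer(channels), n_studies)
    effects <- expand.grid(direction = c("More", "Less"),
                           parameter = c("Duration", "Occurrence",
                                         "Contribution", "GEV"),
                           stringsAsFactors = FALSE)
    studies <- vector("list", n_studies)
    for (s in seq_len(n_studies)) {
      mon <- sim_montage(ch[s], seed = NULL)
      base <- prototype_maps(protos, mon)
      maps <- vapply(seq_len(n_prototypes), function(k) {
        perturb_map(base[, k], angular_noise_sd)
      }, numeric(mon$n_channels))
      colnames(maps) <- LETTERS[seq_len(n_prototypes)]
      fnd <- NULL
      if (findings) {
        rows <- lapply(seq_len(n_prototypes), function(k) {
          if (stats::runif(1) < 0.5) {
            e <- effects[sample.int(nrow(effects), 1L), ]
            data.frame(map_label = LETTERS[k],
                       contrast = paste0("Synthetic condition ", k,
                                         " vs. rest"),
                       effect = paste(e$direction, e$parameter),
                       stringsAsFactors = FALSE)
          } else {
            data.frame(map_label = LETTERS[k], contrast = "",
                       effect = "No findings", stringsAsFactors = FALSE)
          }
        })
        fnd <- do.call(rbind, rows)
      }
      studies[[s]] <- ms_study(
        sprintf("Synthetic %03d", s), mon, maps,
        n_subjects = subjects_range[1L] +
          sample.int(subjects_range[2L] - subjects_range[1L] + 1L, 1L) - 1L,
        metadata = list(
          ground_truth_class = paste(seq_len(n_prototypes), collapse = ","),
          generator = "sim_atlas",
          seed = as.character(seed %||% "NULL")),
        findings = fnd)
    }
    list(studies = studies, prototypes = protos)
  }
  out <- if (is.null(seed)) gen() else with_seed(seed, gen())
  atlas <- ms_atlas(out$studies)
  truth <- atlas_map_index(atlas)
  truth$class <- rep(seq_len(n_prototypes), times = n_studies)
  attr(atlas, "truth") <- truth
  attr(atlas, "prototypes") <- out$prototypes
  atlas
}

#' Simulate microstate-structured EEG
#'
#' Generates a piecewise-constant state sequence with geometric run
#' lengths (mean \code{mean_state_duration_ms}; consecutive states always
#' differ, so empirical run lengths match the nominal mean), then for
#' every sample emits random polarity x random positive amplitude x the
#' state's prototype map, plus average-referenced spatial white noise
#' scaled so the ratio of map GFP to noise GFP equals \code{snr}.
#'
#' @param prototypes channels x K matrix of canonical maps, or an
#'   \code{ms_prototypes} (evaluated on \code{montage}).
#' @param montage [ms_montage()] of the recording.
#' @param duration_s recording length in seconds (default 10).
#' @param sampling_rate Hz (default 250).
#' @param mean_state_duration_ms mean microstate duration (default 80).
#' @param snr map-to-noise GFP ratio; \code{Inf} for noise-free.
#' @param amplitude_scale overall scale in uV (default 10).
#' @param seed optional integer seed.
#' @return a list with \code{eeg} (an [ms_eeg()]) and \code{labels} (the
#'   ground-truth \code{ms_assignments}).
#' @export
sim_eeg <- function(prototypes, montage = montage_1020(), duration_s = 10,
                    sampling_rate = 250, mean_state_duration_ms = 80,
                    snr = 4, amplitude_scale = 10, seed = NULL) {
  maps <- if (inherits(prototypes, "ms_prototypes")) {
    prototype_maps(prototypes, montage)
  } else {
    as.matrix(prototypes)
  }
  if (nrow(maps) != montage$n_channels)
    stop_ms("prototype maps do not match the montage")
  for (j in seq_len(ncol(maps))) maps[, j] <- canonicalize_map(maps[, j])
  K <- ncol(maps)
  n <- nrow(maps)
  T_ <- max(1L, round(duration_s * sampling_rate))
  mean_len <- mean_state_duration_ms / 1000 * sampling_rate
  if (mean_len < 1) stop_ms("mean state duration is below one sample")
  gen <- function() {
    labels <- integer(0L)
    cur <- 0L
    while (length(labels) < T_) {
      nxt <- if (K == 1L) 1L else sample(setdiff(seq_len(K), cur), 1L)
      len <- stats::rgeom(1L, prob = 1 / mean_len) + 1L
      labels <- c(labels, rep(nxt, len))
      cur <- nxt
    }
    labels <- labels[seq_len(T_)]
    amp <- abs(stats::rnorm(T_, mean = 1, sd = 0.2))
    amp <- pmax(amp, 0.1)
    sgn <- sample(c(-1, 1), T_, replace = TRUE)
    X <- maps[, labels, drop = FALSE] * rep(amp * sgn, each = n)
    if (is.finite(snr)) {
      Z <- matrix(stats::rnorm(n * T_), n, T_)
      Z <- sweep(Z, 2L, colMeans(Z))
      zg <- sqrt(colMeans(Z^2))
      ## per-sample noise GFP = (map GFP x amplitude) / snr
      mg <- apply(maps, 2L, gfp)[labels]
      Z <- sweep(Z, 2L, amp * mg / (snr * zg), "*")
      X <- X + Z
    }
    list(X = amplitude_scale * X, labels = labels)
  }
  out <- if (is.null(seed)) gen() else with_seed(seed, gen())
  eeg <- ms_eeg(out$X, montage, sampling_rate)
  truth <- structure(list(K = K, labels = out$labels, n_samples = T_,
                          degenerate_samples = 0L,
                          sampling_rate = sampling_rate),
                     class = "ms_assignments")
  list(eeg = eeg, labels = truth)
}
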