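## Across-study meta-microstate maps: subject-weighted, polarity-invariant
## modified k-means over all study template maps on a common montage.

#' Prepare clustering items from an atlas
#'
#' Resamples every study's template maps onto the common montage,
#' canonicalizes them, and attaches each study's subject count as the item
#' weight.
#'
#' @param atlas an [ms_atlas()].
#' @param montage common [ms_montage()] onto which all maps are
#'   interpolated ("a reasonably general electrode setup"); defaults to
#'   the built-in 19-channel 10-20 layout.
#' @param config a [spline_config()].
#' @return a list with \code{items} (channels x n matrix of canonical
#'   maps), \code{weights} (numeric, the owning study's n_subjects) and
#'   \code{index} (data frame study_id, map_label).
#' @export
prepare_items <- function(atlas, montage = montage_1020(),
                          config = spline_config()) {
  stopifnot(inherits(atlas, "ms_atlas"))
  rs <- lapply(atlas$studies, resample_study, target = montage,
               config = config)
  items <- do.call(cbind, lapply(rs, `[[`, "maps"))
  weights <- unlist(lapply(rs, function(s) rep(s$n_subjects, ncol(s$maps))),
                    use.names = FALSE)
  idx <- atlas_map_index(atlas)
  colnames(items) <- paste0(idx$study_id, "_", idx$map_label)
  list(items = items, weights = as.numeric(weights), index = idx)
}

## Dominant eigenvector of the weighted outer-product sum of a class,
## with the deterministic sign rule (largest-magnitude element positive).
dominant_map <- function(X, w) {
  S <- X %*% (w * t(X))
  v <- eigen(S, symmetric = TRUE)$vectors[, 1L]
  i0 <- which.max(abs(v))
  if (v[i0] < 0) v <- -v
  v
}

#' Modified k-means clustering of template maps
#'
#' Polarity-invariant k-means: items are assigned to the class whose map
#' has the largest squared correlation with them (ties to the lowest
#' class index), and each class map is updated as the dominant eigenvector
#' of the class's weighted outer-product sum
#' \eqn{S_k = \sum_{i: L_i = k} w_i x_i x_i^T}.  The objective is the
#' weighted explained variance
#' \eqn{\sum_i w_i (x_i^T t_{L_i})^2 / \sum_i w_i}; both steps are
#' non-decreasing in it, and iteration stops when assignments are
#' unchanged, the relative objective change falls below \code{tol}, or
#' \code{max_iter} is reached.  Each restart initializes the class maps
#' with K distinct items drawn without replacement; the best restart by
#' objective is returned.  A class emptied during iteration is reseeded
#' with the currently worst-fit item.
#'
#' @param items channels x n matrix of canonical maps (columns), or the
#'   list returned by [prepare_items()].
#' @param weights per-item positive weights (default all 1; for
#'   across-study clustering these are the studies' subject counts).
#' @param K number of classes (<= number of items).
#' @param restarts number of random restarts (>= 1).
#' @param seed optional integer; when given, results are reproducible and
#'   the caller's RNG state is left untouched.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter iteration cap per restart.
#' @param init optional integer vector of K distinct item indices used to
#'   initialize every restart (mainly for testing).
#' @return an object of class \code{ms_metasolution}: \code{K},
#'   \code{montage} (if items came from [prepare_items()]),
#'   \code{maps} (channels x K canonical meta-maps),
#'   \code{assignments} (per item class index), \code{objective},
#'   \code{seed}, \code{restarts}, \code{iterations}.
#' @export
modified_kmeans <- function(items, weights = NULL, K, restarts = 50L,
                            seed = NULL, tol = 1e-9, max_iter = 500L,
                            init = NULL) {
  montage <- NULL
  index <- NULL
  if (is.list(items) && !is.null(items$items)) {
    weights <- weights %||% items$weights
    index <- items$index
    items <- items$items
  }
  X <- as.matrix(items)
  n <- ncol(X)
  if (!is_count(K) || K > n)
    stop_ms("K must be a positive integer <= number of items (", n, ")")
  if (!is_count(restarts)) stop_ms("restarts must be >= 1")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(!is.finite(w)) || any(w <= 0))
    stop_ms("weights must be ", n, " positive numbers")
  for (j in seq_len(n)) X[, j] <- canonicalize_map(X[, j])
  if (!is.null(init)) {
    init <- as.integer(init)
    if (length(init) != K || anyDuplicated(init) || any(init < 1 | init > n))
      stop_ms("init must be K distinct item indices")
  }

  run_once <- function() {
    sel <- if (is.null(init)) sample.int(n, K) else init
    Tm <- X[, sel, drop = FALSE]
    L <- integer(n)
    obj <- -Inf
    for (it in seq_len(max_iter)) {
      A2 <- crossprod(X, Tm)^2              # n x K squared correlations
      Lnew <- max.col(A2, ties.method = "first")
      ## reseed any emptied class with the currently worst-fit item that
      ## is not the sole member of its own class
      for (k in seq_len(K)) {
        if (!any(Lnew == k)) {
          fit <- A2[cbind(seq_len(n), Lnew)]
          sizes <- tabulate(Lnew, K)
          movable <- which(sizes[Lnew] > 1L)
          worst <- movable[which.min(fit[movable])]
          Lnew[worst] <- k
        }
      }
      for (k in seq_len(K)) {
        sel_k <- Lnew == k
        Tm[, k] <- dominant_map(X[, sel_k, drop = FALSE], w[sel_k])
      }
      fit <- crossprod(X, Tm)^2
      obj_new <- sum(w * fit[cbind(seq_len(n), Lnew)]) / sum(w)
      done <- (it > 1L && identical(Lnew, L)) ||
        abs(obj_new - obj) <= tol * max(obj, .Machine$double.eps)
      L <- Lnew
      obj <- obj_new
      if (done) break
    }
    list(maps = Tm, assignments = L, objective = obj, iterations = it)
  }

  run_all <- function() {
    best <- NULL
    for (r in seq_len(restarts)) {
      cand <- run_once()
      if (is.null(best) || cand$objective > best$objective) best <- cand
    }
    best
  }
  best <- if (is.null(seed)) run_all() else with_seed(seed, run_all())

  colnames(best$maps) <- paste0("M", seq_len(K))
  structure(list(K = as.integer(K), montage = montage, maps = best$maps,
                 assignments = best$assignments, objective = best$objective,
                 weights = w, index = index, seed = seed,
                 restarts = as.integer(restarts),
                 iterations = best$iterations),
            class = "ms_metasolution")
}

#' Wrap a fixed set of template maps as a meta-map solution
#'
#' Useful for backfitting an externally given template set (e.g. a
#' normative reference or synthetic prototypes) with [backfit_maps()] /
#' [backfit_eeg()].
#'
#' @param maps channels x K matrix of maps (canonicalized internally).
#' @param montage the [ms_montage()] the maps live on.
#' @return an \code{ms_metasolution} with no item assignments.
#' @export
as_metasolution <- function(maps, montage) {
  stopifnot(inherits(montage, "ms_montage"))
  maps <- as.matrix(maps)
  if (nrow(maps) != montage$n_channels)
    stop_ms("maps have ", nrow(maps), " channels but montage has ",
            montage$n_channels)
  maps <- canonicalize_columns(maps)
  attr(maps, "input_was_canonical") <- NULL
  if (is.null(colnames(maps))) colnames(maps) <- paste0("M", seq_len(ncol(maps)))
  structure(list(K = ncol(maps), montage = montage, maps = maps,
                 assignments = NULL, objective = NA_real_, weights = NULL,
                 index = NULL, seed = NULL, restarts = 0L, iterations = 0L),
            class = "ms_metasolution")
}

#' @export
print.ms_metasolution <- function(x, ...) {
  cat("Meta-microstate solution: K =", x$K, "classes")
  if (!is.na(x$objective))
    cat(", weighted explained variance =", round(x$objective, 4))
  cat("\n")
  if (!is.null(x$assignments))
    cat("  class sizes:", paste(tabulate(x$assignments, x$K), collapse = " "),
        "\n")
  invisible(x)
}

#' Meta-cluster an atlas over a range of cluster numbers
#'
#' Resamples all study maps to the common montage ([prepare_items()]),
#' runs the subject-weighted [modified_kmeans()] for every K in
#' \code{k_min..k_max} (default 4 to 7, the usual range in resting-state
#' microstate work), and aligns classes across the solutions
#' ([align_solutions()]).
#'
#' @inheritParams prepare_items
#' @param k_min,k_max inclusive cluster-number range.
#' @param restarts,seed,tol,max_iter passed to [modified_kmeans()]; the
#'   whole range shares one seeded RNG stream, so identical inputs and
#'   seed give identical results.
#' @param align align classes across K (default TRUE).
#' @param reference optional channels x R matrix of reference maps on the
#'   common montage used to order the smallest-K solution.
#' @return an object of class \code{ms_metaclusters}: \code{solutions}
#'   (named list, one \code{ms_metasolution} per K), \code{items},
#'   \code{weights}, \code{index}, \code{montage}, \code{alignment}.
#' @export
metacluster <- function(atlas, montage = montage_1020(), k_min = 4L,
                        k_max = 7L, restarts = 50L, seed = NULL,
                        config = spline_config(), tol = 1e-9,
                        max_iter = 500L, align = TRUE, reference = NULL) {
  if (!is_count(k_min) || !is_count(k_max) || k_max < k_min)
    stop_ms("need 1 <= k_min <= k_max")
  prep <- prepare_items(atlas, montage, config)
  if (k_max > ncol(prep$items))
    stop_ms("k_max = ", k_max, " exceeds the number of items (",
            ncol(prep$items), ")")
  run_all <- function() {
    lapply(seq(k_min, k_max), function(K) {
      sol <- modified_kmeans(prep$items, prep$weights, K = K,
                             restarts = restarts, seed = NULL, tol = tol,
                             max_iter = max_iter)
      sol$montage <- montage
      sol$index <- prep$index
      sol$seed <- seed
      sol
    })
  }
  sols <- if (is.null(seed)) run_all() else with_seed(seed, run_all())
  names(sols) <- as.character(seq(k_min, k_max))
  run <- structure(list(solutions = sols, items = prep$items,
                        weights = prep$weights, index = prep$index,
                        montage = montage, seed = seed, alignment = NULL),
                   class = "ms_metaclusters")
  if (align && length(sols) >= 1L)
    run <- align_solutions(run, reference = reference)
  run
}

#' @export
print.ms_metaclusters <- function(x, ...) {
  ks <- names(x$solutions)
  obj <- vapply(x$solutions, `[[`, 0, "objective")
  cat("Meta-microstate clustering over K =", paste(ks, collapse = ", "),
      "(", ncol(x$items), "maps from",
      length(unique(x$index$study_id)), "studies )\n")
  cat("  weighted explained variance:",
      paste(sprintf("K=%s: %.4f", ks, obj), collapse = "  "), "\n")
  invisible(x)
}

## Best injective assignment of the rows of an SV table to distinct
## columns, maximizing total SV; exhaustive over all injections (row count
## <= 7 in practice).  Returns the column index chosen for each row.
best_injection <- function(sv) {
  nr <- nrow(sv)
  nc <- ncol(sv)
  stopifnot(nr <= nc)
  best <- NULL
  best_total <- -Inf
  rec <- function(row, used, picks, total) {
    if (row > nr) {
      if (total > best_total) {
        best_total <<- total
        best <<- picks
      }
      return(invisible())
    }
    for (k in seq_len(nc)) {
      if (!used[k]) {
        used[k] <- TRUE
        rec(row + 1L, used, c(picks, k), total + sv[row, k])
        used[k] <- FALSE
      }
    }
  }
  rec(1L, logical(nc), integer(), 0)
  best
}

## Apply a class permutation to a solution (new order of old classes).
permute_solution <- function(sol, ord) {
  sol$maps <- sol$maps[, ord, drop = FALSE]
  colnames(sol$maps) <- paste0("M", seq_len(sol$K))
  if (!is.null(sol$assignments))
    sol$assignments <- match(sol$assignments, ord)
  sol
}

## Total assigned weight per class of a solution.
class_weights <- function(sol) {
  w <- sol$weights %||% rep(1, length(sol$assignments))
  vapply(seq_len(sol$K), function(k) sum(w[sol$assignments == k]), 0)
}

#' Align meta-map classes across cluster numbers
#'
#' Orders the classes of each solution so that corresponding topographies
#' line up across K: the smallest-K solution is ordered against a
#' user-supplied reference set if given (by maximum-total-SV matching),
#' otherwise by descending total assigned weight; each subsequent solution
#' is then reordered by the optimal one-to-one matching (maximum total
#' shared variance, found by exhaustive search over injections) against
#' the previous solution, with unmatched classes appended last by
#' descending assigned weight.  A manual permutation override per K is
#' accepted and recorded.
#'
#' @param run an \code{ms_metaclusters} from [metacluster()].
#' @param reference optional channels x R matrix (R >= smallest K) of
#'   reference maps on the common montage.
#' @param override optional named list mapping K (as character) to a
#'   permutation of 1..K applied after automatic alignment.
#' @return the run with reordered solutions and an \code{alignment}
#'   record.
#' @export
align_solutions <- function(run, reference = NULL, override = NULL) {
  stopifnot(inherits(run, "ms_metaclusters"))
  ks <- as.integer(names(run$solutions))
  ord_k <- order(ks)
  sols <- run$solutions[ord_k]
  ks <- ks[ord_k]
  log <- list()

  ## order the base solution
  base <- sols[[1L]]
  if (!is.null(reference)) {
    ref <- as.matrix(reference)
    if (nrow(ref) != nrow(base$maps))
      stop_ms("reference maps must be on the common montage")
    for (j in seq_len(ncol(ref))) ref[, j] <- canonicalize_map(ref[, j])
    if (ncol(ref) < base$K)
      stop_ms("reference must contain at least ", base$K, " maps")
    sv <- 100 * (crossprod(base$maps, ref))^2    # K x R
    picks <- best_injection(sv)                  # ref column per base class
    ord <- order(picks)
    log$base <- list(method = "reference", order = ord)
  } else if (!is.null(base$assignments)) {
    ord <- order(class_weights(base), decreasing = TRUE)
    log$base <- list(method = "weight", order = ord)
  } else {
    ord <- seq_len(base$K)
    log$base <- list(method = "identity", order = ord)
  }
  sols[[1L]] <- permute_solution(base, ord)

  ## chain each next solution to the previous one
  if (length(sols) >= 2L) {
    for (i in 2:length(sols)) {
      prev <- sols[[i - 1L]]
      cur <- sols[[i]]
      sv <- 100 * (crossprod(prev$maps, cur$maps))^2  # Kprev x Kcur
      picks <- best_injection(sv)                     # cur class per prev class
      rest <- setdiff(seq_len(cur$K), picks)
      if (length(rest) > 1L && !is.null(cur$assignments)) {
        cw <- class_weights(cur)
        rest <- rest[order(cw[rest], decreasing = TRUE)]
      }
      ord <- c(picks, rest)
      sols[[i]] <- permute_solution(cur, ord)
      log[[paste0("K", cur$K)]] <- list(matched = picks, appended = rest,
                                        total_sv = sum(sv[cbind(seq_len(prev$K), picks)]))
    }
  }

  ## manual overrides
  if (!is.null(override)) {
    for (kname in names(override)) {
      perm <- as.integer(override[[kname]])
      pos <- match(kname, as.character(ks))
      if (is.na(pos))
        stop_ms("override names a K not in the run: ", kname)
      K <- sols[[pos]]$K
      if (length(perm) != K || !setequal(perm, seq_len(K)))
        stop_ms("override for K=", kname, " is not a permutation of 1..", K)
      sols[[pos]] <- permute_solution(sols[[pos]], perm)
      log[[paste0("override_K", kname)]] <- perm
    }
  }

  run$solutions <- sols
  names(run$solutions) <- as.character(ks)
  run$alignment <- log
  run
}

## ---- run (de)serialization for the CLI --------------------------------

#' Read / write a meta-clustering run as JSON
#'
#' Serializes the common montage, per-K meta-maps, assignments and
#' objectives; numeric values survive the round trip to within 1e-12.
#'
#' @param run an \code{ms_metaclusters}.
#' @param path file path.
#' @return \code{read_metaclusters} returns an \code{ms_metaclusters}
#'   (without the original item matrix); \code{write_metaclusters}
#'   returns \code{path} invisibly.
#' @export
write_metaclusters <- function(run, path) {
  stopifnot(inherits(run, "ms_metaclusters"))
  ub <- jsonlite::unbox
  doc <- list(
    montage = list(labels = run$montage$labels,
                   positions = unname(run$montage$positions)),
    index = list(study_id = run$index$study_id,
                 map_label = run$index$map_label),
    weights = run$weights,
    seed = if (is.null(run$seed)) NULL else ub(run$seed),
    solutions = lapply(run$solutions, function(s) {
      list(K = ub(s$K),
           objective = ub(s$objective),
           assignments = s$assignments,
           maps = lapply(seq_len(s$K), function(k) unname(s$maps[, k])))
    }))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_metaclusters
#' @export
read_metaclusters <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  montage <- ms_montage(unlist(doc$montage$labels),
                        do.call(rbind, lapply(doc$montage$positions, unlist)))
  idx <- data.frame(study_id = unlist(doc$index$study_id),
                    map_label = unlist(doc$index$map_label),
                    stringsAsFactors = FALSE)
  weights <- as.numeric(unlist(doc$weights))
  sols <- lapply(doc$solutions, function(s) {
    maps <- do.call(cbind, lapply(s$maps, unlist))
    colnames(maps) <- paste0("M", seq_len(ncol(maps)))
    rownames(maps) <- montage$labels
    structure(list(K = as.integer(s$K), montage = montage, maps = maps,
                   assignments = as.integer(unlist(s$assignments)),
                   objective = as.numeric(s$objective), weights = weights,
                   index = idx, seed = doc$seed, restarts = NA_integer_,
                   iterations = NA_integer_),
              class = "ms_metasolution")
  })
  names(sols) <- names(doc$solutions)
  structure(list(solutions = sols, items = NULL, weights = weights,
                 index = idx, montage = montage, seed = doc$seed,
                 alignment = NULL),
            class = "ms_metaclusters")
}
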