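# Phase 1: per-population multilocus ordering (open-path TSP over the
# recombination-fraction matrix), jackknife order stability, and
# skeleton-map filtering.

#' Order the markers of one dataset
#'
#' Finds a marker order minimizing the sum of adjacent recombination
#' fractions.  The exact solver is an open-path Held-Karp dynamic program
#' (feasible up to 16 markers); the heuristic is an evolution-strategy
#' search with 2-opt and Or-opt local search.  The returned order is
#' orientation-normalized: the first marker name sorts lexicographically
#' before the last.
#'
#' @param rf an `rf_matrix` (or plain symmetric matrix with dimnames).
#' @param solver `"heuristic"` or `"exact"`.
#' @param rng_seed integer seed for the heuristic.
#' @param iters,stall heuristic perturbation budget.
#' @param dataset_id carried into the result.
#' @return a `marker_map`.
#' @export
order_single <- function(rf, solver = c("heuristic", "exact"),
                         rng_seed = 1L, iters = 200L, stall = 60L,
                         dataset_id = NA_integer_) {
  solver <- match.arg(solver)
  d <- if (is.matrix(rf)) rf else rf$rf
  m <- nrow(d)
  if (solver == "exact") {
    if (m > 16) stop("exact solver limited to 16 markers; use the heuristic")
    idx <- cpp_held_karp(d)
  } else {
    idx <- cpp_tsp_heuristic(d, as.integer(iters), as.integer(stall),
                             as.integer(rng_seed))
  }
  ord <- rownames(d)[idx]
  ord <- normalize_orientation(ord)
  map_length(ord, if (is.matrix(rf)) rf else rf, dataset_id = dataset_id)
}

normalize_orientation <- function(ord) {
  if (length(ord) >= 2 && ord[1] > ord[length(ord)]) rev(ord) else ord
}

#' Jackknife stability of a marker order
#'
#' Repeatedly drops a fraction of the individuals, re-estimates the
#' recombination-fraction matrix, re-orders, and scores each marker by how
#' often its immediate neighborhood (both neighbors; the single neighbor
#' at map ends) is reproduced relative to the base order.
#'
#' @param dataset a [map_dataset()].
#' @param base_order the phase-1 order (character vector or `marker_map`).
#' @param n_replicates jackknife replicates (>= 1).
#' @param drop_fraction fraction of individuals removed per replicate,
#'   in (0, 1).
#' @param rng_seed integer seed.
#' @param iters heuristic budget per replicate.
#' @return object of class `"stability_report"`: per-marker neighborhood
#'   retention frequency, replicate count, drop fraction.
#' @export
jackknife_stability <- function(dataset, base_order, n_replicates = 100L,
                                drop_fraction = 0.2, rng_seed = 1L,
                                iters = 50L) {
  if (inherits(base_order, "marker_map")) base_order <- base_order$order
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (drop_fraction <= 0 || drop_fraction >= 1)
    stop("drop_fraction must be in (0,1)")
  set.seed(rng_seed)
  n <- dataset$n_ind
  keep_n <- max(2L, round((1 - drop_fraction) * n))
  succ <- setNames(numeric(length(base_order)), base_order)
  base_nbrs <- neighbor_sets(base_order)
  for (rep in seq_len(n_replicates)) {
    cols <- sample(n, keep_n)
    sub <- dataset
    sub$geno <- dataset$geno[, cols, drop = FALSE]
    sub$n_ind <- keep_n
    rfm <- suppressWarnings(build_rf_matrix(sub))
    ordmap <- order_single(rfm, "heuristic", rng_seed = rng_seed + rep,
                           iters = iters, stall = 25L)
    ord <- orient_to(ordmap$order, base_order)
    nb <- neighbor_sets(ord)
    for (mk in base_order) {
      if (!is.null(nb[[mk]]) && setequal(nb[[mk]], base_nbrs[[mk]]))
        succ[mk] <- succ[mk] + 1
    }
  }
  structure(list(frequency = succ / n_replicates,
                 n_replicates = n_replicates,
                 drop_fraction = drop_fraction),
            class = "stability_report")
}

neighbor_sets <- function(ord) {
  m <- length(ord)
  out <- vector("list", m)
  names(out) <- ord
  for (p in seq_len(m))
    out[[p]] <- ord[c(p - 1, p + 1)[c(p - 1, p + 1) >= 1 & c(p - 1, p + 1) <= m]]
  out
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Jackknife stability: %d replicates, drop %.0f%%, mean retention %.2f\n",
              x$n_replicates, 100 * x$drop_fraction, mean(x$frequency)))
  invisible(x)
}

#' Skeleton-map filtering
#'
#' Removes markers that (i) are absolutely linked to another marker
#' (recombination fraction 0), (ii) violate monotonic growth of
#' recombination with subsequent neighbors, or (iii) have unstable
#' location under jackknife resampling.  In consensus mode only unique
#' markers are removed under these rules; a shared marker is removed only
#' when it is absolutely linked to another *shared* marker (one of the
#' twins is kept), so that as many shared anchors as possible survive
#' into the consensus step.
#'
#' @param dataset a [map_dataset()].
#' @param map the phase-1 `marker_map`.
#' @param rf the dataset's `rf_matrix`.
#' @param stability optional `stability_report`; rule (iii) is skipped
#'   when absent.
#' @param consensus_mode apply the shared-marker retention rule.
#' @param shared character vector of shared marker names (required in
#'   consensus mode).
#' @param stability_threshold retention frequency below which a marker is
#'   unstable.
#' @param mono_window how many subsequent neighbors rule (ii) checks.
#' @return list with `map` (filtered `marker_map`) and `removed`
#'   (data frame: marker, rule).
#' @export
skeleton_filter <- function(dataset, map, rf, stability = NULL,
                            consensus_mode = FALSE, shared = character(0),
                            stability_threshold = 0.7, mono_window = 4L) {
  ord <- map$order
  stab <- if (is.null(stability)) setNames(rep(1, length(ord)), ord) else
    stability$frequency[ord]
  is_shared <- ord %in% shared
  names(is_shared) <- ord
  removed <- character(0); rule <- character(0)
  removable <- function(mk) !consensus_mode || !is_shared[[mk]]

  # (i) absolute linkage: rf == 0 twins
  for (p in seq_along(ord)[-1]) {
    a <- ord[p - 1]; b <- ord[p]
    if (a %in% removed || b %in% removed) next
    if (rf$rf[a, b] == 0) {
      pair <- c(a, b)
      if (consensus_mode) {
        cand <- pair[!is_shared[pair]]
        if (length(cand) == 0) {
          # both shared: twin rule, drop the less stable one
          cand <- pair[which.min(stab[pair])]
        } else if (length(cand) == 2) {
          cand <- pair[which.min(stab[pair])]
        }
      } else {
        cand <- pair[which.min(stab[pair])]
      }
      removed <- c(removed, cand[1]); rule <- c(rule, "absolute_linkage")
    }
  }

  # (ii) monotonic growth of rf with subsequent neighbors
  keep1 <- setdiff(ord, removed)
  n_mean <- mean(rf$n[upper.tri(rf$n)])
  for (p in seq_along(keep1)) {
    mk <- keep1[p]
    if (!removable(mk)) next
    for (dir in c(-1, 1)) {
      ds <- seq_len(mono_window)
      pos <- p + dir * ds
      pos <- pos[pos >= 1 & pos <= length(keep1)]
      if (length(pos) < 2) next
      vals <- rf$rf[mk, keep1[pos]]
      se <- sqrt(pmax(vals * (1 - vals), 0.25 / 4) / max(n_mean, 1))
      viol <- any(diff(vals) < -2 * se[-1])
      if (viol) {
        removed <- c(removed, mk); rule <- c(rule, "non_monotone")
        break
      }
    }
    if (mk %in% removed) next
  }

  # (iii) jackknife instability
  if (!is.null(stability)) {
    for (mk in setdiff(ord, removed)) {
      if (!removable(mk)) next
      if (!is.na(stab[mk]) && stab[mk] < stability_threshold) {
        removed <- c(removed, mk); rule <- c(rule, "unstable")
      }
    }
  }

  kept <- setdiff(ord, removed)
  list(map = map_length(kept, rf, dataset_id = map$dataset_id),
       removed = data.frame(marker = removed, rule = rule,
                            stringsAsFactors = FALSE))
}
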