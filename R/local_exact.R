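# Exact resolution of a single conflict region by the two-stage
# tabulation scheme: (1) per dataset, tables of the minimal path
# a -> T -> b for every anchor pair (a, b) and every subset T of that
# dataset's unique markers in the region; (2) enumeration of the k!
# candidate orders of the region's shared markers, with the optimal
# assignment of unique markers to the k+1 intervals found by a
# subset-partition dynamic program over the tables.

#' Construct a conflict region by hand
#'
#' Mostly useful for exercising the region solver outside the pipeline;
#' the pipeline builds regions with [delineate_regions()].
#'
#' @param shared region shared markers (reference order).
#' @param dataset_ids integer ids of the datasets involved.
#' @param flank_left,flank_right character vectors named by dataset id
#'   (`NA` for a free end at the linkage-group boundary).
#' @param uniq list named by dataset id of unique markers in the region.
#' @param phase1_suborders optional list (named by dataset id) of the
#'   phase-1 shared suborders, used to break ties between equal-cost
#'   orders.
#' @return a `conflict_region`.
#' @export
conflict_region <- function(shared, dataset_ids, flank_left, flank_right,
                            uniq, phase1_suborders = NULL) {
  structure(list(shared = shared, k = length(shared),
                 dataset_ids = as.integer(dataset_ids),
                 flank_left = flank_left, flank_right = flank_right,
                 uniq = uniq,
                 n_unique = vapply(uniq, length, integer(1)),
                 phase1_suborders = phase1_suborders),
            class = "conflict_region")
}

region_flank <- function(region, i, side) {
  v <- if (side == "left") region$flank_left else region$flank_right
  key <- as.character(i)
  if (!is.null(names(v)) && key %in% names(v)) v[[key]]
  else if (i <= length(v)) v[[i]] else NA_character_
}

region_uniq <- function(region, i) {
  key <- as.character(i)
  u <- if (!is.null(names(region$uniq)) && key %in% names(region$uniq))
    region$uniq[[key]]
  else if (i <= length(region$uniq)) region$uniq[[i]] else NULL
  if (is.null(u)) character(0) else u
}

#' Computational complexity of exact region solving
#'
#' Stage 1 builds, per dataset, `2^n ((k+2)(k+1)/2 - 1)` table entries
#' (every anchor pair except the bounding flank pair, times every subset
#' of the `n` unique markers).  Stage 2 tests `k! (k+1)^n` combinations
#' of shared orders and interval assignments.  The exact solver is
#' considered feasible when `k + n_i < max_total` and both `k` and each
#' `n_i` are below `max_side` (defaults 15 and 11).
#'
#' @param region a `conflict_region`.
#' @param max_total,max_side feasibility caps.
#' @return list with `stage1_entries` (per dataset), `stage2_combinations`,
#'   `feasible`, `k`, `n`.
#' @export
estimate_complexity <- function(region, max_total = 15, max_side = 11) {
  k <- region$k
  n <- region$n_unique
  stage1 <- 2^n * ((k + 2) * (k + 1) / 2 - 1)
  stage2 <- factorial(k) * prod((k + 1)^n)
  feasible <- all(k + n < max_total) && k < max_side && all(n < max_side)
  list(stage1_entries = stage1, stage2_combinations = stage2,
       feasible = feasible, k = k, n = n)
}

# Subset DP over the unique markers of one dataset: minimal path cost
# from `start` (an anchor name, or NA for a free end) through every
# subset, ending at each possible last unique marker.  cost/par are
# indexed [subset mask + 1, unique index].
subset_dp <- function(rfm, uniq, start) {
  n <- length(uniq)
  size <- bitwShiftL(1L, n)
  cost <- matrix(Inf, size, max(n, 1L))
  par <- matrix(0L, size, max(n, 1L))
  for (j in seq_len(n)) {
    mask <- bitwShiftL(1L, j - 1L)
    cost[mask + 1L, j] <- if (is.na(start)) 0 else rfm[start, uniq[j]]
  }
  if (n >= 2) {
    bits <- bitwShiftL(1L, seq_len(n) - 1L)
    for (mask in seq_len(size - 1L)) {
      inset <- which(bitwAnd(mask, bits) != 0L)
      outset <- which(bitwAnd(mask, bits) == 0L)
      if (!length(outset)) next
      for (j in inset) {
        c0 <- cost[mask + 1L, j]
        if (!is.finite(c0)) next
        nm <- mask + bits[outset]
        nc <- c0 + rfm[uniq[j], uniq[outset]]
        sel <- nc < cost[cbind(nm + 1L, outset)]
        if (any(sel)) {
          idx <- cbind(nm + 1L, outset)[sel, , drop = FALSE]
          cost[idx] <- nc[sel]
          par[idx] <- j
        }
      }
    }
  }
  list(cost = cost, par = par)
}

# Reconstruct the internal order of subset `mask` ending at unique index
# `last`.
dp_walk <- function(dp, mask, last) {
  out <- integer(0)
  while (last != 0L) {
    out <- c(last, out)
    prev <- dp$par[mask + 1L, last]
    mask <- mask - bitwShiftL(1L, last - 1L)
    last <- prev
  }
  out
}

#' Build per-dataset insertion tables for a conflict region
#'
#' For each dataset, runs the subset dynamic program from every anchor
#' (the region's shared markers present in the dataset, plus its frozen
#' flanks) and from the free end, and materializes the minimal-cost
#' entry `a -> T -> b` for every anchor pair and subset `T`.
#'
#' @param region a `conflict_region`.
#' @param problem the [consensus_problem()] supplying rf matrices.
#' @param check refuse oversized regions (the GES fallback disables this
#'   to reuse the tables for its own evaluations when the unique-marker
#'   counts, which drive the table size, are small).
#' @return list per dataset id: `anchors`, `uniq`, `dp`, `dp_open`,
#'   `entry` (cost lookup array), `rf`.
#' @export
build_insertion_tables <- function(region, problem, check = TRUE) {
  cx <- estimate_complexity(region)
  if (check && !cx$feasible)
    stop(errorCondition(
      sprintf("conflict region too large for exact tabulation (k=%d, n=%s); use solve_region_ges()",
              cx$k, paste(cx$n, collapse = ",")),
      class = c("syncmap_infeasible", "error", "condition")))
  ids <- seq_along(problem$datasets)
  tables <- setNames(vector("list", length(ids)), ids)
  for (i in ids) {
    mk <- problem$datasets[[i]]$markers
    anchors <- c(region_flank(region, i, "left"),
                 region$shared[region$shared %in% mk],
                 region_flank(region, i, "right"))
    anchors <- unique(anchors[!is.na(anchors)])
    uniq <- region_uniq(region, i)
    if (length(anchors) + length(uniq) == 0) next
    rfm <- problem$rf[[i]]$rf
    n <- length(uniq)
    size <- bitwShiftL(1L, n)
    dp <- lapply(setNames(anchors, anchors), function(a) subset_dp(rfm, uniq, a))
    dp_open <- subset_dp(rfm, uniq, NA_character_)
    # entry[a_idx, b_idx, mask+1]: cost of a -> T -> b; index nA+1 = open end
    nA <- length(anchors)
    entry <- array(Inf, dim = c(nA + 1L, nA + 1L, size))
    ends <- c(anchors, NA_character_)
    for (ai in seq_len(nA + 1L)) {
      d <- if (ai == nA + 1L) dp_open else dp[[ai]]
      for (bi in seq_len(nA + 1L)) {
        if (ai == bi && ai <= nA) next
        tail_cost <- if (bi == nA + 1L) rep(0, max(n, 1)) else
          if (n > 0) rfm[uniq, ends[bi]] else 0
        if (n > 0) {
          cols <- lapply(seq_len(n), function(j) d$cost[, j] + tail_cost[j])
          entry[ai, bi, ] <- do.call(pmin, cols)
        }
        # empty subset
        entry[ai, bi, 1L] <-
          if (ai == nA + 1L || bi == nA + 1L) 0 else rfm[ends[ai], ends[bi]]
      }
    }
    tables[[i]] <- list(anchors = anchors, uniq = uniq, dp = dp,
                        dp_open = dp_open, entry = entry, rf = rfm)
  }
  tables
}

# Count materialized stage-1 entries by direct enumeration: unordered
# anchor pairs excluding the bounding flank pair, times subsets.
#' Count insertion-table entries by enumeration
#'
#' Walks the materialized table of one dataset and counts the stored
#' (anchor pair, subset) entries, excluding the pair of bounding flanks.
#' Useful as an independent check of the closed-form table size.
#'
#' @param tables output of [build_insertion_tables()].
#' @param region the region the tables were built for.
#' @param i dataset id.
#' @return integer count.
#' @export
table_entry_count <- function(tables, region, i) {
  tb <- tables[[as.character(i)]]
  if (is.null(tb)) return(0L)
  fl <- region_flank(region, i, "left")
  fr <- region_flank(region, i, "right")
  n_entries <- 0L
  nA <- length(tb$anchors)
  size <- bitwShiftL(1L, length(tb$uniq))
  for (ai in seq_len(nA)) for (bi in seq_len(nA)) {
    if (bi <= ai) next
    a <- tb$anchors[ai]; b <- tb$anchors[bi]
    if (!is.na(fl) && !is.na(fr) &&
        setequal(c(a, b), c(fl, fr))) next
    for (mask in 0:(size - 1L)) n_entries <- n_entries + 1L
  }
  n_entries
}

# Internal-order lookup for reconstruction.
table_entry_order <- function(tb, a, b, mask) {
  uniq <- tb$uniq
  if (mask == 0L) return(character(0))
  dp <- if (is.na(a)) tb$dp_open else tb$dp[[a]]
  members <- which(bitwAnd(mask, bitwShiftL(1L, seq_along(uniq) - 1L)) != 0L)
  ends <- dp$cost[mask + 1L, members]
  tail_cost <- if (is.na(b)) 0 else tb$rf[uniq[members], b]
  tot <- ends + tail_cost
  j <- members[which.min(tot)]
  uniq[dp_walk(dp, mask, j)]
}

entry_cost <- function(tb, a, b, mask) {
  nA <- length(tb$anchors)
  ai <- if (is.na(a)) nA + 1L else match(a, tb$anchors)
  bi <- if (is.na(b)) nA + 1L else match(b, tb$anchors)
  tb$entry[ai, bi, mask + 1L]
}

# Optimal assignment of one dataset's unique markers to the intervals of
# an anchor sequence (subset-partition DP over table entries).  Returns
# cost and the full suborder with unique markers interleaved.
assign_unique <- function(tb, anchor_seq, free_left, free_right) {
  uniq <- tb$uniq
  n <- length(uniq)
  full <- bitwShiftL(1L, n) - 1L
  if (!length(anchor_seq)) {
    # dataset has no anchors in the region: free open path over uniq
    if (n == 0) return(list(cost = 0, order = character(0)))
    ends <- tb$dp_open$cost[full + 1L, seq_len(n)]
    j <- which.min(ends)
    return(list(cost = ends[j],
                order = uniq[dp_walk(tb$dp_open, full, j)]))
  }
  ints <- list()
  if (free_left) ints[[length(ints) + 1]] <- c(NA_character_, anchor_seq[1])
  if (length(anchor_seq) >= 2)
    for (j in seq_len(length(anchor_seq) - 1))
      ints[[length(ints) + 1]] <- c(anchor_seq[j], anchor_seq[j + 1])
  if (free_right)
    ints[[length(ints) + 1]] <- c(anchor_seq[length(anchor_seq)], NA_character_)
  nint <- length(ints)
  if (n == 0 || nint == 0) {
    cost <- sum(vapply(ints, function(ab) entry_cost(tb, ab[1], ab[2], 0L),
                       numeric(1)))
    if (n > 0 && nint == 0) stop("unique markers but no interval to place them")
    return(list(cost = cost, order = anchor_seq))
  }
  f <- matrix(Inf, nint + 1L, full + 2L)
  choice <- matrix(NA_integer_, nint + 1L, full + 2L)
  f[1L, 1L] <- 0
  for (q in seq_len(nint)) {
    ab <- ints[[q]]
    icost <- vapply(0:full, function(Tm) entry_cost(tb, ab[1], ab[2], Tm),
                    numeric(1))
    for (S in 0:full) {
      Tm <- S
      repeat {
        base <- f[q, bitwXor(S, Tm) + 1L]
        if (is.finite(base)) {
          val <- base + icost[Tm + 1L]
          if (val < f[q + 1L, S + 1L]) {
            f[q + 1L, S + 1L] <- val
            choice[q + 1L, S + 1L] <- Tm
          }
        }
        if (Tm == 0L) break
        Tm <- bitwAnd(Tm - 1L, S)
      }
    }
  }
  cost <- f[nint + 1L, full + 1L]
  S <- full
  masks <- integer(nint)
  for (q in rev(seq_len(nint))) {
    masks[q] <- choice[q + 1L, S + 1L]
    S <- bitwXor(S, masks[q])
  }
  ord <- character(0)
  for (q in seq_len(nint)) {
    ab <- ints[[q]]
    inner <- table_entry_order(tb, ab[1], ab[2], masks[q])
    if (q == 1 && !free_left) ord <- ab[1]
    ord <- c(ord, inner, if (!is.na(ab[2])) ab[2])
  }
  list(cost = cost, order = ord)
}

permutations_of <- function(x) {
  n <- length(x)
  if (n <= 1) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    rest <- permutations_of(x[-i])
    for (p in rest) out[[length(out) + 1]] <- c(x[i], p)
  }
  out
}

#' Exactly solve one conflict region
#'
#' Enumerates every order of the region's shared markers; for each
#' candidate, the optimal placement of each dataset's unique markers into
#' the intervals between anchors is found independently per dataset
#' through the insertion tables (a subset-partition dynamic program,
#' equivalent to enumerating all `(k+1)^n` interval assignments).  The
#' returned order minimizes the weighted total region length, i.e. it is
#' the global constrained optimum; frozen flank edges are included in the
#' region cost so candidates are comparable.  Ties are broken toward the
#' order with the fewest discordant pairs against the phase-1 suborders,
#' then lexicographically.
#'
#' @param region a `conflict_region`.
#' @param problem the [consensus_problem()].
#' @param tables optional precomputed [build_insertion_tables()] output.
#' @param max_total,max_side feasibility caps (see [estimate_complexity()]).
#' @return a `region_solution`: `shared_order`, `orders` (per-dataset full
#'   suborder, flanks included), `costs` (per dataset), `total` (weighted).
#' @export
solve_region <- function(region, problem, tables = NULL,
                         max_total = 15, max_side = 11) {
  cx <- estimate_complexity(region, max_total, max_side)
  if (!cx$feasible)
    stop(errorCondition(
      sprintf("conflict region too large for exact solving (k=%d); use solve_region_ges()",
              cx$k),
      class = c("syncmap_infeasible", "error", "condition")))
  if (is.null(tables)) tables <- build_insertion_tables(region, problem)
  ids <- which(!vapply(tables, is.null, logical(1)))
  w <- problem$weights
  perms <- permutations_of(region$shared)
  best <- NULL
  best_key <- NULL
  for (g_r in perms) {
    total <- 0
    sols <- list()
    for (i in ids) {
      tb <- tables[[i]]
      anchor_seq <- c(
        if (!is.na(region_flank(region, i, "left"))) region_flank(region, i, "left"),
        g_r[g_r %in% tb$anchors],
        if (!is.na(region_flank(region, i, "right"))) region_flank(region, i, "right"))
      sol <- assign_unique(tb, anchor_seq,
                           free_left = is.na(region_flank(region, i, "left")),
                           free_right = is.na(region_flank(region, i, "right")))
      sols[[as.character(i)]] <- sol
      total <- total + w[i] * sol$cost
    }
    key <- c(region_discordance(g_r, region), paste(g_r, collapse = " "))
    if (is.null(best) || total < best$total - 1e-12 ||
        (abs(total - best$total) <= 1e-12 &&
         (as.numeric(key[1]) < as.numeric(best_key[1]) ||
          (key[1] == best_key[1] && key[2] < best_key[2])))) {
      best <- list(shared_order = g_r, sols = sols, total = total)
      best_key <- key
    }
  }
  costs <- vapply(best$sols, function(s) s$cost, numeric(1))
  structure(list(shared_order = best$shared_order,
                 orders = lapply(best$sols, function(s) s$order),
                 costs = costs, total = best$total),
            class = "region_solution")
}

# Discordant pairs of a candidate order against the phase-1 suborders.
region_discordance <- function(g_r, region) {
  disc <- 0
  if (!is.null(region$phase1_suborders)) {
    for (p in region$phase1_suborders) {
      common <- intersect(g_r, p)
      if (length(common) < 2) next
      sc <- concordance_score(p, g_r)
      npair <- choose(length(common), 2)
      disc <- disc + (npair - sc) / 2
    }
  }
  disc
}

#' @export
print.region_solution <- function(x, ...) {
  cat(sprintf("Region solution: shared order %s, weighted total %.4f\n",
              paste(x$shared_order, collapse = " < "), x$total))
  invisible(x)
}
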