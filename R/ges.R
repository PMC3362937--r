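# Guided evolution strategy for the synchronized TSP over the whole
# chromosome: mutate candidate shared orders, screen cheaply by the
# skeleton criterion against a learned threshold q, and evaluate the
# full criterion by anchor-constrained placement of unique markers.

#' Parameters of the guided-evolution-strategy search
#'
#' The multi-parametric mutation generator is controlled by six
#' parameters: rates of segment reversal, segment translocation and point
#' exchange, the mean segment lengths of the two segment moves
#' (geometric laws), and a bias of mutation sites toward long adjacent
#' intervals (0 = uniform sites, 1 = fully proportional to interval
#' length).
#'
#' @param rev_rate,trans_rate,swap_rate per-mutation application rates.
#' @param rev_len_mean,trans_len_mean mean segment lengths (>= 1).
#' @param site_bias in \[0, 1\].
#' @param mu,lambda evolution-strategy population sizes (lambda >= mu >= 1).
#' @param max_iter,stall_limit iteration budget and stop-after-no-improvement.
#' @param q_margin relative margin of the skeleton-screen threshold q.
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @return a `ges_params` list.
#' @export
ges_params <- function(rev_rate = 0.6, rev_len_mean = 3,
                       trans_rate = 0.3, trans_len_mean = 2,
                       swap_rate = 0.2, site_bias = 0.5,
                       mu = 1L, lambda = 10L,
                       max_iter = 2000L, stall_limit = 400L,
                       q_margin = 0.02, seed = 1L) {
  rates <- c(rev_rate, trans_rate, swap_rate)
  if (any(rates < 0 | rates > 1)) stop("mutation rates must be in [0,1]")
  if (site_bias < 0 || site_bias > 1) stop("site_bias must be in [0,1]")
  if (lambda < mu || mu < 1) stop("need lambda >= mu >= 1")
  structure(list(rev_rate = rev_rate, rev_len_mean = rev_len_mean,
                 trans_rate = trans_rate, trans_len_mean = trans_len_mean,
                 swap_rate = swap_rate, site_bias = site_bias,
                 mu = as.integer(mu), lambda = as.integer(lambda),
                 max_iter = as.integer(max_iter),
                 stall_limit = as.integer(stall_limit),
                 q_margin = q_margin, seed = as.integer(seed)),
            class = "ges_params")
}

seg_len_draw <- function(mean_len, max_len) {
  if (mean_len <= 1) return(1L)
  min(max_len, 1L + stats::rgeom(1, 1 / mean_len))
}

mutation_site <- function(m, weights, bias) {
  if (is.null(weights) || bias <= 0) return(sample.int(m, 1))
  w <- (1 - bias) / m + bias * weights / sum(weights)
  sample.int(m, 1, prob = w)
}

#' Mutate a shared-marker order
#'
#' Applies segment reversal, segment translocation and/or point exchange,
#' each with its configured rate; segment lengths follow shifted
#' geometric laws and mutation sites can be biased toward positions with
#' long adjacent intervals.  With all rates zero the order is returned
#' unchanged.
#'
#' @param g_best character vector, the incumbent shared order.
#' @param params a [ges_params()].
#' @param gap_weights optional per-position weights (length of `g_best`)
#'   biasing mutation sites toward low-confidence zones.
#' @return a valid permutation of `g_best`.
#' @export
mutate_order <- function(g_best, params, gap_weights = NULL) {
  g <- g_best
  m <- length(g)
  if (m < 2) return(g)
  applied <- FALSE
  if (runif(1) < params$rev_rate) {
    len <- max(2L, seg_len_draw(params$rev_len_mean, m))
    i <- min(mutation_site(m, gap_weights, params$site_bias), m - len + 1L)
    g[i:(i + len - 1L)] <- rev(g[i:(i + len - 1L)])
    applied <- TRUE
  }
  if (runif(1) < params$trans_rate) {
    len <- seg_len_draw(params$trans_len_mean, m - 1L)
    i <- min(mutation_site(m, gap_weights, params$site_bias), m - len + 1L)
    seg <- g[i:(i + len - 1L)]
    rest <- g[-(i:(i + len - 1L))]
    pos <- sample.int(length(rest) + 1L, 1) - 1L
    g <- append(rest, seg, after = pos)
    applied <- TRUE
  }
  if (runif(1) < params$swap_rate) {
    ij <- sample.int(m, 2)
    g[ij] <- g[rev(ij)]
    applied <- TRUE
  }
  if (!applied && (params$rev_rate + params$trans_rate + params$swap_rate) > 0) {
    len <- max(2L, seg_len_draw(params$rev_len_mean, m))
    i <- min(mutation_site(m, gap_weights, params$site_bias), m - len + 1L)
    g[i:(i + len - 1L)] <- rev(g[i:(i + len - 1L)])
  }
  g
}

#' Place unique markers around a fixed shared order
#'
#' Builds the best full map of one dataset embedding the shared order
#' `g(i)` exactly: cheapest-insertion construction of the unique markers
#' followed by three local-search moves that preserve the anchor order -
#' single-marker reinsertion, reinsertion of a reversed run of unique
#' markers, and exchange of two unique markers - iterated to a local
#' optimum.
#'
#' @param g shared order (character vector over the problem's shared set).
#' @param dataset a [map_dataset()].
#' @param rf the dataset's `rf_matrix`.
#' @return a `marker_map` whose restriction to shared markers equals
#'   `g(i)`.
#' @export
place_unique <- function(g, dataset, rf) {
  anchors <- shared_projection(g, dataset$markers)
  uniq <- setdiff(dataset$markers, g)
  uniq <- intersect(uniq, rownames(rf$rf))
  anchors <- intersect(anchors, rownames(rf$rf))
  rfm <- rf$rf
  if (length(anchors) && length(uniq) && length(uniq) <= 6) {
    # few unique markers: optimal interval assignment is cheap
    ex <- place_unique_exact(anchors, uniq, rfm)
    return(map_length(ex$order, rf, dataset_id = dataset$id))
  }
  start <- anchors
  if (!length(start)) {
    if (!length(uniq)) stop("dataset has no markers to place")
    start <- uniq[1]
    uniq <- uniq[-1]
  }
  # two construction orders (cheapest-first and tightest-linkage-first),
  # each refined by the local moves; keep the better local optimum
  best_ord <- NULL
  orders_in <- list(NULL,
                    if (length(uniq) > 1)
                      uniq[order(apply(rfm[uniq, start, drop = FALSE], 1, min))])
  for (fixed in unique(orders_in)) {
    ord <- start
    pool <- uniq
    while (length(pool)) {
      if (is.null(fixed)) {
        cand <- pool
      } else {
        cand <- intersect(fixed, pool)[1]
      }
      best <- NULL
      for (u in cand) {
        dc <- insertion_deltas(ord, u, rfm)
        j <- which.min(dc)
        if (is.null(best) || dc[j] < best$delta)
          best <- list(u = u, slot = j, delta = dc[j])
      }
      ord <- append(ord, best$u, after = best$slot - 1L)
      pool <- setdiff(pool, best$u)
    }
    if (length(uniq)) ord <- improve_placement(ord, uniq, rfm)
    if (is.null(best_ord) || path_cost(ord, rfm) < path_cost(best_ord, rfm))
      best_ord <- ord
  }
  map_length(best_ord, rf, dataset_id = dataset$id)
}

# Exact anchored placement for small unique-marker counts: subset DP per
# interval (both chromosome ends free) plus a subset-partition DP over
# the intervals.
place_unique_exact <- function(anchors, uniq, rfm) {
  n <- length(uniq)
  full <- bitwShiftL(1L, n) - 1L
  ints <- c(list(c(NA_character_, anchors[1])),
            if (length(anchors) >= 2)
              lapply(seq_len(length(anchors) - 1), function(j)
                c(anchors[j], anchors[j + 1])),
            list(c(anchors[length(anchors)], NA_character_)))
  nint <- length(ints)
  dps <- lapply(ints, function(ab) subset_dp(rfm, uniq, ab[1]))
  icost <- lapply(seq_len(nint), function(q) {
    ab <- ints[[q]]
    d <- dps[[q]]
    tail_cost <- if (is.na(ab[2])) rep(0, n) else rfm[uniq, ab[2]]
    costs <- do.call(pmin, c(lapply(seq_len(n), function(j)
      d$cost[, j] + tail_cost[j]), list(Inf)))
    costs[1] <- if (is.na(ab[1]) || is.na(ab[2])) 0 else rfm[ab[1], ab[2]]
    costs
  })
  f <- matrix(Inf, nint + 1L, full + 2L)
  choice <- matrix(NA_integer_, nint + 1L, full + 2L)
  f[1L, 1L] <- 0
  for (q in seq_len(nint)) {
    ic <- icost[[q]]
    for (S in 0:full) {
      Tm <- S
      repeat {
        base <- f[q, bitwXor(S, Tm) + 1L]
        if (is.finite(base)) {
          val <- base + ic[Tm + 1L]
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
  S <- full
  masks <- integer(nint)
  for (q in rev(seq_len(nint))) {
    masks[q] <- choice[q + 1L, S + 1L]
    S <- bitwXor(S, masks[q])
  }
  ord <- character(0)
  for (q in seq_len(nint)) {
    ab <- ints[[q]]
    inner <- character(0)
    if (masks[q] > 0L) {
      d <- dps[[q]]
      members <- which(bitwAnd(masks[q], bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
      tail_cost <- if (is.na(ab[2])) 0 else rfm[uniq[members], ab[2]]
      j <- members[which.min(d$cost[masks[q] + 1L, members] + tail_cost)]
      inner <- uniq[dp_walk(d, masks[q], j)]
    }
    if (q == 1) ord <- c(inner, ab[2])
    else ord <- c(ord, inner, if (!is.na(ab[2])) ab[2])
  }
  list(cost = f[nint + 1L, full + 1L], order = ord)
}

# Cost change of inserting marker u into each slot (1 = before first).
insertion_deltas <- function(ord, u, rfm) {
  m <- length(ord)
  left <- c(NA, ord)           # slot s has left neighbor ord[s-1]
  right <- c(ord, NA)
  dl <- ifelse(is.na(left), 0, rfm[u, ifelse(is.na(left), ord[1], left)])
  dr <- ifelse(is.na(right), 0, rfm[u, ifelse(is.na(right), ord[m], right)])
  mid <- ifelse(is.na(left) | is.na(right), 0,
                rfm[cbind(ifelse(is.na(left), ord[1], left),
                          ifelse(is.na(right), ord[m], right))])
  dl + dr - mid
}

path_cost <- function(ord, rfm) {
  if (length(ord) < 2) return(0)
  sum(rfm[cbind(ord[-length(ord)], ord[-1])])
}

# Local search preserving anchor order: Reinsert, Reverse-Reinsert (runs
# of consecutive unique markers), Exchange 1*1.
improve_placement <- function(ord, uniq, rfm) {
  repeat {
    improved <- FALSE
    base <- path_cost(ord, rfm)
    # Reinsert
    for (u in uniq) {
      rest <- ord[ord != u]
      dc <- insertion_deltas(rest, u, rfm)
      j <- which.min(dc)
      cand <- append(rest, u, after = j - 1L)
      if (path_cost(cand, rfm) < base - 1e-12) {
        ord <- cand; base <- path_cost(ord, rfm); improved <- TRUE
      }
    }
    # Reinsert runs of consecutive unique markers, in either orientation
    # (the reversed variant is the Reverse-Reinsert move)
    runs <- unique_runs(ord, uniq)
    for (run in runs) {
      if (length(run) < 2) next
      rest <- ord[!(ord %in% run)]
      seg <- ord[ord %in% run]
      bestc <- NULL
      for (pos in 0:length(rest)) {
        for (s in list(seg, rev(seg))) {
          cand <- append(rest, s, after = pos)
          cc <- path_cost(cand, rfm)
          if (is.null(bestc) || cc < bestc$c) bestc <- list(o = cand, c = cc)
        }
      }
      if (bestc$c < base - 1e-12) {
        ord <- bestc$o; base <- bestc$c; improved <- TRUE
      }
    }
    # Exchange 1*1
    if (length(uniq) >= 2) {
      for (a_i in seq_along(uniq)[-length(uniq)]) {
        for (b_i in (a_i + 1):length(uniq)) {
          cand <- ord
          pa <- match(uniq[a_i], cand); pb <- match(uniq[b_i], cand)
          cand[c(pa, pb)] <- cand[c(pb, pa)]
          if (path_cost(cand, rfm) < base - 1e-12) {
            ord <- cand; base <- path_cost(ord, rfm); improved <- TRUE
          }
        }
      }
    }
    if (!improved) break
  }
  ord
}

unique_runs <- function(ord, uniq) {
  isu <- ord %in% uniq
  runs <- list()
  cur <- character(0)
  for (p in seq_along(ord)) {
    if (isu[p]) cur <- c(cur, ord[p])
    else { if (length(cur)) runs[[length(runs) + 1]] <- cur; cur <- character(0) }
  }
  if (length(cur)) runs[[length(runs) + 1]] <- cur
  runs
}

# Full criterion for a shared order: weighted sum of the per-dataset
# lengths after anchor-constrained placement of unique markers.
full_criterion <- function(g, problem) {
  maps <- vector("list", length(problem$datasets))
  total <- 0
  for (i in seq_along(problem$datasets)) {
    maps[[i]] <- place_unique(g, problem$datasets[[i]], problem$rf[[i]])
    total <- total + problem$weights[i] * maps[[i]]$length_S
  }
  list(S = total, maps = maps)
}

# Quick skeleton start g**: heuristic TSP on the weighted-average rf
# matrix of the shared markers, refined by 2-opt on the true skeleton
# criterion.
skeleton_start <- function(problem, seed = 1L) {
  shared <- problem$shared
  R <- length(shared)
  D <- matrix(0, R, R, dimnames = list(shared, shared))
  Wm <- matrix(0, R, R)
  for (i in seq_along(problem$datasets)) {
    mk <- intersect(shared, problem$datasets[[i]]$markers)
    idx <- match(mk, shared)
    D[idx, idx] <- D[idx, idx] + problem$weights[i] * problem$rf[[i]]$rf[mk, mk]
    Wm[idx, idx] <- Wm[idx, idx] + problem$weights[i]
  }
  Dm <- ifelse(Wm > 0, D / pmax(Wm, 1e-12), 0.5)
  diag(Dm) <- 0
  dimnames(Dm) <- list(shared, shared)
  ord <- order_single(Dm, "heuristic", rng_seed = seed, iters = 150L)$order
  # 2-opt on the actual skeleton criterion
  best <- skeleton_criterion(ord, problem)
  m <- length(ord)
  repeat {
    improved <- FALSE
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      cand <- ord
      cand[i:j] <- rev(cand[i:j])
      s <- skeleton_criterion(cand, problem)
      if (s < best - 1e-12) { ord <- cand; best <- s; improved <- TRUE }
    }
    if (!improved) break
  }
  ord
}

#' Guided-evolution-strategy consensus search
#'
#' Implements the global phase-2 method: the initial solution is the
#' better (by the full criterion) of the local-method order `g_star` and
#' a quick skeleton-only solution; the search then mutates the incumbent
#' shared order, screens each mutant by the skeleton criterion against a
#' learned threshold `q`, evaluates survivors with the full criterion
#' via [place_unique()], and keeps improvements.  `q` is recomputed from
#' the best recorded (S_shared, S) pairs after every accepted step.  The
#' incumbent criterion is non-increasing and the returned solution is
#' conflict-free by construction (every dataset embeds the same shared
#' order).
#'
#' @param problem a [consensus_problem()].
#' @param g_star optional starting shared order from the local method.
#' @param params a [ges_params()].
#' @return list with `shared_order`, `maps`, `S_total`, `S_shared`,
#'   `trace` (incumbent after each accepted step), `threshold_state`,
#'   `eval_stats` (mutants screened vs fully evaluated).
#' @export
ges_consensus <- function(problem, g_star = NULL, params = ges_params()) {
  if (!length(problem$shared)) stop("problem has no shared markers")
  set.seed(params$seed)
  g2 <- skeleton_start(problem, seed = params$seed)
  cands <- list(g2)
  if (!is.null(g_star)) cands <- c(list(g_star), cands)
  evals <- lapply(cands, full_criterion, problem = problem)
  Ss <- vapply(evals, function(e) e$S, numeric(1))
  pick <- which.min(Ss)
  g_best <- cands[[pick]]
  best <- evals[[pick]]
  pairs <- data.frame(S_shared = skeleton_criterion(g_best, problem),
                      S = best$S)
  q <- pairs$S_shared[1] * (1 + params$q_margin)
  trace <- best$S
  n_screened <- 0L; n_evaluated <- 0L
  stall <- 0L
  gapw <- gap_weights_for(g_best, problem)
  for (t in seq_len(params$max_iter)) {
    if (stall >= params$stall_limit) break
    improved_any <- FALSE
    for (l in seq_len(params$lambda)) {
      g_t <- mutate_order(g_best, params, gapw)
      n_screened <- n_screened + 1L
      s_sh <- skeleton_criterion(g_t, problem)
      if (s_sh <= q) {
        n_evaluated <- n_evaluated + 1L
        ev <- full_criterion(g_t, problem)
        if (ev$S < best$S - 1e-12) {
          g_best <- g_t
          best <- ev
          pairs <- rbind(pairs, data.frame(S_shared = s_sh, S = ev$S))
          top <- head(pairs[order(pairs$S), , drop = FALSE], 5)
          q <- max(top$S_shared) * (1 + params$q_margin)
          gapw <- gap_weights_for(g_best, problem)
          improved_any <- TRUE
        }
      }
      trace <- c(trace, best$S)
    }
    stall <- if (improved_any) 0L else stall + params$lambda
  }
  list(shared_order = g_best, maps = best$maps, S_total = best$S,
       S_shared = skeleton_criterion(g_best, problem),
       trace = trace,
       threshold_state = list(pairs = pairs, q = q),
       eval_stats = c(screened = n_screened, evaluated = n_evaluated))
}

# Position weights for mutation-site bias: mean adjacent recombination
# fraction around each position of g, averaged over datasets.
gap_weights_for <- function(g, problem) {
  m <- length(g)
  if (m < 2) return(NULL)
  w <- numeric(m)
  cnt <- numeric(m)
  for (i in seq_along(problem$datasets)) {
    gi <- shared_projection(g, problem$datasets[[i]]$markers)
    if (length(gi) < 2) next
    adj <- problem$rf[[i]]$rf[cbind(gi[-length(gi)], gi[-1])]
    pos <- match(gi, g)
    for (j in seq_along(adj)) {
      w[pos[j]] <- w[pos[j]] + adj[j]
      w[pos[j + 1]] <- w[pos[j + 1]] + adj[j]
      cnt[pos[j]] <- cnt[pos[j]] + 1
      cnt[pos[j + 1]] <- cnt[pos[j + 1]] + 1
    }
  }
  out <- ifelse(cnt > 0, w / cnt, mean(w[cnt > 0]))
  if (all(!is.finite(out)) || sum(out) == 0) NULL else pmax(out, 1e-6)
}

#' Heuristic solver for an oversized conflict region
#'
#' Runs the GES loop restricted to one conflict region: candidate orders
#' of the region's shared markers are evaluated by the weighted region
#' cost with per-dataset unique markers placed by anchor-constrained
#' best insertion (flanks frozen).
#'
#' @param region a `conflict_region`.
#' @param problem the [consensus_problem()].
#' @param params a [ges_params()].
#' @return a `region_solution` (not guaranteed optimal).
#' @export
solve_region_ges <- function(region, problem, params = ges_params()) {
  set.seed(params$seed)
  ids <- seq_along(problem$datasets)
  w <- problem$weights
  # with few unique markers per dataset the stage-1 tables are small even
  # for many shared markers, giving exact placement per candidate order
  use_tables <- all(region$n_unique <= 10)
  tables <- if (use_tables)
    build_insertion_tables(region, problem, check = FALSE)
  eval_region <- function(g_r) {
    total <- 0
    sols <- list()
    for (i in ids) {
      mk <- problem$datasets[[i]]$markers
      anchors_i <- g_r[g_r %in% mk]
      uniq <- region_uniq(region, i)
      fl <- region_flank(region, i, "left")
      fr <- region_flank(region, i, "right")
      seqi <- c(if (!is.na(fl)) fl, anchors_i, if (!is.na(fr)) fr)
      if (!length(seqi) && !length(uniq)) next
      if (use_tables) {
        sol <- assign_unique(tables[[i]], seqi,
                             free_left = is.na(fl), free_right = is.na(fr))
        sols[[as.character(i)]] <- sol
        total <- total + w[i] * sol$cost
        next
      }
      rfm <- problem$rf[[i]]$rf
      ord <- seqi
      pool <- uniq
      while (length(pool)) {
        bestu <- NULL
        for (u in pool) {
          dc <- insertion_deltas(ord, u, rfm)
          # flanks frozen: no insertion outside them
          lo <- if (!is.na(fl)) 2L else 1L
          hi <- if (!is.na(fr)) length(ord) else length(ord) + 1L
          dc[setdiff(seq_along(dc), lo:hi)] <- Inf
          j <- which.min(dc)
          if (is.null(bestu) || dc[j] < bestu$delta)
            bestu <- list(u = u, slot = j, delta = dc[j])
        }
        ord <- append(ord, bestu$u, after = bestu$slot - 1L)
        pool <- setdiff(pool, bestu$u)
      }
      cost <- path_cost(ord, rfm)
      sols[[as.character(i)]] <- list(cost = cost, order = ord)
      total <- total + w[i] * cost
    }
    list(total = total, sols = sols)
  }
  # starts: the region's reference order plus each full phase-1 suborder
  starts <- list(region$shared)
  for (p1 in region$phase1_suborders)
    if (!is.null(p1) && setequal(p1, region$shared))
      starts[[length(starts) + 1]] <- p1
  evs <- lapply(starts, eval_region)
  pick <- which.min(vapply(evs, `[[`, numeric(1), "total"))
  g_best <- starts[[pick]]
  best <- evs[[pick]]
  # local search over short reversals (includes adjacent transpositions)
  local_pass <- function(g_best, best) {
    k <- length(g_best)
    repeat {
      improved <- FALSE
      for (len in 2:min(3, k)) {
        for (i in seq_len(k - len + 1)) {
          g_t <- g_best
          g_t[i:(i + len - 1)] <- rev(g_t[i:(i + len - 1)])
          ev <- eval_region(g_t)
          if (ev$total < best$total - 1e-12) {
            g_best <- g_t; best <- ev; improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    list(g = g_best, ev = best)
  }
  lp <- local_pass(g_best, best)
  g_best <- lp$g; best <- lp$ev
  stall <- 0L
  for (t in seq_len(params$max_iter)) {
    if (stall >= params$stall_limit) break
    g_t <- mutate_order(g_best, params)
    ev <- eval_region(g_t)
    if (ev$total < best$total - 1e-12) {
      lp <- local_pass(g_t, ev)
      g_best <- lp$g; best <- lp$ev
      stall <- 0L
    } else stall <- stall + 1L
  }
  structure(list(shared_order = g_best,
                 orders = lapply(best$sols, function(s) s$order),
                 costs = vapply(best$sols, function(s) s$cost, numeric(1)),
                 total = best$total),
            class = "region_solution")
}
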