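# The two-phase pipeline: phase-1 ordering per dataset, pre-correction,
# conflict delineation, exact or heuristic region solving, optional
# global GES polish, and the cost-of-consensus report.

#' Control parameters for [consensus_map()]
#'
#' @param solver phase-1 solver, `"heuristic"` or `"exact"` (exact only
#'   up to 16 markers).
#' @param iters phase-1 heuristic perturbation budget.
#' @param jackknife_reps jackknife replicates for the stability filter
#'   (0 disables rule (iii) of the skeleton filter).
#' @param drop_fraction jackknife drop fraction.
#' @param stability_threshold retention frequency below which a marker
#'   counts as unstable.
#' @param skeleton_filtering apply the skeleton filter at all.
#' @param gap_threshold,length_tolerance pre-correction parameters (see
#'   [pre_correct()]).
#' @param max_total,max_side exact-region feasibility caps.
#' @param exact_budget stage-2 operation budget above which a region is
#'   handed to the GES fallback even though tabulation would be feasible
#'   in principle.
#' @param global_polish run a whole-chromosome GES pass from the merged
#'   local solution.
#' @param ges GES parameters for oversized regions / the polish pass.
#' @param high_cost_cM per-dataset map-length inflation (cM) above which
#'   a dataset is flagged high-cost.
#' @param seed master RNG seed for the run.
#' @return a list of class `"syncmap_control"`.
#' @export
syncmap_control <- function(solver = c("heuristic", "exact"), iters = 200L,
                            jackknife_reps = 0L, drop_fraction = 0.2,
                            stability_threshold = 0.7,
                            skeleton_filtering = TRUE,
                            gap_threshold = 0.3, length_tolerance = 0.02,
                            max_total = 15, max_side = 11,
                            exact_budget = 2e5,
                            global_polish = FALSE,
                            ges = NULL, high_cost_cM = 10, seed = 1L) {
  solver <- match.arg(solver)
  if (is.null(ges)) ges <- ges_params(seed = seed, max_iter = 400L,
                                      stall_limit = 150L)
  structure(list(solver = solver, iters = as.integer(iters),
                 jackknife_reps = as.integer(jackknife_reps),
                 drop_fraction = drop_fraction,
                 stability_threshold = stability_threshold,
                 skeleton_filtering = skeleton_filtering,
                 gap_threshold = gap_threshold,
                 length_tolerance = length_tolerance,
                 max_total = max_total, max_side = max_side,
                 exact_budget = exact_budget,
                 global_polish = global_polish, ges = ges,
                 high_cost_cM = high_cost_cM, seed = as.integer(seed)),
            class = "syncmap_control")
}

#' Fit a consensus map
#'
#' The main entry point: runs the full two-phase analysis on a
#' [consensus_problem()].  Phase 1 orders each dataset independently
#' (minimum sum of adjacent recombination fractions) and optionally
#' filters skeleton maps; phase 2 aligns orientations, applies
#' inversion/transposition pre-correction, delineates conflict regions,
#' solves each exactly where feasible (otherwise by GES), stitches the
#' region solutions back, and optionally polishes globally.  The result
#' embeds one shared-marker order in every dataset, so it is
#' conflict-free by construction.
#'
#' @param problem a [consensus_problem()], e.g. from [make_problem()] or
#'   [read_manifest()].
#' @param weights `"equal"`, `"inverse_length"` (weights `1/L_i` from the
#'   phase-1 lengths), or a numeric vector.
#' @param control a [syncmap_control()].
#' @return an object of class `"consensus_map"` with components
#'   `shared_order`, `maps` (per-dataset consensus `marker_map`s),
#'   `phase1_maps`, `S_total`, `S_shared`, `conflicts` (initial),
#'   `regions`, `region_solutions`, `cost` (the cost-of-consensus
#'   report), `removed` (skeleton-filter log), `weights`, `control`.
#' @export
consensus_map <- function(problem, weights = c("equal", "inverse_length"),
                          control = syncmap_control()) {
  stopifnot(inherits(problem, "consensus_problem"))
  set.seed(control$seed)
  nds <- length(problem$datasets)
  shared <- problem$shared

  usable <- vapply(problem$datasets, function(d)
    sum(d$markers %in% shared) >= 2, logical(1))
  if (!all(usable))
    warning("datasets with <2 shared markers excluded: ",
            paste(which(!usable), collapse = ", "))

  # ---- phase 1: individual ordering + skeleton filtering ----
  phase1 <- vector("list", nds)
  removed <- vector("list", nds)
  for (i in seq_len(nds)) {
    rf <- problem$rf[[i]]
    mp <- order_single(rf, control$solver, rng_seed = control$seed + i,
                       iters = control$iters, dataset_id = i)
    if (control$skeleton_filtering) {
      stab <- NULL
      if (control$jackknife_reps > 0)
        stab <- jackknife_stability(problem$datasets[[i]], mp,
                                    n_replicates = control$jackknife_reps,
                                    drop_fraction = control$drop_fraction,
                                    rng_seed = control$seed + 1000L + i)
      fl <- skeleton_filter(problem$datasets[[i]], mp, rf, stability = stab,
                            consensus_mode = TRUE, shared = shared,
                            stability_threshold = control$stability_threshold)
      if (nrow(fl$removed) > 0) {
        # re-optimize on the retained markers so the individual map is
        # the skeleton's own optimum, not a thinned copy of the full one
        fl$map <- order_single(sub_rf(rf, fl$map$order), control$solver,
                               rng_seed = control$seed + i,
                               iters = control$iters, dataset_id = i)
      }
      phase1[[i]] <- fl$map
      removed[[i]] <- fl$removed
    } else {
      phase1[[i]] <- mp
      removed[[i]] <- data.frame(marker = character(0), rule = character(0))
    }
  }

  if (!is.character(weights)) {
    w <- weights
  } else {
    weights <- match.arg(weights)
    w <- compute_weights(problem, weights, phase1)
  }
  prob_w <- problem
  prob_w$weights <- w
  # downstream steps see the skeleton-filtered marker sets
  prob_w$datasets <- lapply(seq_len(nds), function(i) {
    d <- problem$datasets[[i]]
    keep <- phase1[[i]]$order
    d$geno <- d$geno[keep, , drop = FALSE]
    d$markers <- keep
    d
  })

  # ---- orientation alignment + pre-correction ----
  orders <- align_orientations(lapply(phase1, `[[`, "order"), shared = shared)
  phase1 <- lapply(seq_len(nds), function(i)
    map_length(orders[[i]], problem$rf[[i]], dataset_id = i))
  pc <- pre_correct(phase1, problem$rf, shared = shared,
                    gap_threshold = control$gap_threshold,
                    length_tolerance = control$length_tolerance)
  maps <- pc$maps

  # ---- conflict analysis + region solving ----
  conflicts <- detect_conflicts(maps, shared = shared, warn = FALSE)
  regions <- list()
  region_solutions <- list()
  if (nrow(conflicts) > 0 || length(attr(conflicts, "higher_order"))) {
    regions <- delineate_regions(maps, conflicts, shared = shared)
    orders <- align_orientations(lapply(maps, `[[`, "order"), shared = shared)
    for (rg_i in seq_along(regions)) {
      rg <- regions[[rg_i]]
      cx <- estimate_complexity(rg, control$max_total, control$max_side)
      sol <- if (cx$feasible &&
                 cx$stage2_combinations <= control$exact_budget)
        solve_region(rg, prob_w,
                     max_total = control$max_total,
                     max_side = control$max_side)
        else solve_region_ges(rg, prob_w, params = control$ges)
      region_solutions[[rg_i]] <- sol
      orders <- stitch_region(orders, rg, sol)
    }
    maps <- lapply(seq_len(nds), function(i)
      map_length(orders[[i]], problem$rf[[i]], dataset_id = i))
  }

  # ---- consensus shared order + conflict-free guarantee ----
  g <- merge_shared_order(lapply(maps, `[[`, "order"), shared)
  conserved <- all(vapply(seq_len(nds), function(i)
    setequal(maps[[i]]$order, phase1[[i]]$order), logical(1)))
  if (!conserved ||
      !conflict_free(lapply(maps, `[[`, "order"), shared = shared)) {
    # enforce the merged order everywhere (anchored re-placement)
    maps <- lapply(seq_len(nds), function(i)
      place_unique(g, prob_w$datasets[[i]], prob_w$rf[[i]]))
    g <- merge_shared_order(lapply(maps, `[[`, "order"), shared)
  }

  # ---- optional global polish ----
  polish <- NULL
  if (control$global_polish) {
    polish <- ges_consensus(prob_w, g_star = g, params = control$ges)
    S_cur <- sum(w * vapply(maps, `[[`, numeric(1), "length_S"))
    if (polish$S_total < S_cur - 1e-12) {
      g <- polish$shared_order
      maps <- polish$maps
      maps <- lapply(seq_len(nds), function(i) {
        m <- maps[[i]]; m$dataset_id <- i; m })
    }
  }

  maps <- lapply(seq_len(nds), function(i) {
    m <- maps[[i]]
    m2 <- map_length(orient_to(m$order, phase1[[i]]$order),
                     problem$rf[[i]], dataset_id = i)
    m2
  })

  S_total <- sum(w * vapply(maps, `[[`, numeric(1), "length_S"))
  cost <- cost_report(phase1, maps, high_cost_cM = control$high_cost_cM)

  fit <- structure(list(
    shared_order = g,
    maps = maps,
    phase1_maps = phase1,
    S_total = S_total,
    S_shared = skeleton_criterion(g, prob_w),
    conflicts = conflicts,
    regions = regions,
    region_solutions = region_solutions,
    precorrection_log = pc$log,
    cost = cost,
    removed = removed,
    weights = w,
    control = control,
    problem = problem), class = "consensus_map")
  fit
}

# Replace each dataset's window of a region with the solved suborder.
stitch_region <- function(orders, region, sol) {
  for (key in names(sol$orders)) {
    i <- as.integer(key)
    sub <- sol$orders[[key]]
    if (!length(sub)) next
    ord <- orders[[i]]
    fl <- region_flank(region, i, "left")
    fr <- region_flank(region, i, "right")
    a <- if (is.na(fl)) 1L else match(fl, ord)
    b <- if (is.na(fr)) length(ord) else match(fr, ord)
    if (is.na(a) || is.na(b)) next
    orders[[i]] <- c(if (a > 1) ord[1:(a - 1)], sub,
                     if (b < length(ord)) ord[(b + 1):length(ord)])
    # sub includes the flanks themselves when frozen
    orders[[i]] <- orders[[i]][!duplicated(orders[[i]])]
  }
  orders
}

# Merge conflict-free partial orders of shared markers into one total
# order (Kahn's algorithm, mean-normalized-rank priority for ties).
merge_shared_order <- function(orders, shared) {
  proj <- align_orientations(lapply(orders, function(o) o[o %in% shared]))
  present <- unique(unlist(proj))
  if (!length(present)) return(character(0))
  rank_mean <- vapply(present, function(m) {
    r <- vapply(proj, function(p) {
      pos <- match(m, p)
      if (is.na(pos) || length(p) < 2) NA_real_ else (pos - 1) / (length(p) - 1)
    }, numeric(1))
    mean(r, na.rm = TRUE)
  }, numeric(1))
  succ <- list(); indeg <- setNames(integer(length(present)), present)
  seen <- character(0)
  for (p in proj) {
    if (length(p) < 2) next
    for (j in seq_len(length(p) - 1)) for (k in (j + 1):length(p)) {
      key <- paste(p[j], p[k])
      if (key %in% seen) next
      seen <- c(seen, key)
      succ[[p[j]]] <- c(succ[[p[j]]], p[k])
      indeg[p[k]] <- indeg[p[k]] + 1L
    }
  }
  out <- character(0)
  avail <- present[indeg[present] == 0L]
  while (length(avail)) {
    nxt <- avail[which.min(rank_mean[avail])]
    out <- c(out, nxt)
    avail <- setdiff(avail, nxt)
    for (s in succ[[nxt]]) {
      indeg[s] <- indeg[s] - 1L
      if (indeg[s] == 0L) avail <- c(avail, s)
    }
  }
  if (length(out) < length(present)) {
    # cycle (conflicting input): fall back to mean-rank order
    out <- present[order(rank_mean[present])]
  }
  out
}

#' Per-dataset weights for the consensus criterion
#'
#' Equal weights, or the inverse of each dataset's individual (phase-1)
#' map length `1/L_i`, which down-weights noise-inflated datasets.
#'
#' @param problem a [consensus_problem()].
#' @param mode `"equal"` or `"inverse_length"`.
#' @param phase1_maps list of phase-1 `marker_map`s (required for
#'   `"inverse_length"`).
#' @return numeric weight vector.
#' @export
compute_weights <- function(problem, mode = c("equal", "inverse_length"),
                            phase1_maps = NULL) {
  mode <- match.arg(mode)
  if (mode == "equal") return(rep(1, length(problem$datasets)))
  if (is.null(phase1_maps)) stop("inverse_length weights need phase-1 maps")
  L <- vapply(phase1_maps, `[[`, numeric(1), "length_S")
  if (any(L <= 0)) stop("zero phase-1 map length; cannot form 1/L weights")
  1 / L
}

# Cost-of-consensus report: per-dataset individual vs consensus lengths
# and a per-marker attribution of the difference (half of each incident
# adjacent-interval change, so attributions sum to the dataset delta).
cost_report <- function(phase1, maps, high_cost_cM = 10) {
  nds <- length(maps)
  per <- data.frame(dataset = seq_len(nds),
                    L_ind = vapply(phase1, `[[`, numeric(1), "length_cM"),
                    L_cons = vapply(maps, `[[`, numeric(1), "length_cM"))
  per$delta <- per$L_cons - per$L_ind
  per$high_cost <- per$delta > high_cost_cM
  attribution <- lapply(seq_len(nds), function(i) {
    inc_c <- incident_cM(maps[[i]])
    inc_i <- incident_cM(phase1[[i]])
    mk <- union(names(inc_c), names(inc_i))
    d <- setNames(numeric(length(mk)), mk)
    d[names(inc_c)] <- d[names(inc_c)] + inc_c
    d[names(inc_i)] <- d[names(inc_i)] - inc_i
    sort(d, decreasing = TRUE)
  })
  structure(list(per_dataset = per, attribution = attribution,
                 high_cost_cM = high_cost_cM),
            class = "cost_report")
}

incident_cM <- function(map) {
  ord <- map$order
  adj <- map$adjacent_rf * 100
  inc <- setNames(numeric(length(ord)), ord)
  if (length(adj)) for (j in seq_along(adj)) {
    inc[j] <- inc[j] + adj[j] / 2
    inc[j + 1] <- inc[j + 1] + adj[j] / 2
  }
  inc
}

#' @export
print.cost_report <- function(x, ...) {
  print(x$per_dataset, row.names = FALSE)
  invisible(x)
}

#' Recovery coefficient of the consensus shared order
#'
#' The fraction of shared markers whose immediate neighborhood (both
#' neighbors, or the single neighbor at the map ends) in the consensus
#' order matches the true simulated order, after orientation alignment
#' and restriction to the markers present in both orders.
#'
#' @param solution a `consensus_map` fit, or a character shared order.
#' @param ground_truth the true shared order (character), or the
#'   `"ground_truth"` attribute of [make_problem()].
#' @return fraction in \[0, 1\].
#' @export
recovery_coefficient <- function(solution, ground_truth) {
  g <- if (inherits(solution, "consensus_map")) solution$shared_order
       else solution
  truth <- if (is.list(ground_truth)) ground_truth$true_shared_order
           else ground_truth
  if (is.null(truth)) stop("ground truth not available")
  common <- intersect(g, truth)
  if (length(common) < 2) stop("fewer than 2 markers common with ground truth")
  g <- g[g %in% common]
  truth <- truth[truth %in% common]
  g <- orient_to(g, truth)
  nb_g <- neighbor_sets(g)
  nb_t <- neighbor_sets(truth)
  mean(vapply(common, function(m)
    setequal(nb_g[[m]], nb_t[[m]]), logical(1)))
}

#' Rank marker removals that would reduce the cost of consensus
#'
#' For each dataset whose consensus map is inflated beyond the threshold,
#' re-solves the conflict regions with each candidate marker removed from
#' that dataset and ranks the removals by how much they reduce the
#' inflation.  When no single removal is sufficient, joint removal of the
#' top candidate pairs is evaluated.  Proposals are never applied
#' automatically.
#'
#' @param solution a `consensus_map` fit.
#' @param cost_threshold_cM inflation above which a dataset is examined.
#' @param max_joint evaluate pairs among this many top single candidates
#'   when singles do not reach the threshold.
#' @return data frame: `dataset`, `markers`, `delta_before`,
#'   `delta_after`, `reduction_cM`, ranked by reduction.
#' @export
suggest_removals <- function(solution, cost_threshold_cM = 10,
                             max_joint = 3L) {
  per <- solution$cost$per_dataset
  out <- data.frame(dataset = integer(0), markers = character(0),
                    delta_before = numeric(0), delta_after = numeric(0),
                    reduction_cM = numeric(0), stringsAsFactors = FALSE)
  hot <- per$dataset[per$delta > cost_threshold_cM]
  if (!length(hot) || !length(solution$regions)) return(out)
  problem <- solution$problem
  for (i in hot) {
    cands <- unlist(lapply(solution$regions, function(rg) {
      mk <- problem$datasets[[i]]$markers
      c(intersect(rg$shared, mk), region_uniq(rg, i))
    }))
    cands <- unique(cands)
    if (!length(cands)) next
    rows <- lapply(cands, function(mset)
      eval_removal(solution, i, mset))
    rows <- do.call(rbind, rows)
    if (all(rows$delta_after > cost_threshold_cM) && nrow(rows) >= 2) {
      top <- head(rows$markers[order(-rows$reduction_cM)], max_joint)
      prs <- combn(top, 2, simplify = FALSE)
      rows2 <- do.call(rbind, lapply(prs, function(p)
        eval_removal(solution, i, p)))
      rows <- rbind(rows, rows2)
    }
    out <- rbind(out, rows)
  }
  out[order(-out$reduction_cM), , drop = FALSE]
}

# Delta for dataset i after removing marker set `mset` from it: re-fit
# both the individual and the consensus map of that dataset without the
# markers (consensus order of the other datasets kept fixed).
eval_removal <- function(solution, i, mset) {
  problem <- solution$problem
  rf <- problem$rf[[i]]
  keep_ind <- setdiff(solution$phase1_maps[[i]]$order, mset)
  ord_ind <- order_single(sub_rf(rf, keep_ind), "heuristic",
                          rng_seed = solution$control$seed + i, iters = 100L)
  g <- setdiff(solution$shared_order, mset)
  ds <- problem$datasets[[i]]
  ds$markers <- setdiff(ds$markers, mset)
  ds$geno <- ds$geno[ds$markers, , drop = FALSE]
  cons <- place_unique(g, ds, rf)
  delta_before <- solution$cost$per_dataset$delta[i]
  delta_after <- cons$length_cM - ord_ind$length_cM
  data.frame(dataset = i, markers = paste(mset, collapse = "+"),
             delta_before = delta_before, delta_after = delta_after,
             reduction_cM = delta_before - delta_after,
             stringsAsFactors = FALSE)
}

sub_rf <- function(rf, markers) {
  new_rf_matrix(rf$rf[markers, markers, drop = FALSE],
                rf$n[markers, markers, drop = FALSE],
                rf$unreliable[markers, markers, drop = FALSE],
                rf$cross_type)
}

#' Build the integral map of a consensus solution
#'
#' A directed graph over all markers: each dataset contributes the chain
#' of its consensus map, with edge attributes `dataset` and
#' `distance_cM`.  The consensus shared order forms the backbone; unique
#' markers from different datasets lying between the same pair of shared
#' flanks, with no cross-dataset order information, appear as parallel
#' branches - a *loop* - rather than being forced into a linear order
#' (distances are never averaged across datasets).  Refuses conflicting
#' input; the graph is acyclic.
#'
#' @param solution a conflict-free `consensus_map` fit.
#' @return an `igraph` graph with vertex attribute `shared` and edge
#'   attributes `dataset`, `distance_cM`, `loop_id` (NA off loops).
#' @export
build_integral_map <- function(solution) {
  if (!conflict_free(solution)) stop("solution is not conflict-free")
  shared <- solution$problem$shared
  g_cons <- solution$shared_order
  orders <- lapply(solution$maps, `[[`, "order")
  orders <- lapply(orders, orient_to, ref = g_cons)
  edges <- data.frame(from = character(0), to = character(0),
                      dataset = integer(0), distance_cM = numeric(0),
                      stringsAsFactors = FALSE)
  seg_key <- character(0); seg_ds <- integer(0); seg_rows <- list()
  for (i in seq_along(orders)) {
    ord <- orders[[i]]
    adj <- map_length(ord, solution$problem$rf[[i]])$adjacent_rf * 100
    if (length(ord) < 2) next
    rows <- data.frame(from = ord[-length(ord)], to = ord[-1],
                       dataset = i, distance_cM = adj,
                       stringsAsFactors = FALSE)
    edges <- rbind(edges, rows)
    # branch segments: runs of unique markers between shared flanks
    sh_pos <- which(ord %in% shared)
    bounds <- c(0, sh_pos, length(ord) + 1)
    for (b in seq_len(length(bounds) - 1)) {
      lo <- bounds[b]; hi <- bounds[b + 1]
      if (hi - lo > 1) {  # at least one unique marker strictly between
        key <- paste(if (lo >= 1) ord[lo] else "<start>",
                     if (hi <= length(ord)) ord[hi] else "<end>")
        seg_key <- c(seg_key, key); seg_ds <- c(seg_ds, i)
        seg_rows[[length(seg_rows) + 1]] <-
          which(edges$dataset == i &
                  edges$from %in% ord[max(lo, 1):min(hi, length(ord))] &
                  edges$to %in% ord[max(lo, 1):min(hi, length(ord))])
      }
    }
  }
  gr <- igraph::graph_from_data_frame(edges, directed = TRUE)
  igraph::V(gr)$shared <- as.integer(igraph::V(gr)$name %in% shared)
  loop_id <- rep(NA_integer_, nrow(edges))
  if (length(seg_key)) {
    tab <- table(seg_key)
    loops <- names(tab)[tab >= 2]
    for (li in seq_along(loops)) {
      idx <- which(seg_key == loops[li])
      for (t in idx) loop_id[seg_rows[[t]]] <- li
    }
  }
  igraph::E(gr)$loop_id <- loop_id
  gr
}

#' Write an integral map to GraphML and/or DOT
#'
#' @param graph result of [build_integral_map()].
#' @param graphml,dot output paths (either may be `NULL`).
#' @export
write_integral_map <- function(graph, graphml = NULL, dot = NULL) {
  if (!is.null(graphml)) igraph::write_graph(graph, graphml, format = "graphml")
  if (!is.null(dot)) igraph::write_graph(graph, dot, format = "dot")
  invisible(graph)
}
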