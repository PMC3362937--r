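# Shared fixture builders (all data generated in code).

# rf matrix from true cM positions via the Haldane map function.
rf_from_positions <- function(pos) {
  mk <- names(pos)
  d <- abs(outer(pos, pos, "-"))
  rf <- haldane(d)
  dimnames(rf) <- list(mk, mk)
  syncmap:::new_rf_matrix(rf, matrix(1000L, length(mk), length(mk),
                                     dimnames = list(mk, mk)))
}

# Random symmetric rf matrix (no metric structure implied).
random_rf <- function(mk, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(mk)
  rf <- matrix(0, m, m, dimnames = list(mk, mk))
  v <- runif(m * (m - 1) / 2, 0.01, 0.5)
  rf[upper.tri(rf)] <- v
  rf <- rf + t(rf)
  syncmap:::new_rf_matrix(rf, matrix(1000L, m, m, dimnames = list(mk, mk)))
}

# Consensus problem from explicit per-dataset marker sets and rf
# matrices (dummy genotypes; only names and rf are used downstream).
toy_problem <- function(markers_list, rf_list, weights = NULL) {
  datasets <- lapply(seq_along(markers_list), function(i) {
    geno <- matrix(0L, length(markers_list[[i]]), 2,
                   dimnames = list(markers_list[[i]], NULL))
    map_dataset(geno, "F2", id = i)
  })
  consensus_problem(datasets, weights = weights, rf = rf_list)
}

# Fresh clean simulated single dataset + its rf.
sim_one <- function(n_markers = 12, n = 200, seed = 1, cross = "F2", ...) {
  tm <- draw_true_map(n_markers, rng_seed = seed, ...)
  ds <- simulate_population(tm, cross, n, rng_seed = seed + 1)
  list(tm = tm, ds = ds, rf = build_rf_matrix(ds))
}

# Map-like whole-problem instances: rf derived from jittered true
# positions per dataset, so the skeleton and full criteria correlate as
# they do on mapping data.
small_problem <- function(seed, n_datasets = 2, k = 4, n_uniq = 2,
                          jitter = 0.25) {
  set.seed(seed)
  shared <- paste0("s", seq_len(k))
  n_tot <- k + n_uniq
  base_pos <- sort(runif(n_tot, 0, 12 * n_tot))
  markers_list <- list()
  rf_list <- list()
  for (i in seq_len(n_datasets)) {
    uniq <- if (n_uniq) paste0("u", i, "_", seq_len(n_uniq)) else character(0)
    slots <- sample(n_tot)
    mk <- character(n_tot)
    mk[sort(slots[seq_len(k)])] <- shared
    mk[setdiff(seq_len(n_tot), sort(slots[seq_len(k)]))] <- uniq
    pos <- base_pos * exp(rnorm(1, 0, 0.1))
    names(pos) <- mk
    rf <- rf_from_positions(pos)
    noise <- matrix(exp(rnorm(n_tot^2, 0, jitter)), n_tot)
    noise <- (noise + t(noise)) / 2
    rf$rf <- pmin(pmax(rf$rf * noise, 0), 0.5)
    diag(rf$rf) <- 0
    markers_list[[i]] <- mk
    rf_list[[i]] <- rf
  }
  toy_problem(markers_list, rf_list)
}
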