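test_that("ordering recovers the unique 3-marker optimum", {
  rf <- random_rf(c("a", "b", "c"))
  rf$rf[] <- 0
  rf$rf["a", "b"] <- rf$rf["b", "a"] <- 0.1
  rf$rf["b", "c"] <- rf$rf["c", "b"] <- 0.1
  rf$rf["a", "c"] <- rf$rf["c", "a"] <- 0.2
  for (solver in c("exact", "heuristic")) {
    m <- order_single(rf, solver)
    expect_equal(m$order, c("a", "b", "c"))
    expect_equal(m$length_S, 0.2)
  }
})

test_that("Held-Karp equals the exhaustive permutation minimum", {
  for (s in 1:8) {
    mk <- paste0("m", 1:6)
    rf <- random_rf(mk, seed = 60 + s)
    m <- order_single(rf, "exact")
    expect_equal(m$length_S, oracle_best_path(mk, rf$rf), tolerance = 1e-6)
  }
  expect_error(order_single(random_rf(paste0("x", 1:17), seed = 1), "exact"),
               "16 markers")
})

test_that("the heuristic matches the exact optimum on most random instances and never beats it", {
  n_equal <- 0
  n_runs <- 60
  for (s in seq_len(n_runs)) {
    mk <- paste0("m", 1:9)
    rf <- random_rf(mk, seed = 200 + s)
    he <- order_single(rf, "heuristic", rng_seed = s, iters = 150)
    ex <- order_single(rf, "exact")
    expect_gte(he$length_S, ex$length_S - 1e-9)
    if (he$length_S <= ex$length_S + 1e-9) n_equal <- n_equal + 1
  }
  expect_gte(n_equal / n_runs, 0.95)
})

test_that("clean simulated 50-marker maps are recovered near-perfectly", {
  # the heuristic must reach at least the true order's criterion value,
  # and any residual deviations are local (high recovery coefficient)
  for (s in 1:3) {
    p <- make_problem(n_markers = 50, n_datasets = 1, n_individuals = 100,
                      rng_seed = 70 + s)
    m <- order_single(p$rf[[1]], "heuristic", rng_seed = s, iters = 200)
    truth <- attr(p, "ground_truth")$true_order
    expect_lte(m$length_S, map_length(truth, p$rf[[1]])$length_S + 1e-9)
    expect_gte(recovery_coefficient(m$order, truth), 0.85)
  }
})

test_that("jackknife stability is high for clean data and flags a planted noise marker", {
  sim <- sim_one(n_markers = 10, n = 400, seed = 81, frac_short = 0,
                 long_range = c(8, 15))
  base <- order_single(sim$rf, "heuristic", rng_seed = 1)
  st <- jackknife_stability(sim$ds, base, n_replicates = 15,
                            drop_fraction = 0.2, rng_seed = 2)
  expect_true(all(st$frequency >= 0 & st$frequency <= 1))
  expect_gt(mean(st$frequency), 0.9)

  # plant an unlinked marker: its neighborhood cannot be stable
  ds2 <- sim$ds
  set.seed(5)
  noise_row <- matrix(sample(0:2, ds2$n_ind, replace = TRUE,
                             prob = c(.25, .5, .25)), 1)
  rownames(noise_row) <- "junk"
  ds2$geno <- rbind(ds2$geno, noise_row)
  ds2$markers <- rownames(ds2$geno)
  base2 <- order_single(build_rf_matrix(ds2), "heuristic", rng_seed = 1)
  st2 <- jackknife_stability(ds2, base2, n_replicates = 15,
                             drop_fraction = 0.2, rng_seed = 3)
  expect_lt(st2$frequency["junk"], min(1, mean(st2$frequency[sim$ds$markers]) + 0.05))

  expect_error(jackknife_stability(sim$ds, base, n_replicates = 0), ">= 1")
  expect_error(jackknife_stability(sim$ds, base, drop_fraction = 1.2),
               "drop_fraction")
})

test_that("skeleton filter removes absolutely linked twins but keeps shared markers", {
  sim <- sim_one(n_markers = 6, n = 150, seed = 91)
  ds <- sim$ds
  twin <- ds$geno[3, , drop = FALSE]
  rownames(twin) <- "twin"
  ds$geno <- rbind(ds$geno, twin)
  ds$markers <- rownames(ds$geno)
  rf <- build_rf_matrix(ds)
  mp <- order_single(rf, "heuristic", rng_seed = 1)
  # unique twin: one of the two rf-0 markers goes
  fl <- skeleton_filter(ds, mp, rf, consensus_mode = TRUE,
                        shared = sim$ds$markers)
  expect_true("twin" %in% fl$removed$marker)
  expect_true(all(fl$removed$rule == "absolute_linkage"))
  # same marker shared: retained unless linked to another *shared* marker
  fl2 <- skeleton_filter(ds, mp, rf, consensus_mode = TRUE,
                         shared = c(sim$ds$markers, "twin"))
  expect_equal(sum(fl2$removed$rule == "absolute_linkage"), 1)
})

test_that("clean data passes the skeleton filter untouched", {
  sim <- sim_one(n_markers = 12, n = 300, seed = 95)
  mp <- order_single(sim$rf, "heuristic", rng_seed = 1)
  fl <- skeleton_filter(sim$ds, mp, sim$rf)
  expect_equal(nrow(fl$removed), 0)
  expect_identical(fl$map$order, mp$order)
})

test_that("unstable markers are removed unless shared in consensus mode", {
  sim <- sim_one(n_markers = 5, n = 150, seed = 97)
  mp <- order_single(sim$rf, "heuristic", rng_seed = 1)
  stab <- structure(list(frequency = setNames(c(1, 1, 0.3, 1, 1), mp$order),
                         n_replicates = 50L, drop_fraction = 0.2),
                    class = "stability_report")
  low <- mp$order[3]
  fl <- skeleton_filter(sim$ds, mp, sim$rf, stability = stab,
                        consensus_mode = TRUE, shared = character(0),
                        stability_threshold = 0.7)
  expect_true(low %in% fl$removed$marker)
  fl2 <- skeleton_filter(sim$ds, mp, sim$rf, stability = stab,
                         consensus_mode = TRUE, shared = low,
                         stability_threshold = 0.7)
  expect_false(low %in% fl2$removed$marker)
})
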