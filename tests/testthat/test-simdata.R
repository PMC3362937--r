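test_that("true-map intervals follow the configured mixture", {
  tm <- draw_true_map(20, frac_short = 1, short_range = c(1, 1), rng_seed = 1)
  expect_equal(tm$intervals_cM, rep(1, 19))

  tm1 <- draw_true_map(50, rng_seed = 7)
  tm2 <- draw_true_map(50, rng_seed = 7)
  tm3 <- draw_true_map(50, rng_seed = 8)
  expect_identical(tm1$intervals_cM, tm2$intervals_cM)
  expect_false(identical(tm1$intervals_cM, tm3$intervals_cM))
  expect_true(all(tm1$intervals_cM >= 1 & tm1$intervals_cM <= 20))

  # expected total length 49 * (0.75*2.5 + 0.25*12) = 238.9 cM
  set.seed(99)
  tot <- replicate(120, sum(draw_true_map(50)$intervals_cM))
  expect_lt(abs(mean(tot) - 238.9), 3 * sd(tot) / sqrt(length(tot)))

  expect_error(draw_true_map(1), "at least 2")
  expect_error(draw_true_map(10, short_range = c(4, 1)), "invalid")
})

test_that("zero-length intervals give identical genotype columns", {
  tm <- list(markers = c("a", "b"), intervals_cM = 0)
  for (cross in c("F2", "BC", "RIL")) {
    ds <- simulate_population(tm, cross, 50, rng_seed = 3)
    expect_identical(ds$geno["a", ], ds$geno["b", ])
  }
})

test_that("F2 recombination and segregation match theory", {
  tm <- list(markers = c("a", "b"), intervals_cM = 10)
  ds <- simulate_population(tm, "F2", 10000, rng_seed = 5)
  est <- rf_f2_codominant(ds$geno["a", ], ds$geno["b", ])
  r_true <- haldane(10)
  se <- sqrt(r_true * (1 - r_true) / (2 * 10000))  # ~2N informative meioses
  expect_lt(abs(est$rf - r_true), 3 * se + 0.003)

  ds2 <- simulate_population(list(markers = c("a", "b"), intervals_cM = 50),
                             "F2", 1000, rng_seed = 6)
  tab <- table(factor(ds2$geno["a", ], 0:2))
  p <- suppressWarnings(stats::chisq.test(tab, p = c(.25, .5, .25))$p.value)
  expect_gt(p, 0.001)
})

test_that("RIL genotypes reflect the 2r/(1+2r) fixed-line expansion", {
  tm <- list(markers = c("a", "b"), intervals_cM = 20)
  r <- haldane(20)
  ds <- simulate_population(tm, "RIL", 8000, rng_seed = 9)
  R_obs <- mean(ds$geno["a", ] != ds$geno["b", ])
  R_exp <- 2 * r / (1 + 2 * r)
  expect_lt(abs(R_obs - R_exp), 3 * sqrt(R_exp * (1 - R_exp) / 8000))
  est <- rf_ril(ds$geno["a", ], ds$geno["b", ])
  expect_lt(abs(est$rf - r), 0.02)
})

test_that("apply_noise is an identity at zero rates and calibrated otherwise", {
  sim <- sim_one(n_markers = 10, n = 150, seed = 11)
  same <- apply_noise(sim$ds, noise_spec(), rng_seed = 1)
  expect_identical(same$geno, sim$ds$geno)
  expect_equal(nrow(attr(same, "change_log")), 0)

  tm <- draw_true_map(50, rng_seed = 12)
  ds <- simulate_population(tm, "F2", 150, rng_seed = 13)
  nds <- apply_noise(ds, noise_spec(missing_rate = 0.4), rng_seed = 14)
  p_obs <- mean(is.na(nds$geno))
  se <- sqrt(0.4 * 0.6 / length(nds$geno))
  expect_lt(abs(p_obs - 0.4), 3 * se)

  # informative pair size under 40% missing at N = 150: about 54-56
  rf <- build_rf_matrix(nds)
  expect_gt(mean(rf$n[upper.tri(rf$n)]), 48)
  expect_lt(mean(rf$n[upper.tri(rf$n)]), 60)
})

test_that("misclassification only touches the configured stratum", {
  sim <- sim_one(n_markers = 20, n = 100, seed = 21)
  spec <- noise_spec(error_locus_fraction = 0.2,
                     error_individual_fraction = 0.1,
                     h_to_a = 0.5, h_to_b = 0.5, a_to_h = 1, b_to_h = 1)
  out <- apply_noise(sim$ds, spec, rng_seed = 2)
  log <- attr(out, "change_log")
  expect_gt(nrow(log), 0)
  expect_lte(length(unique(log$marker)), 4)      # 20% of 20 loci
  expect_lte(length(unique(log$individual)), 10) # 10% of 100 individuals
  untouched <- setdiff(rownames(sim$ds$geno), unique(log$marker))
  expect_identical(out$geno[untouched, ], sim$ds$geno[untouched, ])
})

test_that("make_problem builds the shared registry and naming convention", {
  p <- make_problem(n_markers = 12, n_datasets = 3, n_individuals = 40,
                    shared_fraction = 1, rng_seed = 31)
  expect_false(any(grepl("_", attr(p, "ground_truth")$true_order)))
  expect_equal(length(p$shared), 12)

  mask <- matrix(TRUE, 8, 3)
  mask[2, 2:3] <- FALSE   # marker 2 unique to dataset 1
  mask[5, c(1, 3)] <- FALSE
  p2 <- make_problem(n_markers = 8, n_datasets = 3, n_individuals = 40,
                     shared_mask = mask, rng_seed = 32)
  expect_setequal(p2$shared, attr(p2, "ground_truth")$true_order[-c(2, 5)])
  expect_true("mar2_1" %in% p2$datasets[[1]]$markers)
  expect_false("mar2_1" %in% p2$datasets[[2]]$markers)
  expect_equal(sort(unname(p2$registry[["mar1"]])), 1:3)
})

test_that("a simulated problem round-trips through file I/O", {
  p <- make_problem(n_markers = 10, n_datasets = 3, n_individuals = 30,
                    noise = noise_spec(missing_rate = 0.2),
                    shared_fraction = 0.6, rng_seed = 33)
  dir <- tempfile("simprob")
  man <- write_problem(p, dir)
  p2 <- read_manifest(man)
  expect_equal(length(p2$datasets), 3)
  for (i in 1:3) {
    expect_equal(unname(p2$datasets[[i]]$geno), unname(p$datasets[[i]]$geno))
    expect_identical(rownames(p2$datasets[[i]]$geno),
                     rownames(p$datasets[[i]]$geno))
  }
  expect_setequal(p2$shared, p$shared)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_identical(gt$true_order, attr(p, "ground_truth")$true_order)
})
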