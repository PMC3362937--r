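# (small_problem and oracle_consensus live in the helpers)

test_that("the mutation generator is an identity at zero rates and stays a permutation", {
  g <- paste0("s", 1:10)
  p0 <- ges_params(rev_rate = 0, trans_rate = 0, swap_rate = 0)
  set.seed(1)
  expect_identical(mutate_order(g, p0), g)
  p <- ges_params()
  set.seed(2)
  for (i in 1:50) {
    g2 <- mutate_order(g, p)
    expect_setequal(g2, g)
    expect_length(g2, 10)
  }
})

test_that("a length-2 reversal is exactly one adjacent transposition", {
  g <- paste0("s", 1:8)
  p <- ges_params(rev_rate = 1, rev_len_mean = 1, trans_rate = 0,
                  swap_rate = 0, site_bias = 0)
  set.seed(3)
  for (i in 1:20) {
    g2 <- mutate_order(g, p)
    d <- which(g2 != g)
    expect_length(d, 2)
    expect_equal(diff(d), 1)
    expect_identical(g2[d], g[rev(d)])
  }
})

test_that("segment lengths follow the configured geometric law", {
  set.seed(4)
  draws <- replicate(4000, syncmap:::seg_len_draw(3, 1000))
  # law: 1 + Geometric(p = 1/3)
  p <- 1 / 3
  k <- 1:12
  expected <- dgeom(k - 1, p)
  obs <- tabulate(pmin(draws, 13), nbins = 13)[1:12]
  expected <- expected / sum(dgeom(0:11, p))
  chi <- suppressWarnings(chisq.test(obs, p = expected, rescale.p = TRUE))
  expect_gt(chi$p.value, 0.001)
})

test_that("place_unique embeds the shared order and finds optimal single insertions", {
  prob <- small_problem(11, n_datasets = 1, k = 4, n_uniq = 0)
  g <- paste0("s", c(2, 4, 1, 3))
  m <- place_unique(g, prob$datasets[[1]], prob$rf[[1]])
  expect_identical(m$order, g)

  # one unique marker, 4 anchors: equals the best of the 5 slots
  prob1 <- small_problem(12, n_datasets = 2, k = 4, n_uniq = 1)
  g <- paste0("s", 1:4)
  m1 <- place_unique(g, prob1$datasets[[1]], prob1$rf[[1]])
  rfm <- prob1$rf[[1]]$rf
  slots <- vapply(0:4, function(pos)
    oracle_path_cost(append(g, "u1_1", after = pos), rfm), numeric(1))
  expect_equal(m1$length_S, min(slots))
})

test_that("anchored placement matches the exact insertion optimum on most small instances", {
  n_match <- 0; n_runs <- 40
  for (s in seq_len(n_runs)) {
    prob <- small_problem(1000 + s, n_datasets = 1, k = 3,
                          n_uniq = sample(2:3, 1))
    g <- sample(paste0("s", 1:3))
    m <- place_unique(g, prob$datasets[[1]], prob$rf[[1]])
    uniq <- setdiff(prob$datasets[[1]]$markers, g)
    opt <- min(vapply(enumerate_embeddings(g, uniq), oracle_path_cost,
                      numeric(1), rfm = prob$rf[[1]]$rf))
    expect_gte(m$length_S, opt - 1e-9)
    if (m$length_S <= opt + 1e-9) n_match <- n_match + 1
    emb <- m$order[m$order %in% g]
    expect_identical(emb, g)
  }
  expect_gte(n_match / n_runs, 0.9)
})

test_that("GES matches the exact consensus optimum on solvable instances and never beats it", {
  n_eq <- 0; n_runs <- 25
  for (s in seq_len(n_runs)) {
    prob <- small_problem(2000 + s, n_datasets = 2, k = 4, n_uniq = 2)
    opt <- oracle_consensus(prob)
    fit <- ges_consensus(prob, params = ges_params(seed = s, max_iter = 150,
                                                   stall_limit = 80))
    expect_gte(fit$S_total, opt - 1e-9)
    if (fit$S_total <= opt + 1e-9) n_eq <- n_eq + 1
    # anytime monotonicity of the incumbent
    expect_true(all(diff(fit$trace) <= 1e-12))
    # feasibility: common shared order embedded everywhere
    for (i in 1:2) {
      emb <- fit$maps[[i]]$order[fit$maps[[i]]$order %in% prob$shared]
      expect_identical(emb, fit$shared_order[fit$shared_order %in% emb])
    }
  }
  expect_gte(n_eq / n_runs, 0.9)
})

test_that("the skeleton screen prunes full evaluations", {
  prob <- small_problem(3000, n_datasets = 3, k = 6, n_uniq = 3)
  fit <- ges_consensus(prob, params = ges_params(seed = 9, max_iter = 300,
                                                 stall_limit = 300))
  st <- fit$eval_stats
  expect_gt(st["screened"], 0)
  expect_lt(st["evaluated"] / st["screened"], 0.5)
})

test_that("GES keeps an already-optimal start unchanged", {
  prob <- small_problem(4000, n_datasets = 2, k = 3, n_uniq = 1)
  # exact optimum by enumeration
  opt <- oracle_consensus(prob)
  best_g <- NULL
  for (g in all_perms(prob$shared)) {
    tot <- 0
    for (i in 1:2) {
      uniq <- setdiff(prob$datasets[[i]]$markers, prob$shared)
      tot <- tot + min(vapply(enumerate_embeddings(g[g %in% prob$datasets[[i]]$markers], uniq),
                              oracle_path_cost, numeric(1),
                              rfm = prob$rf[[i]]$rf))
    }
    if (abs(tot - opt) < 1e-12 && is.null(best_g)) best_g <- g
  }
  fit <- ges_consensus(prob, g_star = best_g,
                       params = ges_params(seed = 2, max_iter = 100))
  expect_equal(fit$S_total, opt, tolerance = 1e-9)
})
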