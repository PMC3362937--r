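# Random constrained instances for the region solver.
random_region_instance <- function(seed, n_datasets = 2, k = 3, n_max = 2) {
  set.seed(seed)
  shared <- paste0("s", seq_len(k))
  flanks <- c("FL", "FR")
  uniq <- lapply(seq_len(n_datasets), function(i) {
    n_i <- sample(0:n_max, 1)
    if (n_i) paste0("u", i, "_", seq_len(n_i)) else character(0)
  })
  markers_list <- lapply(seq_len(n_datasets), function(i)
    c("FL", shared, uniq[[i]], "FR"))
  rf_list <- lapply(seq_len(n_datasets), function(i)
    random_rf(markers_list[[i]], seed = seed * 100 + i))
  prob <- toy_problem(markers_list, rf_list,
                      weights = runif(n_datasets, 0.5, 2))
  ids <- seq_len(n_datasets)
  region <- conflict_region(
    shared, ids,
    flank_left = setNames(rep("FL", n_datasets), ids),
    flank_right = setNames(rep("FR", n_datasets), ids),
    uniq = setNames(uniq, ids))
  list(region = region, problem = prob)
}

test_that("complexity formulas match the printed closed forms", {
  rg <- conflict_region(paste0("s", 1:4), 1L,
                        flank_left = c(`1` = "FL"),
                        flank_right = c(`1` = "FR"),
                        uniq = list(`1` = paste0("u", 1:10)))
  cx <- estimate_complexity(rg)
  expect_equal(unname(cx$stage1_entries), 1024 * 14)   # 2^10 ((4+2)(4+1)/2 - 1)
  expect_equal(cx$stage2_combinations, 24 * 5^10)      # 4! * 5^10
  expect_true(cx$feasible)

  rg0 <- conflict_region(paste0("s", 1:5), 1L,
                         flank_left = c(`1` = "FL"),
                         flank_right = c(`1` = "FR"),
                         uniq = list(`1` = character(0)))
  expect_equal(estimate_complexity(rg0)$stage2_combinations, factorial(5))

  rg_big <- conflict_region(paste0("s", 1:6), 1L,
                            flank_left = c(`1` = "FL"),
                            flank_right = c(`1` = "FR"),
                            uniq = list(`1` = paste0("u", 1:9)))
  expect_false(estimate_complexity(rg_big)$feasible)
})

test_that("stage-1 table size matches direct enumeration of stored entries", {
  for (s in 1:5) {
    inst <- random_region_instance(s, n_datasets = 1, k = sample(2:4, 1),
                                   n_max = 3)
    tables <- build_insertion_tables(inst$region, inst$problem)
    cx <- estimate_complexity(inst$region)
    counted <- table_entry_count(tables, inst$region, 1)
    expect_equal(counted, unname(cx$stage1_entries[1]))
  }
})

test_that("insertion-table entries equal factorial-oracle path minima", {
  inst <- random_region_instance(11, n_datasets = 1, k = 2, n_max = 0)
  inst$region$uniq[["1"]] <- paste0("u1_", 1:3)
  inst$region$n_unique <- c(`1` = 3L)
  mk <- c("FL", paste0("s", 1:2), "u1_1", "u1_2", "u1_3", "FR")
  rf <- random_rf(mk, seed = 1111)
  inst$problem <- toy_problem(list(mk), list(rf))
  tables <- build_insertion_tables(inst$region, inst$problem)
  tb <- tables[["1"]]
  rfm <- rf$rf
  # empty subset: entry is the direct rf
  expect_equal(syncmap:::entry_cost(tb, "FL", "s1", 0L), rfm["FL", "s1"])
  # full subset between each anchor pair vs explicit 3! permutations
  full <- 7L
  for (a in tb$anchors) for (b in tb$anchors) {
    if (a == b) next
    perms <- all_perms(tb$uniq)
    o <- min(vapply(perms, function(p)
      oracle_path_cost(c(a, p, b), rfm), numeric(1)))
    expect_equal(syncmap:::entry_cost(tb, a, b, full), o)
  }
})

test_that("solve_region equals exhaustive constrained enumeration", {
  for (s in 1:25) {
    nd <- sample(2:3, 1)
    inst <- random_region_instance(300 + s, n_datasets = nd,
                                   k = sample(2:3, 1), n_max = 2)
    if (inst$region$k + sum(inst$region$n_unique) > 7) next
    sol <- solve_region(inst$region, inst$problem)
    orc <- oracle_region(inst$region, inst$problem)
    expect_equal(sol$total, orc, tolerance = 1e-9)
    # every per-dataset suborder embeds the same shared order
    for (key in names(sol$orders)) {
      emb <- sol$orders[[key]][sol$orders[[key]] %in% inst$region$shared]
      gi <- sol$shared_order[sol$shared_order %in% emb]
      expect_identical(emb, gi)
    }
  }
})

test_that("regions with free ends (linkage-group boundary) solve exactly", {
  for (s in 1:8) {
    inst <- random_region_instance(500 + s, n_datasets = 2, k = 2, n_max = 1)
    inst$region$flank_left[] <- NA_character_
    sol <- solve_region(inst$region, inst$problem)
    orc <- oracle_region(inst$region, inst$problem)
    expect_equal(sol$total, orc, tolerance = 1e-9)
  }
})

test_that("solving a conflict-free region returns the incumbent at zero extra cost", {
  pos <- c(FL = 0, s1 = 10, s2 = 20, FR = 30)
  rf <- rf_from_positions(pos)
  prob <- toy_problem(rep(list(names(pos)), 2), list(rf, rf))
  rg <- conflict_region(c("s1", "s2"), 1:2,
                        flank_left = c(`1` = "FL", `2` = "FL"),
                        flank_right = c(`1` = "FR", `2` = "FR"),
                        uniq = list(`1` = character(0), `2` = character(0)),
                        phase1_suborders = list(c("s1", "s2"), c("s1", "s2")))
  sol <- solve_region(rg, prob)
  expect_identical(sol$shared_order, c("s1", "s2"))
  expect_equal(sol$total,
               2 * oracle_path_cost(names(pos), rf$rf))
})

test_that("consensus cost per dataset is never below its unconstrained region optimum", {
  for (s in 1:10) {
    inst <- random_region_instance(700 + s, n_datasets = 2, k = 3, n_max = 1)
    sol <- solve_region(inst$region, inst$problem)
    for (i in 1:2) {
      mk <- inst$problem$datasets[[i]]$markers
      rfm <- inst$problem$rf[[i]]$rf
      inner <- setdiff(mk, c("FL", "FR"))
      unconstrained <- oracle_best_path(mk, rfm, first = "FL", last = "FR")
      expect_gte(sol$costs[[as.character(i)]], unconstrained - 1e-9)
    }
  }
})

test_that("region solving is pure: identical output on repeated calls", {
  inst <- random_region_instance(901, n_datasets = 2, k = 3, n_max = 2)
  s1 <- solve_region(inst$region, inst$problem)
  s2 <- solve_region(inst$region, inst$problem)
  expect_identical(s1, s2)
})

test_that("oversized regions are refused with a feasibility error", {
  rg <- conflict_region(paste0("s", 1:12), 1L,
                        flank_left = c(`1` = "FL"),
                        flank_right = c(`1` = "FR"),
                        uniq = list(`1` = character(0)))
  prob <- toy_problem(list(c("FL", paste0("s", 1:12), "FR")),
                      list(random_rf(c("FL", paste0("s", 1:12), "FR"), 1)))
  expect_error(solve_region(rg, prob), class = "syncmap_infeasible")
  expect_error(build_insertion_tables(rg, prob), class = "syncmap_infeasible")
})
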