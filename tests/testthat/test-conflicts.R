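test_that("pairwise conflicts are detected after orientation alignment", {
  expect_equal(nrow(detect_conflicts(list(c("a", "b", "c"), c("a", "b", "c")),
                                     shared = c("a", "b", "c"))), 0)
  # reversal alone is not a conflict
  expect_equal(nrow(detect_conflicts(list(c("a", "b", "c"), c("c", "b", "a")),
                                     shared = c("a", "b", "c"))), 0)
  cf <- detect_conflicts(list(c("x", "a", "b", "y"), c("x", "b", "a", "y")),
                         shared = c("x", "a", "b", "y"))
  expect_equal(nrow(cf), 1)
  expect_setequal(c(cf$marker_a, cf$marker_b), c("a", "b"))
  expect_warning(detect_conflicts(list(c("a", "b"), c("c", "d")),
                                  shared = c("a", "b", "c", "d")),
                 "skipped")
})

test_that("conflict counts agree with the brute-force oracle on random maps", {
  set.seed(7)
  mk <- paste0("m", 1:8)
  for (rep in 1:15) {
    orders <- lapply(1:3, function(i) {
      o <- mk
      # perturb a few local swaps so instances are near-consistent
      for (k in 1:2) {
        j <- sample(7, 1)
        o[c(j, j + 1)] <- o[c(j + 1, j)]
      }
      if (runif(1) < 0.5) rev(o) else o
    })
    cf <- detect_conflicts(orders, shared = mk, warn = FALSE)
    expect_equal(attr(cf, "n_conflict_pairs"),
                 oracle_conflict_count(orders, mk))
  }
})

test_that("overlapping conflicts merge into one region; disjoint conflicts stay apart", {
  shared <- c("a", "b", "c", "d", "e")
  maps <- list(c("a", "b", "c", "d", "e"),
               c("b", "a", "c", "d", "e"),
               c("a", "c", "d", "b", "e"))
  cf <- detect_conflicts(maps, shared = shared, warn = FALSE)
  rg <- delineate_regions(maps, cf, shared = shared)
  expect_length(rg, 1)
  expect_setequal(rg[[1]]$shared, c("a", "b", "c", "d"))
  # right flank is e everywhere; left end touches the group boundary
  expect_true(all(rg[[1]]$flank_right == "e"))
  expect_true(all(is.na(rg[[1]]$flank_left)))

  maps2 <- list(c("a", "b", "c", "d", "e"),
                c("b", "a", "c", "e", "d"))
  cf2 <- detect_conflicts(maps2, shared = shared, warn = FALSE)
  rg2 <- delineate_regions(maps2, cf2, shared = shared)
  expect_length(rg2, 2)
  sets <- lapply(rg2, `[[`, "shared")
  expect_true(any(vapply(sets, setequal, TRUE, y = c("a", "b"))))
  expect_true(any(vapply(sets, setequal, TRUE, y = c("d", "e"))))
})

test_that("unique markers inside the window join the region", {
  shared <- c("s1", "s2", "s3", "s4")
  maps <- list(c("s1", "u1", "s2", "s3", "s4"),
               c("s1", "s3", "u2", "s2", "s4"))
  cf <- detect_conflicts(maps, shared = shared, warn = FALSE)
  rg <- delineate_regions(maps, cf, shared = shared)
  expect_length(rg, 1)
  expect_setequal(rg[[1]]$shared, c("s2", "s3"))
  expect_equal(rg[[1]]$flank_left[["1"]], "s1")
  expect_equal(rg[[1]]$flank_right[["1"]], "s4")
  expect_setequal(syncmap:::region_uniq(rg[[1]], 1), "u1")
  expect_setequal(syncmap:::region_uniq(rg[[1]], 2), "u2")
  # every conflict pair lies inside exactly one region
  for (t in seq_len(nrow(cf)))
    expect_equal(sum(vapply(rg, function(r)
      all(c(cf$marker_a[t], cf$marker_b[t]) %in% r$shared), logical(1))), 1L)
})

test_that("inversion across a large gap is corrected when it removes conflicts", {
  # true arrangement a b c d e f; dataset 2 has the distal part beyond a
  # 0.31-rf gap reversed
  pos <- c(a = 0, b = 5, c = 10, d = 60, e = 65, f = 70)
  rf1 <- rf_from_positions(pos)
  rf2 <- rf_from_positions(pos)
  maps <- list(map_length(names(pos), rf1, dataset_id = 1),
               map_length(c("a", "b", "c", "f", "e", "d"), rf2, dataset_id = 2))
  expect_gte(maps[[2]]$adjacent_rf[3], 0.3)
  before <- attr(detect_conflicts(maps, shared = names(pos), warn = FALSE),
                 "n_conflict_pairs")
  expect_gt(before, 0)
  out <- pre_correct(maps, list(rf1, rf2), shared = names(pos))
  after <- attr(detect_conflicts(out$maps, shared = names(pos), warn = FALSE),
                "n_conflict_pairs")
  expect_equal(after, 0)
  expect_gt(nrow(out$log), 0)
  expect_lte(out$maps[[2]]$length_S, maps[[2]]$length_S + 0.02 + 1e-9)
})

test_that("maps without large gaps pass pre-correction unchanged", {
  pos <- c(a = 0, b = 5, c = 12, d = 20)
  rf <- rf_from_positions(pos)
  maps <- list(map_length(names(pos), rf, dataset_id = 1),
               map_length(c("a", "c", "b", "d"), rf, dataset_id = 2))
  out <- pre_correct(maps, list(rf, rf), shared = names(pos))
  expect_identical(out$maps[[2]]$order, c("a", "c", "b", "d"))
  expect_equal(nrow(out$log), 0)
})

test_that("transposition across a loose interval is found by the move search", {
  # dataset 2 carries segment (d e) translocated to the front past a
  # large gap; moving it back resolves all conflicts
  pos <- c(a = 0, b = 4, c = 8, d = 70, e = 74)
  rf <- rf_from_positions(pos)
  maps <- list(map_length(names(pos), rf, dataset_id = 1),
               map_length(c("d", "e", "a", "b", "c"), rf, dataset_id = 2))
  out <- pre_correct(maps, list(rf, rf), shared = names(pos))
  after <- attr(detect_conflicts(out$maps, shared = names(pos), warn = FALSE),
                "n_conflict_pairs")
  expect_equal(after, 0)
})
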