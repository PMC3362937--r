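# Independent brute-force oracles, deliberately written without reusing
# the package's internal algorithms.

oracle_path_cost <- function(ord, rfm) {
  s <- 0
  for (j in seq_along(ord)[-1]) s <- s + rfm[ord[j - 1], ord[j]]
  s
}

all_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in all_perms(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
  out
}

# Minimum open-path length over all permutations (optionally with fixed
# first/last elements).
oracle_best_path <- function(mk, rfm, first = NULL, last = NULL) {
  free <- setdiff(mk, c(first, last))
  best <- Inf
  for (p in all_perms(free)) {
    ord <- c(first, p, last)
    best <- min(best, oracle_path_cost(ord, rfm))
  }
  best
}

# All interleavings of `uniq` (any internal order) into a fixed anchor
# sequence, preserving the anchor order.
enumerate_embeddings <- function(anchors, uniq) {
  if (!length(uniq)) return(list(anchors))
  out <- list()
  for (i in seq_along(uniq)) {
    sub <- enumerate_embeddings(anchors, uniq[-i])
    for (s in sub) {
      for (pos in 0:length(s)) {
        cand <- append(s, uniq[i], after = pos)
        # keep anchor order intact (always true for insertions)
        out[[length(out) + 1]] <- cand
      }
    }
  }
  unique(out)
}

# Exhaustive constrained enumeration for a conflict region: all shared
# orders x all per-dataset unique-marker interleavings (flanks frozen
# where present).  Returns the minimal weighted total.
oracle_region <- function(region, problem) {
  w <- problem$weights
  best <- Inf
  for (g_r in all_perms(region$shared)) {
    total <- 0
    for (i in seq_along(problem$datasets)) {
      mk <- problem$datasets[[i]]$markers
      fl <- syncmap:::region_flank(region, i, "left")
      fr <- syncmap:::region_flank(region, i, "right")
      anchors <- c(if (!is.na(fl)) fl, g_r[g_r %in% mk], if (!is.na(fr)) fr)
      uniq <- syncmap:::region_uniq(region, i)
      if (!length(anchors) && !length(uniq)) next
      rfm <- problem$rf[[i]]$rf
      sub_best <- Inf
      if (!length(anchors)) {
        for (p in all_perms(uniq))
          sub_best <- min(sub_best, oracle_path_cost(p, rfm))
      } else {
        for (emb in enumerate_embeddings(anchors, uniq)) {
          # frozen flanks: nothing may be placed outside them
          if (!is.na(fl) && emb[1] != fl) next
          if (!is.na(fr) && emb[length(emb)] != fr) next
          sub_best <- min(sub_best, oracle_path_cost(emb, rfm))
        }
      }
      total <- total + w[i] * sub_best
    }
    best <- min(best, total)
  }
  best
}

# Quadratic all-pairs conflict scan with exhaustive orientation search
# (pick the orientation assignment minimizing total discordance, then
# count remaining discordant shared pairs).
oracle_conflict_count <- function(orders, shared) {
  P <- length(orders)
  proj <- lapply(orders, function(o) o[o %in% shared])
  best <- Inf
  for (mask in 0:(2^(P - 1) - 1)) {
    flip <- c(FALSE, as.logical(bitwAnd(bitwShiftL(1L, 0:(P - 2)), mask)))
    pr <- lapply(seq_len(P), function(i) if (flip[i]) rev(proj[[i]]) else proj[[i]])
    cnt <- 0
    for (i in seq_len(P - 1)) for (j in (i + 1):P) {
      common <- intersect(pr[[i]], pr[[j]])
      if (length(common) < 2) next
      for (a in seq_along(common)[-1]) for (b in seq_len(a - 1)) {
        da <- match(common[a], pr[[i]]) - match(common[b], pr[[i]])
        db <- match(common[a], pr[[j]]) - match(common[b], pr[[j]])
        if (sign(da) != sign(db)) cnt <- cnt + 1
      }
    }
    best <- min(best, cnt)
  }
  best
}

# Grid-search F2 likelihood oracle on the 3x3 genotype table.
oracle_f2_grid <- function(g1, g2, grid = seq(1e-4, 0.5, length.out = 2000)) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  probs <- function(r) {
    p <- matrix(0, 3, 3)
    p[1, 1] <- p[3, 3] <- (1 - r)^2 / 4
    p[1, 3] <- p[3, 1] <- r^2 / 4
    p[1, 2] <- p[2, 1] <- p[2, 3] <- p[3, 2] <- r * (1 - r) / 2
    p[2, 2] <- ((1 - r)^2 + r^2) / 2
    p
  }
  tab <- table(factor(g1, 0:2), factor(g2, 0:2))
  ll <- vapply(grid, function(r) sum(tab * log(probs(r) + 1e-300)), numeric(1))
  grid[which.max(ll)]
}

# Exact reference for small whole-problem instances: enumerate shared
# orders x per-dataset optimal embeddings.
oracle_consensus <- function(problem) {
  best <- Inf
  for (g in all_perms(problem$shared)) {
    total <- 0
    for (i in seq_along(problem$datasets)) {
      mk <- problem$datasets[[i]]$markers
      anchors <- g[g %in% mk]
      uniq <- setdiff(mk, problem$shared)
      rfm <- problem$rf[[i]]$rf
      sub <- min(vapply(enumerate_embeddings(anchors, uniq), oracle_path_cost,
                        numeric(1), rfm = rfm))
      total <- total + problem$weights[i] * sub
    }
    best <- min(best, total)
  }
  best
}
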