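# Conflict analysis between phase-1 maps: pairwise conflict detection,
# transitive delineation of conflict regions with frozen shared flanks,
# and inversion/transposition pre-correction of maps distorted across a
# large interval.

#' Detect shared-marker conflicts between maps
#'
#' For every pair of maps, orientations are first aligned (maximizing
#' concordant shared pairs); every pair of shared markers common to both
#' maps that appears in opposite relative order is then reported.
#' Higher-order conflicts (cyclic precedence among three or more maps
#' without any pairwise conflict) are detected on the union precedence
#' graph and reported in the `"higher_order"` attribute; their markers
#' are absorbed into conflict regions by [delineate_regions()].
#'
#' @param maps list of marker orders (character vectors or `marker_map`s).
#' @param shared character vector of shared marker names; inferred as
#'   markers occurring in at least two maps when omitted.
#' @param warn warn when a pair of maps has fewer than 2 shared markers
#'   in common (the pair is skipped).
#' @return data frame with columns `marker_a`, `marker_b`, and
#'   `datasets` (list column of the dataset index pairs in conflict), one
#'   row per unordered marker pair.  Attributes: `"n_conflict_pairs"`
#'   (total over dataset pairs) and `"higher_order"`.
#' @export
detect_conflicts <- function(maps, shared = NULL, warn = TRUE) {
  orders <- extract_orders(maps)
  if (is.null(shared)) {
    occ <- table(unlist(orders))
    shared <- names(occ)[occ >= 2]
  }
  proj <- lapply(orders, function(o) o[o %in% shared])
  proj <- align_orientations(proj)
  acc <- list()
  total <- 0L
  np <- length(proj)
  if (np >= 2) {
    for (i in seq_len(np - 1)) for (j in (i + 1):np) {
      common <- intersect(proj[[i]], proj[[j]])
      if (length(common) < 2) {
        if (warn) warning(sprintf("maps %d and %d share <2 markers; skipped", i, j))
        next
      }
      pa <- match(common, proj[[i]])
      pb <- match(common, proj[[j]])
      sa <- sign(outer(pa, pa, "-"))
      sb <- sign(outer(pb, pb, "-"))
      disc <- which(sa * sb < 0 & upper.tri(sa), arr.ind = TRUE)
      total <- total + nrow(disc)
      if (nrow(disc)) {
        for (t in seq_len(nrow(disc))) {
          mm <- sort(c(common[disc[t, 1]], common[disc[t, 2]]))
          key <- paste(mm, collapse = "\r")
          acc[[key]] <- unique(c(acc[[key]], i, j))
        }
      }
    }
  }
  if (length(acc)) {
    keys <- strsplit(names(acc), "\r", fixed = TRUE)
    out <- data.frame(marker_a = vapply(keys, `[`, "", 1),
                      marker_b = vapply(keys, `[`, "", 2),
                      stringsAsFactors = FALSE)
    out$datasets <- unname(acc)
  } else {
    out <- data.frame(marker_a = character(0), marker_b = character(0),
                      stringsAsFactors = FALSE)
    out$datasets <- list()
  }
  attr(out, "n_conflict_pairs") <- total
  attr(out, "higher_order") <- higher_order_conflicts(proj, out)
  out
}

# Cycles in the union precedence graph that survive after removing the
# pairwise-conflicting pairs: strongly connected components of size >= 2.
higher_order_conflicts <- function(proj, pair_conflicts) {
  edges <- character(0)
  confl_keys <- if (nrow(pair_conflicts))
    paste(pair_conflicts$marker_a, pair_conflicts$marker_b) else character(0)
  for (p in proj) {
    if (length(p) < 2) next
    cmb <- combn(seq_along(p), 2)
    a <- p[cmb[1, ]]; b <- p[cmb[2, ]]
    key <- paste(pmin(a, b), pmax(a, b))
    keep <- !(key %in% confl_keys)
    edges <- c(edges, rbind(a[keep], b[keep]))
  }
  if (!length(edges)) return(list())
  gr <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE))
  comp <- igraph::components(gr, mode = "strong")
  sizes <- comp$csize
  big <- which(sizes >= 2)
  lapply(big, function(ci)
    names(comp$membership)[comp$membership == ci])
}

count_conflicts <- function(orders, shared) {
  attr(detect_conflicts(orders, shared = shared, warn = FALSE),
       "n_conflict_pairs")
}

#' Delineate conflict regions
#'
#' Merges overlapping pairwise-conflict spans transitively into maximal
#' regions and extends each region's boundaries to the nearest
#' non-conflicting shared marker on each side (a boundary is absent only
#' where the region reaches the end of the linkage group, in which case
#' that side remains free during solving).  Unique markers lying inside a
#' region's window in any dataset belong to the region.
#'
#' @param maps list of full marker orders (character vectors or
#'   `marker_map`s), one per dataset, assumed orientation-aligned.
#' @param conflicts result of [detect_conflicts()] on these maps.
#' @param shared shared marker names.
#' @return list of `conflict_region` objects, each with elements
#'   `shared` (region shared markers), `k`, `dataset_ids`, `flank_left`,
#'   `flank_right` (per dataset, `NA` at a free end), `uniq` (per-dataset
#'   unique markers inside the window) and `n_unique`.
#' @export
delineate_regions <- function(maps, conflicts, shared = NULL) {
  orders <- extract_orders(maps)
  if (is.null(shared)) {
    occ <- table(unlist(orders))
    shared <- names(occ)[occ >= 2]
  }
  orders <- align_orientations(orders, shared = shared)
  proj <- lapply(orders, function(o) o[o %in% shared])
  conf_markers <- unique(c(conflicts$marker_a, conflicts$marker_b,
                           unlist(attr(conflicts, "higher_order"))))
  if (!length(conf_markers)) return(list())

  # seed components: each conflicting pair is one component
  comp_of <- seq_len(nrow(conflicts))
  groups <- lapply(seq_len(nrow(conflicts)), function(t)
    c(conflicts$marker_a[t], conflicts$marker_b[t]))
  for (ho in attr(conflicts, "higher_order"))
    groups[[length(groups) + 1]] <- ho

  # closure: a group's window in each dataset sweeps in every shared
  # marker lying between its members; groups sharing a marker merge.
  repeat {
    changed <- FALSE
    for (gidx in seq_along(groups)) {
      g <- groups[[gidx]]
      for (p in proj) {
        pos <- match(g, p)
        pos <- pos[!is.na(pos)]
        if (length(pos) < 2) next
        lo <- min(pos); hi <- max(pos)
        # a boundary must be a non-conflicting marker: sweep the window
        # outward over adjacent conflict markers (they join the region,
        # forcing a merge with their own region below)
        while (lo > 1 && p[lo - 1] %in% conf_markers) lo <- lo - 1
        while (hi < length(p) && p[hi + 1] %in% conf_markers) hi <- hi + 1
        inside <- p[seq(lo, hi)]
        new <- setdiff(inside, g)
        if (length(new)) {
          groups[[gidx]] <- g <- c(g, new)
          changed <- TRUE
        }
      }
    }
    # merge groups with common markers
    gi <- 1
    while (gi < length(groups)) {
      gj <- gi + 1
      while (gj <= length(groups)) {
        if (length(intersect(groups[[gi]], groups[[gj]]))) {
          groups[[gi]] <- union(groups[[gi]], groups[[gj]])
          groups[[gj]] <- NULL
          changed <- TRUE
        } else gj <- gj + 1
      }
      gi <- gi + 1
    }
    if (!changed) break
  }

  ids <- seq_along(orders)
  regions <- lapply(groups, function(g) {
    fl <- fr <- setNames(rep(NA_character_, length(ids)), ids)
    uniq <- setNames(vector("list", length(ids)), ids)
    sub1 <- setNames(vector("list", length(ids)), ids)
    involved <- logical(length(ids))
    for (i in ids) {
      p <- proj[[i]]
      pos <- match(g, p)
      pos <- pos[!is.na(pos)]
      if (!length(pos)) { uniq[[i]] <- character(0); next }
      involved[i] <- TRUE
      lo <- min(pos); hi <- max(pos)
      if (lo > 1) fl[i] <- p[lo - 1]
      if (hi < length(p)) fr[i] <- p[hi + 1]
      sub1[[i]] <- p[lo:hi]
      # full-order window: between the flanks (or map ends)
      o <- orders[[i]]
      a <- if (is.na(fl[i])) 1L else match(fl[i], o) + 1L
      b <- if (is.na(fr[i])) length(o) else match(fr[i], o) - 1L
      inside <- if (a <= b) o[a:b] else character(0)
      uniq[[i]] <- setdiff(inside, shared)
    }
    # region order reference: the first involved dataset's suborder
    ref <- proj[[which(involved)[1]]]
    g_sorted <- g[order(match(g, ref))]
    conflict_region(g_sorted, ids[involved], fl, fr, uniq,
                    phase1_suborders = sub1[involved])
  })
  regions
}

#' @export
print.conflict_region <- function(x, ...) {
  cat(sprintf("Conflict region: k = %d shared (%s), unique per dataset: %s\n",
              x$k, paste(x$shared, collapse = ", "),
              paste(x$n_unique[as.character(x$dataset_ids)], collapse = "/")))
  invisible(x)
}

#' Inversion/transposition pre-correction of phase-1 maps
#'
#' A large interval in one map (adjacent recombination fraction at or
#' above `gap_threshold`) can carry a whole segment reversed or relocated
#' relative to the other maps, producing many pairwise conflicts.  For
#' each such gap this step tries reversing the flanking segment
#' (inversion) and relocating it to every other position in either
#' orientation (transposition); a move is accepted iff it strictly
#' reduces the total conflict-pair count and inflates that map's own
#' length by at most `length_tolerance`.
#'
#' @param maps list of `marker_map` objects (one per dataset).
#' @param rf_list list of `rf_matrix` objects matching `maps`.
#' @param shared shared marker names.
#' @param gap_threshold recombination fraction defining a "large" interval.
#' @param length_tolerance maximum accepted per-move increase of the
#'   map's own length (criterion units).
#' @return list with `maps` (corrected) and `log` (data frame of accepted
#'   operations).
#' @export
pre_correct <- function(maps, rf_list, shared = NULL, gap_threshold = 0.3,
                        length_tolerance = 0.02) {
  orders <- lapply(maps, function(m) m$order)
  if (is.null(shared)) {
    occ <- table(unlist(orders))
    shared <- names(occ)[occ >= 2]
  }
  log <- data.frame(dataset = integer(0), op = character(0),
                    gap_position = integer(0),
                    conflicts_before = integer(0), conflicts_after = integer(0),
                    stringsAsFactors = FALSE)
  base_conf <- count_conflicts(orders, shared)
  for (pass in 1:3) {
    improved <- FALSE
    for (i in seq_along(orders)) {
      ord <- orders[[i]]
      rf <- rf_list[[i]]
      len0 <- map_length(ord, rf)$length_S
      adj <- map_length(ord, rf)$adjacent_rf
      gaps <- which(adj >= gap_threshold)
      for (gpos in gaps) {
        segs <- list(suffix = (gpos + 1):length(ord), prefix = 1:gpos)
        best <- NULL
        for (sg in segs) {
          cands <- segment_moves(ord, sg)
          for (cand in cands) {
            new_orders <- orders
            new_orders[[i]] <- cand$order
            nc <- count_conflicts(new_orders, shared)
            if (nc < base_conf) {
              len1 <- map_length(cand$order, rf)$length_S
              if (len1 - len0 <= length_tolerance &&
                  (is.null(best) || nc < best$nc ||
                   (nc == best$nc && len1 < best$len))) {
                best <- list(order = cand$order, nc = nc, len = len1,
                             op = cand$op)
              }
            }
          }
        }
        if (!is.null(best)) {
          orders[[i]] <- best$order
          log <- rbind(log, data.frame(
            dataset = i, op = best$op, gap_position = gpos,
            conflicts_before = base_conf,
            conflicts_after = best$nc, stringsAsFactors = FALSE))
          base_conf <- best$nc
          improved <- TRUE
          break  # recompute gaps for this map
        }
      }
    }
    if (!improved || base_conf == 0) break
  }
  out_maps <- lapply(seq_along(maps), function(i)
    map_length(orders[[i]], rf_list[[i]], dataset_id = maps[[i]]$dataset_id))
  list(maps = out_maps, log = log)
}

# All inversion / transposition candidates for a segment of an order.
segment_moves <- function(ord, seg_idx) {
  m <- length(ord)
  seg <- ord[seg_idx]
  rest <- ord[-seg_idx]
  cands <- list(list(order = replace(ord, seg_idx, rev(seg)), op = "inversion"))
  for (pos in 0:length(rest)) {
    for (orient in 1:2) {
      s <- if (orient == 1) seg else rev(seg)
      new <- append(rest, s, after = pos)
      if (!identical(new, ord))
        cands[[length(cands) + 1]] <- list(order = new, op = "transposition")
    }
  }
  cands
}
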