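# Optimization criteria for synchronized consensus ordering, and the
# orientation conventions all order comparisons rely on.

#' @keywords internal
is_subsequence <- function(sub, full) {
  pos <- match(sub, full)
  !anyNA(pos) && !is.unsorted(pos, strictly = TRUE)
}

# Concordant minus discordant ordered pairs between two orders, over their
# common markers.  Positive: same orientation.
concordance_score <- function(ord_a, ord_b) {
  common <- intersect(ord_a, ord_b)
  if (length(common) < 2) return(0L)
  pa <- match(common, ord_a)
  pb <- match(common, ord_b)
  sa <- sign(outer(pa, pa, "-"))
  sb <- sign(outer(pb, pb, "-"))
  agree <- sa * sb
  sum(agree[upper.tri(agree)])
}

# Orient `ord` against a reference order (reverse it when more marker pairs
# are discordant than concordant).  A map and its reversal are the same
# solution, so every comparison starts here.  Ties keep `ord` as given.
orient_to <- function(ord, ref) {
  if (concordance_score(ref, ord) < 0) rev(ord) else ord
}

# Orient each order in a list consistently: order 1 anchors, later orders
# are aligned against the concatenated evidence of the already-oriented ones.
align_orientations <- function(orders, shared = NULL) {
  if (length(orders) <= 1) return(orders)
  keep <- function(o) if (is.null(shared)) o else o[o %in% shared]
  out <- orders
  for (i in seq_along(orders)[-1]) {
    score <- 0L
    for (j in seq_len(i - 1))
      score <- score + concordance_score(keep(out[[j]]), keep(out[[i]]))
    if (score < 0) out[[i]] <- rev(out[[i]])
  }
  out
}

#' Consensus optimization criterion
#'
#' The weighted sum of per-dataset map lengths, `S = sum_i w_i * S_i`,
#' evaluated for explicit per-dataset orders that must all embed the
#' projections of a common shared-marker order `g`.  This is the quantity
#' consensus ordering minimizes over all non-conflicting orders.
#'
#' @param g character vector: order of the shared markers.
#' @param problem a [consensus_problem()].
#' @param per_dataset_orders list of full marker orders, one per dataset,
#'   each embedding `g` restricted to that dataset (up to whole-map
#'   reversal).
#' @return the weighted total length (sum of adjacent recombination
#'   fractions, weighted per dataset).
#' @export
criterion_S <- function(g, problem, per_dataset_orders) {
  stopifnot(length(per_dataset_orders) == length(problem$datasets))
  total <- 0
  for (i in seq_along(problem$datasets)) {
    ord <- per_dataset_orders[[i]]
    gi <- shared_projection(g, problem$datasets[[i]]$markers)
    if (length(gi) >= 2) {
      ord_al <- orient_to(ord, gi)
      if (!is_subsequence(gi, ord_al))
        stop(sprintf("dataset %d order does not embed the shared order",
                     problem$datasets[[i]]$id))
      ord <- ord_al
    }
    total <- total + problem$weights[i] * map_length(ord, problem$rf[[i]])$length_S
  }
  total
}

#' Skeleton criterion
#'
#' The cheap screening criterion `S_shared = sum_i w_i * S_i(g(i))`: the
#' weighted sum of map lengths of the shared markers alone, ignoring
#' unique-marker placement.  Used to pre-screen candidate shared orders
#' before the full criterion is evaluated.
#'
#' @inheritParams criterion_S
#' @return non-negative weighted total.
#' @export
skeleton_criterion <- function(g, problem) {
  if (length(g) == 0) stop("empty shared-marker order")
  total <- 0
  for (i in seq_along(problem$datasets)) {
    gi <- shared_projection(g, problem$datasets[[i]]$markers)
    total <- total + problem$weights[i] * map_length(gi, problem$rf[[i]])$length_S
  }
  total
}

#' Check that a set of maps is free of shared-marker conflicts
#'
#' Two maps conflict when a pair of shared markers common to both appears
#' in opposite relative order (after aligning map orientations).  Returns
#' `TRUE` iff no pair of datasets exhibits any conflicting shared pair.
#'
#' @param x either a fitted consensus map (see [consensus_map()]), or a
#'   list of marker orders (character vectors or `marker_map` objects).
#' @param shared character vector of shared marker names (derived
#'   automatically when `x` is a fit or when omitted: markers occurring in
#'   at least two orders).
#' @return logical.
#' @export
conflict_free <- function(x, shared = NULL) {
  orders <- extract_orders(x)
  if (is.null(shared)) shared <- infer_shared(x, orders)
  nrow(detect_conflicts(orders, shared = shared, warn = FALSE)) == 0
}

extract_orders <- function(x) {
  if (inherits(x, "consensus_map")) {
    lapply(x$maps, function(m) m$order)
  } else if (is.list(x)) {
    lapply(x, function(o) if (inherits(o, "marker_map")) o$order else o)
  } else stop("cannot extract marker orders from this object")
}

infer_shared <- function(x, orders) {
  if (inherits(x, "consensus_map")) return(x$problem$shared)
  occ <- table(unlist(orders))
  names(occ)[occ >= 2]
}
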