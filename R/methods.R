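# S3 methods for the fitted consensus map.

#' @export
print.consensus_map <- function(x, ...) {
  cat("Consensus genetic map\n")
  cat(sprintf("  datasets: %d   shared markers: %d   total markers: %d\n",
              length(x$maps), length(x$shared_order),
              length(unique(unlist(lapply(x$maps, `[[`, "order"))))))
  cat(sprintf("  weighted criterion S = %.4f (skeleton %.4f)\n",
              x$S_total, x$S_shared))
  cat(sprintf("  initial conflicts: %d marker pairs in %d region(s); final: %s\n",
              nrow(x$conflicts), length(x$regions),
              if (conflict_free(x)) "conflict-free" else "UNRESOLVED"))
  invisible(x)
}

#' @export
summary.consensus_map <- function(object, ...) {
  per <- object$cost$per_dataset
  structure(list(per_dataset = per,
                 shared_order = object$shared_order,
                 n_conflicts = nrow(object$conflicts),
                 n_regions = length(object$regions),
                 S_total = object$S_total,
                 conflict_free = conflict_free(object)),
            class = "summary.consensus_map")
}

#' @export
print.summary.consensus_map <- function(x, ...) {
  cat("Consensus mapping summary\n")
  cat(sprintf("  criterion S = %.4f; %d initial conflict pair(s) in %d region(s); %s\n",
              x$S_total, x$n_conflicts, x$n_regions,
              if (x$conflict_free) "final maps conflict-free"
              else "conflicts remain"))
  cat("  Per-dataset map lengths (cM):\n")
  print(x$per_dataset, row.names = FALSE)
  cat("  Consensus shared order:\n  ",
      paste(x$shared_order, collapse = " "), "\n")
  invisible(x)
}

#' Plot shared-marker positions across datasets
#'
#' Draws, for each dataset, the cM positions of the shared markers in
#' the consensus map, connected across datasets; crossing lines indicate
#' where the consensus reordered a population's phase-1 arrangement.
#'
#' @param x a `consensus_map` fit.
#' @param which `"consensus"` or `"phase1"` maps.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.consensus_map <- function(x, which = c("consensus", "phase1"), ...) {
  which <- match.arg(which)
  maps <- if (which == "consensus") x$maps else x$phase1_maps
  g <- x$shared_order
  pos <- sapply(maps, function(m) {
    p <- c(0, cumsum(m$adjacent_rf)) * 100
    names(p) <- m$order
    p[g]
  })
  graphics::matplot(t(pos), type = "b", pch = 16, lty = 1,
                    xlab = "dataset", ylab = "position (cM)",
                    main = sprintf("Shared-marker positions (%s)", which), ...)
  invisible(x)
}
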