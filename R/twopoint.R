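# Two-point recombination-fraction estimation per cross type, and the
# complete pairwise matrix all ordering criteria consume.

#' Two-point recombination fraction for a backcross pair
#'
#' The direct count estimator: recombinants over informative (both
#' non-missing) individuals, truncated at 0.5.
#'
#' @param g1,g2 genotype vectors coded 0 (A) / 1 (H) with `NA` missing.
#' @return list with `rf` and `n` (informative count).
#' @export
rf_bc <- function(g1, g2) {
  res <- cpp_rf_pair(as.integer(g1), as.integer(g2), 1L)
  if (res$n == 0) warning("no informative individuals for pair")
  res
}

#' Two-point recombination fraction for a codominant F2 pair
#'
#' Maximum-likelihood estimate from the 3x3 joint genotype table.  The
#' double-heterozygote class mixes the two phases, so the likelihood is
#' maximized numerically on \[0, 0.5\] (golden-section search; the
#' likelihood is unimodal).
#'
#' @param g1,g2 genotype vectors coded 0 (A) / 1 (H) / 2 (B), `NA` missing.
#' @return list with `rf` and `n`.
#' @export
rf_f2_codominant <- function(g1, g2) {
  res <- cpp_rf_pair(as.integer(g1), as.integer(g2), 2L)
  if (res$n == 0) warning("no informative individuals for pair")
  res
}

#' Two-point recombination fraction for a RIL pair
#'
#' Observed line discordance R is mapped to the meiotic recombination
#' fraction as R / (2 (1 - R)), the inverse of the selfing-RIL
#' expansion 2r / (1 + 2r), clamped to \[0, 0.5\].
#'
#' @param g1,g2 genotype vectors coded 0 (A) / 2 (B), `NA` missing.
#' @return list with `rf` and `n`.
#' @export
rf_ril <- function(g1, g2) {
  mism <- mean(g1 != g2, na.rm = TRUE)
  if (!is.nan(mism) && mism >= 2 / 3)
    warning("line discordance >= 2/3; recombination fraction clamped to 0.5")
  res <- cpp_rf_pair(as.integer(g1), as.integer(g2), 3L)
  if (res$n == 0) warning("no informative individuals for pair")
  res
}

#' Build the pairwise recombination-fraction matrix for a dataset
#'
#' Estimates the recombination fraction for every marker pair with the
#' estimator matching the cross type.  Markers with no genotype scores at
#' all are excluded with a warning.  Pairs with fewer than
#' `min_informative` informative individuals are flagged unreliable and
#' their estimate replaced by the smallest two-hop sum
#' `min_x rf(a,x) + rf(x,b)` over reliable links (capped at 0.5), so the
#' ordering criterion always sees a complete matrix.
#'
#' @param dataset a [map_dataset()].
#' @param min_informative reliability threshold on informative pairs.
#' @return an `rf_matrix` object: `rf`, `n`, `unreliable` matrices.
#' @export
build_rf_matrix <- function(dataset, min_informative = 10L) {
  g <- dataset$geno
  all_missing <- rowSums(!is.na(g)) == 0
  if (any(all_missing)) {
    warning("excluding markers with no scores: ",
            paste(rownames(g)[all_missing], collapse = ", "))
    g <- g[!all_missing, , drop = FALSE]
  }
  if (nrow(g) < 2) stop("need at least 2 scored markers")
  res <- cpp_rf_matrix(g, cross_code(dataset$cross_type))
  rf <- res$rf; n <- res$n
  dimnames(rf) <- dimnames(n) <- list(rownames(g), rownames(g))
  unreliable <- n < min_informative
  diag(unreliable) <- FALSE
  if (any(unreliable)) {
    ok <- !unreliable
    rf_ok <- rf
    rf_ok[!ok] <- NA_real_
    idx <- which(unreliable & upper.tri(unreliable), arr.ind = TRUE)
    for (t in seq_len(nrow(idx))) {
      a <- idx[t, 1]; b <- idx[t, 2]
      two_hop <- rf_ok[a, ] + rf_ok[, b]
      two_hop[c(a, b)] <- NA_real_
      imp <- suppressWarnings(min(two_hop, na.rm = TRUE))
      if (!is.finite(imp)) imp <- 0.5
      rf[a, b] <- rf[b, a] <- min(imp, 0.5)
    }
  }
  rf[is.na(rf)] <- 0.5
  new_rf_matrix(rf, n, unreliable, dataset$cross_type)
}

#' Write a recombination-fraction matrix to TSV
#'
#' @param rf an `rf_matrix`.
#' @param path output file.
#' @export
write_rf_matrix <- function(rf, path) {
  write.table(data.frame(marker = rownames(rf$rf), rf$rf,
                         check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
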