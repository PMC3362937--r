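# Simulator for multi-population single-chromosome mapping data: a true
# map with a mixture of short and long intervals, meiosis without
# interference (Haldane), per-dataset missing data and genotype
# misclassification, and shared/unique marker structure with ground truth
# for recovery scoring.

#' Draw a true marker map
#'
#' Interval lengths are drawn from a mixture of uniforms: with probability
#' `frac_short` from `U[short_range]`, otherwise from `U[long_range]`
#' (defaults 75% on \[1, 4\] cM and 25% on \[4, 20\] cM).
#'
#' @param n_markers number of markers (>= 2).
#' @param frac_short mixture weight of the short-interval component.
#' @param short_range,long_range cM ranges of the two components.
#' @param rng_seed optional integer seed (set for reproducibility).
#' @return object of class `"true_map"`: `markers` (names in true order)
#'   and `intervals_cM`.
#' @export
draw_true_map <- function(n_markers, frac_short = 0.75,
                          short_range = c(1, 4), long_range = c(4, 20),
                          rng_seed = NULL) {
  if (n_markers < 2) stop("need at least 2 markers")
  if (short_range[1] > short_range[2] || long_range[1] > long_range[2] ||
      any(c(short_range, long_range) < 0))
    stop("invalid interval ranges")
  if (frac_short < 0 || frac_short > 1) stop("frac_short must be in [0,1]")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  k <- n_markers - 1
  short <- runif(k) < frac_short
  len <- ifelse(short,
                runif(k, short_range[1], short_range[2]),
                runif(k, long_range[1], long_range[2]))
  structure(list(markers = paste0("mar", seq_len(n_markers)),
                 intervals_cM = len),
            class = "true_map")
}

#' @export
print.true_map <- function(x, ...) {
  cat(sprintf("True map: %d markers, %.1f cM\n",
              length(x$markers), sum(x$intervals_cM)))
  invisible(x)
}

# One meiotic gamete per column: allele at marker 1 is Bernoulli(1/2),
# subsequent alleles switch with the interval's recombination fraction.
sim_gametes <- function(r_intervals, n) {
  m <- length(r_intervals) + 1
  g <- matrix(0L, m, n)
  g[1, ] <- rbinom(n, 1, 0.5)
  for (j in seq_along(r_intervals)) {
    flip <- rbinom(n, 1, r_intervals[j])
    g[j + 1, ] <- (g[j, ] + flip) %% 2L
  }
  g
}

#' Simulate genotypes for one mapping population
#'
#' Meiosis is simulated marker by marker with no crossover interference:
#' the per-interval recombination fraction is `haldane(d)`.  F2
#' individuals are the sum of two independent gametes; BC individuals are
#' one gamete against a tester (codes A/H); RIL genotypes are drawn
#' directly from the fixed-line distribution with the effective
#' recombination fraction `2r/(1+2r)` per interval.
#'
#' @param true_map a [draw_true_map()] result (or a list with
#'   `markers` and `intervals_cM`).
#' @param cross_type `"F2"`, `"BC"` or `"RIL"`.
#' @param n_individuals sample size.
#' @param id dataset id.
#' @param rng_seed optional integer seed.
#' @return a [map_dataset()].
#' @export
simulate_population <- function(true_map, cross_type = c("F2", "BC", "RIL"),
                                n_individuals, id = 1L, rng_seed = NULL) {
  cross_type <- match.arg(cross_type)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  r <- haldane(true_map$intervals_cM)
  m <- length(true_map$markers)
  geno <- switch(cross_type,
    F2 = sim_gametes(r, n_individuals) + sim_gametes(r, n_individuals),
    BC = sim_gametes(r, n_individuals),           # 0 = A (tester homo), 1 = H
    RIL = {
      r_ril <- 2 * r / (1 + 2 * r)
      2L * sim_gametes(r_ril, n_individuals)      # 0 = A, 2 = B fixed lines
    })
  storage.mode(geno) <- "integer"
  rownames(geno) <- true_map$markers
  map_dataset(geno, cross_type, id = id)
}

#' Noise specification for simulated genotypes
#'
#' Describes per-cell missingness and the genotype misclassification
#' model: within a stratum of `error_locus_fraction` of the loci and
#' `error_individual_fraction` of the individuals, heterozygotes are
#' misscored as either homozygote with probabilities `h_to_a` / `h_to_b`,
#' and each homozygote as heterozygote with `a_to_h` / `b_to_h`
#' (defaults 5%/5% and 10%/10%).
#'
#' @param missing_rate fraction of cells set missing, in \[0, 1\].
#' @param error_locus_fraction fraction of loci subject to misclassification.
#' @param error_individual_fraction fraction of individuals affected.
#' @param h_to_a,h_to_b,a_to_h,b_to_h misclassification probabilities.
#' @return object of class `"noise_spec"`.
#' @export
noise_spec <- function(missing_rate = 0, error_locus_fraction = 0,
                       error_individual_fraction = 0,
                       h_to_a = 0.05, h_to_b = 0.05,
                       a_to_h = 0.10, b_to_h = 0.10) {
  p <- c(missing_rate, error_locus_fraction, error_individual_fraction,
         h_to_a, h_to_b, a_to_h, b_to_h)
  if (any(p < 0 | p > 1)) stop("all noise probabilities must be in [0,1]")
  if (h_to_a + h_to_b > 1) stop("h_to_a + h_to_b must be <= 1")
  structure(list(missing_rate = missing_rate,
                 error_locus_fraction = error_locus_fraction,
                 error_individual_fraction = error_individual_fraction,
                 h_to_a = h_to_a, h_to_b = h_to_b,
                 a_to_h = a_to_h, b_to_h = b_to_h),
            class = "noise_spec")
}

#' Apply missingness and misclassification to a dataset
#'
#' Missing scores are independent per cell.  Misclassification is applied
#' only to the randomly selected locus-by-individual stratum given by the
#' spec, with the stated transition probabilities.  A change log records
#' every altered cell.
#'
#' @param dataset a [map_dataset()].
#' @param spec a [noise_spec()].
#' @param locus_subset optional character vector restricting which loci
#'   may be selected for misclassification (used to model distinct locus
#'   strata with different error loads).
#' @param rng_seed optional integer seed.
#' @return the modified dataset, with attribute `"change_log"` (data frame
#'   of marker, individual, from, to).
#' @export
apply_noise <- function(dataset, spec, locus_subset = NULL, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  g <- dataset$geno
  log_marker <- character(0); log_ind <- integer(0)
  log_from <- integer(0); log_to <- integer(0)

  if (spec$error_locus_fraction > 0 && spec$error_individual_fraction > 0) {
    pool <- if (is.null(locus_subset)) rownames(g) else
      intersect(locus_subset, rownames(g))
    n_loci <- round(spec$error_locus_fraction * length(pool))
    n_inds <- round(spec$error_individual_fraction * ncol(g))
    loci <- sample(pool, n_loci)
    inds <- sample(ncol(g), n_inds)
    for (mk in loci) {
      for (ii in inds) {
        v <- g[mk, ii]
        if (is.na(v)) next
        u <- runif(1)
        new <- v
        if (v == 1L) {
          if (u < spec$h_to_a) new <- 0L
          else if (u < spec$h_to_a + spec$h_to_b) new <- 2L
        } else if (v == 0L) {
          if (u < spec$a_to_h) new <- 1L
        } else {
          if (u < spec$b_to_h) new <- 1L
        }
        if (new != v) {
          g[mk, ii] <- new
          log_marker <- c(log_marker, mk); log_ind <- c(log_ind, ii)
          log_from <- c(log_from, v); log_to <- c(log_to, new)
        }
      }
    }
  }
  if (spec$missing_rate > 0) {
    drop <- matrix(runif(length(g)) < spec$missing_rate, nrow(g))
    newly <- drop & !is.na(g)
    if (any(newly)) {
      idx <- which(newly, arr.ind = TRUE)
      log_marker <- c(log_marker, rownames(g)[idx[, 1]])
      log_ind <- c(log_ind, idx[, 2])
      log_from <- c(log_from, g[newly]); log_to <- c(log_to, rep(NA_integer_, sum(newly)))
      g[newly] <- NA_integer_
    }
  }
  out <- dataset
  out$geno <- g
  attr(out, "change_log") <- data.frame(
    marker = log_marker, individual = log_ind,
    from = log_from, to = log_to, stringsAsFactors = FALSE)
  out
}

#' Build a simulated consensus-mapping problem with ground truth
#'
#' Generates one true map, assigns each marker as shared (present in all
#' datasets) or unique (present in exactly one, round-robin), simulates
#' each population, applies its noise spec, and assembles a
#' [consensus_problem()].  Marker naming follows the convention
#' `mar<k>` for shared and `mar<k>_<i>` for a marker unique to dataset
#' `i`, with `<k>` giving the true position rank.
#'
#' @param n_markers markers on the chromosome.
#' @param n_datasets number of mapping populations.
#' @param n_individuals sample size, recycled across datasets.
#' @param cross_type recycled across datasets.
#' @param noise a [noise_spec()], or a list of one per dataset.
#' @param shared_fraction probability a marker is shared; ignored when
#'   `shared_mask` is given.
#' @param shared_mask optional logical matrix (markers x datasets) of
#'   marker presence; every row must have at least one `TRUE`, and rows
#'   with a single `TRUE` are unique markers.
#' @param true_map optional pre-drawn [draw_true_map()]; drawn here
#'   otherwise.
#' @param rng_seed integer seed for the whole construction.
#' @param ... passed to [draw_true_map()].
#' @return a `consensus_problem` with attribute `"ground_truth"`: a list
#'   with the true overall order, the per-dataset true orders, and the
#'   true shared order.
#' @export
make_problem <- function(n_markers = 50, n_datasets = 8, n_individuals = 100,
                         cross_type = "F2", noise = noise_spec(),
                         shared_fraction = 1, shared_mask = NULL,
                         true_map = NULL, rng_seed = NULL,
                         min_informative = 10L, ...) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (is.null(true_map)) true_map <- draw_true_map(n_markers, ...)
  n_markers <- length(true_map$markers)
  if (inherits(noise, "noise_spec")) noise <- rep(list(noise), n_datasets)
  n_individuals <- rep_len(n_individuals, n_datasets)
  cross_type <- rep_len(cross_type, n_datasets)

  if (is.null(shared_mask)) {
    shared <- runif(n_markers) < shared_fraction
    shared_mask <- matrix(FALSE, n_markers, n_datasets)
    shared_mask[shared, ] <- TRUE
    uniq_idx <- which(!shared)
    if (length(uniq_idx))
      shared_mask[cbind(uniq_idx, ((seq_along(uniq_idx) - 1) %% n_datasets) + 1)] <- TRUE
  } else {
    if (nrow(shared_mask) != n_markers || ncol(shared_mask) != n_datasets)
      stop("shared_mask must be markers x datasets")
    if (any(rowSums(shared_mask) == 0))
      stop("every marker must be present in at least one dataset")
  }
  presence <- rowSums(shared_mask)
  # names: shared markers keep mar<k>; unique markers get the set suffix
  names_final <- true_map$markers
  for (k in which(presence == 1)) {
    i <- which(shared_mask[k, ])
    names_final[k] <- paste0(true_map$markers[k], "_", i)
  }

  datasets <- vector("list", n_datasets)
  for (i in seq_len(n_datasets)) {
    pop <- simulate_population(true_map, cross_type[i], n_individuals[i], id = i)
    rownames(pop$geno) <- names_final
    keep <- shared_mask[, i]
    pop$geno <- pop$geno[keep, , drop = FALSE]
    pop$markers <- rownames(pop$geno)
    datasets[[i]] <- apply_noise(pop, noise[[i]])
  }
  prob <- consensus_problem(datasets, min_informative = min_informative)
  attr(prob, "ground_truth") <- list(
    true_order = names_final,
    true_map = true_map,
    shared_mask = shared_mask,
    per_dataset_order = lapply(seq_len(n_datasets),
                               function(i) names_final[shared_mask[, i]]),
    true_shared_order = names_final[presence >= 2])
  prob
}
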