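#' @useDynLib syncmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rbinom setNames aggregate
#' @importFrom utils combn head read.delim write.table
NULL

GENO_LEVELS <- c("A", "H", "B")

#' Construct a mapping-population dataset
#'
#' A dataset is a genotype matrix for one mapping population of a single
#' chromosome: rows are markers (rownames are marker names), columns are
#' individuals.  Genotypes are coded `A` and `B` for the two homozygotes,
#' `H` for the heterozygote, and `NA` for missing scores.  Character
#' matrices using codes `A/H/B` with `-` or `U` for missing are accepted
#' and converted.
#'
#' Markers that occur (by name) in two or more datasets of a
#' [consensus_problem()] are *shared*; markers present in a single dataset
#' are *unique* to it.
#'
#' @param geno genotype matrix, markers x individuals, with rownames.
#'   Either an integer matrix with codes 0 (A), 1 (H), 2 (B) and `NA`,
#'   or a character matrix with codes `A/H/B/-/U`.
#' @param cross_type one of `"F2"`, `"BC"`, `"RIL"`.
#' @param id integer identifier of the population.
#' @return an object of class `"map_dataset"`.
#' @export
map_dataset <- function(geno, cross_type = c("F2", "BC", "RIL"), id = 1L) {
  cross_type <- match.arg(cross_type)
  if (is.null(rownames(geno))) stop("genotype matrix must have marker rownames")
  if (anyDuplicated(rownames(geno))) stop("duplicated marker names")
  if (is.character(geno)) {
    g <- matrix(NA_integer_, nrow(geno), ncol(geno), dimnames = dimnames(geno))
    g[geno == "A"] <- 0L
    g[geno == "H"] <- 1L
    g[geno == "B"] <- 2L
    bad <- !(geno %in% c(GENO_LEVELS, "-", "U", NA))
    if (any(bad)) stop("unknown genotype codes: ",
                       paste(unique(geno[bad]), collapse = ", "))
    geno <- g
  }
  storage.mode(geno) <- "integer"
  if (any(geno < 0L | geno > 2L, na.rm = TRUE)) stop("genotype codes must be 0/1/2/NA")
  if (cross_type == "BC" && any(geno == 2L, na.rm = TRUE))
    stop("BC genotypes must be coded A/H only")
  if (cross_type == "RIL" && any(geno == 1L, na.rm = TRUE))
    stop("RIL genotypes must be coded A/B only (lines fixed by selfing)")
  structure(
    list(id = as.integer(id), cross_type = cross_type, geno = geno,
         markers = rownames(geno), n_ind = ncol(geno)),
    class = "map_dataset")
}

#' @export
print.map_dataset <- function(x, ...) {
  cat(sprintf("Mapping dataset %d (%s): %d markers x %d individuals, %.1f%% missing\n",
              x$id, x$cross_type, nrow(x$geno), x$n_ind,
              100 * mean(is.na(x$geno))))
  invisible(x)
}

cross_code <- function(cross_type) {
  match(cross_type, c("BC", "F2", "RIL"))
}

#' Haldane map function
#'
#' Converts a map distance in centimorgans to a recombination fraction
#' under no interference, and back.
#'
#' @param d_cM distance in cM.
#' @return recombination fraction in [0, 0.5).
#' @export
haldane <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

#' @rdname haldane
#' @param r recombination fraction.
#' @export
haldane_inv <- function(r) -50 * log(1 - 2 * r)

new_rf_matrix <- function(rf, n, unreliable = NULL, cross_type = NA_character_) {
  if (is.null(unreliable))
    unreliable <- matrix(FALSE, nrow(rf), ncol(rf), dimnames = dimnames(rf))
  structure(list(rf = rf, n = n, unreliable = unreliable,
                 cross_type = cross_type, markers = rownames(rf)),
            class = "rf_matrix")
}

#' @export
print.rf_matrix <- function(x, ...) {
  cat(sprintf("Pairwise recombination fractions: %d markers (%s), mean informative n = %.1f\n",
              nrow(x$rf), x$cross_type,
              mean(x$n[upper.tri(x$n)])))
  invisible(x)
}

rf_lookup <- function(rf, order) {
  miss <- setdiff(order, rownames(rf$rf))
  if (length(miss))
    stop("markers absent from rf matrix: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Map length of a marker order
#'
#' Computes the multilocus map solution for a given order: adjacent
#' recombination fractions, their sum (the map-length criterion, in
#' Morgan-like units of summed recombination fractions), and the cM
#' report `100 * sum`.
#'
#' @param order character vector of marker names (a permutation of a subset
#'   of the rf matrix's markers).
#' @param rf an `rf_matrix` (or a plain symmetric numeric matrix).
#' @param dataset_id optional id carried into the result.
#' @return object of class `"marker_map"` with elements `order`,
#'   `adjacent_rf`, `length_S`, `length_cM`.
#' @export
map_length <- function(order, rf, dataset_id = NA_integer_) {
  if (is.matrix(rf)) rf <- new_rf_matrix(rf, rf * 0)
  if (anyDuplicated(order)) stop("order contains duplicated markers")
  rf_lookup(rf, order)
  m <- length(order)
  adj <- if (m >= 2) rf$rf[cbind(order[-m], order[-1])] else numeric(0)
  structure(list(order = order, adjacent_rf = unname(adj),
                 length_S = sum(adj), length_cM = 100 * sum(adj),
                 dataset_id = dataset_id),
            class = "marker_map")
}

#' @export
print.marker_map <- function(x, ...) {
  cat(sprintf("Marker map: %d markers, length %.3f (%.1f cM)\n",
              length(x$order), x$length_S, x$length_cM))
  invisible(x)
}

#' Assemble a consensus-mapping problem
#'
#' Bundles several mapping-population datasets, their pairwise
#' recombination-fraction matrices, and per-dataset weights.  The shared
#' registry (which markers occur in which datasets) is derived from marker
#' names: a marker occurring in two or more datasets is shared.
#'
#' @param datasets list of [map_dataset()] objects.
#' @param weights optional positive per-dataset weights (default all 1).
#' @param rf optional precomputed list of `rf_matrix` objects, one per
#'   dataset; computed with [build_rf_matrix()] when omitted.
#' @param min_informative pairs with fewer informative individuals are
#'   flagged unreliable (passed to [build_rf_matrix()]).
#' @return object of class `"consensus_problem"`.
#' @export
consensus_problem <- function(datasets, weights = NULL, rf = NULL,
                              min_informative = 10L) {
  if (length(datasets) < 1) stop("need at least one dataset")
  ids <- vapply(datasets, function(d) d$id, integer(1))
  if (anyDuplicated(ids)) stop("dataset ids must be unique")
  if (is.null(weights)) weights <- rep(1, length(datasets))
  if (length(weights) != length(datasets) || any(weights <= 0))
    stop("weights must be positive, one per dataset")
  if (is.null(rf)) rf <- lapply(datasets, build_rf_matrix,
                                min_informative = min_informative)
  occ <- table(unlist(lapply(datasets, function(d) d$markers)))
  shared <- names(occ)[occ >= 2]
  registry <- lapply(setNames(shared, shared), function(m)
    ids[vapply(datasets, function(d) m %in% d$markers, logical(1))])
  structure(list(datasets = datasets, rf = rf, weights = weights,
                 shared = shared, registry = registry,
                 markers_all = names(occ)),
            class = "consensus_problem")
}

#' @export
print.consensus_problem <- function(x, ...) {
  cat(sprintf("Consensus problem: %d datasets, %d markers (%d shared)\n",
              length(x$datasets), length(x$markers_all), length(x$shared)))
  invisible(x)
}

#' Project a shared order onto one dataset
#'
#' @param g character vector: an order of the shared markers.
#' @param markers markers present in the dataset.
#' @return the subsequence of `g` restricted to `markers`.
#' @export
shared_projection <- function(g, markers) g[g %in% markers]
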