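# File interfaces: delimited genotype matrices, dataset manifests
# (YAML or JSON), and map/problem output.

#' Read a genotype matrix from delimited text
#'
#' Rows are markers, columns individuals; the first column holds marker
#' names.  Codes `A/H/B`, with `-` or `U` (or empty) for missing.
#'
#' @param path TSV/CSV file.
#' @param cross_type passed to [map_dataset()].
#' @param id dataset id.
#' @param sep field separator (guessed from the extension by default).
#' @return a [map_dataset()].
#' @export
read_genotypes <- function(path, cross_type = "F2", id = 1L, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  mk <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  mat[mat %in% c("", "-", "U", "NA")] <- NA
  rownames(mat) <- mk
  map_dataset(mat, cross_type, id = id)
}

#' Write a dataset's genotypes to TSV
#'
#' @param dataset a [map_dataset()].
#' @param path output file.
#' @export
write_genotypes <- function(dataset, path) {
  codes <- matrix(c("A", "H", "B")[dataset$geno + 1L], nrow(dataset$geno))
  codes[is.na(codes)] <- "-"
  df <- data.frame(marker = rownames(dataset$geno), codes,
                   stringsAsFactors = FALSE, check.names = FALSE)
  colnames(df) <- c("marker", paste0("ind", seq_len(ncol(codes))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a consensus-mapping manifest
#'
#' The manifest (YAML or JSON) lists the datasets:
#' `datasets: [{path, cross_type, id, weight}, ...]`, with paths relative
#' to the manifest file.
#'
#' @param path manifest file.
#' @param min_informative passed to [consensus_problem()].
#' @return a [consensus_problem()].
#' @export
read_manifest <- function(path, min_informative = 10L) {
  man <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML manifests; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- man$datasets
  if (is.data.frame(entries)) entries <- split(entries, seq_len(nrow(entries)))
  base <- dirname(path)
  datasets <- lapply(seq_along(entries), function(i) {
    e <- as.list(entries[[i]])
    p <- e$path
    if (!file.exists(p)) p <- file.path(base, e$path)
    read_genotypes(p, cross_type = e$cross_type %||NA% "F2",
                   id = e$id %||NA% i)
  })
  weights <- vapply(seq_along(entries), function(i)
    as.numeric(as.list(entries[[i]])$weight %||NA% 1), numeric(1))
  consensus_problem(datasets, weights = weights,
                    min_informative = min_informative)
}

`%||NA%` <- function(a, b) if (is.null(a) || all(is.na(a))) b else a

#' Write per-dataset consensus maps to TSV
#'
#' One row per marker per dataset: `marker`, `position_cM` (1-based cM
#' position from the left end of that dataset's map), `shared_flag`,
#' `dataset_id`.
#'
#' @param solution a `consensus_map` fit (or a list of `marker_map`s).
#' @param path output file.
#' @param shared shared marker names (taken from the fit when possible).
#' @export
write_maps <- function(solution, path, shared = NULL) {
  maps <- if (inherits(solution, "consensus_map")) solution$maps else solution
  if (is.null(shared) && inherits(solution, "consensus_map"))
    shared <- solution$problem$shared
  rows <- do.call(rbind, lapply(maps, function(m) {
    pos <- c(0, cumsum(m$adjacent_rf)) * 100
    data.frame(marker = m$order, position_cM = round(pos, 3),
               shared_flag = as.integer(m$order %in% shared),
               dataset_id = m$dataset_id, stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated problem to a directory
#'
#' Emits one genotype TSV per dataset, a JSON manifest, and the ground
#' truth (true marker order) as JSON.
#'
#' @param problem a [consensus_problem()] from [make_problem()].
#' @param dir output directory (created if needed).
#' @return the manifest path.
#' @export
write_problem <- function(problem, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_along(problem$datasets), function(i) {
    d <- problem$datasets[[i]]
    f <- sprintf("dataset%02d.tsv", i)
    write_genotypes(d, file.path(dir, f))
    list(path = f, cross_type = d$cross_type, id = d$id, weight = 1)
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(datasets = entries), manifest, auto_unbox = TRUE)
  gt <- attr(problem, "ground_truth")
  if (!is.null(gt))
    jsonlite::write_json(
      list(true_order = gt$true_order,
           true_shared_order = gt$true_shared_order),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  invisible(manifest)
}
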