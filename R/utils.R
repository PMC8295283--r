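#' @useDynLib crisprmat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Deterministic child seeds: one root seed, one independent stream per
# simulated artifact, so adding an artifact never perturbs the others.
.stream_ids <- c(genome = 11L, screen = 23L, chip = 37L, rna = 41L,
                 reads = 53L, truth = 61L, perm = 71L, library = 83L)

child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  id <- .stream_ids[[stream]]
  # affine map into [0, 2^31 - 2]; distinct streams give distinct seeds
  as.integer((as.numeric(seed) * 1103L + id * 7919L) %% (2^31 - 1))
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(child_seed(seed, stream))
  expr
}

geo_mean <- function(x) exp(mean(log(x)))

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Number of genes obtained by pooling candidate category lists
#'
#' Candidate genes for a screen library are typically assembled from
#' several overlapping source lists (e.g. curated transcriptional
#' regulators, differentially expressed genes, binding-site neighbours).
#' The targeted gene set is their union.
#'
#' @param lists a list of character vectors of gene identifiers.
#' @return list with `genes` (sorted union) and `n_targeted`.
#' @export
combine_candidate_lists <- function(lists) {
  stopifnot(is.list(lists))
  genes <- sort(unique(unlist(lists, use.names = FALSE)))
  list(genes = genes, n_targeted = length(genes))
}

write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a counts matrix as TSV (feature ids in first column)
#' @param counts integer matrix with rownames.
#' @param path output file.
#' @param id_col name of the feature-id column.
#' @export
write_count_table <- function(counts, path, id_col = "feature_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write_tsv_table(df, path)
}

#' Read a counts matrix written by [write_count_table()]
#' @param path TSV file, first column feature ids, remaining columns samples.
#' @return integer matrix with feature rownames.
#' @export
read_count_table <- function(path) {
  df <- read_tsv_table(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
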