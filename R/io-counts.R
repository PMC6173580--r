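#' Read and write allele-specific count tables
#'
#' The on-disk format is a TSV with columns `gene_id`, `allele` (`A` or `B`),
#' `assay` (`mrna` or `gdna`), `replicate` (positive integer) and `count`
#' (non-negative integer). Lines starting with `#` are comments. The table
#' must be complete: within each assay, every gene must be present for both
#' alleles in every replicate.
#'
#' @param path TSV file.
#' @return Tibble with the five columns above.
#' @export
read_counts <- function(path) {
  x <- read_tsv_commented(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    allele = readr::col_character(),
    assay = readr::col_character(),
    replicate = readr::col_integer(),
    count = readr::col_double()
  ))
  validate_counts(x)
}

#' @rdname read_counts
#' @param counts Count tibble.
#' @param header Extra comment-header lines to record (e.g. the seed).
#' @export
write_counts <- function(counts, path, header = character(0)) {
  write_tsv_commented(validate_counts(counts), path, header)
}

#' @rdname read_counts
#' @export
validate_counts <- function(counts) {
  counts <- as_tibble(counts)
  need <- c("gene_id", "allele", "assay", "replicate", "count")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop_input("counts table lacks column '%s'", miss[1])
  bad <- setdiff(unique(counts$allele), c("A", "B"))
  if (length(bad)) stop_input("unknown allele label '%s'", bad[1])
  bad <- setdiff(unique(counts$assay), c("mrna", "gdna"))
  if (length(bad)) stop_input("unknown assay label '%s'", bad[1])
  if (any(counts$count < 0) || any(counts$count != floor(counts$count)))
    stop_input("counts must be non-negative integers")
  if (anyDuplicated(counts[c("gene_id", "allele", "assay", "replicate")]))
    stop_input("duplicate (gene, allele, assay, replicate) rows")
  # completeness: full gene x allele x replicate crossing within each assay
  for (a in unique(counts$assay)) {
    sub <- counts[counts$assay == a, ]
    genes <- unique(sub$gene_id)
    reps <- unique(sub$replicate)
    expected <- length(genes) * 2L * length(reps)
    if (nrow(sub) != expected) {
      full <- tidyr::expand_grid(gene_id = genes, allele = c("A", "B"),
                                 replicate = reps)
      miss <- dplyr::anti_join(full, sub, by = names(full))
      stop_input("assay '%s': missing cell gene=%s allele=%s replicate=%s",
                 a, miss$gene_id[1], miss$allele[1], miss$replicate[1])
    }
  }
  counts
}
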