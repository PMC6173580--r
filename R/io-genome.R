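#' Read genome sequences from FASTA
#'
#' Sequences are uppercased and any character outside A, C, G, T, N is
#' mapped to N. Contig identifiers are the first whitespace-delimited token
#' of each header.
#'
#' @param path FASTA file (possibly line-wrapped, mixed case).
#' @return Named character vector of contig sequences.
#' @export
read_fasta <- function(path) {
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop_input("cannot read FASTA '%s': %s",
                                                path, conditionMessage(e)))
  if (length(ss) == 0) stop_input("FASTA file '%s' contains no sequences", path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_input("duplicate contig id '%s' in FASTA '%s'", dup[1], path)
  seqs <- clean_dna(as.character(ss))
  names(seqs) <- ids
  seqs
}

#' @rdname read_fasta
#' @param contigs Named character vector of sequences.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(contigs, path, width = 70) {
  ss <- Biostrings::DNAStringSet(contigs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Only rows whose type column is `gene` are kept; each must carry an `ID`
#' attribute. GFF 1-based inclusive coordinates are converted to the
#' package-internal 0-based half-open convention (`start - 1`, `end`).
#' An optional `target_set=1` attribute marks gene-set membership (e.g.
#' ribosomal protein genes) and round-trips through [write_gff()].
#'
#' @param path GFF3 file.
#' @return Tibble with columns `gene_id`, `contig`, `start`, `end`
#'   (0-based half-open), `strand`, `is_target`.
#' @export
read_gff <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) stop_input("GFF '%s' has no feature rows", path)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9)
  if (length(bad))
    stop_input("GFF '%s' line %d: expected 9 tab-separated columns", path, idx[bad[1]])
  type <- vapply(fields, `[`, "", 3)
  gi <- which(type == "gene")
  if (!length(gi))
    stop_input("GFF '%s' contains no 'gene' rows", path)
  recs <- fields[gi]
  lineno <- idx[gi]
  start1 <- suppressWarnings(as.integer(vapply(recs, `[`, "", 4)))
  end1 <- suppressWarnings(as.integer(vapply(recs, `[`, "", 5)))
  strand <- vapply(recs, `[`, "", 7)
  attrs <- vapply(recs, `[`, "", 9)
  if (anyNA(start1) || anyNA(end1)) {
    b <- which(is.na(start1) | is.na(end1))[1]
    stop_input("GFF '%s' line %d: non-integer coordinates", path, lineno[b])
  }
  b <- which(end1 < start1 | start1 < 1)
  if (length(b))
    stop_input("GFF '%s' line %d: end (%d) < start (%d) or start < 1",
               path, lineno[b[1]], end1[b[1]], start1[b[1]])
  b <- which(!strand %in% c("+", "-"))
  if (length(b))
    stop_input("GFF '%s' line %d: strand must be + or -", path, lineno[b[1]])
  ids <- stringr::str_match(attrs, "(?:^|;)ID=([^;]+)")[, 2]
  b <- which(is.na(ids))
  if (length(b))
    stop_input("GFF '%s' line %d: gene row lacks an ID attribute", path, lineno[b[1]])
  dup <- which(duplicated(ids))
  if (length(dup))
    stop_input("GFF '%s' line %d: duplicate gene ID '%s'",
               path, lineno[dup[1]], ids[dup[1]])
  tibble(
    gene_id = ids,
    contig = vapply(recs, `[`, "", 1),
    start = start1 - 1L,
    end = end1,
    strand = strand,
    is_target = grepl("(^|;)target_set=1", attrs)
  )
}

#' @rdname read_gff
#' @param genes Gene-model tibble as returned by [read_gff()].
#' @export
write_gff <- function(genes, path) {
  attrs <- paste0("ID=", genes$gene_id,
                  ifelse(genes$is_target %||% FALSE, ";target_set=1", ""))
  df <- data.frame(genes$contig, "regevo", "gene",
                   genes$start + 1L, genes$end, ".", genes$strand, ".", attrs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Bundle contig sequences with gene models
#'
#' Validates that every gene's contig exists, intervals lie within contig
#' bounds, coordinates are proper 0-based half-open, and gene ids are unique.
#'
#' @param contigs Named character vector of uppercase ACGTN sequences.
#' @param genes Gene-model tibble (see [read_gff()]).
#' @return A `genome_bundle` list with elements `contigs` and `genes`.
#' @export
genome_bundle <- function(contigs, genes) {
  genes <- as_tibble(genes)
  if (!all(c("gene_id", "contig", "start", "end", "strand") %in% names(genes)))
    stop_input("genes table lacks required columns")
  if (!("is_target" %in% names(genes))) genes$is_target <- FALSE
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stop_input("all contigs must be named")
  missing <- setdiff(unique(genes$contig), names(contigs))
  if (length(missing))
    stop_input("gene contig '%s' not present in sequences", missing[1])
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup)) stop_input("duplicate gene id '%s'", dup[1])
  bad <- which(genes$start < 0 | genes$start >= genes$end)
  if (length(bad))
    stop_input("gene '%s': invalid interval [%d,%d)", genes$gene_id[bad[1]],
               genes$start[bad[1]], genes$end[bad[1]])
  clen <- nchar(contigs)[genes$contig]
  bad <- which(genes$end > clen)
  if (length(bad))
    stop_input("gene '%s' extends beyond its contig", genes$gene_id[bad[1]])
  structure(list(contigs = contigs, genes = genes), class = "genome_bundle")
}

#' @rdname genome_bundle
#' @param fasta,gff Paths to the genome FASTA and GFF3 annotation.
#' @export
read_genome <- function(fasta, gff) {
  genome_bundle(read_fasta(fasta), read_gff(gff))
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat(sprintf("<genome_bundle> %d contigs (%s bp), %d genes (%d in target set)\n",
              length(x$contigs), format(sum(nchar(x$contigs)), big.mark = ","),
              nrow(x$genes), sum(x$genes$is_target)))
  invisible(x)
}
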