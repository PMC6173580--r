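#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join bind_rows distinct n slice pull rename
#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

# Map a DNA string to integer codes 1..4 (A,C,G,T); anything else -> 5 (N).
dna_codes <- function(seq) {
  x <- utf8ToInt(seq)
  out <- rep.int(5L, length(x))
  out[x == 65L] <- 1L # A
  out[x == 67L] <- 2L # C
  out[x == 71L] <- 3L # G
  out[x == 84L] <- 4L # T
  out
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the ACGTN alphabet.
#'
#' @param seq Character vector of DNA strings (uppercase ACGTN).
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(seq) {
  if (length(seq) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# Sanitise raw sequence text: uppercase, non-ACGTN -> N.
clean_dna <- function(seq) {
  gsub("[^ACGTN]", "N", toupper(seq))
}

stop_input <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "regevo_input_error")
}

# TSV writer with a '#'-prefixed comment header (tool version, seed, ...).
write_tsv_commented <- function(x, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) {
    writeLines(paste0("# ", header), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path, col_types = NULL) {
  readr::read_tsv(path, comment = "#", col_types = col_types,
                  progress = FALSE, show_col_types = FALSE)
}
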