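#' Position weight matrices
#'
#' A `pwm` is a length x 4 numeric matrix of per-position, per-base
#' log-likelihood scores over the alphabet A, C, G, T. A window of matching
#' length is scored by summing the score of the observed base at every
#' position; the maximum achievable score is the sum of the per-position
#' column maxima and is always recomputed from the matrix, never trusted from
#' a file.
#'
#' @param scores Numeric matrix with 4 columns (A, C, G, T) and one row per
#'   motif position.
#' @param name Motif name.
#' @return An object of class `pwm`: the score matrix with attributes `name`
#'   and `max_score`.
#' @export
#' @examples
#' m <- pwm(rbind(c(2, -1, -1, -1), c(-1, -1, 2, -1)), "toy")
#' pwm_max_score(m)
#' pwm_consensus(m)
pwm <- function(scores, name = "pwm") {
  scores <- as.matrix(scores)
  if (ncol(scores) != 4)
    stop_input("PWM '%s' must have 4 columns (A,C,G,T), got %d", name, ncol(scores))
  if (nrow(scores) < 1) stop_input("PWM '%s' has no positions", name)
  if (!is.numeric(scores) || anyNA(scores))
    stop_input("PWM '%s' contains non-numeric or missing scores", name)
  dimnames(scores) <- list(NULL, DNA_BASES)
  structure(scores, class = "pwm", name = name,
            max_score = sum(apply(scores, 1, max)))
}

#' @rdname pwm
#' @param x A `pwm` object.
#' @export
pwm_max_score <- function(x) attr(x, "max_score")

#' @rdname pwm
#' @export
pwm_name <- function(x) attr(x, "name")

#' @rdname pwm
#' @export
pwm_length <- function(x) nrow(x)

#' Consensus sequence of a PWM
#'
#' Per-position highest-scoring base; ties resolved in A,C,G,T order.
#'
#' @param x A `pwm` object.
#' @return A character string of length `pwm_length(x)`.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(unclass(x), 1, which.max)], collapse = "")
}

#' Reverse complement of a PWM
#'
#' Scoring a window on the minus strand equals scoring the forward window
#' with the reverse-complemented matrix: rows reversed, A/T and C/G columns
#' swapped.
#'
#' @param x A `pwm` object.
#' @return A `pwm`.
#' @export
pwm_revcomp <- function(x) {
  m <- unclass(x)[rev(seq_len(nrow(x))), c(4L, 3L, 2L, 1L), drop = FALSE]
  pwm(m, name = pwm_name(x))
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s: %d positions, max score %.4g, consensus %s\n",
              pwm_name(x), nrow(x), pwm_max_score(x), pwm_consensus(x)))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Read and write PWM score files
#'
#' The native dialect is a TSV whose first line is `#PWM <name>` followed by
#' one row per motif position with four tab-separated log-likelihood scores
#' in A, C, G, T order. The maximum score is recomputed on read.
#'
#' @param path File path.
#' @return `read_pwm()` returns a [pwm]; `write_pwm()` returns `path`
#'   invisibly.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_input("PWM file '%s' is empty", path)
  m <- regmatches(lines[1], regexec("^#PWM[ \t]+(\\S+)", lines[1]))[[1]]
  if (length(m) != 2)
    stop_input("PWM file '%s': first line must be '#PWM <name>'", path)
  name <- m[2]
  body <- lines[-1]
  if (!length(body)) stop_input("PWM file '%s' has no score rows", path)
  rows <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(rows) != 4)
  if (length(bad))
    stop_input("PWM file '%s' row %d: expected 4 tab-separated fields, got %d",
               path, bad[1], length(rows[[bad[1]]]))
  vals <- suppressWarnings(vapply(rows, as.numeric, numeric(4)))
  if (anyNA(vals)) {
    bad <- which(colSums(is.na(vals)) > 0)[1]
    stop_input("PWM file '%s' row %d: non-numeric score", path, bad)
  }
  pwm(t(vals), name = name)
}

#' @rdname read_pwm
#' @param x A `pwm` object.
#' @export
write_pwm <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#PWM %s", pwm_name(x)), con)
  utils::write.table(format(unclass(x), trim = TRUE, digits = 10), con,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Import a MEME minimal-format motif as a log-likelihood PWM
#'
#' Convenience bridge: reads the first motif of a MEME minimal-format file
#' (letter-probability matrix over ACGT) and converts probabilities to
#' log2-likelihood ratios against a uniform 0.25 background,
#' `log2(p / 0.25)`. Zero probabilities are floored at `eps` before taking
#' the log so the matrix stays finite.
#'
#' @param path MEME minimal-format file.
#' @param eps Probability floor for zero cells.
#' @return A [pwm].
#' @export
read_meme_pwm <- function(path, eps = 1e-4) {
  lines <- readLines(path, warn = FALSE)
  mi <- grep("^MOTIF\\b", lines)
  if (!length(mi)) stop_input("no MOTIF block in '%s'", path)
  name <- strsplit(trimws(lines[mi[1]]), "\\s+")[[1]][2]
  li <- grep("^letter-probability matrix", lines)
  li <- li[li > mi[1]]
  if (!length(li)) stop_input("no letter-probability matrix in '%s'", path)
  rows <- list()
  for (i in seq(li[1] + 1, length(lines))) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != 4 || anyNA(suppressWarnings(as.numeric(f)))) break
    rows[[length(rows) + 1L]] <- as.numeric(f)
  }
  if (!length(rows)) stop_input("empty probability matrix in '%s'", path)
  p <- pmax(do.call(rbind, rows), eps)
  pwm(log2(p / 0.25), name = name %||% "meme")
}
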