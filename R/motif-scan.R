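#' Extract upstream intergenic regions
#'
#' For every gene, takes up to `max_len` bases immediately 5' of the gene,
#' truncated at the nearest boundary of any other annotated gene (so shared
#' divergent promoters are assigned to both genes in full) or at the contig
#' edge. Minus-strand genes yield the reverse complement, so every returned
#' sequence reads left to right toward the gene: position 0 is farthest from
#' the gene and the last base abuts the gene start. Genes whose upstream
#' space is fully covered by another gene get a zero-length region and are
#' dropped with a warning.
#'
#' @param genome A [genome_bundle()].
#' @param max_len Maximum promoter length in bp (default 1000).
#' @return Tibble with columns `gene_id`, `contig`, `strand`, `g_start`,
#'   `g_end` (genomic 0-based half-open span of the region), `length`, `seq`
#'   (toward-gene orientation), `is_target`.
#' @export
extract_upstream <- function(genome, max_len = 1000) {
  stopifnot(inherits(genome, "genome_bundle"), max_len >= 1)
  genes <- genome$genes
  clen <- nchar(genome$contigs)[genes$contig]
  # nearest other-gene boundary on the 5' side, computed per contig:
  # + strand: largest end among genes starting strictly before this start;
  # - strand: smallest start among genes ending strictly after this end.
  lim_plus <- rep(0L, nrow(genes))
  lim_minus <- as.integer(clen)
  for (ct in unique(genes$contig)) {
    idx <- which(genes$contig == ct)
    if (length(idx) < 2) next
    st <- genes$start[idx]; en <- genes$end[idx]
    for (j in seq_along(idx)) {
      up <- en[st < st[j]]
      if (length(up)) lim_plus[idx[j]] <- max(up)
      dn <- st[en > en[j]]
      if (length(dn)) lim_minus[idx[j]] <- min(dn)
    }
  }
  plus <- genes$strand == "+"
  a <- ifelse(plus, pmax(0L, genes$start - max_len, lim_plus), genes$end)
  b <- ifelse(plus, genes$start, pmin(clen, genes$end + max_len, lim_minus))
  empty <- b <= a
  if (any(empty)) {
    warn(sprintf("%d gene(s) with no upstream intergenic space dropped: %s",
                 sum(empty),
                 paste(utils::head(genes$gene_id[empty], 5), collapse = ", ")))
  }
  keep <- which(!empty)
  seqs <- substring(genome$contigs[genes$contig[keep]], a[keep] + 1L, b[keep])
  minus <- !plus[keep]
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  tibble(gene_id = genes$gene_id[keep], contig = genes$contig[keep],
         strand = genes$strand[keep],
         g_start = as.integer(a[keep]), g_end = as.integer(b[keep]),
         length = as.integer(b[keep] - a[keep]), seq = unname(seqs),
         is_target = genes$is_target[keep])
}

#' Score one window under a PWM
#'
#' Sum of the per-position log-likelihood scores of the observed bases. An N
#' (or any non-ACGT character) contributes the per-position minimum, the
#' pessimistic choice that keeps assembly gaps from creating spurious hits.
#'
#' @param pwm A [pwm] object.
#' @param window DNA string of length `pwm_length(pwm)`.
#' @return Numeric scalar score.
#' @export
score_window <- function(pwm, window) {
  L <- nrow(pwm)
  if (nchar(window) != L)
    stop_input("window length %d != PWM length %d", nchar(window), L)
  m <- cbind(unclass(pwm), apply(unclass(pwm), 1, min))
  sum(m[cbind(seq_len(L), dna_codes(window))])
}

# Scores of all forward-frame windows of `codes` under score matrix `m`
# (already augmented with the N column). Returns numeric vector indexed by
# 0-based window start.
slide_scores <- function(m, codes) {
  L <- nrow(m)
  n <- length(codes) - L + 1L
  if (n < 1) return(numeric(0))
  s <- numeric(n)
  mu <- unname(m)
  for (i in seq_len(L)) {
    s <- s + mu[i, codes[i:(i + n - 1L)]]
  }
  s
}

#' Scan a promoter region with a PWM on both strands
#'
#' Every window whose score is at least `threshold` is reported, on either
#' strand; minus-strand windows are scored as the reverse complement of the
#' forward-frame window, and all coordinates are reported in the region's
#' forward (toward-gene) frame. The hit midpoint is
#' `start + floor(motif_length / 2)`.
#'
#' @param pwm A [pwm].
#' @param seq Region sequence (uppercase ACGTN), toward-gene orientation.
#' @param threshold Minimum score to report.
#' @return Tibble with columns `start` (0-based), `strand`, `midpoint`,
#'   `score`, sorted by `start` then strand (`+` first).
#' @export
scan_region <- function(pwm, seq, threshold) {
  L <- nrow(pwm)
  codes <- dna_codes(seq)
  if (length(codes) < L)
    return(tibble(start = integer(0), strand = character(0),
                  midpoint = integer(0), score = numeric(0)))
  fw <- cbind(unclass(pwm), apply(unclass(pwm), 1, min))
  rcp <- pwm_revcomp(pwm)
  rv <- cbind(unclass(rcp), apply(unclass(rcp), 1, min))
  sf <- slide_scores(fw, codes)
  sr <- slide_scores(rv, codes)
  keep_f <- which(sf >= threshold)
  keep_r <- which(sr >= threshold)
  hits <- tibble(
    start = c(keep_f, keep_r) - 1L,
    strand = rep(c("+", "-"), c(length(keep_f), length(keep_r))),
    score = c(sf[keep_f], sr[keep_r])
  )
  hits$midpoint <- hits$start + L %/% 2L
  hits[order(hits$start, hits$strand), c("start", "strand", "midpoint", "score")]
}

#' Scan many regions
#'
#' @param regions Region tibble from [extract_upstream()] (needs `gene_id`
#'   and `seq`).
#' @param pwm A [pwm].
#' @param threshold Minimum score; defaults to half the maximum achievable
#'   score, the conventional presence cutoff.
#' @return Tibble of hits with `gene_id`, `pwm`, `start`, `strand`,
#'   `midpoint`, `score`.
#' @export
scan_regions <- function(regions, pwm, threshold = 0.5 * pwm_max_score(pwm)) {
  res <- purrr::map2(regions$gene_id, regions$seq, function(g, s) {
    h <- scan_region(pwm, s, threshold)
    if (nrow(h)) h$gene_id <- g
    h
  })
  out <- bind_rows(res)
  if (!nrow(out))
    return(tibble(gene_id = character(0), pwm = character(0),
                  start = integer(0), strand = character(0),
                  midpoint = integer(0), score = numeric(0)))
  out$pwm <- pwm_name(pwm)
  out[, c("gene_id", "pwm", "start", "strand", "midpoint", "score")]
}

#' Best (strongest) hit of a scan
#'
#' Maximal-score hit; ties broken by smaller start, then `+` strand before
#' `-`. `best_hit()` operates on hits from a single region; `best_hits()`
#' applies the same rule within each `gene_id`.
#'
#' @param hits Hit tibble from [scan_region()] or [scan_regions()].
#' @return One-row tibble (or zero rows if `hits` is empty).
#' @export
best_hit <- function(hits) {
  if (!nrow(hits)) return(hits)
  o <- order(-hits$score, hits$start, hits$strand != "+")
  hits[o[1], ]
}

#' @rdname best_hit
#' @export
best_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits |>
    group_by(.data$gene_id) |>
    arrange(dplyr::desc(.data$score), .data$start, .data$strand != "+",
            .by_group = TRUE) |>
    slice(1) |>
    ungroup()
}

#' Motif presence calls
#'
#' `has_site()` asks whether any window on either strand of `seq` scores at
#' least `frac` of the PWM's maximum achievable score (the presence
#' convention, default 50% of max). `site_presence()` vectorises the call
#' over a region table and also reports each region's best score.
#'
#' @param seq Region sequence.
#' @param pwm A [pwm].
#' @param frac Fraction of the maximum score, in (0, 1].
#' @return `has_site()`: logical scalar. `site_presence()`: tibble
#'   `gene_id`, `pwm`, `best_score`, `present`, plus `is_target` if present
#'   in `regions`.
#' @export
has_site <- function(seq, pwm, frac = 0.5) {
  stopifnot(frac > 0, frac <= 1)
  nrow(scan_region(pwm, seq, frac * pwm_max_score(pwm))) > 0
}

#' @rdname has_site
#' @param regions Region tibble from [extract_upstream()].
#' @export
site_presence <- function(regions, pwm, frac = 0.5) {
  stopifnot(frac > 0, frac <= 1)
  thr <- frac * pwm_max_score(pwm)
  best <- vapply(regions$seq, function(s) {
    h <- scan_region(pwm, s, -Inf)
    if (nrow(h)) max(h$score) else -Inf
  }, numeric(1), USE.NAMES = FALSE)
  out <- tibble(gene_id = regions$gene_id, pwm = pwm_name(pwm),
                best_score = best, present = best >= thr)
  if ("is_target" %in% names(regions)) out$is_target <- regions$is_target
  out
}
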