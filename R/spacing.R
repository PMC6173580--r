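#' Profile query-site locations relative to an anchor motif
#'
#' Each promoter is anchored at its strongest hit to `anchor_pwm` (ties:
#' smaller start, then + strand); the signed offset of every `query_pwm`
#' hit above `query_threshold` is then collected as query midpoint minus
#' anchor midpoint in the toward-gene frame, so positive offsets lie
#' downstream of the anchor (toward the gene). Offsets are binned into
#' left-closed bins `[b, b + bin_size)` and each promoter counts at most
#' once per bin; bin proportions are relative to the number of anchored
#' promoters.
#'
#' @param regions Region tibble from [extract_upstream()].
#' @param anchor_pwm,query_pwm [pwm] objects.
#' @param query_threshold Minimum query-hit score.
#' @param bin_size Bin width in bp (1 for single-base profiles, 10 for
#'   coarse profiles).
#' @param require_presence If TRUE (default), only promoters where the
#'   anchor motif passes the presence cutoff contribute.
#' @param presence_frac Presence cutoff as a fraction of the anchor's
#'   maximum score.
#' @return A `rel_loc_profile` object: list with `offsets` (tibble
#'   `gene_id`, `offset`), `bins` (tibble `bin_start`, `n_promoters`,
#'   `proportion`), `n_anchored`, and the parameters.
#' @export
relative_locations <- function(regions, anchor_pwm, query_pwm,
                               query_threshold,
                               bin_size = 1,
                               require_presence = TRUE,
                               presence_frac = 0.5) {
  stopifnot(bin_size >= 1)
  offs <- vector("list", nrow(regions))
  n_anchored <- 0L
  for (i in seq_len(nrow(regions))) {
    s <- regions$seq[i]
    ah <- best_hit(scan_region(anchor_pwm, s, -Inf))
    if (!nrow(ah)) next
    if (require_presence &&
        ah$score[1] < presence_frac * pwm_max_score(anchor_pwm)) next
    n_anchored <- n_anchored + 1L
    qh <- scan_region(query_pwm, s, query_threshold)
    if (nrow(qh)) {
      offs[[i]] <- tibble(gene_id = regions$gene_id[i],
                          offset = qh$midpoint - ah$midpoint[1])
    }
  }
  offsets <- bind_rows(offs)
  if (!nrow(offsets))
    offsets <- tibble(gene_id = character(0), offset = integer(0))
  bins <- offsets |>
    mutate(bin_start = floor(.data$offset / bin_size) * bin_size) |>
    distinct(.data$gene_id, .data$bin_start) |>
    dplyr::count(.data$bin_start, name = "n_promoters") |>
    mutate(proportion = if (n_anchored > 0) .data$n_promoters / n_anchored
           else 0)
  structure(list(offsets = offsets, bins = bins, n_anchored = n_anchored,
                 anchor = pwm_name(anchor_pwm), query = pwm_name(query_pwm),
                 bin_size = bin_size, query_threshold = query_threshold),
            class = "rel_loc_profile")
}

#' @export
print.rel_loc_profile <- function(x, ...) {
  cat(sprintf("<rel_loc_profile> anchor %s, query %s: %d offsets over %d anchored promoters (bin %d bp)\n",
              x$anchor, x$query, nrow(x$offsets), x$n_anchored, x$bin_size))
  invisible(x)
}

#' Genome-wide search for promoters with paired sites at constrained spacing
#'
#' Finds promoters carrying an anchor site facing toward the gene (+ strand
#' in the toward-gene frame) with score above `min_score`, together with a
#' partner site (either strand, score above `min_score`) whose midpoint lies
#' `window[1]` to `window[2]` bp downstream of the anchor midpoint. The
#' partner motif gets no orientation filter (it is typically
#' quasi-palindromic). Every qualifying (anchor, partner) pair is returned;
#' use `dplyr::n_distinct(calls$gene_id)` for per-gene summary counts.
#'
#' @param regions Region tibble from [extract_upstream()].
#' @param anchor_pwm,partner_pwm [pwm] objects.
#' @param min_score Strict lower score bound for both sites (default 6).
#' @param window Inclusive spacing window in bp, midpoint to midpoint
#'   (default `c(52, 78)`).
#' @return Tibble: `gene_id`, `anchor_start`, `anchor_midpoint`,
#'   `anchor_score`, `partner_start`, `partner_strand`, `partner_midpoint`,
#'   `partner_score`, `spacing`.
#' @export
pair_search <- function(regions, anchor_pwm, partner_pwm,
                        min_score = 6.0, window = c(52, 78)) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  calls <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    s <- regions$seq[i]
    ah <- scan_region(anchor_pwm, s, -Inf)
    ah <- ah[ah$strand == "+" & ah$score > min_score, ]
    if (!nrow(ah)) next
    ph <- scan_region(partner_pwm, s, -Inf)
    ph <- ph[ph$score > min_score, ]
    if (!nrow(ph)) next
    grid <- tidyr::expand_grid(a = seq_len(nrow(ah)), p = seq_len(nrow(ph)))
    sp <- ph$midpoint[grid$p] - ah$midpoint[grid$a]
    keep <- sp >= window[1] & sp <= window[2]
    if (!any(keep)) next
    grid <- grid[keep, ]
    calls[[i]] <- tibble(
      gene_id = regions$gene_id[i],
      anchor_start = ah$start[grid$a],
      anchor_midpoint = ah$midpoint[grid$a],
      anchor_score = ah$score[grid$a],
      partner_start = ph$start[grid$p],
      partner_strand = ph$strand[grid$p],
      partner_midpoint = ph$midpoint[grid$p],
      partner_score = ph$score[grid$p],
      spacing = sp[keep]
    )
  }
  out <- bind_rows(calls)
  if (!nrow(out))
    out <- tibble(gene_id = character(0), anchor_start = integer(0),
                  anchor_midpoint = integer(0), anchor_score = numeric(0),
                  partner_start = integer(0), partner_strand = character(0),
                  partner_midpoint = integer(0), partner_score = numeric(0),
                  spacing = integer(0))
  out
}
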