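#' Exact hypergeometric tail probability
#'
#' Probability of observing at least (`direction = "ge"`) or at most
#' (`direction = "le"`) `k` marked genes among `n` drawn without replacement
#' from `M` genes of which `K` are marked. Computed through the log-space
#' tail of the hypergeometric distribution for numerical safety.
#'
#' @param k Observed marked count in the draw.
#' @param M Population size (all genes).
#' @param K Marked genes in the population.
#' @param n Draw (gene-set) size.
#' @param direction `"ge"` for the upper (enrichment) tail, `"le"` for the
#'   lower (depletion) tail. Both tails include the observed point mass.
#' @return Probability in (0, 1].
#' @export
#' @examples
#' hypergeom_tail(4, M = 10, K = 5, n = 4, direction = "ge") # 5/210
hypergeom_tail <- function(k, M, K, n, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  if (any(c(k, M, K, n) < 0) || K > M || n > M || k > min(K, n))
    stop_input("invalid hypergeometric parameters k=%s M=%s K=%s n=%s",
               k, M, K, n)
  lp <- if (direction == "ge") {
    stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE, log.p = TRUE)
  } else {
    stats::phyper(k, K, M - K, n, lower.tail = TRUE, log.p = TRUE)
  }
  exp(lp)
}

#' Classify enrichment strength from -log10(P)
#'
#' `"high"` above 6, `"moderate"` above 3 up to 6, `"absent"` otherwise;
#' both boundaries are strict, so exactly 3 or 6 falls in the lower class.
#'
#' @param neg_log10 Numeric vector of -log10 enrichment P values.
#' @return Character vector of classes.
#' @export
classify_enrichment <- function(neg_log10) {
  stopifnot(all(neg_log10 >= 0))
  ifelse(neg_log10 > 6, "high", ifelse(neg_log10 > 3, "moderate", "absent"))
}

#' Test a gene set for motif-presence enrichment
#'
#' Compares per-gene motif presence in a gene set against the genome under
#' the hypergeometric distribution: the genome is the population (`M` genes,
#' `K` with at least one site), the set is the draw (`n` genes, `k` with a
#' site). Both the enrichment tail `P(X >= k)` and the depletion tail
#' `P(X <= k)` are reported; only enrichment is classified - depletion is
#' reported but never classed.
#'
#' @param presence Tibble with columns `gene_id` and `present` (one row per
#'   genome gene), as returned by [site_presence()].
#' @param set_genes Character vector of gene ids forming the set (must be a
#'   subset of `presence$gene_id`), or NULL to use `presence$is_target`.
#' @return One-row tibble: `n`, `k`, `M`, `K`, `proportion` (`k/n`),
#'   `p_enrich`, `p_deplete`, `neg_log10`, `class`.
#' @export
motif_enrichment <- function(presence, set_genes = NULL) {
  if (is.null(set_genes)) {
    if (!("is_target" %in% names(presence)))
      stop_input("supply set_genes or an is_target column")
    set_genes <- presence$gene_id[presence$is_target]
  }
  if (!length(set_genes)) stop_input("gene set is empty")
  missing <- setdiff(set_genes, presence$gene_id)
  if (length(missing))
    stop_input("set gene '%s' absent from presence table", missing[1])
  in_set <- presence$gene_id %in% set_genes
  M <- nrow(presence)
  K <- sum(presence$present)
  n <- sum(in_set)
  k <- sum(presence$present[in_set])
  p_en <- hypergeom_tail(k, M, K, n, "ge")
  p_de <- hypergeom_tail(k, M, K, n, "le")
  nl10 <- -log10(p_en)
  tibble(n = n, k = k, M = M, K = K, proportion = k / n,
         p_enrich = p_en, p_deplete = p_de, neg_log10 = nl10,
         class = classify_enrichment(nl10))
}
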