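#' Normalize allelic counts and form per-replicate log2 ratios
#'
#' Two-step normalization of hybrid mRNA counts before any testing. First,
#' each mRNA count is divided by the total mRNA reads of its replicate
#' (library size; by default both alleles of a replicate share one library
#' total, since the hybrid's two alleles are sequenced together). Second, it
#' is divided by the gene's mean genomic-DNA count for the same allele,
#' averaged across the gDNA replicates; this cancels mappability, length and
#' copy-number effects, including a diploid (two-copy) parental genome.
#' The differential allelic expression of a gene in a replicate is the
#' normalized allele-A value over allele B, reported as log2.
#'
#' Genes with a zero mean gDNA count for either allele, or a zero mRNA count
#' for either allele in any replicate, have an undefined ratio and are
#' excluded with status `"excluded-zero"` rather than pseudocounted.
#'
#' @param counts Count tibble (see [read_counts()]).
#' @param totals `"replicate"` (default) to use the whole replicate's mRNA
#'   total as the library size, or `"allele"` for per-allele totals.
#' @return Tibble: `gene_id`, `replicate`, `log2_ratio`, `status`. Excluded
#'   genes appear once per replicate with `NA` ratios.
#' @export
ase_normalize <- function(counts, totals = c("replicate", "allele")) {
  totals <- match.arg(totals)
  counts <- validate_counts(counts)
  mrna <- counts[counts$assay == "mrna", ]
  gdna <- counts[counts$assay == "gdna", ]
  if (!nrow(gdna)) stop_input("no gDNA rows in counts table")
  tot <- if (totals == "replicate") {
    mrna |> group_by(.data$replicate) |>
      summarise(total = sum(.data$count), .groups = "drop")
  } else {
    mrna |> group_by(.data$replicate, .data$allele) |>
      summarise(total = sum(.data$count), .groups = "drop")
  }
  gmean <- gdna |>
    group_by(.data$gene_id, .data$allele) |>
    summarise(gdna_mean = mean(.data$count), .groups = "drop")
  x <- mrna |>
    left_join(tot, by = intersect(c("replicate", "allele"), names(tot))) |>
    left_join(gmean, by = c("gene_id", "allele"))
  excluded <- x |>
    group_by(.data$gene_id) |>
    summarise(excl = any(.data$gdna_mean == 0) | any(.data$count == 0),
              .groups = "drop")
  x <- x |>
    mutate(norm = .data$count / .data$total / .data$gdna_mean) |>
    select("gene_id", "allele", "replicate", "norm") |>
    tidyr::pivot_wider(names_from = "allele", values_from = "norm") |>
    left_join(excluded, by = "gene_id") |>
    mutate(log2_ratio = ifelse(.data$excl, NA_real_, log2(.data$A / .data$B)),
           status = ifelse(.data$excl, "excluded-zero", "tested")) |>
    select("gene_id", "replicate", "log2_ratio", "status")
  arrange(x, .data$gene_id, .data$replicate)
}

#' One-sample t-test on per-replicate log2 allelic ratios
#'
#' Two-sided one-sample t-test of mean log2 ratio = 0 with R - 1 degrees of
#' freedom. Zero-variance inputs are degenerate: a nonzero mean gives an
#' epsilon p-value (1e-300), a zero mean gives p = 1.
#'
#' @param log2_ratios Numeric vector, one value per replicate (length >= 2).
#' @return One-row tibble `t`, `p`, `degenerate`.
#' @export
ase_gene_test <- function(log2_ratios) {
  r <- log2_ratios
  if (length(r) < 2) stop_input("need at least 2 replicates")
  m <- mean(r)
  s <- stats::sd(r)
  if (s == 0) {
    if (m == 0) return(tibble(t = 0, p = 1, degenerate = TRUE))
    return(tibble(t = sign(m) * Inf, p = 1e-300, degenerate = TRUE))
  }
  t <- m / (s / sqrt(length(r)))
  tibble(t = t, p = 2 * stats::pt(-abs(t), df = length(r) - 1),
         degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_i = min_{j >= rank(i)} p_(j) * m / j`, capped
#' at 1.
#'
#' @param p Numeric vector of p-values (tested genes only).
#' @return Numeric vector of q-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Per-gene differential allelic expression test
#'
#' Runs the full per-gene pipeline: normalization ([ase_normalize()]),
#' two-sided one-sample t-tests on the log2 ratios across replicates, and
#' Benjamini-Hochberg FDR control over the tested genes. Excluded genes are
#' kept in the output with `NA` statistics.
#'
#' @param counts Count tibble (see [read_counts()]).
#' @param fdr FDR level for the `significant` flag (default 0.05).
#' @param totals Library-size convention, see [ase_normalize()].
#' @return Tibble: `gene_id`, `n_reps`, `mean_log2`, `t`, `p`, `q`,
#'   `significant`, `degenerate`, `status`.
#' @export
ase_test <- function(counts, fdr = 0.05, totals = "replicate") {
  norm <- ase_normalize(counts, totals = totals)
  res <- norm |>
    group_by(.data$gene_id) |>
    summarise(n_reps = dplyr::n(),
              status = .data$status[1],
              mean_log2 = mean(.data$log2_ratio),
              sd_log2 = stats::sd(.data$log2_ratio),
              .groups = "drop")
  tested <- res$status == "tested"
  t <- rep(NA_real_, nrow(res)); p <- rep(NA_real_, nrow(res))
  degen <- rep(NA, nrow(res))
  zv <- tested & res$sd_log2 == 0
  ok <- tested & !zv
  t[ok] <- res$mean_log2[ok] / (res$sd_log2[ok] / sqrt(res$n_reps[ok]))
  p[ok] <- 2 * stats::pt(-abs(t[ok]), df = res$n_reps[ok] - 1)
  degen[ok] <- FALSE
  t[zv] <- sign(res$mean_log2[zv]) * Inf
  p[zv] <- ifelse(res$mean_log2[zv] == 0, 1, 1e-300)
  t[zv & res$mean_log2 == 0] <- 0
  degen[zv] <- TRUE
  q <- rep(NA_real_, nrow(res))
  q[tested] <- bh_adjust(p[tested])
  res |>
    mutate(t = t, p = p, q = q,
           significant = !is.na(q) & q <= fdr & .data$status == "tested",
           degenerate = degen) |>
    select("gene_id", "n_reps", "mean_log2", "t", "p", "q",
           "significant", "degenerate", "status")
}

#' Group-level directional cis-regulatory test
#'
#' Asks whether a gene group (e.g. the ribosomal protein genes) has evolved
#' expression in a concerted direction. The group statistic is the geometric
#' mean fold change, `2^mean(mean_log2)` over the group. Enrichment of
#' directional genes is then tested with the hypergeometric upper tail in
#' both directions - genes at least `fold`-fold up (mean_log2 >=
#' log2(fold)) and at least `fold`-fold down - and the reported `p` is the
#' tail matching the geometric-mean direction (p = 1 when the geometric
#' mean is exactly 1).
#'
#' @param results Per-gene tibble from [ase_test()].
#' @param group_genes Character vector of gene ids (must be tested genes).
#' @param fold Fold-change threshold (default 1.1).
#' @param group_name Label for the output row.
#' @return One-row tibble: `group`, `n`, `M`, `geo_mean_fold`, `direction`,
#'   `k_up`, `K_up`, `p_up`, `k_down`, `K_down`, `p_down`, `p`.
#' @export
group_directional_test <- function(results, group_genes, fold = 1.1,
                                   group_name = "group") {
  tested <- results[results$status == "tested", ]
  if (!length(group_genes)) stop_input("empty gene group")
  miss <- setdiff(group_genes, tested$gene_id)
  if (length(miss))
    stop_input("group gene '%s' is not among tested genes", miss[1])
  in_grp <- tested$gene_id %in% group_genes
  lf <- log2(fold)
  M <- nrow(tested); n <- sum(in_grp)
  up <- tested$mean_log2 >= lf
  dn <- tested$mean_log2 <= -lf
  k_up <- sum(up[in_grp]); K_up <- sum(up)
  k_dn <- sum(dn[in_grp]); K_dn <- sum(dn)
  p_up <- hypergeom_tail(k_up, M, K_up, n, "ge")
  p_dn <- hypergeom_tail(k_dn, M, K_dn, n, "ge")
  gm_log <- mean(tested$mean_log2[in_grp])
  direction <- if (gm_log > 0) "up-A" else if (gm_log < 0) "down-A" else "none"
  p <- switch(direction, `up-A` = p_up, `down-A` = p_dn, none = 1)
  tibble(group = group_name, n = n, M = M,
         geo_mean_fold = 2^gm_log, direction = direction,
         k_up = k_up, K_up = K_up, p_up = p_up,
         k_down = k_dn, K_down = K_dn, p_down = p_dn, p = p)
}
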