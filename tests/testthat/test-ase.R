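make_counts <- function(mrna_a, mrna_b, gdna_a, gdna_b) {
  # single-gene helper with equal library sizes balanced by a filler gene
  genes <- c("g1", "g2")
  reps <- seq_along(mrna_a)
  rows <- list()
  tot <- max(mrna_a + mrna_b) * 2
  for (r in reps) {
    filler_a <- tot - mrna_a[r]
    filler_b <- tot - mrna_b[r]
    rows[[r]] <- tibble::tibble(
      gene_id = rep(genes, each = 2),
      allele = rep(c("A", "B"), 2),
      assay = "mrna", replicate = r,
      count = c(mrna_a[r], mrna_b[r], filler_a, filler_b)
    )
  }
  gd <- tibble::tibble(
    gene_id = rep(genes, each = 2),
    allele = rep(c("A", "B"), 2),
    assay = "gdna", replicate = 1L,
    count = c(gdna_a, gdna_b, 100, 100)
  )
  dplyr::bind_rows(c(rows, list(gd)))
}

test_that("normalization divides by library totals then mean gDNA", {
  # mrna A=100, B=50 with equal replicate totals; gdna A=200, B=400
  counts <- make_counts(100, 50, 200, 400)
  norm <- ase_normalize(counts)
  g1 <- norm[norm$gene_id == "g1", ]
  # (100/T)/200 over (50/T)/400 = 4 => log2 = 2
  expect_equal(g1$log2_ratio, 2.0)
  expect_equal(g1$status, "tested")
})

test_that("equal counts give zero log-ratios and zeros are excluded", {
  counts <- make_counts(c(80, 80), c(80, 80), 300, 300)
  norm <- ase_normalize(counts)
  expect_equal(norm$log2_ratio[norm$gene_id == "g1"], c(0, 0))

  z <- make_counts(c(10, 10), c(0, 5), 100, 100)
  norm <- ase_normalize(z)
  expect_true(all(norm$status[norm$gene_id == "g1"] == "excluded-zero"))
  expect_true(all(is.na(norm$log2_ratio[norm$gene_id == "g1"])))

  zg <- make_counts(c(10, 10), c(5, 5), 100, 0)
  norm <- ase_normalize(zg)
  expect_true(all(norm$status[norm$gene_id == "g1"] == "excluded-zero"))
})

test_that("library-size and ploidy rescalings leave log2 ratios unchanged", {
  set.seed(101)
  sim <- simulate_ase(300, n_reps = 4, effect = rnorm(300, 0, 0.5))
  base <- ase_normalize(sim$counts)

  # multiply all mRNA counts of replicate 2 by a constant
  scaled <- sim$counts
  sel <- scaled$assay == "mrna" & scaled$replicate == 2
  scaled$count[sel] <- scaled$count[sel] * 7
  expect_equal(ase_normalize(scaled)$log2_ratio, base$log2_ratio,
               tolerance = 1e-12)

  # double allele B genome-wide in both mRNA and gDNA (extra ploidy)
  dbl <- sim$counts
  sel <- dbl$allele == "B"
  dbl$count[sel] <- dbl$count[sel] * 2
  expect_equal(ase_normalize(dbl)$log2_ratio, base$log2_ratio,
               tolerance = 1e-12)
})

test_that("allele swap negates every mean log2 ratio and preserves p-values", {
  set.seed(103)
  sim <- simulate_ase(400, n_reps = 5, effect = rnorm(400, 0, 0.4),
                      dispersion = 0.05)
  res <- ase_test(sim$counts)
  swapped <- sim$counts
  swapped$allele <- ifelse(swapped$allele == "A", "B", "A")
  res2 <- ase_test(swapped)
  tested <- res$status == "tested"
  expect_equal(res2$mean_log2[tested], -res$mean_log2[tested],
               tolerance = 1e-12)
  expect_equal(res2$p[tested], res$p[tested], tolerance = 1e-12)
})

test_that("the one-sample t-test matches the df-2 closed form", {
  got <- ase_gene_test(c(1.0, 1.2, 0.8))
  expect_equal(got$t, 1 / (0.2 / sqrt(3)), tolerance = 1e-6)
  # closed-form df = 2 CDF: F(t) = 1/2 (1 + t / sqrt(t^2 + 2))
  tt <- got$t
  want_p <- 2 * (1 - 0.5 * (1 + tt / sqrt(tt^2 + 2)))
  expect_equal(got$p, want_p, tolerance = 1e-10)
  expect_equal(got$p, 0.013072, tolerance = 1e-4) # value of the closed form

  expect_equal(ase_gene_test(c(-1, 1))$t, 0)
  expect_equal(ase_gene_test(c(-1, 1))$p, 1)
  degen <- ase_gene_test(c(0, 0, 0))
  expect_equal(degen$p, 1)
  expect_true(degen$degenerate)
  degen2 <- ase_gene_test(c(0.5, 0.5))
  expect_lt(degen2$p, 1e-100)
  expect_true(degen2$degenerate)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  m <- length(p)
  want <- rev(cummin(rev(sort(p) * m / seq_len(m))))[order(order(p))]
  expect_equal(bh_adjust(p), pmin(want, 1))
})

test_that("per-gene p-values are calibrated under the global null", {
  set.seed(107)
  pvals <- unlist(replicate(4, {
    sim <- simulate_ase(800, n_reps = 7, effect = 0, dispersion = 0.05)
    res <- ase_test(sim$counts)
    list(res$p[res$status == "tested" & !res$degenerate])
  }))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
  # the small-p tail drives BH: it must not be inflated
  expect_lte(mean(pvals < 0.001), 0.002)
})

test_that("planted effects are recovered with small bias and detected", {
  set.seed(109)
  effects <- c(rep(1, 50), rep(0, 950))
  sim <- simulate_ase(1000, n_reps = 7, effect = effects, dispersion = 0.05)
  res <- ase_test(sim$counts)
  res <- dplyr::left_join(res, sim$truth, by = "gene_id")
  tested <- res$status == "tested"
  expect_lt(abs(mean(res$mean_log2[tested] - res$effect[tested])), 0.05)
  planted <- tested & res$effect == 1
  expect_gte(mean(res$significant[planted]), 0.9)
})

test_that("the diploid gDNA artifact is fully corrected under the null", {
  set.seed(113)
  sim <- simulate_ase(4000, n_reps = 3, effect = 0, ploidy_b = 2)
  res <- ase_test(sim$counts)
  expect_lt(abs(median(res$mean_log2[res$status == "tested"])), 0.02)
})

test_that("group directional test reproduces the exact combinatorial example", {
  # group of 5 with 4 genes >= 1.1-fold up; genome 100 with 20 such genes
  res <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:100),
    mean_log2 = c(rep(log2(1.2), 4), -0.01,           # group: 4 up, 1 flat
                  rep(log2(1.2), 16), rep(0, 79)),
    status = "tested"
  )
  out <- group_directional_test(res, sprintf("g%03d", 1:5), fold = 1.1)
  expect_equal(out$k_up, 4)
  expect_equal(out$K_up, 20)
  expect_equal(out$direction, "up-A")
  expect_equal(out$p, 403104 / 75287520, tolerance = 1e-12)
  expect_equal(out$p_up, out$p)

  # perfectly balanced group: geometric mean 1, no direction, p = 1
  bal <- tibble::tibble(gene_id = c("a", "b", sprintf("x%02d", 1:20)),
                        mean_log2 = c(1, -1, rnorm(20, 0, 0.01)),
                        status = "tested")
  out2 <- group_directional_test(bal, c("a", "b"))
  expect_equal(out2$geo_mean_fold, 1.0)
  expect_equal(out2$direction, "none")
  expect_equal(out2$p, 1)

  expect_error(group_directional_test(res, character(0)), "empty")
  expect_error(group_directional_test(res, "zzz"), "not among tested")
})

test_that("a planted coordinated shift in a gene group is detected", {
  set.seed(127)
  hits <- 0
  nsim <- 20
  for (i in seq_len(nsim)) {
    effects <- c(rep(0.26, 100), rep(0, 3900)) # ~1.2-fold concerted shift
    sim <- simulate_ase(4000, n_reps = 7, effect = effects, dispersion = 0.04)
    res <- ase_test(sim$counts)
    grp <- sim$truth$gene_id[sim$truth$effect > 0]
    grp <- intersect(grp, res$gene_id[res$status == "tested"])
    out <- group_directional_test(res, grp, fold = 1.1)
    if (out$p < 0.01) hits <- hits + 1
  }
  expect_gte(hits, ceiling(0.95 * nsim))
})
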