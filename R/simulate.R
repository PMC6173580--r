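#' Simulate an annotated genome
#'
#' Generates i.i.d. background sequence at a stated GC content, laid out as
#' one contig per gene with the gene body and its dedicated upstream
#' intergenic block, alternating gene orientation between + and - so both
#' strand conventions are exercised. Because each contig holds one gene,
#' [extract_upstream()] recovers each intergenic block exactly (truncated at
#' the contig edge), which makes planted-site coordinates exact.
#'
#' Randomness comes from R's global RNG; call `set.seed()` first for
#' reproducible genomes.
#'
#' @param n_genes Number of genes (>= 1).
#' @param intergenic_len Length of each upstream intergenic block, a single
#'   value or a vector recycled over genes.
#' @param gene_len Gene body length.
#' @param gc GC content of the background sequence, in (0, 1).
#' @param target_genes Gene ids (of the form `g0001`...) flagged as the
#'   target set.
#' @return A [genome_bundle()].
#' @export
make_genome <- function(n_genes, intergenic_len = 500, gene_len = 300,
                        gc = 0.40, target_genes = character(0)) {
  stopifnot(n_genes >= 1, all(intergenic_len >= 1), gene_len >= 1,
            gc > 0, gc < 1)
  ilen <- rep_len(as.integer(intergenic_len), n_genes)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  ids <- sprintf("g%04d", seq_len(n_genes))
  strands <- rep_len(c("+", "-"), n_genes)
  contigs <- character(n_genes)
  genes <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    L <- ilen[i] + gene_len
    seq <- paste(sample(DNA_BASES, L, replace = TRUE, prob = probs),
                 collapse = "")
    contigs[i] <- seq
    if (strands[i] == "+") {
      gs <- ilen[i]; ge <- L # intergenic first, then gene
    } else {
      gs <- 0L; ge <- gene_len # gene first, intergenic after (5' on -)
    }
    genes[[i]] <- tibble(gene_id = ids[i], contig = sprintf("c%04d", i),
                         start = gs, end = ge, strand = strands[i],
                         is_target = ids[i] %in% target_genes)
  }
  names(contigs) <- sprintf("c%04d", seq_len(n_genes))
  genome_bundle(contigs, bind_rows(genes))
}

# Degrade a consensus window to a target score fraction by greedy
# minimal-loss substitutions. Returns list(seq, score).
degrade_consensus <- function(pwm, score_frac) {
  if (score_frac <= 0 || score_frac > 1)
    stop_input("score_frac must be in (0, 1]")
  m <- unclass(pwm)
  L <- nrow(m)
  best <- apply(m, 1, which.max)
  target <- score_frac * pwm_max_score(pwm)
  # candidate single-base substitutions, cheapest loss first
  cand <- do.call(rbind, lapply(seq_len(L), function(i) {
    data.frame(pos = i, base = seq_len(4),
               loss = m[i, best[i]] - m[i, ])
  }))
  cand <- cand[cand$loss > 0, ]
  cand <- cand[order(cand$loss), ]
  cur <- best
  score <- pwm_max_score(pwm)
  used <- rep(FALSE, L)
  for (r in seq_len(nrow(cand))) {
    if (used[cand$pos[r]]) next # one substitution per position
    if (score - cand$loss[r] >= target) {
      cur[cand$pos[r]] <- cand$base[r]
      score <- score - cand$loss[r]
      used[cand$pos[r]] <- TRUE
    }
  }
  list(seq = paste(DNA_BASES[cur], collapse = ""), score = score)
}

#' Plant motif instances in promoter regions
#'
#' Writes motif instances of controlled score into intergenic regions at
#' prescribed positions. Each site starts from the PWM consensus and is
#' degraded by greedy minimal-loss substitutions until its score is as close
#' as possible to, but never below, `score_frac` of the maximum score.
#' Positions are given as `gap`: the number of bases between the motif's
#' gene-proximal end and the gene start, in the toward-gene frame. `strand`
#' is the motif's orientation within that frame.
#'
#' @param genome A [genome_bundle()].
#' @param pwm A [pwm].
#' @param sites Tibble with columns `gene_id`, `gap`, and optionally
#'   `strand` (default `+`) and `score_frac` (default 1).
#' @param max_len Promoter length used to compute planted region-frame
#'   coordinates in the returned truth table.
#' @return List with the modified `genome` and `truth`, a tibble recording
#'   for every planted site its gene, gap, strand, planted score,
#'   region-frame `start` and `midpoint` (assuming extraction at
#'   `max_len`), and sequence written.
#' @export
plant_sites <- function(genome, pwm, sites, max_len = 1000) {
  sites <- as_tibble(sites)
  if (!("strand" %in% names(sites))) sites$strand <- "+"
  if (!("score_frac" %in% names(sites))) sites$score_frac <- 1
  regions <- extract_upstream(genome, max_len = max_len)
  L <- pwm_length(pwm)
  truth <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    sp <- sites[i, ]
    g <- genome$genes[genome$genes$gene_id == sp$gene_id, ]
    if (!nrow(g)) stop_input("plant target gene '%s' not found", sp$gene_id)
    reg <- regions[regions$gene_id == sp$gene_id, ]
    if (!nrow(reg) || sp$gap + L > reg$length)
      stop_input("planted site does not fit in the region of '%s'", sp$gene_id)
    inst <- degrade_consensus(pwm, sp$score_frac)
    motif <- if (sp$strand == "+") inst$seq else revcomp(inst$seq)
    # toward-gene frame start of the motif within the region
    rstart <- reg$length - sp$gap - L
    contig <- genome$contigs[[g$contig]]
    if (g$strand == "+") {
      a <- reg$g_start + rstart # genomic 0-based
      substr(contig, a + 1L, a + L) <- motif
    } else {
      # region frame is the reverse complement of [g_start, g_end)
      a <- reg$g_end - rstart - L
      substr(contig, a + 1L, a + L) <- revcomp(motif)
    }
    genome$contigs[[g$contig]] <- contig
    truth[[i]] <- tibble(gene_id = sp$gene_id, pwm = pwm_name(pwm),
                         gap = sp$gap, strand = sp$strand,
                         score_frac = sp$score_frac, score = inst$score,
                         region_start = rstart,
                         region_midpoint = rstart + L %/% 2L,
                         planted_seq = inst$seq)
  }
  list(genome = genome, truth = bind_rows(truth))
}

#' Plant anchor/partner site pairs at fixed spacing
#'
#' Plants a toward-gene-oriented anchor site and a partner site whose
#' midpoint lies `spacing` bp downstream (toward the gene) of the anchor
#' midpoint, as used by the paired-site search.
#'
#' @param genome A [genome_bundle()].
#' @param anchor_pwm,partner_pwm [pwm] objects.
#' @param pairs Tibble with columns `gene_id`, `spacing`, and optionally
#'   `partner_gap` (bases between the partner's gene-proximal end and the
#'   gene start, default 10) and `score_frac` (both sites, default 1).
#' @param max_len As in [plant_sites()].
#' @return List with `genome` and `truth` (one row per pair: gene,
#'   spacing, anchor and partner region-frame midpoints).
#' @export
plant_pairs <- function(genome, anchor_pwm, partner_pwm, pairs,
                        max_len = 1000) {
  pairs <- as_tibble(pairs)
  if (!("score_frac" %in% names(pairs))) pairs$score_frac <- 1
  La <- pwm_length(anchor_pwm); Lp <- pwm_length(partner_pwm)
  # with gap g, midpoint = region_len - g - L + floor(L/2); solving
  # partner_mid - anchor_mid = spacing for the anchor gap:
  partner_gap <- if ("partner_gap" %in% names(pairs)) pairs$partner_gap
                 else rep(10L, nrow(pairs))
  anchor_gap <- pairs$spacing + partner_gap -
    (La - La %/% 2L) + (Lp - Lp %/% 2L)
  anchor <- plant_sites(genome, anchor_pwm,
                        tibble(gene_id = pairs$gene_id, gap = anchor_gap,
                               strand = "+", score_frac = pairs$score_frac),
                        max_len = max_len)
  partner <- plant_sites(anchor$genome, partner_pwm,
                         tibble(gene_id = pairs$gene_id, gap = partner_gap,
                                strand = "+", score_frac = pairs$score_frac),
                         max_len = max_len)
  list(genome = partner$genome,
       truth = tibble(gene_id = pairs$gene_id, spacing = pairs$spacing,
                      anchor_midpoint = anchor$truth$region_midpoint,
                      partner_midpoint = partner$truth$region_midpoint,
                      anchor_score = anchor$truth$score,
                      partner_score = partner$truth$score))
}

#' Simulate a Yule (pure-birth) tree
#'
#' Unit speciation rate, `n_tips` extant tips, branch lengths retained.
#' Deterministic under `set.seed()`.
#'
#' @param n_tips Number of tips (>= 2).
#' @return A rooted `phylo` tree with tips `t1`, `t2`, ...
#' @export
make_tree <- function(n_tips) {
  stopifnot(n_tips >= 2)
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  validate_tree(tr)
}

#' Forward-simulate a binary character on a tree
#'
#' Draws the root state from the model's root prior and runs the two-state
#' chain forward down every branch, recording the true history: the number
#' of gains and losses on each branch and overall.
#'
#' @param tree Rooted `phylo` tree.
#' @param model List with `q01`, `q10` and optionally `root_prior`.
#' @return List: `states` (named 0/1 vector over tips), `node_states`
#'   (per ape node index), `truth` (tibble `edge`, `gains`, `losses`),
#'   `gains`, `losses` (totals).
#' @export
simulate_character <- function(tree, model) {
  tree <- validate_tree(tree)
  prior <- model$root_prior %||% c(0.5, 0.5)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  ns <- integer(nn)
  root <- ntip + 1L
  ns[root] <- as.integer(stats::runif(1) < prior[2])
  rates <- c(model$q01, model$q10) # leaving-state rate by current state
  eg <- integer(nrow(tree$edge)); el <- integer(nrow(tree$edge))
  for (i in rev(seq_len(nrow(tree$edge)))) { # preorder
    s <- ns[tree$edge[i, 1]]
    t <- tree$edge.length[i]
    pos <- 0
    repeat {
      r <- rates[s + 1L]
      if (r <= 0) break
      pos <- pos + stats::rexp(1, r)
      if (pos >= t) break
      if (s == 0L) eg[i] <- eg[i] + 1L else el[i] <- el[i] + 1L
      s <- 1L - s
    }
    ns[tree$edge[i, 2]] <- s
  }
  states <- ns[seq_len(ntip)]
  names(states) <- tree$tip.label
  list(states = states, node_states = ns,
       truth = tibble(edge = seq_len(nrow(tree$edge)), gains = eg, losses = el),
       gains = sum(eg), losses = sum(el))
}

#' Simulate an allele-specific expression count table
#'
#' Emulates an interspecies-hybrid experiment with known truth. Per-gene
#' baseline expression is lognormal; a per-gene mappability/length factor
#' multiplies both the mRNA and gDNA means of a gene (and cancels under
#' gDNA normalization). Allele B's mRNA mean is the allele A mean times
#' `2^(-effect)` times `ploidy_b`, so `effect` is the true log2 allelic
#' effect (A over B) after ploidy correction. Biological replicate noise is
#' a per-gene, per-replicate lognormal jitter of the allelic ratio with
#' standard deviation `rep_noise` on the log2 scale, split symmetrically
#' between the alleles. mRNA counts are negative binomial with variance
#' `(1 + dispersion) * mu` (extra-Poisson inflation; exactly Poisson when
#' `dispersion = 0`); gDNA counts are Poisson around `gdna_depth` times the
#' gene factor times ploidy. The gDNA depth default is high (deep genomic
#' sequencing) because the per-gene test treats the gDNA correction as a
#' known constant; shallow gDNA would make it anti-conservative.
#'
#' @param n_genes Number of genes.
#' @param n_reps mRNA replicates (>= 2; 7 matches the larger hybrid).
#' @param effect Per-gene true log2 effect: scalar or length-`n_genes`
#'   vector.
#' @param ploidy_b Copy number of the allele-B genome (2 emulates a diploid
#'   parent).
#' @param dispersion Negative-binomial dispersion of mRNA counts.
#' @param n_gdna_reps gDNA replicates.
#' @param depth Mean mRNA depth per gene; `gdna_depth` likewise for gDNA.
#' @param gdna_depth Mean gDNA depth per gene per copy.
#' @param rep_noise Biological replicate noise of the allelic ratio
#'   (log2-scale standard deviation).
#' @return List: `counts` (tibble in [read_counts()] layout) and `truth`
#'   (tibble `gene_id`, `effect`, `ploidy_b`).
#' @export
simulate_ase <- function(n_genes, n_reps = 7, effect = 0, ploidy_b = 1,
                         dispersion = 0, n_gdna_reps = 2,
                         depth = 200, gdna_depth = 5000, rep_noise = 0.2) {
  stopifnot(n_genes >= 1, n_reps >= 2, n_gdna_reps >= 1, ploidy_b > 0)
  effect <- rep_len(effect, n_genes)
  ids <- sprintf("g%05d", seq_len(n_genes))
  base <- stats::rlnorm(n_genes, meanlog = log(depth), sdlog = 0.5)
  gfac <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 0.4)
  mu_a <- base * gfac
  mu_b <- base * gfac * 2^(-effect) * ploidy_b
  draw <- function(mu) {
    mu <- pmax(mu, 1e-9)
    if (dispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = mu / dispersion)
    } else {
      stats::rpois(length(mu), mu)
    }
  }
  # biological replicate noise on the allelic ratio, split between alleles
  eps <- matrix(stats::rnorm(n_genes * n_reps, 0, rep_noise), n_genes, n_reps)
  mrna <- tidyr::expand_grid(replicate = seq_len(n_reps),
                             allele = c("A", "B")) |>
    purrr::pmap(function(replicate, allele) {
      mu <- if (allele == "A") mu_a * 2^(eps[, replicate] / 2)
            else mu_b * 2^(-eps[, replicate] / 2)
      tibble(gene_id = ids, allele = allele, assay = "mrna",
             replicate = replicate, count = draw(mu))
    }) |>
    bind_rows()
  gmu_a <- gdna_depth * gfac
  gmu_b <- gdna_depth * gfac * ploidy_b
  gdna <- tidyr::expand_grid(replicate = seq_len(n_gdna_reps),
                             allele = c("A", "B")) |>
    purrr::pmap(function(replicate, allele) {
      mu <- if (allele == "A") gmu_a else gmu_b
      tibble(gene_id = ids, allele = allele, assay = "gdna",
             replicate = replicate, count = stats::rpois(length(mu), mu))
    }) |>
    bind_rows()
  list(counts = bind_rows(mrna, gdna),
       truth = tibble(gene_id = ids, effect = effect, ploidy_b = ploidy_b))
}
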