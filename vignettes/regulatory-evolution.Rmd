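---
title: "Methods: quantifying parallel cis-regulatory evolution with regevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying parallel cis-regulatory evolution with regevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regevo)
library(dplyr)
```

regevo implements a complete desk-scale workflow for studying how
transcription-factor binding sites in gene promoters are gained and lost
across a clade, and whether a gene group (typically the ribosomal protein
genes, RPGs) has evolved its expression in a concerted direction in *cis*.
The workflow has four statistical components — promoter motif scanning,
gene-set enrichment, stochastic character mapping on a phylogeny, and
allele-specific expression (ASE) analysis in interspecies hybrids — plus a
set of simulators that generate every input with known ground truth. This
vignette explains the models, the defaults, the numerical choices, and what
the synthetic data do and do not establish about real data.

## Promoter extraction and PWM scanning

A gene's promoter proxy is the intergenic sequence immediately 5' of the
gene, up to `max_len = 1000` bp. One kilobase is the conventional choice for
compact fungal genomes, where intergenic distances are short and regulatory
sites sit close to the gene; results in this family of analyses are robust
to 500–1500 bp. The region is truncated at the nearest boundary of any
other annotated gene, without regard to that gene's strand: a shared
divergent promoter is deliberately assigned to *both* flanking genes in
full, since either gene may be regulated from anywhere in the shared
interval. A gene whose 5' flank is entirely covered by another gene gets no
region and is dropped with a warning. Minus-strand genes are
reverse-complemented so every stored region reads left to right *toward*
the gene; all downstream coordinates live in this toward-gene frame.

Binding sites are scored with position weight matrices (PWMs) carrying
per-position, per-base log-likelihood scores. A window of matching length
scores the sum of its per-position values; both strands are scanned at
every offset, the minus strand by scoring the reverse complement (computed,
equivalently, with the reverse-complemented matrix). Three conventions
matter:

* **Ambiguity codes.** An `N` contributes the per-position *minimum* score.
  This is pessimistic by design: assembly gaps can never fabricate a hit.
* **Site location.** A hit's position is the motif midpoint,
  `start + floor(length / 2)`. For odd motif lengths the floor makes the
  convention deterministic.
* **Presence.** A promoter "has" a site when any window on either strand
  reaches a fraction `frac = 0.5` of the PWM's maximum achievable score
  (the column-max sum, always recomputed from the matrix). The 50% cutoff
  is the conventional presence threshold for this type of survey and is a
  plain argument everywhere it appears.

Matrices are taken as-is, with no per-genome GC-content renormalization.
The scan asks which sequences most resemble the canonical site, not which
are most surprising given local base composition; composition effects are
soaked up downstream by the enrichment test, which compares a gene set
against the same genome scanned with the same matrix.

## Gene-set enrichment

Presence is a per-gene Boolean — at least one site — not a site count, so
a long promoter with five sites counts once. With `M` genes genome-wide,
`K` of them with a site, and `k` of the `n` set genes with a site, the
enrichment P value is the exact hypergeometric upper tail
`P(X >= k)` (computed in log space via `stats::phyper`), and the depletion
tail `P(X <= k)` is reported alongside. Enrichment strength is classified
on `-log10(P)`: *high* above 6, *moderate* above 3 up to 6, *absent*
otherwise. Both boundaries are strict — a value of exactly 3 or 6 falls in
the lower class; the choice at the boundary is arbitrary and is documented
rather than guessed, since real values land exactly on a boundary with
probability zero. Depletion is reported but never classified. When motif
presence is converted to the binary character for the phylogenetic
analysis below, the *moderate-or-better* rule (`-log10(P) > 3`) is used.

## Gains and losses on the phylogeny

Motif presence per species is a binary character on a rooted tree with
branch lengths. The two-state Mk model has gain rate `q01` and loss rate
`q10` per unit branch length; the transition matrix has the closed form
`P(t) = pi + (I - pi) exp(-(q01 + q10) t)` with `pi` the stationary
distribution. Two model variants are fitted by maximum likelihood with
Felsenstein pruning: ER (equal rates, one parameter, bounded 1-D
optimisation on the log scale) and ARD (all rates different, 2-D
L-BFGS-B started from the ER optimum, with a guard that the ARD likelihood
can never fall below the nested ER optimum). The root prior is fixed at
(1/2, 1/2); the data here are rarely informative about the root, and the
equal prior is the standard neutral default. A constant character carries
no rate information: the fit warns and pins both rates at a floor of
`1e-8` rather than 0, so downstream path sampling remains well-defined.

Histories are then drawn as stochastic character maps, conditional on the
tip data and on the fitted rates (empirical Bayes — the conventional
default of the standard tools; integrating over a rate posterior by MCMC
is out of scope and would mostly widen the loss interval under ARD).
Sampling is two-stage:

1. **Node states.** One pruning pass computes per-node conditional
   likelihoods; node states are then drawn root-down from the exact
   conditionals. This stage is vectorised across all requested maps at
   once.
2. **Branch paths.** Each branch is filled in by endpoint-conditioned path
   sampling via uniformization: with dominating rate
   `lambda = 1.05 * max(q01, q10)`, the number of virtual jumps is drawn
   from its endpoint-conditioned distribution (Poisson mixture truncated
   at cumulative mass `1 - 1e-12`), the discrete bridge is sampled jump by
   jump, jump times are uniform order statistics, and self-transitions are
   collapsed. The 5% cushion on `lambda` keeps the kernel strictly
   aperiodic so short branches mix correctly.

`sample_maps()` records per-map gain/loss counts and node states, which is
all the summaries need; 10,000 maps on a 162-tip tree take seconds.
`sample_map()` (or `detail = TRUE`) retains full per-branch segment paths,
with counts derived from those same paths so segments and counts can never
disagree. Summaries report the mean and the 95% highest-posterior-density
interval of the per-map gain and loss counts. On discrete counts the HPD
is defined as the shortest contiguous run of sorted samples holding at
least the target mass, ties resolved toward the smaller lower bound, so
both bounds are attained sample values and print as integers. Nodes whose
fraction of maps in the derived state falls strictly between 0.2 and 0.8
are flagged as uncertain ancestral reconstructions.

Correctness is established against independent oracles: the pruning
likelihood against exhaustive summation over all internal-node state
assignments (trees up to 6 tips, agreement to 1e-10) and against a
closed-form two-tip expression; the path sampler against rejection
sampling of forward trajectories (total-variation distance below 0.02 at
10^4 samples); sampled node-state frequencies against exact marginal
ancestral probabilities computed by an inside–outside pass (maximum
deviation below 0.02 at 10^4 maps); and every sampled history is bounded
below by the Fitch parsimony score.

## Allele-specific expression in hybrids

In an interspecies hybrid both parental alleles share one nucleus and one
*trans* environment, so a reproducible expression imbalance between
alleles isolates *cis*-regulatory divergence. Per-gene, per-allele read
counts from mRNA and genomic DNA (gDNA) are normalized in two steps:

1. divide each mRNA count by the total mRNA reads of its replicate (both
   alleles together form one library, so the replicate total is the
   natural size factor; a per-allele variant is available via `totals`);
2. divide by the gene-and-allele mean gDNA count, averaged across the gDNA
   replicates of the hybrid, which cancels mappability, gene length, and
   copy number — including a diploid parental genome contributing two
   copies of one allele.

The differential allelic expression of a gene in a replicate is the log2
ratio of the normalized allele-A value over allele B. Genes with zero mean
gDNA for either allele, or a zero mRNA count for either allele in any
replicate, have undefined ratios and are excluded (`excluded-zero`) rather
than pseudocounted — a pseudocount would shrink exactly the genes where
the data are weakest toward no effect, silently. Each tested gene gets a
two-sided one-sample t-test of mean log2 ratio = 0 across replicates
(R − 1 degrees of freedom), and Benjamini–Hochberg adjustment controls the
FDR at 0.05 over the tested genes. Zero-variance genes are degenerate
cases: p = 1 at mean zero, an epsilon p-value (1e-300, flagged) otherwise.

The group-level question — has a gene group moved together? — is answered
in two parts, which keeps the magnitude and the evidence separate: the
group statistic is the geometric mean fold change `2^mean(mean_log2)`, and
the evidence is a hypergeometric upper tail asking whether the group is
enriched for genes at least 1.1-fold up (or down) relative to the
genome-wide tally of such genes. Both directions are tested; the reported
p is the direction matching the geometric mean (p = 1 if the geometric
mean is exactly 1). The 1.1-fold threshold is applied to the per-gene
*mean* log2 ratio — the per-gene point estimate — not to single
replicates; detection rates are insensitive to moderate changes of this
threshold. The threshold and FDR level are plain arguments.

## The simulators, and what passing tests establish

Every input has a generator that records its ground truth, so each
inference stage can be scored against what was planted.

* `make_genome()` draws i.i.d. background sequence at a stated GC content
  (default 0.40, a typical fungal intergenic composition), one contig per
  gene with alternating orientation, each gene preceded by its own
  intergenic block. One gene per contig makes planted coordinates exact:
  extraction truncates only at contig edges. Real promoters are not
  i.i.d. — they have composition heterogeneity, repeats, and nucleosome-
  driven structure — so recovery rates on synthetic genomes certify the
  *scanning machinery*, not motif biology.
* `plant_sites()` writes motif instances at exact positions, orientations,
  and scores: starting from the consensus it applies greedy minimal-loss
  substitutions (at most one per position) until the score is as close as
  possible to, but never below, the requested fraction of the maximum.
  This gives sharp control around the 50% presence cutoff: sites planted
  at 60% of max always pass at 50% and are never guaranteed at 70%.
  `plant_pairs()` places a toward-gene anchor and a partner at an exact
  midpoint-to-midpoint spacing, for validating the paired-site search
  (anchor facing the gene, both scores above 6.0, spacing 52–78 bp
  downstream by default).
* `make_tree()` draws Yule (pure-birth, unit-rate) trees;
  `simulate_character()` runs the two-state chain forward from a root
  state drawn from the prior and keeps the per-branch true gain/loss
  history, giving the end-to-end benchmark: mean inferred gains over
  sampled maps against forward-simulation truth.
* `simulate_ase()` draws lognormal baseline expression (median depth 200,
  sdlog 0.5 — deep RNA-seq coverage), a per-gene mappability factor
  applied to mRNA and gDNA alike (which the normalization must cancel), an
  allele-B mean scaled by `2^(-effect) * ploidy_b`, biological replicate
  noise as a per-gene, per-replicate lognormal jitter of the allelic ratio
  (`rep_noise = 0.2` on the log2 scale, split symmetrically between the
  alleles — the dominant variance component in replicated hybrid
  experiments), negative-binomial mRNA counts and Poisson gDNA counts
  (5000 per copy per replicate, deep genomic sequencing). `dispersion` is
  parametrized as extra-Poisson variance inflation,
  `Var = (1 + dispersion) * mu` (exactly Poisson at 0); per-replicate
  log2-ratio noise at the defaults is therefore ~0.2 — the scale at which
  seven replicates give near-full power for two-fold effects while the
  genome-wide null stays controlled. The alternative quadratic
  parametrization (`Var = mu + a mu^2`) puts a depth-independent floor of
  ~0.46 on that noise and is not what this generator means by dispersion.

The gDNA divisor deserves a warning. Because every replicate of a gene is
divided by the *same* replicate-averaged gDNA count, gDNA sampling noise
becomes a per-gene offset that is invisible to the within-gene t-test: it
shifts the mean without inflating the replicate variance. The test is
therefore only calibrated when gDNA counts are deep enough that this
offset is small against the replicate noise — with the defaults the
offset's log2 sd is ~0.02 against replicate noise of ~0.2. With shallow
gDNA (tens to hundreds of reads per gene) and strong replicate
reproducibility, the per-gene test becomes sharply anti-conservative; the
defaults emulate the deep-coverage regime in which the method is valid.

## Numerical and interface conventions

* Coordinates are 0-based half-open everywhere inside the package; GFF's
  1-based inclusive convention is converted exactly once, at I/O.
* Score ties in `best_hit()` resolve to the smaller start, then `+`
  strand: deterministic anchoring.
* Binned location profiles use left-closed bins `[b, b + size)`; each
  promoter counts at most once per bin, and proportions are over anchored
  promoters.
* Spacing windows are inclusive on both ends, measured midpoint to
  midpoint in the toward-gene frame; "downstream" means toward the gene.
  Midpoint (rather than edge-to-edge) spacing is exposed and documented
  since the two differ by a constant for fixed motif lengths.
* The anchor for location profiles is the best hit even when it fails the
  presence cutoff; profiles restrict to presence-passing promoters by
  default (`require_presence = TRUE`).
* No orientation filter is applied to the partner motif in the paired-site
  search: the typical partner site is quasi-palindromic and its strand
  is not meaningful at this resolution.
* All tabular outputs of the command-line interface are TSVs with `#`
  comment headers recording the package version, command line, and seed.

## Problem sizes

The shipped test-suite and acceptance runs use: 1000 random (PWM, region)
pairs against a brute-force scanning oracle; every population size up to
60 against an exact big-integer hypergeometric oracle; trees of 2–6 tips
for exhaustive likelihood checks; 500-tip trees, 20 replicates, for rate
recovery (target: within ±50% of the true rate in at least 18); 162-tip
trees with 10,000 maps for the production-scale mapping run and 2,000 maps
per replicate for end-to-end gain recovery; 1,000–4,000 genes and 3 or 7
replicates for the ASE power, ploidy-correction, and null-calibration
runs. These sizes were chosen so each check is decisive for the property
it tests while the whole suite runs comfortably on a laptop core.

## Known limitations

* Rates are point estimates; map counts do not propagate rate
  uncertainty. Under ARD with few losses the loss count is the quantity
  most sensitive to this choice.
* The Mk model ignores interspecies hybridization and horizontal transfer;
  a reticulate history would be forced into extra gains/losses.
* Enrichment treats genes as exchangeable; phylogenetic non-independence
  *within* a genome (tandem duplicates sharing promoters) is not modelled.
* The ASE t-test assumes approximately normal log ratios across
  replicates; at very low counts a count-based GLM would be preferable,
  and genes hitting zeros are excluded rather than modelled.
* The synthetic genomes' i.i.d. background understates the false-hit rate
  real low-complexity sequence would produce at permissive thresholds.
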