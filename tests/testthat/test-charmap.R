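two_tip_tree <- function(t1 = 1, t2 = 1) {
  tr <- ape::read.tree(text = sprintf("(A:%g,B:%g);", t1, t2))
  tr
}

test_that("Mk likelihood matches two-state closed forms", {
  tr <- two_tip_tree()
  # no change possible: likelihood is the root prior of the observed state
  expect_equal(mk_loglik(tr, c(A = 0, B = 0), 0, 0), log(0.5))
  # ER q = 0.5, both tips 0: 0.5 * (P00(1)^2 + P10(1)^2)
  p00 <- 0.5 * (1 + exp(-2 * 0.5))
  p10 <- 0.5 * (1 - exp(-2 * 0.5))
  want <- log(0.5 * (p00^2 + p10^2))
  expect_equal(mk_loglik(tr, c(A = 0, B = 0), 0.5, 0.5), want,
               tolerance = 1e-10)
  expect_equal(exp(want), 0.283834, tolerance = 1e-6)
})

test_that("pruning equals exhaustive internal-state summation on trees up to 6 tips", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(3:6, 1)
    tr <- make_tree(n)
    states <- stats::setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    q01 <- runif(1, 0.01, 2)
    q10 <- runif(1, 0.01, 2)
    want <- log(oracle_mk_lik(tr, states, q01, q10))
    expect_equal(mk_loglik(tr, states, q01, q10), want, tolerance = 1e-10)
  }
})

test_that("ARD log-likelihood is never below the nested ER fit", {
  set.seed(23)
  for (i in 1:5) {
    tr <- make_tree(40)
    sim <- simulate_character(tr, list(q01 = 0.3, q10 = 0.3))
    if (length(unique(sim$states)) == 1) next
    er <- fit_mk(tr, sim$states, "ER")
    ard <- fit_mk(tr, sim$states, "ARD")
    expect_gte(ard$loglik, er$loglik - 1e-6)
  }
})

test_that("a constant character yields floor rates with a warning", {
  tr <- make_tree(8)
  expect_warning(fit <- fit_mk(tr, stats::setNames(rep(1, 8), tr$tip.label)),
                 "constant")
  expect_equal(fit$q01, 1e-8)
  expect_equal(fit$q10, 1e-8)
})

test_that("tidy and glance expose rates and fit summaries", {
  set.seed(31)
  tr <- make_tree(30)
  sim <- simulate_character(tr, list(q01 = 0.5, q10 = 0.5))
  fit <- fit_mk(tr, sim$states, "ARD")
  td <- tidy(fit)
  expect_equal(td$term, c("q01", "q10"))
  expect_equal(td$estimate, c(fit$q01, fit$q10))
  gl <- glance(fit)
  expect_equal(gl$logLik, fit$loglik)
  expect_equal(gl$n_tips, 30)
})

test_that("branch paths respect endpoints, parity, and durations", {
  set.seed(41)
  model <- list(q01 = 1, q10 = 1)
  for (i in 1:50) {
    a <- sample(0:1, 1); b <- sample(0:1, 1)
    t <- runif(1, 0.2, 2)
    path <- sample_branch_path(model, t, a, b)
    expect_equal(path$state[1], a)
    expect_equal(path$state[nrow(path)], b)
    expect_equal(sum(path$duration), t)
    if (nrow(path) > 1) expect_true(all(diff(path$state) != 0))
    expect_equal((nrow(path) - 1) %% 2, abs(a - b) %% 2) # parity
  }
  # near-zero rates: start = end pairs carry no changes
  lowq <- list(q01 = 1e-9, q10 = 1e-9)
  path <- sample_branch_path(lowq, 1, 0, 0)
  expect_equal(nrow(path), 1)
  expect_error(sample_branch_path(list(q01 = 0, q10 = 0), 1, 0, 1),
               "impossible endpoint")
})

test_that("endpoint-conditioned change counts match a rejection-sampling oracle", {
  set.seed(47)
  n <- 4000
  got <- replicate(n, nrow(sample_branch_path(list(q01 = 1, q10 = 1), 1, 0, 0)) - 1)
  want <- oracle_rejection_changes(1, 1, 1, 0, 0, n)
  lev <- 0:max(got, want)
  tv <- 0.5 * sum(abs(tabulate(factor(got, lev), length(lev)) / n -
                        tabulate(factor(want, lev), length(lev)) / n))
  expect_lt(tv, 0.05)
})

test_that("sampled maps are tip-consistent and bounded below by parsimony", {
  set.seed(53)
  tr <- make_tree(12)
  sim <- simulate_character(tr, list(q01 = 0.4, q10 = 0.4))
  if (length(unique(sim$states)) == 1) {
    sim$states[1] <- 1 - sim$states[1]
  }
  model <- list(q01 = 0.4, q10 = 0.4)
  cm <- sample_maps(tr, sim$states, model, nmaps = 300)
  ntip <- length(tr$tip.label)
  # tip rows of the node-state matrix equal the observed character
  expect_true(all(cm$node_states[seq_len(ntip), ] ==
                    sim$states[cm$tree$tip.label]))
  pars <- fitch_score(tr, sim$states)
  expect_true(all(cm$gains + cm$losses >= pars))
})

test_that("count_transitions agrees with an independent segment scanner", {
  set.seed(59)
  tr <- make_tree(8)
  sim <- simulate_character(tr, list(q01 = 0.6, q10 = 0.6))
  if (length(unique(sim$states)) == 1) sim$states[1] <- 1 - sim$states[1]
  model <- list(q01 = 0.6, q10 = 0.6)
  for (i in 1:20) {
    map <- sample_map(tr, sim$states, model)
    got <- count_transitions(map)
    # naive scanner over the segment table
    g <- 0L; l <- 0L
    for (e in unique(map$segments$edge)) {
      s <- map$segments$state[map$segments$edge == e]
      for (j in seq_along(s)[-1]) {
        if (s[j] > s[j - 1]) g <- g + 1L
        if (s[j] < s[j - 1]) l <- l + 1L
      }
    }
    expect_equal(got, c(gains = g, losses = l))
    # a map's segment durations reconstruct every branch length
    by_edge <- tapply(map$segments$duration, map$segments$edge, sum)
    expect_equal(as.numeric(by_edge[as.character(seq_len(nrow(map$tree$edge)))]),
                 map$tree$edge.length, tolerance = 1e-12)
  }
})

test_that("in the low-rate limit a single derived tip implies one change", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  states <- c(A = 1, B = 0, C = 0, D = 0)
  model <- list(q01 = 1e-4, q10 = 1e-4)
  set.seed(61)
  cm <- sample_maps(tr, states, model, nmaps = 2000)
  expect_gte(mean(cm$gains + cm$losses == 1), 0.95)

  # constant character with floor rates: virtually no changes
  cm0 <- sample_maps(tr, c(A = 0, B = 0, C = 0, D = 0),
                     list(q01 = 1e-8, q10 = 1e-8), nmaps = 500)
  expect_gte(mean(cm0$gains + cm0$losses == 0), 0.99)
})

test_that("node-state proportions converge to exact pruning marginals", {
  set.seed(67)
  tr <- make_tree(20)
  sim <- simulate_character(tr, list(q01 = 0.5, q10 = 0.3))
  if (length(unique(sim$states)) == 1) sim$states[1] <- 1 - sim$states[1]
  model <- list(q01 = 0.5, q10 = 0.3, root_prior = c(0.5, 0.5))
  marg <- node_marginals(tr, sim$states, model)
  cm <- sample_maps(tr, sim$states, model, nmaps = 6000)
  prop <- rowMeans(cm$node_states == 1)
  expect_lt(max(abs(prop - marg$p1)), 0.025)
  # tips are pinned to their data
  ntip <- length(tr$tip.label)
  expect_equal(marg$p1[seq_len(ntip)],
               unname(as.numeric(sim$states[cm$tree$tip.label])))
})

test_that("marginals match exhaustive enumeration on a small tree", {
  set.seed(71)
  tr <- make_tree(5)
  states <- stats::setNames(c(1, 0, 1, 0, 0), tr$tip.label)
  q01 <- 0.7; q10 <- 0.2
  marg <- node_marginals(tr, states, list(q01 = q01, q10 = q10))
  # enumeration oracle: P(node = 1 | data) by summing path products
  tr_po <- ape::reorder.phylo(tr, "postorder")
  ntip <- 5; nint <- tr_po$Nnode
  tot <- 0; per_node <- numeric(ntip + nint)
  for (code in 0:(2^nint - 1)) {
    assign <- as.integer(intToBits(code))[seq_len(nint)]
    full <- c(states[tr_po$tip.label], assign)
    lik <- 0.5 # root prior
    for (e in seq_len(nrow(tr_po$edge))) {
      P <- mk_ptrans(q01, q10, tr_po$edge.length[e])
      lik <- lik * P[full[tr_po$edge[e, 1]] + 1, full[tr_po$edge[e, 2]] + 1]
    }
    tot <- tot + lik
    per_node <- per_node + lik * (full == 1)
  }
  expect_equal(marg$p1, unname(per_node / tot), tolerance = 1e-10)
})

test_that("under equal rates, relabelling states swaps gains and losses", {
  set.seed(73)
  tr <- make_tree(25)
  sim <- simulate_character(tr, list(q01 = 0.4, q10 = 0.4))
  if (length(unique(sim$states)) == 1) sim$states[1] <- 1 - sim$states[1]
  model <- list(q01 = 0.4, q10 = 0.4)
  cm1 <- sample_maps(tr, sim$states, model, nmaps = 4000)
  cm2 <- sample_maps(tr, 1 - sim$states, model, nmaps = 4000)
  # equal-rates symmetry: the flipped character's gains are the original's
  # losses, up to Monte-Carlo error
  se <- sqrt(var(cm1$gains) / 4000 + var(cm2$losses) / 4000)
  expect_lt(abs(mean(cm1$gains) - mean(cm2$losses)), 4 * se + 0.05)
  ll1 <- mk_loglik(tr, sim$states, 0.4, 0.4)
  ll2 <- mk_loglik(tr, 1 - sim$states, 0.4, 0.4)
  expect_equal(ll1, ll2, tolerance = 1e-10) # exact likelihood symmetry
})

test_that("HPD intervals are the shortest attained windows", {
  expect_equal(unname(hpd_interval(rep(3, 10), 0.95)), c(3, 3))
  x <- c(1, 2, 2, 2, 3, 3, 4, 9, 10, 20)
  # brute force over all contiguous windows of 8 sorted values
  s <- sort(x); k <- ceiling(0.8 * length(s))
  widths <- sapply(seq_len(length(s) - k + 1),
                   function(i) s[i + k - 1] - s[i])
  i <- which.min(widths)
  want <- c(s[i], s[i + k - 1])
  expect_equal(unname(hpd_interval(x, 0.8)), want)
  # tie on width resolves to the smallest lower bound
  expect_equal(unname(hpd_interval(c(0, 1, 2, 3), 0.5)), c(0, 1))
})

test_that("summarize_maps reports means, HPDs, and uncertain nodes", {
  set.seed(79)
  tr <- make_tree(15)
  sim <- simulate_character(tr, list(q01 = 0.5, q10 = 0.5))
  if (length(unique(sim$states)) == 1) sim$states[1] <- 1 - sim$states[1]
  cm <- sample_maps(tr, sim$states, list(q01 = 0.5, q10 = 0.5), nmaps = 500)
  sm <- summarize_maps(cm)
  expect_equal(sm$events$mean[1], mean(cm$gains))
  expect_equal(unname(unlist(sm$events[1, c("hpd_lower", "hpd_upper")])),
               unname(hpd_interval(cm$gains, 0.95)))
  prop <- rowMeans(cm$node_states == 1)
  expect_equal(sm$nodes$uncertain, prop > 0.2 & prop < 0.8)
  td <- tidy(cm)
  expect_equal(nrow(td), 500)
  expect_equal(td$gains, cm$gains)
})

test_that("fits agree with an independent Mk implementation", {
  skip_if_not_installed("phytools")
  set.seed(83)
  tr <- make_tree(30)
  sim <- simulate_character(tr, list(q01 = 0.4, q10 = 0.2))
  if (length(unique(sim$states)) == 1) sim$states[1] <- 1 - sim$states[1]
  ref <- phytools::fitMk(tr, stats::setNames(as.factor(sim$states),
                                             names(sim$states)),
                         model = "ARD", pi = "equal")
  q01_ref <- ref$rates[ref$index.matrix[1, 2]]
  q10_ref <- ref$rates[ref$index.matrix[2, 1]]
  # identical likelihood surface at the reference optimum
  expect_equal(mk_loglik(tr, sim$states, q01_ref, q10_ref),
               as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  fit <- fit_mk(tr, sim$states, "ARD")
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
  expect_equal(fit$q01, q01_ref, tolerance = 0.05)
  expect_equal(fit$q10, q10_ref, tolerance = 0.05)
})
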