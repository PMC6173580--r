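# Uniformization setup: dominating rate, DTMC kernel R = I + Q/lambda, and
# its powers up to the Poisson truncation point for branch length t.
unif_setup <- function(q01, q10) {
  lambda <- 1.05 * max(q01, q10)
  if (lambda <= 0) return(list(lambda = 0))
  R <- diag(2) + matrix(c(-q01, q10, q01, -q10), 2, 2) / lambda
  list(lambda = lambda, R = R)
}

# Powers R^0..R^nmax as a list; nmax covers Poisson(lambda*t) mass 1 - 1e-12.
unif_powers <- function(u, t) {
  nmax <- max(1L, stats::qpois(1 - 1e-12, u$lambda * t))
  pows <- vector("list", nmax + 1L)
  pows[[1]] <- diag(2)
  for (n in seq_len(nmax)) pows[[n + 1L]] <- pows[[n]] %*% u$R
  pows
}

# Sample the number of virtual (uniformized) jumps on a branch of length t
# conditioned on endpoints a, b (0/1), for m independent draws.
sample_njumps <- function(u, pows, t, a, b, m) {
  nmax <- length(pows) - 1L
  w <- stats::dpois(0:nmax, u$lambda * t) *
    vapply(pows, function(M) M[a + 1L, b + 1L], numeric(1))
  if (sum(w) <= 0) stop_input("impossible endpoint pair (%d -> %d)", a, b)
  sample.int(nmax + 1L, m, replace = TRUE, prob = w) - 1L
}

# Sample DTMC bridge state sequences for m draws that all have n virtual
# jumps between endpoints a and b; returns the number of real state changes
# per draw (self-transitions collapsed).
bridge_changes <- function(u, pows, n, a, b, m) {
  if (n == 0L) return(integer(m))
  cur <- rep.int(a, m)
  changes <- integer(m)
  for (j in seq_len(n)) {
    rem <- pows[[n - j + 1L]]
    w0 <- u$R[cbind(cur + 1L, 1L)] * rem[1L, b + 1L]
    w1 <- u$R[cbind(cur + 1L, 2L)] * rem[2L, b + 1L]
    p1 <- w1 / (w0 + w1)
    nxt <- as.integer(stats::runif(m) < p1)
    changes <- changes + as.integer(nxt != cur)
    cur <- nxt
  }
  changes
}

#' Sample an endpoint-conditioned CTMC path on one branch
#'
#' Draws a full trajectory of the two-state chain over a branch of length
#' `t`, conditioned on the states at both ends, by uniformization: the
#' number of virtual jumps is drawn from its endpoint-conditioned
#' distribution, the discrete bridge between the endpoints is sampled jump
#' by jump, virtual jump times are uniform order statistics, and
#' self-transitions are collapsed. Consecutive segment states therefore
#' alternate.
#'
#' @param model List with `q01` and `q10` (e.g. an `mk_fit`).
#' @param t Branch length (> 0).
#' @param start_state,end_state States in \{0, 1\}.
#' @return Tibble with columns `state` and `duration`; durations sum to `t`.
#' @export
sample_branch_path <- function(model, t, start_state, end_state) {
  stopifnot(t >= 0, start_state %in% 0:1, end_state %in% 0:1)
  a <- as.integer(start_state); b <- as.integer(end_state)
  u <- unif_setup(model$q01, model$q10)
  if (u$lambda == 0 || t == 0) {
    if (a != b)
      stop_input("impossible endpoint pair (%d -> %d) with zero rates", a, b)
    return(tibble(state = a, duration = t))
  }
  if (mk_ptrans(model$q01, model$q10, t)[a + 1L, b + 1L] <= 0)
    stop_input("impossible endpoint pair (%d -> %d)", a, b)
  pows <- unif_powers(u, t)
  n <- sample_njumps(u, pows, t, a, b, 1L)
  if (n == 0L) return(tibble(state = a, duration = t))
  # sample the bridge states explicitly (times needed here)
  s <- integer(n + 1L)
  s[1] <- a
  for (j in seq_len(n)) {
    rem <- pows[[n - j + 1L]]
    w <- u$R[s[j] + 1L, ] * rem[, b + 1L]
    s[j + 1L] <- sample.int(2L, 1L, prob = w) - 1L
  }
  times <- c(0, sort(stats::runif(n, 0, t)), t)
  keep <- c(TRUE, diff(s) != 0)
  starts <- times[-(n + 2L)][keep]
  bounds <- c(starts[-1], t)
  tibble(state = s[keep], duration = bounds - starts)
}

#' Sample stochastic character maps
#'
#' Draws full histories of a binary character on the tree, conditional on
#' the observed tip states and the model rates (empirical Bayes: rates are
#' held at their supplied values). Internal-node states are drawn from the
#' pruning conditionals root-down; each branch is then filled in by
#' endpoint-conditioned path sampling. `sample_maps()` is vectorised over
#' maps and by default records, per map, only the gain/loss counts and node
#' states, which is what the downstream summaries use; set `detail = TRUE`
#' (or use `sample_map()`) to keep full per-branch segment paths.
#'
#' @param tree Rooted `phylo` tree.
#' @param states Binary character (see [mk_loglik()]).
#' @param model An `mk_fit` or list with `q01`, `q10`, `root_prior`.
#' @param nmaps Number of maps (the conventional production run is 10000).
#' @param detail Keep full segment paths per map (slower, memory-heavy).
#' @return A `char_maps` object: `gains` and `losses` (integer per map),
#'   `node_states` (matrix, nodes x maps), `tree`, `model`, and `maps`
#'   (list of per-map segment tibbles when `detail = TRUE`).
#' @export
sample_maps <- function(tree, states, model, nmaps = 10000, detail = FALSE) {
  tree <- validate_tree(tree)
  states <- as_binary_states(states, tree)
  prior <- model$root_prior %||% c(0.5, 0.5)
  pr <- mk_prune(tree, states, model$q01, model$q10)
  tree <- pr$tree
  ntip <- pr$ntip
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  NS <- matrix(0L, nn, nmaps)
  NS[seq_len(ntip), ] <- states[tree$tip.label]
  w <- prior * pr$D[root, ]
  NS[root, ] <- as.integer(stats::runif(nmaps) < w[2] / sum(w))
  for (i in rev(seq_len(nrow(tree$edge)))) { # preorder
    ch <- tree$edge[i, 2]
    if (ch <= ntip) next
    sp <- NS[tree$edge[i, 1], ]
    P <- pr$P[[i]]
    w1 <- P[cbind(sp + 1L, 2L)] * pr$D[ch, 2]
    w0 <- P[cbind(sp + 1L, 1L)] * pr$D[ch, 1]
    NS[ch, ] <- as.integer(stats::runif(nmaps) < w1 / (w0 + w1))
  }
  gains <- integer(nmaps)
  losses <- integer(nmaps)
  u <- unif_setup(model$q01, model$q10)
  maps <- if (detail) {
    lapply(seq_len(nmaps), function(z) vector("list", nrow(tree$edge)))
  }
  for (i in seq_len(nrow(tree$edge))) {
    t <- tree$edge.length[i]
    a_all <- NS[tree$edge[i, 1], ]
    b_all <- NS[tree$edge[i, 2], ]
    if (u$lambda == 0 || t == 0) {
      if (any(a_all != b_all))
        stop_input("impossible endpoint pair with zero rates")
      if (detail) {
        for (m in seq_len(nmaps)) {
          maps[[m]][[i]] <- tibble(state = a_all[m], duration = t)
        }
      }
      next
    }
    if (detail) {
      # full paths carry the counts, so counts and segments always agree
      for (m in seq_len(nmaps)) {
        path <- sample_branch_path(model, t, a_all[m], b_all[m])
        maps[[m]][[i]] <- path
        d <- diff(path$state)
        gains[m] <- gains[m] + sum(d == 1L)
        losses[m] <- losses[m] + sum(d == -1L)
      }
      next
    }
    pows <- unif_powers(u, t)
    for (a in 0:1) for (b in 0:1) {
      sel <- which(a_all == a & b_all == b)
      if (!length(sel)) next
      njump <- sample_njumps(u, pows, t, a, b, length(sel))
      ch <- integer(length(sel))
      for (n in unique(njump)) {
        grp <- which(njump == n)
        ch[grp] <- bridge_changes(u, pows, n, a, b, length(grp))
      }
      # changes alternate starting from state a
      if (a == 0L) {
        gains[sel] <- gains[sel] + (ch + 1L) %/% 2L
        losses[sel] <- losses[sel] + ch %/% 2L
      } else {
        losses[sel] <- losses[sel] + (ch + 1L) %/% 2L
        gains[sel] <- gains[sel] + ch %/% 2L
      }
    }
  }
  if (detail) {
    maps <- lapply(maps, function(segs) {
      dplyr::bind_rows(segs, .id = "edge") |>
        mutate(edge = as.integer(.data$edge))
    })
  }
  structure(list(gains = gains, losses = losses, node_states = NS,
                 tree = tree, model = model, nmaps = nmaps,
                 maps = if (detail) maps),
            class = "char_maps")
}

#' @rdname sample_maps
#' @return `sample_map()` returns a single `char_map`: list with `tree`,
#'   `node_states` (0/1 per ape node index) and `segments` (tibble `edge`,
#'   `state`, `duration`, in order along each branch from parent to child).
#' @export
sample_map <- function(tree, states, model) {
  cm <- sample_maps(tree, states, model, nmaps = 1, detail = TRUE)
  structure(list(tree = cm$tree, node_states = cm$node_states[, 1],
                 segments = cm$maps[[1]]),
            class = "char_map")
}

#' Count gains and losses in one character map
#'
#' Gains are 0 to 1 boundaries between consecutive segments within a branch;
#' losses are 1 to 0 boundaries. Node boundaries contribute nothing because
#' a branch's first state always equals the parent node state.
#'
#' @param map A `char_map` from [sample_map()].
#' @return Named integer vector `c(gains = , losses = )`.
#' @export
count_transitions <- function(map) {
  segs <- map$segments
  gains <- 0L; losses <- 0L
  for (e in unique(segs$edge)) {
    s <- segs$state[segs$edge == e]
    if (length(s) > 1) {
      d <- diff(s)
      gains <- gains + sum(d == 1L)
      losses <- losses + sum(d == -1L)
    }
  }
  c(gains = gains, losses = losses)
}

#' Highest posterior density interval of discrete samples
#'
#' Shortest contiguous window of the sorted samples containing at least
#' `mass` of them; ties resolved toward the smallest lower bound. Bounds are
#' always attained sample values, matching how integer gain/loss counts are
#' reported.
#'
#' @param x Numeric samples.
#' @param mass Target probability mass (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, mass = 0.95) {
  stopifnot(length(x) >= 1, mass > 0, mass <= 1)
  s <- sort(x)
  n <- length(s)
  k <- ceiling(mass * n)
  lo <- s[seq_len(n - k + 1L)]
  hi <- s[seq.int(k, n)]
  i <- which.min(hi - lo) # first minimum = smallest lower bound
  c(lower = lo[i], upper = hi[i])
}

#' Summarize sampled character maps
#'
#' Means and HPD intervals of the per-map gain and loss counts, plus the
#' per-node fraction of maps in state 1. Nodes whose fraction falls strictly
#' between 0.2 and 0.8 are flagged as uncertain ancestral reconstructions.
#'
#' @param x A `char_maps` object from [sample_maps()].
#' @param mass HPD mass (default 0.95).
#' @return A `map_summary`: list with `events` (tibble `event`, `mean`,
#'   `hpd_lower`, `hpd_upper`) and `nodes` (tibble `node`, `is_tip`,
#'   `prop1`, `uncertain`).
#' @export
summarize_maps <- function(x, mass = 0.95) {
  stopifnot(inherits(x, "char_maps"))
  hg <- hpd_interval(x$gains, mass)
  hl <- hpd_interval(x$losses, mass)
  events <- tibble(
    event = c("gains", "losses"),
    mean = c(mean(x$gains), mean(x$losses)),
    hpd_lower = c(hg[1], hl[1]),
    hpd_upper = c(hg[2], hl[2])
  )
  ntip <- length(x$tree$tip.label)
  prop1 <- rowMeans(x$node_states == 1L)
  nodes <- tibble(node = seq_along(prop1),
                  is_tip = seq_along(prop1) <= ntip,
                  prop1 = prop1,
                  uncertain = prop1 > 0.2 & prop1 < 0.8)
  structure(list(events = events, nodes = nodes, nmaps = x$nmaps,
                 mass = mass),
            class = "map_summary")
}

#' @export
print.char_maps <- function(x, ...) {
  cat(sprintf("<char_maps> %d maps on %d tips: mean gains %.2f, mean losses %.2f\n",
              x$nmaps, length(x$tree$tip.label), mean(x$gains), mean(x$losses)))
  invisible(x)
}

#' @export
print.map_summary <- function(x, ...) {
  cat(sprintf("<map_summary> over %d maps (HPD mass %.2f)\n", x$nmaps, x$mass))
  print(x$events)
  cat(sprintf("%d uncertain internal nodes\n",
              sum(x$nodes$uncertain & !x$nodes$is_tip)))
  invisible(x)
}

#' @method tidy char_maps
#' @export
tidy.char_maps <- function(x, ...) {
  tibble(map = seq_along(x$gains), gains = x$gains, losses = x$losses)
}

#' @method glance char_maps
#' @export
glance.char_maps <- function(x, ...) {
  tibble(nmaps = x$nmaps, mean_gains = mean(x$gains),
         mean_losses = mean(x$losses),
         q01 = x$model$q01, q10 = x$model$q10)
}

#' @method tidy map_summary
#' @export
tidy.map_summary <- function(x, ...) x$events
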