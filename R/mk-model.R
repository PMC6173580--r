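#' Two-state Mk transition probabilities
#'
#' Closed-form transition matrix of the binary-character continuous-time
#' Markov chain with gain rate `q01` (0 to 1) and loss rate `q10` (1 to 0)
#' over elapsed branch length `t`:
#' `P(t) = pi + (I - pi) * exp(-(q01 + q10) t)` row-wise, where `pi` is the
#' stationary distribution. With both rates zero the identity is returned.
#'
#' @param q01,q10 Non-negative rates per unit branch length.
#' @param t Branch length.
#' @return 2 x 2 matrix with rows/cols in state order 0, 1.
#' @export
mk_ptrans <- function(q01, q10, t) {
  stopifnot(q01 >= 0, q10 >= 0, t >= 0)
  tot <- q01 + q10
  if (tot == 0) return(diag(2))
  e <- exp(-tot * t)
  pi0 <- q10 / tot
  pi1 <- q01 / tot
  matrix(c(pi0 + pi1 * e, pi0 * (1 - e),
           pi1 * (1 - e), pi1 + pi0 * e), 2, 2)
}

# Normalize a character specification to a named 0/1 integer vector covering
# every tip of the tree.
as_binary_states <- function(states, tree) {
  if (is.data.frame(states)) {
    cols <- intersect(c("species", "tip", "gene_id", "label"), names(states))
    if (!length(cols) || !("state" %in% names(states)))
      stop_input("states table needs a species column and a state column")
    x <- states$state
    names(x) <- states[[cols[1]]]
    states <- x
  }
  if (is.null(names(states))) stop_input("states must be named by tip label")
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss)) stop_input("no state for tip '%s'", miss[1])
  x <- as.integer(states[tree$tip.label])
  if (anyNA(x) || !all(x %in% c(0L, 1L)))
    stop_input("states must be 0 or 1")
  names(x) <- tree$tip.label
  x
}

# Felsenstein pruning pass. Returns the conditional-likelihood matrix D
# ((Ntip + Nnode) x 2, rescaled per internal node) together with the summed
# log of the rescaling constants and the per-edge transition matrices.
mk_prune <- function(tree, states, q01, q10) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  D <- matrix(0, ntip + nnode, 2)
  D[(ntip + 1L):(ntip + nnode), ] <- 1
  D[cbind(seq_len(ntip), states[tree$tip.label] + 1L)] <- 1
  P <- lapply(tree$edge.length, function(t) mk_ptrans(q01, q10, t))
  logscale <- 0
  parents <- tree$edge[, 1]
  children <- tree$edge[, 2]
  for (i in seq_along(parents)) {
    msg <- P[[i]] %*% D[children[i], ]
    D[parents[i], ] <- D[parents[i], ] * msg
    if (i == length(parents) || parents[i + 1] != parents[i]) {
      mx <- max(D[parents[i], ])
      if (mx <= 0) stop_input("zero likelihood during pruning")
      D[parents[i], ] <- D[parents[i], ] / mx
      logscale <- logscale + log(mx)
    }
  }
  list(tree = tree, D = D, logscale = logscale, P = P, ntip = ntip)
}

#' Mk log-likelihood of a binary character on a rooted tree
#'
#' Felsenstein pruning with the closed-form two-state transition
#' probabilities; the root is summed over states weighted by `root_prior`.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param states Named 0/1 vector (names = tip labels), or a tibble with
#'   `species` and `state` columns.
#' @param q01,q10 Gain and loss rates.
#' @param root_prior Length-2 prior on the root state, default (1/2, 1/2).
#' @return Log-likelihood (numeric scalar).
#' @export
mk_loglik <- function(tree, states, q01, q10, root_prior = c(0.5, 0.5)) {
  tree <- validate_tree(tree)
  states <- as_binary_states(states, tree)
  stopifnot(length(root_prior) == 2, all(root_prior >= 0),
            abs(sum(root_prior) - 1) < 1e-9)
  pr <- mk_prune(tree, states, q01, q10)
  root <- pr$ntip + 1L
  log(sum(root_prior * pr$D[root, ])) + pr$logscale
}

#' Fit a two-state Mk model by maximum likelihood
#'
#' Estimates the gain and loss rates of motif presence on the tree. `"ER"`
#' constrains the two rates to be equal (1-D bounded optimisation); `"ARD"`
#' lets gain and loss differ (2-D quasi-Newton on log rates, started from
#' the ER optimum). The root prior is fixed at (1/2, 1/2). A constant
#' character carries no information about the rates; it yields a warning and
#' rates at `floor_rate`.
#'
#' @param tree Rooted `phylo` tree.
#' @param states Binary character (see [mk_loglik()]).
#' @param kind `"ER"` (equal rates) or `"ARD"` (all rates different).
#' @param floor_rate Lower bound and constant-character fallback rate.
#' @param upper_rate Upper optimisation bound.
#' @return An `mk_fit` object with elements `kind`, `q01`, `q10`, `loglik`,
#'   `root_prior`, `tree`, `states`.
#' @export
fit_mk <- function(tree, states, kind = c("ER", "ARD"),
                   floor_rate = 1e-8, upper_rate = 1e3) {
  kind <- match.arg(kind)
  tree <- validate_tree(tree)
  states <- as_binary_states(states, tree)
  prior <- c(0.5, 0.5)
  mk_fit_obj <- function(q01, q10) {
    structure(list(kind = kind, q01 = q01, q10 = q10,
                   loglik = mk_loglik(tree, states, q01, q10, prior),
                   root_prior = prior, tree = tree, states = states),
              class = "mk_fit")
  }
  if (length(unique(states)) == 1L) {
    warn("character is constant; rates set to the floor")
    return(mk_fit_obj(floor_rate, floor_rate))
  }
  nll_er <- function(lq) -mk_loglik(tree, states, exp(lq), exp(lq), prior)
  opt_er <- stats::optimize(nll_er, c(log(floor_rate), log(upper_rate)))
  q_er <- exp(opt_er$minimum)
  if (kind == "ER") return(mk_fit_obj(q_er, q_er))
  nll <- function(lq) -mk_loglik(tree, states, exp(lq[1]), exp(lq[2]), prior)
  opt <- stats::optim(log(c(q_er, q_er)), nll, method = "L-BFGS-B",
                      lower = log(floor_rate), upper = log(upper_rate))
  fit <- mk_fit_obj(exp(opt$par[1]), exp(opt$par[2]))
  # guard: ARD must never fall below the nested ER optimum
  er_ll <- -opt_er$objective
  if (fit$loglik < er_ll) fit <- mk_fit_obj(q_er, q_er)
  fit
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("<mk_fit> %s model: q01 (gain) = %.6g, q10 (loss) = %.6g, logLik = %.4f, %d tips\n",
              x$kind, x$q01, x$q10, x$loglik, length(x$tree$tip.label)))
  invisible(x)
}

#' @export
logLik.mk_fit <- function(object, ...) {
  structure(object$loglik, df = if (object$kind == "ER") 1 else 2,
            class = "logLik")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy mk_fit
#' @export
tidy.mk_fit <- function(x, ...) {
  tibble(term = c("q01", "q10"), rate = c("gain", "loss"),
         estimate = c(x$q01, x$q10))
}

#' @method glance mk_fit
#' @export
glance.mk_fit <- function(x, ...) {
  k <- if (x$kind == "ER") 1 else 2
  tibble(kind = x$kind, logLik = x$loglik, AIC = 2 * k - 2 * x$loglik,
         n_tips = length(x$tree$tip.label))
}

#' Marginal ancestral-state probabilities
#'
#' Exact per-node marginal posterior probability of state 1 given the tip
#' data and the model, by the standard inside-outside (down/up) extension of
#' the pruning pass. Tip rows reproduce the observed states.
#'
#' @param tree Rooted `phylo` tree.
#' @param states Binary character.
#' @param model An `mk_fit` (or any list with `q01`, `q10`, `root_prior`).
#' @return Tibble `node` (ape node index), `is_tip`, `p1`.
#' @export
node_marginals <- function(tree, states, model) {
  tree <- validate_tree(tree)
  states <- as_binary_states(states, tree)
  prior <- model$root_prior %||% c(0.5, 0.5)
  pr <- mk_prune(tree, states, model$q01, model$q10)
  tree <- pr$tree
  ntip <- pr$ntip
  nn <- ntip + tree$Nnode
  U <- matrix(0, nn, 2)
  U[ntip + 1L, ] <- prior
  edges <- rev(seq_len(nrow(tree$edge))) # preorder
  for (i in edges) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    sibs <- which(tree$edge[, 1] == p & tree$edge[, 2] != ch)
    sibprod <- rep(1, 2)
    for (j in sibs) sibprod <- sibprod * as.vector(pr$P[[j]] %*% pr$D[tree$edge[j, 2], ])
    U[ch, ] <- as.vector((U[p, ] * sibprod) %*% pr$P[[i]])
  }
  w <- U * pr$D
  p1 <- w[, 2] / rowSums(w)
  tibble(node = seq_len(nn), is_tip = seq_len(nn) <= ntip, p1 = p1)
}
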