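# Independent oracles used across the suite. These are deliberately naive
# implementations kept separate from the package's own code paths.

## ---- exact big-integer combinatorics (base-1e7 limb vectors) ----

big_from_int <- function(x) {
  out <- numeric(0)
  repeat {
    out <- c(out, x %% 1e7)
    x <- x %/% 1e7
    if (x == 0) break
  }
  out
}

big_add <- function(x, y) {
  n <- max(length(x), length(y))
  x <- c(x, numeric(n - length(x)))
  y <- c(y, numeric(n - length(y)))
  s <- x + y
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% 1e7
    s[i] <- s[i] %% 1e7
  }
  if (carry > 0) s <- c(s, big_from_int(carry))
  s
}

big_mul <- function(x, y) {
  res <- numeric(length(x) + length(y))
  for (i in seq_along(x)) {
    if (x[i] == 0) next
    for (j in seq_along(y)) {
      k <- i + j - 1L
      res[k] <- res[k] + x[i] * y[j]
      # immediate carry keeps limbs < 2^53
      carry <- res[k] %/% 1e7
      res[k] <- res[k] %% 1e7
      res[k + 1L] <- res[k + 1L] + carry
    }
  }
  while (length(res) > 1 && res[length(res)] == 0) res <- res[-length(res)]
  res
}

big_to_num <- function(x) sum(x * 1e7^(seq_along(x) - 1))

# Exact Pascal triangle up to n, as nested lists of bignums.
big_choose_table <- function(nmax) {
  C <- vector("list", nmax + 1L)
  C[[1]] <- list(big_from_int(1))
  for (n in seq_len(nmax)) {
    row <- vector("list", n + 1L)
    row[[1]] <- big_from_int(1)
    row[[n + 1L]] <- big_from_int(1)
    if (n > 1) {
      for (k in seq_len(n - 1L)) {
        row[[k + 1L]] <- big_add(C[[n]][[k]], C[[n]][[k + 1L]])
      }
    }
    C[[n + 1L]] <- row
  }
  C
}

# Exact hypergeometric tail P(X >= k) or P(X <= k) by big-integer
# combinatorial summation; `tab` from big_choose_table(M).
oracle_hyper_tail <- function(k, M, K, n, direction, tab) {
  jmax <- min(K, n)
  jmin <- max(0L, n - (M - K))
  js <- if (direction == "ge") seq.int(k, jmax) else seq.int(jmin, k)
  num <- numeric(1) # bignum zero
  for (j in js) {
    term <- big_mul(tab[[K + 1L]][[j + 1L]], tab[[M - K + 1L]][[n - j + 1L]])
    num <- big_add(num, term)
  }
  big_to_num(num) / big_to_num(tab[[M + 1L]][[n + 1L]])
}

## ---- brute-force PWM scanning ----

oracle_score_window <- function(pwm, window) {
  m <- unclass(pwm)
  chars <- strsplit(window, "")[[1]]
  tot <- 0
  for (i in seq_along(chars)) {
    j <- match(chars[i], c("A", "C", "G", "T"))
    tot <- tot + if (is.na(j)) min(m[i, ]) else m[i, j]
  }
  unname(tot)
}

oracle_revcomp <- function(s) {
  paste(rev(chartr("ACGTN", "TGCAN", strsplit(s, "")[[1]])), collapse = "")
}

# All windows x both strands, naive per-window scoring.
oracle_scan <- function(pwm, seq, threshold) {
  L <- nrow(pwm)
  n <- nchar(seq) - L + 1L
  rows <- list()
  if (n >= 1) {
    for (w in seq_len(n)) {
      win <- substr(seq, w, w + L - 1L)
      for (strand in c("+", "-")) {
        sc <- oracle_score_window(pwm, if (strand == "+") win else oracle_revcomp(win))
        if (sc >= threshold) {
          rows[[length(rows) + 1L]] <- data.frame(
            start = w - 1L, strand = strand,
            midpoint = w - 1L + L %/% 2L, score = sc)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(start = integer(0), strand = character(0),
                      midpoint = integer(0), score = numeric(0))
  out[order(out$start, out$strand), ]
}

## ---- exhaustive Mk likelihood (trees <= ~10 tips) ----

oracle_mk_lik <- function(tree, states, q01, q10, root_prior = c(0.5, 0.5)) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  total <- 0
  for (code in 0:(2^nint - 1)) {
    assign <- as.integer(intToBits(code))[seq_len(nint)]
    full <- c(states[tree$tip.label], assign)
    lik <- root_prior[full[ntip + 1L] + 1L]
    for (e in seq_len(nrow(tree$edge))) {
      P <- mk_ptrans(q01, q10, tree$edge.length[e])
      lik <- lik * P[full[tree$edge[e, 1]] + 1L, full[tree$edge[e, 2]] + 1L]
    }
    total <- total + lik
  }
  total
}

## ---- forward CTMC simulation / rejection path sampling ----

forward_ctmc_changes <- function(q01, q10, t, a) {
  s <- a
  pos <- 0
  changes <- 0L
  repeat {
    r <- if (s == 0L) q01 else q10
    if (r <= 0) break
    pos <- pos + stats::rexp(1, r)
    if (pos >= t) break
    changes <- changes + 1L
    s <- 1L - s
  }
  list(end = s, changes = changes)
}

# Distribution of change counts conditional on endpoints, by rejection.
oracle_rejection_changes <- function(q01, q10, t, a, b, nsamp) {
  out <- integer(nsamp)
  i <- 0L
  while (i < nsamp) {
    sim <- forward_ctmc_changes(q01, q10, t, a)
    if (sim$end == b) {
      i <- i + 1L
      out[i] <- sim$changes
    }
  }
  out
}

## ---- Fitch parsimony score (via phangorn, independent of the package) ----

fitch_score <- function(tree, states) {
  dat <- phangorn::phyDat(matrix(as.character(states[tree$tip.label]),
                                 ncol = 1,
                                 dimnames = list(tree$tip.label, NULL)),
                          type = "USER", levels = c("0", "1"))
  phangorn::fitch(tree, dat)
}

## ---- random fixtures ----

random_pwm <- function(len = NULL, name = "rand") {
  if (is.null(len)) len <- sample(4:12, 1)
  pwm(matrix(stats::runif(len * 4, -3, 3), len, 4), name = name)
}

random_region <- function(len = NULL, gc = 0.4, n_frac = 0) {
  if (is.null(len)) len <- sample(20:200, 1)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs)
  if (n_frac > 0) {
    nn <- rbinom(1, len, n_frac)
    if (nn > 0) chars[sample(len, nn)] <- "N"
  }
  paste(chars, collapse = "")
}
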