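# Independent oracles used across the suite. Each deliberately recomputes the
# quantity by a different route than the package (enumeration, brute force,
# direct likelihood optimization).

# Exhaustive Benjamini-Hochberg step-up: for each i, q_i is the minimum over
# all ranks j >= rank(i) of p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    ri <- which(o == i) # rank of p[i]
    cand <- vapply(ri:m, function(j) p[o[j]] * m / j, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}

# Negative log Breslow partial likelihood with analytic gradient, maximized
# directly (independent of survival::coxph's Newton iterations).
cox_oracle <- function(time, event, x) {
  x <- as.matrix(x)
  events <- which(event == 1)
  nll <- function(beta) {
    eta <- as.numeric(x %*% beta)
    s <- 0
    for (i in events) {
      risk <- time >= time[i]
      s <- s - (eta[i] - log(sum(exp(eta[risk]))))
    }
    s
  }
  gr <- function(beta) {
    eta <- as.numeric(x %*% beta)
    g <- numeric(ncol(x))
    for (i in events) {
      risk <- time >= time[i]
      w <- exp(eta[risk])
      xbar <- colSums(x[risk, , drop = FALSE] * w) / sum(w)
      g <- g - (x[i, ] - xbar)
    }
    g
  }
  fit <- stats::optim(rep(0, ncol(x)), nll, gr, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 1000))
  fit$par
}

# Exhaustive 2-partition within-cluster SSE minimizer (n <= 12 or so).
best_bipartition_sse <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  sse_of <- function(idx) {
    a <- x[idx, , drop = FALSE]
    b <- x[-idx, , drop = FALSE]
    sum(sweep(a, 2, colMeans(a))^2) + sum(sweep(b, 2, colMeans(b))^2)
  }
  best <- Inf
  # fix sample 1 in cluster A to halve the enumeration
  others <- 2:n
  for (size_a in 0:(n - 2)) {
    combs <- utils::combn(others, size_a)
    for (c in seq_len(ncol(combs))) {
      idx <- c(1, combs[, c])
      if (length(idx) == n) next
      best <- min(best, sse_of(idx))
    }
  }
  best
}

kmeans_sse <- function(x, labels) {
  sum(vapply(unique(labels), function(l) {
    a <- x[labels == l, , drop = FALSE]
    sum(sweep(a, 2, colMeans(a))^2)
  }, numeric(1)))
}

# Consensus matrix recomputed pairwise from explicitly stored partitions.
consensus_oracle <- function(partitions, n) {
  co <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  for (p in partitions) {
    for (a in seq_along(p$items)) {
      for (b in seq_along(p$items)) {
        i <- p$items[a]; j <- p$items[b]
        cnt[i, j] <- cnt[i, j] + 1
        if (p$labels[a] == p$labels[b]) co[i, j] <- co[i, j] + 1
      }
    }
  }
  m <- ifelse(cnt > 0, co / ifelse(cnt > 0, cnt, 1), 0)
  diag(m) <- 1
  m
}

# Small planted two/three-cloud expression matrix (genes x samples).
make_clouds <- function(k, n, g = 20, sep = 4, noise = 0.5, seed = 1) {
  set.seed(seed)
  lab <- rep(seq_len(k), length.out = n)
  mu <- matrix(stats::rnorm(g * k, 0, sep), g, k)
  x <- mu[, lab] + matrix(stats::rnorm(g * n, 0, noise), g, n)
  dimnames(x) <- list(sprintf("g%03d", seq_len(g)), sprintf("s%03d", seq_len(n)))
  list(x = x, labels = lab)
}

# Adjusted Rand index (chance-corrected partition agreement).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  s_ij <- sum_comb(as.vector(tab))
  s_a <- sum_comb(rowSums(tab))
  s_b <- sum_comb(colSums(tab))
  expected <- s_a * s_b / choose(n, 2)
  (s_ij - expected) / ((s_a + s_b) / 2 - expected)
}
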