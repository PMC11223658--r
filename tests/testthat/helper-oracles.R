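# Independent oracles used across test files. Each is a deliberately naive,
# formula-level implementation kept separate from the package code paths.

# Biweight midcorrelation of two vectors, straight from the definition.
oracle_bicor <- function(x, y) {
  w_of <- function(v) {
    med <- median(v)
    u <- (v - med) / (9 * median(abs(v - med)))
    (v - med) * (1 - u^2)^2 * (abs(u) < 1)
  }
  a <- w_of(x); b <- w_of(y)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# Topological overlap by explicit triple loop.
oracle_tom <- function(a) {
  g <- nrow(a)
  k <- rowSums(a)
  out <- diag(g)
  for (i in seq_len(g)) for (j in seq_len(g)) {
    if (i == j) next
    l <- sum(a[i, -c(i, j)] * a[-c(i, j), j])
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# kwithin by explicit double loop over gene pairs.
oracle_kwithin <- function(x) {
  g <- nrow(x)
  out <- numeric(g)
  for (i in seq_len(g)) {
    s <- 0
    for (j in seq_len(g)) if (j != i) s <- s + cor(x[i, ], x[j, ])
    out[i] <- s
  }
  out
}

# Benjamini-Hochberg by the literal step-up rule.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Upper hypergeometric tail P(X >= k) via exact binomial coefficients.
oracle_hyper_upper <- function(k, K, n, N) {
  i <- k:min(K, n)
  if (k <= max(0, K + n - N)) return(1)
  sum(choose(n, i) * choose(N - n, K - i)) / choose(N, K)
}

# Exact two-sided Mann-Whitney P by recursive enumeration of the group-A
# index sets (no combn, no rank identity): counts assignments at least as
# extreme in either direction.
oracle_mw_p <- function(x, y) {
  pool <- c(x, y)
  na <- length(x); nb <- length(y)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_stat(x, y)
  lo <- min(u_obs, na * nb - u_obs); hi <- max(u_obs, na * nb - u_obs)
  count <- c(total = 0, extreme = 0)
  recurse <- function(start, chosen) {
    if (length(chosen) == na) {
      u <- u_stat(pool[chosen], pool[-chosen])
      count["total"] <<- count["total"] + 1
      if (u <= lo + 1e-9 || u >= hi - 1e-9)
        count["extreme"] <<- count["extreme"] + 1
      return(invisible())
    }
    for (nxt in start:(na + nb)) {
      if (na + nb - nxt + 1 < na - length(chosen)) break
      recurse(nxt + 1, c(chosen, nxt))
    }
  }
  recurse(1, integer(0))
  unname(count["extreme"] / count["total"])
}

# Pearson r -> two-sided P through the t transform.
oracle_cor_p <- function(r, n) {
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), df = n - 2)
}

# Small planted-module expression fixture on the latent (log) scale.
sim_two_group_module <- function(n_genes, n, rho_a, rho_b, noise_sd = 0.6325) {
  la <- noise_sd * sqrt(rho_a / (1 - rho_a))
  lb <- noise_sd * sqrt(rho_b / (1 - rho_b))
  xa <- outer(rep(la, n_genes), rnorm(n)) +
    matrix(rnorm(n_genes * n, sd = noise_sd), n_genes)
  xb <- outer(rep(lb, n_genes), rnorm(n)) +
    matrix(rnorm(n_genes * n, sd = noise_sd), n_genes)
  rownames(xa) <- rownames(xb) <- sprintf("g%03d", seq_len(n_genes))
  list(a = xa, b = xb)
}

# Wrap two latent matrices as an expr_matrix + partition + metadata triple.
as_module_fixture <- function(xa, xb) {
  colnames(xa) <- sprintf("A%02d", seq_len(ncol(xa)))
  colnames(xb) <- sprintf("B%02d", seq_len(ncol(xb)))
  m <- expression_matrix(2^cbind(xa, xb), "tpm")
  part <- module_partition(setNames(rep("mod1", nrow(xa)), rownames(xa)))
  list(m = log2_transform(m, 0), part = part,
       a = colnames(xa), b = colnames(xb))
}
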