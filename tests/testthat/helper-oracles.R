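# Independent brute-force oracles. Each one recomputes a quantity from its
# defining formula or by exhaustive enumeration, via a code path disjoint
# from the package implementation (log-choose arithmetic instead of dhyper,
# explicit loops instead of vectorized cumulants).

# Exact 2x2 Fisher p by enumerating the hypergeometric support with
# binomial-coefficient arithmetic.
oracle_fisher <- function(tb, sidedness = "two-sided") {
  a <- tb[1, 1]; b <- tb[1, 2]; c2 <- tb[2, 1]; d <- tb[2, 2]
  N <- a + b + c2 + d
  K <- a + b
  n <- a + c2
  lo <- max(0, n - (N - K))
  hi <- min(n, K)
  x <- lo:hi
  p <- exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))
  pa <- p[x == a]
  switch(sidedness,
    "two-sided" = sum(p[p <= pa * (1 + 1e-7)]),
    "greater"   = sum(p[x >= a]),
    "less"      = sum(p[x <= a])
  )
}

# Direct-formula BH: adjusted value of the i-th smallest p is
# min_{j >= i} p_(j) * m / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, vapply(i:m, function(j) p[o[j]] * m / j, 0))
  }
  q
}

# Product-limit estimator as an explicit loop over distinct times.
oracle_km <- function(time, event) {
  ut <- sort(unique(time))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ut, surv = surv)
}

# Permutation p-value of the 2-group log-rank statistic: every assignment of
# subjects to the two group sizes.
oracle_perm_logrank_p <- function(time, event, group) {
  group <- as.character(group)
  lv <- unique(group)
  stopifnot(length(lv) == 2)
  n <- length(time)
  n1 <- sum(group == lv[1])
  stat_obs <- logrank_test(time, event, group)$statistic
  combs <- utils::combn(n, n1)
  stats_perm <- apply(combs, 2, function(ix) {
    g <- rep(lv[2], n)
    g[ix] <- lv[1]
    logrank_test(time, event, g)$statistic
  })
  mean(stats_perm >= stat_obs - 1e-12)
}

# Full enumeration of rank assignments for the two-sample Wilcoxon;
# two-sided p by distance of U from its null mean.
oracle_perm_wilcoxon_p <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  mu <- nx * length(y) / 2
  u_of <- function(ix) sum(r[ix]) - nx * (nx + 1) / 2
  obs <- abs(u_of(seq_len(nx)) - mu)
  combs <- utils::combn(n, nx)
  us <- apply(combs, 2, function(ix) abs(u_of(ix) - mu))
  mean(us >= obs - 1e-12)
}

# Full enumeration of 3-group label assignments for the Kruskal-Wallis
# statistic.
oracle_perm_kw_p <- function(groups) {
  stopifnot(length(groups) == 3)
  sizes <- lengths(groups)
  vals <- unlist(groups, use.names = FALSE)
  n <- length(vals)
  h_obs <- kruskal_wallis(groups)$statistic
  hs <- c()
  idx1 <- utils::combn(n, sizes[1])
  for (i in seq_len(ncol(idx1))) {
    rest <- setdiff(seq_len(n), idx1[, i])
    idx2 <- utils::combn(length(rest), sizes[2])
    for (j in seq_len(ncol(idx2))) {
      g2 <- rest[idx2[, j]]
      g3 <- setdiff(rest, g2)
      hs <- c(hs, kruskal_wallis(list(vals[idx1[, i]], vals[g2],
                                      vals[g3]))$statistic)
    }
  }
  mean(hs >= h_obs - 1e-12)
}

# Pairwise correlation by the covariance formula, explicit loops.
oracle_cor <- function(m) {
  g <- nrow(m)
  out <- matrix(NA_real_, g, g)
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      xi <- m[i, ] - mean(m[i, ])
      xj <- m[j, ] - mean(m[j, ])
      den <- sqrt(sum(xi^2) * sum(xj^2))
      if (den > 0) out[i, j] <- sum(xi * xj) / den
    }
  }
  out
}

# Random small survival instance with ties, used by several tests.
random_surv_instance <- function(n, max_t = 10) {
  list(time = sample(seq_len(2 * max_t), n, replace = TRUE) / 2,
       event = stats::rbinom(n, 1, 0.7))
}

# Small labelled expression fixture.
make_expr <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- if (is.null(genes)) sprintf("g%02d", seq_len(nrow(m))) else genes
  colnames(m) <- if (is.null(samples)) sprintf("s%02d", seq_len(ncol(m))) else samples
  m
}
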