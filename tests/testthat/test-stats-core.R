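# Statistical primitives against brute-force and reference oracles.

test_that("fisher_exact_2x2 matches enumeration on stated and random tables", {
  # single possible table given margins
  expect_equal(fisher_exact_2x2(matrix(c(0, 5, 0, 5), 2, byrow = TRUE))$p_value, 1)
  # frozen enumeration cases
  tb <- matrix(c(5, 0, 0, 5), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(tb)$p_value, oracle_fisher(tb), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(tb)$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  tb <- matrix(c(3, 7, 1, 9), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(tb, "greater")$p_value, oracle_fisher(tb, "greater"),
               tolerance = 1e-12)

  set.seed(11)
  for (rep in 1:50) {
    tb <- matrix(rpois(4, 5), 2, 2)
    if (sum(tb) == 0) tb[1, 1] <- 1
    for (sd_ in c("two-sided", "greater", "less")) {
      expect_equal(fisher_exact_2x2(tb, sd_)$p_value, oracle_fisher(tb, sd_),
                   tolerance = 1e-12)
      expect_equal(fisher_exact_2x2(tb, sd_)$p_value,
                   fisher.test(tb, alternative = sub("two-sided", "two.sided", sd_))$p.value,
                   tolerance = 1e-10)
    }
  }
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "degenerate margins")
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2, 2)), "non-negative")
})

test_that("fisher_exact_2x2 full-sweep equivalence on small totals", {
  # acceptance runs the full N <= 30 sweep; here N <= 10 keeps unit tests fast
  for (N in 1:10) {
    for (a in 0:N) for (b in 0:(N - a)) for (c2 in 0:(N - a - b)) {
      tb <- matrix(c(a, b, c2, N - a - b - c2), 2, 2, byrow = TRUE)
      expect_equal(fisher_exact_2x2(tb)$p_value, oracle_fisher(tb),
                   tolerance = 1e-12)
    }
  }
})

test_that("bh_adjust matches the direct step-up formula and is order-invariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)

  set.seed(5)
  p <- runif(50)
  expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  expect_equal(bh_adjust(p), p.adjust(p, method = "BH"), tolerance = 1e-12)

  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm], tolerance = 1e-14)

  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(numeric(0)), "non-empty")
})

test_that("one_way_anova agrees with the sum-of-squares decomposition", {
  r <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # p -> 0 as jitter -> 0 around fully separated groups
  p_prev <- 1
  for (jit in c(1e-1, 1e-3, 1e-5)) {
    set.seed(1)
    r <- one_way_anova(list(rnorm(3, 0, jit), rnorm(3, 1, jit)))
    expect_lt(r$p_value, p_prev)
    p_prev <- r$p_value
  }

  set.seed(21)
  for (rep in 1:20) {
    groups <- lapply(c(4, 6, 5), function(n) rnorm(n, mean = runif(1, -1, 1)))
    mine <- one_way_anova(groups)
    ref <- anova(lm(y ~ g, data = data.frame(
      y = unlist(groups), g = factor(rep(seq_along(groups), lengths(groups))))))
    expect_equal(mine$statistic, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  }

  degen <- one_way_anova(list(c(2, 2), c(2, 2)))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)
  expect_error(one_way_anova(list(1, c(1, 2))), "at least 2")
})

test_that("kruskal_wallis and wilcoxon_rank_sum match enumeration oracles", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0)
  expect_equal(kruskal_wallis(list(c(5, 5), c(5, 5)))$p_value, 1)

  # exact Wilcoxon equals the full rank-assignment enumeration
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(w$p_value, oracle_perm_wilcoxon_p(c(1, 2), c(3, 4)),
               tolerance = 1e-12)
  set.seed(3)
  for (rep in 1:10) {
    x <- rnorm(4)
    y <- rnorm(5)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, oracle_perm_wilcoxon_p(x, y),
                 tolerance = 1e-12)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                 wilcox.test(x, y)$p.value, tolerance = 1e-10)
  }

  # chi-square KW p tracks the full label-permutation p on tiny groups
  set.seed(9)
  perm_p <- chisq_p <- numeric(10)
  for (i in 1:10) {
    groups <- list(rnorm(2), rnorm(2), rnorm(2))
    perm_p[i] <- oracle_perm_kw_p(groups)
    chisq_p[i] <- kruskal_wallis(groups)$p_value
  }
  expect_gte(cor(perm_p, chisq_p, method = "spearman"), 0.9)

  expect_error(kruskal_wallis(list(numeric(0), 1:3)), "at least 1")
})

test_that("kruskal_wallis on 2 groups equals the uncorrected normal Wilcoxon", {
  set.seed(17)
  for (rep in 1:20) {
    x <- rnorm(12)
    y <- rnorm(15, 0.3)
    if (rep %% 2 == 0) { # exercise the tie-corrected branch too
      x <- round(x)
      y <- round(y)
    }
    kw <- kruskal_wallis(list(x, y))
    w <- wilcoxon_rank_sum(x, y, continuity = FALSE, exact = FALSE)
    expect_equal(kw$p_value, w$p_value, tolerance = 1e-8)
  }
})

test_that("pearson_correlation_matrix matches the covariance formula", {
  m <- make_expr(rbind(1:6, -(1:6), rnorm(6)))
  r <- pearson_correlation_matrix(m)
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(unname(r[1, 2]), -1)
  expect_identical(r, t(r))

  set.seed(23)
  m <- make_expr(matrix(rnorm(30), 5, 6))
  r <- pearson_correlation_matrix(m)
  expect_equal(unname(r), oracle_cor(m), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(r >= -1 & r <= 1))

  # zero-variance rows are flagged and NA
  m2 <- make_expr(rbind(rep(2, 6), rnorm(6)))
  r2 <- pearson_correlation_matrix(m2)
  expect_identical(attr(r2, "zero_variance"), c(TRUE, FALSE))
  expect_true(all(is.na(r2[1, ])))
  expect_equal(unname(r2[2, 2]), 1)

  # missing values: pairwise complete, cross-checked against stats::cor
  m3 <- make_expr(matrix(rnorm(40), 5, 8))
  m3[1, 2] <- NA
  m3[4, c(1, 5)] <- NA
  r3 <- pearson_correlation_matrix(m3)
  ref <- cor(t(m3), use = "pairwise.complete.obs")
  expect_equal(unname(r3), unname(ref), tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(pearson_correlation_matrix(make_expr(matrix(1:5, 5, 1))),
               "at least 2")
})

test_that("row_anova matches one_way_anova gene by gene", {
  set.seed(31)
  expr <- make_expr(matrix(rnorm(200), 20, 10))
  expr[3, 1] <- NA
  idx <- list(a = 1:4, b = 5:7, c = 8:10)
  va <- sigstrat:::row_anova(expr, idx)
  for (g in 1:20) {
    ref <- one_way_anova(lapply(idx, function(ix) expr[g, ix]))
    expect_equal(va$statistic[g], ref$statistic, tolerance = 1e-10)
    expect_equal(va$p_value[g], ref$p_value, tolerance = 1e-10)
  }
})
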