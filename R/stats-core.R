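# Exact and rank-based statistical primitives. Every routine here is written
# directly from its defining formula so it can be checked against brute-force
# enumeration or permutation oracles in the test suite.

#' Construct a test result
#'
#' Lightweight container for the output of the hypothesis tests in this
#' package: a statistic, a p-value, the sidedness of the alternative and an
#' optional chi-square degrees of freedom.
#'
#' @param statistic Numeric test statistic.
#' @param p_value P-value in \[0, 1\].
#' @param sidedness One of `"two-sided"`, `"greater"`, `"less"`.
#' @param df Optional degrees of freedom (chi-square family statistics only).
#' @param method Human-readable test name.
#' @param degenerate Logical flag set when a degenerate input forced the
#'   conventional (statistic 0, p 1) result.
#' @return An object of class `sig_test`.
#' @export
test_result <- function(statistic, p_value, sidedness = "two-sided", df = NULL,
                        method = "", degenerate = FALSE) {
  assert_that(is.numeric(p_value) && length(p_value) == 1 &&
                !is.na(p_value) && p_value >= 0 && p_value <= 1,
              "p_value must be a single number in [0, 1]")
  assert_that(sidedness %in% c("two-sided", "greater", "less"),
              "invalid sidedness")
  structure(
    list(statistic = as.numeric(statistic), p_value = as.numeric(p_value),
         sidedness = sidedness, df = df, method = method,
         degenerate = isTRUE(degenerate)),
    class = "sig_test"
  )
}

#' @export
print.sig_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (%s%s)%s\n",
              if (nzchar(x$method)) x$method else "test",
              x$statistic, x$p_value, x$sidedness,
              if (!is.null(x$df)) sprintf(", df = %d", x$df) else "",
              if (x$degenerate) " [degenerate input]" else ""))
  invisible(x)
}

as_2x2 <- function(table) {
  tb <- as.matrix(table)
  assert_that(all(dim(tb) == c(2L, 2L)), "table must be 2x2")
  assert_that(is.numeric(tb) && !anyNA(tb) && all(tb >= 0) &&
                all(abs(tb - round(tb)) < 1e-8),
              "table cells must be non-negative integers")
  round(tb)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact test of association in a 2x2 contingency table under the
#' hypergeometric distribution with fixed margins. The two-sided p-value sums
#' the probabilities of all tables no more probable than the observed one
#' (the convention of common statistical software); one-sided p-values are
#' the corresponding hypergeometric tails.
#'
#' @param table 2x2 matrix of non-negative integer counts; rows = condition of
#'   interest vs rest, columns = group 1 vs group 2.
#' @param sidedness `"two-sided"` (default), `"greater"` or `"less"`; one-sided
#'   alternatives refer to the (1,1) cell at fixed margins.
#' @return A [test_result()] whose statistic is the sample odds ratio
#'   (ad / bc, possibly infinite).
#' @examples
#' fisher_exact_2x2(matrix(c(8, 2, 1, 9), 2, byrow = TRUE), "greater")
#' @export
fisher_exact_2x2 <- function(table, sidedness = c("two-sided", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  tb <- as_2x2(table)
  N <- sum(tb)
  if (N == 0) stop("degenerate margins: all cells are zero", call. = FALSE)
  a <- tb[1, 1]
  K <- tb[1, 1] + tb[1, 2]   # row-1 margin
  n <- tb[1, 1] + tb[2, 1]   # column-1 margin
  lo <- max(0, n - (N - K))
  hi <- min(n, K)
  x <- lo:hi
  dens <- stats::dhyper(x, K, N - K, n)
  p_obs <- dens[match(a, x)]
  p <- switch(sidedness,
    "two-sided" = sum(dens[dens <= p_obs * (1 + 1e-7)]),
    "greater"   = sum(dens[x >= a]),
    "less"      = sum(dens[x <= a])
  )
  or <- (tb[1, 1] * tb[2, 2]) / (tb[1, 2] * tb[2, 1])
  test_result(or, min(p, 1), sidedness, method = "Fisher exact test (2x2)")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment: the adjusted value of the i-th
#' smallest p is `min_{j >= i} p_(j) * m / j`, clipped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, in the input order.
#' @export
bh_adjust <- function(p) {
  assert_that(is.numeric(p) && length(p) >= 1, "p must be a non-empty numeric vector")
  assert_that(!anyNA(p) && all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

check_groups <- function(groups, min_size = 2L) {
  assert_that(is.list(groups) && length(groups) >= 2, "need at least 2 groups")
  groups <- lapply(groups, function(g) {
    g <- as.numeric(g)
    g[!is.na(g)]
  })
  sizes <- lengths(groups)
  assert_that(all(sizes >= min_size),
              sprintf("every group needs at least %d non-missing values", min_size))
  groups
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA F-test from the between/within sum of
#' squares decomposition.
#'
#' @param groups List of numeric vectors (>= 2 groups, >= 2 values each; NAs
#'   dropped).
#' @return A [test_result()] with the F statistic and p from F(k-1, N-k).
#'   Zero total variance yields statistic 0, p 1, flagged degenerate.
#' @export
one_way_anova <- function(groups) {
  groups <- check_groups(groups, min_size = 2L)
  k <- length(groups)
  ni <- lengths(groups)
  N <- sum(ni)
  all_v <- unlist(groups, use.names = FALSE)
  gm <- mean(all_v)
  mi <- vapply(groups, mean, 0)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum(vapply(seq_len(k), function(i) sum((groups[[i]] - mi[i])^2), 0))
  sst <- ssb + ssw
  if (sst <= 1e-12 * N * (1 + gm^2)) {
    return(test_result(0, 1, "greater", method = "one-way ANOVA", degenerate = TRUE))
  }
  df1 <- k - 1L
  df2 <- N - k
  if (ssw == 0) {
    return(test_result(Inf, 0, "greater", method = "one-way ANOVA"))
  }
  f <- (ssb / df1) / (ssw / df2)
  test_result(f, stats::pf(f, df1, df2, lower.tail = FALSE), "greater",
              method = "one-way ANOVA")
}

#' Kruskal-Wallis rank sum test
#'
#' Tie-corrected Kruskal-Wallis H statistic with the chi-square reference
#' distribution on k - 1 degrees of freedom.
#'
#' @param groups List of numeric vectors, each with >= 1 non-missing value
#'   (>= 2 groups).
#' @return A [test_result()]. All-tied input (tie correction factor 0) gives
#'   statistic 0, p 1, flagged degenerate.
#' @export
kruskal_wallis <- function(groups) {
  groups <- check_groups(groups, min_size = 1L)
  k <- length(groups)
  ni <- lengths(groups)
  N <- sum(ni)
  all_v <- unlist(groups, use.names = FALSE)
  r <- rank(all_v)
  idx <- rep(seq_len(k), ni)
  ri <- tapply(r, idx, mean)
  h <- 12 / (N * (N + 1)) * sum(ni * (ri - (N + 1) / 2)^2)
  ties <- table(all_v)
  cf <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (cf <= 0) {
    return(test_result(0, 1, "two-sided", df = k - 1L,
                       method = "Kruskal-Wallis", degenerate = TRUE))
  }
  h <- h / cf
  test_result(h, stats::pchisq(h, df = k - 1L, lower.tail = FALSE),
              "two-sided", df = k - 1L, method = "Kruskal-Wallis")
}

#' Wilcoxon rank sum (Mann-Whitney) test
#'
#' Exact p-value from the null distribution of the Mann-Whitney U statistic
#' when the combined sample size is at most `exact_limit` and there are no
#' ties; otherwise a normal approximation with tie correction and (optional)
#' continuity correction.
#'
#' @param x,y Numeric vectors (NAs dropped; both non-empty).
#' @param sidedness Alternative hypothesis; `"greater"` means x tends larger.
#' @param continuity Apply the continuity correction in the normal
#'   approximation (default TRUE). Set FALSE to recover the algebraic identity
#'   with the 2-group Kruskal-Wallis test.
#' @param exact Force (`TRUE`)/suppress (`FALSE`) the exact computation;
#'   default `NULL` picks it automatically.
#' @param exact_limit Combined-size cutoff for the automatic exact rule.
#' @return A [test_result()] whose statistic is Mann-Whitney U for x.
#' @export
wilcoxon_rank_sum <- function(x, y, sidedness = c("two-sided", "greater", "less"),
                              continuity = TRUE, exact = NULL, exact_limit = 20L) {
  sidedness <- match.arg(sidedness)
  x <- as.numeric(x[!is.na(x)])
  y <- as.numeric(y[!is.na(y)])
  assert_that(length(x) >= 1 && length(y) >= 1, "both groups must be non-empty")
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (is.null(exact)) exact <- (nx + ny) <= exact_limit && !ties
  if (exact && ties) {
    warning("ties present; falling back to the normal approximation")
    exact <- FALSE
  }
  if (exact) {
    p <- switch(sidedness,
      "two-sided" = {
        p1 <- if (u > nx * ny / 2) {
          stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE)
        } else {
          stats::pwilcox(u, nx, ny)
        }
        min(1, 2 * p1)
      },
      "greater" = stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE),
      "less"    = stats::pwilcox(u, nx, ny)
    )
    return(test_result(u, p, sidedness, method = "Wilcoxon rank sum (exact)"))
  }
  n <- nx + ny
  mu <- nx * ny / 2
  tab <- table(r)
  sig2 <- nx * ny / 12 * ((n + 1) - sum(tab^3 - tab) / (n * (n - 1)))
  if (sig2 <= 0) {
    return(test_result(u, 1, sidedness,
                       method = "Wilcoxon rank sum (normal approximation)",
                       degenerate = TRUE))
  }
  sg <- sqrt(sig2)
  cc <- if (continuity) 0.5 else 0
  p <- switch(sidedness,
    "two-sided" = {
      z <- u - mu
      z <- (z - sign(z) * cc) / sg
      min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    },
    "greater" = stats::pnorm((u - mu - cc) / sg, lower.tail = FALSE),
    "less"    = stats::pnorm((u - mu + cc) / sg)
  )
  test_result(u, p, sidedness, method = "Wilcoxon rank sum (normal approximation)")
}

#' Gene-gene Pearson correlation matrix
#'
#' Correlation of every pair of rows (genes) across columns (samples).
#' Zero-variance rows have undefined correlations: their entries are `NA` and
#' they are flagged in the `zero_variance` attribute. With missing values,
#' correlations use pairwise complete observations.
#'
#' @param m Numeric genes x samples matrix with >= 2 columns.
#' @return Symmetric matrix with unit diagonal for non-degenerate rows;
#'   attribute `zero_variance` is a logical vector over rows.
#' @export
pearson_correlation_matrix <- function(m) {
  assert_that(is.matrix(m) && is.numeric(m), "m must be a numeric matrix")
  assert_that(ncol(m) >= 2, "at least 2 samples are required")
  g <- nrow(m)
  if (!anyNA(m)) {
    mu <- rowMeans(m)
    cm <- m - mu
    ss <- rowSums(cm^2)
    zero_var <- !is.finite(ss) | ss <= 0
    z <- cm / sqrt(pmax(ss, .Machine$double.xmin))
    r <- tcrossprod(z)
  } else {
    r <- matrix(NA_real_, g, g)
    zero_var <- logical(g)
    for (i in seq_len(g)) {
      zero_var[i] <- {
        v <- m[i, ][!is.na(m[i, ])]
        length(v) < 2 || stats::var(v) == 0
      }
    }
    for (i in seq_len(g)) {
      for (j in i:g) {
        if (zero_var[i] || zero_var[j]) next
        ok <- !is.na(m[i, ]) & !is.na(m[j, ])
        if (sum(ok) < 2) next
        xi <- m[i, ok] - mean(m[i, ok])
        xj <- m[j, ok] - mean(m[j, ok])
        den <- sqrt(sum(xi^2) * sum(xj^2))
        if (den > 0) r[i, j] <- r[j, i] <- sum(xi * xj) / den
      }
    }
  }
  r <- (r + t(r)) / 2
  r[r > 1] <- 1
  r[r < -1] <- -1
  r[zero_var, ] <- NA_real_
  r[, zero_var] <- NA_real_
  diag(r)[!zero_var] <- 1
  dimnames(r) <- list(rownames(m), rownames(m))
  attr(r, "zero_variance") <- unname(zero_var)
  r
}

# Vectorised per-gene one-way ANOVA across the rows of an expression matrix.
# Equivalent to applying one_way_anova() row by row (asserted in tests), but
# ~100x faster for thousands of genes. Rows where any group has < 2
# non-missing values get NA.
row_anova <- function(expr, group_idx) {
  k <- length(group_idx)
  g <- nrow(expr)
  cnt <- sm <- ssw <- matrix(0, g, k)
  for (j in seq_len(k)) {
    xj <- expr[, group_idx[[j]], drop = FALSE]
    ok <- !is.na(xj)
    cnt[, j] <- rowSums(ok)
    sm[, j] <- rowSums(xj, na.rm = TRUE)
    mj <- sm[, j] / cnt[, j]
    ssw[, j] <- rowSums((xj - mj)^2, na.rm = TRUE)
  }
  N <- rowSums(cnt)
  gm <- rowSums(sm) / N
  mj <- sm / cnt
  ssb <- rowSums(cnt * (mj - gm)^2)
  ssw_t <- rowSums(ssw)
  df1 <- k - 1L
  df2 <- N - k
  f <- (ssb / df1) / (ssw_t / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  sst <- ssb + ssw_t
  degen <- sst <= 1e-12 * N * (1 + gm^2)
  p[degen] <- 1
  f[degen] <- 0
  zero_within <- !degen & ssw_t == 0
  p[zero_within] <- 0
  f[zero_within] <- Inf
  bad <- rowSums(cnt < 2) > 0
  p[bad] <- NA_real_
  f[bad] <- NA_real_
  list(statistic = f, p_value = p, group_means = mj)
}
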