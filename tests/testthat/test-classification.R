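# Per-sample thresholded counting, Fisher calls, four-way category, and the
# cohort-level classifiers.

test_that("count_beyond_threshold uses inclusive comparisons and skips NAs", {
  expr <- make_expr(matrix(0, 3, 4))
  sig <- gene_signature("s", rownames(expr))
  expect_equal(unname(count_beyond_threshold(expr, sig, -0.5, "at_or_below")),
               rep(0L, 4), ignore_attr = TRUE)

  expr[1, 1] <- -0.5   # exactly at the boundary: counted ("-0.5 or under")
  expr[2, 2] <- 1      # exactly at the high boundary
  expect_identical(unname(count_beyond_threshold(expr, sig, -0.5, "at_or_below")[1]), 1L)
  expect_identical(unname(count_beyond_threshold(expr, sig, 1, "at_or_above")[2]), 1L)

  expr[, 3] <- NA      # all-missing sample is unclassifiable
  cnt <- count_beyond_threshold(expr, sig, -0.5, "at_or_below")
  expect_true(is.na(cnt[3]))

  set.seed(51)
  m <- make_expr(matrix(rnorm(50), 10, 5))
  sig10 <- gene_signature("s10", rownames(m))
  cnt <- count_beyond_threshold(m, sig10, -0.2, "at_or_below")
  # per-cell enumeration oracle
  manual <- sapply(1:5, function(j) sum(sapply(1:10, function(i) m[i, j] <= -0.2)))
  expect_equal(unname(cnt), as.integer(manual), ignore_attr = TRUE)

  expect_error(count_beyond_threshold(m, gene_signature("x", c("zz1", "zz2")),
                                      0, "at_or_below"), "zz1")
  expect_warning(count_beyond_threshold(m, gene_signature("y", c("g01", "nope")),
                                        0, "at_or_below"), "dropped")
})

test_that("call_sample_status tests counts against the rounded cohort mean", {
  # uniform cohort: nobody exceeds the average
  st <- call_sample_status(setNames(rep(5L, 8), paste0("s", 1:8)), 20, 0.1)
  expect_true(all(!st$positive))
  expect_true(all(st$p_value >= 0.5))

  # one extreme sample against an all-zero cohort
  counts <- setNames(c(20L, rep(0L, 9)), paste0("s", 1:10))
  st <- call_sample_status(counts, 20, 0.1)
  k0 <- round(mean(counts))            # 2
  p_manual <- oracle_fisher(matrix(c(20, 0, k0, 20 - k0), 2, 2, byrow = TRUE),
                            "greater")
  expect_equal(st$p_value[1], p_manual, tolerance = 1e-12)
  expect_true(st$positive[1])
  expect_true(all(!st$positive[-1]))

  # invariance under sample permutation
  set.seed(52)
  counts <- setNames(rbinom(12, 30, 0.3), paste0("s", 1:12))
  st1 <- call_sample_status(counts, 30)
  perm <- sample(12)
  st2 <- call_sample_status(counts[perm], 30)
  expect_equal(st2$p_value, st1$p_value[perm])

  expect_error(call_sample_status(counts, 0), "positive")
})

test_that("four_way_category pairs calls deterministically and partitions", {
  ra <- setNames(c("RA-D", "RA-ND", "RA-D"), c("a", "b", "c"))
  erk <- setNames(c("ERK-I", "ERK-NI", "ERK-NI"), c("a", "b", "c"))
  cat4 <- four_way_category(ra, erk)
  expect_identical(as.character(cat4),
                   c("RA-D/ERK-I", "RA-ND/ERK-NI", "RA-D/ERK-NI"))
  # order-insensitive pairing
  cat4b <- four_way_category(ra, erk[c("c", "a", "b")])
  expect_identical(cat4, cat4b)
  expect_identical(sum(table(cat4)), 3L)
  expect_error(four_way_category(ra, erk[c("a", "b")]), "same samples")
})

test_that("classify_samples recovers planted calls when the mechanism is isolated", {
  # latent loading 0 isolates the count/Fisher mechanism (see vignette)
  conc <- sapply(1:10, function(s) {
    cf <- cohort_config(n_samples = 120, category_probs = c(0.5, 0.125, 0.25, 0.125),
                        anti_corr_loading = 0, seed = 6000 + s)
    ch <- generate_cohort(cf)
    st <- classify_samples(ch$expression, ch$ra_signature, ch$erk_signature)
    truth_rad <- ch$truth$category %in% c("RA-D/ERK-NI", "RA-D/ERK-I")
    mean((st$ra_call == "RA-D") == truth_rad)
  })
  expect_gte(mean(conc), 0.95)
})

test_that("null cohorts stay within the positive-call rate bound", {
  rates <- sapply(1:8, function(s) {
    ch <- generate_cohort(cohort_config(n_samples = 100, effect_ra = 0,
                                        effect_erk = 0, anti_corr_loading = 0,
                                        seed = 6100 + s))
    st <- classify_samples(ch$expression, ch$ra_signature, ch$erk_signature)
    mean(c(st$ra_call == "RA-D", st$erk_call == "ERK-I"))
  })
  alpha <- 0.1
  bound <- alpha + 3 * sqrt(alpha * (1 - alpha) / 200)
  expect_true(all(rates <= bound))
})

test_that("raising the low threshold never decreases counts", {
  set.seed(53)
  m <- make_expr(matrix(rnorm(200), 20, 10))
  sig <- gene_signature("s", rownames(m))
  prev <- count_beyond_threshold(m, sig, -1.5, "at_or_below")
  for (thr in c(-1, -0.5, 0)) {
    cur <- count_beyond_threshold(m, sig, thr, "at_or_below")
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("zscore_classify retains cohort-upregulated genes then splits samples", {
  z <- make_expr(matrix(1, 4, 6))
  sig <- gene_signature("s", rownames(z))
  res <- zscore_classify(z, sig)
  expect_setequal(res$retained_genes, rownames(z))
  expect_true(all(res$labels == "high"))

  # gene-wise standardization of the same cohort retains nothing
  set.seed(54)
  raw <- make_expr(matrix(rnorm(60), 6, 10))
  zc <- t(scale(t(raw)))
  dimnames(zc) <- dimnames(raw)
  expect_error(zscore_classify(zc, gene_signature("s", rownames(raw))),
               "not cohort-upregulated")

  # planted high/low subgroups against an external (normal-tissue) reference:
  # 40 samples shifted +1, 20 shifted -1 on the signature genes, so the
  # signature stays cohort-upregulated while the subgroups separate
  hits <- sapply(1:10, function(s) {
    set.seed(7000 + s)
    n <- 60
    zm <- make_expr(matrix(rnorm(20 * n), 20, n))
    high <- 1:40
    zm[1:8, high] <- zm[1:8, high] + 1
    zm[1:8, -high] <- zm[1:8, -high] - 1
    res <- zscore_classify(zm, gene_signature("h", rownames(zm)[1:8]))
    mean((res$labels == "high") == (seq_len(n) %in% high))
  })
  expect_gte(mean(hits), 0.95)
})

test_that("change_enrichment flags directional fold changes and tests 2x2", {
  set.seed(55)
  base <- make_expr(matrix(rnorm(300 * 4, sd = 0.1), 300, 4))
  same <- change_enrichment(base, base, gene_signature("s", rownames(base)[1:30]),
                            "down")
  expect_equal(same$percent_changed, 0)
  expect_equal(same$test$p_value, 1)

  # planted: signature genes shifted down 1 log2 in cancer
  cancer <- base
  cancer[1:50, ] <- cancer[1:50, ] - 1
  res <- change_enrichment(cancer, base, gene_signature("s", rownames(base)[1:50]),
                           "down", fold_change_cut = 1.5)
  expect_lt(res$test$p_value, 0.001)
  expect_gt(res$percent_changed, res$background_percent)

  expect_error(change_enrichment(base, base,
                                 gene_signature("all", rownames(base)), "down"),
               "background")
})

test_that("signature_score is the unweighted mean over present genes", {
  set.seed(56)
  m <- make_expr(matrix(rnorm(40), 4, 10))
  one <- signature_score(m, gene_signature("one", rownames(m)[2]))
  expect_equal(one$score, unname(m[2, ]))

  cm <- make_expr(matrix(2.5, 3, 4))
  expect_true(all(signature_score(cm, gene_signature("c", rownames(cm)))$score == 2.5))

  m[1, 3] <- NA
  sc <- signature_score(m, gene_signature("s", rownames(m)))
  expect_equal(sc$n_genes_used[3], 3L)
  expect_equal(sc$score[3], mean(m[2:4, 3]))
})

test_that("RA and ERK scores anti-correlate under the latent factor", {
  neg <- sapply(1:15, function(s) {
    ch <- generate_cohort(cohort_config(n_samples = 100, effect_ra = 0,
                                        effect_erk = 0, anti_corr_loading = 0.8,
                                        seed = 7100 + s))
    a <- signature_score(ch$expression, ch$ra_signature)$score
    b <- signature_score(ch$expression, ch$erk_signature)$score
    cor(a, b)
  })
  expect_true(all(neg < 0))
})

test_that("score_bin_compare groups score A by quantile bins of score B", {
  set.seed(57)
  n <- 90
  b_score <- rnorm(n)
  a_score <- -0.8 * b_score + rnorm(n, sd = 0.3)
  sa <- data.frame(sample_id = paste0("s", 1:n), score = a_score,
                   n_genes_used = 5L)
  sb <- data.frame(sample_id = paste0("s", 1:n), score = b_score,
                   n_genes_used = 5L)
  out <- score_bin_compare(sa, sb, n_bins = 3)
  expect_equal(nrow(out), 3)
  expect_equal(sum(out$n), n)
  # anti-correlated scores: mean A decreases across increasing B bins
  expect_true(all(diff(out$mean_score_a) < 0))
  expect_true(all(diff(out$mean_score_b) > 0))
})
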