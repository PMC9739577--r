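# Kaplan-Meier, log-rank, uncensored location tests, events-only curves.

test_that("km_estimate reproduces hand-computed product limits", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$surv, c(2 / 3, 2 / 3, 0))
  expect_equal(km$n_risk, c(3L, 2L, 1L))

  all_cens <- km_estimate(c(1, 5, 9), c(0, 0, 0))
  expect_true(all(all_cens$surv == 1))

  # no censoring: survival equals 1 - ECDF at event times
  set.seed(61)
  t <- rexp(30)
  km <- km_estimate(t, rep(1, 30))
  expect_equal(km$surv, 1 - ecdf(t)(km$time), tolerance = 1e-12)

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("km_estimate matches the independent product-limit oracle and survfit", {
  skip_if_not_installed("survival")
  set.seed(62)
  for (rep in 1:25) {
    inst <- random_surv_instance(sample(5:50, 1))
    km <- km_estimate(inst$time, inst$event)
    orc <- oracle_km(inst$time, inst$event)
    expect_equal(km$time, orc$time)
    expect_equal(km$surv, orc$surv, tolerance = 1e-12)
    sf <- survival::survfit(survival::Surv(inst$time, inst$event) ~ 1)
    expect_equal(km$surv, sf$surv, tolerance = 1e-12)
  }
})

test_that("km_surv_at and km_rmst evaluate the step function correctly", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km_surv_at(km, c(0.5, 1, 2.9, 10)), c(1, 2 / 3, 2 / 3, 0))
  # rmst of the same curve up to 3: 1*1 + 2/3*2 ... piecewise by hand
  expect_equal(km_rmst(km, 3), 1 * 1 + (3 - 1) * 2 / 3)

  # exponential sanity: rmst(tau) ~ (1 - exp(-h tau))/h
  set.seed(63)
  t <- rexp(4000, 0.2)
  km2 <- km_estimate(t, rep(1, 4000))
  expect_equal(km_rmst(km2, 10), (1 - exp(-2)) / 0.2, tolerance = 0.1)
})

test_that("logrank_test matches survdiff and degenerates sensibly", {
  skip_if_not_installed("survival")
  # identical groups
  t <- c(1, 2, 3, 4)
  lr <- logrank_test(rep(t, 2), rep(1, 8), rep(1:2, each = 4))
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)

  # no events
  lr0 <- logrank_test(c(1, 2, 3, 4), rep(0, 4), rep(1:2, 2))
  expect_true(lr0$degenerate)
  expect_equal(lr0$p_value, 1)

  set.seed(64)
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    g <- sample(1:2, n, replace = TRUE)
    if (length(unique(g)) < 2) next
    inst <- random_surv_instance(n)
    mine <- logrank_test(inst$time, inst$event, g)
    if (sum(inst$event) == 0) next
    ref <- survival::survdiff(survival::Surv(inst$time, inst$event) ~ g)
    expect_equal(mine$statistic, unname(ref$chisq), tolerance = 1e-10)
  }

  # k = 3: the (O-E)^2/E form recomputed from survdiff's observed/expected
  for (rep in 1:10) {
    n <- 60
    g <- sample(1:3, n, replace = TRUE)
    inst <- random_surv_instance(n)
    if (sum(inst$event) == 0 || length(unique(g)) < 3) next
    mine <- logrank_test(inst$time, inst$event, g)
    ref <- survival::survdiff(survival::Surv(inst$time, inst$event) ~ g)
    expect_equal(mine$statistic, sum((ref$obs - ref$exp)^2 / ref$exp),
                 tolerance = 1e-10)
    expect_equal(mine$df, 2L)
  }
})

test_that("logrank_test is invariant to relabeling and time rescaling", {
  set.seed(65)
  inst <- random_surv_instance(30)
  g <- sample(c("x", "y"), 30, replace = TRUE)
  a <- logrank_test(inst$time, inst$event, g)
  b <- logrank_test(inst$time, inst$event, ifelse(g == "x", "y", "x"))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  c_ <- logrank_test(inst$time * 7.3, inst$event, g)
  expect_equal(a$statistic, c_$statistic, tolerance = 1e-12)
})

test_that("small-sample log-rank p agrees in rank with the permutation oracle", {
  set.seed(66)
  mine <- perm <- numeric(12)
  for (i in 1:12) {
    n1 <- sample(3:4, 1)
    n2 <- sample(3:4, 1)
    shift <- runif(1, 0, 3)
    time <- c(rexp(n1), rexp(n2) + shift)
    event <- rbinom(n1 + n2, 1, 0.85)
    event[1] <- 1
    g <- rep(1:2, c(n1, n2))
    mine[i] <- logrank_test(time, event, g)$p_value
    perm[i] <- oracle_perm_logrank_p(time, event, g)
  }
  expect_gte(cor(mine, perm, method = "spearman"), 0.9)
})

test_that("uncensored_location_test gates pairwise Wilcoxon on the KW p", {
  # identical distributions: gate closed
  set.seed(67)
  t <- rep(c(1, 2, 3, 4, 5), 3)
  g <- rep(1:3, each = 5)
  res <- uncensored_location_test(t, rep(1, 15), g)
  expect_gte(res$kw$p_value, 0.05)
  expect_equal(nrow(res$pairwise), 0)

  # gate contract over random instances
  for (s in 1:15) {
    set.seed(800 + s)
    n <- 36
    g <- rep(1:3, each = 12)
    t <- rexp(n, rate = c(1, 1.5, 3)[g])
    e <- rbinom(n, 1, 0.8)
    if (min(table(g[e == 1])) < 1) next
    res <- suppressWarnings(uncensored_location_test(t, e, g))
    if (res$kw$p_value >= 0.05) {
      expect_equal(nrow(res$pairwise), 0)
    } else {
      expect_equal(nrow(res$pairwise), choose(length(unique(g[e == 1])), 2))
      expect_true(all(res$pairwise$p_value >= 0 & res$pairwise$p_value <= 1))
    }
  }

  # power on shifted exponentials (scaled from the spec-scale simulation)
  rej <- sapply(1:30, function(s) {
    set.seed(900 + s)
    g <- rep(1:3, each = 50)
    med <- log(2)
    t <- c(rexp(50), rexp(50) + 2 * med, rexp(50) + 4 * med)
    uncensored_location_test(t, rep(1, 150), g)$kw$p_value < 0.05
  })
  expect_gte(mean(rej), 0.9)

  # a group with zero events is dropped with a warning
  t <- c(rexp(10), rexp(10), rexp(10))
  e <- c(rep(1, 10), rep(0, 10), rep(1, 10))
  expect_warning(res <- uncensored_location_test(t, e, rep(1:3, each = 10)),
                 "dropped")
})

test_that("events_only_curve is the ECDF complement on the event subset", {
  n <- 10
  eo <- events_only_curve(1:n, rep(1, n))
  expect_equal(eo$surv, (n - seq_len(n)) / n)

  set.seed(68)
  inst <- random_surv_instance(40)
  if (sum(inst$event) == 0) inst$event[1] <- 1
  eo <- events_only_curve(inst$time, inst$event)
  sub_km <- km_estimate(inst$time[inst$event == 1], rep(1, sum(inst$event)))
  expect_equal(eo, sub_km)

  expect_error(events_only_curve(c(1, 2), c(0, 0)), "no events")
})
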