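# Survival machinery: product-limit estimation, k-group log-rank,
# Kruskal-Wallis/pairwise-Wilcoxon on uncensored times, events-only curves.

check_surv_input <- function(time, event) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  assert_that(length(time) == length(event) && length(time) >= 1,
              "time and event must be equal-length, non-empty")
  assert_that(!anyNA(time) && !anyNA(event), "missing times/events not allowed")
  assert_that(all(time >= 0) && all(is.finite(time)),
              "times must be finite and non-negative")
  assert_that(all(event %in% c(0, 1)), "events must be 0 (censored) or 1 (event)")
  list(time = time, event = event)
}

#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator of the survival function under right
#' censoring. Subjects censored at an event time are counted at risk at that
#' time (deaths precede censorings at ties).
#'
#' @param time Non-negative follow-up times.
#' @param event 1 = event, 0 = censored.
#' @return A data frame of class `survival_curve` with one row per distinct
#'   time: `time`, `n_risk`, `n_event`, `n_censor`, `surv` (non-increasing,
#'   starting from 1 before the first event).
#' @export
km_estimate <- function(time, event) {
  d <- check_surv_input(time, event)
  ut <- sort(unique(d$time))
  f <- match(d$time, ut)
  n_event <- tabulate(f[d$event == 1], nbins = length(ut))
  n_censor <- tabulate(f[d$event == 0], nbins = length(ut))
  n_risk <- rev(cumsum(rev(tabulate(f, nbins = length(ut)))))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = ut, n_risk = as.integer(n_risk),
                    n_event = as.integer(n_event),
                    n_censor = as.integer(n_censor), surv = surv)
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("survival_curve: %d distinct times, %d events, final S = %.3f\n",
              nrow(x), sum(x$n_event), x$surv[nrow(x)]))
  invisible(x)
}

#' Survival probability at given times
#'
#' Step-function evaluation of a [km_estimate()] curve (right-continuous).
#'
#' @param curve A `survival_curve`.
#' @param times Times at which to evaluate.
#' @return Numeric vector of survival probabilities.
#' @export
km_surv_at <- function(curve, times) {
  idx <- findInterval(times, curve$time)
  ifelse(idx == 0, 1, curve$surv[pmax(idx, 1)])
}

#' Restricted mean survival time
#'
#' Area under the Kaplan-Meier curve up to `tau`.
#'
#' @param curve A `survival_curve`.
#' @param tau Upper integration limit.
#' @return Restricted mean survival time.
#' @export
km_rmst <- function(curve, tau) {
  ts <- c(0, curve$time[curve$time < tau], tau)
  s <- c(1, km_surv_at(curve, curve$time[curve$time < tau]))
  sum(s * diff(ts))
}

# Per-group at-risk and event counts at the distinct event times.
logrank_counts <- function(time, event, group) {
  dt <- sort(unique(time[event == 1]))
  k <- nlevels(group)
  nrisk <- matrix(0, length(dt), k)
  devt <- matrix(0, length(dt), k)
  for (j in seq_len(k)) {
    tg <- sort(time[group == levels(group)[j]])
    nrisk[, j] <- length(tg) - findInterval(dt, tg, left.open = TRUE)
    te <- time[group == levels(group)[j] & event == 1]
    if (length(te)) devt[, j] <- tabulate(match(te, dt), nbins = length(dt))
  }
  list(dt = dt, nrisk = nrisk, devt = devt)
}

#' k-sample log-rank test
#'
#' Compares k survival curves via observed-versus-expected event counts at
#' each distinct event time. For k = 2 the chi-square statistic is
#' `(O1 - E1)^2 / V` with the exact hypergeometric variance `V`; for k > 2 it
#' is the conventional `sum_g (O_g - E_g)^2 / E_g` approximation, both on
#' k - 1 degrees of freedom.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param group Group label per subject (>= 2 non-empty groups).
#' @return A [test_result()]; no events at all gives statistic 0, p 1,
#'   flagged degenerate.
#' @export
logrank_test <- function(time, event, group) {
  d <- check_surv_input(time, event)
  group <- droplevels(factor(group))
  assert_that(length(group) == length(d$time), "group must match time/event length")
  k <- nlevels(group)
  assert_that(k >= 2, "need at least 2 non-empty groups")
  if (sum(d$event) == 0) {
    return(test_result(0, 1, "two-sided", df = k - 1L,
                       method = "log-rank", degenerate = TRUE))
  }
  cc <- logrank_counts(d$time, d$event, group)
  n <- rowSums(cc$nrisk)
  dd <- rowSums(cc$devt)
  E <- cc$nrisk * (dd / n)
  O <- colSums(cc$devt)
  Eg <- colSums(E)
  if (k == 2) {
    ok <- n > 1
    v <- sum(dd[ok] * (cc$nrisk[ok, 1] / n[ok]) *
               (1 - cc$nrisk[ok, 1] / n[ok]) * (n[ok] - dd[ok]) / (n[ok] - 1))
    if (v <= 0) {
      return(test_result(0, 1, "two-sided", df = 1L,
                         method = "log-rank", degenerate = TRUE))
    }
    stat <- (O[1] - Eg[1])^2 / v
  } else {
    term <- (O - Eg)^2 / Eg
    term[Eg == 0] <- 0
    stat <- sum(term)
  }
  test_result(stat, stats::pchisq(stat, df = k - 1L, lower.tail = FALSE),
              "two-sided", df = k - 1L, method = "log-rank")
}

#' Pairwise log-rank tests between all group pairs
#'
#' @param time,event Follow-up data.
#' @param group Group label per subject.
#' @param adjust P-value adjustment method for the set of pairwise tests
#'   (`"none"` default; any [stats::p.adjust()] method).
#' @return Data frame with `group1`, `group2`, `statistic`, `p_value`.
#' @export
logrank_pairwise <- function(time, event, group, adjust = "none") {
  group <- droplevels(factor(group))
  lv <- levels(group)
  assert_that(length(lv) >= 2, "need at least 2 groups")
  pairs <- utils::combn(lv, 2)
  res <- apply(pairs, 2, function(pr) {
    sel <- group %in% pr
    tr <- logrank_test(time[sel], event[sel], droplevels(group[sel]))
    c(statistic = tr$statistic, p_value = tr$p_value)
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    statistic = res["statistic", ],
                    p_value = stats::p.adjust(res["p_value", ], method = adjust),
                    stringsAsFactors = FALSE)
  attr(out, "adjust") <- adjust
  out
}

#' Location comparison of uncensored survival times
#'
#' Restricts to subjects with an observed event, runs a Kruskal-Wallis test
#' across groups, and — only when its p-value falls below `kw_alpha` — runs
#' pairwise Wilcoxon rank sum tests between all group pairs (the gatekeeping
#' procedure). Groups without any event are dropped with a warning.
#'
#' @param time,event Follow-up data.
#' @param group Group labels.
#' @param kw_alpha Gate for the pairwise stage (default 0.05).
#' @param adjust Adjustment for the pairwise Wilcoxon p-values (`"holm"`
#'   default, `"none"` to disable; the source analysis does not state one).
#' @return List with `kw` (a [test_result()]) and `pairwise` (data frame,
#'   empty when the gate is not passed).
#' @export
uncensored_location_test <- function(time, event, group, kw_alpha = 0.05,
                                     adjust = c("holm", "none")) {
  adjust <- match.arg(adjust)
  d <- check_surv_input(time, event)
  group <- droplevels(factor(group))
  keep <- d$event == 1
  tab <- table(group[keep])
  empty <- names(tab)[tab == 0]
  if (length(empty)) {
    warning(sprintf("group(s) without events dropped: %s",
                    paste(empty, collapse = ", ")))
  }
  glv <- names(tab)[tab > 0]
  assert_that(length(glv) >= 2, "need >= 2 groups with uncensored observations")
  times_by_group <- split(d$time[keep], droplevels(factor(group[keep], levels = glv)))
  kw <- kruskal_wallis(times_by_group)
  pairwise <- data.frame(group1 = character(), group2 = character(),
                         statistic = numeric(), p_value = numeric(),
                         stringsAsFactors = FALSE)
  if (kw$p_value < kw_alpha) {
    prs <- utils::combn(glv, 2)
    stat <- p <- numeric(ncol(prs))
    for (i in seq_len(ncol(prs))) {
      wt <- wilcoxon_rank_sum(times_by_group[[prs[1, i]]],
                              times_by_group[[prs[2, i]]])
      stat[i] <- wt$statistic
      p[i] <- wt$p_value
    }
    pairwise <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                           statistic = stat,
                           p_value = stats::p.adjust(p, method = adjust),
                           stringsAsFactors = FALSE)
  }
  list(kw = kw, pairwise = pairwise)
}

#' Events-only survival curve
#'
#' Descriptive curve over the subjects who experienced the event: filters to
#' `event == 1` and applies the product-limit estimator, which on all-event
#' input equals one minus the empirical CDF of the event times. This
#' conditions on the outcome and is *not* an estimate of the survival
#' function; it is provided for the events-only display convention.
#'
#' @param time,event Follow-up data (>= 1 event required).
#' @return A `survival_curve` over the event subset.
#' @export
events_only_curve <- function(time, event) {
  d <- check_surv_input(time, event)
  sel <- d$event == 1
  if (!any(sel)) stop("no events: events-only curve undefined", call. = FALSE)
  km_estimate(d$time[sel], d$event[sel])
}
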