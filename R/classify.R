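# Per-sample signature classification: thresholded counting of signature
# genes, Fisher exact comparison against the cohort average, and the four-way
# RA/ERK stratification.

#' Classification parameters
#'
#' Tunable thresholds of the stratification procedure. Defaults follow the
#' published analysis: a signature gene counts as "lost" at log2 expression
#' -0.5 or under, "gained" at 1 or over (both inclusive, on the same
#' median-normalized log2 scale as the input matrix), the per-sample Fisher
#' test is called positive at p < 0.1, and cohort-level change enrichment
#' uses a 1.5-fold cut.
#'
#' @param low_threshold Log2 value at or below which a gene counts as lost.
#' @param high_threshold Log2 value at or above which a gene counts as gained.
#' @param fisher_alpha Strict p-value cutoff for the per-sample Fisher call.
#' @param fold_change_cut Linear fold cut for cohort-level change enrichment.
#' @return A list of class `classification_params`.
#' @export
classification_params <- function(low_threshold = -0.5, high_threshold = 1,
                                  fisher_alpha = 0.1, fold_change_cut = 1.5) {
  assert_that(low_threshold < high_threshold,
              "low_threshold must be below high_threshold")
  assert_that(fisher_alpha > 0 && fisher_alpha < 1, "fisher_alpha must be in (0,1)")
  assert_that(fold_change_cut > 1, "fold_change_cut must exceed 1")
  structure(list(low_threshold = low_threshold, high_threshold = high_threshold,
                 fisher_alpha = fisher_alpha, fold_change_cut = fold_change_cut),
            class = "classification_params")
}

sig_rows <- function(expr, sig) {
  assert_that(inherits(sig, "gene_signature"), "sig must be a gene_signature")
  present <- sig$genes[sig$genes %in% rownames(expr)]
  missing <- setdiff(sig$genes, present)
  if (!length(present)) {
    stop(sprintf("no signature gene present in the matrix; missing: %s%s",
                 paste(utils::head(missing, 10), collapse = ", "),
                 if (length(missing) > 10) ", ..." else ""), call. = FALSE)
  }
  if (length(missing)) {
    warning(sprintf("%d signature gene(s) absent from the matrix were dropped",
                    length(missing)))
  }
  present
}

#' Count signature genes beyond a threshold in each sample
#'
#' Counts, per sample, the signature genes whose expression is at or below
#' (`"at_or_below"`) or at or above (`"at_or_above"`) the threshold —
#' inclusive comparisons, matching "-0.5 or under" / "1 or over". Missing
#' cells are never counted; a sample with no non-missing signature value gets
#' `NA` (unclassifiable downstream).
#'
#' @param expr Genes x samples log2 matrix with dimnames.
#' @param sig A [gene_signature()]; genes absent from the matrix are dropped
#'   with a warning (error if none remain).
#' @param threshold Log2 threshold.
#' @param mode `"at_or_below"` or `"at_or_above"`.
#' @return Named integer vector of counts with attributes `genes_used`
#'   (effective gene list) and `n_informative` (non-missing signature values
#'   per sample).
#' @export
count_beyond_threshold <- function(expr, sig, threshold,
                                   mode = c("at_or_below", "at_or_above")) {
  mode <- match.arg(mode)
  validate_expression(expr)
  genes <- sig_rows(expr, sig)
  sub <- expr[genes, , drop = FALSE]
  hit <- if (mode == "at_or_below") sub <= threshold else sub >= threshold
  counts <- as.integer(colSums(hit, na.rm = TRUE))
  informative <- colSums(!is.na(sub))
  counts[informative == 0] <- NA_integer_
  names(counts) <- colnames(expr)
  attr(counts, "genes_used") <- genes
  attr(counts, "n_informative") <- informative
  counts
}

#' Call per-sample signature status against the cohort average
#'
#' For each sample with count `k` out of `G` signature genes, tests whether
#' `k` is significantly higher than the cohort average count via a one-sided
#' Fisher exact test on the table `[[k, G-k], [round(mean k), G-round(mean
#' k)]]` (the cohort average treated as a pseudo-sample of the same signature
#' size; nearest-integer rounding, ties to even). A sample is called positive
#' iff p < alpha.
#'
#' @param counts Named integer vector from [count_beyond_threshold()]; `NA`
#'   counts give `NA` calls.
#' @param signature_size Number of signature genes counted against (G > 0).
#' @param alpha Strict positivity cutoff (default 0.1).
#' @return Data frame with columns `sample_id`, `count`, `p_value`,
#'   `positive`; attribute `construction` records the 2x2 convention,
#'   `reference_count` the rounded cohort average.
#' @export
call_sample_status <- function(counts, signature_size, alpha = 0.1) {
  assert_that(signature_size >= 1, "signature_size must be positive")
  assert_that(length(counts) >= 2, "need at least 2 samples")
  ok <- !is.na(counts)
  assert_that(any(ok), "all samples are unclassifiable (no informative counts)")
  assert_that(all(counts[ok] >= 0 & counts[ok] <= signature_size),
              "counts must lie in [0, signature_size]")
  kbar <- mean(counts[ok])
  k0 <- round(kbar)
  p <- rep(NA_real_, length(counts))
  for (i in which(ok)) {
    tb <- matrix(c(counts[i], signature_size - counts[i],
                   k0, signature_size - k0), 2, 2, byrow = TRUE)
    p[i] <- fisher_exact_2x2(tb, "greater")$p_value
  }
  res <- data.frame(
    sample_id = if (is.null(names(counts))) as.character(seq_along(counts))
                else names(counts),
    count = as.integer(counts),
    p_value = p,
    positive = p < alpha,
    stringsAsFactors = FALSE
  )
  attr(res, "construction") <-
    "one-sided greater Fisher on [[k, G-k], [round(mean k), G-round(mean k)]]; positive iff p < alpha"
  attr(res, "reference_count") <- k0
  attr(res, "alpha") <- alpha
  res
}

#' Combine RA and ERK calls into the four-way category
#'
#' @param ra_calls Named character vector with values `"RA-D"` / `"RA-ND"`
#'   (NA allowed for unclassifiable samples).
#' @param erk_calls Named character vector with values `"ERK-I"` / `"ERK-NI"`
#'   over the same sample set.
#' @return Named factor with levels `RA-ND/ERK-NI`, `RA-ND/ERK-I`,
#'   `RA-D/ERK-NI`, `RA-D/ERK-I`.
#' @export
four_way_category <- function(ra_calls, erk_calls) {
  assert_that(!is.null(names(ra_calls)) && !is.null(names(erk_calls)),
              "calls must be named by sample")
  assert_that(setequal(names(ra_calls), names(erk_calls)) &&
                length(ra_calls) == length(erk_calls),
              "RA and ERK calls must cover the same samples")
  erk_calls <- erk_calls[names(ra_calls)]
  assert_that(all(ra_calls %in% c("RA-D", "RA-ND") | is.na(ra_calls)),
              "ra_calls must be 'RA-D' or 'RA-ND'")
  assert_that(all(erk_calls %in% c("ERK-I", "ERK-NI") | is.na(erk_calls)),
              "erk_calls must be 'ERK-I' or 'ERK-NI'")
  lv <- c("RA-ND/ERK-NI", "RA-ND/ERK-I", "RA-D/ERK-NI", "RA-D/ERK-I")
  cat <- factor(paste(ra_calls, erk_calls, sep = "/"), levels = lv)
  cat[is.na(ra_calls) | is.na(erk_calls)] <- NA
  names(cat) <- names(ra_calls)
  cat
}

#' Stratify a cohort by two signatures
#'
#' End-to-end per-sample stratification: counts RA-signature genes at or
#' below the low threshold and ERK-signature genes at or above the high
#' threshold, tests each sample's counts against the cohort averages
#' ([call_sample_status()]), and crosses the RA-D/RA-ND and ERK-I/ERK-NI
#' calls into the four-way category.
#'
#' @param expr Genes x samples log2 matrix (median-normalized scale).
#' @param ra_sig,erk_sig [gene_signature()] objects (RA-dependent and
#'   ERK-dependent upregulated genes).
#' @param params A [classification_params()] list.
#' @return Data frame (class `stratification_result`) with columns
#'   `sample_id`, `count_low`, `p_low`, `ra_call`, `count_high`, `p_high`,
#'   `erk_call`, `category`; attributes carry the construction metadata of
#'   both Fisher calls.
#' @export
classify_samples <- function(expr, ra_sig, erk_sig,
                             params = classification_params()) {
  assert_that(inherits(params, "classification_params"),
              "params must come from classification_params()")
  cl <- count_beyond_threshold(expr, ra_sig, params$low_threshold, "at_or_below")
  ch <- count_beyond_threshold(expr, erk_sig, params$high_threshold, "at_or_above")
  g_ra <- length(attr(cl, "genes_used"))
  g_erk <- length(attr(ch, "genes_used"))
  st_ra <- call_sample_status(cl, g_ra, params$fisher_alpha)
  st_erk <- call_sample_status(ch, g_erk, params$fisher_alpha)
  ra_call <- ifelse(st_ra$positive, "RA-D", "RA-ND")
  erk_call <- ifelse(st_erk$positive, "ERK-I", "ERK-NI")
  names(ra_call) <- names(erk_call) <- colnames(expr)
  category <- four_way_category(ra_call, erk_call)
  res <- data.frame(
    sample_id = colnames(expr),
    count_low = st_ra$count, p_low = st_ra$p_value, ra_call = ra_call,
    count_high = st_erk$count, p_high = st_erk$p_value, erk_call = erk_call,
    category = as.character(category),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(res) <- c("stratification_result", "data.frame")
  attr(res, "params") <- params
  attr(res, "ra_reference_count") <- attr(st_ra, "reference_count")
  attr(res, "erk_reference_count") <- attr(st_erk, "reference_count")
  attr(res, "construction") <- attr(st_ra, "construction")
  res
}

#' Two-way Z-score classification of a cohort
#'
#' Stage 1 keeps the signature genes whose cohort-mean Z-score is positive
#' (the signature must be upregulated in the cohort); stage 2 labels each
#' sample `"high"` iff its mean Z over the retained genes is positive,
#' `"low"` otherwise. Z-scores must be computed against an external reference
#' population: gene-wise standardization of the cohort itself makes every
#' cohort-mean Z zero and triggers the documented error.
#'
#' @param z_matrix Genes x samples matrix of Z-scores.
#' @param sig A [gene_signature()].
#' @return List with `labels` (named character, `"high"`/`"low"`) and
#'   `retained_genes`.
#' @export
zscore_classify <- function(z_matrix, sig) {
  validate_expression(z_matrix, "Z-score matrix")
  genes <- sig_rows(z_matrix, sig)
  sub <- z_matrix[genes, , drop = FALSE]
  gene_mean <- rowMeans(sub, na.rm = TRUE)
  # "> 0" beyond numerical noise, so that gene-wise self-standardization
  # (every cohort mean exactly 0 up to rounding) retains nothing
  retained <- genes[gene_mean > sqrt(.Machine$double.eps)]
  if (!length(retained)) {
    stop("signature not cohort-upregulated: no signature gene has mean Z > 0",
         call. = FALSE)
  }
  score <- colMeans(z_matrix[retained, , drop = FALSE], na.rm = TRUE)
  labels <- ifelse(score > 0, "high", "low")
  names(labels) <- colnames(z_matrix)
  list(labels = labels, retained_genes = retained, sample_mean_z = score)
}

#' Cohort-level change enrichment of a signature
#'
#' Flags each gene as "changed" when the difference of mean log2 expression
#' (cancer minus normal) exceeds `log2(fold_change_cut)` in the required
#' direction, then tests whether changed genes are over-represented in the
#' signature versus the background with a one-sided (greater) Fisher exact
#' test on the signature x changed 2x2 table.
#'
#' @param expr_cancer,expr_normal Genes x samples log2 matrices sharing a
#'   gene universe (intersection used).
#' @param sig A [gene_signature()].
#' @param direction `"down"` (signature expected to lose expression in
#'   cancer) or `"up"`.
#' @param fold_change_cut Linear fold cut (default 1.5).
#' @return List with `percent_changed` (% of signature genes changed),
#'   `background_percent`, `table` (the 2x2), and `test` (a [test_result()]).
#' @export
change_enrichment <- function(expr_cancer, expr_normal, sig,
                              direction = c("down", "up"),
                              fold_change_cut = 1.5) {
  direction <- match.arg(direction)
  validate_expression(expr_cancer, "cancer matrix")
  validate_expression(expr_normal, "normal matrix")
  assert_that(ncol(expr_normal) >= 1, "need at least one normal sample")
  universe <- intersect(rownames(expr_cancer), rownames(expr_normal))
  assert_that(length(universe) >= 2, "matrices share too few genes")
  genes <- sig$genes[sig$genes %in% universe]
  assert_that(length(genes) >= 1, "no signature gene in the shared universe")
  background <- setdiff(universe, genes)
  if (!length(background)) {
    stop("signature exhausts the gene universe: no background genes",
         call. = FALSE)
  }
  delta <- rowMeans(expr_cancer[universe, , drop = FALSE], na.rm = TRUE) -
    rowMeans(expr_normal[universe, , drop = FALSE], na.rm = TRUE)
  cut <- log2(fold_change_cut)
  changed <- if (direction == "down") delta < -cut else delta > cut
  changed[is.na(changed)] <- FALSE
  a <- sum(changed[genes])
  b <- length(genes) - a
  c_ <- sum(changed[background])
  d <- length(background) - c_
  tb <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
               dimnames = list(c("signature", "background"),
                               c("changed", "unchanged")))
  list(
    percent_changed = 100 * a / length(genes),
    background_percent = 100 * c_ / length(background),
    table = tb,
    test = fisher_exact_2x2(tb, "greater")
  )
}

#' Per-sample signature score
#'
#' Unweighted mean expression (or mean Z) over the signature genes present in
#' the matrix, skipping missing cells.
#'
#' @param expr Genes x samples matrix.
#' @param sig A [gene_signature()].
#' @return Data frame with `sample_id`, `score`, `n_genes_used` (non-missing
#'   signature values per sample; score is `NA` when 0).
#' @export
signature_score <- function(expr, sig) {
  validate_expression(expr)
  genes <- sig_rows(expr, sig)
  sub <- expr[genes, , drop = FALSE]
  n_used <- colSums(!is.na(sub))
  score <- colMeans(sub, na.rm = TRUE)
  score[n_used == 0] <- NA_real_
  data.frame(sample_id = colnames(expr), score = as.numeric(score),
             n_genes_used = as.integer(n_used),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare one signature score across bins of another
#'
#' Bins samples by quantiles of score B (tertiles by default) and reports the
#' mean of score A within each bin — the "score of pathway A among patients
#' with low/middle/high pathway B" summary.
#'
#' @param score_a,score_b Data frames from [signature_score()] over the same
#'   samples.
#' @param n_bins Number of quantile bins (default 3).
#' @return Data frame with `bin`, `n`, `mean_score_a`, `mean_score_b`.
#' @export
score_bin_compare <- function(score_a, score_b, n_bins = 3) {
  assert_that(n_bins >= 2, "need at least 2 bins")
  assert_that(setequal(score_a$sample_id, score_b$sample_id),
              "score tables must cover the same samples")
  b <- score_b[match(score_a$sample_id, score_b$sample_id), ]
  ok <- !is.na(score_a$score) & !is.na(b$score)
  qs <- stats::quantile(b$score[ok], probs = seq(0, 1, length.out = n_bins + 1),
                        na.rm = TRUE)
  qs[1] <- -Inf
  qs[length(qs)] <- Inf
  bin <- cut(b$score, breaks = unique(qs), include.lowest = TRUE,
             labels = FALSE)
  out <- data.frame(
    bin = sort(unique(bin[ok])),
    n = as.integer(tapply(ok[ok], bin[ok], length)),
    mean_score_a = as.numeric(tapply(score_a$score[ok], bin[ok], mean)),
    mean_score_b = as.numeric(tapply(b$score[ok], bin[ok], mean)),
    row.names = NULL
  )
  out
}
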