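# Synthetic cohort generator with full planted truth: subtype-structured
# log2 expression, two anti-correlated signatures tied through a shared
# latent factor, and proportional-hazards survival with category-dependent
# hazard ratios and independent uniform censoring.

#' Cohort generator configuration
#'
#' Defaults describe the stated world the downstream tests assume: a cohort
#' of 200 tumors and 1000 genes with two disjoint 50-gene signatures; RA-D
#' samples lose 1.5 log2 units on the RA signature, ERK-I samples gain 1.5
#' on the ERK signature; a standard-normal per-sample latent factor enters
#' the signature genes with loading 0.8 and opposite signs (minus for RA,
#' plus for ERK), producing the inverse correlation between the two scores;
#' i.i.d. Gaussian log2 noise (sd 0.5, typical tumor-cohort residual
#' spread); exponential survival with hazard ratio 2 per adverse call and
#' uniform censoring tuned to roughly 30% censored; relapse-free hazards are
#' 1.5x the survival hazards. Category frequencies follow the published
#' four-way split (103/19/19/18 of 159).
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param sig_size_ra,sig_size_erk Signature sizes (disjoint gene sets).
#' @param category_probs Probabilities of RA-ND/ERK-NI, RA-ND/ERK-I,
#'   RA-D/ERK-NI, RA-D/ERK-I (sum to 1).
#' @param effect_ra Log2 shift of RA-signature genes in RA-D samples
#'   (negative).
#' @param effect_erk Log2 shift of ERK-signature genes in ERK-I samples
#'   (positive).
#' @param anti_corr_loading Loading of the shared standard-normal latent
#'   factor on the signature genes, in \[0, 1\].
#' @param noise_sd Gaussian log2 noise SD.
#' @param baseline_hazard Baseline exponential hazard (1/time unit).
#' @param hr_ra,hr_erk Hazard ratios multiplied in for RA-D and ERK-I.
#' @param censor_max Upper bound of the uniform censoring time.
#' @param seed Integer seed; same seed gives byte-identical output.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 200, n_genes = 1000,
                          sig_size_ra = 50, sig_size_erk = 50,
                          category_probs = c(103, 19, 19, 18) / 159,
                          effect_ra = -1.5, effect_erk = 1.5,
                          anti_corr_loading = 0.8, noise_sd = 0.5,
                          baseline_hazard = 0.015, hr_ra = 2, hr_erk = 2,
                          censor_max = 180, seed = 1) {
  assert_that(n_samples >= 4 && n_genes >= 2, "cohort too small")
  assert_that(sig_size_ra >= 1 && sig_size_erk >= 1 &&
                sig_size_ra + sig_size_erk <= n_genes,
              "signatures must be disjoint and fit in the gene universe")
  assert_that(length(category_probs) == 4 &&
                abs(sum(category_probs) - 1) < 1e-12 &&
                all(category_probs >= 0),
              "category_probs must be 4 non-negative values summing to 1")
  assert_that(anti_corr_loading >= 0 && anti_corr_loading <= 1,
              "anti_corr_loading must be in [0, 1]")
  assert_that(noise_sd >= 0 && baseline_hazard > 0 && censor_max > 0 &&
                hr_ra > 0 && hr_erk > 0, "invalid noise/hazard parameters")
  structure(as.list(environment()), class = "cohort_config")
}

category_levels <- function() {
  c("RA-ND/ERK-NI", "RA-ND/ERK-I", "RA-D/ERK-NI", "RA-D/ERK-I")
}

# Subtype label attached per planted category, purely to exercise
# subtype-stratified reporting.
category_subtype <- function(category) {
  c("RA-ND/ERK-NI" = "LumA", "RA-ND/ERK-I" = "LumB",
    "RA-D/ERK-NI" = "HER2", "RA-D/ERK-I" = "Basal")[category]
}

#' Generate a synthetic tumor cohort with planted truth
#'
#' Expression is gene baseline 0, plus the category effect on the matching
#' signature genes, plus `loading * latent` with sign +1 for ERK genes and
#' -1 for RA genes (latent ~ N(0,1) per sample), plus N(0, noise_sd) noise.
#' Survival times are exponential with hazard `baseline * hr_ra^[RA-D] *
#' hr_erk^[ERK-I]`; relapse-free times use the same construction with
#' hazards scaled by 1.5. Censoring is independent Uniform(0, censor_max)
#' for both endpoints. Fully deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return List with `expression` (genes x samples matrix), `clinical` (data
#'   frame: `sample_id`, `os_time`, `os_event`, `rfs_time`, `rfs_event`,
#'   `subtype`), `ra_signature`, `erk_signature` ([gene_signature()]s), and
#'   `truth` (data frame: planted `category`, `cluster`, `latent`,
#'   `os_hazard`, `rfs_hazard`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  assert_that(inherits(config, "cohort_config"),
              "config must come from cohort_config()")
  cf <- config
  with_local_seed(cf$seed, {
    n <- cf$n_samples
    g <- cf$n_genes
    gene_ids <- sprintf("g%04d", seq_len(g))
    sample_ids <- sprintf("s%03d", seq_len(n))
    ra_genes <- gene_ids[seq_len(cf$sig_size_ra)]
    erk_genes <- gene_ids[cf$sig_size_ra + seq_len(cf$sig_size_erk)]

    category <- sample(category_levels(), n, replace = TRUE,
                       prob = cf$category_probs)
    ra_d <- category %in% c("RA-D/ERK-NI", "RA-D/ERK-I")
    erk_i <- category %in% c("RA-ND/ERK-I", "RA-D/ERK-I")
    latent <- stats::rnorm(n)

    expr <- matrix(stats::rnorm(g * n, sd = cf$noise_sd), g, n,
                   dimnames = list(gene_ids, sample_ids))
    expr[ra_genes, ra_d] <- expr[ra_genes, ra_d] + cf$effect_ra
    expr[erk_genes, erk_i] <- expr[erk_genes, erk_i] + cf$effect_erk
    expr[ra_genes, ] <- expr[ra_genes, ] +
      rep(-cf$anti_corr_loading * latent, each = length(ra_genes))
    expr[erk_genes, ] <- expr[erk_genes, ] +
      rep(cf$anti_corr_loading * latent, each = length(erk_genes))

    os_hazard <- cf$baseline_hazard * cf$hr_ra^ra_d * cf$hr_erk^erk_i
    rfs_hazard <- 1.5 * os_hazard
    os_t <- stats::rexp(n, os_hazard)
    os_c <- stats::runif(n, 0, cf$censor_max)
    rfs_t <- stats::rexp(n, rfs_hazard)
    rfs_c <- stats::runif(n, 0, cf$censor_max)

    clinical <- data.frame(
      sample_id = sample_ids,
      os_time = pmin(os_t, os_c),
      os_event = as.integer(os_t <= os_c),
      rfs_time = pmin(rfs_t, rfs_c),
      rfs_event = as.integer(rfs_t <= rfs_c),
      subtype = unname(category_subtype(category)),
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      sample_id = sample_ids,
      category = category,
      cluster = match(category, category_levels()),
      latent = latent,
      os_hazard = os_hazard,
      rfs_hazard = rfs_hazard,
      stringsAsFactors = FALSE
    )
    list(
      expression = expr,
      clinical = clinical,
      ra_signature = gene_signature("RA_dependent_up", ra_genes, "up",
                                    provenance = list(test = "external",
                                                      planted = TRUE)),
      erk_signature = gene_signature("ERK_dependent_up", erk_genes, "up",
                                     provenance = list(test = "external",
                                                       planted = TRUE)),
      truth = truth,
      config = cf
    )
  })
}

#' Generate a two-group differential-expression experiment
#'
#' Two-group log2 expression with the first `n_de` genes shifted by
#' `log2_effect` in the condition group; i.i.d. Gaussian noise elsewhere.
#' The default noise SD (0.3 log2 units) reflects the tight replicate
#' variability of cultured cell lines rather than tumor heterogeneity.
#'
#' @param n_per_group Samples per group (>= 2).
#' @param n_genes Number of genes.
#' @param n_de Number of planted differential genes (<= n_genes).
#' @param log2_effect Planted shift, in log2 units.
#' @param noise_sd Gaussian noise SD (default 0.3).
#' @param seed Integer seed.
#' @return List with `expression`, `groups` (named vector,
#'   `"control"`/`"condition"`), and `de_genes` (planted set).
#' @export
generate_de_experiment <- function(n_per_group = 5, n_genes = 1000, n_de = 50,
                                   log2_effect = 2, noise_sd = 0.3, seed = 1) {
  assert_that(n_de <= n_genes, "n_de must not exceed n_genes")
  assert_that(n_per_group >= 2, "need at least 2 samples per group")
  with_local_seed(seed, {
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    sample_ids <- sprintf("s%02d", seq_len(2 * n_per_group))
    groups <- rep(c("control", "condition"), each = n_per_group)
    names(groups) <- sample_ids
    expr <- matrix(stats::rnorm(n_genes * 2 * n_per_group, sd = noise_sd),
                   n_genes, 2 * n_per_group,
                   dimnames = list(gene_ids, sample_ids))
    de_genes <- character(0)
    if (n_de > 0) {
      de_genes <- gene_ids[seq_len(n_de)]
      expr[de_genes, groups == "condition"] <-
        expr[de_genes, groups == "condition"] + log2_effect
    }
    list(expression = expr, groups = groups, de_genes = de_genes)
  })
}

#' Generate well-separated Gaussian blobs
#'
#' Planted-cluster data for stability testing: `k` isotropic Gaussian
#' clusters (SD `noise_sd`) with centers `separation * noise_sd` apart along
#' orthogonal axes.
#'
#' @param n_per_cluster Samples per cluster.
#' @param k Number of clusters.
#' @param n_features Feature dimension (>= k).
#' @param separation Center offset in units of `noise_sd` (default 10).
#' @param noise_sd Within-cluster SD.
#' @param seed Integer seed.
#' @return List with `x` (samples x features) and `cluster` (planted labels).
#' @export
generate_blobs <- function(n_per_cluster = 30, k = 3, n_features = 2,
                           separation = 10, noise_sd = 1, seed = 1) {
  assert_that(n_features >= 1 && k >= 1, "invalid dimensions")
  with_local_seed(seed, {
    n <- n_per_cluster * k
    labels <- rep(seq_len(k), each = n_per_cluster)
    centers <- matrix(0, k, n_features)
    for (j in seq_len(k)) {
      centers[j, ((j - 1) %% n_features) + 1] <-
        centers[j, ((j - 1) %% n_features) + 1] +
        separation * noise_sd * ceiling(j / n_features)
    }
    x <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * n_features, sd = noise_sd), n, n_features)
    rownames(x) <- sprintf("s%03d", seq_len(n))
    list(x = x, cluster = labels)
  })
}
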