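# sigstrat

Signature-based tumor stratification and survival analysis.

## What problem this addresses

Bulk tumor cohorts can be stratified by the *activity* of signaling pathways
rather than by mutations: a pathway that is suppressed in a tumor leaves a
footprint of down-shifted target genes, an activated one a footprint of
up-shifted targets. `sigstrat` implements a complete, testable version of one
such analysis for breast cancer: retinoic-acid-receptor (RAR) signaling —
whose target-gene signature tends to be *lost* in tumors — crossed with
MEK/ERK signaling, whose target signature tends to be *gained*. Each tumor is
classified on both axes and the resulting four categories are related to
overall and relapse-free survival. The package is aimed at computational
biologists who want the full pipeline (signature derivation → per-sample
classification → survival and cluster-stability analysis) as reusable,
seedable, unit-tested components rather than a one-off script.

## The core procedure

1. **Signature derivation.** From grouped log2 expression, keep genes with a
   condition-vs-control difference of group means strictly greater than
   `log2(fold)` (e.g. "more than 3-fold") and a one-way ANOVA p-value passing
   a Benjamini–Hochberg FDR cutoff (`derive_signature()`), or filter an
   external differential-expression table (`signature_from_de_table()`).
2. **Per-sample thresholded counting.** For each tumor, count the RA-signature
   genes with log2 expression ≤ −0.5 ("lost") and the ERK-signature genes
   with log2 expression ≥ +1 ("gained"), on a median-normalized scale
   (`count_beyond_threshold()`).
3. **Fisher call against the cohort average.** A sample with count *k* out of
   *G* signature genes is compared with the rounded cohort-average count
   *k̄* via a one-sided Fisher exact test on `[[k, G−k], [k̄, G−k̄]]`; it is
   called RA-D (RA-signature decreased) or ERK-I (ERK-signature increased)
   when p < 0.1 (`call_sample_status()`).
4. **Four-way category and survival.** The two calls cross into
   RA-ND/ERK-NI, RA-ND/ERK-I, RA-D/ERK-NI, RA-D/ERK-I; Kaplan–Meier curves
   per category are compared with a k-group log-rank test
   (`km_estimate()`, `logrank_test()`), with a Kruskal–Wallis → pairwise
   Wilcoxon gatekeeping procedure on uncensored times
   (`uncensored_location_test()`).
5. **Cluster stability.** Patients are k-means-clustered on the standardized
   signature genes; the number of clusters is fixed by bootstrap-Jaccard
   stability (all per-cluster mean Jaccard > 0.85; `choose_k()`).

A fully seeded synthetic cohort generator (`generate_cohort()`) plants
categories, an anti-correlating latent factor shared by the two signatures,
and proportional-hazards survival, so every stage is testable end-to-end
without any external download.

## Worked example

```r
library(sigstrat)

cohort <- generate_cohort(cohort_config(seed = 42))
strat  <- classify_samples(cohort$expression, cohort$ra_signature,
                           cohort$erk_signature)
table(strat$category)
#>   RA-D/ERK-I  RA-D/ERK-NI  RA-ND/ERK-I RA-ND/ERK-NI
#>           44           34            9          113

logrank_test(cohort$clinical$os_time, cohort$clinical$os_event,
             strat$category)
#> log-rank: statistic = 16.5864, p = 0.0008596 (two-sided, df = 3)

ra  <- signature_score(cohort$expression, cohort$ra_signature)
erk <- signature_score(cohort$expression, cohort$erk_signature)
cor(ra$score, erk$score)
#> [1] -0.719

b  <- generate_blobs(seed = 42)          # 3 planted clusters
ck <- choose_k(b$x, 2:6, n_bootstrap = 50, seed = 42)
ck$k_star
#> [1] 3
ck$reports[["3"]]
#> stability_report: k = 3, mean Jaccard = 1.000, 1.000, 1.000 (n_bootstrap = 50) [chosen]
```

The category table shows the four-way stratification of the 200 synthetic
tumors; the log-rank p-value says the four Kaplan–Meier curves differ
(planted hazard ratio 2 per adverse call); the negative score correlation is
the planted inverse RA/ERK coupling; and the stability report selects the
planted number of clusters with perfectly stable bootstrap Jaccard indices.

## Command line

```sh
Rscript inst/cli/sigstrat.R simulate --out-dir sim/ --seed 7
Rscript inst/cli/sigstrat.R classify --expr sim/expression.tsv \
    --ra-sig ra.gmt --erk-sig erk.gmt --out strat.tsv
Rscript inst/cli/sigstrat.R survival --clinical sim/clinical.tsv \
    --strata strat.tsv --endpoint os --out-dir surv/
Rscript inst/cli/sigstrat.R run-all --expr sim/expression.tsv \
    --clinical sim/clinical.tsv --ra-sig ra.gmt --erk-sig erk.gmt \
    --out-dir results/ --seed 7
```

Exit codes: 0 success, 2 validation error, 3 computation error.

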