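# End-to-end pipeline driver: classification -> four-way survival ->
# signature-score correlation -> stability clustering -> cluster-level
# survival, with a JSON run manifest.

#' Pipeline configuration
#'
#' Collects the inputs and parameters of a full stratification run. Inputs
#' may be given as file paths (read at run time) or as in-memory objects.
#'
#' @param expression Path to an expression TSV, or a genes x samples matrix.
#' @param clinical Path to a clinical TSV, or a data frame.
#' @param ra_signature,erk_signature Path to a GMT/gene-list file, or a
#'   [gene_signature()].
#' @param params A [classification_params()].
#' @param endpoints Survival endpoints to analyze (subset of `"os"`, `"rfs"`).
#' @param k_range Candidate cluster numbers for stability selection.
#' @param n_bootstrap Bootstrap resamples for stability.
#' @param out_dir Output directory (created if needed).
#' @param seed Root seed; all stage substreams derive from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, clinical, ra_signature, erk_signature,
                            params = classification_params(),
                            endpoints = c("os", "rfs"), k_range = 2:6,
                            n_bootstrap = 50, out_dir = tempfile("sigstrat_"),
                            seed = 1) {
  assert_that(all(endpoints %in% c("os", "rfs")) && length(endpoints) >= 1,
              "endpoints must be a subset of 'os', 'rfs'")
  structure(as.list(environment()), class = "pipeline_config")
}

load_signature_input <- function(x, default_name) {
  if (inherits(x, "gene_signature")) return(x)
  assert_that(is.character(x) && length(x) == 1, "signature must be a path or gene_signature")
  if (!file.exists(x)) stop("signature file not found: ", x, call. = FALSE)
  if (grepl("\\.gmt$", x, ignore.case = TRUE)) {
    sigs <- read_gmt(x)
    return(sigs[[1]])
  }
  read_gene_list(x, name = default_name)
}

load_pipeline_inputs <- function(config) {
  expr <- if (is.matrix(config$expression)) config$expression else {
    if (!file.exists(config$expression)) {
      stop("expression file not found: ", config$expression, call. = FALSE)
    }
    read_expression(config$expression)
  }
  clinical <- if (is.data.frame(config$clinical)) config$clinical else {
    if (!file.exists(config$clinical)) {
      stop("clinical file not found: ", config$clinical, call. = FALSE)
    }
    read_clinical(config$clinical)
  }
  list(
    expression = expr,
    clinical = clinical,
    ra_signature = load_signature_input(config$ra_signature, "RA_dependent_up"),
    erk_signature = load_signature_input(config$erk_signature, "ERK_dependent_up")
  )
}

run_stage <- function(stage, manifest_env, code) {
  tryCatch(force(code), error = function(e) {
    manifest_env$manifest$failed_stage <- stage
    path <- file.path(manifest_env$out_dir, "manifest.json")
    try(write_manifest(manifest_env$manifest, path), silent = TRUE)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

manifest_hash <- function(manifest) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  core <- manifest[setdiff(names(manifest), c("manifest_hash"))]
  jsonlite::write_json(core, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full stratification pipeline
#'
#' Executes, in order: per-sample classification into the four RA/ERK
#' categories; Kaplan-Meier curves and k-group log-rank per category, for
#' each requested endpoint; RA-vs-ERK signature-score correlation; bootstrap
#' stability selection of the cluster number on the standardized signature
#' genes; and cluster-level survival comparison (log-rank plus the
#' Kruskal-Wallis/pairwise-Wilcoxon location test on uncensored times). One
#' TSV is written per stage plus a JSON manifest carrying the package
#' version, all parameters, the seed, and a config hash; a rerun with the
#' same inputs and seed reproduces the manifest hash. Inputs on disk are
#' never modified.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "pipeline_config"),
              "config must come from pipeline_config()")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  menv <- new.env()
  menv$out_dir <- out_dir
  menv$manifest <- list(
    package = "sigstrat",
    version = as.character(utils::packageVersion("sigstrat")),
    seed = config$seed,
    params = unclass(config$params),
    endpoints = config$endpoints,
    k_range = config$k_range,
    n_bootstrap = config$n_bootstrap,
    classification_construction = paste(
      "one-sided greater Fisher on [[k, G-k], [round(mean k), G-round(mean k)]];",
      "positive iff p < alpha"
    )
  )

  inputs <- run_stage("load_inputs", menv, load_pipeline_inputs(config))
  expr <- inputs$expression
  clinical <- inputs$clinical
  assert_that(setequal(clinical$sample_id, colnames(expr)),
              "clinical table and expression matrix must cover the same samples")
  clinical <- clinical[match(colnames(expr), clinical$sample_id), ]

  strat <- run_stage("classify", menv, {
    s <- classify_samples(expr, inputs$ra_signature, inputs$erk_signature,
                          config$params)
    write_stratification(s, file.path(out_dir, "stratification.tsv"))
    s
  })

  category_tests <- run_stage("category_survival", menv, {
    res <- list()
    for (ep in config$endpoints) {
      tcol <- paste0(ep, "_time")
      ecol <- paste0(ep, "_event")
      ok <- !is.na(strat$category) & !is.na(clinical[[tcol]]) &
        !is.na(clinical[[ecol]])
      grp <- factor(strat$category[ok], levels = category_levels())
      grp <- droplevels(grp)
      lr <- logrank_test(clinical[[tcol]][ok], clinical[[ecol]][ok], grp)
      curves <- lapply(split(seq_len(sum(ok)), grp), function(ix) {
        km_estimate(clinical[[tcol]][ok][ix], clinical[[ecol]][ok][ix])
      })
      curve_tab <- do.call(rbind, lapply(names(curves), function(gname) {
        cbind(endpoint = ep, group = gname, as.data.frame(curves[[gname]]))
      }))
      res[[ep]] <- list(logrank = lr, curves = curves, table = curve_tab)
    }
    all_curves <- do.call(rbind, lapply(res, function(r) r$table))
    utils::write.table(all_curves, file.path(out_dir, "category_km.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tests <- data.frame(
      endpoint = config$endpoints,
      test = "logrank_4way",
      statistic = vapply(res, function(r) r$logrank$statistic, 0),
      df = vapply(res, function(r) as.integer(r$logrank$df), 0L),
      p_value = vapply(res, function(r) r$logrank$p_value, 0)
    )
    utils::write.table(tests, file.path(out_dir, "category_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })

  scores <- run_stage("signature_scores", menv, {
    ra <- signature_score(expr, inputs$ra_signature)
    erk <- signature_score(expr, inputs$erk_signature)
    ok <- !is.na(ra$score) & !is.na(erk$score)
    r <- stats::cor(ra$score[ok], erk$score[ok])
    tab <- data.frame(sample_id = ra$sample_id, ra_score = ra$score,
                      erk_score = erk$score)
    utils::write.table(tab, file.path(out_dir, "signature_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(table = tab, correlation = r)
  })

  stability <- run_stage("stability", menv, {
    feats <- cluster_features(expr, list(inputs$ra_signature,
                                         inputs$erk_signature))
    ck <- choose_k(feats, config$k_range, n_bootstrap = config$n_bootstrap,
                   seed = derive_seed(config$seed, 101))
    rep_tab <- do.call(rbind, lapply(ck$reports, function(r) {
      data.frame(k = r$k, cluster = seq_len(r$k),
                 mean_jaccard = r$per_cluster_mean_jaccard,
                 chosen = r$chosen)
    }))
    utils::write.table(rep_tab, file.path(out_dir, "stability.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ck
  })

  cluster_surv <- run_stage("cluster_survival", menv, {
    chosen <- stability$reports[[as.character(stability$k_star)]]
    cl_labels <- chosen$cluster
    names(cl_labels) <- colnames(expr)
    cl <- cl_labels[clinical$sample_id]
    res <- list()
    for (ep in config$endpoints) {
      tcol <- paste0(ep, "_time")
      ecol <- paste0(ep, "_event")
      ok <- !is.na(cl) & !is.na(clinical[[tcol]]) & !is.na(clinical[[ecol]])
      lr <- logrank_test(clinical[[tcol]][ok], clinical[[ecol]][ok],
                         factor(cl[ok]))
      loc <- suppressWarnings(
        tryCatch(uncensored_location_test(clinical[[tcol]][ok],
                                          clinical[[ecol]][ok],
                                          factor(cl[ok])),
                 error = function(e) NULL))
      res[[ep]] <- list(logrank = lr, location = loc)
    }
    tab <- data.frame(
      endpoint = rep(config$endpoints, each = 2),
      test = rep(c("logrank_clusters", "kruskal_wallis_uncensored"),
                 length(config$endpoints)),
      statistic = unlist(lapply(res, function(r) {
        c(r$logrank$statistic,
          if (is.null(r$location)) NA_real_ else r$location$kw$statistic)
      })),
      p_value = unlist(lapply(res, function(r) {
        c(r$logrank$p_value,
          if (is.null(r$location)) NA_real_ else r$location$kw$p_value)
      }))
    )
    utils::write.table(tab, file.path(out_dir, "cluster_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(assignments = cl_labels, tests = res)
  })

  menv$manifest$score_correlation <- scores$correlation
  menv$manifest$k_star <- stability$k_star
  menv$manifest$k_star_stable <- stability$stable
  menv$manifest$category_counts <- as.list(table(
    factor(strat$category, levels = category_levels())))
  menv$manifest$outputs <- c("stratification.tsv", "category_km.tsv",
                             "category_tests.tsv", "signature_scores.tsv",
                             "stability.tsv", "cluster_tests.tsv")
  menv$manifest$manifest_hash <- manifest_hash(menv$manifest)
  write_manifest(menv$manifest, file.path(out_dir, "manifest.json"))

  invisible(list(
    stratification = strat,
    category_survival = category_tests,
    scores = scores,
    stability = stability,
    cluster_survival = cluster_surv,
    manifest = menv$manifest,
    out_dir = out_dir
  ))
}
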