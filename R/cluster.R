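# k-means grouping of patients and bootstrap-Jaccard cluster stability, used
# to fix the number of expression clusters.

#' Lloyd k-means clustering
#'
#' Plain Lloyd iterations to convergence (maximum centroid shift below `tol`
#' or `max_iter` sweeps), best of `n_init` random restarts by within-cluster
#' sum of squares. An empty cluster arising during iteration is re-seeded at
#' the point farthest from its assigned centroid. Deterministic given `seed`.
#'
#' @param x Samples x features numeric matrix (finite values).
#' @param k Number of clusters (1 <= k <= nrow(x)).
#' @param n_init Number of random restarts (default 10).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @param max_iter,tol Convergence controls.
#' @return List of class `kmeans_fit`: `cluster` (1..k per sample), `centers`
#'   (k x features), `wcss`, `iterations`.
#' @export
kmeans_cluster <- function(x, k, n_init = 10, seed = NULL,
                           max_iter = 300, tol = 1e-8) {
  x <- as.matrix(x)
  assert_that(is.numeric(x) && all(is.finite(x)), "x must be finite numeric")
  n <- nrow(x)
  assert_that(k >= 1 && k <= n, "k must lie in [1, n_samples]")
  with_local_seed(seed, {
    best <- NULL
    for (init in seq_len(n_init)) {
      fit <- lloyd_once(x, k, max_iter, tol)
      if (is.null(best) || fit$wcss < best$wcss) best <- fit
    }
    class(best) <- "kmeans_fit"
    best
  })
}

lloyd_once <- function(x, k, max_iter, tol) {
  n <- nrow(x)
  centers <- x[sample.int(n, k), , drop = FALSE]
  xx <- rowSums(x^2)
  prev_wcss <- Inf
  assign <- rep(1L, n)
  for (it in seq_len(max_iter)) {
    d2 <- outer(xx, rowSums(centers^2), "+") - 2 * x %*% t(centers)
    assign <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters at the point farthest from its current centroid;
    # each point may be moved at most once (degenerate data can tie at
    # distance 0, which would otherwise ping-pong a single point forever)
    reseeded <- FALSE
    locked <- rep(FALSE, n)
    repeat {
      sizes <- tabulate(assign, nbins = k)
      empty <- which(sizes == 0)
      if (!length(empty) || all(locked)) break
      reseeded <- TRUE
      dmin <- d2[cbind(seq_len(n), assign)]
      dmin[locked] <- -Inf
      far <- which.max(dmin)
      locked[far] <- TRUE
      assign[far] <- empty[1]
    }
    cnts <- tabulate(assign, nbins = k)
    present <- which(cnts > 0)
    new_centers <- centers
    new_centers[present, ] <- rowsum(x, assign) / cnts[present]
    wcss <- sum((x - new_centers[assign, , drop = FALSE])^2)
    # Lloyd monotonicity: WCSS may not increase except when a centroid was
    # re-seeded to rescue an empty cluster (numerical slack only)
    if (!reseeded && wcss > prev_wcss * (1 + 1e-8) + 1e-12) {
      stop("internal error: WCSS increased during Lloyd iteration")
    }
    shift <- max(rowSums((new_centers - centers)^2))
    centers <- new_centers
    prev_wcss <- wcss
    if (shift < tol) break
  }
  list(cluster = assign, centers = centers, wcss = wcss, iterations = it)
}

# Multiset Jaccard similarity of two logical membership vectors over the same
# index multiset (resampled duplicates counted once per occurrence).
jaccard_sim <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Bootstrap-Jaccard cluster stability at a fixed k
#'
#' Clusters the full data at `k`, then for each bootstrap resample of the
#' samples (with replacement) re-clusters at the same `k` and records, for
#' each original cluster, the Jaccard similarity to its best-matching
#' bootstrap cluster over the resampled sample multiset (duplicates
#' counted). An original cluster absent from a resample scores 0 for that
#' draw. Reports per-original-cluster means over resamples.
#'
#' @param x Samples x features matrix.
#' @param k Number of clusters.
#' @param n_bootstrap Number of resamples (>= 20; default 100).
#' @param seed Integer seed (required for reproducibility).
#' @param n_init Restarts per k-means run.
#' @return List of class `stability_report`: `k`, `per_cluster_mean_jaccard`,
#'   `n_bootstrap`, `seed`, `chosen` (filled by [choose_k()]), plus the
#'   original `cluster` vector.
#' @export
bootstrap_jaccard <- function(x, k, n_bootstrap = 100, seed = 1, n_init = 5) {
  x <- as.matrix(x)
  assert_that(n_bootstrap >= 20, "n_bootstrap must be at least 20")
  n <- nrow(x)
  orig <- kmeans_cluster(x, k, n_init = n_init, seed = derive_seed(seed, 0))
  jac <- matrix(0, n_bootstrap, k)
  with_local_seed(derive_seed(seed, 1), {
    for (b in seq_len(n_bootstrap)) {
      idx <- sample.int(n, n, replace = TRUE)
      bfit <- lloyd_best(x[idx, , drop = FALSE], k, n_init)
      o <- orig$cluster[idx]
      for (j in seq_len(k)) {
        aj <- o == j
        if (!any(aj)) {
          jac[b, j] <- 0
          next
        }
        jac[b, j] <- max(vapply(seq_len(k), function(l) {
          jaccard_sim(aj, bfit$cluster == l)
        }, 0))
      }
    }
  })
  structure(list(k = k, per_cluster_mean_jaccard = colMeans(jac),
                 n_bootstrap = n_bootstrap, seed = seed, chosen = NA,
                 cluster = orig$cluster, centers = orig$centers),
            class = "stability_report")
}

# n_init restarts drawing from the current RNG stream (no local re-seeding,
# so the bootstrap loop stays a single reproducible stream).
lloyd_best <- function(x, k, n_init, max_iter = 300, tol = 1e-8) {
  best <- NULL
  for (i in seq_len(n_init)) {
    fit <- lloyd_once(x, k, max_iter, tol)
    if (is.null(best) || fit$wcss < best$wcss) best <- fit
  }
  best
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability_report: k = %d, mean Jaccard = %s (n_bootstrap = %d)%s\n",
              x$k, paste(sprintf("%.3f", x$per_cluster_mean_jaccard),
                         collapse = ", "),
              x$n_bootstrap,
              if (isTRUE(x$chosen)) " [chosen]" else ""))
  invisible(x)
}

#' Choose the number of clusters by bootstrap stability
#'
#' Runs [bootstrap_jaccard()] for every k in `k_range` and selects the
#' largest k whose clusters are all stable (minimum per-cluster mean Jaccard
#' strictly above `jaccard_hi`, default 0.85). When no k qualifies, the k
#' maximizing the minimum Jaccard is returned with `stable = FALSE`.
#'
#' @param x Samples x features matrix.
#' @param k_range Integer vector of candidate k (within \[2, n-1\]).
#' @param jaccard_hi Stability cutoff (default 0.85).
#' @param n_bootstrap Resamples per k.
#' @param seed Integer seed.
#' @param n_init Restarts per k-means run.
#' @return List with `k_star`, `stable` (logical), and `reports` (one
#'   `stability_report` per k, with `chosen` filled in).
#' @export
choose_k <- function(x, k_range, jaccard_hi = 0.85, n_bootstrap = 100,
                     seed = 1, n_init = 5) {
  x <- as.matrix(x)
  k_range <- sort(unique(as.integer(k_range)))
  assert_that(length(k_range) >= 1, "k_range must be non-empty")
  assert_that(all(k_range >= 2 & k_range <= nrow(x) - 1),
              "k_range must lie within [2, n_samples - 1]")
  reports <- lapply(k_range, function(k) {
    bootstrap_jaccard(x, k, n_bootstrap = n_bootstrap,
                      seed = derive_seed(seed, k), n_init = n_init)
  })
  names(reports) <- as.character(k_range)
  min_jac <- vapply(reports, function(r) min(r$per_cluster_mean_jaccard), 0)
  qualifies <- min_jac > jaccard_hi
  if (any(qualifies)) {
    k_star <- max(k_range[qualifies])
    stable <- TRUE
  } else {
    k_star <- k_range[which.max(min_jac)]
    stable <- FALSE
  }
  for (i in seq_along(reports)) {
    reports[[i]]$chosen <- k_range[i] == k_star
  }
  list(k_star = k_star, stable = stable, reports = reports)
}

#' Standardize genes and assemble a clustering feature matrix
#'
#' Builds the samples x features matrix used for patient clustering: the
#' union of the signature gene rows, each gene standardized to zero mean and
#' unit variance across samples (constant genes dropped).
#'
#' @param expr Genes x samples matrix.
#' @param sigs List of [gene_signature()] objects.
#' @return Samples x genes matrix of standardized expression.
#' @export
cluster_features <- function(expr, sigs) {
  validate_expression(expr)
  genes <- unique(unlist(lapply(sigs, function(s) s$genes)))
  genes <- genes[genes %in% rownames(expr)]
  assert_that(length(genes) >= 1, "no signature gene present in the matrix")
  sub <- expr[genes, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  keep <- is.finite(sds) & sds > 0
  assert_that(any(keep), "all candidate features are constant")
  z <- (sub[keep, , drop = FALSE] - rowMeans(sub[keep, , drop = FALSE])) /
    sds[keep]
  t(z)
}
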