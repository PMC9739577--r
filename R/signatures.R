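# Directed gene signatures and their derivation from expression data.

#' Construct a gene signature
#'
#' A named, directed set of gene IDs with derivation metadata. Direction
#' records whether the signature genes were up- or downregulated in the
#' condition of interest.
#'
#' @param name Signature name.
#' @param genes Character vector of gene IDs (duplicates collapsed with a
#'   warning).
#' @param direction `"up"` or `"down"`.
#' @param provenance Named list of derivation metadata (fold threshold, alpha,
#'   test used, ...).
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes, direction = c("up", "down"),
                           provenance = list()) {
  direction <- match.arg(direction)
  assert_that(is.character(name) && length(name) == 1 && nzchar(name),
              "name must be a non-empty string")
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    warning(sprintf("signature '%s': duplicate genes collapsed", name))
    genes <- unique(genes)
  }
  if (!is.null(provenance$fold_threshold)) {
    assert_that(provenance$fold_threshold > 1, "fold_threshold must exceed 1")
  }
  structure(list(name = name, genes = genes, direction = direction,
                 provenance = provenance),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s' (%s): %d genes\n",
              x$name, x$direction, length(x$genes)))
  if (length(x$genes)) {
    shown <- utils::head(x$genes, 6)
    cat("  ", paste(shown, collapse = ", "),
        if (length(x$genes) > 6) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$genes)

resolve_groups <- function(expr, groups) {
  if (!is.null(names(groups))) {
    assert_that(setequal(names(groups), colnames(expr)),
                "group labels must cover exactly the samples of the matrix")
    groups <- groups[colnames(expr)]
  } else {
    assert_that(length(groups) == ncol(expr),
                "unnamed group labels must match the number of samples")
  }
  factor(as.character(groups))
}

#' Derive an up/downregulated gene signature from grouped expression data
#'
#' Selects genes whose condition-vs-control difference of group means on the
#' log2 scale strictly exceeds `log2(fold_threshold)` ("more than N-fold") and
#' whose one-way ANOVA p-value across all groups, Benjamini-Hochberg adjusted
#' if requested, is at most `alpha`. Genes missing in more than
#' `max_missing` of the samples of any group are excluded before testing (a
#' stand-in for background-level probe filtering; see the methods vignette).
#'
#' @param expr Numeric genes x samples log2 expression matrix with dimnames.
#' @param groups Group label per sample; a named vector (names = sample IDs)
#'   covering exactly the columns of `expr`, or an unnamed vector in column
#'   order. Every group needs >= 2 samples.
#' @param condition Label of the condition of interest.
#' @param control Label of the control group; defaults to the only other
#'   group when exactly two are present.
#' @param fold_threshold Linear fold-change cutoff (> 1); strict.
#' @param alpha Significance cutoff; non-strict (p <= alpha).
#' @param adjust `"BH"` (default) or `"none"`.
#' @param direction `"up"` selects condition > control, `"down"` the reverse.
#' @param max_missing Per-group missingness fraction above which a gene is
#'   excluded (default 0.5).
#' @param name Signature name; a default is built from the labels.
#' @return A [gene_signature()]; empty (with a warning) when nothing passes.
#' @export
derive_signature <- function(expr, groups, condition, control = NULL,
                             fold_threshold = 3, alpha = 0.05,
                             adjust = c("BH", "none"),
                             direction = c("up", "down"),
                             max_missing = 0.5, name = NULL) {
  adjust <- match.arg(adjust)
  direction <- match.arg(direction)
  validate_expression(expr)
  assert_that(fold_threshold > 1, "fold_threshold must exceed 1")
  assert_that(alpha > 0 && alpha <= 1, "alpha must be in (0, 1]")
  fg <- resolve_groups(expr, groups)
  lv <- levels(fg)
  assert_that(condition %in% lv, sprintf("condition '%s' not among groups", condition))
  if (is.null(control)) {
    assert_that(length(lv) == 2,
                "control must be given when there are more than two groups")
    control <- setdiff(lv, condition)
  }
  assert_that(control %in% lv && control != condition, "invalid control group")
  group_idx <- split(seq_len(ncol(expr)), fg)
  assert_that(all(lengths(group_idx) >= 2), "every group needs at least 2 samples")

  miss_frac <- vapply(group_idx, function(ix) {
    rowMeans(is.na(expr[, ix, drop = FALSE]))
  }, numeric(nrow(expr)))
  miss_frac <- matrix(miss_frac, nrow = nrow(expr))
  keep <- rowSums(miss_frac > max_missing) == 0

  aov <- row_anova(expr, group_idx)
  lfc <- aov$group_means[, match(condition, names(group_idx))] -
    aov$group_means[, match(control, names(group_idx))]
  p <- aov$p_value
  testable <- keep & !is.na(p)
  p_use <- rep(NA_real_, length(p))
  p_use[testable] <- if (adjust == "BH") bh_adjust(p[testable]) else p[testable]

  cut <- log2(fold_threshold)
  pass_fold <- if (direction == "up") lfc > cut else lfc < -cut
  sel <- testable & pass_fold & !is.na(lfc) & p_use <= alpha
  sel[is.na(sel)] <- FALSE
  genes <- rownames(expr)[sel]
  if (is.null(name)) {
    name <- sprintf("%s_vs_%s_%s", condition, control, direction)
  }
  if (!length(genes)) {
    warning("no genes pass the fold/significance filter; returning an empty signature")
  }
  gene_signature(name, genes, direction, provenance = list(
    fold_threshold = fold_threshold, alpha = alpha,
    test = "anova", adjust = adjust,
    condition = condition, control = control,
    n_tested = sum(testable), n_excluded_missing = sum(!keep)
  ))
}

#' Filter a differential-expression table into a signature
#'
#' Consumes an externally computed differential-expression table (e.g. from a
#' count-based DE tool) and keeps genes with |log2FC| strictly greater than
#' `log2(fold_threshold)`, sign matching `direction`, and p strictly below
#' `alpha`.
#'
#' @param table Data frame with columns `gene_id`, `log2fc` and `pvalue`
#'   (optionally `padj`).
#' @param fold_threshold Linear fold-change cutoff (> 1); strict.
#' @param alpha P-value cutoff; strict (p < alpha).
#' @param direction `"up"` or `"down"`.
#' @param p_col Which p-value column to filter on.
#' @param name Signature name.
#' @return A [gene_signature()].
#' @export
signature_from_de_table <- function(table, fold_threshold = 2, alpha = 0.05,
                                    direction = c("up", "down"),
                                    p_col = c("pvalue", "padj"),
                                    name = "de_signature") {
  direction <- match.arg(direction)
  p_col <- match.arg(p_col)
  assert_that(is.data.frame(table) && nrow(table) >= 1, "table must be non-empty")
  needed <- c("gene_id", "log2fc", p_col)
  assert_that(all(needed %in% names(table)),
              sprintf("table must have columns: %s", paste(needed, collapse = ", ")))
  assert_that(fold_threshold > 1, "fold_threshold must exceed 1")
  bad <- which(is.na(table$gene_id) | !is.finite(table$log2fc) |
                 is.na(table[[p_col]]) | table[[p_col]] < 0 | table[[p_col]] > 1)
  if (length(bad)) {
    stop(sprintf("malformed rows in DE table: %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  assert_that(!anyDuplicated(table$gene_id), "duplicate gene_id rows in DE table")
  cut <- log2(fold_threshold)
  sel <- if (direction == "up") table$log2fc > cut else table$log2fc < -cut
  sel <- sel & table[[p_col]] < alpha
  gene_signature(name, table$gene_id[sel], direction, provenance = list(
    fold_threshold = fold_threshold, alpha = alpha, test = "fold+p",
    p_col = p_col
  ))
}

#' Read gene signatures from a GMT file
#'
#' Standard tab-separated gene-set format: one set per line, fields are name,
#' description, then gene IDs. Duplicate genes within a set are collapsed
#' with a warning.
#'
#' @param path File path.
#' @param direction Direction assigned to all signatures (GMT stores none).
#' @return Named list of [gene_signature()] objects.
#' @export
read_gmt <- function(path, direction = "up") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  sigs <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop("malformed GMT line (need name, description, >= 1 gene): ",
           substr(ln, 1, 40), call. = FALSE)
    }
    gene_signature(f[1], f[-(1:2)], direction,
                   provenance = list(test = "external", description = f[2]))
  })
  names(sigs) <- vapply(sigs, function(s) s$name, "")
  sigs
}

#' Write gene signatures to a GMT file
#'
#' @param sigs A [gene_signature()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sigs, path) {
  if (inherits(sigs, "gene_signature")) sigs <- list(sigs)
  lines <- vapply(sigs, function(s) {
    assert_that(inherits(s, "gene_signature"), "sigs must be gene_signature objects")
    assert_that(length(s$genes) >= 1, "cannot write an empty signature to GMT")
    desc <- s$provenance$description
    if (is.null(desc)) desc <- sprintf("direction=%s", s$direction)
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain one-gene-per-line signature file
#'
#' @param path File path.
#' @param name Signature name (defaults to the file name).
#' @param direction Assigned direction.
#' @return A [gene_signature()].
#' @export
read_gene_list <- function(path, name = NULL, direction = "up") {
  genes <- trimws(readLines(path, warn = FALSE))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("empty gene list file: ", path, call. = FALSE)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  gene_signature(name, genes, direction, provenance = list(test = "external"))
}

#' Write a signature as a plain gene list
#'
#' @param sig A [gene_signature()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(sig, path) {
  assert_that(inherits(sig, "gene_signature"), "sig must be a gene_signature")
  writeLines(sig$genes, path)
  invisible(path)
}
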