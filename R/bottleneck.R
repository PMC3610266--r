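#' mRNA concentration among the top-expressed genes
#'
#' Sorts genes by normalized expression at one timepoint and reports the
#' share of total mRNA contributed by the top fraction `q` of genes, plus
#' the Gini coefficient of the expression distribution (Lorenz-curve form).
#'
#' @param expr An `expression_matrix`.
#' @param timepoint Timepoint (hours).
#' @param q Top fraction of genes, in (0, 1); `ceiling(q * n)` genes are
#'   taken.
#' @return List with `timepoint`, `q`, `n`, `share` and `gini`.
#' @export
expression_concentration <- function(expr, timepoint, q = 0.01) {
  stopifnot(q > 0, q <= 1)
  v <- expr_values_at(expr, timepoint)
  if (all(v == 0)) stop("all-zero expression at timepoint ", timepoint)
  n <- length(v)
  vs <- sort(v, decreasing = TRUE)
  k <- ceiling(q * n)
  share <- sum(vs[seq_len(k)]) / sum(vs)
  asc <- sort(v)
  gini <- sum((2 * seq_len(n) - n - 1) * asc) / (n * sum(asc))
  list(timepoint = timepoint, q = q, n = n, share = share, gini = gini)
}

#' Fold suppression of a gene category at the switch
#'
#' `fold = (summed counts of the category at a pre timepoint) / (same at
#' tp_at)`; values above 1 indicate suppression at `tp_at`. The raw-count
#' route sees genome-wide (bottleneck) depletion through the realized
#' library yield; the normalized route only sees composition changes. Both
#' are reported, along with the per-pre-timepoint maximum ("up to" folds).
#'
#' @param expr An `expression_matrix`.
#' @param gene_ids Genes in the category.
#' @param tp_pre One or more pre-switch timepoints.
#' @param tp_at The suppressed timepoint.
#' @return List with `per_pre` (data.frame: tp_pre, fold_raw, fold_norm),
#'   `max_fold_raw`, `max_fold_norm`, `infinite` flag.
#' @export
category_suppression <- function(expr, gene_ids, tp_pre, tp_at) {
  gene_ids <- intersect(gene_ids, rownames(expr$values))
  if (length(gene_ids) == 0L) stop("empty category")
  at_raw <- sum(expr$counts[gene_ids, library_column(expr$libraries, tp_at)])
  at_norm <- sum(expr_values_at(expr, tp_at)[gene_ids])
  per <- do.call(rbind, lapply(tp_pre, function(tp) {
    pre_raw <- sum(expr$counts[gene_ids, library_column(expr$libraries, tp)])
    pre_norm <- sum(expr_values_at(expr, tp)[gene_ids])
    data.frame(tp_pre = tp,
               fold_raw = if (at_raw > 0) pre_raw / at_raw else Inf,
               fold_norm = if (at_norm > 0) pre_norm / at_norm else Inf)
  }))
  list(per_pre = per, max_fold_raw = max(per$fold_raw),
       max_fold_norm = max(per$fold_norm),
       infinite = any(!is.finite(c(per$fold_raw, per$fold_norm))))
}

#' Paired induction test for a flagged gene set
#'
#' Paired t-test on `log2(normalized expression + c)` between a pre-switch
#' and the switch timepoint over a flagged gene set (e.g. ribonucleases).
#' Zero-variance paired differences are reported with a `degenerate` flag
#' rather than a numeric p-value.
#'
#' @param expr An `expression_matrix`.
#' @param gene_ids Flagged genes (need >= 2 present in the matrix).
#' @param tp_pre,tp_switch Timepoints compared (hours).
#' @param alternative `"two.sided"` (default, conservative), `"greater"`
#'   for the one-sided induction direction.
#' @param pseudocount Added before log2.
#' @return List with `n`, `log2fold` (per gene), `median_fold`, `n_induced`,
#'   `t`, `p` and `degenerate`.
#' @export
induction_test <- function(expr, gene_ids, tp_pre, tp_switch,
                           alternative = "two.sided", pseudocount = 0.5) {
  gene_ids <- intersect(gene_ids, rownames(expr$values))
  if (length(gene_ids) < 2L) stop("need >= 2 flagged genes with expression")
  x <- log2(expr_values_at(expr, tp_pre)[gene_ids] + pseudocount)
  y <- log2(expr_values_at(expr, tp_switch)[gene_ids] + pseudocount)
  diffs <- y - x
  res <- list(n = length(gene_ids), log2fold = diffs,
              median_fold = 2^stats::median(diffs),
              n_induced = sum(diffs > 0))
  if (stats::sd(diffs) < 1e-12) {
    res$t <- NA_real_; res$p <- NA_real_; res$degenerate <- TRUE
  } else {
    tt <- stats::t.test(y, x, paired = TRUE, alternative = alternative)
    res$t <- unname(tt$statistic); res$p <- tt$p.value
    res$degenerate <- FALSE
  }
  res
}
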