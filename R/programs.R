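#' Upper-quartile normalized RPKM expression matrix
#'
#' Values are reads per kilobase per million aligned reads (RPKM, library
#' size = realized total counts after rRNA masking), then scaled between
#' libraries by each library's upper quartile of nonzero values divided by
#' the geometric mean of those quartiles. rRNA-flagged genes are removed
#' before any quantity is computed.
#'
#' @param counts A [count_table()] of long-library counts.
#' @param genes Gene annotation (supplies lengths and the rRNA mask).
#' @return An object of class `expression_matrix`: `values` (normalized),
#'   `counts` (raw, rRNA-masked), `libraries` (with `lib_size` and
#'   `size_factor`) and `gene_length`.
#' @export
normalize_expression <- function(counts, genes) {
  m <- counts$counts
  gi <- match(rownames(m), genes$gene_id)
  if (anyNA(gi)) stop("count table contains genes absent from the annotation")
  keep <- !genes$rRNA[gi]
  m <- m[keep, , drop = FALSE]
  len <- genes$length[gi][keep]
  lib_size <- colSums(m)
  if (any(lib_size == 0)) {
    stop("library with all-zero counts: ",
         paste(colnames(m)[lib_size == 0], collapse = ", "))
  }
  rpkm <- sweep(m / (len / 1000), 2, lib_size / 1e6, "/")
  uq <- apply(rpkm, 2, function(v) stats::quantile(v[v > 0], 0.75, names = FALSE))
  size_factor <- uq / exp(mean(log(uq)))
  values <- sweep(rpkm, 2, size_factor, "/")
  libs <- counts$libraries
  libs$lib_size <- lib_size
  libs$size_factor <- size_factor
  structure(list(values = values, counts = m, libraries = libs,
                 gene_length = stats::setNames(len, rownames(m))),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d libraries (UQ-RPKM)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Normalized expression at one timepoint
#'
#' @param expr An `expression_matrix`.
#' @param timepoint Sampling time (hours).
#' @param kind Library kind to match (default `"long"` when present).
#' @return Named numeric vector over genes.
#' @export
expr_values_at <- function(expr, timepoint, kind = NULL) {
  if (is.null(kind) && "long" %in% expr$libraries$kind) kind <- "long"
  j <- library_column(expr$libraries, timepoint, kind)
  expr$values[, j]
}

#' Prominently expressed genes (analysis universe)
#'
#' Genes ranked by their maximum normalized expression across the time
#' course; the top half (ceiling at odd counts) is returned. Boundary ties
#' are broken by lexicographic gene id, making the set deterministic.
#'
#' @param expr An `expression_matrix`.
#' @return Character vector of gene ids, in rank order.
#' @export
prominent_genes <- function(expr) {
  if (nrow(expr$values) == 0L) stop("empty expression matrix")
  maxv <- apply(expr$values, 1, max)
  ids <- rownames(expr$values)
  o <- order(-maxv, ids)
  ids[o][seq_len(ceiling(length(ids) / 2))]
}

#' Per-gene switch fold changes and the changed fraction
#'
#' `log2FC = log2((post + c)/(pre + c))` with pseudocount `c` (default 0.5
#' RPKM); the changed fraction is the proportion of universe genes (default
#' the prominent set) whose absolute fold change exceeds `fc_threshold`.
#'
#' @param expr An `expression_matrix`.
#' @param pre_tp,post_tp The two timepoints compared (hours; must differ).
#' @param fc_threshold Fold-change threshold (linear scale, default 2).
#' @param pseudocount Pseudocount in RPKM units.
#' @param universe Gene ids over which the changed fraction is computed.
#' @return List with `log2fc` (named, all genes), `changed` (logical) and
#'   `changed_fraction`.
#' @export
switch_fold_changes <- function(expr, pre_tp, post_tp, fc_threshold = 2,
                                pseudocount = 0.5,
                                universe = prominent_genes(expr)) {
  if (identical(pre_tp, post_tp)) stop("pre_tp and post_tp must differ")
  v_pre <- expr_values_at(expr, pre_tp)
  v_post <- expr_values_at(expr, post_tp)
  l2fc <- log2((v_post + pseudocount) / (v_pre + pseudocount))
  changed <- abs(l2fc) > log2(fc_threshold)
  list(log2fc = l2fc, changed = changed,
       changed_fraction = mean(changed[universe]))
}

#' Phase-program clustering of expression profiles
#'
#' Profiles (log2 of normalized expression plus pseudocount) are centered
#' and scaled per gene; the distance is 1 - Pearson correlation and the
#' agglomeration is complete linkage. The tree is cut into `k` clusters and
#' each cluster's phase is the phase of its centroid's argmax timepoint:
#' pre-switch timepoints map to `exponential`, the switch to `transitional`,
#' post-switch to `stationary`. Constant (zero-variance) profiles are
#' excluded with a warning.
#'
#' @param expr An `expression_matrix`.
#' @param switch_tp The switch timepoint (hours).
#' @param gene_ids Genes to cluster (default: the prominent set).
#' @param k Number of clusters (default 3).
#' @param pseudocount Added before log2.
#' @return List with `assignments` (gene_id, cluster, phase,
#'   peak_timepoint), `centroids`, `tree` (hclust), `excluded`.
#' @export
cluster_phases <- function(expr, switch_tp, gene_ids = prominent_genes(expr),
                           k = 3, pseudocount = 0.5) {
  if (length(gene_ids) < 2L) stop("need at least two genes to cluster")
  X <- log2(expr$values[gene_ids, , drop = FALSE] + pseudocount)
  sds <- apply(X, 1, stats::sd)
  excluded <- gene_ids[sds == 0]
  if (length(excluded)) {
    warning("excluding constant profiles: ", paste(excluded, collapse = ", "))
    X <- X[sds > 0, , drop = FALSE]
  }
  Z <- t(scale(t(X)))
  d <- stats::as.dist(1 - stats::cor(t(Z)))
  tree <- stats::hclust(d, method = "complete")
  cl <- stats::cutree(tree, k = min(k, nrow(Z)))
  cent <- rowsum(Z, cl) / as.vector(table(cl))
  tps <- expr$libraries$timepoint
  peak_j <- apply(cent, 1, which.max)
  phase_of <- function(tp) {
    if (tp < switch_tp) "exponential" else if (tp == switch_tp) "transitional"
    else "stationary"
  }
  cl_phase <- vapply(tps[peak_j], phase_of, character(1))
  assignments <- data.frame(gene_id = rownames(Z), cluster = unname(cl),
                            phase = cl_phase[cl],
                            peak_timepoint = tps[peak_j][cl],
                            stringsAsFactors = FALSE)
  list(assignments = assignments, centroids = cent, tree = tree,
       excluded = excluded)
}

## one-sided Fisher exact p for the 2x2 table [a b; c d]
## (hypergeometric tail: a successes drawn in a+b from a+c of a+b+c+d)
fisher_p <- function(a, b, c, d, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (alternative == "greater") {
    stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  } else {
    stats::phyper(a, a + c, b + d, a + b, lower.tail = TRUE)
  }
}

#' Functional-category enrichment of a gene set
#'
#' One-sided Fisher exact test of each category against the universe, with
#' Benjamini-Hochberg adjustment across the tested categories.
#'
#' @param gene_set Character vector of gene ids (must be a subset of
#'   `universe`).
#' @param universe Character vector of all gene ids under consideration.
#' @param categories Named character vector mapping gene_id -> category
#'   label (genes absent from it are ignored), or a gene annotation
#'   data.frame with `gene_id` and `category`.
#' @param alternative `"greater"` (enrichment, default) or `"less"`.
#' @return data.frame with the 2x2 counts `a`,`b`,`c`,`d`, `odds_ratio`,
#'   `fold_enrichment`, `p` and BH-adjusted `q` per category.
#' @export
category_enrichment <- function(gene_set, universe, categories,
                                alternative = "greater") {
  if (is.data.frame(categories)) {
    categories <- stats::setNames(categories$category, categories$gene_id)
  }
  if (!all(gene_set %in% universe)) stop("gene_set must be a subset of universe")
  cat_u <- categories[universe]
  absent <- setdiff(unique(categories), unique(cat_u))
  if (length(absent)) {
    warning("categories absent from universe skipped: ",
            paste(absent, collapse = ", "))
  }
  in_set <- universe %in% gene_set
  N <- length(universe)
  res <- do.call(rbind, lapply(sort(unique(cat_u[!is.na(cat_u)])), function(cc) {
    in_cat <- !is.na(cat_u) & cat_u == cc
    a <- sum(in_set & in_cat); b <- sum(in_set & !in_cat)
    c_ <- sum(!in_set & in_cat); d <- sum(!in_set & !in_cat)
    data.frame(category = cc, a = a, b = b, c = c_, d = d,
               odds_ratio = (a * d) / (b * c_),
               fold_enrichment = (a / (a + b)) / ((a + c_) / N),
               p = fisher_p(a, b, c_, d, alternative),
               stringsAsFactors = FALSE)
  }))
  res$q <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}
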