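# Independent brute-force oracles used to validate the analytical paths.

# one-sided (enrichment) Fisher p by explicit hypergeometric tail summation
hyper_tail_oracle <- function(a, b, c, d) {
  n1 <- a + b
  K <- a + c
  N <- a + b + c + d
  ks <- a:min(n1, K)
  sum(choose(K, ks) * choose(N - K, n1 - ks)) / choose(N, n1)
}

# naive O(n^3) agglomerative complete-linkage: returns merge heights and the
# partition (list of sorted member sets) after each merge
complete_linkage_oracle <- function(D) {
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best_h <- Inf; best <- c(0L, 0L)
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        h <- max(D[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[2]]] <- NULL
    partitions[[length(partitions) + 1L]] <- lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# canonical string form of a partition (set of sets) for comparison
partition_key <- function(sets) {
  paste(sort(vapply(sets, function(s) paste(sort(s), collapse = ","),
                    character(1))), collapse = "|")
}

# exhaustive border-permutation oracle: distribution of median fold change
# over all size-k subsets
perm_median_oracle <- function(fc, k, obs) {
  perms <- utils::combn(length(fc), k, function(ix) median(fc[ix]))
  mean(perms >= obs - 1e-12)
}

# minimal expression_matrix for toy inputs
mock_expr <- function(values, timepoints, counts = values, kind = "long") {
  libs <- data.frame(library_id = paste0("lib", seq_along(timepoints)),
                     timepoint = timepoints, kind = kind,
                     stringsAsFactors = FALSE)
  colnames(values) <- libs$library_id
  structure(list(values = values, counts = counts, libraries = libs,
                 gene_length = stats::setNames(rep(1000, nrow(values)),
                                               rownames(values))),
            class = "expression_matrix")
}
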