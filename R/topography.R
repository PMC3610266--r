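#' Fraction of the genome transcribed, and saturation metrics
#'
#' Pools a set of per-base stranded coverage tracks and reports the fraction
#' of positions represented from either strand, the fraction represented
#' ignoring strand, and the fraction of expressed nucleotides represented
#' singly (a saturation indicator).
#'
#' @param tracks List of per-base [coverage_track()]s (pooled by summation).
#' @param min_cov Minimum pooled coverage for a position to count as
#'   transcribed (>= 1).
#' @return List with `either_strand`, `unstranded` and `singleton_fraction`.
#' @export
transcribed_fraction <- function(tracks, min_cov = 1) {
  if (length(tracks) == 0L) stop("empty track set")
  stopifnot(min_cov >= 1)
  plus <- Reduce(`+`, lapply(tracks, `[[`, "plus"))
  minus_list <- lapply(tracks, `[[`, "minus")
  stranded <- !any(vapply(minus_list, is.null, logical(1)))
  minus <- if (stranded) Reduce(`+`, minus_list) else numeric(length(plus))
  total <- plus + minus
  list(either_strand = mean(plus >= min_cov | minus >= min_cov),
       unstranded = mean(total >= min_cov),
       singleton_fraction = if (any(total >= 1)) {
         sum(total == 1) / sum(total >= 1)
       } else NA_real_)
}

#' Binned leading/lagging strand preference
#'
#' Each position is assigned a replichore from its position relative to the
#' replication origin and terminus; leading coverage `L` is plus-strand
#' coverage on replichore 1 and minus-strand coverage on replichore 2, and
#' the preference per bin is `P = (L - G)/(L + G)` with `G` the lagging
#' coverage. Bins with no coverage are reported missing.
#'
#' @param track A stranded per-base [coverage_track()].
#' @param chrom A [chromosome_model()].
#' @param bin_size Bin width in bp (default 10 kb, the macro-region scale).
#' @return List of class `binned_genome_stat` with `values` in `[-1, 1]`.
#' @export
strand_preference <- function(track, chrom, bin_size = 10000) {
  if (!track$stranded) stop("strand_preference requires a stranded track")
  L <- as.integer(chrom$genome_length)
  pos <- seq_len(L) - 1L
  repl1 <- replichore1(pos, chrom)
  lead <- ifelse(repl1, track$plus, track$minus)
  lagg <- ifelse(repl1, track$minus, track$plus)
  bin <- pos %/% bin_size
  ls <- rowsum(lead, bin)[, 1]
  gs <- rowsum(lagg, bin)[, 1]
  p <- ifelse(ls + gs > 0, (ls - gs) / (ls + gs), NA_real_)
  structure(list(bin_size = bin_size, values = unname(p),
                 timepoint = track$timepoint,
                 statistic = "strand_preference"),
            class = "binned_genome_stat")
}

## TRUE for positions on the origin->terminus replichore (clockwise)
replichore1 <- function(pos, chrom) {
  L <- chrom$genome_length
  rel <- (pos - chrom$origin) %% L
  ter <- (chrom$terminus - chrom$origin) %% L
  rel < ter
}

#' Macro-region enrichment across the time course, with switch detection
#'
#' For every timepoint and region, computes the mean normalized expression
#' and the log2 enrichment `E = log2(mean in region / genome-wide mean)`,
#' plus the core-referenced contrast `log2(mean noncore / mean core)`. A
#' macro-region switch is called when the non-core enrichment changes by at
#' least `2 * epsilon` log2 units between the pre- and post-switch
#' timepoints; `switch_sign` is the direction of the non-core change. The
#' core-referenced `noncore_shift` (change of the contrast across the
#' switch) is the estimator of an injected non-core fold change: the
#' genome-mean reference absorbs part of a repression that spans half the
#' genome, the core reference does not.
#'
#' @param x Either an expression matrix (see [normalize_expression()]),
#'   aggregated per region over gene labels, or a numeric matrix of binned
#'   normalized coverage (rows = bins, columns = timepoints).
#' @param ... Method arguments, see below.
#' @return List with `series` (timepoint x region data.frame of `mean_expr`
#'   and `E`), `contrast` (per-timepoint `log2(noncore/core)`),
#'   `noncore_shift`, `switch_detected`, `switch_sign` and `epsilon`.
#' @export
region_enrichment <- function(x, ...) UseMethod("region_enrichment")

#' @rdname region_enrichment
#' @param genes Gene annotation with a `region` column (gene route).
#' @param switch_tp Declared switch timepoint (hours).
#' @param epsilon Detection threshold in log2 units (default 0.2).
#' @export
region_enrichment.expression_matrix <- function(x, genes, switch_tp,
                                                epsilon = 0.2, ...) {
  ids <- rownames(x$values)
  reg <- genes$region[match(ids, genes$gene_id)]
  tps <- x$libraries$timepoint
  series <- do.call(rbind, lapply(seq_along(tps), function(j) {
    v <- x$values[, j]
    region_enrich_one(v, reg, tps[j])
  }))
  finish_region_enrichment(series, switch_tp, epsilon)
}

#' @rdname region_enrichment
#' @param partition A [region_partition()] (bin route).
#' @param bin_size Bin width of the rows of `x`.
#' @param timepoints Timepoints (hours) labelling the columns of `x`.
#' @export
region_enrichment.matrix <- function(x, partition, bin_size, timepoints,
                                     switch_tp, epsilon = 0.2, ...) {
  lab <- region_base_labels(partition)
  bin <- (seq_along(lab) - 1L) %/% bin_size
  ## majority label per bin
  bl <- vapply(split(lab, bin), function(v) {
    names(which.max(table(v)))
  }, character(1))
  stopifnot(length(bl) == nrow(x))
  series <- do.call(rbind, lapply(seq_along(timepoints), function(j) {
    region_enrich_one(x[, j], bl, timepoints[j])
  }))
  finish_region_enrichment(series, switch_tp, epsilon)
}

region_enrich_one <- function(v, labels, tp) {
  labs <- sort(unique(labels))
  means <- vapply(labs, function(l) {
    if (!any(labels == l)) stop("region with zero bins: ", l)
    mean(v[labels == l])
  }, numeric(1))
  gm <- mean(v)
  data.frame(timepoint = tp, region = labs, mean_expr = means,
             E = log2(means / gm), row.names = NULL)
}

finish_region_enrichment <- function(series, switch_tp, epsilon) {
  nc <- series[series$region == "noncore", ]
  co <- series[series$region == "core", ]
  contrast <- data.frame(timepoint = nc$timepoint,
                         log2_nc_vs_core = log2(nc$mean_expr / co$mean_expr))
  before <- nc$timepoint < switch_tp
  after <- nc$timepoint > switch_tp
  dE <- mean(nc$E[after]) - mean(nc$E[before])
  shift <- mean(contrast$log2_nc_vs_core[after]) -
    mean(contrast$log2_nc_vs_core[before])
  list(series = series, contrast = contrast,
       noncore_shift = shift,
       switch_detected = is.finite(dE) && abs(dE) >= 2 * epsilon,
       switch_sign = sign(dE), epsilon = epsilon)
}

#' Transposon induction at the macro-region borders
#'
#' Tests whether transposon-flagged genes within `window` bp of a
#' core/non-core border are specifically induced at the switch. The test
#' statistic is the median log2 fold change (switch vs pre) of the border
#' transposon set; significance is reported both as a one-sided rank-sum
#' p-value against all other genes and as a label-permutation p-value
#' (exhaustive enumeration whenever the number of distinct subsets does not
#' exceed `n_perm`, Monte Carlo otherwise).
#'
#' @param expr An expression matrix (see [normalize_expression()]).
#' @param genes Gene annotation with `transposon` flags.
#' @param partition A [region_partition()] supplying the borders.
#' @param switch_pair Numeric pair `c(pre_timepoint, switch_timepoint)`.
#' @param window Border window in bp (default 5 kb).
#' @param n_perm Number of permutations.
#' @param seed RNG seed for Monte Carlo permutations.
#' @param pseudocount Added to expression before log2.
#' @return List with `fold` (2^median log2FC), `median_log2fc`, `p_mw`,
#'   `p_perm`, `n_target` and `exhaustive`.
#' @export
border_induction <- function(expr, genes, partition, switch_pair,
                             window = 5000, n_perm = 10000, seed = 1,
                             pseudocount = 0.5) {
  v_pre <- expr_values_at(expr, switch_pair[1])
  v_sw <- expr_values_at(expr, switch_pair[2])
  fc <- log2((v_sw + pseudocount) / (v_pre + pseudocount))
  ids <- rownames(expr$values)
  gi <- match(ids, genes$gene_id)
  L <- partition$genome_length
  mid <- circ_midpoint(genes$start[gi], genes$end[gi], L)
  near <- Reduce(`|`, lapply(partition$borders, function(b) {
    circ_dist(mid, b, L) <= window
  }))
  target <- genes$transposon[gi] & near
  k <- sum(target)
  if (k == 0L) {
    stop(sprintf("no transposon-flagged genes within %d bp of a border", window))
  }
  stat <- stats::median(fc[target])
  p_mw <- stats::wilcox.test(fc[target], fc[!target],
                             alternative = "greater", exact = FALSE)$p.value
  n <- length(fc)
  n_comb <- choose(n, k)
  if (is.finite(n_comb) && n_comb <= n_perm) {
    perm <- utils::combn(n, k, function(ix) stats::median(fc[ix]))
    p_perm <- mean(perm >= stat - 1e-12)
    exhaustive <- TRUE
  } else {
    set.seed(seed)
    perm <- replicate(n_perm, stats::median(fc[sample.int(n, k)]))
    p_perm <- (1 + sum(perm >= stat - 1e-12)) / (n_perm + 1)
    exhaustive <- FALSE
  }
  list(fold = 2^stat, median_log2fc = stat, p_mw = p_mw, p_perm = p_perm,
       n_target = k, exhaustive = exhaustive)
}

#' Antisense transcription within gene bodies
#'
#' Pools stranded coverage tracks and reports the fraction of gene-body
#' coverage that is antisense to the annotation, overall and per
#' relative-position decile (5' to 3' in gene orientation).
#'
#' @param tracks List of stranded per-base [coverage_track()]s.
#' @param genes Gene annotation.
#' @param chrom A [chromosome_model()].
#' @return List with `overall` and `positional_profile` (10 deciles).
#' @export
antisense_fraction <- function(tracks, genes, chrom) {
  if (any(!vapply(tracks, `[[`, logical(1), "stranded"))) {
    stop("antisense_fraction requires stranded tracks")
  }
  L <- as.integer(chrom$genome_length)
  plus <- Reduce(`+`, lapply(tracks, `[[`, "plus"))
  minus <- Reduce(`+`, lapply(tracks, `[[`, "minus"))
  sense_d <- numeric(10); anti_d <- numeric(10)
  for (i in seq_len(nrow(genes))) {
    idx <- interval_positions(genes$start[i], genes$end[i], L)
    if (genes$strand[i] == "-") idx <- rev(idx)  # 5' -> 3'
    len <- length(idx)
    dec <- floor(10 * (seq_len(len) - 1) / len) + 1L
    if (genes$strand[i] == "+") {
      s <- plus[idx]; a <- minus[idx]
    } else {
      s <- minus[idx]; a <- plus[idx]
    }
    sense_d <- sense_d + rowsum(s, dec, reorder = TRUE)[, 1]
    anti_d <- anti_d + rowsum(a, dec, reorder = TRUE)[, 1]
  }
  tot <- sense_d + anti_d
  list(overall = sum(anti_d) / sum(tot),
       positional_profile = ifelse(tot > 0, anti_d / tot, 0))
}

#' Intergenic ncRNA candidate intervals
#'
#' Finds maximal runs of intergenic positions (no same-strand gene overlap)
#' whose per-million-normalized coverage reaches `min_expr` in at least one
#' long library. Runs separated by gaps shorter than `merge_gap` are merged;
#' candidates must have length within `[min_len, max_len]`. A candidate is
#' flagged `supported` when fragment libraries cover at least half of its
#' positions on the same strand.
#'
#' @param long_tracks List of stranded per-base [coverage_track()]s.
#' @param frag_tracks Optional list of fragment-library tracks.
#' @param genes Gene annotation.
#' @param chrom A [chromosome_model()].
#' @param min_len,max_len Candidate length bounds in bp.
#' @param min_expr Minimum normalized (reads-per-million per-base) coverage.
#' @param merge_gap Runs separated by gaps shorter than this are merged.
#' @return data.frame of candidates: `start`, `end` (0-based half-open, may
#'   wrap), `strand`, `length`, `mean_expr`, `supported`.
#' @export
intergenic_candidates <- function(long_tracks, frag_tracks = NULL, genes,
                                  chrom, min_len = 50, max_len = 1000,
                                  min_expr = 1, merge_gap = 20) {
  if (min_len > max_len) stop("min_len > max_len")
  L <- as.integer(chrom$genome_length)
  out <- list()
  for (str in c("+", "-")) {
    vec_name <- if (str == "+") "plus" else "minus"
    genic <- logical(L)
    gs <- genes[genes$strand == str, , drop = FALSE]
    for (i in seq_len(nrow(gs))) {
      genic[interval_positions(gs$start[i], gs$end[i], L)] <- TRUE
    }
    norm <- lapply(long_tracks, function(tr) {
      tr[[vec_name]] / tr$library_size * 1e6
    })
    expressed <- Reduce(`|`, lapply(norm, function(v) v >= min_expr))
    mask <- expressed & !genic
    mask <- fill_short_gaps(mask, merge_gap, circular = chrom$circular)
    runs <- circular_runs(mask, circular = chrom$circular)
    if (nrow(runs) == 0L) next
    runs$length <- interval_length(runs$start, runs$end, L)
    runs <- runs[runs$length >= min_len & runs$length <= max_len, ,
                 drop = FALSE]
    if (nrow(runs) == 0L) next
    norm_mean <- Reduce(pmax, norm)  # best library per position
    frag_any <- if (!is.null(frag_tracks)) {
      Reduce(`|`, lapply(frag_tracks, function(tr) tr[[vec_name]] > 0))
    } else NULL
    runs$strand <- str
    runs$mean_expr <- vapply(seq_len(nrow(runs)), function(i) {
      mean(norm_mean[interval_positions(runs$start[i], runs$end[i], L)])
    }, numeric(1))
    runs$supported <- vapply(seq_len(nrow(runs)), function(i) {
      if (is.null(frag_any)) return(FALSE)
      mean(frag_any[interval_positions(runs$start[i], runs$end[i], L)]) >= 0.5
    }, logical(1))
    out[[str]] <- runs
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), length = integer(0),
                      mean_expr = numeric(0), supported = logical(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$start), c("start", "end", "strand", "length",
                          "mean_expr", "supported")]
}

## set interior FALSE runs shorter than gap to TRUE (circular-aware)
fill_short_gaps <- function(mask, gap, circular = TRUE) {
  if (gap <= 1 || !any(mask)) return(mask)
  r <- rle(mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  n_run <- length(r$values)
  for (i in seq_len(n_run)) {
    if (r$values[i]) next
    if (r$lengths[i] >= gap) next
    interior <- i > 1L && i < n_run
    wraps <- circular && (i == 1L || i == n_run) &&
      ((i == 1L && r$values[n_run]) || (i == n_run && r$values[1L]))
    if (interior || wraps) mask[starts[i]:ends[i]] <- TRUE
  }
  mask
}

## TRUE runs as 0-based half-open intervals; joins a run crossing the origin
circular_runs <- function(mask, circular = TRUE) {
  r <- rle(mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  keep <- r$values
  runs <- data.frame(start = starts[keep], end = ends[keep])
  if (circular && nrow(runs) > 1L && mask[1L] && mask[length(mask)]) {
    first <- 1L; last <- nrow(runs)
    runs$start[first] <- runs$start[last]  # wrapped interval (start > end)
    runs <- runs[-last, , drop = FALSE]
  }
  runs
}
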