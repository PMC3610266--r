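#' Strand-specific transcribed-region mask from long libraries
#'
#' Positions whose per-million-normalized coverage reaches `threshold` in at
#' least one long library, per strand.
#'
#' @param tracks List of stranded per-base [coverage_track()]s.
#' @param threshold Normalized coverage threshold (reads-per-million scale).
#' @return List with logical vectors `plus` and `minus`.
#' @export
transcribed_mask <- function(tracks, threshold = 1) {
  if (length(tracks) == 0L) stop("no long-library tracks supplied")
  one <- function(vec_name) {
    Reduce(`|`, lapply(tracks, function(tr) {
      tr[[vec_name]] / tr$library_size * 1e6 >= threshold
    }))
  }
  list(plus = one("plus"), minus = one("minus"))
}

#' Filter degraded-fragment reads
#'
#' Keeps reads whose length lies within `[min_len, max_len]` nt and that lie
#' fully within a transcribed region on the same strand as the matched long
#' libraries (reads aligning antisense to transcribed regions are removed as
#' putative bona-fide small RNAs, not degradation products). The operation
#' is idempotent.
#'
#' @param reads data.frame of reads: `start` (0-based), `length` (nt),
#'   `strand` (`+`/`-`).
#' @param mask A [transcribed_mask()] from the matched long libraries.
#' @param min_len,max_len Fragment size window in nt (defaults 20-50).
#' @param genome_length Chromosome length (for wrap-aware positions).
#' @return The filtered data.frame; attribute `discarded` reports counts
#'   removed by the length and sense rules.
#' @export
filter_fragments <- function(reads, mask, min_len = 20, max_len = 50,
                             genome_length = length(mask$plus)) {
  if (!any(mask$plus) && !any(mask$minus)) stop("no transcribed regions")
  stopifnot(all(reads$length > 0),
            all(reads$start >= 0 & reads$start < genome_length))
  len_ok <- reads$length >= min_len & reads$length <= max_len
  sense_ok <- vapply(seq_len(nrow(reads)), function(i) {
    if (!len_ok[i]) return(FALSE)
    idx <- interval_positions(reads$start[i],
                              (reads$start[i] + reads$length[i]) %% genome_length,
                              genome_length)
    m <- if (reads$strand[i] == "+") mask$plus else mask$minus
    all(m[idx])
  }, logical(1))
  keep <- len_ok & sense_ok
  out <- reads[keep, , drop = FALSE]
  attr(out, "discarded") <- c(length_rule = sum(!len_ok),
                              sense_rule = sum(len_ok & !sense_ok))
  out
}

#' Per-gene degradation index across timepoints
#'
#' `DI = log2((F + c)/N_F) - log2((S + c)/N_S)` with `F`/`S` the full-length
#' and fragment counts, `N` the library sizes and pseudocount `c`. Genes
#' with fewer than `min_full` full-length reads are masked. `relative_DI`
#' is DI centered to the median over unmasked genes at each timepoint, and
#' genes are classed `faster` / `neutral` / `slower` at `relative_DI`
#' thresholds of minus/plus `delta` log2 units (lower DI = faster
#' degradation).
#'
#' @param full Long-library [count_table()].
#' @param frag Fragment-library [count_table()].
#' @param pseudocount Pseudocount `c` (default 0.5).
#' @param min_full Full-length count below which a gene is masked.
#' @param delta Classification threshold in log2 units.
#' @param library_sizes Optional list with numeric vectors `full` and
#'   `frag` named by library id; defaults to the `depth` column of the
#'   library metadata (nominal anchor depths) or, failing that, to column
#'   sums.
#' @return data.frame of class `degradation_table`: one row per gene and
#'   shared timepoint with `full_count`, `fragment_count`, `DI`,
#'   `relative_DI`, `class` and `masked`.
#' @export
degradation_index <- function(full, frag, pseudocount = 0.5, min_full = 10,
                              delta = 1, library_sizes = NULL) {
  if (!setequal(full$genes, frag$genes)) {
    d1 <- setdiff(full$genes, frag$genes); d2 <- setdiff(frag$genes, full$genes)
    stop("mismatched gene sets; only in full: ",
         paste(utils::head(d1, 5), collapse = ","),
         "; only in fragment: ", paste(utils::head(d2, 5), collapse = ","))
  }
  tps <- intersect(full$libraries$timepoint, frag$libraries$timepoint)
  if (length(tps) == 0L) stop("no shared timepoints")
  lib_n <- function(ct, j, which_set) {
    if (!is.null(library_sizes)) {
      return(library_sizes[[which_set]][[ct$libraries$library_id[j]]])
    }
    if (!is.null(ct$libraries$depth)) return(ct$libraries$depth[j])
    sum(ct$counts[, j])
  }
  genes <- full$genes
  out <- do.call(rbind, lapply(tps, function(tp) {
    jf <- library_column(full, tp, "long")
    js <- library_column(frag, tp, "fragment")
    Fc <- full$counts[, jf]
    Sc <- frag$counts[genes, js]
    NF <- lib_n(full, jf, "full"); NS <- lib_n(frag, js, "frag")
    di <- log2((Fc + pseudocount) / NF) - log2((Sc + pseudocount) / NS)
    masked <- Fc < min_full
    di[masked] <- NA_real_
    rel <- di - stats::median(di[!masked])
    cls <- ifelse(is.na(rel), NA_character_,
                  ifelse(rel <= -delta, "faster",
                         ifelse(rel >= delta, "slower", "neutral")))
    data.frame(gene_id = genes, timepoint = tp, full_count = Fc,
               fragment_count = Sc, DI = di, relative_DI = rel,
               class = cls, masked = masked, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("degradation_table", class(out))
  attr(out, "params") <- list(pseudocount = pseudocount, min_full = min_full,
                              delta = delta)
  out
}

#' Genome-wide degradation shift between two timepoints
#'
#' Difference of the unmasked-gene median DI (`tp_b` minus `tp_a`);
#' negative values indicate accelerated degradation at `tp_b`. Only
#' meaningful when library sizes are anchored externally (nominal depths),
#' since per-million normalization cancels any purely global rate change.
#'
#' @param table A [degradation_index()] result.
#' @param tp_a,tp_b Timepoints (hours).
#' @return List with `delta_median_DI`.
#' @export
global_degradation_shift <- function(table, tp_a, tp_b) {
  med <- function(tp) {
    d <- table[table$timepoint == tp & !table$masked, "DI"]
    if (length(d) == 0L) stop("timepoint absent: ", tp)
    stats::median(d)
  }
  list(delta_median_DI = med(tp_b) - med(tp_a))
}

#' Stability enrichment of mRNA classes
#'
#' For each class, the fold is the linear-scale stability ratio
#' `2^(mean relative_DI of class - mean of complement)` (fold > 1 = more
#' stable than the rest of the transcriptome); p-values are two-sided
#' rank-sum tests of relative_DI class vs complement, BH-adjusted across
#' classes.
#'
#' @param table A [degradation_index()] result.
#' @param classes Named character vector gene_id -> class label, or a gene
#'   annotation data.frame (`gene_id`, `category`).
#' @param timepoint Timepoint (hours).
#' @param class_labels Which labels to test (default: all present).
#' @param min_n Minimum unmasked class size; smaller classes are skipped
#'   with a warning.
#' @return data.frame with `class`, `n`, `fold`, `p`, `q`.
#' @export
stability_class_enrichment <- function(table, classes, timepoint,
                                       class_labels = NULL, min_n = 3) {
  if (is.data.frame(classes)) {
    classes <- stats::setNames(classes$category, classes$gene_id)
  }
  tt <- table[table$timepoint == timepoint & !table$masked, , drop = FALSE]
  if (nrow(tt) == 0L) stop("timepoint absent or fully masked: ", timepoint)
  lab <- classes[tt$gene_id]
  if (is.null(class_labels)) class_labels <- sort(unique(lab[!is.na(lab)]))
  rows <- list()
  for (cc in class_labels) {
    inc <- !is.na(lab) & lab == cc
    if (sum(inc) < min_n) {
      warning("class too small, skipped: ", cc)
      next
    }
    x <- tt$relative_DI[inc]; y <- tt$relative_DI[!inc]
    rows[[cc]] <- data.frame(
      class = cc, n = sum(inc), fold = 2^(mean(x) - mean(y)),
      p = stats::wilcox.test(x, y, alternative = "two.sided",
                             exact = FALSE)$p.value,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no class with >= min_n unmasked genes")
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Relative-DI browser track over gene bodies
#'
#' Paints each unmasked gene's body with its relative DI; masked genes are
#' omitted. Records are sorted and must be non-overlapping.
#'
#' @param table A [degradation_index()] result.
#' @param genes Gene annotation.
#' @param timepoint Timepoint (hours).
#' @param path Optional output bedGraph path; when `NULL` the records are
#'   returned as a data.frame.
#' @param chrom_name Chromosome name for bedGraph rows.
#' @return data.frame of records (start, end, value), or the path.
#' @export
degradation_track <- function(table, genes, timepoint, path = NULL,
                              chrom_name = "chr") {
  tt <- table[table$timepoint == timepoint & !table$masked, , drop = FALSE]
  gi <- match(tt$gene_id, genes$gene_id)
  rec <- data.frame(start = genes$start[gi], end = genes$end[gi],
                    value = tt$relative_DI)
  rec <- rec[order(rec$start), , drop = FALSE]
  rownames(rec) <- NULL
  if (is.null(path)) {
    if (nrow(rec) > 1L && any(rec$start[-1] < rec$end[-nrow(rec)])) {
      stop("overlapping gene bodies in degradation track")
    }
    return(rec)
  }
  write_bedgraph_records(rec, path, chrom_name)
}
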