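#' Chromosome model for a (circular) bacterial chromosome
#'
#' Holds the replication geometry used by strand-preference and all circular
#' interval arithmetic. Internal coordinates are 0-based, half-open
#' everywhere; conversion to/from 1-based formats happens only at file
#' boundaries.
#'
#' @param name Chromosome name (as used in GFF3/BED/bedGraph files).
#' @param genome_length Chromosome length in bp.
#' @param circular Is the chromosome circular? Default `TRUE`.
#' @param origin Position of the replication origin (oriC), 0-based.
#' @param terminus Position of the replication terminus. Defaults to the
#'   point diametrically opposite the origin (replichore symmetry is the
#'   standard null when the terminus is not annotated).
#' @return An object of class `chromosome_model`.
#' @export
chromosome_model <- function(name, genome_length, circular = TRUE,
                             origin = 0, terminus = NULL) {
  genome_length <- as.numeric(genome_length)
  stopifnot(length(genome_length) == 1L, genome_length >= 2)
  if (is.null(terminus)) {
    terminus <- (origin + floor(genome_length / 2)) %% genome_length
  }
  if (origin < 0 || origin >= genome_length ||
      terminus < 0 || terminus >= genome_length) {
    stop("origin and terminus must lie in [0, genome_length)")
  }
  if (origin == terminus) stop("origin and terminus must differ")
  structure(list(name = as.character(name), genome_length = genome_length,
                 circular = isTRUE(circular), origin = origin,
                 terminus = terminus),
            class = "chromosome_model")
}

#' @export
print.chromosome_model <- function(x, ...) {
  cat(sprintf("<chromosome_model> %s: %d bp, %s, oriC=%d, ter=%d\n",
              x$name, as.integer(x$genome_length),
              if (x$circular) "circular" else "linear",
              as.integer(x$origin), as.integer(x$terminus)))
  invisible(x)
}

## ---- circular interval arithmetic (0-based half-open; start > end wraps) ----

interval_length <- function(start, end, genome_length) {
  ifelse(end > start, end - start, genome_length - start + end)
}

## 1-based indices into a per-base vector covered by [start, end), wrapping
interval_positions <- function(start, end, genome_length) {
  if (end > start) {
    seq.int(start + 1L, end)
  } else {
    c(seq.int(start + 1L, genome_length), seq_len(end))
  }
}

circ_midpoint <- function(start, end, genome_length) {
  (start + interval_length(start, end, genome_length) / 2) %% genome_length
}

circ_dist <- function(a, b, genome_length) {
  d <- abs(a - b) %% genome_length
  pmin(d, genome_length - d)
}

## ---- region partition ----

#' Core/non-core macro-region partition of the chromosome
#'
#' The partition must tile the chromosome exactly once (sorted, no gaps, no
#' overlaps, covering `[0, genome_length)`). Borders are the positions where
#' the label changes, including position of the first interval when the last
#' and first labels differ on a circular chromosome.
#'
#' @param intervals data.frame with columns `start`, `end` (0-based
#'   half-open) and `label` (`"core"`/`"noncore"`).
#' @param genome_length Chromosome length in bp.
#' @return An object of class `region_partition` with elements `intervals`,
#'   `borders` and `genome_length`.
#' @export
region_partition <- function(intervals, genome_length) {
  stopifnot(is.data.frame(intervals),
            all(c("start", "end", "label") %in% names(intervals)))
  iv <- intervals[order(intervals$start), , drop = FALSE]
  if (nrow(iv) == 0L) stop("empty region partition")
  if (iv$start[1] != 0) {
    stop(sprintf("region partition has a gap before interval (%d,%d,%s)",
                 iv$start[1], iv$end[1], iv$label[1]))
  }
  if (nrow(iv) > 1L) {
    for (i in seq_len(nrow(iv) - 1L)) {
      if (iv$end[i] != iv$start[i + 1L]) {
        stop(sprintf(
          "region partition %s at interval (%d,%d,%s) vs (%d,%d,%s)",
          if (iv$end[i] < iv$start[i + 1L]) "gap" else "overlap",
          iv$start[i], iv$end[i], iv$label[i],
          iv$start[i + 1L], iv$end[i + 1L], iv$label[i + 1L]))
      }
    }
  }
  if (iv$end[nrow(iv)] != genome_length) {
    stop(sprintf("region partition does not reach genome end (%d != %d)",
                 iv$end[nrow(iv)], as.integer(genome_length)))
  }
  lab <- as.character(iv$label)
  prev <- c(lab[length(lab)], lab[-length(lab)])
  borders <- sort(iv$start[lab != prev])
  structure(list(intervals = iv, borders = borders,
                 genome_length = genome_length),
            class = "region_partition")
}

#' Region label at genomic positions
#'
#' @param partition A [region_partition()].
#' @param pos Vector of 0-based positions.
#' @return Character vector of labels.
#' @export
region_at <- function(partition, pos) {
  iv <- partition$intervals
  idx <- findInterval(pos %% partition$genome_length, iv$start)
  as.character(iv$label[idx])
}

## per-base label vector (length genome_length)
region_base_labels <- function(partition) {
  iv <- partition$intervals
  rep(as.character(iv$label), times = iv$end - iv$start)
}

## ---- gene annotation ----

GENE_COLS <- c("gene_id", "start", "end", "strand", "length", "category",
               "region", "transposon", "ribonuclease", "rRNA",
               "transcription_factor")

#' Validate a gene-annotation table
#'
#' Checks intervals against the chromosome model: ids unique, strands in
#' `+`/`-`, `end != start`, coordinates within bounds; origin-spanning genes
#' (`start > end`) are permitted only on a circular chromosome.
#'
#' @param genes data.frame with at least `gene_id`, `start`, `end`, `strand`.
#' @param chrom A [chromosome_model()].
#' @return The validated data.frame (with a computed `length` column),
#'   invisibly usable downstream.
#' @export
validate_genes <- function(genes, chrom) {
  stopifnot(is.data.frame(genes))
  need <- c("gene_id", "start", "end", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicated gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  bad <- !genes$strand %in% c("+", "-")
  if (any(bad)) stop("unknown strand character for gene ", genes$gene_id[which(bad)[1]])
  L <- chrom$genome_length
  out <- genes$start < 0 | genes$start >= L | genes$end < 0 | genes$end > L
  if (any(out)) stop("gene outside chromosome bounds: ", genes$gene_id[which(out)[1]])
  if (any(genes$end == genes$start)) {
    stop("zero-length gene: ", genes$gene_id[which(genes$end == genes$start)[1]])
  }
  wrapped <- genes$end < genes$start
  if (any(wrapped) && !chrom$circular) {
    stop("origin-spanning gene on non-circular chromosome: ",
         genes$gene_id[which(wrapped)[1]])
  }
  genes$length <- interval_length(genes$start, genes$end, L)
  genes
}

## ensure optional columns exist with defaults
complete_gene_columns <- function(genes) {
  if (is.null(genes$category)) genes$category <- "unknown"
  for (fl in c("transposon", "ribonuclease", "rRNA", "transcription_factor")) {
    if (is.null(genes[[fl]])) genes[[fl]] <- FALSE
  }
  if (is.null(genes$region)) genes$region <- NA_character_
  genes
}

## ---- coverage track ----

#' Per-base (or per-bin) strand-specific coverage track
#'
#' @param plus Numeric vector of coverage on the plus strand (one value per
#'   bin; `bin_size = 1` means per-base).
#' @param minus Coverage on the minus strand, or `NULL` for an unstranded
#'   track.
#' @param library_id Library identifier.
#' @param timepoint Sampling time in hours.
#' @param bin_size Bin width in bp.
#' @param library_size Total aligned reads in the library (must be > 0).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(plus, minus = NULL, library_id = "lib",
                           timepoint = NA_real_, bin_size = 1,
                           library_size = NULL) {
  if (any(plus < 0) || (!is.null(minus) && any(minus < 0))) {
    stop("coverage values must be >= 0")
  }
  if (!is.null(minus) && length(minus) != length(plus)) {
    stop("plus and minus vectors differ in length")
  }
  if (is.null(library_size)) {
    library_size <- sum(plus) + if (is.null(minus)) 0 else sum(minus)
  }
  if (library_size <= 0) stop("library_size must be > 0")
  structure(list(library_id = library_id, timepoint = timepoint,
                 stranded = !is.null(minus), plus = plus, minus = minus,
                 bin_size = bin_size, library_size = library_size),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s t=%sh %s, %d bins (bin=%d bp), N=%g\n",
              x$library_id, format(x$timepoint),
              if (x$stranded) "stranded" else "unstranded",
              length(x$plus), as.integer(x$bin_size), x$library_size))
  invisible(x)
}

## ---- count table ----

#' Gene-by-library count table
#'
#' @param counts Non-negative integer matrix, rows = genes, cols = libraries.
#' @param libraries data.frame with one row per column of `counts`:
#'   `library_id`, `timepoint`, `kind` (`"long"` or `"fragment"`), and
#'   optionally `depth` (nominal sequencing depth).
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, libraries) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative count entries")
  stopifnot(is.data.frame(libraries), nrow(libraries) == ncol(counts),
            all(c("library_id", "timepoint", "kind") %in% names(libraries)))
  if (anyDuplicated(rownames(counts))) stop("duplicated gene ids in counts")
  if (anyDuplicated(libraries$library_id)) stop("duplicated library ids")
  colnames(counts) <- libraries$library_id
  structure(list(genes = rownames(counts), libraries = libraries,
                 counts = counts),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d genes x %d libraries (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$libraries$kind), collapse = "+")))
  invisible(x)
}

## column index of the library at a timepoint (and kind)
library_column <- function(ct_or_libs, timepoint, kind = NULL) {
  libs <- if (is.data.frame(ct_or_libs)) ct_or_libs else ct_or_libs$libraries
  hit <- libs$timepoint == timepoint
  if (!is.null(kind)) hit <- hit & libs$kind == kind
  w <- which(hit)
  if (length(w) == 0L) stop("no library at timepoint ", timepoint)
  w[1]
}
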