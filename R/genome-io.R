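#' Read annotation, region partition and functional flags
#'
#' Reads a GFF3 gene annotation (1-based inclusive, converted to the internal
#' 0-based half-open convention), a BED file tiling the chromosome with
#' core/non-core macro-region labels, and a TSV mapping `gene_id` to a
#' functional category and flags. Genes without an explicit region label are
#' assigned by midpoint lookup in the partition.
#'
#' @param gff_path Path to a GFF3 file with gene features (attribute `ID` or
#'   `locus_tag` names the gene).
#' @param region_bed Path to a BED file whose intervals tile the chromosome;
#'   the name field carries the `core`/`noncore` label.
#' @param flags_tsv Optional path to a TSV with columns `gene_id`,
#'   `category`, `flags` (comma-separated subset of
#'   `transposon,ribonuclease,rRNA,transcription_factor`).
#' @param circular Is the chromosome circular? Default `TRUE`.
#' @param origin,terminus Replication origin/terminus (0-based); terminus
#'   defaults to the point opposite the origin.
#' @return A list with elements `chrom` ([chromosome_model()]), `genes`
#'   (validated annotation data.frame) and `partition`
#'   ([region_partition()]).
#' @export
read_annotation <- function(gff_path, region_bed, flags_tsv = NULL,
                            circular = TRUE, origin = 0, terminus = NULL) {
  bed <- rtracklayer::import(region_bed, format = "BED")
  iv <- data.frame(start = GenomicRanges::start(bed) - 1L,
                   end = GenomicRanges::end(bed),
                   label = as.character(bed$name),
                   stringsAsFactors = FALSE)
  gff <- rtracklayer::import(gff_path, format = "gff3")
  ## chromosome length from the ##sequence-region pragma when present,
  ## otherwise from the extent of the region partition
  sl <- sequence_region_length(gff_path)
  genome_length <- if (!is.na(sl)) sl else max(iv$end)
  chrom_name <- as.character(GenomicRanges::seqnames(bed))[1]
  chrom <- chromosome_model(chrom_name, genome_length, circular = circular,
                            origin = origin, terminus = terminus)
  partition <- region_partition(iv, genome_length)

  if (any(gff$type == "gene")) gff <- gff[gff$type == "gene"]
  ids <- if (!is.null(gff$ID) && !all(is.na(gff$ID))) gff$ID else gff$locus_tag
  if (is.null(ids)) stop("GFF3 features carry neither ID nor locus_tag")
  genes <- data.frame(gene_id = as.character(ids),
                      start = GenomicRanges::start(gff) - 1L,
                      end = GenomicRanges::end(gff),
                      strand = as.character(GenomicRanges::strand(gff)),
                      stringsAsFactors = FALSE)
  genes <- complete_gene_columns(genes)
  if (!is.null(flags_tsv)) {
    fl <- utils::read.delim(flags_tsv, stringsAsFactors = FALSE)
    m <- match(genes$gene_id, fl$gene_id)
    if (!is.null(fl$category)) {
      genes$category <- ifelse(is.na(m), genes$category, fl$category[m])
    }
    if (!is.null(fl$flags)) {
      flag_str <- as.character(fl$flags)[m]
      flag_str <- ifelse(is.na(flag_str), "", flag_str)
      for (f in c("transposon", "ribonuclease", "rRNA", "transcription_factor")) {
        genes[[f]] <- vapply(strsplit(flag_str, ","),
                             function(v) f %in% trimws(v), logical(1))
      }
    }
    if (!is.null(fl$region)) {
      genes$region <- ifelse(is.na(m), NA_character_, fl$region[m])
    }
  }
  mid <- circ_midpoint(genes$start, genes$end, genome_length)
  genes$region <- ifelse(is.na(genes$region), region_at(partition, mid),
                         genes$region)
  genes <- validate_genes(genes, chrom)
  list(chrom = chrom, genes = genes, partition = partition)
}

## ##sequence-region <name> <start 1-based> <end> -> chromosome length
sequence_region_length <- function(path) {
  hdr <- readLines(path, n = 100L)
  m <- grep("^##sequence-region", hdr, value = TRUE)
  if (length(m) == 0L) return(NA_real_)
  as.numeric(strsplit(m[1], "[[:space:]]+")[[1]][4])
}

#' Read a bedGraph file into a dense per-base vector
#'
#' bedGraph intervals are 0-based half-open; positions not covered by any
#' record are 0. Overlapping records are rejected (the format forbids them).
#'
#' @param path bedGraph file path.
#' @param chrom A [chromosome_model()] (gives the vector length and bounds).
#' @return Numeric vector of length `genome_length`.
#' @export
read_bedgraph <- function(path, chrom) {
  L <- as.integer(chrom$genome_length)
  v <- numeric(L)
  raw <- readLines(path, warn = FALSE)
  n_data <- sum(!grepl("^(#|track|browser)", raw) & nzchar(raw))
  if (n_data == 0L) return(v)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L) return(v)
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  score <- as.numeric(gr$score)
  o <- order(start0)
  start0 <- start0[o]; end0 <- end0[o]; score <- score[o]
  if (any(score < 0)) stop("negative coverage value in ", path)
  if (any(end0 > L)) {
    if (!chrom$circular) stop("bedGraph interval beyond genome length in ", path)
    stop("bedGraph interval beyond genome length in ", path)
  }
  if (length(start0) > 1L && any(start0[-1] < end0[-length(end0)])) {
    stop("overlapping bedGraph records in ", path)
  }
  for (i in seq_along(start0)) {
    v[(start0[i] + 1L):end0[i]] <- score[i]
  }
  v
}

#' Read one or two bedGraph files into a coverage track
#'
#' @param plus_path bedGraph of plus-strand (or unstranded) coverage.
#' @param minus_path Optional bedGraph of minus-strand coverage; omit for an
#'   unstranded track.
#' @param chrom A [chromosome_model()].
#' @inheritParams coverage_track
#' @return A [coverage_track()].
#' @export
read_coverage <- function(plus_path, minus_path = NULL, chrom,
                          library_id = "lib", timepoint = NA_real_,
                          library_size = NULL) {
  plus <- read_bedgraph(plus_path, chrom)
  minus <- if (is.null(minus_path)) NULL else read_bedgraph(minus_path, chrom)
  coverage_track(plus, minus, library_id = library_id, timepoint = timepoint,
                 bin_size = 1, library_size = library_size)
}

## merge adjacent equal-valued bins; drop NA; rows as 0-based half-open
bedgraph_records <- function(values, bin_size = 1, genome_length = NULL) {
  if (is.null(genome_length)) genome_length <- length(values) * bin_size
  keyed <- ifelse(is.na(values), "NA", format(values, digits = 15))
  r <- rle(keyed)
  ends_bin <- cumsum(r$lengths)
  starts_bin <- ends_bin - r$lengths
  keep <- r$values != "NA"
  start <- starts_bin[keep] * bin_size
  end <- pmin(ends_bin[keep] * bin_size, genome_length)
  idx <- cumsum(r$lengths)[keep] # any bin index inside each run
  val <- values[starts_bin[keep] + 1L]
  data.frame(start = start, end = end, value = val)
}

#' Write a genome track as bedGraph or TSV
#'
#' bedGraph mode merges adjacent equal-valued bins and omits missing values;
#' TSV mode writes `gene_id`/`value` (or `bin`/`value`) with `NA` kept.
#' Floating values are printed with 6 significant digits.
#'
#' @param values Numeric vector; per-bin values (bedGraph) or values named by
#'   gene for TSV mode.
#' @param path Output file path.
#' @param mode `"bedgraph"` or `"tsv"`.
#' @param chrom_name Chromosome name for bedGraph rows.
#' @param bin_size Bin width in bp (1 = per-base).
#' @param genome_length Chromosome length (caps the final bin).
#' @return The path, invisibly.
#' @export
write_track <- function(values, path, mode = c("bedgraph", "tsv"),
                        chrom_name = "chr", bin_size = 1,
                        genome_length = NULL) {
  mode <- match.arg(mode)
  if (any(is.infinite(values))) stop("track values must be finite or NA")
  if (mode == "bedgraph") {
    rec <- bedgraph_records(values, bin_size, genome_length)
    lines <- sprintf("%s\t%d\t%d\t%s", chrom_name,
                     as.integer(rec$start), as.integer(rec$end),
                     sprintf("%.6g", rec$value))
    writeLines(lines, path)
  } else {
    key <- if (!is.null(names(values))) names(values) else seq_along(values) - 1L
    df <- data.frame(gene_id = key,
                     value = ifelse(is.na(values), NA,
                                    signif(as.numeric(values), 6)))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

## write explicit (start,end,value) records (used for gene-body tracks)
write_bedgraph_records <- function(rec, path, chrom_name = "chr") {
  rec <- rec[order(rec$start), , drop = FALSE]
  if (nrow(rec) > 1L && any(rec$start[-1] < rec$end[-nrow(rec)])) {
    stop("overlapping records in bedGraph output")
  }
  lines <- sprintf("%s\t%d\t%d\t%s", chrom_name,
                   as.integer(rec$start), as.integer(rec$end),
                   sprintf("%.6g", rec$value))
  writeLines(lines, path)
  invisible(path)
}

#' Sum coverage over gene bodies into read counts
#'
#' Per-gene count = sum of per-base coverage over the gene interval (sense
#' strand only when `sense_only`), divided by the read length when the input
#' is per-base coverage from fixed-length reads, rounded to the nearest
#' integer. Bases shared by overlapping genes are counted for every
#' overlapping gene. Origin-spanning genes are handled on a circular model.
#'
#' @param track A stranded [coverage_track()] (per-base).
#' @param genes Validated gene annotation data.frame.
#' @param sense_only Count only coverage on the gene's own strand (requires a
#'   stranded track). If `FALSE`, both strands are summed.
#' @param read_length Read length in bp used to convert summed base coverage
#'   to read counts (1 = report base coverage).
#' @return Named integer vector of counts (one per gene).
#' @export
count_reads_in_genes <- function(track, genes, sense_only = TRUE,
                                 read_length = 1) {
  if (sense_only && !track$stranded) {
    stop("sense_only counting requires a stranded coverage track")
  }
  if (track$bin_size != 1) stop("count_reads_in_genes expects per-base coverage")
  L <- length(track$plus)
  n <- nrow(genes)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- interval_positions(genes$start[i], genes$end[i], L)
    if (sense_only) {
      v <- if (genes$strand[i] == "+") track$plus else track$minus
      s <- sum(v[idx])
    } else {
      s <- sum(track$plus[idx]) +
        if (track$stranded) sum(track$minus[idx]) else 0
    }
    out[i] <- round(s / read_length)
  }
  names(out) <- genes$gene_id
  out
}

## ---- writers used by the simulator / pipeline ----

write_annotation_gff3 <- function(genes, chrom, path) {
  if (any(genes$end < genes$start)) {
    stop("GFF3 writer does not support origin-spanning genes")
  }
  hdr <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d", chrom$name,
                   as.integer(chrom$genome_length)))
  attrs <- sprintf("ID=%s", genes$gene_id)
  lines <- sprintf("%s\tswitchtome\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   chrom$name, as.integer(genes$start + 1L),
                   as.integer(genes$end), genes$strand, attrs)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

write_regions_bed <- function(partition, chrom, path) {
  iv <- partition$intervals
  writeLines(sprintf("%s\t%d\t%d\t%s", chrom$name, as.integer(iv$start),
                     as.integer(iv$end), iv$label), path)
  invisible(path)
}

write_flags_tsv <- function(genes, path) {
  flags <- apply(genes[, c("transposon", "ribonuclease", "rRNA",
                           "transcription_factor")], 1L, function(r) {
    paste(c("transposon", "ribonuclease", "rRNA",
            "transcription_factor")[as.logical(r)], collapse = ",")
  })
  df <- data.frame(gene_id = genes$gene_id, category = genes$category,
                   flags = flags, region = genes$region)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_counts_tsv <- function(ct, path) {
  df <- data.frame(gene_id = ct$genes, ct$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_counts_tsv <- function(path, libraries) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  count_table(m, libraries)
}
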