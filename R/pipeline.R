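#' Run the full analysis pipeline
#'
#' Orchestrates topography -> programs -> bottleneck -> degradome over
#' either an in-memory synthetic dataset (when `config` is a
#' [sim_config()]) or on-disk inputs (annotation GFF3, regions BED, flags
#' TSV, count TSVs with a library-metadata TSV). All stage outputs are
#' written as TSV (and bedGraph tracks) into `outdir`, together with a
#' `summary.tsv` of headline statistics and a `manifest.tsv` listing every
#' output with its md5 content hash. Outputs are byte-identical across
#' reruns with the same inputs and seed (no timestamps are written).
#'
#' @param config A [sim_config()] (simulation mode) or a named list of
#'   paths with elements `annotation`, `regions`, `flags`, `counts_long`,
#'   `libraries` and optionally `counts_fragment` (file mode); a path to a
#'   YAML file holding such a list is also accepted.
#' @param outdir Output directory.
#' @param pre_tp,switch_tp Pre-switch and switch timepoints (hours);
#'   defaults are taken from the simulation config in simulation mode and
#'   are required in file mode.
#' @param bin_size Bin size for genome-scale statistics (bp).
#' @param seed Seed for the permutation test.
#' @param coverage Compute coverage-based topography statistics (simulation
#'   mode only; dominates run time on large genomes).
#' @return Invisibly, a list of stage results and the manifest.
#' @export
run_all <- function(config, outdir, pre_tp = NULL, switch_tp = NULL,
                    bin_size = 10000, seed = 1, coverage = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  notices <- character(0)

  if (inherits(config, "sim_config")) {
    truth <- generate_genome(config)
    chrom <- truth$chrom; genes <- truth$genes; partition <- truth$partition
    tc <- generate_timecourse(truth, config, coverage = coverage)
    counts_long <- tc$counts
    tracks <- tc$coverage
    counts_frag <- generate_fragments(truth, config)
    tps <- config$timepoints
    if (is.null(switch_tp)) switch_tp <- tps[config$switch_index]
    if (is.null(pre_tp)) pre_tp <- tps[config$switch_index - 1L]
  } else {
    ann <- read_annotation(config$annotation, config$regions, config$flags)
    chrom <- ann$chrom; genes <- ann$genes; partition <- ann$partition
    libs <- utils::read.delim(config$libraries, stringsAsFactors = FALSE)
    counts_long <- read_counts_tsv(config$counts_long,
                                   libs[libs$kind == "long", ])
    counts_frag <- if (!is.null(config$counts_fragment)) {
      read_counts_tsv(config$counts_fragment, libs[libs$kind == "fragment", ])
    } else NULL
    tracks <- NULL
    if (is.null(switch_tp) || is.null(pre_tp)) {
      stop("file mode requires pre_tp and switch_tp")
    }
  }
  p <- function(f) file.path(outdir, f)
  summary_rows <- list()
  add <- function(stat, value) {
    summary_rows[[length(summary_rows) + 1L]] <<-
      data.frame(statistic = stat, value = signif(value, 6))
  }

  ## ---- programs ----
  expr <- normalize_expression(counts_long, genes)
  prom <- prominent_genes(expr)
  fc <- switch_fold_changes(expr, pre_tp, switch_tp, universe = prom)
  phases <- cluster_phases(expr, switch_tp, gene_ids = prom)
  enr <- category_enrichment(
    phases$assignments$gene_id[phases$assignments$phase == "exponential"],
    prom, genes)
  utils::write.table(data.frame(gene_id = rownames(expr$values),
                                signif(expr$values, 6)),
                     p("expression.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(phases$assignments, p("phases.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(enr[1], signif(enr[-1], 6)), p("enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  add("changed_fraction", fc$changed_fraction)

  ## ---- topography ----
  re <- region_enrichment(expr, genes = genes, switch_tp = switch_tp)
  utils::write.table(cbind(re$series[1:2], signif(re$series[-(1:2)], 6)),
                     p("region_enrichment.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  add("noncore_shift", re$noncore_shift)
  add("switch_detected", as.numeric(re$switch_detected))
  bi <- tryCatch(
    border_induction(expr, genes, partition, c(pre_tp, switch_tp),
                     seed = seed),
    error = function(e) NULL)
  if (!is.null(bi)) {
    add("border_fold", bi$fold)
    add("border_p_perm", bi$p_perm)
  } else {
    notices <- c(notices, "border_induction skipped: no transposons near borders")
  }
  if (!is.null(tracks)) {
    tf <- transcribed_fraction(tracks)
    add("transcribed_either_strand", tf$either_strand)
    add("transcribed_unstranded", tf$unstranded)
    af <- antisense_fraction(tracks, genes, chrom)
    add("antisense_overall", af$overall)
    sp <- strand_preference(tracks[[1]], chrom, bin_size)
    add("median_strand_preference", stats::median(sp$values, na.rm = TRUE))
    write_track(sp$values, p("strand_preference.bedGraph"),
                mode = "bedgraph", chrom_name = chrom$name,
                bin_size = bin_size, genome_length = chrom$genome_length)
  }

  ## ---- bottleneck ----
  conc <- expression_concentration(expr, switch_tp, q = 0.01)
  add("top1pct_share", conc$share)
  add("gini", conc$gini)
  transl <- genes$gene_id[genes$category == "translation" & !genes$rRNA]
  if (length(transl)) {
    sup <- category_suppression(expr, transl,
                                tp_pre = expr$libraries$timepoint[
                                  expr$libraries$timepoint < switch_tp],
                                tp_at = switch_tp)
    add("translation_suppression_fold_raw", sup$max_fold_raw)
  }
  rn <- genes$gene_id[genes$ribonuclease]
  if (length(rn) >= 2) {
    ind <- induction_test(expr, rn, pre_tp, switch_tp)
    add("rnase_n", ind$n)
    add("rnase_n_induced", ind$n_induced)
    add("rnase_p", ind$p)
  }

  ## ---- degradome (optional) ----
  di <- NULL
  if (!is.null(counts_frag)) {
    di <- degradation_index(counts_long, counts_frag)
    utils::write.table(
      data.frame(di[c("gene_id", "timepoint", "full_count",
                      "fragment_count")],
                 DI = signif(di$DI, 6), relative_DI = signif(di$relative_DI, 6),
                 class = di$class, masked = di$masked),
      p("degradation_index.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    se <- stability_class_enrichment(di, genes, switch_tp,
                                     class_labels = intersect(
                                       c("transcription_factor",
                                         "ribosome-related"),
                                       genes$category))
    utils::write.table(cbind(se[1:2], signif(se[-(1:2)], 6)),
                       p("stability_enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    degradation_track(di, genes, switch_tp,
                      path = p("relative_DI.bedGraph"),
                      chrom_name = chrom$name)
    tpf <- sort(unique(di$timepoint))
    if (length(tpf) >= 2) {
      gs <- global_degradation_shift(di, tpf[1], switch_tp)
      add("delta_median_DI", gs$delta_median_DI)
    }
  } else {
    notices <- c(notices, "degradome stage skipped: no fragment counts")
  }

  summary <- do.call(rbind, summary_rows)
  utils::write.table(summary, p("summary.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (length(notices)) {
    writeLines(notices, p("notices.txt"))
    message(paste(notices, collapse = "\n"))
  }
  files <- sort(setdiff(list.files(outdir, recursive = TRUE), "manifest.tsv"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(outdir, files))))
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(summary = summary, manifest = manifest, expr = expr,
                 fold_changes = fc, phases = phases, region = re,
                 degradation = di))
}
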