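#' Configuration for the synthetic time-course generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: a circular chromosome split into core and non-core macro-regions
#' with transposon clusters at the two region borders, seven sampling times
#' spanning a metabolic switch, heavy-tailed (log-normal) gene expression
#' sampled negative-binomially, a global mRNA bottleneck at the switch,
#' ribonuclease induction at the switch, and class-targeted degradation
#' rates feeding matched fragment (degradome) libraries.
#'
#' Randomness is two-level: structural draws (gene placement, categories,
#' programs, per-gene rates) and count-level sampling use independent
#' sub-seeds derived from `seed`, so a fixed structure can be resampled.
#'
#' @param seed Integer master seed.
#' @param genome_length Chromosome length in bp.
#' @param n_genes Number of genes.
#' @param gene_length_mean,gene_length_sd,min_gene_length Gene-length model (bp).
#' @param noncore_fraction Fraction of the chromosome in the non-core region.
#' @param n_border_transposons Transposon-flagged genes clustered at the two
#'   core/non-core borders.
#' @param transposon_window Maximum distance (bp) of a transposon-gene
#'   midpoint from a border.
#' @param timepoints Sampling times in hours.
#' @param switch_index 1-based index of the switch timepoint in `timepoints`.
#' @param leading_bias Probability that a gene lies on the leading strand of
#'   its replichore.
#' @param expression_logmean,expression_logsd Log-normal (natural-log)
#'   parameters of per-gene base expression; the default sd puts the top-1%
#'   mRNA share near 0.25-0.30.
#' @param nb_dispersion Negative-binomial dispersion of long-library counts
#'   (0 = deterministic rounded expectations).
#' @param read_length Read length (bp) used when synthesizing coverage.
#' @param long_depth,fragment_depth Nominal reads per long / fragment library.
#' @param fragment_timepoints Times (hours) at which fragment libraries are
#'   sampled.
#' @param bottleneck_factor Global mRNA scale at the switch timepoint.
#' @param noncore_postswitch_log2fc Log2 fold applied to non-core genes
#'   strictly after the switch timepoint.
#' @param transposon_switch_log2fc,rnase_switch_log2fc Log2 fold applied to
#'   flagged genes at the switch timepoint only.
#' @param program_fractions Named fractions of `pre`/`post`/`constitutive`
#'   program genes (must sum to 1).
#' @param program_floor Expression multiplier of a program gene in its off
#'   phase.
#' @param program_switch_level Multipliers of `pre`/`post` genes at the
#'   switch timepoint itself (graded transition).
#' @param class_degradation_log2 Named map category -> log2 shift of the
#'   degradation index at/after the switch (negative = faster degradation,
#'   i.e. rate multiplier `2^-value`).
#' @param rate_logsd Per-gene log2 sd of continuous degradation-rate
#'   heterogeneity.
#' @param switch_rate_factor Genome-wide degradation-rate multiplier at the
#'   switch timepoint.
#' @param antisense_leak Fraction of each gene's reads deposited antisense,
#'   with a linear weight doubling over the 3' third of the gene body.
#' @param n_ribonucleases_max Cap on ribonuclease-flagged genes (1 gene in 80
#'   up to this cap).
#' @param n_rrna rRNA-flagged genes (masked from expression statistics).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 2e6,
                       n_genes = 2000,
                       gene_length_mean = 900,
                       gene_length_sd = 200,
                       min_gene_length = 150,
                       noncore_fraction = 0.5,
                       n_border_transposons = 20,
                       transposon_window = 5000,
                       timepoints = c(28, 36, 40, 51, 66, 82, 93),
                       switch_index = 4L,
                       leading_bias = 0.75,
                       expression_logmean = 0,
                       expression_logsd = 1.75,
                       nb_dispersion = 0.1,
                       read_length = 50,
                       long_depth = 1e6,
                       fragment_depth = 5e5,
                       fragment_timepoints = c(40, 51, 93),
                       bottleneck_factor = 0.4,
                       noncore_postswitch_log2fc = -2,
                       transposon_switch_log2fc = 3,
                       rnase_switch_log2fc = 2,
                       program_fractions = c(pre = 0.3, post = 0.3,
                                             constitutive = 0.4),
                       program_floor = 0.1,
                       program_switch_level = c(pre = 0.3, post = 0.5),
                       class_degradation_log2 = c("ribosome-related" = -2,
                                                  "transcription_factor" = 1),
                       rate_logsd = 1.5,
                       switch_rate_factor = 2,
                       antisense_leak = 0.03,
                       n_ribonucleases_max = 24,
                       n_rrna = 4) {
  cfg <- as.list(environment())
  stopifnot(cfg$long_depth > 0, cfg$fragment_depth > 0,
            cfg$noncore_fraction > 0, cfg$noncore_fraction < 1,
            cfg$nb_dispersion >= 0,
            cfg$switch_index > 1L, cfg$switch_index < length(cfg$timepoints),
            abs(sum(cfg$program_fractions) - 1) < 1e-8,
            cfg$antisense_leak >= 0, cfg$antisense_leak < 1)
  if (!all(cfg$fragment_timepoints %in% cfg$timepoints)) {
    stop("fragment_timepoints must be a subset of timepoints")
  }
  structure(cfg, class = "sim_config")
}

## independent named sub-seeds (kept below 2^31)
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 99991) %% 2147483629)
}

SIM_CATEGORIES <- c("translation", "ribosome-related", "transcription_factor",
                    "transcription regulation", "carbohydrate metabolism",
                    "energy production", "lipid metabolism",
                    "cell wall biogenesis", "secretion and transport",
                    "signal transduction", "secondary metabolism",
                    "transposase")

## region-biased category frequencies (core enriched for housekeeping,
## non-core for adaptive/secondary functions); transposase assigned by flag
CAT_PROB_CORE <- c(0.14, 0.10, 0.05, 0.06, 0.12, 0.14,
                   0.08, 0.08, 0.07, 0.06, 0.10, 0)
CAT_PROB_NONCORE <- c(0.04, 0.02, 0.06, 0.08, 0.08, 0.06,
                      0.08, 0.06, 0.14, 0.10, 0.28, 0)

## allocate gene lengths (in order) to free arcs proportional to arc length,
## then repair until every arc holds its genes within a 97% packing cap
allocate_to_arcs <- function(lens, arc_len) {
  n <- length(lens)
  k <- split_counts(n, arc_len)
  arc_sum <- function(k) {
    bounds <- cumsum(c(0L, k))
    vapply(seq_along(k), function(a) {
      if (k[a] == 0L) 0 else sum(lens[(bounds[a] + 1L):bounds[a + 1L]])
    }, numeric(1))
  }
  for (iter in seq_len(n)) {
    s <- arc_sum(k)
    over <- which(s > 0.97 * arc_len)
    if (length(over) == 0L) return(k)
    slack <- 0.97 * arc_len - s
    to <- which.max(slack)
    if (slack[to] < max(lens)) {
      stop("genome too small to place n_genes without overlap; increase ",
           "genome_length or reduce n_genes/gene_length_mean")
    }
    k[over[1]] <- k[over[1]] - 1L
    k[to] <- k[to] + 1L
  }
  stop("genome too small to place n_genes without overlap; increase ",
       "genome_length or reduce n_genes/gene_length_mean")
}

## split n items between two arcs proportional to arc length
split_counts <- function(n, weights) {
  k <- floor(n * weights / sum(weights))
  rem <- n - sum(k)
  if (rem > 0) {
    o <- order(n * weights / sum(weights) - k, decreasing = TRUE)
    k[o[seq_len(rem)]] <- k[o[seq_len(rem)]] + 1L
  }
  k
}

#' Generate the synthetic chromosome, annotation and ground truth
#'
#' Places non-overlapping genes, assigns strands with a leading-strand
#' majority per replichore, clusters transposon genes within
#' `transposon_window` of the two core/non-core borders, flags
#' ribonucleases and rRNA genes, draws functional categories with
#' region-biased frequencies, assigns expression programs and per-gene
#' degradation rates, and precomputes the expected expression matrix — the
#' complete ground truth for recovery tests.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_truth` with elements `chrom`, `genes`,
#'   `partition`, `expected` (genes x timepoints expected expression, per-base
#'   intensity scale), `rates` (linear degradation rates, genes x timepoints),
#'   `libscale` (per-timepoint global mRNA scale), `borders` and `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 1L))
  L <- as.integer(config$genome_length)
  n <- config$n_genes

  c1 <- round(L * (1 - config$noncore_fraction))
  partition <- region_partition(
    data.frame(start = c(0, c1), end = c(c1, L),
               label = c("core", "noncore")), L)
  borders <- partition$borders  # c(0, c1)
  chrom <- chromosome_model("chr", L, circular = TRUE, origin = 0)

  ## --- transposon clusters at the two borders ---
  n_bt <- config$n_border_transposons
  k_per <- split_counts(n_bt, c(1, 1))
  gap <- 50L
  t_start <- integer(0); t_end <- integer(0)
  for (bi in seq_along(borders)) {
    k <- k_per[bi]
    if (k == 0L) next
    lens <- pmax(300L, round(stats::rnorm(k, 800, 100)))
    span <- sum(lens) + gap * (k - 1L)
    if (span / 2 + max(lens) > config$transposon_window + max(lens)) {
      # span check below via midpoint assertion
    }
    cur <- (borders[bi] - floor(span / 2)) %% L
    for (j in seq_len(k)) {
      if (cur + lens[j] > L) cur <- 0L  # avoid origin-spanning genes
      t_start <- c(t_start, cur); t_end <- c(t_end, cur + lens[j])
      cur <- cur + lens[j] + gap
    }
  }
  mid_t <- circ_midpoint(t_start, t_end, L)
  d_border <- pmin(circ_dist(mid_t, borders[1], L),
                   circ_dist(mid_t, borders[2], L))
  if (any(d_border > config$transposon_window)) {
    stop("transposon cluster exceeds the border window; reduce ",
         "n_border_transposons or widen transposon_window")
  }

  ## --- remaining genes fill the free arcs between the clusters ---
  occ <- logical(L)
  margin <- 100L
  for (j in seq_along(t_start)) {
    idx <- interval_positions((t_start[j] - margin) %% L,
                              (t_end[j] + margin) %% L, L)
    occ[idx] <- TRUE
  }
  r <- rle(occ)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  free <- data.frame(start = starts[!r$values], end = ends[!r$values])
  n_rest <- n - n_bt
  lens <- pmax(config$min_gene_length,
               round(stats::rnorm(n_rest, config$gene_length_mean,
                                  config$gene_length_sd)))
  arc_len <- free$end - free$start
  k_arc <- allocate_to_arcs(lens, arc_len)
  g_start <- integer(0); g_end <- integer(0)
  taken <- 0L
  for (a in seq_len(nrow(free))) {
    m <- k_arc[a]
    if (m == 0L) next
    la <- lens[(taken + 1L):(taken + m)]; taken <- taken + m
    slack <- arc_len[a] - sum(la)
    cuts <- sort(stats::runif(m)) * slack
    st <- free$start[a] + round(cuts) + cumsum(c(0, la[-m]))
    g_start <- c(g_start, st); g_end <- c(g_end, st + la)
  }

  start <- c(t_start, g_start); end <- c(t_end, g_end)
  transposon <- c(rep(TRUE, length(t_start)), rep(FALSE, length(g_start)))
  o <- order(start)
  start <- start[o]; end <- end[o]; transposon <- transposon[o]

  ## --- strands: leading-strand majority per replichore ---
  mid <- circ_midpoint(start, end, L)
  repl1 <- mid >= chrom$origin & mid < chrom$terminus
  leading <- ifelse(repl1, "+", "-")
  lagging <- ifelse(repl1, "-", "+")
  on_leading <- stats::runif(n) < config$leading_bias
  strand <- ifelse(on_leading, leading, lagging)

  region <- region_at(partition, mid)

  ## --- flags and categories ---
  ribonuclease <- logical(n)
  n_rn <- min(config$n_ribonucleases_max, floor(n / 80))
  pool <- which(!transposon)
  if (n_rn > 0) ribonuclease[sample(pool, n_rn)] <- TRUE
  rRNA <- logical(n)
  pool2 <- which(!transposon & !ribonuclease)
  if (config$n_rrna > 0) rRNA[sample(pool2, config$n_rrna)] <- TRUE

  category <- character(n)
  is_core <- region == "core"
  category[is_core] <- sample(SIM_CATEGORIES, sum(is_core), replace = TRUE,
                              prob = CAT_PROB_CORE)
  category[!is_core] <- sample(SIM_CATEGORIES, sum(!is_core), replace = TRUE,
                               prob = CAT_PROB_NONCORE)
  category[transposon] <- "transposase"
  category[rRNA] <- "translation"
  transcription_factor <- category == "transcription_factor"

  ## --- expression programs (exact configured fractions, permuted) ---
  kf <- split_counts(n, config$program_fractions)
  program <- sample(rep(names(config$program_fractions), times = kf))
  program[rRNA] <- "constitutive"

  base_expr <- stats::rlnorm(n, meanlog = config$expression_logmean,
                             sdlog = config$expression_logsd)
  rate_log2_gene <- stats::rnorm(n, 0, config$rate_logsd)

  genes <- data.frame(
    gene_id = sprintf("SER_%04d", seq_len(n)),
    start = start, end = end, strand = strand,
    category = category, region = region,
    transposon = transposon, ribonuclease = ribonuclease, rRNA = rRNA,
    transcription_factor = transcription_factor,
    program = program, base_expr = base_expr,
    rate_log2 = rate_log2_gene,
    stringsAsFactors = FALSE)
  genes <- validate_genes(genes, chrom)

  truth <- structure(
    list(chrom = chrom, genes = genes, partition = partition,
         borders = borders, config = config),
    class = "synthetic_truth")
  truth <- complete_truth(truth)
  truth
}

## expected expression, degradation rates and library scales (deterministic
## given the structure)
complete_truth <- function(truth) {
  cfg <- truth$config
  g <- truth$genes
  tps <- cfg$timepoints
  s <- cfg$switch_index
  nT <- length(tps)
  n <- nrow(g)

  mult <- matrix(1, n, nT)
  for (j in seq_len(nT)) {
    m <- rep(1, n)
    pre <- g$program == "pre"; post <- g$program == "post"
    if (j < s) {
      m[post] <- cfg$program_floor
    } else if (j == s) {
      m[pre] <- cfg$program_switch_level[["pre"]]
      m[post] <- cfg$program_switch_level[["post"]]
    } else {
      m[pre] <- cfg$program_floor
      m[g$region == "noncore"] <- m[g$region == "noncore"] *
        2^cfg$noncore_postswitch_log2fc
    }
    if (j == s) {
      m[g$transposon] <- m[g$transposon] * 2^cfg$transposon_switch_log2fc
      m[g$ribonuclease] <- m[g$ribonuclease] * 2^cfg$rnase_switch_log2fc
    }
    mult[, j] <- m
  }
  expected <- g$base_expr * mult
  colnames(expected) <- as.character(tps)
  rownames(expected) <- g$gene_id

  rate_log2 <- matrix(rep(g$rate_log2, nT), n, nT)
  for (j in seq_len(nT)) {
    if (j >= s && length(cfg$class_degradation_log2)) {
      hit <- match(g$category, names(cfg$class_degradation_log2))
      shift <- ifelse(is.na(hit), 0, -cfg$class_degradation_log2[hit])
      rate_log2[, j] <- rate_log2[, j] + shift
    }
    if (j == s) rate_log2[, j] <- rate_log2[, j] + log2(cfg$switch_rate_factor)
  }
  rates <- 2^rate_log2
  dimnames(rates) <- dimnames(expected)

  libscale <- rep(1, nT)
  libscale[s] <- cfg$bottleneck_factor

  truth$expected <- expected
  truth$rates <- rates
  truth$libscale <- libscale
  truth
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d genes, %d bp genome, %d timepoints (switch at %gh)\n",
              nrow(x$genes), as.integer(x$chrom$genome_length),
              length(x$config$timepoints),
              x$config$timepoints[x$config$switch_index]))
  invisible(x)
}

#' Sample the long-library time course (counts and coverage)
#'
#' Counts are negative-binomial with mean proportional to expected
#' expression x gene length x nominal depth, scaled by the global bottleneck
#' factor at the switch timepoint (`nb_dispersion = 0` gives rounded
#' expectations). Coverage tracks spread each gene's reads uniformly over
#' its body on the sense strand, with `antisense_leak` of the signal placed
#' on the opposite strand under a linear weight that doubles over the 3'
#' third of the gene.
#'
#' @param truth Output of [generate_genome()].
#' @param config The same [sim_config()].
#' @param coverage Also synthesize per-base coverage tracks? (They dominate
#'   memory/time for large genomes.)
#' @param seed Count-level sub-seed override (defaults to the one derived
#'   from `config$seed`), allowing count resampling over a fixed structure.
#' @return List with `counts` (a long-library [count_table()]), `coverage`
#'   (list of [coverage_track()] per timepoint, or `NULL`) and `truth`.
#' @export
generate_timecourse <- function(truth, config = truth$config,
                                coverage = TRUE, seed = NULL) {
  set.seed(if (is.null(seed)) sub_seed(config$seed, 2L) else seed)
  g <- truth$genes
  tps <- config$timepoints
  w <- truth$expected * g$length
  prop <- sweep(w, 2, colSums(w), "/")
  mu <- sweep(prop * config$long_depth, 2, truth$libscale, "*")
  if (config$nb_dispersion == 0) {
    counts <- round(mu)
  } else {
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = 1 / config$nb_dispersion),
                     nrow(mu), ncol(mu))
  }
  dimnames(counts) <- list(g$gene_id, sprintf("long_%gh", tps))
  libs <- data.frame(library_id = colnames(counts), timepoint = tps,
                     kind = "long", depth = config$long_depth,
                     stringsAsFactors = FALSE)
  ct <- count_table(counts, libs)

  cov <- NULL
  if (coverage) {
    cov <- lapply(seq_along(tps), function(j) {
      synth_coverage(g, counts[, j], truth$chrom, config,
                     library_id = libs$library_id[j], timepoint = tps[j])
    })
    names(cov) <- libs$library_id
  }
  list(counts = ct, coverage = cov, truth = truth)
}

## deterministic expected-coverage synthesis for one library
synth_coverage <- function(genes, counts, chrom, config, library_id = "lib",
                           timepoint = NA_real_) {
  L <- as.integer(chrom$genome_length)
  plus <- numeric(L); minus <- numeric(L)
  leak <- config$antisense_leak
  rl <- config$read_length
  for (i in seq_len(nrow(genes))) {
    if (counts[i] == 0) next
    idx <- interval_positions(genes$start[i], genes$end[i], L)
    len <- length(idx)
    total <- counts[i] * rl
    sense_d <- total * (1 - leak) / len
    if (leak > 0) {
      f <- if (len > 1) (seq_len(len) - 1) / (len - 1) else 0
      wgt <- 1 + pmax(0, f - 2 / 3) * 3      # 5'->3' ramp, doubles over last third
      if (genes$strand[i] == "-") wgt <- rev(wgt)  # genomic orientation
      anti_d <- total * leak * wgt / sum(wgt)
    }
    if (genes$strand[i] == "+") {
      plus[idx] <- plus[idx] + sense_d
      if (leak > 0) minus[idx] <- minus[idx] + anti_d
    } else {
      minus[idx] <- minus[idx] + sense_d
      if (leak > 0) plus[idx] <- plus[idx] + anti_d
    }
  }
  coverage_track(plus, minus, library_id = library_id, timepoint = timepoint,
                 bin_size = 1, library_size = sum(counts))
}

#' Sample degraded-fragment libraries
#'
#' Per-gene fragment expectation is proportional to the long-library
#' expectation times the true degradation rate; each library is a
#' multinomial draw whose realized size scales with the total degradation
#' flux (the configured `fragment_depth` is recorded as the nominal anchor
#' depth).
#'
#' @inheritParams generate_timecourse
#' @param timepoints Fragment-library timepoints (default from the config).
#' @return A fragment-library [count_table()].
#' @export
generate_fragments <- function(truth, config = truth$config,
                               timepoints = config$fragment_timepoints,
                               seed = NULL) {
  set.seed(if (is.null(seed)) sub_seed(config$seed, 3L) else seed)
  g <- truth$genes
  jj <- match(timepoints, config$timepoints)
  stopifnot(!anyNA(jj))
  counts <- sapply(jj, function(j) {
    w <- truth$expected[, j] * g$length
    u <- w * truth$rates[, j]
    flux_scale <- sum(u) / sum(w)
    N <- round(config$fragment_depth * flux_scale)
    as.vector(stats::rmultinom(1, N, u / sum(u)))
  })
  dimnames(counts) <- list(g$gene_id, sprintf("frag_%gh", timepoints))
  libs <- data.frame(library_id = colnames(counts), timepoint = timepoints,
                     kind = "fragment", depth = config$fragment_depth,
                     stringsAsFactors = FALSE)
  count_table(counts, libs)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits annotation GFF3, regions BED, flags TSV, long and fragment count
#' TSVs, a library-metadata TSV, per-library coverage bedGraphs (optional)
#' and the ground-truth TSV.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if missing).
#' @param coverage Write per-base coverage bedGraphs (large for big genomes).
#' @return Invisibly, the list of written paths.
#' @export
simulate_dataset <- function(config, outdir, coverage = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- generate_genome(config)
  tc <- generate_timecourse(truth, config, coverage = coverage)
  frag <- generate_fragments(truth, config)
  p <- function(f) file.path(outdir, f)
  paths <- c(annotation = p("annotation.gff3"), regions = p("regions.bed"),
             flags = p("flags.tsv"), counts_long = p("counts_long.tsv"),
             counts_fragment = p("counts_fragment.tsv"),
             libraries = p("libraries.tsv"), truth = p("truth.tsv"))
  write_annotation_gff3(truth$genes, truth$chrom, paths["annotation"])
  write_regions_bed(truth$partition, truth$chrom, paths["regions"])
  write_flags_tsv(truth$genes, paths["flags"])
  write_counts_tsv(tc$counts, paths["counts_long"])
  write_counts_tsv(frag, paths["counts_fragment"])
  utils::write.table(rbind(tc$counts$libraries, frag$libraries),
                     paths["libraries"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tt <- truth$genes[, c("gene_id", "region", "program", "base_expr",
                        "rate_log2", "category")]
  utils::write.table(tt, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (coverage) {
    covdir <- p("coverage")
    dir.create(covdir, showWarnings = FALSE)
    for (tr in tc$coverage) {
      for (strand in c("plus", "minus")) {
        f <- file.path(covdir, sprintf("%s_%s.bedGraph", tr$library_id, strand))
        write_track(tr[[strand]], f, mode = "bedgraph",
                    chrom_name = truth$chrom$name,
                    genome_length = truth$chrom$genome_length)
        paths <- c(paths, f)
      }
    }
  }
  invisible(paths)
}
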