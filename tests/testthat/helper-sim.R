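# Shared simulated datasets, generated once per test run. Seeds are fixed;
# problem sizes are stated in the methods vignette.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (!exists(key, envir = .sim_cache)) assign(key, make(), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# small genome for fast unit tests
small_config <- function(seed = 7) {
  sim_config(seed = seed, genome_length = 4e5, n_genes = 320,
             long_depth = 3e5, fragment_depth = 1.5e5)
}

small_sim <- function() {
  cached("small", function() {
    cfg <- small_config()
    truth <- generate_genome(cfg)
    tc <- generate_timecourse(truth, cfg)
    frag <- generate_fragments(truth, cfg)
    list(cfg = cfg, truth = truth, counts = tc$counts,
         coverage = tc$coverage, frag = frag)
  })
}

# the default study conditions (full scale), for recovery tests
default_sim <- function() {
  cached("default", function() {
    cfg <- sim_config(seed = 101)
    truth <- generate_genome(cfg)
    tc <- generate_timecourse(truth, cfg)
    frag <- generate_fragments(truth, cfg)
    expr <- normalize_expression(tc$counts, truth$genes)
    list(cfg = cfg, truth = truth, counts = tc$counts,
         coverage = tc$coverage, frag = frag, expr = expr)
  })
}

# --- circular rotation of a whole dataset (coordinate-shift invariance) ---

rotate_vec <- function(v, k) {
  L <- length(v); k <- k %% L
  if (k == 0) v else c(v[(L - k + 1):L], v[1:(L - k)])
}

rotate_track <- function(tr, k) {
  coverage_track(rotate_vec(tr$plus, k),
                 if (tr$stranded) rotate_vec(tr$minus, k) else NULL,
                 library_id = tr$library_id, timepoint = tr$timepoint,
                 bin_size = tr$bin_size, library_size = tr$library_size)
}

rotate_genes <- function(genes, k, L) {
  genes$start <- (genes$start + k) %% L
  genes$end <- ((genes$end + k - 1) %% L) + 1
  genes
}

rotate_partition <- function(part, k) {
  lab <- rotate_vec(switchtome:::region_base_labels(part), k)
  r <- rle(lab)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  region_partition(data.frame(start = starts, end = ends, label = r$values),
                   part$genome_length)
}
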