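test_that("degradation index matches its closed form", {
  tb <- two_gene_tables(c(100, 100), c(100, 100))
  di <- degradation_index(tb$full, tb$frag)
  expect_equal(di$DI, c(0, 0))
  tb2 <- two_gene_tables(c(100, 100), c(400, 100))
  di2 <- degradation_index(tb2$full, tb2$frag)
  expect_equal(di2$DI[1], log2(100.5 / 400.5))
  # doubling the fragment library depth with counts fixed adds exactly 1
  tb3 <- two_gene_tables(c(100, 100), c(400, 100), depth_s = 2000)
  di3 <- degradation_index(tb3$full, tb3$frag)
  expect_equal(di3$DI, di2$DI + 1)
  # mismatched gene sets are rejected with the differences named
  bad <- two_gene_tables(c(10, 10), c(10, 10))
  rownames(bad$frag$counts) <- c("g1", "zz")
  bad$frag$genes <- c("g1", "zz")
  expect_error(degradation_index(tb$full, bad$frag), "zz")
})

test_that("DI is antisymmetric and relative DI is median-centered", {
  set.seed(8)
  n <- 50
  f <- rpois(n, 200); s <- rpois(n, 150)
  ids <- paste0("g", 1:n)
  full <- long_counts(matrix(f, ncol = 1, dimnames = list(ids, NULL)), 40,
                      depth = 5000)
  frag <- frag_counts(matrix(s, ncol = 1, dimnames = list(ids, NULL)), 40,
                      depth = 5000)
  di <- degradation_index(full, frag, min_full = 0)
  # swap roles (relabelling kinds so timepoint/kind lookups still resolve)
  full2 <- long_counts(matrix(s, ncol = 1, dimnames = list(ids, NULL)), 40,
                       depth = 5000)
  frag2 <- frag_counts(matrix(f, ncol = 1, dimnames = list(ids, NULL)), 40,
                       depth = 5000)
  di_sw <- degradation_index(full2, frag2, min_full = 0)
  expect_equal(di_sw$DI, -di$DI)
  expect_lt(abs(median(di$relative_DI)), 1e-9)
  # classification thresholds at +/- delta
  expect_true(all(di$class[di$relative_DI <= -1] == "faster"))
  expect_true(all(di$class[di$relative_DI >= 1] == "slower"))
  expect_true(all(di$class[abs(di$relative_DI) < 1] == "neutral"))
  # masking: genes under min_full have no DI
  dim10 <- degradation_index(full, frag, min_full = 1000)
  expect_true(all(dim10$masked) && all(is.na(dim10$DI)))
})

test_that("global degradation shift responds only to rate changes", {
  tb <- two_gene_tables(c(100, 200), c(50, 100))
  di <- degradation_index(tb$full, tb$frag)
  expect_equal(global_degradation_shift(di, 40, 40)$delta_median_DI, 0)
  # permuting gene labels leaves the shift unchanged
  perm <- two_gene_tables(c(200, 100), c(100, 50))
  dip <- degradation_index(perm$full, perm$frag)
  expect_equal(global_degradation_shift(dip, 40, 40)$delta_median_DI,
               global_degradation_shift(di, 40, 40)$delta_median_DI)
})

test_that("a genome-wide rate doubling shifts the median DI by -1", {
  cfg <- sim_config(seed = 17, genome_length = 8e5, n_genes = 600,
                    long_depth = 5e5, fragment_depth = 2.5e5,
                    bottleneck_factor = 1, rate_logsd = 0,
                    class_degradation_log2 = c(), switch_rate_factor = 2,
                    transposon_switch_log2fc = 0, rnase_switch_log2fc = 0,
                    program_fractions = c(pre = 0, post = 0,
                                          constitutive = 1),
                    noncore_postswitch_log2fc = 0)
  truth <- generate_genome(cfg)
  tc <- generate_timecourse(truth, cfg, coverage = FALSE)
  fr <- generate_fragments(truth, cfg)
  di <- degradation_index(tc$counts, fr)
  gs <- global_degradation_shift(di, 40, 51)
  expect_equal(gs$delta_median_DI, -1, tolerance = 0.1)
  # with all rates equal within a timepoint, expected DI spread is zero-
  # centered: median relative DI is 0 and classes are overwhelmingly neutral
  tab51 <- di[di$timepoint == 51 & !di$masked, ]
  expect_gt(mean(tab51$class == "neutral"), 0.95)
})

test_that("stability class enrichment reports folds and rank-sum p", {
  ids <- paste0("g", 1:40)
  rel <- c(rep(1, 10), rep(0, 30))
  tab <- data.frame(gene_id = ids, timepoint = 40, full_count = 100,
                    fragment_count = 100, DI = rel, relative_DI = rel,
                    class = "neutral", masked = FALSE)
  classes <- setNames(rep(c("tf", "other"), c(10, 30)), ids)
  res <- suppressWarnings(
    stability_class_enrichment(tab, classes, 40, class_labels = "tf"))
  expect_equal(res$fold, 2)
  expect_lt(res$p, 0.01)
  # identical class and complement: fold 1, p ~ 1
  tab2 <- tab; tab2$relative_DI <- rep(c(0.5, -0.5), 20)
  res2 <- stability_class_enrichment(tab2, classes, 40,
                                     class_labels = "other")
  expect_equal(res2$fold, 1, tolerance = 0.15)
  expect_gt(res2$p, 0.5)
  # undersized classes are skipped with a warning
  small <- setNames(rep(c("tiny", "rest"), c(2, 38)), ids)
  expect_warning(stability_class_enrichment(tab, small, 40),
                 "too small")
})

test_that("fragment filtering applies length and sense rules idempotently", {
  mask <- list(plus = c(rep(TRUE, 60), rep(FALSE, 40)),
               minus = rep(FALSE, 100))
  reads <- data.frame(start = c(0, 5, 10, 70, 50),
                      length = c(60, 30, 30, 30, 30),
                      strand = c("+", "-", "+", "+", "+"))
  out <- filter_fragments(reads, mask)
  # 60 nt read out (length), antisense read out (sense), read in untran-
  # scribed region out, read spanning the region edge out
  expect_equal(out$start, 10)
  expect_equal(attr(out, "discarded"),
               c(length_rule = 1, sense_rule = 3))
  # idempotence
  out2 <- filter_fragments(out, mask)
  expect_equal(out2$start, out$start)
  expect_equal(attr(out2, "discarded"), c(length_rule = 0, sense_rule = 0))
  expect_error(filter_fragments(reads, list(plus = rep(FALSE, 100),
                                            minus = rep(FALSE, 100))),
               "no transcribed regions")
})

test_that("transcribed mask thresholds per-million coverage per strand", {
  tr <- coverage_track(c(10, 0, 5), c(0, 2, 0), library_size = 1e6)
  m <- transcribed_mask(list(tr), threshold = 3)
  expect_equal(m$plus, c(TRUE, FALSE, TRUE))
  expect_equal(m$minus, c(FALSE, FALSE, FALSE))
})

test_that("degradation track paints unmasked gene bodies only", {
  g <- validate_genes(data.frame(gene_id = c("g1", "g2"),
                                 start = c(0, 200), end = c(100, 300),
                                 strand = "+"),
                      chromosome_model("chr", 1000))
  tab <- data.frame(gene_id = c("g1", "g2"), timepoint = 40,
                    full_count = c(100, 5), fragment_count = c(25, 5),
                    DI = c(-2, NA), relative_DI = c(-2, NA),
                    class = c("faster", NA), masked = c(FALSE, TRUE))
  rec <- degradation_track(tab, g, 40)
  expect_equal(nrow(rec), 1)
  expect_equal(unlist(rec), c(start = 0, end = 100, value = -2))
  f <- withr::local_tempfile(fileext = ".bedGraph")
  degradation_track(tab, g, 40, path = f)
  expect_equal(readLines(f), "chr\t0\t100\t-2")
})
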