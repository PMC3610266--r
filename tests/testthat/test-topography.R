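test_that("transcribed fraction counts strands and singletons correctly", {
  tr <- coverage_track(c(1, 0), c(0, 0), library_size = 1)
  got <- transcribed_fraction(list(tr))
  expect_equal(got$either_strand, 0.5)
  expect_equal(got$unstranded, 0.5)
  expect_equal(got$singleton_fraction, 1.0)
  tr2 <- coverage_track(c(2, 2), c(2, 2), library_size = 8)
  got2 <- transcribed_fraction(list(tr2))
  expect_equal(got2$either_strand, 1.0)
  expect_equal(got2$singleton_fraction, 0.0)
  tr3 <- coverage_track(c(1, 2, 3), c(0, 0, 0), library_size = 6)
  expect_equal(transcribed_fraction(list(tr3), min_cov = 3)$unstranded, 1 / 3)
  expect_error(transcribed_fraction(list()), "empty")
  # monotone non-increasing in min_cov (brute force over positions)
  set.seed(11)
  tr4 <- coverage_track(rpois(50, 2), rpois(50, 2), library_size = 200)
  fr <- sapply(1:6, function(mc) {
    unlist(transcribed_fraction(list(tr4), min_cov = mc)[1:2])
  })
  expect_true(all(diff(fr["either_strand", ]) <= 0))
  expect_true(all(diff(fr["unstranded", ]) <= 0))
  brute <- mean(sapply(seq_len(50), function(i) {
    tr4$plus[i] >= 3 || tr4$minus[i] >= 3
  }))
  expect_equal(transcribed_fraction(list(tr4), min_cov = 3)$either_strand,
               brute)
})

test_that("strand preference is replichore-aware and antisymmetric", {
  cm <- chromosome_model("chr", 200, origin = 0, terminus = 100)
  plus <- rep(30, 200); minus <- rep(10, 200)
  tr <- coverage_track(plus, minus, library_size = 100)
  sp <- strand_preference(tr, cm, bin_size = 50)
  # replichore 1 (positions 0-99): leading = plus -> P = 0.5
  expect_equal(sp$values[1:2], c(0.5, 0.5))
  # replichore 2: leading = minus -> P = -0.5
  expect_equal(sp$values[3:4], c(-0.5, -0.5))
  swapped <- coverage_track(minus, plus, library_size = 100)
  expect_equal(strand_preference(swapped, cm, bin_size = 50)$values,
               -sp$values)
  # empty bins are missing, values bounded
  set.seed(3)
  tr2 <- coverage_track(c(rpois(100, 1), rep(0, 100)),
                        c(rpois(100, 1), rep(0, 100)), library_size = 100)
  v <- strand_preference(tr2, cm, bin_size = 50)$values
  expect_true(all(is.na(v[3:4])))
  expect_true(all(abs(v[!is.na(v)]) <= 1))
  expect_error(strand_preference(coverage_track(plus), cm), "stranded")
})

test_that("strand preference is invariant under bin refinement of
           piecewise-constant coverage", {
  cm <- chromosome_model("chr", 400, origin = 0, terminus = 200)
  set.seed(9)
  plus <- rep(rpois(4, 20), each = 100)
  minus <- rep(rpois(4, 20), each = 100)
  tr <- coverage_track(plus, minus, library_size = 100)
  coarse <- strand_preference(tr, cm, bin_size = 100)$values
  fine <- strand_preference(tr, cm, bin_size = 50)$values
  expect_equal(fine, rep(coarse, each = 2))
})

test_that("region enrichment matches closed forms and detects the switch", {
  part <- region_partition(data.frame(start = c(0, 50), end = c(50, 100),
                                      label = c("core", "noncore")), 100)
  # all bins equal -> E = 0 everywhere
  m <- matrix(3, nrow = 10, ncol = 2)
  re <- region_enrichment(m, partition = part, bin_size = 10,
                          timepoints = c(40, 51), switch_tp = 51)
  expect_equal(re$series$E, rep(0, 4))
  # noncore mean 5, core mean 20 -> E_noncore = log2(0.4)
  m2 <- matrix(rep(c(20, 5), each = 5), nrow = 10, ncol = 2)
  re2 <- region_enrichment(m2, partition = part, bin_size = 10,
                           timepoints = c(40, 51), switch_tp = 51)
  expect_equal(re2$series$E[re2$series$region == "noncore"][1],
               log2(5 / 12.5))
  # linear-scale identity: region means recombine to the genome mean
  w <- c(core = 0.5, noncore = 0.5)
  s1 <- re2$series[re2$series$timepoint == 40, ]
  expect_equal(sum(w[s1$region] * 2^s1$E), 1)
  # random label permutations carry no enrichment in expectation
  set.seed(21)
  vals <- matrix(rlnorm(200, 0, 1), ncol = 1)
  e_perm <- replicate(100, {
    lab <- sample(rep(c("core", "noncore"), each = 100))
    r <- switchtome:::region_enrich_one(vals[, 1], lab, 0)
    r$E
  })
  expect_lt(max(abs(rowMeans(e_perm))), 0.2)
})

test_that("border induction permutation p matches exhaustive enumeration", {
  # 20-gene toy, 5 transposons at +3 log2, 15 background at 0 (no noise)
  g <- validate_genes(data.frame(
    gene_id = sprintf("g%02d", 1:20), start = seq(0, 1900, by = 100),
    end = seq(50, 1950, by = 100), strand = "+",
    transposon = rep(c(TRUE, FALSE), c(5, 15))),
    chromosome_model("chr", 2000))
  g <- switchtome:::complete_gene_columns(g)
  part <- region_partition(data.frame(start = c(0, 1000), end = c(1000, 2000),
                                      label = c("core", "noncore")), 2000)
  v_pre <- rep(10, 20)
  v_post <- ifelse(g$transposon, 80.5 + 0.5 * 8 - 0.5, 10)  # exact +3 log2
  v_post[g$transposon] <- (10 + 0.5) * 8 - 0.5
  vals_pre <- matrix(v_pre, ncol = 1, dimnames = list(g$gene_id, NULL))
  expr <- mock_expr(cbind(vals_pre, v_post), c(40, 51))
  bi <- border_induction(expr, g, part, c(40, 51), window = 2000,
                         n_perm = 20000, seed = 1)
  expect_true(bi$exhaustive)
  expect_equal(bi$median_log2fc, 3)
  fc <- log2((expr$values[, 2] + 0.5) / (expr$values[, 1] + 0.5))
  expect_equal(bi$p_perm, perm_median_oracle(fc, 5, 3))
  # exact tail mass: subsets whose median reaches +3 need >= 3 of the 5
  # induced genes among their 5 picks
  exact <- (choose(5, 3) * choose(15, 2) + choose(5, 4) * choose(15, 1) +
              choose(5, 5)) / choose(20, 5)
  expect_equal(bi$p_perm, exact)
  # identical fold changes everywhere -> no induction signal
  expr0 <- mock_expr(cbind(vals_pre, v_pre * 2), c(40, 51))
  bi0 <- suppressWarnings(border_induction(expr0, g, part, c(40, 51),
                                           window = 2000, n_perm = 1000))
  expect_equal(bi0$fold, 2 * (10 + 0.25) / (10 + 0.5), tolerance = 0.05)
  expect_gt(bi0$p_mw, 0.3)
  expect_error(border_induction(expr, g, part, c(40, 51), window = 0),
               "no transposon")
})

test_that("antisense fraction and positional profile follow the coverage", {
  cm <- chromosome_model("chr", 100)
  g <- validate_genes(data.frame(gene_id = "g1", start = 0, end = 100,
                                 strand = "+"), cm)
  tr <- coverage_track(rep(97, 100), rep(3, 100), library_size = 100)
  af <- antisense_fraction(list(tr), g, cm)
  expect_equal(af$overall, 0.03)
  tr0 <- coverage_track(rep(5, 100), rep(0, 100), library_size = 5)
  af0 <- antisense_fraction(list(tr0), g, cm)
  expect_equal(af0$overall, 0)
  expect_equal(af0$positional_profile, rep(0, 10), ignore_attr = TRUE)
  # orientation awareness: antisense at high coordinates of a minus-strand
  # gene is 5' antisense, not 3'
  gm <- validate_genes(data.frame(gene_id = "g1", start = 0, end = 100,
                                  strand = "-"), cm)
  anti <- c(rep(0, 90), rep(10, 10))
  trm <- coverage_track(anti, rep(90, 100), library_size = 100)
  afm <- antisense_fraction(list(trm), gm, cm)
  expect_gt(afm$positional_profile[1], 0)
  expect_equal(afm$positional_profile[10], 0, ignore_attr = TRUE)
})

test_that("intergenic candidate calling applies run, merge and support rules", {
  cm <- chromosome_model("chr", 1000)
  g <- validate_genes(data.frame(gene_id = "g1", start = 0, end = 300,
                                 strand = "+"), cm)
  mk <- function(v) coverage_track(v, rep(0, 1000), library_size = 100)
  # one 100 nt intergenic block at 10x
  v <- rep(0, 1000); v[501:600] <- 10
  cand <- intergenic_candidates(list(mk(v)), NULL, g, cm, min_expr = 1)
  expect_equal(nrow(cand), 1)
  expect_equal(c(cand$start, cand$end, cand$length), c(500, 600, 100))
  # same block overlapping a same-strand gene: nothing
  v2 <- rep(0, 1000); v2[251:350] <- 10
  cand2 <- intergenic_candidates(list(mk(v2)), NULL, g, cm, min_expr = 1)
  expect_equal(sum(cand2$start < 300 & cand2$strand == "+"), 0)
  # two 60 nt runs separated by a 10 bp gap merge into one 130 nt candidate
  v3 <- rep(0, 1000); v3[501:560] <- 10; v3[571:630] <- 10
  cand3 <- intergenic_candidates(list(mk(v3)), NULL, g, cm, min_expr = 1)
  expect_equal(nrow(cand3), 1)
  expect_equal(cand3$length, 130)
  # fragment support requires >= 50% covered positions
  fv <- rep(0, 1000); fv[501:580] <- 1
  cand4 <- intergenic_candidates(list(mk(v3)), list(mk(fv)), g, cm,
                                 min_expr = 1)
  expect_true(cand4$supported)
  fv2 <- rep(0, 1000); fv2[501:520] <- 1
  cand5 <- intergenic_candidates(list(mk(v3)), list(mk(fv2)), g, cm,
                                 min_expr = 1)
  expect_false(cand5$supported)
  expect_error(intergenic_candidates(list(mk(v)), NULL, g, cm,
                                     min_len = 100, max_len = 50),
               "min_len")
})

test_that("simulated topography recovers the injected genome organisation", {
  sim <- default_sim()
  g <- sim$truth$genes
  chrom <- sim$truth$chrom
  # 75% leading-strand bias shows as positive genome-median preference
  sp <- strand_preference(sim$coverage[[1]], chrom)
  expect_gt(median(sp$values, na.rm = TRUE), 0)
  # 3' -biased antisense leak: rising deciles in the last third, above the
  # flat 5' levels
  af <- antisense_fraction(sim$coverage, g, chrom)
  expect_equal(af$overall, sim$cfg$antisense_leak, tolerance = 1e-10)
  pp <- af$positional_profile
  expect_true(all(diff(pp[8:10]) > 0))
  expect_gt(pp[10], mean(pp[1:6]))
})
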