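test_that("normalization reproduces RPKM arithmetic and masks rRNA", {
  # 100 reads on a 1 kb gene in a 1e6-read library -> 100 RPKM
  g <- toy_genes(c("a", "filler"), c(1000, 1000))
  m <- matrix(c(100, 999900), ncol = 1, dimnames = list(g$gene_id, NULL))
  e <- normalize_expression(make_counts(m, 40), g)
  expect_equal(e$values["a", 1], 100)
  # proportional libraries normalize identically
  m2 <- cbind(m, m * 2)
  e2 <- normalize_expression(make_counts(m2, c(40, 51)), g)
  expect_equal(e2$values[, 1], e2$values[, 2])
  # three-gene toy against hand-computed upper-quartile RPKM
  g3 <- toy_genes(c("a", "b", "c"), rep(1000, 3))
  m3 <- matrix(c(10, 20, 40), ncol = 1, dimnames = list(g3$gene_id, NULL))
  e3 <- normalize_expression(make_counts(m3, 40), g3)
  rpkm <- c(10, 20, 40) / 1 / (70 / 1e6)
  uq <- unname(quantile(rpkm, 0.75))
  expect_equal(unname(e3$values[, 1]), rpkm / (uq / uq))
  # rRNA genes are removed before any quantity is computed
  g4 <- toy_genes(c("a", "b", "rrn"), rep(1000, 3),
                  rRNA = c(FALSE, FALSE, TRUE))
  m4 <- matrix(c(100, 300, 99600), ncol = 1,
               dimnames = list(g4$gene_id, NULL))
  e4 <- normalize_expression(make_counts(m4, 40), g4)
  expect_equal(rownames(e4$values), c("a", "b"))
  expect_equal(unname(e4$libraries$lib_size), 400)
  expect_error(normalize_expression(
    make_counts(matrix(0, 2, 1, dimnames = list(c("a", "b"), NULL)), 40),
    toy_genes(c("a", "b"), c(1000, 1000))), "all-zero")
})

test_that("prominent gene selection takes the deterministic top half", {
  g <- toy_genes(paste0("g", 1:4), rep(1000, 4))
  vals <- matrix(c(5, 1, 10, 3), ncol = 1,
                 dimnames = list(g$gene_id, NULL))
  e <- mock_expr(vals, 40)
  expect_equal(prominent_genes(e), c("g3", "g1"))
  # odd counts: ceiling
  e5 <- mock_expr(matrix(c(5, 1, 10, 3, 2), ncol = 1,
                         dimnames = list(paste0("g", 1:5), NULL)), 40)
  expect_length(prominent_genes(e5), 3)
  # boundary ties broken lexicographically
  et <- mock_expr(matrix(c(7, 3, 3, 1), ncol = 1,
                         dimnames = list(c("d", "c", "b", "a"), NULL)), 40)
  expect_equal(prominent_genes(et), c("d", "b"))
})

test_that("switch fold changes use the declared pseudocount", {
  vals <- cbind(c(10, 5), c(40, 5))
  rownames(vals) <- c("a", "b")
  e <- mock_expr(vals, c(40, 51))
  fc <- switch_fold_changes(e, 40, 51, universe = c("a", "b"))
  expect_equal(unname(fc$log2fc["a"]), log2(40.5 / 10.5))
  expect_true(fc$changed["a"])
  expect_equal(fc$changed_fraction, 0.5)
  # unchanged expression -> zero changed fraction
  e0 <- mock_expr(cbind(c(10, 5), c(10, 5)), c(40, 51))
  rownames(e0$values) <- c("a", "b")
  fc0 <- switch_fold_changes(e0, 40, 51, universe = c("a", "b"))
  expect_equal(fc0$changed_fraction, 0)
  expect_error(switch_fold_changes(e, 40, 40), "differ")
})

test_that("complete-linkage clustering matches the brute-force oracle", {
  # identical profiles land in the same cluster at height 0; perfect
  # anticorrelation sits at distance 2
  vals <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 3, 2, 1))
  e <- mock_expr(vals, c(28, 40, 51, 66))
  ph <- cluster_phases(e, 51, gene_ids = rownames(vals), k = 2)
  cl <- ph$assignments$cluster
  expect_equal(cl[1], cl[2])
  expect_false(cl[1] == cl[3])
  X <- log2(vals + 0.5)
  D <- 1 - cor(t(X))
  expect_equal(max(ph$tree$height), max(D[1:2, 3]))
  expect_lt(min(ph$tree$height), 1e-12)

  # random toys: tree equals the O(n^3) enumeration (heights and partitions)
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    vals <- matrix(rlnorm(n * 6, 2, 1), n,
                   dimnames = list(paste0("g", 1:n), NULL))
    e <- mock_expr(vals, c(28, 36, 40, 51, 66, 93))
    ph <- cluster_phases(e, 51, gene_ids = rownames(vals), k = 2)
    Z <- t(scale(t(log2(vals + 0.5))))
    D <- 1 - cor(t(Z))
    oracle <- complete_linkage_oracle(D)
    expect_equal(sort(ph$tree$height), sort(oracle$heights),
                 tolerance = 1e-10)
    for (k in 2:(n - 1)) {
      ct <- cutree(ph$tree, k)
      expect_equal(partition_key(split(seq_len(n), ct)),
                   partition_key(oracle$partitions[[n - k]]))
    }
  }
})

test_that("clustering is invariant to per-gene affine transforms", {
  set.seed(5)
  vals <- matrix(rlnorm(8 * 7, 3, 1), 8,
                 dimnames = list(paste0("g", 1:8), NULL))
  tps <- c(28, 36, 40, 51, 66, 82, 93)
  # apply the affine transform on the log scale where the profile lives
  lv <- log2(vals + 0.5)
  lv2 <- lv * rep(runif(8, 0.5, 2), 7) + rep(runif(8, -1, 1), 7)
  e1 <- mock_expr(2^lv - 0.5, tps)
  e2 <- mock_expr(2^lv2 - 0.5, tps)
  t1 <- cluster_phases(e1, 51, gene_ids = rownames(vals), k = 3)
  t2 <- cluster_phases(e2, 51, gene_ids = rownames(vals), k = 3)
  expect_equal(t1$tree$height, t2$tree$height, tolerance = 1e-8)
  expect_equal(cutree(t1$tree, 3), cutree(t2$tree, 3))
})

test_that("constant profiles are excluded with a warning", {
  vals <- rbind(a = c(1, 2, 3), b = c(2, 2, 2), c = c(3, 1, 2))
  e <- mock_expr(vals, c(40, 51, 66))
  expect_warning(ph <- cluster_phases(e, 51, gene_ids = rownames(vals), k = 2),
                 "constant")
  expect_equal(ph$excluded, "b")
  expect_false("b" %in% ph$assignments$gene_id)
})

test_that("category enrichment equals hypergeometric closed forms", {
  # universe 10, category 5, set 5, overlap 5 -> p = 1/252
  universe <- paste0("g", 1:10)
  cats <- setNames(rep(c("x", "y"), each = 5), universe)
  res <- category_enrichment(universe[1:5], universe, cats)
  expect_equal(res$p[res$category == "x"], 1 / 252)
  expect_equal(res$a[res$category == "x"], 5)
  # overlap at expectation -> fold enrichment 1
  res2 <- category_enrichment(universe[c(1, 2, 6, 7)], universe, cats)
  expect_equal(res2$fold_enrichment, c(1, 1))
  # set = universe -> p = 1 for every category
  res3 <- category_enrichment(universe, universe, cats)
  expect_true(all(res3$p == 1))
  expect_true(all(res3$q >= res3$p - 1e-15 & res3$q <= 1))
  expect_error(category_enrichment(c("zz"), universe, cats), "subset")
})

test_that("phase recovery works on the small simulation", {
  sim <- small_sim()
  g <- sim$truth$genes
  expr <- normalize_expression(sim$counts, g)
  ph <- cluster_phases(expr, 51)
  a <- ph$assignments
  pr <- g$program[match(a$gene_id, g$gene_id)]
  acc <- mean(c(a$phase[pr == "pre"] == "exponential",
                a$phase[pr == "post"] == "stationary"))
  expect_gt(acc, 0.9)
})
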