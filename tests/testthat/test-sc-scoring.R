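test_that("qc_filter applies strict boundaries on genes and mito fraction", {
  # sparse matrix with > 8000 genes, built in code: boundary cells
  n_genes <- 8101
  genes <- c(sprintf("G%05d", seq_len(n_genes - 1)), "MT-1")
  m <- Matrix::sparseMatrix(
    i = c(seq_len(8000),            # cell 1: exactly 8000 detected genes
          seq_len(8001),            # cell 2: 8001 detected genes
          1:89, n_genes,            # cell 3: 11% mito (11 of 100 counts)
          1:90, n_genes),           # cell 4: exactly 10% mito
    j = c(rep(1, 8000), rep(2, 8001), rep(3, 90), rep(4, 91)),
    x = c(rep(1, 8000), rep(1, 8001), rep(1, 89), 11,
          rep(1, 90), 10),
    dims = c(n_genes, 4), dimnames = list(genes, paste0("c", 1:4))
  )
  qc <- qc_filter(m)
  expect_identical(qc$report$kept, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(qc$report$n_genes[1:2], c(8000, 8001))
  expect_equal(qc$report$mito_frac[3], 11 / 100)
  expect_equal(qc$report$mito_frac[4], 0.10)

  expect_error(qc_filter(m, max_genes = 10, max_mito_frac = 0.001),
               "all cells removed")
})

test_that("qc_filter equals a brute-force per-cell scan on synthetic data", {
  sim <- make_network(200, module_size = 20, rng_seed = 5)
  sc <- make_single_cell(sim$truth, n_cells = 60, rng_seed = 6)
  gene_cut <- as.integer(stats::median(Matrix::colSums(sc$counts > 0)))
  qc <- qc_filter(sc$counts, max_genes = gene_cut, max_mito_frac = 0.10)
  dense <- as.matrix(sc$counts)
  mito <- grepl("^MT-", rownames(dense), ignore.case = TRUE)
  brute_keep <- vapply(seq_len(ncol(dense)), function(j) {
    !(sum(dense[, j] > 0) > gene_cut ||
        sum(dense[mito, j]) / sum(dense[, j]) > 0.10)
  }, logical(1))
  expect_identical(qc$report$kept, brute_keep)
})

test_that("normalization is depth-invariant with exact per-cell totals", {
  counts <- Matrix::sparseMatrix(
    i = c(1, 2, 1, 1), j = c(1, 1, 2, 3), x = c(300, 200, 500, 50),
    dims = c(3, 3), dimnames = list(c("g1", "g2", "g3"), c("a", "b", "c"))
  )
  nm <- normalize_cells(counts)
  # single detected gene with the whole total: log2(1 + 10000)
  expect_equal(nm["g1", "b"], log2(1 + 1e4), tolerance = 1e-12)
  expect_equal(nm["g3", "a"], 0)  # zero count stays zero
  # pre-log totals equal the scale factor
  pre <- 2^as.matrix(nm) - 1
  expect_equal(unname(Matrix::colSums(pre)), rep(1e4, 3), tolerance = 1e-9)
  # doubling all counts of a cell changes nothing
  doubled <- counts; doubled[, 1] <- doubled[, 1] * 2
  expect_equal(as.matrix(normalize_cells(doubled))[, 1],
               as.matrix(nm)[, 1], tolerance = 1e-12)
  # detected-gene counts are unchanged by normalization
  expect_equal(Matrix::colSums(nm > 0), Matrix::colSums(counts > 0))

  zero <- counts; zero[, 2] <- 0
  expect_error(normalize_cells(zero), "b")
})

test_that("planted case cells score higher than control cells", {
  wins <- vapply(1:5, function(seed) {
    sim <- make_network(400, module_size = 30, rng_seed = seed)
    co <- make_cohorts(sim$truth, cases_per_cohort = 40,
                       controls_per_cohort = 60, rng_seed = seed + 50)[[1]]
    genes <- sim$truth$module_genes[1:20]
    m <- fit_elastic_logistic(t(co$values[genes, ]), co$labels,
                              folds = 5, repeats = 2, rule = "min",
                              rng_seed = seed)
    sc <- make_single_cell(sim$truth, n_cells = 200, rng_seed = seed + 100)
    qc <- qc_filter(sc$counts)
    nm <- normalize_cells(qc$counts)
    scored <- score_cells(m, nm)
    keep <- sc$cells$barcode %in% scored$barcode
    is_case <- sc$cells$is_case[keep]
    mean(scored$score[is_case]) > mean(scored$score[!is_case])
  }, logical(1))
  expect_true(all(wins))
})

test_that("score_cells guards degenerate inputs", {
  sim <- make_network(200, module_size = 20, rng_seed = 9)
  sc <- make_single_cell(sim$truth, n_cells = 50, n_high_mito = 0,
                         rng_seed = 10)
  nm <- normalize_cells(sc$counts)
  genes <- sim$truth$module_genes[1:10]
  set.seed(11)
  m <- structure(
    list(genes = genes,
         gene_means = stats::setNames(rnorm(10, 5), genes),
         gene_sds = stats::setNames(rep(1, 10), genes),
         intercept = 0.2,
         coefficients = stats::setNames(rnorm(10), genes),
         mixing = 0.5, lambda = 0.1, k = 10),
    class = "marker_model"
  )
  scored <- score_cells(m, nm)
  expect_true(all(is.finite(scored$score)))
  # a gene constant across cells is dropped by the z-score guard
  nm2 <- nm; nm2[genes[1], ] <- 3
  expect_true(all(is.finite(score_cells(m, nm2)$score)))
  # all model genes absent -> error
  missing_all <- nm[setdiff(rownames(nm), genes), ]
  expect_error(score_cells(m, missing_all), "missing")
})

test_that("cluster enrichment matches exact hypergeometric arithmetic", {
  # one cluster of 10 all-high cells among 100 cells with 20 high total
  high <- rep(FALSE, 100)
  high[1:20] <- TRUE
  clusters <- c(rep("c1", 10), rep("c2", 90))  # c1 = 10 high cells
  enr <- cluster_enrichment(high, clusters)
  p_exact <- choose(20, 10) * choose(80, 0) / choose(100, 10)
  expect_equal(enr$p_value[enr$cluster == "c1"], p_exact, tolerance = 1e-10)
  expect_lt(enr$p_value[enr$cluster == "c1"], 0.05)
  # conservation: per-cluster high counts sum to the total
  expect_equal(sum(enr$n_high), sum(high))

  # identical composition in every cluster -> nothing significant
  high2 <- rep(c(TRUE, FALSE, FALSE, FALSE), 25)
  cl2 <- rep(c("a", "b"), each = 50)
  expect_true(all(!cluster_enrichment(high2, cl2)$significant))

  expect_warning(
    cluster_enrichment(high, factor(clusters, levels = c("c1", "c2", "c3"))),
    "empty"
  )
  expect_error(cluster_enrichment(high, rep("one", 100)), "2 non-empty")
})

test_that("shuffled cluster labels are not anti-conservative", {
  # hypergeometric p-values are discrete, hence conservative under the
  # null; assert the empirical CDF never rises significantly above uniform
  set.seed(13)
  high <- rep(c(TRUE, FALSE), c(100, 400))
  allp <- unlist(lapply(1:200, function(i) {
    cl <- sample(rep(1:10, each = 50))
    cluster_enrichment(high, cl)$p_value
  }))
  ks <- suppressWarnings(
    stats::ks.test(allp, "punif", alternative = "greater")
  )
  expect_gt(ks$p.value, 0.01)
  expect_lte(mean(allp < 0.05), 0.06)
})
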