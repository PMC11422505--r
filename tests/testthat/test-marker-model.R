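test_that("stratified split reproduces the canonical 28/183 vs 9/61 sizes", {
  labels <- rep(c("case", "control"), c(37, 244))
  sp <- split_train_test(labels, train_frac = 0.75, rng_seed = 1)
  expect_equal(sum(labels[sp$train] == "case"), 28)
  expect_equal(sum(labels[sp$train] == "control"), 183)
  expect_equal(sum(labels[sp$test] == "case"), 9)
  expect_equal(sum(labels[sp$test] == "control"), 61)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(labels))

  sp2 <- split_train_test(labels, train_counts = c(case = 28, control = 183),
                          rng_seed = 2)
  expect_equal(sum(labels[sp2$train] == "case"), 28)

  expect_identical(split_train_test(labels, rng_seed = 3),
                   split_train_test(labels, rng_seed = 3))
  expect_error(split_train_test(rep(c("case", "control"), c(1, 50))),
               "empty")
  expect_error(split_train_test(rep("control", 10)), "both classes")
})

test_that("huge lambda collapses to the null model predicting prevalence", {
  set.seed(1)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("g", 1:4)))
  y <- rep(c(1, 0), c(15, 35))
  m <- fit_elastic_logistic(X, y, lambda = c(1e6, 1e5), folds = 5,
                            repeats = 2, rng_seed = 1)
  expect_true(all(m$coefficients == 0))
  expect_equal(m$intercept, stats::qlogis(0.3), tolerance = 1e-6)
  sc <- predict_score(m, t(X))
  expect_equal(unname(sc), rep(0.3, 50), tolerance = 1e-6)
})

test_that("separable data reaches training AUPRC 1 at small lambda", {
  set.seed(2)
  X <- cbind(g1 = c(rnorm(20, 3), rnorm(30, -3)), g2 = rnorm(50))
  y <- rep(c(1, 0), c(20, 30))
  m <- fit_elastic_logistic(X, y, folds = 5, repeats = 2, rule = "min",
                            rng_seed = 2)
  expect_equal(auprc(predict_score(m, t(X)), y), 1.0)
})

test_that("predict_score standardization policies and invariances", {
  set.seed(3)
  X <- matrix(rnorm(300, 5), 50, 6, dimnames = list(NULL, paste0("g", 1:6)))
  y <- as.integer(X[, 1] + rnorm(50, 0, 0.5) > 5)
  m <- fit_elastic_logistic(X, y, folds = 5, repeats = 2, rule = "min",
                            rng_seed = 3)

  expr <- t(X)
  # gene order in the input matrix is irrelevant
  expect_equal(predict_score(m, expr), predict_score(m, expr[6:1, ]))
  # a sample at the training means scores exactly plogis(intercept)
  mean_sample <- matrix(m$gene_means, ncol = 1,
                        dimnames = list(m$genes, "s0"))
  expect_equal(unname(predict_score(m, mean_sample)),
               stats::plogis(m$intercept))
  # missing model genes contribute zero: equal to zeroing the coefficient
  dropped <- expr[-1, ]
  m_zeroed <- m; m_zeroed$coefficients[1] <- 0
  expect_equal(predict_score(m, dropped), predict_score(m_zeroed, expr))
  unrelated <- matrix(0, 2, 2, dimnames = list(c("zz1", "zz2"), c("a", "b")))
  expect_error(predict_score(m, unrelated), "missing")

  # monotone in any gene with positive coefficient
  pos_gene <- names(which(m$coefficients > 0))[1]
  expect_false(is.na(pos_gene))
  bumped <- expr; bumped[pos_gene, ] <- bumped[pos_gene, ] + 1
  expect_true(all(predict_score(m, bumped) >= predict_score(m, expr)))

  # dataset policy: invariant to per-gene affine rescaling of the input
  rescaled <- expr * 3 + 10
  expect_equal(predict_score(m, expr, standardize = "dataset"),
               predict_score(m, rescaled, standardize = "dataset"))
})

test_that("model JSON serialization round-trips scores exactly", {
  set.seed(4)
  X <- matrix(rnorm(200, 5), 40, 5, dimnames = list(NULL, paste0("g", 1:5)))
  y <- rep(c(1, 0), c(12, 28))
  m <- fit_elastic_logistic(X, y, folds = 5, repeats = 2, rng_seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_marker_model(m, path)
  m2 <- read_marker_model(path)
  expect_equal(predict_score(m2, t(X)), predict_score(m, t(X)),
               tolerance = 1e-15)
})

test_that("auprc matches hand values and the brute-force oracle", {
  expect_equal(auprc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)),
               1 * (1 / 2) + (2 / 3) * (1 / 2))
  expect_equal(auprc(c(0.9, 0.8, 0.2), c(1, 1, 0)), 1.0)   # perfect ranking
  expect_equal(auprc(rep(0.5, 10), rep(c(1, 0), c(3, 7))), 0.3) # prevalence
  expect_error(auprc(c(0.1, 0.2), c(1, 1)), "positive and")

  set.seed(5)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # force ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(auprc(scores, labels), brute_ap(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("panel-size rule picks the smallest k within one SE of the best", {
  k <- seq(10, 100, 10)
  plateau <- c(0.55, 0.7, 0.8, 0.9, 0.9, 0.91, 0.9, 0.9, 0.91, 0.9)
  se <- rep(0.015, 10)
  expect_equal(markernet:::choose_k_rule(k, plateau, se), 40)
  # strictly increasing with large SE: smallest k can win
  expect_equal(markernet:::choose_k_rule(k, seq(0.5, 0.95, length.out = 10),
                                         rep(0.5, 10)), 10)
  expect_equal(markernet:::choose_k_rule(10, 0.8, 0.01), 10)
})

test_that("select_k runs the CV grid and respects overrides", {
  run <- planted_run(31, n_genes = 400, module_size = 30, cases = 40,
                     controls = 60)
  ranking <- rank_candidates(run$prop, 60)
  expr <- run$cohorts[[1]]$values
  labels <- run$cohorts[[1]]$labels
  sel <- select_k(ranking, expr, labels, k_grid = c(10, 20, 30),
                  folds = 5, repeats = 2, rng_seed = 1)
  expect_s3_class(sel, "cv_selection")
  expect_true(sel$chosen_k %in% c(10, 20, 30))
  expect_equal(nrow(sel$table), 3)
  expect_true(all(sel$table$auprc_mean >= 0 & sel$table$auprc_mean <= 1))

  sel10 <- select_k(ranking, expr, labels, k_grid = 10, folds = 5,
                    repeats = 2, rng_seed = 1)
  expect_equal(sel10$chosen_k, 10)
  selov <- select_k(ranking, expr, labels, k_grid = c(10, 20), folds = 5,
                    repeats = 2, rng_seed = 1, chosen_k = 20)
  expect_equal(selov$chosen_k, 20)
  expect_error(select_k(ranking, expr, labels, k_grid = 1000), "exceeds")
})

test_that("no leakage: permuted labels give chance-level held-out AUPRC", {
  run <- planted_run(41, n_genes = 400, module_size = 30, cases = 40,
                     controls = 80)
  ranking <- rank_candidates(run$prop, 40)
  expr <- run$cohorts[[1]]$values
  labels <- run$cohorts[[1]]$labels
  set.seed(41)
  gaps <- replicate(5, {
    perm <- sample(labels)
    sp <- split_train_test(perm, rng_seed = sample.int(1e6, 1))
    m <- fit_elastic_logistic(t(expr[ranking, sp$train]), perm[sp$train],
                              folds = 5, repeats = 2,
                              rng_seed = sample.int(1e6, 1))
    ap <- auprc(predict_score(m, expr[, sp$test]), perm[sp$test])
    ap - mean(perm[sp$test] == "case")
  })
  expect_lte(abs(mean(gaps)), 2 * stats::sd(gaps) + 1e-8)
})
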