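test_that("preprocess_network cleans self-loops, duplicates, and low-confidence edges", {
  edges <- data.frame(a = c("A", "B", "C"), b = c("B", "A", "C"))
  net <- suppressWarnings(preprocess_network(edges))
  expect_setequal(net$nodes, c("A", "B"))
  expect_equal(sum(net$adjacency != 0) / 2, 1)
  expect_warning(preprocess_network(edges), "dropped")

  wedges <- data.frame(a = c("A", "B"), b = c("B", "C"),
                       conf = c(0.6, 0.9))
  net2 <- suppressWarnings(preprocess_network(wedges, min_confidence = 0.7))
  expect_setequal(net2$nodes, c("B", "C"))
  expect_equal(unname(net2$adjacency["B", "C"]), 0.9)

  # duplicate pair keeps the max confidence
  dup <- data.frame(a = c("A", "B"), b = c("B", "A"), conf = c(0.5, 0.8))
  net3 <- preprocess_network(dup)
  expect_equal(unname(net3$adjacency["A", "B"]), 0.8)

  expect_error(preprocess_network(data.frame(a = "A", b = "A")), "empty graph")
  expect_error(preprocess_network(data.frame(a = "A", b = "B", conf = 1.4)),
               "confidences")
})

test_that("components without seeds or support end with (near) zero scores", {
  edges <- data.frame(a = c("A", "B", "X"), b = c("B", "C", "Y"))
  expect_warning(net <- preprocess_network(edges), "components")
  g <- compute_guidance(net, "A")
  w <- stats::setNames(c(1, 0, 0, 0, 0), c("A", "B", "C", "X", "Y"))
  pr <- guided_stationary(net, g, w)
  expect_lt(pr$score["X"] + pr$score["Y"], 1e-9)
})

test_that("guidance matches symmetry and closed-form solutions", {
  # seeds = all nodes of a k-regular graph (cycle) -> uniform guidance
  n <- 6
  ring <- data.frame(a = sprintf("R%d", 1:n), b = sprintf("R%d", c(2:n, 1)))
  net <- preprocess_network(ring)
  g <- compute_guidance(net, net$nodes)
  expect_equal(unname(g[net$nodes]), rep(1 / n, n), tolerance = 1e-9)

  # 3-node path, seed {A}, beta = 0.5: dense 3x3 solve
  net3 <- preprocess_network(data.frame(a = c("A", "B"), b = c("B", "C")))
  g3 <- compute_guidance(net3, "A")
  W <- matrix(c(0, 1, 0, 0.5, 0, 0.5, 0, 1, 0), 3, 3, byrow = TRUE)
  g_exact <- solve(diag(3) - 0.5 * t(W), 0.5 * c(1, 0, 0))
  expect_lt(max(abs(g3[c("A", "B", "C")] - g_exact)), 1e-10)

  # flooring keeps every node strictly positive
  edges <- data.frame(a = c("A", "X"), b = c("B", "Y"))
  net2 <- suppressWarnings(preprocess_network(edges))
  g2 <- compute_guidance(net2, "A")
  expect_true(all(g2 > 0))

  expect_error(compute_guidance(net3, "ZZZ"), "missing")
})

test_that("restart-only limit, conservation, and tie-breaking hold", {
  net <- random_network(60, seed = 8)
  n <- length(net$nodes)
  set.seed(8)
  w <- stats::setNames(numeric(n), net$nodes)
  w[sample(net$nodes, 10)] <- runif(10, 0.5, 2)
  g <- compute_guidance(net, sample(net$nodes, 3))

  # alpha = 1: s = r exactly after one iteration
  pr1 <- guided_stationary(net, g, w, propagation_config(alpha = 1))
  expect_identical(pr1$iterations, 1L)
  expect_equal(unname(pr1$score), unname(w / sum(w)), tolerance = 1e-15)

  pr <- guided_stationary(net, g, w)
  expect_true(pr$converged)
  expect_lt(abs(sum(pr$score) - 1), 1e-9)
  expect_true(all(pr$score >= 0))
  expect_identical(sort(unname(pr$rank)), seq_len(n))

  # bit-identical scores break ties by gene symbol, and ranking is total
  tied <- structure(pr, class = "propagation_result")
  tied$score[c("N002", "N001")] <- 0.123
  ord <- order(-tied$score, names(tied$score), method = "radix")
  expect_lt(which(names(tied$score)[ord] == "N001"),
            which(names(tied$score)[ord] == "N002"))

  expect_identical(rank_candidates(pr, n), names(sort(pr$rank)))
  expect_error(rank_candidates(pr, 0), "positive")
  expect_error(rank_candidates(pr, n + 1), "exceeds")
})

test_that("uniform guidance reduces the guided walk to classic RWR", {
  for (seed in c(3, 4)) {
    net <- random_network(80, weighted = FALSE, seed = seed)
    n <- length(net$nodes)
    set.seed(seed)
    w <- stats::setNames(runif(n), net$nodes)
    gu <- stats::setNames(rep(1 / n, n), net$nodes)
    pr <- guided_stationary(net, gu, w, propagation_config(tol = 1e-14))
    s_classic <- classic_rwr(as.matrix(net$adjacency), w / sum(w), 0.5)
    expect_lt(max(abs(pr$score - s_classic)), 1e-12)
  }
})

test_that("power iteration agrees with the dense linear solve", {
  for (seed in 1:5) {
    net <- random_network(40 + 20 * seed, weighted = seed %% 2 == 0,
                          seed = seed)
    n <- length(net$nodes)
    set.seed(seed + 100)
    w <- stats::setNames(numeric(n), net$nodes)
    w[sample(net$nodes, 8)] <- runif(8, 0.5, 3)
    g <- compute_guidance(net, sample(net$nodes, 3))
    pr <- guided_stationary(net, g, w)
    s_dense <- dense_guided_solve(net$adjacency, as.vector(g[net$nodes]),
                                  w / sum(w), 0.5)
    expect_lt(sum(abs(pr$score - s_dense)), 1e-8)
  }
})

test_that("scores scale-invariant in weights and monotone in own weight", {
  net <- random_network(50, seed = 12)
  n <- length(net$nodes)
  set.seed(12)
  w <- stats::setNames(numeric(n), net$nodes)
  support <- sample(net$nodes, 10)
  w[support] <- runif(10, 0.5, 2)
  g <- compute_guidance(net, sample(net$nodes, 2))
  base <- guided_stationary(net, g, w)
  scaled <- guided_stationary(net, g, w * 7.3)
  expect_lt(max(abs(base$score - scaled$score)), 1e-12)

  for (i in 1:20) {
    target <- sample(support, 1)
    w2 <- w
    w2[target] <- w2[target] * (1 + runif(1, 0.1, 2))
    bumped <- guided_stationary(net, g, w2)
    expect_gte(bumped$score[target], base$score[target] - 1e-12)
  }
})

test_that("determinism: identical inputs give identical ranks", {
  run <- planted_run(21, n_genes = 400, module_size = 30, cases = 20,
                     controls = 20)
  rerun <- planted_run(21, n_genes = 400, module_size = 30, cases = 20,
                       controls = 20)
  expect_identical(run$prop$rank, rerun$prop$rank)
  expect_identical(run$prop$score, rerun$prop$score)
})
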