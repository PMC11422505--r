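# Independent brute-force oracles. These deliberately use naive, literal
# implementations of each definition so they share no code path with the
# package.

# BH step-up: adj p_i = min(1, min over j with rank_j >= rank_i of p_j*n/rank_j)
brute_bh <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(n), function(i) {
    tail_ratios <- vapply(which(r >= r[i]), function(j) n / r[j] * p[j],
                          numeric(1))
    min(1, min(tail_ratios))
  }, numeric(1))
}

# average precision via explicit threshold sweep
brute_ap <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  ap <- 0
  for (t0 in thr) {
    sel <- scores >= t0
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / n_pos
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# dense linear-system solution of the guided walk:
# s = alpha * (I - (1-alpha) P^T)^-1 r with P(u,v) = A_uv g_v / sum_v A_uv g_v
dense_guided_solve <- function(A, g, r, alpha) {
  A <- as.matrix(A)
  n <- nrow(A)
  P <- matrix(0, n, n)
  for (u in seq_len(n)) {
    w <- A[u, ] * g
    P[u, ] <- w / sum(w)
  }
  as.vector(solve(diag(n) - (1 - alpha) * t(P), alpha * r))
}

# classic (unguided) random walk with restart, dense power iteration
classic_rwr <- function(A, r, alpha, tol = 1e-14, max_iter = 100000) {
  A <- as.matrix(A)
  P <- A / rowSums(A)
  s <- r
  for (i in seq_len(max_iter)) {
    s_new <- (1 - alpha) * as.vector(t(P) %*% s) + alpha * r
    if (sum(abs(s_new - s)) < tol) return(s_new)
    s <- s_new
  }
  s
}

# product-limit estimate by direct evaluation at one time point
brute_km_at <- function(time, event, t0) {
  ut <- sort(unique(time[event == 1]))
  ut <- ut[ut <= t0]
  s <- 1
  for (ti in ut) {
    n_i <- sum(time >= ti)
    d_i <- sum(time == ti & event == 1)
    s <- s * (1 - d_i / n_i)
  }
  s
}

# random connected test network (optionally confidence-weighted)
random_network <- function(n, p = 0.06, weighted = FALSE, seed = 1) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) > 0) break
    p <- min(1, p * 1.3)
  }
  el <- igraph::as_edgelist(g)
  genes <- sprintf("N%03d", seq_len(n))
  df <- data.frame(protein_a = genes[el[, 1]], protein_b = genes[el[, 2]],
                   stringsAsFactors = FALSE)
  if (weighted) df$confidence <- stats::runif(nrow(df), 0.3, 1)
  suppressWarnings(preprocess_network(df))
}

toy_cohort <- function(values, labels, id = "toy") {
  structure(list(cohort_id = id, values = values, labels = labels),
            class = "cohort_expression")
}

# one full synthetic run: network + cohorts -> DE -> weights -> propagation
planted_run <- function(seed, n_genes = 2000, module_size = 50,
                        cases = 60, controls = 60, noise_sd = 0.25) {
  sim <- make_network(n_genes, module_size = module_size, rng_seed = seed)
  cohorts <- make_cohorts(sim$truth, cases_per_cohort = cases,
                          controls_per_cohort = controls,
                          noise_sd = noise_sd, rng_seed = seed + 1000L)
  de <- lapply(cohorts, differential_test)
  degs <- lapply(de, filter_degs)
  w <- build_weights(de, degs, sim$network$nodes)
  g <- compute_guidance(sim$network, sim$truth$seed_genes)
  prop <- guided_stationary(sim$network, g, w)
  list(sim = sim, cohorts = cohorts, de = de, degs = degs, weights = w,
       guidance = g, prop = prop)
}
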