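#' @keywords internal
new_gene_network <- function(adjacency) {
  adjacency <- methods::as(adjacency, "CsparseMatrix")
  stopifnot(nrow(adjacency) == ncol(adjacency),
            !is.null(rownames(adjacency)))
  structure(
    list(
      nodes = rownames(adjacency),
      adjacency = adjacency,
      degree_w = Matrix::rowSums(adjacency)
    ),
    class = "gene_network"
  )
}

#' Build a gene network from a raw edge list
#'
#' Cleans a StringDB-style undirected edge list into the propagation
#' substrate: drops edges below `min_confidence`, removes self-loops,
#' collapses duplicate/reciprocal pairs keeping the maximum confidence,
#' and symmetrizes. Nodes appearing only in dropped edges vanish (with a
#' warning). Multiple connected components are kept, with a warning that
#' scores in components holding neither seeds nor support genes will be
#' zero.
#'
#' @param raw_edges Data frame whose first two columns are gene symbols and
#'   whose optional third column is an edge confidence in (0, 1\]; absent
#'   confidences default to 1.
#' @param min_confidence Drop edges with confidence below this value.
#'
#' @return A `gene_network`: list with `nodes`, sparse symmetric
#'   `adjacency` (confidence-weighted), and weighted degrees `degree_w`.
#' @export
preprocess_network <- function(raw_edges, min_confidence = 0) {
  stopifnot(is.data.frame(raw_edges), ncol(raw_edges) >= 2)
  a <- trimws(as.character(raw_edges[[1]]))
  b <- trimws(as.character(raw_edges[[2]]))
  conf <- if (ncol(raw_edges) >= 3) as.numeric(raw_edges[[3]]) else rep(1, length(a))
  if (any(is.na(conf) | conf <= 0 | conf > 1)) {
    stop("edge confidences must lie in (0, 1]")
  }
  all_nodes <- sort(unique(c(a, b)))

  keep <- conf >= min_confidence & a != b
  a <- a[keep]; b <- b[keep]; conf <- conf[keep]
  if (!length(a)) stop("empty graph after filtering")

  # canonical unordered pairs; keep max confidence among duplicates
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  conf <- vapply(split(conf, key), max, numeric(1))
  pairs <- do.call(rbind, strsplit(names(conf), "\r", fixed = TRUE))

  nodes <- sort(unique(c(pairs[, 1], pairs[, 2])))
  dropped <- setdiff(all_nodes, nodes)
  if (length(dropped)) {
    warning(length(dropped), " node(s) with no retained edges dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  }
  i <- match(pairs[, 1], nodes)
  j <- match(pairs[, 2], nodes)
  adj <- Matrix::sparseMatrix(
    i = c(i, j), j = c(j, i), x = rep(unname(conf), 2),
    dims = c(length(nodes), length(nodes)),
    dimnames = list(nodes, nodes)
  )
  net <- new_gene_network(adj)
  comps <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected")
  )
  if (comps$no > 1) {
    warning("network has ", comps$no, " connected components; scores in ",
            "components containing neither seeds nor support genes will be 0")
  }
  net
}

#' Propagation configuration
#'
#' @param alpha Restart probability of the guided walk, in (0, 1\]
#'   (default 0.5).
#' @param gamma Flow rate of the prior-knowledge diffusion (default 1).
#'   The guidance stage restarts at seeds with probability
#'   `beta = 1 / (1 + gamma)`, so `gamma = 1` gives `beta = 0.5`.
#' @param tol L1 convergence tolerance of the power iterations.
#' @param max_iter Maximum power iterations.
#' @param guidance_floor Relative floor applied to guidance values so the
#'   guided transition matrix stays well-defined on nodes unreachable from
#'   the seeds.
#' @return A `propagation_config` list.
#' @export
propagation_config <- function(alpha = 0.5, gamma = 1, tol = 1e-10,
                               max_iter = 10000L, guidance_floor = 1e-12) {
  stopifnot(alpha > 0, alpha <= 1, gamma > 0, tol > 0, max_iter >= 1,
            guidance_floor > 0)
  structure(list(alpha = alpha, gamma = gamma, tol = tol,
                 max_iter = as.integer(max_iter),
                 guidance_floor = guidance_floor),
            class = "propagation_config")
}

#' Diffuse prior knowledge from seed genes (guidance values)
#'
#' Runs a random walk with restart on the confidence-weighted network,
#' restarting uniformly on the seed genes with probability
#' `beta = 1 / (1 + gamma)`. The stationary distribution g(v) measures
#' each gene's proximity to the prior-knowledge seeds ("fluid" injected at
#' the seeds). After convergence, g is floored at
#' `guidance_floor * max(g)` so that every node retains positive guidance.
#'
#' @param net A `gene_network`.
#' @param seeds Character vector of seed gene symbols; at least one must be
#'   in the network (missing ones are reported).
#' @param cfg A [propagation_config()].
#' @return Named numeric vector g over the network nodes (sums to 1 before
#'   flooring), with attributes `iterations` and `converged`.
#' @export
compute_guidance <- function(net, seeds, cfg = propagation_config()) {
  stopifnot(inherits(net, "gene_network"))
  seeds_in <- intersect(seeds, net$nodes)
  if (!length(seeds_in)) {
    stop("no seed gene found in the network; missing: ",
         paste(seeds, collapse = ", "))
  }
  beta <- 1 / (1 + cfg$gamma)
  n <- length(net$nodes)
  u <- stats::setNames(numeric(n), net$nodes)
  u[seeds_in] <- 1 / length(seeds_in)
  A <- net$adjacency
  dw <- net$degree_w
  if (any(dw == 0)) stop("network contains degree-0 nodes")

  g <- u
  iter <- 0L
  converged <- FALSE
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    g_new <- beta * u + (1 - beta) * as.vector(A %*% (g / dw))
    delta <- sum(abs(g_new - g))
    g <- g_new
    if (delta < cfg$tol) { converged <- TRUE; break }
  }
  if (!converged) warning("guidance walk did not converge in ",
                          cfg$max_iter, " iterations")
  names(g) <- net$nodes
  g <- pmax(g, cfg$guidance_floor * max(g))
  attr(g, "iterations") <- iter
  attr(g, "converged") <- converged
  g
}

#' Guidance-biased random walk with restart at weighted support genes
#'
#' The walker restarts with probability `alpha` at the "new information"
#' genes, with restart mass proportional to their node weights (averaged
#' |log2FC|). From node u it otherwise steps to a neighbor v with
#' probability proportional to `c(u,v) * g(v)`: edge confidence times the
#' neighbor's guidance, so transitions are biased toward genes close to
#' the prior-knowledge seeds. The stationary distribution s is found by
#' power iteration from s0 = r until the L1 change falls below `cfg$tol`.
#'
#' @param net A `gene_network`.
#' @param guidance Named guidance vector from [compute_guidance()].
#' @param weights A `node_weighting` from [build_weights()] (or a named
#'   nonnegative vector).
#' @param cfg A [propagation_config()].
#' @return A `propagation_result`: list with `score` (named, sums to 1),
#'   `guidance`, `rank` (1-based, descending score, ties broken by gene
#'   symbol), `support`, `iterations`, `converged`.
#' @export
guided_stationary <- function(net, guidance, weights,
                              cfg = propagation_config()) {
  stopifnot(inherits(net, "gene_network"))
  w_in <- if (inherits(weights, "node_weighting")) weights$weights else weights
  if (any(w_in < 0)) stop("node weights must be nonnegative")
  w <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  common <- intersect(names(w_in), net$nodes)
  w[common] <- w_in[common]
  support <- names(w)[w > 0]
  if (!length(support)) stop("no support gene with positive weight in the network")

  g <- guidance[net$nodes]
  if (any(is.na(g) | g <= 0)) {
    stop("guidance must be positive for every network node")
  }
  A <- net$adjacency
  r <- w / sum(w)
  rs <- as.vector(A %*% g)          # row sums of the guided kernel
  alpha <- cfg$alpha

  s <- r
  iter <- 0L
  converged <- FALSE
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    s_new <- (1 - alpha) * (g * as.vector(A %*% (s / rs))) + alpha * r
    delta <- sum(abs(s_new - s))
    s <- s_new
    if (delta < cfg$tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("guided walk did not converge within ", cfg$max_iter,
            " iterations; returning last iterate (converged = FALSE)")
  }
  s <- stats::setNames(as.vector(s), net$nodes)
  ord <- order(-s, net$nodes, method = "radix")
  rank <- integer(length(s))
  rank[ord] <- seq_along(s)
  names(rank) <- net$nodes
  structure(
    list(score = s, guidance = stats::setNames(as.vector(g), net$nodes),
         rank = rank, support = support, iterations = iter,
         converged = converged, alpha = alpha),
    class = "propagation_result"
  )
}

#' Top-ranked candidate genes
#'
#' Returns the first `top_n` genes by descending stationary score. Seed
#' genes are not excluded: established markers legitimately rank among
#' the candidates.
#'
#' @param result A `propagation_result`.
#' @param top_n Number of genes to return (1..n).
#' @return Character vector of gene symbols in rank order.
#' @export
rank_candidates <- function(result, top_n) {
  stopifnot(inherits(result, "propagation_result"))
  n <- length(result$rank)
  if (top_n <= 0) stop("`top_n` must be positive")
  if (top_n > n) stop("`top_n` exceeds the number of ranked genes (", n, ")")
  names(sort(result$rank))[seq_len(top_n)]
}

#' @method print gene_network
#' @export
print.gene_network <- function(x, ...) {
  cat("Gene network:", length(x$nodes), "nodes,",
      sum(x$adjacency != 0) / 2, "edges\n")
  invisible(x)
}

#' @method print propagation_result
#' @export
print.propagation_result <- function(x, ...) {
  top <- names(sort(x$rank))[seq_len(min(5, length(x$rank)))]
  cat("Propagation result:", length(x$score), "genes;",
      length(x$support), "support genes;",
      x$iterations, "iterations",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("Top genes:", paste(top, collapse = ", "), "\n")
  invisible(x)
}
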