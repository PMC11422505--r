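#' Generate a synthetic gene network with a planted disease module
#'
#' Builds a scale-free protein-interaction-like graph by preferential
#' attachment, then densifies a randomly chosen module of `module_size`
#' genes until its internal edge density reaches `target_density`.
#' Degree heterogeneity mimics real PPI networks, while the densified
#' module emulates the clustering of disease genes that network
#' propagation exploits. The module carries the planted truth: a set of
#' seed genes (clinically established markers in a real analysis) and
#' signed log2 fold-change effects used by [make_cohorts()] and
#' [make_single_cell()].
#'
#' @param n_genes Number of genes (nodes). Must exceed `module_size`.
#' @param module_size Size of the planted disease module.
#' @param attach_m Edges added per node during preferential attachment.
#' @param rng_seed Integer seed; identical seeds reproduce the output exactly.
#' @param n_seeds Number of seed genes sampled from the module (default 6,
#'   matching the six canonical clinical markers a real analysis would use).
#' @param effect_size Magnitude of the planted log2 fold change (case vs
#'   control) for module genes; signs are random.
#' @param n_cohorts Number of cohorts for which per-cohort DE gene sets are
#'   planted.
#' @param de_frac Fraction of module genes planted as differentially
#'   expressed in each cohort (default 1: the whole module).
#' @param target_density Minimum internal edge density of the module.
#'
#' @return A list with elements `network` (a `gene_network`, see
#'   [preprocess_network()]) and `truth` (a `synthetic_truth` list with
#'   `genes`, `module_genes`, `seed_genes`, `de_genes_per_cohort`,
#'   `effect_sizes`, `hazard_coefficient`).
#' @export
make_network <- function(n_genes, module_size = 50L, attach_m = 3L, rng_seed = 1L,
                         n_seeds = 6L, effect_size = 2, n_cohorts = 2L,
                         de_frac = 1, target_density = 0.2) {
  if (module_size >= n_genes) {
    stop("`module_size` must be strictly smaller than `n_genes`")
  }
  if (attach_m < 1) stop("`attach_m` must be >= 1")
  if (n_seeds < 1 || n_seeds > module_size) {
    stop("`n_seeds` must be between 1 and `module_size`")
  }
  set.seed(rng_seed)
  g <- igraph::sample_pa(n_genes, m = attach_m, directed = FALSE)
  g <- igraph::simplify(g)
  genes <- sprintf("G%06d", seq_len(n_genes))
  igraph::V(g)$name <- genes

  module <- sort(sample(genes, module_size))
  # densify the module: add missing internal edges until density target met
  pairs <- utils::combn(module, 2)
  n_pairs <- ncol(pairs)
  target <- ceiling(target_density * n_pairs)
  present <- vapply(seq_len(n_pairs), function(i) {
    igraph::are_adjacent(g, pairs[1, i], pairs[2, i])
  }, logical(1))
  n_missing_needed <- target - sum(present)
  if (n_missing_needed > 0) {
    absent <- which(!present)
    add <- sample(absent, n_missing_needed)
    g <- igraph::add_edges(g, as.vector(pairs[, add]))
  }

  seeds <- sort(sample(module, n_seeds))
  effects <- stats::setNames(
    effect_size * sample(c(-1, 1), module_size, replace = TRUE), module
  )
  n_de <- max(1L, round(de_frac * module_size))
  de_sets <- lapply(seq_len(n_cohorts), function(i) sort(sample(module, n_de)))
  names(de_sets) <- sprintf("cohort%d", seq_len(n_cohorts))

  adj <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  adj <- methods::as(adj, "dMatrix")
  net <- new_gene_network(adj)

  truth <- structure(
    list(
      genes = genes,
      module_genes = module,
      seed_genes = seeds,
      de_genes_per_cohort = de_sets,
      effect_sizes = effects,
      hazard_coefficient = 1.1
    ),
    class = "synthetic_truth"
  )
  list(network = net, truth = truth)
}

#' Simulate case/control expression cohorts with planted effects
#'
#' Each cohort is an independent gene x sample matrix on log2 scale:
#' per-gene baselines are Normal(`baseline_mean`, `baseline_sd`), sample
#' noise is i.i.d. Normal(0, `noise_sd`), and case samples of the cohort's
#' planted DE genes are shifted by the true effect sizes. Baselines are
#' drawn independently per cohort (cross-platform level shifts are not a
#' property the downstream analysis relies on; differential signal is
#' within-cohort).
#'
#' @param truth A `synthetic_truth` from [make_network()].
#' @param n_cohorts Number of cohorts; must not exceed the number of planted
#'   per-cohort DE sets.
#' @param cases_per_cohort,controls_per_cohort Samples per class per cohort.
#' @param noise_sd Standard deviation of the sample-level Gaussian noise.
#' @param rng_seed Integer seed.
#' @param baseline_mean,baseline_sd Per-gene baseline distribution.
#'
#' @return A list of `cohort_expression` objects, each a list with
#'   `cohort_id`, `values` (gene x sample matrix) and `labels`
#'   ("case"/"control" per sample).
#' @export
make_cohorts <- function(truth, n_cohorts = 2L, cases_per_cohort = 60L,
                         controls_per_cohort = 60L, noise_sd = 0.25,
                         rng_seed = 1L, baseline_mean = 5, baseline_sd = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (length(truth$genes) == 0L || length(truth$module_genes) == 0L) {
    stop("`truth` has empty gene sets")
  }
  if (noise_sd <= 0) stop("`noise_sd` must be > 0")
  if (n_cohorts > length(truth$de_genes_per_cohort)) {
    stop("`truth` plants DE sets for only ",
         length(truth$de_genes_per_cohort), " cohorts")
  }
  set.seed(rng_seed)
  genes <- truth$genes
  lapply(seq_len(n_cohorts), function(i) {
    n <- cases_per_cohort + controls_per_cohort
    baseline <- stats::rnorm(length(genes), baseline_mean, baseline_sd)
    values <- matrix(stats::rnorm(length(genes) * n, 0, noise_sd),
                     nrow = length(genes), ncol = n,
                     dimnames = list(genes, sprintf("C%d_S%03d", i, seq_len(n))))
    values <- values + baseline
    labels <- c(rep("case", cases_per_cohort), rep("control", controls_per_cohort))
    de <- intersect(truth$de_genes_per_cohort[[i]], genes)
    if (cases_per_cohort > 0 && length(de)) {
      values[de, labels == "case"] <-
        values[de, labels == "case"] + truth$effect_sizes[de]
    }
    structure(
      list(cohort_id = sprintf("cohort%d", i), values = values, labels = labels),
      class = "cohort_expression"
    )
  })
}

#' Simulate survival data whose hazard increases with a known score
#'
#' Event times are Exponential with rate
#' `baseline_rates[stratum] * exp(beta * score)`; censoring times are
#' independent Exponential(`censor_rate`) (no censoring if
#' `censor_rate <= 0`). This is the planted ground truth against which the
#' stratified Cox stage is validated: the per-unit-score log hazard ratio
#' is exactly `beta` within every stratum.
#'
#' @param scores Per-sample scores in \[0, 1\].
#' @param strata Per-sample stratum labels; every label must appear in
#'   `names(baseline_rates)`.
#' @param beta Log hazard ratio per unit score (default 1.1).
#' @param baseline_rates Named vector of per-stratum baseline event rates.
#' @param censor_rate Rate of the independent Exponential censoring process.
#' @param rng_seed Integer seed.
#'
#' @return A data frame with columns `sample`, `time`, `event` (1 =
#'   observed), `stratum`, `score`.
#' @export
make_survival <- function(scores, strata, beta = 1.1,
                          baseline_rates = c(low = 0.02, intermediate = 0.04,
                                             high = 0.10),
                          censor_rate = 0.01, rng_seed = 1L) {
  if (any(scores < 0 | scores > 1)) stop("all `scores` must lie in [0, 1]")
  if (any(baseline_rates <= 0)) stop("all `baseline_rates` must be > 0")
  strata <- as.character(strata)
  if (length(strata) != length(scores)) {
    stop("`scores` and `strata` must have equal length")
  }
  unknown <- setdiff(unique(strata), names(baseline_rates))
  if (length(unknown)) {
    stop("unknown stratum label(s): ", paste(unknown, collapse = ", "))
  }
  set.seed(rng_seed)
  n <- length(scores)
  rate <- baseline_rates[strata] * exp(beta * scores)
  t_event <- stats::rexp(n, rate)
  t_cens <- if (censor_rate > 0) stats::rexp(n, censor_rate) else rep(Inf, n)
  data.frame(
    sample = sprintf("S%04d", seq_len(n)),
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    stratum = strata,
    score = scores,
    stringsAsFactors = FALSE
  )
}

#' Simulate a sparse single-cell count matrix with planted case cells
#'
#' Per-cell counts are Poisson with gene rates proportional to
#' `2^(log2 profile)` of the cell's class (control baseline, or baseline
#' plus planted effects for case cells), scaled so expected depth equals
#' `depth_mean`. Mitochondrial genes (symbols prefixed `MT-`) receive a
#' fixed share of each cell's rate mass; `n_high_mito` cells are planted
#' with an elevated mitochondrial share so the >10%-mito QC filter has
#' known true positives.
#'
#' @param truth A `synthetic_truth` from [make_network()].
#' @param n_cells Number of cells.
#' @param frac_case_cells Probability a cell is a case cell (0 < p < 1).
#' @param depth_mean Expected total counts per cell.
#' @param rng_seed Integer seed.
#' @param n_mito_genes Number of `MT-` genes appended to the gene universe.
#' @param mito_frac Baseline mitochondrial share of the rate mass.
#' @param n_high_mito Number of planted high-mito QC violators.
#' @param high_mito_frac Mitochondrial share for planted violators.
#'
#' @return A list with `counts` (sparse gene x cell `dgCMatrix`) and
#'   `cells` (data frame: `barcode`, `is_case`, `planted_high_mito`).
#' @export
make_single_cell <- function(truth, n_cells = 500L, frac_case_cells = 0.3,
                             depth_mean = 2000L, rng_seed = 1L,
                             n_mito_genes = 10L, mito_frac = 0.05,
                             n_high_mito = 3L, high_mito_frac = 0.25) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (frac_case_cells <= 0 || frac_case_cells >= 1) {
    stop("`frac_case_cells` must be strictly between 0 and 1")
  }
  set.seed(rng_seed)
  nuclear <- truth$genes
  mito <- sprintf("MT-G%02d", seq_len(n_mito_genes))
  genes <- c(nuclear, mito)

  mu <- stats::rnorm(length(nuclear), 5, 1)
  names(mu) <- nuclear
  mu_case <- mu
  eff <- truth$effect_sizes[names(truth$effect_sizes) %in% nuclear]
  mu_case[names(eff)] <- mu_case[names(eff)] + eff
  mu_mito <- stats::rnorm(n_mito_genes, 5, 1)

  rate_profile <- function(m, mf) {
    nuc <- 2^m / sum(2^m) * (1 - mf)
    mt <- 2^mu_mito / sum(2^mu_mito) * mf
    c(nuc, mt)
  }

  is_case <- stats::rbinom(n_cells, 1, frac_case_cells) == 1
  high_mito <- rep(FALSE, n_cells)
  if (n_high_mito > 0) high_mito[sample(n_cells, min(n_high_mito, n_cells))] <- TRUE

  counts <- matrix(0L, nrow = length(genes), ncol = n_cells,
                   dimnames = list(genes, sprintf("CELL%04d", seq_len(n_cells))))
  profiles <- list(
    control = rate_profile(mu, mito_frac),
    case = rate_profile(mu_case, mito_frac),
    control_hm = rate_profile(mu, high_mito_frac),
    case_hm = rate_profile(mu_case, high_mito_frac)
  )
  for (j in seq_len(n_cells)) {
    key <- paste0(if (is_case[j]) "case" else "control",
                  if (high_mito[j]) "_hm" else "")
    counts[, j] <- stats::rpois(length(genes), depth_mean * profiles[[key]])
  }
  list(
    counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
    cells = data.frame(
      barcode = colnames(counts),
      is_case = is_case,
      planted_high_mito = high_mito,
      stringsAsFactors = FALSE
    )
  )
}

#' @method print synthetic_truth
#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic truth:", length(x$genes), "genes;",
      length(x$module_genes), "module genes;",
      length(x$seed_genes), "seeds;",
      length(x$de_genes_per_cohort), "cohort DE sets\n")
  invisible(x)
}

#' @method print cohort_expression
#' @export
print.cohort_expression <- function(x, ...) {
  cat("Cohort", x$cohort_id, "-", nrow(x$values), "genes x",
      ncol(x$values), "samples (", sum(x$labels == "case"), "case /",
      sum(x$labels == "control"), "control )\n")
  invisible(x)
}
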