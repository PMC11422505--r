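# Deterministic per-stage RNG substreams: every stochastic stage seeds from
# the single pipeline rng_seed plus a stage-name hash, so stages can be
# rerun independently and reruns are byte-identical.
#' @keywords internal
substream_seed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147480009
  as.integer((as.numeric(seed) * 48271 + h) %% 2147480009)
}

# FNV-1a over a JSON rendering of the config; good enough to detect
# config changes in the run manifest.
#' @keywords internal
config_hash <- function(config) {
  s <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), ch) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Fold change by the delta-delta-Ct method
#'
#' Relative qPCR quantification: the target gene's Ct is normalized to a
#' reference gene within each of the sample and the calibrator, and the
#' fold change is `2^-(dCt_sample - dCt_calibrator)`.
#'
#' @param ct_gene_sample,ct_ref_gene_sample Target and reference-gene Ct
#'   in the sample of interest.
#' @param ct_gene_calibrator,ct_ref_gene_calibrator Target and
#'   reference-gene Ct in the calibrator sample.
#' @return Fold change of the target gene relative to the calibrator.
#' @export
ddct_fold_change <- function(ct_gene_sample, ct_ref_gene_sample,
                             ct_gene_calibrator, ct_ref_gene_calibrator) {
  stopifnot(is.finite(ct_gene_sample), is.finite(ct_ref_gene_sample),
            is.finite(ct_gene_calibrator), is.finite(ct_ref_gene_calibrator))
  ddct <- (ct_gene_sample - ct_ref_gene_sample) -
    (ct_gene_calibrator - ct_ref_gene_calibrator)
  2^(-ddct)
}

## ---- readers / writers ---------------------------------------------------

#' Read and write the pipeline's tabular formats
#'
#' Plain TSV conventions: expression matrices are genes x samples with a
#' `gene` first column and sample IDs in the header; edge lists have two
#' gene columns plus an optional confidence; labels are `sample`/`label`
#' pairs; weights are `gene`/`weight` pairs. Gene symbols are treated
#' case-sensitively and whitespace-trimmed. All round-trips are lossless
#' to full double precision.
#'
#' @param path File path.
#' @param mat,edges,df,weights Object to write.
#' @name pipeline_tsv
NULL

#' @rdname pipeline_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a gene column plus samples")
  genes <- trimws(as.character(df[[1]]))
  if (anyDuplicated(genes)) stop("duplicate gene symbols in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- genes
  m
}

#' @rdname pipeline_tsv
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_tsv
#' @export
read_edge_list_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("edge list TSV needs at least two gene columns")
  df
}

#' @rdname pipeline_tsv
#' @export
write_edge_list_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_tsv
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "label") %in% names(df))) {
    stop("labels TSV needs `sample` and `label` columns")
  }
  df
}

#' @rdname pipeline_tsv
#' @export
write_labels_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_tsv
#' @export
read_weights_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "weight") %in% names(df))) {
    stop("weights TSV needs `gene` and `weight` columns")
  }
  stats::setNames(df$weight, trimws(df$gene))
}

#' @rdname pipeline_tsv
#' @export
write_weights_tsv <- function(weights, path) {
  utils::write.table(
    data.frame(gene = names(weights), weight = unname(weights)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write a propagation ranking table
#'
#' @param result A `propagation_result`.
#' @param path Output TSV path.
#' @param seeds Optional seed genes, flagged in an `is_seed` column.
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(result, path, seeds = character(0)) {
  ord <- names(sort(result$rank))
  df <- data.frame(
    rank = result$rank[ord],
    gene = ord,
    score = result$score[ord],
    guidance = result$guidance[ord],
    in_support = ord %in% result$support,
    is_seed = ord %in% seeds,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write GMT gene-set files
#'
#' One set per line: name, description, then member genes,
#' tab-separated.
#'
#' @param path File path.
#' @param sets Named list of character vectors.
#' @param descriptions Optional per-set descriptions (defaults to names).
#' @return `read_gmt` returns a named list with a `description` attribute
#'   per set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (k in seq_along(lines)) {
    parts <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("malformed GMT line ", k, ": fewer than 3 fields")
    }
    genes <- trimws(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    sets[[parts[1]]] <- structure(genes, description = parts[2])
  }
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- vapply(seq_along(sets), function(i) {
      d <- attr(sets[[i]], "description")
      if (is.null(d)) names(sets)[i] else d
    }, character(1))
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a sparse count matrix as an MTX triplet directory
#'
#' Standard 10x-style layout: `matrix.mtx`, `features.tsv` (one gene per
#' line), `barcodes.tsv` (one barcode per line).
#'
#' @param counts Sparse gene x cell matrix.
#' @param dir Directory path.
#' @return `read_mtx_dir` returns a `dgCMatrix` with dimnames.
#' @export
write_mtx_dir <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_mtx_dir
#' @export
read_mtx_dir <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  m <- methods::as(m, "CsparseMatrix")
  features <- readLines(file.path(dir, "features.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
    stop("MTX dimensions do not match features/barcodes files")
  }
  dimnames(m) <- list(features, barcodes)
  m
}

#' @rdname pipeline_tsv
#' @export
read_survival_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  if (!all(need %in% names(df))) {
    stop("survival TSV needs columns: ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname pipeline_tsv
#' @export
write_survival_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- configuration and orchestration -------------------------------------

#' Pipeline configuration
#'
#' Validated bag of every tunable the end-to-end pipeline uses. Unknown
#' keys are rejected (both here and when loading from YAML via
#' [read_pipeline_config()]).
#'
#' @param n_genes,module_size,attach_m,n_seeds,effect_size,de_frac Synthetic
#'   network/truth parameters (see [make_network()]).
#' @param n_cohorts,cases_per_cohort,controls_per_cohort,noise_sd Cohort
#'   simulation parameters (see [make_cohorts()]).
#' @param de_method,fdr_cut,lfc_cut Differential-expression settings.
#' @param min_confidence Edge-confidence floor for network preprocessing.
#' @param alpha,gamma,tol,max_iter,guidance_floor Propagation settings
#'   (see [propagation_config()]).
#' @param top_n Length of the candidate ranking retained.
#' @param k_grid,folds,repeats,mixing,lambda_rule Panel-size selection
#'   settings (see [select_k()]).
#' @param train_frac Stratified train fraction for the model split.
#' @param high_threshold Score threshold flagging high-score cells.
#' @param split_method Survival dichotomization (`"median"` or
#'   `"threshold"`).
#' @param rng_seed Single seed from which all stage substreams derive.
#' @param out_dir Run directory for artifacts (created if missing).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(n_genes = 2000L, module_size = 50L,
                            attach_m = 3L, n_seeds = 6L, effect_size = 2,
                            de_frac = 1, n_cohorts = 2L,
                            cases_per_cohort = 60L, controls_per_cohort = 60L,
                            noise_sd = 0.25, de_method = "welch",
                            fdr_cut = 0.05, lfc_cut = 1, min_confidence = 0,
                            alpha = 0.5, gamma = 1, tol = 1e-10,
                            max_iter = 10000L, guidance_floor = 1e-12,
                            top_n = 500L, k_grid = seq(10L, 100L, 10L),
                            folds = 10L, repeats = 10L, mixing = 0.5,
                            lambda_rule = "1se", train_frac = 0.75,
                            high_threshold = 0.5, split_method = "median",
                            rng_seed = 1L, out_dir = tempfile("markernet_run_")) {
  cfg <- list(
    n_genes = n_genes, module_size = module_size, attach_m = attach_m,
    n_seeds = n_seeds, effect_size = effect_size, de_frac = de_frac,
    n_cohorts = n_cohorts, cases_per_cohort = cases_per_cohort,
    controls_per_cohort = controls_per_cohort, noise_sd = noise_sd,
    de_method = de_method, fdr_cut = fdr_cut, lfc_cut = lfc_cut,
    min_confidence = min_confidence, alpha = alpha, gamma = gamma,
    tol = tol, max_iter = max_iter, guidance_floor = guidance_floor,
    top_n = top_n, k_grid = k_grid, folds = folds, repeats = repeats,
    mixing = mixing, lambda_rule = lambda_rule, train_frac = train_frac,
    high_threshold = high_threshold, split_method = split_method,
    rng_seed = rng_seed, out_dir = out_dir
  )
  stopifnot(
    cfg$n_genes > cfg$module_size, cfg$attach_m >= 1,
    cfg$fdr_cut > 0, cfg$fdr_cut < 1, cfg$lfc_cut >= 0,
    cfg$alpha > 0, cfg$alpha <= 1, cfg$gamma > 0, cfg$tol > 0,
    cfg$noise_sd > 0, cfg$mixing >= 0, cfg$mixing <= 1,
    cfg$lambda_rule %in% c("1se", "min"),
    cfg$de_method %in% c("welch", "moderated"),
    cfg$split_method %in% c("median", "threshold"),
    cfg$train_frac > 0, cfg$train_frac < 1,
    all(cfg$k_grid >= 1), cfg$top_n >= max(cfg$k_grid)
  )
  if (max(cfg$k_grid) > cfg$n_genes) {
    stop("max of `k_grid` exceeds `n_genes`")
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with a subset of the configuration keys.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' Run the full marker-discovery pipeline on synthetic data
#'
#' Executes the six stages end to end -- simulate, differential
#' expression, propagation, panel-size selection, scoring, survival --
#' writing every intermediate artifact plus a machine-readable manifest
#' (package version, seed, config hash, per-stage outputs) to
#' `config$out_dir`. All randomness derives from `config$rng_seed`
#' through named per-stage substreams, so a rerun with the same config is
#' byte-identical.
#'
#' Survival ground truth uses the planted case indicator as the true
#' score (hazard coefficient from the synthetic truth), so the fitted
#' model's high/low score split should stratify survival if and only if
#' the model recovers the planted signal.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage result (`network`, `truth`,
#'   `cohorts`, `de`, `weights`, `propagation`, `ranking`, `selection`,
#'   `model`, `scores`, `test_auprc`, `survival`, `cox`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  stages <- character(0)

  ## 1. simulate
  sim <- make_network(config$n_genes, config$module_size, config$attach_m,
                      rng_seed = substream_seed(config$rng_seed, "network"),
                      n_seeds = config$n_seeds,
                      effect_size = config$effect_size,
                      n_cohorts = config$n_cohorts, de_frac = config$de_frac)
  cohorts <- make_cohorts(sim$truth, n_cohorts = config$n_cohorts,
                          cases_per_cohort = config$cases_per_cohort,
                          controls_per_cohort = config$controls_per_cohort,
                          noise_sd = config$noise_sd,
                          rng_seed = substream_seed(config$rng_seed, "cohorts"))
  for (co in cohorts) {
    write_expression_tsv(co$values,
                         file.path(out, paste0(co$cohort_id, "_expr.tsv")))
    write_labels_tsv(data.frame(sample = colnames(co$values),
                                label = co$labels),
                     file.path(out, paste0(co$cohort_id, "_labels.tsv")))
  }
  writeLines(sim$truth$seed_genes, file.path(out, "seeds.txt"))
  stages <- c(stages, "simulate")

  ## 2. differential expression
  de <- lapply(cohorts, differential_test, method = config$de_method,
               fdr_cut = config$fdr_cut, lfc_cut = config$lfc_cut)
  deg_sets <- lapply(de, filter_degs, fdr_cut = config$fdr_cut,
                     lfc_cut = config$lfc_cut)
  for (i in seq_along(de)) {
    utils::write.table(de[[i]], file.path(out, paste0("de_cohort", i, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  weights <- build_weights(de, deg_sets, sim$network$nodes)
  write_weights_tsv(weights$weights, file.path(out, "weights.tsv"))
  stages <- c(stages, "diffexp")

  ## 3. propagation
  pcfg <- propagation_config(alpha = config$alpha, gamma = config$gamma,
                             tol = config$tol, max_iter = config$max_iter,
                             guidance_floor = config$guidance_floor)
  g <- compute_guidance(sim$network, sim$truth$seed_genes, pcfg)
  prop <- guided_stationary(sim$network, g, weights, pcfg)
  write_ranking_tsv(prop, file.path(out, "ranking.tsv"),
                    seeds = sim$truth$seed_genes)
  ranking <- rank_candidates(prop, min(config$top_n, length(prop$rank)))
  stages <- c(stages, "propagate")

  ## 4. panel-size selection on the pooled training split
  pooled <- do.call(cbind, lapply(cohorts, function(co) co$values))
  labels <- unlist(lapply(cohorts, function(co) co$labels), use.names = FALSE)
  split <- split_train_test(labels, train_frac = config$train_frac,
                            rng_seed = substream_seed(config$rng_seed, "split"))
  sel <- select_k(ranking, pooled[, split$train, drop = FALSE],
                  labels[split$train], k_grid = config$k_grid,
                  mixing = config$mixing, folds = config$folds,
                  repeats = config$repeats, rule = config$lambda_rule,
                  rng_seed = substream_seed(config$rng_seed, "select"))
  utils::write.table(sel$table, file.path(out, "selection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stages <- c(stages, "select")

  ## 5. final model + scores
  genes_k <- ranking[seq_len(sel$chosen_k)]
  model <- fit_elastic_logistic(
    t(pooled[genes_k, split$train, drop = FALSE]), labels[split$train],
    mixing = config$mixing, folds = config$folds, repeats = config$repeats,
    rule = config$lambda_rule,
    rng_seed = substream_seed(config$rng_seed, "fit")
  )
  write_marker_model(model, file.path(out, "model.json"))
  scores <- predict_score(model, pooled, standardize = "training")
  utils::write.table(
    data.frame(sample = names(scores), score = unname(scores),
               partition = ifelse(seq_along(scores) %in% split$train,
                                  "train", "test")),
    file.path(out, "scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  test_auprc <- auprc(scores[split$test], labels[split$test])
  stages <- c(stages, "score")

  ## 6. survival
  is_case <- as.numeric(labels == "case")
  set.seed(substream_seed(config$rng_seed, "survive_strata"))
  strata <- sample(c("low", "intermediate", "high"), length(labels),
                   replace = TRUE)
  surv_tab <- make_survival(
    is_case, strata, beta = sim$truth$hazard_coefficient,
    rng_seed = substream_seed(config$rng_seed, "survive")
  )
  surv_tab$group <- split_by_score(scores, method = config$split_method,
                                   threshold = config$high_threshold)
  write_survival_tsv(surv_tab, file.path(out, "survival.tsv"))
  cox <- stratified_cox(surv_tab$time, surv_tab$event, surv_tab$group,
                        strata = surv_tab$stratum)
  jsonlite::write_json(unclass(cox), file.path(out, "cox.json"),
                       auto_unbox = TRUE, digits = NA)
  stages <- c(stages, "survive")

  manifest <- list(
    package = "markernet",
    version = as.character(utils::packageVersion("markernet")),
    r_version = as.character(getRversion()),
    rng_seed = config$rng_seed,
    config_hash = config_hash(config[setdiff(names(config), "out_dir")]),
    stages = stages,
    chosen_k = sel$chosen_k,
    test_auprc = test_auprc
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(
    network = sim$network, truth = sim$truth, cohorts = cohorts, de = de,
    weights = weights, propagation = prop, ranking = ranking,
    selection = sel, model = model, scores = scores,
    test_auprc = test_auprc, survival = surv_tab, cox = cox,
    manifest = manifest
  ))
}
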