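#' Two-group differential expression on log2 values
#'
#' Tests each gene for a mean difference between case and control samples
#' of one cohort. `log2fc` is the difference of class means (case minus
#' control) of the log2-scale values. Two tests are available:
#'
#' * `"welch"` (default): Welch two-sample t-test with Satterthwaite
#'   degrees of freedom, computed gene-wise.
#' * `"moderated"`: a lightweight moderated t that shrinks each gene's
#'   pooled variance toward the median pooled variance with prior degrees
#'   of freedom 4, adding 4 to the residual df. This stabilizes
#'   small-sample variance estimates in the spirit of empirical-Bayes
#'   moderation without its full machinery.
#'
#' P-values are two-sided; FDR is Benjamini-Hochberg over all genes of the
#' cohort ([bh_adjust()]); `is_deg` applies the strict cutoffs
#' `fdr < fdr_cut & |log2fc| > lfc_cut`.
#'
#' @param cohort A `cohort_expression` (list with `values`: gene x sample
#'   log2 matrix, and `labels`: "case"/"control" per sample).
#' @param method `"welch"` or `"moderated"`.
#' @param fdr_cut,lfc_cut DEG cutoffs (strict inequalities).
#'
#' @return A data frame (one row per gene): `gene`, `log2fc`, `p_value`,
#'   `fdr`, `is_deg`; class `differential_result`.
#' @export
differential_test <- function(cohort, method = c("welch", "moderated"),
                              fdr_cut = 0.05, lfc_cut = 1) {
  method <- match.arg(method)
  x <- cohort$values
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  if (anyDuplicated(rownames(x))) stop("gene symbols must be unique")
  if (any(!is.finite(x))) stop("expression values must be finite")
  labels <- cohort$labels
  case <- labels == "case"
  ctrl <- labels == "control"
  for (cls in c("case", "control")) {
    if (sum(labels == cls) < 2) {
      stop("class '", cls, "' has fewer than 2 samples")
    }
  }
  n1 <- sum(case); n2 <- sum(ctrl)
  x1 <- x[, case, drop = FALSE]
  x2 <- x[, ctrl, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  d <- m1 - m2

  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tstat <- d / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
  } else {
    df0 <- 4
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    s2_prior <- stats::median(s2[s2 > 0])
    if (!length(s2_prior) || is.na(s2_prior)) s2_prior <- 0
    s2_mod <- (df0 * s2_prior + (n1 + n2 - 2) * s2) / (df0 + n1 + n2 - 2)
    tstat <- d / sqrt(s2_mod * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(tstat), df0 + n1 + n2 - 2)
  }
  # degenerate variances: identical values give p = 1 (no evidence),
  # zero variance with a nonzero difference gives p = 0
  zero_se <- !is.finite(tstat) | is.nan(p)
  p[zero_se & d == 0] <- 1
  p[zero_se & d != 0] <- 0
  p <- pmin(pmax(p, 0), 1)

  fdr <- bh_adjust(p)
  res <- data.frame(
    gene = rownames(x),
    log2fc = unname(d),
    p_value = unname(p),
    fdr = unname(fdr),
    is_deg = unname(fdr < fdr_cut & abs(d) > lfc_cut),
    stringsAsFactors = FALSE
  )
  attr(res, "cohort_id") <- cohort$cohort_id
  attr(res, "method") <- method
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment, monotone-enforced and capped at 1, returned in
#' the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("all p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Filter differentially expressed genes at strict cutoffs
#'
#' @param result A `differential_result` from [differential_test()].
#' @param fdr_cut FDR cutoff (gene kept iff `fdr < fdr_cut`).
#' @param lfc_cut Fold-change cutoff (gene kept iff `|log2fc| > lfc_cut`).
#' @return Character vector of DEG symbols.
#' @export
filter_degs <- function(result, fdr_cut = 0.05, lfc_cut = 1) {
  stopifnot(all(c("gene", "log2fc", "fdr") %in% names(result)))
  result$gene[result$fdr < fdr_cut & abs(result$log2fc) > lfc_cut]
}

#' Build node weights from averaged |log2FC| across cohorts
#'
#' The union of per-cohort DEG sets, restricted to genes present in the
#' network, forms the support ("new information" genes). Each support
#' gene's weight is the mean of its |log2fc| over all cohorts in which it
#' was tested -- including cohorts where it did not pass the DEG cutoffs,
#' so that all measured evidence enters the average (set
#' `significant_only = TRUE` to average only over cohorts where the gene
#' was a DEG). Genes absent from a cohort are skipped in that cohort's
#' mean, never imputed. All non-support network genes get weight 0.
#'
#' @param results List of `differential_result` data frames (one per cohort).
#' @param deg_sets List of character vectors of DEGs, parallel to `results`.
#' @param network_nodes Character vector of network gene symbols.
#' @param significant_only Average |log2fc| only over cohorts where the gene
#'   passed the DEG filter (default `FALSE`).
#'
#' @return A `node_weighting`: list with `weights` (named vector over all
#'   `network_nodes`, zero off support) and `support`.
#' @export
build_weights <- function(results, deg_sets, network_nodes,
                          significant_only = FALSE) {
  stopifnot(length(results) >= 1, length(results) == length(deg_sets))
  deg_union <- sort(unique(unlist(deg_sets)))
  off_network <- setdiff(deg_union, network_nodes)
  if (length(off_network)) {
    message(length(off_network), " DEG(s) absent from the network excluded ",
            "from the support (e.g. ",
            paste(utils::head(off_network, 3), collapse = ", "), ")")
  }
  support <- intersect(deg_union, network_nodes)
  if (!length(support)) stop("no DEGs on network")

  acc <- matrix(0, nrow = length(support), ncol = 2,
                dimnames = list(support, c("sum", "n")))
  for (i in seq_along(results)) {
    res <- results[[i]]
    genes <- if (significant_only) intersect(support, deg_sets[[i]])
             else intersect(support, res$gene)
    lfc <- abs(res$log2fc[match(genes, res$gene)])
    keep <- !is.na(lfc)
    acc[genes[keep], "sum"] <- acc[genes[keep], "sum"] + lfc[keep]
    acc[genes[keep], "n"] <- acc[genes[keep], "n"] + 1
  }
  if (any(acc[, "n"] == 0)) {
    # can only happen with significant_only + inconsistent deg_sets
    drop <- rownames(acc)[acc[, "n"] == 0]
    warning(length(drop), " support gene(s) without any measured |log2fc| dropped")
    support <- setdiff(support, drop)
    if (!length(support)) stop("no DEGs on network")
    acc <- acc[support, , drop = FALSE]
  }
  weights <- stats::setNames(numeric(length(network_nodes)), network_nodes)
  weights[support] <- acc[, "sum"] / acc[, "n"]
  structure(list(weights = weights, support = support),
            class = "node_weighting")
}

#' @method print node_weighting
#' @export
print.node_weighting <- function(x, ...) {
  cat("Node weighting:", length(x$support), "support genes of",
      length(x$weights), "network genes; mean weight ",
      signif(mean(x$weights[x$support]), 4), "\n")
  invisible(x)
}
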