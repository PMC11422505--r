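#' Quality-control filter for single-cell count matrices
#'
#' Removes cells whose number of detected genes (count > 0) exceeds
#' `max_genes` or whose mitochondrial count fraction exceeds
#' `max_mito_frac`. Both inequalities are strict: a cell with exactly
#' `max_genes` detected genes, or exactly the mitochondrial cutoff, is
#' kept. Mitochondrial genes are recognized by symbol prefix
#' (case-insensitive `MT-` by default).
#'
#' @param counts Sparse or dense gene x cell matrix of nonnegative
#'   integer counts with gene symbols as row names and unique barcodes as
#'   column names.
#' @param max_genes Detected-gene ceiling (default 8000).
#' @param max_mito_frac Mitochondrial fraction ceiling (default 0.10).
#' @param mito_pattern Regex identifying mitochondrial gene symbols.
#'
#' @return List with `counts` (filtered matrix) and `report` (per-cell
#'   data frame: `barcode`, `n_genes`, `mito_frac`, `kept`).
#' @export
qc_filter <- function(counts, max_genes = 8000L, max_mito_frac = 0.10,
                      mito_pattern = "^MT-") {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  if (anyDuplicated(colnames(counts))) stop("cell barcodes must be unique")
  n_genes <- Matrix::colSums(counts > 0)
  totals <- Matrix::colSums(counts)
  mito <- grepl(mito_pattern, rownames(counts), ignore.case = TRUE)
  mito_counts <- if (any(mito)) {
    Matrix::colSums(counts[mito, , drop = FALSE])
  } else {
    numeric(ncol(counts))
  }
  mito_frac <- ifelse(totals > 0, mito_counts / totals, 0)
  kept <- !(n_genes > max_genes | mito_frac > max_mito_frac)
  if (!any(kept)) stop("all cells removed by QC filter")
  list(
    counts = counts[, kept, drop = FALSE],
    report = data.frame(
      barcode = colnames(counts),
      n_genes = as.integer(n_genes),
      mito_frac = as.numeric(mito_frac),
      kept = kept,
      row.names = NULL,
      stringsAsFactors = FALSE
    )
  )
}

#' Depth-normalize and log-transform single-cell counts
#'
#' Each cell's counts are divided by its total, multiplied by
#' `scale_factor` (counts per 10k by default), and transformed as
#' `log2(1 + x)`. The pseudo-count of 1 keeps zeros at zero. Before the
#' log, every cell's values sum exactly to `scale_factor`, so the result
#' is invariant to sequencing depth.
#'
#' @param counts Sparse gene x cell count matrix.
#' @param scale_factor Per-cell target total before the log (default 1e4).
#' @return Sparse gene x cell matrix of log2-normalized values.
#' @export
normalize_cells <- function(counts, scale_factor = 1e4) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    stop("cell(s) with zero total counts: ",
         paste(utils::head(colnames(counts)[totals == 0], 5), collapse = ", "))
  }
  m <- counts %*% Matrix::Diagonal(x = scale_factor / totals)
  m <- methods::as(m, "CsparseMatrix")
  m@x <- log2(1 + m@x)
  dimnames(m) <- dimnames(counts)
  m
}

#' Score cells with a marker model
#'
#' Applies [predict_score()] to a log-normalized cell matrix using the
#' within-dataset standardization policy (per-gene z-score over cells;
#' model genes absent from the matrix, or without variance across cells,
#' contribute 0 on the standardized scale). Cells with score above
#' `high_threshold` are flagged as high-score cells.
#'
#' @param model A `marker_model`.
#' @param normed Log-normalized gene x cell matrix (see
#'   [normalize_cells()]).
#' @param high_threshold Score above which a cell is called high
#'   (default 0.5).
#' @return Data frame: `barcode`, `score`, `high`.
#' @export
score_cells <- function(model, normed, high_threshold = 0.5) {
  sub <- normed[intersect(model$genes, rownames(normed)), , drop = FALSE]
  if (!nrow(sub)) stop("all model genes are missing from `normed`")
  scores <- predict_score(model, as.matrix(sub), standardize = "dataset")
  data.frame(
    barcode = colnames(normed),
    score = as.numeric(scores),
    high = as.numeric(scores) > high_threshold,
    stringsAsFactors = FALSE
  )
}

#' Per-cluster enrichment of high-score cells
#'
#' For each cluster, tests whether high-score cells are over-represented
#' relative to the overall high-score fraction, using the one-sided
#' hypergeometric tail P(X >= k) for k high cells among the cluster's n
#' cells drawn from N cells containing K high cells in total.
#'
#' @param high_flags Per-cell logical high-score flags.
#' @param clusters Per-cell cluster labels.
#' @param alpha Significance level for the `significant` column.
#' @return Data frame: `cluster`, `n`, `n_high`, `frac`, `p_value`,
#'   `significant`; empty clusters (levels without cells) are skipped with
#'   a warning.
#' @export
cluster_enrichment <- function(high_flags, clusters, alpha = 0.05) {
  stopifnot(is.logical(high_flags), length(high_flags) == length(clusters))
  clusters <- as.factor(clusters)
  empty <- levels(clusters)[tabulate(clusters, nbins = nlevels(clusters)) == 0]
  if (length(empty)) {
    warning("empty cluster(s) skipped: ", paste(empty, collapse = ", "))
    clusters <- droplevels(clusters)
  }
  if (nlevels(clusters) < 2) stop("need at least 2 non-empty clusters")
  N <- length(high_flags)
  K <- sum(high_flags)
  rows <- lapply(levels(clusters), function(cl) {
    idx <- clusters == cl
    n <- sum(idx)
    k <- sum(high_flags[idx])
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(cluster = cl, n = n, n_high = k, frac = k / n,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < alpha
  out
}
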