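#' Stratified train/test split
#'
#' Splits samples into disjoint, exhaustive train and test partitions,
#' preserving the class ratio. Per class, `round(train_frac * n_class)`
#' samples go to training (the default 0.75 reproduces a 28/183 vs 9/61
#' split of 37 cases and 244 controls); exact per-class training counts
#' can be forced with `train_counts`.
#'
#' @param labels Per-sample class labels (two classes).
#' @param train_frac Training fraction (per class, rounded).
#' @param train_counts Optional named vector of per-class training counts,
#'   overriding `train_frac`.
#' @param rng_seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, train_frac = 0.75, train_counts = NULL,
                             rng_seed = 1L) {
  classes <- unique(labels)
  if (length(classes) < 2) stop("both classes must be present")
  set.seed(rng_seed)
  train <- integer(0)
  for (cl in classes) {
    idx <- which(labels == cl)
    n_tr <- if (!is.null(train_counts)) {
      if (is.null(train_counts[[as.character(cl)]])) {
        stop("`train_counts` has no entry for class '", cl, "'")
      }
      train_counts[[as.character(cl)]]
    } else {
      round(train_frac * length(idx))
    }
    if (n_tr < 1 || n_tr > length(idx) - 1) {
      stop("class '", cl, "' would be empty in one partition")
    }
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' @keywords internal
stratified_foldid <- function(y, folds, max_attempts = 5L) {
  for (attempt in seq_len(max_attempts)) {
    foldid <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      foldid[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
    ok <- all(vapply(seq_len(folds), function(f) {
      length(unique(y[foldid == f])) == 2 && length(unique(y[foldid != f])) == 2
    }, logical(1)))
    if (ok) return(foldid)
  }
  stop("could not build stratified folds with both classes in every fold ",
       "after ", max_attempts, " attempts; reduce `folds`")
}

# Repeated stratified K-fold CV over a fixed lambda path. Returns, per
# repeat, the held-out response-scale predictions for every lambda.
#' @keywords internal
repeated_cv_path <- function(X, y, mixing, lambda_seq, folds, repeats) {
  n <- nrow(X)
  lapply(seq_len(repeats), function(r) {
    foldid <- stratified_foldid(y, folds)
    pred <- matrix(NA_real_, n, length(lambda_seq))
    for (f in seq_len(folds)) {
      idx <- which(foldid == f)
      fit <- glmnet::glmnet(X[-idx, , drop = FALSE], y[-idx],
                            family = "binomial", alpha = mixing,
                            lambda = lambda_seq, standardize = FALSE)
      pred[idx, ] <- stats::predict(fit, X[idx, , drop = FALSE],
                                    s = lambda_seq, type = "response")
    }
    list(foldid = foldid, pred = pred)
  })
}

#' @keywords internal
binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

#' @keywords internal
pick_lambda <- function(lambda_seq, dev_mean, dev_se, rule) {
  i_min <- which.min(dev_mean)
  if (rule == "min") return(i_min)
  thr <- dev_mean[i_min] + dev_se[i_min]
  # most regularized (largest lambda) within one SE of the minimum
  which(dev_mean <= thr)[1]
}

#' Fit an elastic-net logistic marker model by repeated cross-validation
#'
#' Fits penalized logistic regression (penalty
#' `lambda * (mixing * L1 + (1 - mixing)/2 * L2)`) along a lambda path
#' with glmnet, selects lambda by repeated stratified K-fold
#' cross-validated binomial deviance (`"1se"`: most regularized model
#' within one standard error of the minimum; `"min"`: the minimum), and
#' keeps the full-data path fit's coefficients at the chosen lambda.
#' Predictors are standardized internally on the training data; the
#' training means and standard deviations are stored in the model so that
#' new data can be scored consistently. Zero-variance genes are dropped
#' with a warning.
#'
#' @param x Sample x gene matrix of log2 expression (training data).
#' @param y Binary outcome: logical, 0/1, or "case"/"control".
#' @param mixing Elastic-net mixing in \[0, 1\] (1 = lasso).
#' @param lambda Optional decreasing lambda sequence; default lets glmnet
#'   build a path of `nlambda` values.
#' @param nlambda Path length when `lambda` is `NULL`.
#' @param folds,repeats Cross-validation folds and repetitions.
#' @param rule Lambda selection rule, `"1se"` or `"min"`.
#' @param rng_seed Integer seed for fold assignment.
#'
#' @return A `marker_model`: list with `genes`, `gene_means`, `gene_sds`,
#'   `intercept`, `coefficients`, `mixing`, `lambda`, `k`, `rule`, and the
#'   CV table `cv` (lambda, dev_mean, dev_se).
#' @export
fit_elastic_logistic <- function(x, y, mixing = 0.5, lambda = NULL,
                                 nlambda = 50L, folds = 10L, repeats = 10L,
                                 rule = c("1se", "min"), rng_seed = 1L) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  y <- normalize_labels(y)
  if (nrow(x) != length(y)) stop("`x` rows and `y` length differ")
  if (nrow(x) < folds) stop("need at least `folds` samples")
  if (length(unique(y)) < 2) stop("both classes must be present")

  mu <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) dropped: ",
            paste(utils::head(colnames(x)[sds == 0], 5), collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    mu <- mu[sds > 0]; sds <- sds[sds > 0]
    if (!ncol(x)) stop("no gene with positive variance")
  }
  Xs <- scale(x, center = mu, scale = sds)

  fit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = mixing,
                        lambda = lambda, nlambda = nlambda,
                        standardize = FALSE)
  lambda_seq <- fit$lambda

  set.seed(rng_seed)
  cv <- repeated_cv_path(Xs, y, mixing, lambda_seq, folds, repeats)
  # fold-level deviances, pooled over repeats
  dev_folds <- do.call(rbind, lapply(cv, function(rep) {
    t(vapply(seq_len(folds), function(f) {
      idx <- rep$foldid == f
      vapply(seq_along(lambda_seq), function(l) {
        binomial_deviance(y[idx], rep$pred[idx, l])
      }, numeric(1))
    }, numeric(length(lambda_seq))))
  }))
  dev_mean <- colMeans(dev_folds)
  dev_se <- apply(dev_folds, 2, stats::sd) / sqrt(nrow(dev_folds))
  i_star <- pick_lambda(lambda_seq, dev_mean, dev_se, rule)

  co <- as.vector(stats::coef(fit, s = lambda_seq[i_star]))
  structure(
    list(
      genes = colnames(x),
      gene_means = mu,
      gene_sds = sds,
      intercept = co[1],
      coefficients = stats::setNames(co[-1], colnames(x)),
      mixing = mixing,
      lambda = lambda_seq[i_star],
      k = ncol(x),
      rule = rule,
      cv = data.frame(lambda = lambda_seq, dev_mean = dev_mean,
                      dev_se = dev_se)
    ),
    class = "marker_model"
  )
}

#' @keywords internal
normalize_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- setdiff(unique(y), c("case", "control"))
    if (length(bad)) stop("character labels must be 'case'/'control'")
    y <- as.integer(y == "case")
  }
  if (is.logical(y)) y <- as.integer(y)
  stopifnot(all(y %in% c(0, 1)))
  y
}

#' Predict marker scores (case probabilities) for an expression matrix
#'
#' Standardizes each model gene and evaluates
#' `plogis(intercept + x . coefficients)` per sample. Two standardization
#' policies are supported: `"training"` uses the means/SDs stored in the
#' model (appropriate for held-out partitions of the training cohort);
#' `"dataset"` z-scores each gene within the supplied matrix (the only
#' policy valid across platforms, used for external datasets and cells).
#' Model genes absent from `expr` -- or with zero variance under the
#' dataset policy -- contribute 0 on the standardized scale.
#'
#' @param model A `marker_model`.
#' @param expr Gene x sample matrix on log2 scale.
#' @param standardize `"training"` or `"dataset"`.
#' @return Named numeric vector of scores in \[0, 1\], one per sample.
#' @export
predict_score <- function(model, expr,
                          standardize = c("training", "dataset")) {
  standardize <- match.arg(standardize)
  stopifnot(inherits(model, "marker_model"), is.matrix(expr),
            !is.null(rownames(expr)))
  present <- intersect(model$genes, rownames(expr))
  if (!length(present)) stop("all model genes are missing from `expr`")

  Z <- matrix(0, nrow = length(model$genes), ncol = ncol(expr),
              dimnames = list(model$genes, colnames(expr)))
  sub <- expr[present, , drop = FALSE]
  if (standardize == "training") {
    Z[present, ] <- (sub - model$gene_means[present]) / model$gene_sds[present]
  } else {
    m <- rowMeans(sub)
    s <- apply(sub, 1, stats::sd)
    ok <- s > 0
    Z[present[ok], ] <- (sub[ok, , drop = FALSE] - m[ok]) / s[ok]
  }
  eta <- model$intercept + as.vector(crossprod(Z, model$coefficients))
  stats::setNames(stats::plogis(eta), colnames(expr))
}

#' Area under the precision-recall curve (average precision)
#'
#' Computes average precision: the step-wise sum of precision at each
#' recall increment, with tied scores grouped so the result does not
#' depend on the order of equal-scored samples. Constant scores give the
#' positive-class prevalence.
#'
#' @param scores Numeric prediction scores (higher = more case-like).
#' @param labels Binary labels (1/TRUE/"case" = positive).
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  y <- normalize_labels(labels)
  stopifnot(length(scores) == length(y))
  n_pos <- sum(y == 1)
  if (n_pos == 0 || n_pos == length(y)) {
    stop("need at least one positive and one negative label")
  }
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; sc <- scores[ord]
  # indices where a tie group of equal scores ends
  grp_end <- c(which(sc[-length(sc)] != sc[-1]), length(sc))
  tp <- cumsum(y)[grp_end]
  precision <- tp / grp_end
  recall_inc <- diff(c(0, tp)) / n_pos
  sum(recall_inc * precision)
}

#' @keywords internal
choose_k_rule <- function(k_grid, auprc_mean, auprc_se) {
  i_best <- which.max(auprc_mean)
  thr <- auprc_mean[i_best] - auprc_se[i_best]
  k_grid[which(auprc_mean >= thr)[1]]
}

#' Select the marker panel size over a top-k grid
#'
#' For each k in `k_grid`, takes the top k propagation-ranked genes
#' present in `expr` and evaluates an elastic-net logistic model by
#' repeated stratified K-fold cross-validation: within the CV, lambda is
#' chosen by the deviance rule, and the held-out AUPRC at that lambda is
#' recorded per fold. The chosen k is the smallest grid value whose mean
#' CV AUPRC is within one standard error of the best mean -- the model
#' economy counterpart of the 1-SE rule. Set `chosen_k` to override
#' manually.
#'
#' @param ranking Character vector of genes in propagation rank order.
#' @param expr Gene x sample training expression matrix (log2 scale).
#' @param labels Per-sample binary labels.
#' @param k_grid Candidate panel sizes (default 10, 20, ..., 100).
#' @param mixing,folds,repeats,rule,rng_seed Passed to the CV machinery
#'   (see [fit_elastic_logistic()]).
#' @param chosen_k Optional manual override of the selected k.
#'
#' @return A `cv_selection`: list with `table` (k, auprc_mean, auprc_se,
#'   lambda), `chosen_k`, `rule`.
#' @export
select_k <- function(ranking, expr, labels, k_grid = seq(10L, 100L, 10L),
                     mixing = 0.5, folds = 10L, repeats = 10L,
                     rule = c("1se", "min"), rng_seed = 1L,
                     chosen_k = NULL) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  y <- normalize_labels(labels)
  avail <- ranking[ranking %in% rownames(expr)]
  if (max(k_grid) > length(avail)) {
    stop("max of `k_grid` (", max(k_grid), ") exceeds the ", length(avail),
         " ranked genes available in `expr`")
  }
  rows <- lapply(k_grid, function(k) {
    genes_k <- avail[seq_len(k)]
    x <- t(expr[genes_k, , drop = FALSE])
    sds <- apply(x, 2, stats::sd)
    x <- x[, sds > 0, drop = FALSE]
    Xs <- scale(x)
    fit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = mixing,
                          nlambda = 50L, standardize = FALSE)
    lambda_seq <- fit$lambda
    set.seed(substream_seed(rng_seed, paste0("select_k", k)))
    cv <- repeated_cv_path(Xs, y, mixing, lambda_seq, folds, repeats)
    dev_folds <- do.call(rbind, lapply(cv, function(rep) {
      t(vapply(seq_len(folds), function(f) {
        idx <- rep$foldid == f
        vapply(seq_along(lambda_seq), function(l) {
          binomial_deviance(y[idx], rep$pred[idx, l])
        }, numeric(1))
      }, numeric(length(lambda_seq))))
    }))
    dev_mean <- colMeans(dev_folds)
    dev_se <- apply(dev_folds, 2, stats::sd) / sqrt(nrow(dev_folds))
    i_star <- pick_lambda(lambda_seq, dev_mean, dev_se, rule)
    fold_auprc <- unlist(lapply(cv, function(rep) {
      vapply(seq_len(folds), function(f) {
        idx <- rep$foldid == f
        auprc(rep$pred[idx, i_star], y[idx])
      }, numeric(1))
    }))
    data.frame(k = k, auprc_mean = mean(fold_auprc),
               auprc_se = stats::sd(fold_auprc) / sqrt(length(fold_auprc)),
               lambda = lambda_seq[i_star])
  })
  tab <- do.call(rbind, rows)
  k_star <- if (is.null(chosen_k)) {
    choose_k_rule(tab$k, tab$auprc_mean, tab$auprc_se)
  } else {
    if (!chosen_k %in% k_grid) stop("`chosen_k` must be in `k_grid`")
    chosen_k
  }
  structure(list(table = tab, chosen_k = k_star, rule = rule),
            class = "cv_selection")
}

#' Write / read a marker model as JSON
#'
#' Serialization keeps full numeric precision, so a written-then-read
#' model scores identically to the original.
#'
#' @param model A `marker_model`.
#' @param path File path.
#' @return `read_marker_model` returns the `marker_model`;
#'   `write_marker_model` returns `path` invisibly.
#' @export
write_marker_model <- function(model, path) {
  stopifnot(inherits(model, "marker_model"))
  obj <- model[c("genes", "gene_means", "gene_sds", "intercept",
                 "coefficients", "mixing", "lambda", "k", "rule")]
  obj$package_version <- as.character(utils::packageVersion("markernet"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_marker_model
#' @export
read_marker_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      genes = obj$genes,
      gene_means = stats::setNames(as.numeric(obj$gene_means), obj$genes),
      gene_sds = stats::setNames(as.numeric(obj$gene_sds), obj$genes),
      intercept = obj$intercept,
      coefficients = stats::setNames(as.numeric(obj$coefficients), obj$genes),
      mixing = obj$mixing,
      lambda = obj$lambda,
      k = obj$k,
      rule = obj$rule
    ),
    class = "marker_model"
  )
}

#' @method print marker_model
#' @export
print.marker_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat("Elastic-net logistic marker model: k =", x$k, "genes (", nz,
      "nonzero ), mixing =", x$mixing, ", lambda =", signif(x$lambda, 4), "\n")
  invisible(x)
}

#' @method print cv_selection
#' @export
print.cv_selection <- function(x, ...) {
  cat("Panel-size selection (", x$rule, " rule): chosen k =", x$chosen_k, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
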