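#' Map Gleason scores to pathological grade strata
#'
#' Gleason 6 maps to low grade, 7 to intermediate, and 8-10 to high.
#' Missing values pass through as `NA` (callers drop them with a logged
#' count); any other value is an error.
#'
#' @param gleason Integer vector of Gleason scores in 6..10 (NA allowed).
#' @return Factor with levels low < intermediate < high.
#' @export
gleason_to_grade <- function(gleason) {
  ok <- is.na(gleason) | (gleason %in% 6:10)
  if (!all(ok)) {
    stop("Gleason score(s) outside 6..10: ",
         paste(unique(gleason[!ok]), collapse = ", "))
  }
  map <- c(`6` = "low", `7` = "intermediate", `8` = "high", `9` = "high",
           `10` = "high")
  factor(unname(map[as.character(gleason)]),
         levels = c("low", "intermediate", "high"))
}

#' Dichotomize marker scores into low/high groups
#'
#' `"median"` labels a sample high iff its score strictly exceeds the
#' median (ties go to low); `"threshold"` uses a fixed cutoff with the
#' same strict rule.
#'
#' @param scores Numeric scores.
#' @param method `"median"` or `"threshold"`.
#' @param threshold Cutoff for the threshold method.
#' @return Factor with levels low, high.
#' @export
split_by_score <- function(scores, method = c("median", "threshold"),
                           threshold = NULL) {
  method <- match.arg(method)
  if (length(unique(scores)) < 2) {
    stop("all scores identical; cannot split into groups")
  }
  cut <- if (method == "median") {
    stats::median(scores)
  } else {
    if (is.null(threshold)) stop("`threshold` required for threshold method")
    threshold
  }
  factor(ifelse(scores > cut, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier product-limit survival estimate
#'
#' Computes S(t) = prod over event times t_i <= t of (1 - d_i / n_i) per
#' group, with right-censored samples contributing to the risk sets up to
#' their censoring time. With no events the estimate is identically 1
#' (and the returned table has no rows for that group).
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (1 = observed, 0 = censored).
#' @param group Optional per-sample group labels (single group if NULL).
#' @return Data frame with one row per distinct event time per group:
#'   `group`, `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (any(time <= 0)) stop("all times must be > 0")
  event <- as.integer(event)
  if (is.null(group)) group <- rep("all", length(time))
  if (length(time) != length(event) || length(time) != length(group)) {
    stop("`time`, `event`, `group` must have equal length")
  }
  out <- lapply(unique(group), function(gr) {
    idx <- group == gr
    if (!any(idx)) stop("empty group: ", gr)
    t_g <- time[idx]; e_g <- event[idx]
    ut <- sort(unique(t_g[e_g == 1]))
    if (!length(ut)) return(NULL)
    n_risk <- vapply(ut, function(t0) sum(t_g >= t0), numeric(1))
    d <- vapply(ut, function(t0) sum(t_g == t0 & e_g == 1), numeric(1))
    data.frame(group = gr, time = ut, n_risk = n_risk, n_event = d,
               survival = cumprod(1 - d / n_risk),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(group = character(0), time = numeric(0),
                      n_risk = numeric(0), n_event = numeric(0),
                      survival = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' (Stratified) log-rank test between score groups
#'
#' Observed-minus-expected event counts summed over (strata x) event
#' times; the statistic is chi-squared with (groups - 1) degrees of
#' freedom under the null.
#'
#' @param time,event,group As in [km_estimate()]; at least two groups and
#'   one event required.
#' @param strata Optional stratification labels (e.g. pathological grade).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(time, event, group, strata = NULL) {
  event <- as.integer(event)
  if (length(unique(group)) < 2) stop("need at least two groups")
  if (sum(event) == 0) stop("no events observed")
  df <- data.frame(time = time, event = event, group = group)
  fml <- survival::Surv(time, event) ~ group
  if (!is.null(strata)) {
    df$stratum <- strata
    fml <- survival::Surv(time, event) ~ group + survival::strata(stratum)
  }
  sd_fit <- survival::survdiff(fml, data = df)
  dof <- length(unique(group)) - 1
  list(
    statistic = unname(sd_fit$chisq),
    df = dof,
    p_value = unname(stats::pchisq(sd_fit$chisq, dof, lower.tail = FALSE))
  )
}

#' Stratified Cox proportional-hazards fit
#'
#' Maximizes the stratified Cox partial likelihood (Breslow tie handling
#' by default): each stratum keeps its own baseline hazard and risk sets,
#' and a single covariate effect is shared across strata. The covariate
#' may be a two-level factor (hazard ratio of high vs the low reference)
#' or numeric (hazard ratio per unit, e.g. per unit marker score).
#' Complete separation surfaces as the usual monotone-likelihood warning
#' with a bounded estimate, never silently.
#'
#' @param time,event Follow-up times and event indicators.
#' @param covariate Two-level factor (reference = "low" when present) or
#'   numeric vector.
#' @param strata Optional stratification labels; NULL fits an ordinary
#'   (single-stratum) Cox model.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return A `cox_result`: list with `log_hr`, `hr`, `se`, `ci95`,
#'   `p_wald`, `p_logrank` (score test), `reference_group`, `n`,
#'   `n_event`.
#' @export
stratified_cox <- function(time, event, covariate, strata = NULL,
                           ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  event <- as.integer(event)
  if (is.character(covariate)) covariate <- factor(covariate)
  if (is.factor(covariate)) {
    covariate <- droplevels(covariate)
    if (nlevels(covariate) < 2) stop("covariate is constant")
    if ("low" %in% levels(covariate)) {
      covariate <- stats::relevel(covariate, ref = "low")
    }
    reference <- levels(covariate)[1]
  } else {
    if (stats::var(covariate) == 0) stop("covariate is constant")
    reference <- NA_character_
  }
  df <- data.frame(time = time, event = event, x = covariate)
  fml <- survival::Surv(time, event) ~ x
  if (!is.null(strata)) {
    df$stratum <- strata
    fml <- survival::Surv(time, event) ~ x + survival::strata(stratum)
  }
  fit <- survival::coxph(fml, data = df, ties = ties)
  s <- summary(fit)
  log_hr <- unname(fit$coefficients[1])
  se <- unname(sqrt(fit$var[1, 1]))
  structure(
    list(
      log_hr = log_hr,
      hr = exp(log_hr),
      se = se,
      ci95 = c(lo = exp(log_hr - 1.96 * se), hi = exp(log_hr + 1.96 * se)),
      p_wald = unname(s$coefficients[1, "Pr(>|z|)"]),
      p_logrank = unname(s$sctest["pvalue"]),
      reference_group = reference,
      n = fit$n,
      n_event = fit$nevent
    ),
    class = "cox_result"
  )
}

#' @method print cox_result
#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Stratified Cox: HR = %.3f (95%% CI %.3f-%.3f), log-rank p = %.3g\n",
              x$hr, x$ci95[["lo"]], x$ci95[["hi"]], x$p_logrank))
  if (!is.na(x$reference_group)) {
    cat("Reference group:", x$reference_group, "\n")
  }
  invisible(x)
}
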