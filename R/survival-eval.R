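# Risk-score evaluation: time-dependent ROC with Youden cutoff, Kaplan-Meier
# with log-rank (overall and per subtype), clinical association tests and
# uni-/multivariate Cox of clinical covariates.

#' Time-dependent ROC at a fixed horizon
#'
#' Uses the cumulative-case / dynamic-control definition: cases are samples
#' with an event at or before the horizon, controls are samples still under
#' observation past it; samples censored at or before the horizon are
#' excluded (no inverse-probability weighting). The AUC is the Mann-Whitney
#' probability `P(score_case > score_control)` with ties counted 1/2. The
#' optimal cutoff maximizes the Youden index `TPR - FPR` over all thresholds
#' (a sample is called high-risk when `score > cutoff`); ties are broken
#' toward the lower threshold.
#'
#' @param scores Named numeric risk scores.
#' @param time,event Survival time and 0/1 event indicator aligned with
#'   `scores` (same length and order, or named and matched by name).
#' @param horizon Evaluation horizon in the same unit as `time`.
#' @return Object of class `TimeROC`: list with `auc`, `cutoff`, `horizon`,
#'   `roc` (data frame `threshold`, `fpr`, `tpr`), `n_case`, `n_control`,
#'   `n_excluded`.
#' @export
time_dependent_roc <- function(scores, time, event, horizon) {
  stopifnot(length(time) == length(scores), length(event) == length(scores))
  is_case <- event == 1 & time <= horizon
  is_control <- time > horizon
  n1 <- sum(is_case); n0 <- sum(is_control)
  if (n1 == 0 || n0 == 0)
    stop("need >= 1 case and >= 1 control at horizon ", horizon,
         " (cases = ", n1, ", controls = ", n0, ")")
  cs <- scores[is_case]; ct <- scores[is_control]
  r <- rank(c(cs, ct))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  thr <- c(-Inf, sort(unique(c(cs, ct))))
  tpr <- vapply(thr, function(c) mean(cs > c), numeric(1))
  fpr <- vapply(thr, function(c) mean(ct > c), numeric(1))
  youden <- tpr - fpr
  # ties (up to floating-point noise) break toward the lower threshold
  best <- which(youden >= max(youden) - 1e-9)[1]
  structure(list(auc = auc, cutoff = thr[best], horizon = horizon,
                 roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 n_case = n1, n_control = n0,
                 n_excluded = length(scores) - n1 - n0),
            class = "TimeROC")
}

#' @method print TimeROC
#' @export
print.TimeROC <- function(x, ...) {
  cat(sprintf("TimeROC at t = %g: AUC = %.4f, Youden cutoff = %.4g (%d cases, %d controls, %d excluded)\n",
              x$horizon, x$auc, x$cutoff, x$n_case, x$n_control, x$n_excluded))
  invisible(x)
}

km_logrank_one <- function(group, time, event) {
  group <- droplevels(factor(group))
  if (nlevels(group) < 2 || min(table(group)) == 0) return(NULL)
  sf <- survival::survfit(survival::Surv(time, event) ~ group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  curve <- data.frame(group = rep(sub("^group=", "", names(sf$strata)), sf$strata),
                      time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                      surv = sf$surv)
  df <- length(sd$n) - 1
  list(curve = curve, chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE),
       n = table(group))
}

#' Kaplan-Meier comparison with log-rank test
#'
#' Product-limit estimator per risk group and the two-group log-rank
#' statistic (hypergeometric-variance form, 1 df for two groups). When
#' `strata` is supplied (e.g. molecular subtype labels) the analysis runs
#' independently within each stratum; a stratum in which one group is empty
#' is skipped with a warning rather than failing the whole comparison.
#'
#' @param group Factor (or coercible) of risk groups per sample.
#' @param time,event Survival time and 0/1 event status.
#' @param strata Optional factor of stratum labels (same length).
#' @return Object of class `KMComparison`. Without strata: list with
#'   `curve`, `chisq`, `p`, `n`. With strata: named list of such lists, one
#'   per evaluated stratum.
#' @export
km_logrank <- function(group, time, event, strata = NULL) {
  if (is.null(strata)) {
    res <- km_logrank_one(group, time, event)
    if (is.null(res)) stop("both groups must be nonempty")
    return(structure(res, class = "KMComparison"))
  }
  strata <- factor(strata)
  out <- list()
  for (lv in levels(strata)) {
    idx <- which(strata == lv)
    res <- km_logrank_one(group[idx], time[idx], event[idx])
    if (is.null(res)) {
      warning("stratum '", lv, "' skipped: a risk group is empty")
      next
    }
    out[[lv]] <- res
  }
  structure(out, class = c("KMComparison", "list"), stratified = TRUE)
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Compare risk scores across clinical variable levels
#'
#' For each clinical variable, risk scores are compared across its levels
#' with a two-sided Wilcoxon rank-sum test (2 levels) or a Kruskal-Wallis
#' test (> 2 levels). Variables with fewer than two levels carrying at least
#' two samples each are skipped with a warning. Significance stars follow
#' the usual `<0.001` / `<0.01` / `<0.05` convention.
#'
#' @param scores Named numeric risk scores.
#' @param clin A `ClinicalTable` (matched to `scores` on `sample`).
#' @param variables Character vector of clinical column names to test.
#' @return Data frame `variable`, `test`, `n_levels`, `p`, `stars`.
#' @export
group_vs_clinical_tests <- function(scores, clin, variables) {
  idx <- match(names(scores), clin$sample)
  if (anyNA(idx)) stop("scores contain samples absent from the clinical table")
  rows <- list()
  for (v in variables) {
    if (!v %in% colnames(clin)) { warning("variable '", v, "' not in clinical table; skipped"); next }
    lev <- factor(clin[[v]][idx])
    ok <- !is.na(lev) & !is.na(scores)
    lev <- droplevels(lev[ok]); sc <- scores[ok]
    counts <- table(lev)
    usable <- names(counts)[counts >= 2]
    if (length(usable) < 2) {
      warning("variable '", v, "' degenerate (fewer than 2 usable levels); skipped")
      next
    }
    keep <- lev %in% usable
    lev <- droplevels(lev[keep]); sc <- sc[keep]
    if (nlevels(lev) == 2) {
      p <- suppressWarnings(stats::wilcox.test(sc ~ lev)$p.value)
      test <- "wilcoxon"
    } else {
      p <- stats::kruskal.test(sc, lev)$p.value
      test <- "kruskal-wallis"
    }
    rows[[v]] <- data.frame(variable = v, test = test, n_levels = nlevels(lev),
                            p = p, stars = significance_stars(p),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) res <- data.frame(variable = character(), test = character(),
                                      n_levels = integer(), p = numeric(),
                                      stars = character())
  rownames(res) <- NULL
  res
}

cox_report_row <- function(fit, terms) {
  sm <- summary(fit)
  data.frame(covariate = terms,
             hr = unname(sm$conf.int[terms, "exp(coef)"]),
             ci_lower = unname(sm$conf.int[terms, "lower .95"]),
             ci_upper = unname(sm$conf.int[terms, "upper .95"]),
             p = unname(sm$coefficients[terms, "Pr(>|z|)"]),
             stringsAsFactors = FALSE)
}

#' Univariate and multivariate Cox models of risk score and clinical covariates
#'
#' Fits one univariate Cox model per covariate (risk score first) and one
#' joint multivariate model containing all of them. Covariates must already
#' be numerically coded (binary/ordinal); covariates aliased in the joint
#' model (exact collinearity) are dropped in listing order with a warning.
#' A warning is emitted when events are fewer than ten per covariate.
#'
#' @param scores Named numeric risk scores.
#' @param clin A `ClinicalTable`.
#' @param covariates Character vector of numerically coded clinical columns.
#' @return Object of class `ClinicalCoxReport`: list with data frames
#'   `univariate` and `multivariate` (columns `covariate`, `hr`, `ci_lower`,
#'   `ci_upper`, `p`) and `dropped` (aliased covariates).
#' @export
clinical_cox <- function(scores, clin, covariates) {
  idx <- match(names(scores), clin$sample)
  if (anyNA(idx)) stop("scores contain samples absent from the clinical table")
  df <- data.frame(time = clin$time[idx], event = clin$event[idx],
                   risk_score = as.numeric(scores))
  for (v in covariates) {
    if (!v %in% colnames(clin)) stop("covariate '", v, "' not in clinical table")
    col <- clin[[v]][idx]
    if (!is.numeric(col)) stop("covariate '", v, "' must be numerically coded")
    df[[v]] <- col
  }
  vars <- c("risk_score", setdiff(covariates, "risk_score"))
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  n_event <- sum(df$event)
  if (n_event < 10 * length(vars))
    warning("only ", n_event, " events for ", length(vars),
            " covariates (< 10 per covariate)")
  uni <- do.call(rbind, lapply(vars, function(v) {
    fit <- survival::coxph(stats::reformulate(v, "survival::Surv(time, event)"),
                           data = df, ties = "efron")
    cox_report_row(fit, v)
  }))
  keep <- vars
  dropped <- character()
  repeat {
    fit <- survival::coxph(stats::reformulate(keep, "survival::Surv(time, event)"),
                           data = df, ties = "efron")
    cf <- stats::coef(fit)
    if (!anyNA(cf)) break
    bad <- names(cf)[which(is.na(cf))[1]]
    warning("covariate '", bad, "' collinear in the joint model; dropped")
    dropped <- c(dropped, bad)
    keep <- setdiff(keep, bad)
  }
  multi <- cox_report_row(fit, keep)
  rownames(uni) <- rownames(multi) <- NULL
  structure(list(univariate = uni, multivariate = multi, dropped = dropped),
            class = "ClinicalCoxReport")
}

#' Harrell's concordance index of a risk score
#'
#' Probability that, of two comparable samples, the one with the higher risk
#' score fails earlier; 0.5 means no discrimination. Computed via
#' [survival::concordance] with `reverse = TRUE` (higher score = higher risk).
#'
#' @param scores Numeric risk scores.
#' @param time,event Survival time and 0/1 event status.
#' @return The concordance index (scalar).
#' @export
harrell_cindex <- function(scores, time, event) {
  fit <- survival::concordance(survival::Surv(time, event) ~ scores, reverse = TRUE)
  unname(fit$concordance)
}
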