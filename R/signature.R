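# Pair selection: uni-Cox screen -> Lasso-Cox (10-fold CV) -> stepwise
# multivariate Cox, then the linear risk score sum(beta_i * S_i).

align_pairs_clinical <- function(pm, clinical) {
  stopifnot(inherits(pm, "PairIndicatorMatrix"), inherits(clinical, "ClinicalTable"))
  clin <- clinical[clinical$eligible, , drop = FALSE]
  samples <- intersect(colnames(pm$S), clin$sample)
  if (length(samples) == 0) stop("no eligible samples shared by pair matrix and clinical table")
  clin <- clin[match(samples, clin$sample), , drop = FALSE]
  list(S = pm$S[, samples, drop = FALSE],
       time = clin$time, event = clin$event, samples = samples, clin = clin)
}

#' Univariate Cox screen of pair indicators
#'
#' Fits one single-covariate Cox proportional-hazards model per pair (Efron
#' tie handling) on the eligible samples shared with the clinical table and
#' reports the Wald test. Pairs that are constant among those samples carry
#' no information and are skipped; fits that fail or do not converge are
#' dropped with a warning.
#'
#' @param pm A `PairIndicatorMatrix`.
#' @param clinical A `ClinicalTable` (only `eligible` rows are used).
#' @param p_max Wald p-value threshold for the `kept` flag (default 0.05,
#'   strict).
#' @return Data frame of class `UniCoxResult`: `pair`, `beta`, `hr`,
#'   `ci_lower`, `ci_upper`, `z`, `p`, `kept`; attribute `n_skipped`.
#' @export
unicox_screen <- function(pm, clinical, p_max = 0.05) {
  al <- align_pairs_clinical(pm, clinical)
  if (sum(al$event) < 10)
    stop("need >= 10 events for the univariate Cox screen (got ", sum(al$event), ")")
  y <- survival::Surv(al$time, al$event)
  rows <- vector("list", nrow(al$S))
  n_skipped <- 0L
  for (i in seq_len(nrow(al$S))) {
    s <- al$S[i, ]
    if (length(unique(s)) < 2) { n_skipped <- n_skipped + 1L; next }
    fit <- tryCatch(survival::coxph(y ~ s, ties = "efron"),
                    error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || !is.finite(stats::coef(fit))) {
      warning("pair ", rownames(al$S)[i], " dropped (Cox fit failed or diverged)")
      next
    }
    sm <- summary(fit)
    rows[[i]] <- data.frame(
      pair = rownames(al$S)[i],
      beta = unname(stats::coef(fit)),
      hr = unname(sm$conf.int[1, "exp(coef)"]),
      ci_lower = unname(sm$conf.int[1, "lower .95"]),
      ci_upper = unname(sm$conf.int[1, "upper .95"]),
      z = unname(sm$coefficients[1, "z"]),
      p = unname(sm$coefficients[1, "Pr(>|z|)"]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) res <- data.frame(pair = character(), beta = numeric(),
                                      hr = numeric(), ci_lower = numeric(),
                                      ci_upper = numeric(), z = numeric(),
                                      p = numeric())
  res$kept <- res$p < p_max
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  attr(res, "p_max") <- p_max
  class(res) <- c("UniCoxResult", "data.frame")
  res
}

#' Lasso-penalized Cox selection with cross-validation
#'
#' L1-penalized Cox regression over a lambda path via [glmnet::cv.glmnet]
#' with `n_folds`-fold cross-validated partial-likelihood deviance. Fold
#' assignment is deterministic given `seed` and stratified by event status so
#' every fold sees events. The default rule takes `lambda.min`; when the
#' active set at the chosen lambda is empty the smallest lambda with at least
#' one nonzero coefficient along the path is used instead (with a message).
#'
#' @param pm A `PairIndicatorMatrix`.
#' @param clinical A `ClinicalTable`.
#' @param pairs Candidate pair IDs (>= 2), typically uni-Cox survivors.
#' @param n_folds Number of CV folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @param lambda_rule `"min"` (default) or `"1se"`.
#' @return List of class `LassoCoxResult`: `selected` (pair IDs with nonzero
#'   coefficients), `beta` (their penalized coefficients), `lambda`, `cvfit`.
#' @export
lasso_cox_select <- function(pm, clinical, pairs, n_folds = 10, seed = 1,
                             lambda_rule = c("min", "1se")) {
  lambda_rule <- match.arg(lambda_rule)
  if (length(pairs) < 2) stop("need >= 2 candidate pairs for the Lasso")
  al <- align_pairs_clinical(subset_pairs(pm, pairs), clinical)
  if (sum(al$event) < n_folds)
    stop("need >= ", n_folds, " events for ", n_folds, "-fold CV")
  x <- t(al$S)
  y <- survival::Surv(al$time, al$event)
  foldid <- integer(nrow(x))
  set.seed(seed)
  for (ev in c(0, 1)) {
    idx <- which(al$event == ev)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  cvfit <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                             type.measure = "deviance")
  lam <- if (lambda_rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  b <- as.vector(stats::coef(cvfit, s = lam))
  names(b) <- colnames(x)
  if (all(b == 0)) {
    nz <- cvfit$glmnet.fit$df > 0
    if (!any(nz)) stop("no lambda on the path yields a nonzero coefficient")
    lam <- max(cvfit$glmnet.fit$lambda[nz])
    message("empty active set at lambda.", lambda_rule,
            "; falling back to largest lambda with a nonzero coefficient")
    b <- as.vector(stats::coef(cvfit, s = lam))
    names(b) <- colnames(x)
  }
  structure(list(selected = names(b)[b != 0], beta = b[b != 0],
                 lambda = lam, lambda_rule = lambda_rule, seed = seed,
                 cvfit = cvfit),
            class = "LassoCoxResult")
}

#' Stepwise multivariate Cox refinement and final signature
#'
#' Starting from the full candidate set, performs bidirectional stepwise
#' selection minimizing AIC over the multivariate Cox model
#' ([MASS::stepAIC]); the final coefficients come from the refitted
#' multivariate model. Duplicate (identical) indicator rows are collapsed to
#' one representative before fitting, and covariates aliased in the full
#' model are dropped with a warning. An empty final model is an error: the
#' signature cannot be established.
#'
#' @param pm A `PairIndicatorMatrix`.
#' @param clinical A `ClinicalTable`.
#' @param candidates Candidate pair IDs (nonempty), typically Lasso-selected.
#' @param provenance Optional list recording the selection history
#'   (uni-Cox survivors, Lasso selection, lambda, seed); stored verbatim.
#' @return Object of class `SignatureModel`: list with `pairs` (retained pair
#'   IDs), `beta` (named multivariate Cox coefficients), `hr`, `ci_lower`,
#'   `ci_upper`, `p` (Wald, per pair), `fit` (the `coxph` object) and
#'   `provenance`.
#' @export
stepwise_multicox <- function(pm, clinical, candidates, provenance = NULL) {
  if (length(candidates) == 0) stop("no candidate pairs for the multivariate model")
  al <- align_pairs_clinical(subset_pairs(pm, candidates), clinical)
  if (sum(al$event) == 0) stop("no events among eligible samples")
  S <- al$S
  dup <- duplicated(as.data.frame(S))
  if (any(dup)) {
    message("dropping ", sum(dup), " duplicated indicator row(s) before stepwise fit")
    S <- S[!dup, , drop = FALSE]
  }
  const <- apply(S, 1, function(s) length(unique(s)) < 2)
  if (any(const)) {
    message("dropping ", sum(const), " constant indicator row(s)")
    S <- S[!const, , drop = FALSE]
  }
  if (nrow(S) == 0) stop("signature cannot be established: no usable candidates")
  ids <- rownames(S)
  vn <- paste0("P", seq_along(ids))
  df <- data.frame(time = al$time, event = al$event, t(S))
  colnames(df) <- c("time", "event", vn)
  full <- survival::coxph(survival::Surv(time, event) ~ ., data = df, ties = "efron")
  cf <- stats::coef(full)
  if (anyNA(cf)) {
    warning("dropping ", sum(is.na(cf)), " aliased covariate(s) from the full model")
    keep_vn <- names(cf)[!is.na(cf)]
    df <- df[, c("time", "event", keep_vn)]
    ids <- ids[match(keep_vn, vn)]
    vn <- keep_vn
    full <- survival::coxph(survival::Surv(time, event) ~ ., data = df, ties = "efron")
  }
  step_fit <- suppressWarnings(
    MASS::stepAIC(full, direction = "both", trace = 0,
                  scope = list(lower = ~ 1, upper = stats::formula(full))))
  cf <- stats::coef(step_fit)
  if (length(cf) == 0)
    stop("signature cannot be established: stepwise selection removed every pair")
  sm <- summary(step_fit)
  kept_ids <- ids[match(names(cf), vn)]
  beta <- unname(cf)
  names(beta) <- kept_ids
  structure(list(pairs = kept_ids, beta = beta,
                 hr = stats::setNames(unname(sm$conf.int[, "exp(coef)"]), kept_ids),
                 ci_lower = stats::setNames(unname(sm$conf.int[, "lower .95"]), kept_ids),
                 ci_upper = stats::setNames(unname(sm$conf.int[, "upper .95"]), kept_ids),
                 p = stats::setNames(unname(sm$coefficients[, "Pr(>|z|)"]), kept_ids),
                 fit = step_fit,
                 provenance = provenance),
            class = "SignatureModel")
}

#' @method print SignatureModel
#' @export
print.SignatureModel <- function(x, ...) {
  cat("SignatureModel:", length(x$pairs), "pairs\n")
  print(data.frame(pair = x$pairs, beta = unname(x$beta), hr = unname(x$hr),
                   p = unname(x$p)))
  invisible(x)
}

#' Linear risk score of a signature
#'
#' `score(sample) = sum_i beta_i * S_i(sample)` over the signature pairs.
#' Deterministic; a model pair absent from the matrix is an error.
#'
#' @param model A `SignatureModel` (or any list with `pairs` and `beta`).
#' @param pm A `PairIndicatorMatrix` containing all model pairs.
#' @return Named numeric vector of per-sample risk scores.
#' @export
risk_score <- function(model, pm) {
  stopifnot(inherits(pm, "PairIndicatorMatrix"))
  miss <- setdiff(model$pairs, rownames(pm$S))
  if (length(miss) > 0) stop("model pair(s) missing from pair matrix: ",
                             paste(miss, collapse = ", "))
  drop(as.numeric(model$beta[model$pairs]) %*% pm$S[model$pairs, , drop = FALSE])
}

#' Dichotomize risk scores at a cutoff
#'
#' @param scores Named numeric risk scores.
#' @param cutoff Numeric cutoff; `high` iff `score > cutoff`.
#' @return Factor with levels `low`, `high`, named like `scores`.
#' @export
risk_groups <- function(scores, cutoff) {
  g <- factor(ifelse(scores > cutoff, "high", "low"), levels = c("low", "high"))
  names(g) <- names(scores)
  g
}

#' Serialize / restore a signature model as versioned JSON
#'
#' Stores pairs, coefficients and provenance (survivor lists, lambda, seed,
#' thresholds) in a plain JSON document; the `coxph` fit object is not
#' serialized. A restored model reproduces [risk_score()] exactly.
#'
#' @param model A `SignatureModel`.
#' @param path Output path for `write_signature_json()`; input path for
#'   `read_signature_json()`.
#' @return `write_signature_json()` returns `path` invisibly;
#'   `read_signature_json()` returns a `SignatureModel` (without `fit`).
#' @export
write_signature_json <- function(model, path) {
  doc <- list(format = "irlpsig-signature", version = 1L,
              pairs = model$pairs, beta = as.list(model$beta),
              hr = as.list(model$hr), p = as.list(model$p),
              provenance = model$provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature_json
#' @export
read_signature_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "irlpsig-signature"))
    stop("not an irlpsig signature document: ", path)
  beta <- unlist(doc$beta)
  structure(list(pairs = doc$pairs, beta = beta[doc$pairs],
                 hr = unlist(doc$hr), p = unlist(doc$p),
                 provenance = doc$provenance),
            class = "SignatureModel")
}
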