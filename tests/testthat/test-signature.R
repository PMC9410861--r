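# Fixture builders: a PairIndicatorMatrix straight from an indicator matrix,
# and a minimal eligible clinical table.
make_pm <- function(S) {
  S <- as.matrix(S); storage.mode(S) <- "integer"
  if (is.null(colnames(S))) colnames(S) <- paste0("s", seq_len(ncol(S)))
  if (is.null(rownames(S))) rownames(S) <- paste0("A", seq_len(nrow(S)), "|B", seq_len(nrow(S)))
  ab <- do.call(rbind, strsplit(rownames(S), "|", fixed = TRUE))
  structure(list(S = S,
                 pairs = data.frame(gene_a = ab[, 1], gene_b = ab[, 2]),
                 one_frequency = rowMeans(S)),
            class = "PairIndicatorMatrix")
}

make_clin <- function(time, event, samples = paste0("s", seq_along(time))) {
  as_clinical_table(data.frame(sample = samples, time = time, event = event),
                    time_unit = "years")
}

sim_two_group <- function(n, beta, seed, cens_rate = 0) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, rate = exp(beta * x))
  if (cens_rate > 0) {
    c <- rexp(n, rate = cens_rate)
    list(time = pmin(t, c), event = as.integer(t <= c), x = x)
  } else list(time = t, event = rep(1L, n), x = x)
}

test_that("uni-Cox beta on the worked 12-subject data matches an independent partial-likelihood maximization", {
  fx <- worked_survival_fixture()
  pm <- make_pm(matrix(fx$x, nrow = 1, dimnames = list("GA|GB", paste0("s", 1:12))))
  clin <- make_clin(fx$time, fx$event)
  res <- unicox_screen(pm, clin)
  oracle_beta <- cox_fit_oracle(fx$time, fx$event, fx$x)
  expect_equal(res$beta, oracle_beta, tolerance = 1e-4)
  expect_equal(res$hr, exp(oracle_beta), tolerance = 1e-4)
})

test_that("uni-Cox screen recovers a hazard ratio of 2 at n = 2000 and respects symmetry", {
  d <- sim_two_group(2000, log(2), seed = 21)
  pm <- make_pm(rbind("GA|GB" = d$x, "GC|GD" = 1L - d$x))
  clin <- make_clin(d$time, d$event)
  res <- unicox_screen(pm, clin)
  b <- res$beta[res$pair == "GA|GB"]
  expect_lt(abs(b - log(2)), 0.1)
  # negating the indicator flips the sign and preserves |z|
  b2 <- res$beta[res$pair == "GC|GD"]
  expect_equal(b2, -b, tolerance = 1e-8)
  expect_equal(abs(res$z[1]), abs(res$z[2]), tolerance = 1e-8)
  expect_equal(res$hr, exp(res$beta), tolerance = 1e-10)
  expect_true(all(res$ci_lower <= res$ci_upper))
})

test_that("constant pairs are skipped and the worked beta also matches via the screen at >= 10 events", {
  d <- sim_two_group(60, 1, seed = 5)
  S <- rbind("GA|GB" = d$x, "GK|GL" = rep(1L, 60))
  res <- unicox_screen(make_pm(S), make_clin(d$time, d$event))
  expect_identical(res$pair, "GA|GB")
  expect_identical(attr(res, "n_skipped"), 1L)
  expect_equal(res$beta, cox_fit_oracle(d$time, d$event, d$x), tolerance = 1e-4)
})

test_that("the Lasso selects a single strongly prognostic pair among noise", {
  set.seed(31)
  n <- 500
  x_true <- rbinom(n, 1, 0.5)
  noise <- matrix(rbinom(9 * n, 1, 0.5), nrow = 9)
  t <- rexp(n, rate = 0.2 * exp(1 * x_true))
  S <- rbind(x_true, noise)
  rownames(S) <- paste0("G", sprintf("%02d", 1:10), "|H", sprintf("%02d", 1:10))
  pm <- make_pm(S)
  clin <- make_clin(t, rep(1L, n))
  sel <- lasso_cox_select(pm, clin, rownames(S), seed = 7)
  expect_true(rownames(S)[1] %in% sel$selected)
  expect_gt(sel$beta[rownames(S)[1]], 0)
})

test_that("under a pure null the Lasso stays sparse on average", {
  n <- 500; p <- 50
  frac <- vapply(1:20, function(seed) {
    set.seed(seed * 101)
    S <- matrix(rbinom(p * n, 1, 0.5), nrow = p,
                dimnames = list(paste0("N", sprintf("%02d", 1:p), "|M", sprintf("%02d", 1:p)),
                                paste0("s", 1:n)))
    t <- rexp(n)
    sel <- tryCatch(
      suppressMessages(lasso_cox_select(make_pm(S), make_clin(t, rep(1L, n)),
                                        rownames(S), seed = seed)),
      error = function(e) list(selected = character()))
    length(sel$selected) / p
  }, numeric(1))
  expect_lte(mean(frac), 0.10)
})

test_that("stepwise multivariate Cox keeps one of two identical covariates and all independent true ones", {
  set.seed(41)
  n <- 800
  S <- matrix(rbinom(3 * n, 1, 0.5), nrow = 3)
  lp <- 0.8 * colSums(S)
  t <- rexp(n, rate = 0.1 * exp(lp))
  Sfull <- rbind(S, S[3, ])  # duplicated covariate
  rownames(Sfull) <- c("GA|GB", "GC|GD", "GE|GF", "GE2|GF2")
  pm <- make_pm(Sfull)
  clin <- make_clin(t, rep(1L, n))
  model <- suppressWarnings(
    stepwise_multicox(pm, clin, rownames(Sfull)))
  expect_setequal(setdiff(model$pairs, c("GE|GF", "GE2|GF2")), c("GA|GB", "GC|GD"))
  expect_identical(sum(c("GE|GF", "GE2|GF2") %in% model$pairs), 1L)
  expect_true(all(model$beta > 0))

  # AIC of the stepwise-chosen model beats every strict submodel of the
  # three distinct covariates (exhaustive scan)
  keep <- c("GA|GB", "GC|GD", "GE|GF")
  df <- data.frame(time = t, event = 1, P1 = S[1, ], P2 = S[2, ], P3 = S[3, ])
  aics <- vapply(0:7, function(mask) {
    vars <- c("P1", "P2", "P3")[bitwAnd(mask, c(1, 2, 4)) > 0]
    f <- if (length(vars) == 0) survival::Surv(time, event) ~ 1
    else stats::reformulate(vars, "survival::Surv(time, event)")
    fit <- survival::coxph(f, data = df, ties = "efron")
    if (length(vars) == 0) -2 * fit$loglik[1] else stats::extractAIC(fit)[2]
  }, numeric(1))
  expect_equal(which.min(aics), 8L) # the full model
})

test_that("stepwise selection with zero events is a precondition error", {
  S <- matrix(rbinom(40, 1, 0.5), nrow = 2,
              dimnames = list(c("GA|GB", "GC|GD"), paste0("s", 1:20)))
  clin <- make_clin(rexp(20), rep(0L, 20))
  expect_error(stepwise_multicox(make_pm(S), clin, rownames(S)), "events")
})

test_that("risk score is the stated linear form, additive over disjoint pair sets", {
  S <- matrix(c(1L, 1L, 0L, 1L, 0L, 0L), nrow = 2, byrow = TRUE,
              dimnames = list(c("GA|GB", "GC|GD"), c("s1", "s2", "s3")))
  pm <- make_pm(S)
  m1 <- list(pairs = "GA|GB", beta = c("GA|GB" = 0.5))
  m2 <- list(pairs = "GC|GD", beta = c("GC|GD" = -1.0))
  m12 <- list(pairs = rownames(S), beta = c("GA|GB" = 0.5, "GC|GD" = -1.0))
  expect_equal(unname(risk_score(m12, pm)), c(-0.5, 0.5, 0))
  expect_equal(risk_score(m12, pm), risk_score(m1, pm) + risk_score(m2, pm))
  expect_error(risk_score(list(pairs = "X|Y", beta = c("X|Y" = 1)), pm), "X\\|Y")
})

test_that("a signature model survives the JSON round trip and rescoring", {
  S <- matrix(rbinom(60, 1, 0.5), nrow = 3,
              dimnames = list(c("GA|GB", "GC|GD", "GE|GF"), paste0("s", 1:20)))
  pm <- make_pm(S)
  model <- structure(list(pairs = rownames(S),
                          beta = setNames(c(0.8, -0.5, 0.25), rownames(S)),
                          hr = setNames(exp(c(0.8, -0.5, 0.25)), rownames(S)),
                          p = setNames(c(0.001, 0.02, 0.2), rownames(S)),
                          provenance = list(lambda = 0.05, seed = 1)),
                     class = "SignatureModel")
  path <- withr::local_tempfile(fileext = ".json")
  write_signature_json(model, path)
  back <- read_signature_json(path)
  expect_identical(back$pairs, model$pairs)
  expect_equal(back$beta, model$beta)
  expect_equal(risk_score(back, pm), risk_score(model, pm))
})
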