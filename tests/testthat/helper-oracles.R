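# Independent brute-force / closed-form oracles used across the suite.
# These deliberately avoid the package's own code paths (and the library
# calls the implementation delegates to) so every check is dual-route.

# Benjamini-Hochberg by the definition: sort, scale by m/i, cumulative
# minimum from the largest, cap at 1, restore input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Pair indicator by a double loop over every pair and sample; genes sorted
# lexicographically, S = 1 iff expr(A) > expr(B), ties 0.
pair_matrix_oracle <- function(X, genes) {
  genes <- sort(genes)
  D <- length(genes)
  ids <- character(0); rows <- list()
  for (i in seq_len(D - 1)) for (j in (i + 1):D) {
    s <- integer(ncol(X))
    for (k in seq_len(ncol(X)))
      s[k] <- if (X[genes[i], k] > X[genes[j], k]) 1L else 0L
    ids <- c(ids, paste(genes[i], genes[j], sep = "|"))
    rows[[length(rows) + 1]] <- s
  }
  S <- do.call(rbind, rows)
  dimnames(S) <- list(ids, colnames(X))
  S
}

# Mann-Whitney AUC by exhaustive comparison with ties counted 1/2.
auc_oracle <- function(case_scores, control_scores) {
  tot <- 0
  for (x in case_scores) for (y in control_scores)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(case_scores) * length(control_scores))
}

# Youden-optimal cutoff by exhaustive scan over all n + 1 thresholds,
# ties broken toward the lower threshold.
youden_oracle <- function(case_scores, control_scores) {
  thr <- c(-Inf, sort(unique(c(case_scores, control_scores))))
  best <- -Inf; best_thr <- thr[1]
  for (c in thr) {
    j <- mean(case_scores > c) - mean(control_scores > c)
    if (j > best + 1e-12) { best <- j; best_thr <- c }
  }
  best_thr
}

# Two-group log-rank chi-square from the O/E/V table worked event time by
# event time with the hypergeometric variance.
logrank_oracle <- function(group, time, event) {
  g <- as.integer(factor(group)) # 1/2
  ev_times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n1 <- sum(at_risk & g == 1); n2 <- sum(at_risk & g == 2)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == 1)
    n <- n1 + n2
    if (n < 2) next
    O <- O + d1
    E <- E + d * n1 / n
    V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Efron-tie partial log-likelihood of a single binary covariate, coded from
# the definition; maximized by stats::optimize as an independent fitter.
efron_loglik <- function(beta, time, event, x) {
  eta <- beta * x
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    sum_r <- sum(exp(eta[R]))
    sum_d <- sum(exp(eta[D]))
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1)
      ll <- ll - log(sum_r - (l / d) * sum_d)
  }
  ll
}

cox_fit_oracle <- function(time, event, x, interval = c(-8, 8)) {
  stats::optimize(function(b) efron_loglik(b, time, event, x),
                  interval = interval, maximum = TRUE, tol = 1e-10)$maximum
}

# Pearson r and its two-sided t-based p from the closed-form sums.
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# Small fixed two-group survival fixture with ties and censoring, used by
# the Cox and log-rank oracle checks.
worked_survival_fixture <- function() {
  data.frame(
    time = c(5, 5, 8, 10, 12, 3, 6, 6, 9, 14, 2, 11),
    event = c(1, 1, 1, 1, 0, 1, 1, 1, 1, 1, 1, 0),
    x = c(0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1))
}

# Tiny deterministic expression fixture builder.
make_expr <- function(values, cohort) {
  ExpressionMatrix(values, cohort)
}
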