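# Association of the risk score with deconvolved immune-cell fractions and
# with an immunosuppression / checkpoint gene panel. All tests are
# rank-based, so results are invariant to monotone rescaling of the score.

spearman_safe <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(rho = NA_real_, p = NA_real_))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  c(rho = unname(ct$estimate), p = ct$p.value)
}

wilcox_safe <- function(x, g) {
  if (length(unique(x)) == 1) return(1)
  suppressWarnings(stats::wilcox.test(x ~ g)$p.value)
}

#' Compare immune-cell fractions between risk groups, per subtype
#'
#' Within each stratum (molecular subtype, or one pooled stratum when
#' `strata` is `NULL`), every cell type's fractions are compared between the
#' low- and high-risk groups with a two-sided Wilcoxon rank-sum test, and
#' correlated with the continuous risk score by Spearman's rho. Wilcoxon
#' p-values are BH-adjusted across cell types within each stratum. Strata
#' where one risk group has fewer than two samples are skipped with a
#' warning (a null result is still a result; only impossible comparisons are
#' skipped).
#'
#' @param fractions Numeric matrix, samples x cell types (e.g. from
#'   [read_cell_fractions()]).
#' @param scores Named numeric risk scores (names = sample IDs).
#' @param groups Factor of risk groups aligned with `scores` (e.g. from
#'   [risk_groups()]).
#' @param strata Optional per-sample stratum labels aligned with `scores`.
#' @return Data frame `stratum`, `cell_type`, `p_wilcox`, `fdr`, `rho`,
#'   `p_rho`, `direction` (`sign(rho)` as "+"/"-"/"0").
#' @export
tiic_group_comparison <- function(fractions, scores, groups, strata = NULL) {
  shared <- intersect(names(scores), rownames(fractions))
  if (length(shared) < 4) stop("need >= 4 samples shared by scores and fractions")
  idx <- match(shared, names(scores))
  scores <- scores[idx]; groups <- factor(groups[idx])
  strata <- if (is.null(strata)) factor(rep("all", length(shared))) else factor(strata[idx])
  fr <- fractions[shared, , drop = FALSE]
  rows <- list()
  for (lv in levels(strata)) {
    in_s <- strata == lv
    g <- droplevels(groups[in_s])
    if (nlevels(g) < 2 || min(table(g)) < 2) {
      warning("stratum '", lv, "' skipped: fewer than 2 samples in a risk group")
      next
    }
    sc <- scores[in_s]
    block <- lapply(colnames(fr), function(ct) {
      x <- fr[in_s, ct]
      sp <- spearman_safe(sc, x)
      data.frame(stratum = lv, cell_type = ct,
                 p_wilcox = wilcox_safe(x, g),
                 rho = sp[["rho"]], p_rho = sp[["p"]],
                 stringsAsFactors = FALSE)
    })
    block <- do.call(rbind, block)
    block$fdr <- stats::p.adjust(block$p_wilcox, method = "BH")
    rows[[lv]] <- block
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(stratum = character(), cell_type = character(),
                      p_wilcox = numeric(), rho = numeric(), p_rho = numeric(),
                      fdr = numeric(), direction = character()))
  res$direction <- ifelse(is.na(res$rho), "0",
                          ifelse(res$rho > 0, "+", ifelse(res$rho < 0, "-", "0")))
  res <- res[, c("stratum", "cell_type", "p_wilcox", "fdr", "rho", "p_rho", "direction")]
  rownames(res) <- NULL
  res
}

#' Correlate checkpoint-panel gene expression with the risk score
#'
#' For each gene of an immunosuppression / checkpoint panel (default LAG3,
#' CTLA4, PDCD1, PDCD1LG2), reports Spearman's rho and p between the risk
#' score and `log2(x + 1)` expression, plus a Wilcoxon rank-sum comparison
#' between risk groups when `groups` is given. Panel genes absent from the
#' matrix are reported as missing; the others proceed. A constant gene gives
#' `rho = NA`.
#'
#' @param mrna_expr [ExpressionMatrix] of coding genes.
#' @param scores Named numeric risk scores.
#' @param groups Optional factor of risk groups aligned with `scores`.
#' @param panel Character vector of panel gene IDs (matched on
#'   version-stripped IDs).
#' @return Data frame `gene`, `rho`, `p`, `p_group`, `missing`.
#' @export
checkpoint_correlation <- function(mrna_expr, scores, groups = NULL,
                                   panel = c("LAG3", "CTLA4", "PDCD1", "PDCD1LG2")) {
  if (length(panel) == 0) stop("checkpoint panel is empty")
  shared <- intersect(names(scores), sample_ids(mrna_expr))
  if (length(shared) < 3) stop("need >= 3 samples shared by scores and expression")
  sc <- scores[shared]
  g <- if (is.null(groups)) NULL else factor(groups[match(shared, names(scores))])
  ids <- gene_ids(mrna_expr)
  key <- strip_gene_version(ids)
  rows <- lapply(panel, function(gene) {
    row <- ids[match(strip_gene_version(gene), key)]
    if (is.na(row))
      return(data.frame(gene = gene, rho = NA_real_, p = NA_real_,
                        p_group = NA_real_, missing = TRUE))
    x <- log2(expr_values(mrna_expr)[row, shared] + 1)
    sp <- spearman_safe(sc, x)
    pg <- if (is.null(g) || nlevels(droplevels(g)) < 2) NA_real_ else wilcox_safe(x, g)
    data.frame(gene = gene, rho = sp[["rho"]], p = sp[["p"]],
               p_group = pg, missing = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
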