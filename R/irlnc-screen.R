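#' Screen immune-related lncRNAs by coexpression with immune genes
#'
#' Computes correlations between every lncRNA and every immune-related coding
#' gene on `log2(x + 1)`-transformed abundances over the shared samples
#' (tumor and normal combined by default). A lncRNA is flagged immune-related
#' when at least one immune gene passes both `r > r_min` and `p < p_max`
#' (strict inequalities). P-values are two-sided, from the t distribution on
#' n - 2 degrees of freedom for Pearson (and the same t approximation on
#' ranks for Spearman).
#'
#' @param lnc_expr [ExpressionMatrix] of lncRNAs.
#' @param mrna_expr [ExpressionMatrix] of coding genes.
#' @param immune_genes Character vector of immune-related gene IDs; matched to
#'   `mrna_expr` rows on version-stripped IDs. Zero matches is an error.
#' @param r_min Correlation threshold (default 0.4).
#' @param p_max P-value threshold (default 0.001).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param samples Optional sample IDs restricting the computation (e.g. tumor
#'   only); default: all samples shared by the two matrices.
#' @return List of class `CoexpressionResult`: `edges` (data frame `lnc`,
#'   `mrna`, `r`, `p` for every tested pair), `immune_lnc` (flagged lncRNA
#'   IDs), `n_skipped_constant` and the thresholds used.
#' @export
coexpression_screen <- function(lnc_expr, mrna_expr, immune_genes,
                                r_min = 0.4, p_max = 0.001,
                                method = c("pearson", "spearman"),
                                samples = NULL) {
  method <- match.arg(method)
  if (is.null(samples))
    samples <- intersect(sample_ids(lnc_expr), sample_ids(mrna_expr))
  if (length(samples) < 3) stop("need >= 3 shared samples for coexpression")
  imm_rows <- gene_ids(mrna_expr)[strip_gene_version(gene_ids(mrna_expr)) %in%
                                    strip_gene_version(immune_genes)]
  if (length(imm_rows) == 0) stop("no immune genes found in the coding matrix")

  L <- log2(expr_values(lnc_expr)[, samples, drop = FALSE] + 1)
  M <- log2(expr_values(mrna_expr)[imm_rows, samples, drop = FALSE] + 1)
  if (method == "spearman") {
    L <- t(apply(L, 1, rank))
    M <- t(apply(M, 1, rank))
  }
  const_l <- apply(L, 1, function(x) stats::sd(x) == 0)
  const_m <- apply(M, 1, function(x) stats::sd(x) == 0)
  n_skipped <- sum(const_l) * nrow(M) + sum(const_m) * sum(!const_l)
  if (any(const_l) || any(const_m))
    warning(n_skipped, " pair(s) with a constant profile skipped")
  L <- L[!const_l, , drop = FALSE]
  M <- M[!const_m, , drop = FALSE]
  if (nrow(L) == 0 || nrow(M) == 0)
    stop("no non-constant profiles left for coexpression")

  n <- length(samples)
  R <- stats::cor(t(L), t(M))
  tval <- R * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
  P <- 2 * stats::pt(-abs(tval), df = n - 2)
  P[abs(R) >= 1] <- 0

  edges <- data.frame(
    lnc = rep(rownames(R), times = ncol(R)),
    mrna = rep(colnames(R), each = nrow(R)),
    r = as.vector(R), p = as.vector(P),
    stringsAsFactors = FALSE)
  hit <- (R > r_min) & (P < p_max)
  immune_lnc <- rownames(R)[rowSums(hit) > 0]
  structure(list(edges = edges, immune_lnc = immune_lnc,
                 n_skipped_constant = n_skipped,
                 r_min = r_min, p_max = p_max, method = method,
                 n_samples = n),
            class = "CoexpressionResult")
}

#' Differential expression of lncRNAs between tumor and normal cohorts
#'
#' Fold change is computed on cohort means with a pseudo-count:
#' `logFC = log2((mean_tumor + eps) / (mean_normal + eps))`. The test is the
#' two-sided Wilcoxon rank-sum on raw abundances; FDR is Benjamini-Hochberg
#' over the tested genes. Direction is `"up"` when `logFC > lfc_min` and
#' `FDR < fdr_max`, `"down"` for `logFC < -lfc_min` and `FDR < fdr_max`,
#' otherwise `"ns"` (thresholds strict).
#'
#' @param lnc_expr [ExpressionMatrix] with both cohorts present (>= 2 samples
#'   each).
#' @param genes Optional subset of genes to test (e.g. the immune-related
#'   lncRNAs from [coexpression_screen()]); default all rows.
#' @param lfc_min Absolute log2 fold-change threshold (default 1.5).
#' @param fdr_max FDR threshold (default 0.5).
#' @param eps Pseudo-count guarding against zero cohort means (default 0.001).
#' @return Data frame of class `DEResult` with columns `gene`, `logFC`, `p`,
#'   `fdr`, `direction`.
#' @export
differential_expression <- function(lnc_expr, genes = NULL,
                                    lfc_min = 1.5, fdr_max = 0.5, eps = 0.001) {
  tum <- cohort_samples(lnc_expr, "tumor")
  nrm <- cohort_samples(lnc_expr, "normal")
  if (length(tum) < 2 || length(nrm) < 2)
    stop("need >= 2 tumor and >= 2 normal samples for differential expression")
  v <- expr_values(lnc_expr)
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(v))
    if (length(miss) > 0) stop("genes not in matrix: ", paste(miss, collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  mt <- rowMeans(v[, tum, drop = FALSE])
  mn <- rowMeans(v[, nrm, drop = FALSE])
  logfc <- log2((mt + eps) / (mn + eps))
  p <- vapply(seq_len(nrow(v)), function(i)
    suppressWarnings(stats::wilcox.test(v[i, tum], v[i, nrm],
                                        alternative = "two.sided")$p.value),
    numeric(1))
  fdr <- stats::p.adjust(p, method = "BH")
  direction <- ifelse(logfc > lfc_min & fdr < fdr_max, "up",
                      ifelse(logfc < -lfc_min & fdr < fdr_max, "down", "ns"))
  res <- data.frame(gene = rownames(v), logFC = logfc, p = p, fdr = fdr,
                    direction = direction, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("DEResult", "data.frame")
  res
}
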