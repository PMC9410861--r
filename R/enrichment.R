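# Coding genes correlated with the signature lncRNAs, and hypergeometric
# gene-set overrepresentation of the pooled correlated genes.

#' Coding genes correlated with signature lncRNAs
#'
#' For each signature lncRNA, screens all coding genes by Pearson correlation
#' on `log2(x + 1)` abundances over the shared samples and keeps genes with
#' `|R| > r_min` and `p < p_max` (strict, two-sided t-based p). Signature
#' lncRNAs absent from the lncRNA matrix are listed in `missing`; the others
#' proceed.
#'
#' @param lnc_expr [ExpressionMatrix] of lncRNAs.
#' @param mrna_expr [ExpressionMatrix] of coding genes.
#' @param signature_lncs Character vector of signature lncRNA IDs.
#' @param r_min Absolute correlation threshold (default 0.6).
#' @param p_max P-value threshold (default 0.05).
#' @param samples Optional sample IDs restricting the computation.
#' @return Object of class `CorrelatedGeneSet`: list with `per_lnc` (named
#'   list of data frames `gene`, `r`, `p`), `pooled` (deduplicated union of
#'   correlated coding genes) and `missing`.
#' @export
correlated_coding_genes <- function(lnc_expr, mrna_expr, signature_lncs,
                                    r_min = 0.6, p_max = 0.05, samples = NULL) {
  if (is.null(samples))
    samples <- intersect(sample_ids(lnc_expr), sample_ids(mrna_expr))
  if (length(samples) < 3) stop("need >= 3 shared samples")
  missing <- setdiff(signature_lncs, gene_ids(lnc_expr))
  present <- setdiff(signature_lncs, missing)
  if (length(missing) > 0)
    warning(length(missing), " signature lncRNA(s) absent from the matrix: ",
            paste(missing, collapse = ", "))
  if (length(present) == 0) stop("no signature lncRNA present in the matrix")
  L <- log2(expr_values(lnc_expr)[present, samples, drop = FALSE] + 1)
  M <- log2(expr_values(mrna_expr)[, samples, drop = FALSE] + 1)
  keep_m <- apply(M, 1, stats::sd) > 0
  M <- M[keep_m, , drop = FALSE]
  n <- length(samples)
  per_lnc <- list()
  for (g in present) {
    x <- L[g, ]
    if (stats::sd(x) == 0) {
      per_lnc[[g]] <- data.frame(gene = character(), r = numeric(), p = numeric())
      next
    }
    r <- as.vector(stats::cor(x, t(M)))
    tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    p[abs(r) >= 1] <- 0
    hit <- abs(r) > r_min & p < p_max
    per_lnc[[g]] <- data.frame(gene = rownames(M)[hit], r = r[hit], p = p[hit],
                               stringsAsFactors = FALSE)
  }
  pooled <- unique(unlist(lapply(per_lnc, `[[`, "gene"), use.names = FALSE))
  structure(list(per_lnc = per_lnc, pooled = pooled, missing = missing,
                 r_min = r_min, p_max = p_max),
            class = "CorrelatedGeneSet")
}

#' Hypergeometric gene-set overrepresentation
#'
#' Classic one-sided overrepresentation test: for a query of `n` genes drawn
#' from a universe of `N`, a set with `K` members in the universe and `k` of
#' them in the query gets `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`;
#' BH adjustment is applied across sets. The query is intersected with the
#' universe first; an empty intersection is an error. Sets with no member in
#' the universe are dropped.
#'
#' @param query Character vector of genes of interest.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector of measurable genes (e.g. all coding
#'   genes in the expression matrix).
#' @return Data frame of class `EnrichmentResult`, sorted by `q`: `set`, `k`
#'   (overlap), `K` (set size in universe), `n` (query size), `N` (universe
#'   size), `p`, `q`.
#' @export
hypergeometric_enrichment <- function(query, sets, universe) {
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  if (length(query) == 0) stop("query is empty after intersecting with the universe")
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  sets <- sets[lengths(sets) > 0]
  if (length(sets) == 0) stop("no gene set overlaps the universe")
  N <- length(universe); n <- length(query)
  k <- vapply(sets, function(s) length(intersect(s, query)), integer(1))
  K <- lengths(sets)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(set = names(sets), k = k, K = K, n = n, N = N,
                    p = p, q = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  res <- res[order(res$q, res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}
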