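#' Binary pair-indicator matrix of lncRNA pairs
#'
#' The core rank statistic of the pipeline. Genes are put in canonical
#' (lexicographic) order; for every unordered pair `{A, B}` with `A < B` the
#' per-sample indicator is `S = 1` when `expr(A) > expr(B)` in that sample and
#' `0` otherwise (ties give 0). Because `S` depends only on the within-sample
#' ordering of two genes, it is invariant to any strictly increasing
#' transformation applied per sample — no cross-sample normalization is
#' needed.
#'
#' @param expr An [ExpressionMatrix] or a plain numeric matrix (genes x
#'   samples).
#' @param genes Character vector of >= 2 gene IDs to pair; all must be rows of
#'   `expr` (a missing gene is an error naming it).
#' @param samples Optional sample IDs to use (e.g. tumor only); default all
#'   columns.
#' @return Object of class `PairIndicatorMatrix`: list with `S` (pairs x
#'   samples 0/1 integer matrix, rownames `"A|B"`), `pairs` (data frame
#'   `gene_a`, `gene_b`) and `one_frequency` (fraction of samples with
#'   `S = 1` per pair). All `choose(D, 2)` candidate pairs are emitted.
#' @export
build_pair_matrix <- function(expr, genes, samples = NULL) {
  v <- if (inherits(expr, "ExpressionMatrix")) expr_values(expr) else as.matrix(expr)
  miss <- setdiff(genes, rownames(v))
  if (length(miss) > 0) stop("gene(s) missing from expression matrix: ",
                             paste(miss, collapse = ", "))
  if (length(genes) < 2) stop("need >= 2 genes to form pairs")
  if (anyDuplicated(genes)) stop("duplicate gene ids in pair gene list")
  if (is.null(samples)) samples <- colnames(v)
  genes <- sort(genes)
  X <- v[genes, samples, drop = FALSE]
  idx <- utils::combn(length(genes), 2)
  S <- (X[idx[1, ], , drop = FALSE] > X[idx[2, ], , drop = FALSE]) + 0L
  pairs <- data.frame(gene_a = genes[idx[1, ]], gene_b = genes[idx[2, ]],
                      stringsAsFactors = FALSE)
  rownames(S) <- paste(pairs$gene_a, pairs$gene_b, sep = "|")
  structure(list(S = S, pairs = pairs, one_frequency = rowMeans(S)),
            class = "PairIndicatorMatrix")
}

#' @method print PairIndicatorMatrix
#' @export
print.PairIndicatorMatrix <- function(x, ...) {
  cat("PairIndicatorMatrix:", nrow(x$S), "pairs x", ncol(x$S), "samples\n")
  invisible(x)
}

#' Remove near-constant pairs (skew filter)
#'
#' Retains exactly the pairs whose indicator takes both values in more than
#' `q_min` of the samples, i.e. `q_min < one_frequency < 1 - q_min` with
#' strict inequalities (a pair at exactly the boundary is removed). Pair
#' order is preserved and the filter is idempotent.
#'
#' @param pm A `PairIndicatorMatrix`.
#' @param q_min Minority-class frequency bound, in (0, 0.5); default 0.2.
#' @return Filtered `PairIndicatorMatrix` (possibly with zero pairs).
#' @export
skew_filter <- function(pm, q_min = 0.2) {
  stopifnot(inherits(pm, "PairIndicatorMatrix"))
  if (!(q_min > 0 && q_min < 0.5)) stop("q_min must be in (0, 0.5)")
  keep <- pm$one_frequency > q_min & pm$one_frequency < 1 - q_min
  if (!any(keep)) message("skew filter removed every pair")
  subset_pairs(pm, rownames(pm$S)[keep])
}

#' Subset a PairIndicatorMatrix by pair IDs or samples
#'
#' @param pm A `PairIndicatorMatrix`.
#' @param pairs Pair IDs (`"A|B"` rownames) to keep, in the given order;
#'   default all.
#' @param samples Sample IDs to keep; default all. `one_frequency` is
#'   recomputed when samples change.
#' @return A `PairIndicatorMatrix`.
#' @export
subset_pairs <- function(pm, pairs = NULL, samples = NULL) {
  stopifnot(inherits(pm, "PairIndicatorMatrix"))
  S <- pm$S
  pr <- pm$pairs
  if (!is.null(pairs)) {
    miss <- setdiff(pairs, rownames(S))
    if (length(miss) > 0) stop("unknown pair id(s): ", paste(miss, collapse = ", "))
    keep <- match(pairs, rownames(S))
    S <- S[keep, , drop = FALSE]
    pr <- pr[keep, , drop = FALSE]
  }
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(S))
    if (length(miss) > 0) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
    S <- S[, samples, drop = FALSE]
  }
  rownames(pr) <- NULL
  structure(list(S = S, pairs = pr, one_frequency = rowMeans(S)),
            class = "PairIndicatorMatrix")
}

#' Write a pair-indicator matrix and its pair summary to TSV
#'
#' @param pm A `PairIndicatorMatrix`.
#' @param path Output TSV for the 0/1 matrix (rows `"A|B"`, columns samples).
#' @param summary_path Optional TSV for per-pair `one_frequency`.
#' @return `path`, invisibly.
#' @export
write_pair_matrix <- function(pm, path, summary_path = NULL) {
  df <- data.frame(pair = rownames(pm$S), pm$S, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path)) {
    sm <- data.frame(pair = rownames(pm$S), gene_a = pm$pairs$gene_a,
                     gene_b = pm$pairs$gene_b, one_frequency = pm$one_frequency)
    utils::write.table(sm, summary_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
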