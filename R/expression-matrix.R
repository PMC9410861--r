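#' Expression matrix with cohort labels
#'
#' Container for a gene-by-sample abundance matrix (FPKM-like, nonnegative)
#' where every sample carries a cohort label (`"tumor"` or `"normal"`).
#' Downstream pair statistics use only within-sample ranks, so the abundance
#' unit (FPKM, TPM, counts-per-million) does not need to be harmonized.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs). All values must be finite and >= 0.
#' @param cohort Named character vector mapping every sample ID to `"tumor"`
#'   or `"normal"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix) and `cohort` (labels aligned to `colnames(values)`).
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(paste0("G", 1:3), c("s1", "s2")))
#' ExpressionMatrix(m, c(s1 = "tumor", s2 = "normal"))
#' @export
ExpressionMatrix <- function(values, cohort) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative or non-finite expression value at gene '",
         rownames(values)[bad[1, 1]], "', sample '", colnames(values)[bad[1, 2]], "'")
  missing <- setdiff(colnames(values), names(cohort))
  if (length(missing) > 0)
    stop("samples without a cohort label: ", paste(missing, collapse = ", "))
  cohort <- as.character(cohort[colnames(values)])
  names(cohort) <- colnames(values)
  if (!all(cohort %in% c("tumor", "normal")))
    stop("cohort labels must be 'tumor' or 'normal'")
  structure(list(values = values, cohort = cohort), class = "ExpressionMatrix")
}

#' @method print ExpressionMatrix
#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "genes x", ncol(x$values), "samples (",
      sum(x$cohort == "tumor"), "tumor,", sum(x$cohort == "normal"), "normal )\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Accessors for ExpressionMatrix components
#'
#' @param x An `ExpressionMatrix`.
#' @return `expr_values()` the numeric matrix; `gene_ids()` / `sample_ids()`
#'   character vectors; `expr_cohort()` the named cohort label vector.
#' @export
expr_values <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  x$values
}

#' @rdname expr_values
#' @export
gene_ids <- function(x) rownames(expr_values(x))

#' @rdname expr_values
#' @export
sample_ids <- function(x) colnames(expr_values(x))

#' @rdname expr_values
#' @export
expr_cohort <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  x$cohort
}

#' Subset an ExpressionMatrix by genes and/or samples
#'
#' @param x An `ExpressionMatrix`.
#' @param genes,samples Character vectors of IDs to retain (default: all).
#'   Unknown IDs are an error.
#' @return A new `ExpressionMatrix`.
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  v <- expr_values(x)
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(v))
    if (length(miss) > 0) stop("genes not in matrix: ", paste(miss, collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(v))
    if (length(miss) > 0) stop("samples not in matrix: ", paste(miss, collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  ExpressionMatrix(v, x$cohort[colnames(v)])
}

#' Sample IDs belonging to one cohort
#'
#' @param x An `ExpressionMatrix`.
#' @param cohort `"tumor"` or `"normal"`.
#' @return Character vector of sample IDs.
#' @export
cohort_samples <- function(x, cohort = c("tumor", "normal")) {
  cohort <- match.arg(cohort)
  names(expr_cohort(x))[expr_cohort(x) == cohort]
}

#' Strip Ensembl-style version suffixes from gene identifiers
#'
#' TCGA-style matrices and curated gene lists frequently disagree on the
#' version suffix of otherwise identical Ensembl IDs (`ENSG00000123456.7`),
#' so every join in this package happens on version-stripped IDs.
#'
#' @param ids Character vector of gene identifiers.
#' @return `ids` with any trailing `.<digits>` removed.
#' @export
strip_gene_version <- function(ids) sub("\\.[0-9]+$", "", ids)
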