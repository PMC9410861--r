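#' Read a gene-by-sample expression TSV
#'
#' Expects a tab-separated file with sample IDs in the header and gene IDs in
#' the first column. Duplicate gene rows (after version stripping the IDs are
#' kept as written; duplication is judged on the written IDs) are collapsed,
#' by default taking the per-sample maximum, and the collapse is reported via
#' `message()`.
#'
#' @param path Path to the TSV file.
#' @param cohort_map Named character vector, sample ID -> `"tumor"`/`"normal"`.
#'   Every sample in the file must be present.
#' @param collapse How to collapse duplicate gene rows: `"max"` (default),
#'   `"mean"` or `"first"`.
#' @return An [ExpressionMatrix].
#' @export
read_expression <- function(path, cohort_map, collapse = c("max", "mean", "first")) {
  collapse <- match.arg(collapse)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression TSV needs a gene column plus >= 1 sample column: ", path)
  genes <- as.character(tab[[1]])
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      if (anyNA(num) && !anyNA(col))
        stop("non-numeric cell in column '", colnames(vals)[j], "' (e.g. row '",
             genes[which(is.na(num))[1]], "')")
      col <- num
    }
    vals[[j]] <- col
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  unknown <- setdiff(colnames(m), names(cohort_map))
  if (length(unknown) > 0)
    stop("samples missing from cohort_map: ", paste(unknown, collapse = ", "))
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    message("collapsing ", length(dup), " duplicated gene id(s) by '", collapse, "'")
    fun <- switch(collapse,
                  max = function(x) apply(x, 2, max),
                  mean = function(x) colMeans(x),
                  first = function(x) x[1, ])
    keep <- m[!duplicated(genes), , drop = FALSE]
    for (g in dup) keep[g, ] <- fun(m[genes == g, , drop = FALSE])
    m <- keep
  }
  ExpressionMatrix(m, cohort_map)
}

#' Write an ExpressionMatrix to TSV
#'
#' Inverse of [read_expression()]: gene IDs in the first column (`gene_id`),
#' sample IDs as header. `read -> write -> read` reproduces values exactly.
#'
#' @param x An [ExpressionMatrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  v <- expr_values(x)
  df <- data.frame(gene_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse gene biotypes from a GTF annotation
#'
#' Reads `gene`-feature rows from a GTF (GENCODE-style attributes) and assigns
#' every gene one of three biotype classes: biotypes listed in
#' `lnc_biotype_names` map to `"lncRNA"`, `"protein_coding"` maps to
#' `"protein_coding"`, everything else to `"other"`. Gene IDs are version
#' stripped. Records without a `gene_id` attribute are skipped with a single
#' warning giving the count.
#'
#' @param path Path to a GTF file.
#' @param lnc_biotype_names Character vector of biotype strings to treat as
#'   long noncoding; the default covers the GENCODE lncRNA classes.
#' @return A `GeneAnnotation` data frame with columns `gene_id`, `symbol`,
#'   `biotype` (factor with levels lncRNA / protein_coding / other).
#' @export
parse_gtf_biotypes <- function(path,
                               lnc_biotype_names = c(
                                 "lncRNA", "lincRNA", "antisense",
                                 "processed_transcript", "sense_intronic",
                                 "sense_overlapping", "3prime_overlapping_ncRNA",
                                 "bidirectional_promoter_lncRNA", "macro_lncRNA",
                                 "non_coding")) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- as.data.frame(gr)
  if ("type" %in% colnames(md)) {
    is_gene <- md$type == "gene"
    if (any(is_gene)) md <- md[is_gene, , drop = FALSE]
  }
  if (!"gene_id" %in% colnames(md)) md$gene_id <- NA_character_
  n_skip <- sum(is.na(md$gene_id) | md$gene_id == "")
  if (n_skip > 0) {
    warning(n_skip, " GTF record(s) without gene_id skipped")
    md <- md[!(is.na(md$gene_id) | md$gene_id == ""), , drop = FALSE]
  }
  if (nrow(md) == 0) stop("no gene records parsed from ", path)
  bt_col <- intersect(c("gene_type", "gene_biotype"), colnames(md))[1]
  raw_bt <- if (!is.na(bt_col)) as.character(md[[bt_col]]) else rep(NA_character_, nrow(md))
  biotype <- ifelse(raw_bt %in% lnc_biotype_names, "lncRNA",
                    ifelse(raw_bt %in% "protein_coding", "protein_coding", "other"))
  symbol <- if ("gene_name" %in% colnames(md)) as.character(md$gene_name) else md$gene_id
  ann <- data.frame(gene_id = strip_gene_version(as.character(md$gene_id)),
                    symbol = symbol,
                    biotype = factor(biotype, levels = c("lncRNA", "protein_coding", "other")),
                    stringsAsFactors = FALSE)
  ann <- ann[!duplicated(ann$gene_id), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("GeneAnnotation", "data.frame")
  ann
}

#' Split an expression matrix into lncRNA and protein-coding partitions
#'
#' Genes are joined to the annotation on version-stripped IDs. Genes absent
#' from the annotation (or annotated `"other"`) are dropped and counted in a
#' `message()`. The two outputs are disjoint by construction.
#'
#' @param expr An [ExpressionMatrix].
#' @param ann A `GeneAnnotation` from [parse_gtf_biotypes()].
#' @return List with `lnc` and `mrna` (`ExpressionMatrix` each) and
#'   `n_dropped`, the number of genes in neither class.
#' @export
split_by_biotype <- function(expr, ann) {
  stopifnot(inherits(ann, "GeneAnnotation"))
  ids <- strip_gene_version(gene_ids(expr))
  bt <- ann$biotype[match(ids, ann$gene_id)]
  lnc_genes <- gene_ids(expr)[!is.na(bt) & bt == "lncRNA"]
  cod_genes <- gene_ids(expr)[!is.na(bt) & bt == "protein_coding"]
  n_dropped <- nrow(expr_values(expr)) - length(lnc_genes) - length(cod_genes)
  if (length(lnc_genes) == 0) stop("no lncRNA genes after annotation join")
  if (length(cod_genes) == 0) stop("no protein-coding genes after annotation join")
  if (n_dropped > 0) message(n_dropped, " gene(s) unannotated or 'other' biotype dropped")
  list(lnc = subset_expression(expr, genes = lnc_genes),
       mrna = subset_expression(expr, genes = cod_genes),
       n_dropped = n_dropped)
}

#' Read an immune-related gene list
#'
#' One identifier per line (ImmPort-style export); blank lines and `#`
#' comments are ignored and IDs are version stripped and de-duplicated.
#'
#' @param path Path to the list file.
#' @return Character vector of gene IDs.
#' @export
read_immune_genes <- function(path) {
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  ids <- unique(strip_gene_version(ids))
  if (length(ids) == 0) stop("immune gene list is empty: ", path)
  ids
}

#' Read a clinical table
#'
#' Requires columns `sample`, `time`, `event`; recognised optional columns are
#' `age`, `sex`, `T_stage`, `N_stage`, `M_stage`, `stage`, `subtype` (others
#' pass through untouched). Samples with missing time or event, negative time,
#' or an event outside {0, 1} are flagged `eligible = FALSE` rather than
#' dropped, so the caller controls exclusion.
#'
#' @param path Path to a TSV.
#' @param time_unit Unit of the `time` column: `"days"`, `"months"` or
#'   `"years"`; stored as an attribute and used by [clinical_time_years()].
#' @param col_map Optional named character vector renaming file columns to the
#'   canonical names, e.g. `c(sample = "bcr_patient_barcode", time = "OS.time")`.
#' @return Data frame of class `ClinicalTable` with attribute `time_unit`.
#' @export
read_clinical <- function(path, time_unit = c("years", "days", "months"),
                          col_map = NULL) {
  time_unit <- match.arg(time_unit)
  clin <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% colnames(clin))
        stop("col_map column not in file: ", col_map[[canon]])
      colnames(clin)[colnames(clin) == col_map[[canon]]] <- canon
    }
  }
  req <- c("sample", "time", "event")
  miss <- setdiff(req, colnames(clin))
  if (length(miss) > 0) stop("clinical table lacks column(s): ", paste(miss, collapse = ", "))
  as_clinical_table(clin, time_unit = time_unit)
}

#' Validate a data frame as a ClinicalTable
#'
#' @param clin Data frame with at least `sample`, `time`, `event`.
#' @param time_unit Unit of `time`.
#' @return The data frame with class `ClinicalTable`, attribute `time_unit`
#'   and a logical `eligible` column.
#' @export
as_clinical_table <- function(clin, time_unit = "years") {
  stopifnot(all(c("sample", "time", "event") %in% colnames(clin)))
  if (anyDuplicated(clin$sample)) stop("duplicate sample ids in clinical table")
  clin$time <- suppressWarnings(as.numeric(clin$time))
  clin$event <- suppressWarnings(as.numeric(clin$event))
  clin$eligible <- !is.na(clin$time) & !is.na(clin$event) &
    clin$time >= 0 & clin$event %in% c(0, 1)
  rownames(clin) <- NULL
  attr(clin, "time_unit") <- time_unit
  class(clin) <- c("ClinicalTable", "data.frame")
  clin
}

#' Survival time in years
#'
#' @param clin A `ClinicalTable`.
#' @return Numeric vector of times converted to years using the table's
#'   declared `time_unit`.
#' @export
clinical_time_years <- function(clin) {
  unit <- attr(clin, "time_unit")
  if (is.null(unit)) unit <- "years"
  clin$time / switch(unit, days = 365.25, months = 12, years = 1)
}

#' Read a CIBERSORT-style immune-cell fraction table
#'
#' Samples in rows (first column = sample ID), cell types in columns.
#' Diagnostic columns named `P-value`, `Correlation`, `RMSE` (and common
#' variants) are tolerated and dropped. Fractions must be nonnegative; rows
#' whose fractions do not sum to 1 within `sum_tol` trigger one warning with
#' the worst deviation.
#'
#' @param path Path to a TSV.
#' @param sum_tol Allowed deviation of each row sum from 1 (default 0.01).
#' @return Numeric matrix, samples x cell types.
#' @export
read_cell_fractions <- function(path, sum_tol = 0.01) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  samples <- as.character(tab[[1]])
  tab <- tab[, -1, drop = FALSE]
  drop <- tolower(colnames(tab)) %in% c("p-value", "p value", "pvalue", "correlation", "rmse",
                                        "absolute score", "absolute score (sig.score)")
  tab <- tab[, !drop, drop = FALSE]
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  rownames(m) <- samples
  if (any(m < 0, na.rm = TRUE)) stop("negative cell fraction in ", path)
  dev <- abs(rowSums(m) - 1)
  if (any(dev > sum_tol))
    warning(sum(dev > sum_tol), " sample(s) with fraction sums off 1 by up to ",
            signif(max(dev), 3))
  m
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (member gene IDs, version
#'   stripped); the descriptions are kept in attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("GMT line(s) with fewer than 3 fields: line ", which(bad)[1])
  sets <- lapply(parts, function(p) unique(strip_gene_version(p[-(1:2)])))
  names(sets) <- vapply(parts, `[[`, "", 1)
  attr(sets, "description") <- vapply(parts, `[[`, "", 2)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
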