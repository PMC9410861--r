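# Ground-truth synthetic cohorts with the statistical structure the pipeline
# assumes: immune-module-driven lncRNA coexpression, tumor/normal shifts,
# pair-indicator-driven Weibull survival with independent censoring, clinical
# covariates, subtype labels, coupled cell fractions and a checkpoint panel.

child_seed <- function(seed, k) {
  # deterministic fan-out of one global seed into per-component seeds,
  # kept strictly below 2^31 - 1
  as.integer((as.double(seed) * 48271 + k * 65537) %% 2147483629)
}

#' Configuration of a synthetic cohort
#'
#' Defaults describe the reference validation cohort used throughout the
#' package: 600 tumors and 60 normals; 200 candidate lncRNAs of which 60 are
#' tied to latent immune modules and 30 are differentially expressed between
#' tumor and normal (|log2 fold change| = 2, about one third up-regulated);
#' 10 true prognostic pairs among the DE lncRNAs with |beta| = 0.8 and
#' alternating sign; Weibull baseline hazard (shape 1.5, scale 8 years,
#' median survival about 6 years at linear predictor 0); 30% target
#' censoring; modest age and stage effects; subtype proportions mirroring a
#' large breast-cancer cohort (LumA > LumB > Basal > Her2).
#'
#' @param n_tumor,n_normal Sample counts per cohort.
#' @param n_lnc Number of candidate lncRNAs.
#' @param n_immune_mrna,n_other_mrna Coding gene counts (immune-related and
#'   background).
#' @param n_modules Number of latent immune modules.
#' @param n_immune_lnc Number of lncRNAs loaded on an immune module.
#' @param n_de Number of differentially expressed immune lncRNAs (must be at
#'   least `2 * n_true_pairs`).
#' @param n_true_pairs Number of true prognostic pairs.
#' @param beta_true Absolute Cox coefficient of each true pair (signs
#'   alternate); 0 gives a global-null cohort.
#' @param de_lfc Absolute log2 fold change of DE lncRNAs (tumor vs normal).
#' @param prob_up Probability that a DE lncRNA is up-regulated in tumor.
#' @param module_loading,noise_sd_immune,noise_sd_other Loadings and log-scale
#'   noise standard deviations of the expression model.
#' @param target_r Minimum population correlation the immune-lncRNA
#'   calibration must achieve (infeasible settings are an error).
#' @param weibull_shape,weibull_scale Baseline hazard parameters (scale in
#'   years).
#' @param censoring_rate Target fraction of censored tumors, in `[0, 1)`.
#' @param gamma_age,gamma_stage Log-hazard effects of (centered) age in years
#'   and tumor stage.
#' @param subtype_props Named proportions of molecular subtype labels
#'   (normalized to sum to 1).
#' @param checkpoint_coupling,fraction_coupling Coupling strengths of the
#'   checkpoint panel (negative) and of the two designated cell types
#'   (Macrophages.M2 positive, T.cells.CD8 negative) to the standardized
#'   true risk score.
#' @return List of class `SimulationConfig`.
#' @export
simulation_config <- function(n_tumor = 600, n_normal = 60,
                              n_lnc = 200, n_immune_mrna = 50, n_other_mrna = 150,
                              n_modules = 4, n_immune_lnc = 60, n_de = 30,
                              n_true_pairs = 10, beta_true = 0.8,
                              de_lfc = 2, prob_up = 0.3,
                              module_loading = 1, noise_sd_immune = 0.5,
                              noise_sd_other = 1, target_r = 0.4,
                              weibull_shape = 1.5, weibull_scale = 8,
                              censoring_rate = 0.3,
                              gamma_age = 0.02, gamma_stage = 0.25,
                              subtype_props = c(LumA = 0.487, LumB = 0.220,
                                                Basal = 0.190, Her2 = 0.103),
                              checkpoint_coupling = 0.6,
                              fraction_coupling = 0.8) {
  cfg <- as.list(environment())
  if (cfg$n_de < 2 * cfg$n_true_pairs)
    stop("n_de must be >= 2 * n_true_pairs")
  if (cfg$n_immune_lnc < cfg$n_de) stop("n_immune_lnc must be >= n_de")
  if (cfg$n_lnc < cfg$n_immune_lnc) stop("n_lnc must be >= n_immune_lnc")
  if (!(cfg$censoring_rate >= 0 && cfg$censoring_rate < 1))
    stop("censoring_rate must be in [0, 1)")
  if (any(cfg$subtype_props < 0) || sum(cfg$subtype_props) <= 0)
    stop("subtype_props must be nonnegative with positive sum")
  cfg$subtype_props <- cfg$subtype_props / sum(cfg$subtype_props)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate lncRNA and coding-gene expression with known truth
#'
#' Immune coding genes load on `n_modules` latent per-sample Gaussian module
#' scores; immune lncRNAs load on the same modules, with noise calibrated so
#' the population correlation with a same-module immune gene exceeds
#' `target_r` (an infeasible calibration is an error naming the parameters).
#' DE lncRNAs share one tumor-cohort log2 mean and receive a normal-cohort
#' shift of `de_lfc` in the drawn direction, so any two DE lncRNAs form a
#' balanced pair indicator in tumors. Values are returned on an FPKM-like
#' scale (`2^log2value`, log-normal). Deterministic given `seed`.
#'
#' @param cfg A `SimulationConfig`.
#' @param seed Integer seed.
#' @return List with `lnc_expr`, `mrna_expr` (both [ExpressionMatrix]) and
#'   `truth` (list: `immune_lnc`, `de` data frame with true log fold
#'   changes, `true_pairs` data frame `gene_a`, `gene_b`, `beta`,
#'   `checkpoint_genes`, module assignments).
#' @export
simulate_expression <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  # population correlation between an immune lncRNA and a same-module immune
  # gene, accounting for the extra between-cohort variance of DE genes
  p_norm <- cfg$n_normal / (cfg$n_tumor + cfg$n_normal)
  var_de <- cfg$de_lfc^2 * p_norm * (1 - p_norm)
  a <- cfg$module_loading
  pop_r <- a^2 / sqrt((a^2 + cfg$noise_sd_immune^2 + var_de) *
                        (a^2 + cfg$noise_sd_immune^2))
  if (pop_r <= cfg$target_r)
    stop("infeasible calibration: population r = ", signif(pop_r, 3),
         " <= target_r = ", cfg$target_r,
         " (module_loading = ", a, ", noise_sd_immune = ", cfg$noise_sd_immune, ")")

  set.seed(child_seed(seed, 1))
  n <- cfg$n_tumor + cfg$n_normal
  tum <- sprintf("TUM%04d", seq_len(cfg$n_tumor))
  nrm <- sprintf("NRM%04d", seq_len(cfg$n_normal))
  samples <- c(tum, nrm)
  cohort <- stats::setNames(rep(c("tumor", "normal"), c(cfg$n_tumor, cfg$n_normal)),
                            samples)
  is_tumor <- cohort == "tumor"

  z <- matrix(stats::rnorm(cfg$n_modules * n), nrow = cfg$n_modules,
              dimnames = list(NULL, samples))

  checkpoints <- c("LAG3", "CTLA4", "PDCD1", "PDCD1LG2")
  imm_ids <- c(checkpoints, sprintf("IMM%04d", seq_len(cfg$n_immune_mrna - length(checkpoints))))
  oth_ids <- sprintf("MRNA%04d", seq_len(cfg$n_other_mrna))
  lnc_ids <- sprintf("LNC%04d", seq_len(cfg$n_lnc))

  mod_of_imm <- rep_len(seq_len(cfg$n_modules), length(imm_ids))
  mu_imm <- stats::runif(length(imm_ids), 2, 6)
  M_imm <- mu_imm + cfg$module_loading * z[mod_of_imm, , drop = FALSE] +
    matrix(stats::rnorm(length(imm_ids) * n, sd = cfg$noise_sd_immune),
           nrow = length(imm_ids))
  mu_oth <- stats::runif(length(oth_ids), 2, 6)
  M_oth <- mu_oth + matrix(stats::rnorm(length(oth_ids) * n, sd = cfg$noise_sd_other),
                           nrow = length(oth_ids))

  immune_lnc <- sort(sample(lnc_ids, cfg$n_immune_lnc))
  mod_of_lnc <- stats::setNames(rep_len(seq_len(cfg$n_modules), length(immune_lnc)),
                                immune_lnc)
  de_genes <- sort(sample(immune_lnc, cfg$n_de))
  de_dir <- ifelse(stats::runif(cfg$n_de) < cfg$prob_up, 1, -1)
  de_lfc <- de_dir * cfg$de_lfc

  pair_genes <- sample(de_genes, 2 * cfg$n_true_pairs)
  ga <- pair_genes[seq_len(cfg$n_true_pairs)]
  gb <- pair_genes[cfg$n_true_pairs + seq_len(cfg$n_true_pairs)]
  swap <- ga > gb  # canonical orientation: gene_a < gene_b
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  betas <- cfg$beta_true * rep_len(c(1, -1), cfg$n_true_pairs)
  true_pairs <- data.frame(gene_a = ga, gene_b = gb, beta = betas,
                           pair = paste(ga, gb, sep = "|"),
                           stringsAsFactors = FALSE)
  # both members of a true pair load on the same immune module: the shared
  # module score cancels in their within-sample comparison, so the pair
  # indicators are mutually independent, gene-level-noise-driven rank flips
  # (distinct prognostic factors rather than redundant readouts of one
  # module contrast)
  mod_of_lnc[gb] <- mod_of_lnc[ga]

  mu_lnc <- stats::setNames(stats::runif(cfg$n_lnc, 2, 6), lnc_ids)
  L <- matrix(0, nrow = cfg$n_lnc, ncol = n, dimnames = list(lnc_ids, samples))
  for (g in lnc_ids) {
    if (g %in% immune_lnc) {
      L[g, ] <- mu_lnc[g] + cfg$module_loading * z[mod_of_lnc[g], ] +
        stats::rnorm(n, sd = cfg$noise_sd_immune)
    } else {
      L[g, ] <- mu_lnc[g] + stats::rnorm(n, sd = cfg$noise_sd_other)
    }
  }
  mu0 <- 4  # shared tumor log2 mean keeps every DE pair indicator balanced
  for (i in seq_along(de_genes)) {
    g <- de_genes[i]
    base <- cfg$module_loading * z[mod_of_lnc[g], ] +
      stats::rnorm(n, sd = cfg$noise_sd_immune)
    L[g, ] <- ifelse(is_tumor, mu0, mu0 - de_lfc[i]) + base
  }

  lnc_expr <- ExpressionMatrix(2^L, cohort)
  M <- rbind(M_imm, M_oth)
  dimnames(M) <- list(c(imm_ids, oth_ids), samples)
  mrna_expr <- ExpressionMatrix(2^M, cohort)
  truth <- list(immune_lnc = immune_lnc,
                de = data.frame(gene = de_genes, lfc_true = de_lfc,
                                stringsAsFactors = FALSE),
                true_pairs = true_pairs,
                checkpoint_genes = checkpoints,
                immune_mrna = imm_ids,
                module_of_lnc = mod_of_lnc,
                module_of_imm = stats::setNames(mod_of_imm, imm_ids),
                population_r = pop_r)
  list(lnc_expr = lnc_expr, mrna_expr = mrna_expr, truth = truth)
}

#' Simulate survival and clinical covariates from true pair indicators
#'
#' Event times follow a proportional-hazards model with Weibull baseline:
#' `h(t | sample) = h0(t) * exp(sum_i beta_i S_i + gamma' z)`, drawn by
#' inverse-transform sampling of the cumulative hazard (shape 1 reduces to
#' the exponential case). Independent exponential censoring is calibrated by
#' root finding so the expected censored fraction matches
#' `cfg$censoring_rate`; an achieved rate more than 10 percentage points off
#' target triggers a warning. Age, sex, stage (with T/N/M consistent with
#' it) and subtype labels are drawn per the configuration.
#'
#' @param cfg A `SimulationConfig`.
#' @param truth Truth list from [simulate_expression()].
#' @param pm_truth `PairIndicatorMatrix` of the true pairs over tumor samples
#'   (build with [build_pair_matrix()] on the simulated tumor expression and
#'   subset to `truth$true_pairs$pair`).
#' @param seed Integer seed.
#' @return A `ClinicalTable` (time in years) for the tumor samples, with
#'   attribute `lp` (the true linear predictor).
#' @export
simulate_survival <- function(cfg, truth, pm_truth, seed = 1) {
  stopifnot(inherits(cfg, "SimulationConfig"),
            inherits(pm_truth, "PairIndicatorMatrix"))
  set.seed(child_seed(seed, 2))
  samples <- colnames(pm_truth$S)
  n <- length(samples)
  tp <- truth$true_pairs
  lp_pairs <- if (nrow(tp) > 0) {
    miss <- setdiff(tp$pair, rownames(pm_truth$S))
    if (length(miss) > 0) stop("true pair(s) missing from pm_truth: ",
                               paste(miss, collapse = ", "))
    drop(tp$beta %*% pm_truth$S[tp$pair, , drop = FALSE])
  } else rep(0, n)

  age <- pmin(pmax(round(stats::rnorm(n, 58, 12)), 25), 90)
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.99, 0.01))
  stage <- sample(1:4, n, replace = TRUE, prob = c(0.35, 0.40, 0.17, 0.08))
  t_stage <- pmin(pmax(stage + sample(c(-1, 0, 1), n, replace = TRUE,
                                      prob = c(0.2, 0.6, 0.2)), 1), 4)
  n_stage <- pmin(pmax(stage - 1 + sample(c(0, 1), n, replace = TRUE,
                                          prob = c(0.6, 0.4)), 0), 3)
  m_stage <- as.integer(stage == 4)
  subtype <- sample(names(cfg$subtype_props), n, replace = TRUE,
                    prob = cfg$subtype_props)

  lp <- lp_pairs + cfg$gamma_age * (age - 58) + cfg$gamma_stage * (stage - 2)
  u <- stats::runif(n)
  etime <- cfg$weibull_scale * (-log(u) * exp(-lp))^(1 / cfg$weibull_shape)

  if (cfg$censoring_rate > 0) {
    # P(C < T | T = t) = 1 - exp(-r t) for C ~ Exp(r); calibrate r so the
    # mean over the drawn event times hits the target censored fraction
    f <- function(logr) mean(1 - exp(-exp(logr) * etime)) - cfg$censoring_rate
    r <- exp(stats::uniroot(f, c(-20, 20))$root)
    ctime <- stats::rexp(n, rate = r)
    time <- pmin(etime, ctime)
    event <- as.integer(etime <= ctime)
  } else {
    time <- etime
    event <- rep(1L, n)
  }
  achieved <- 1 - mean(event)
  if (abs(achieved - cfg$censoring_rate) > 0.10)
    warning("achieved censoring rate ", round(achieved, 3),
            " is > 10 points from target ", cfg$censoring_rate)

  clin <- data.frame(sample = samples, time = time, event = event,
                     age = age, sex = sex, T_stage = t_stage,
                     N_stage = n_stage, M_stage = m_stage, stage = stage,
                     subtype = subtype, stringsAsFactors = FALSE)
  clin <- as_clinical_table(clin, time_unit = "years")
  attr(clin, "lp") <- stats::setNames(lp, samples)
  clin
}

#' Simulate a complete cohort with ground truth
#'
#' Fans the global seed out to per-component child seeds and assembles all
#' pipeline inputs: expression matrices, clinical table, immune gene list,
#' true-pair indicator matrix and true risk score, a cell-fraction table
#' whose `Macrophages.M2` (positively) and `T.cells.CD8` (negatively)
#' fractions are coupled to the true risk score, a checkpoint panel coupled
#' negatively to it, and a gene-set collection with one set concentrated in
#' the immune coding genes of the modules the true-pair lncRNAs load on.
#'
#' @param cfg A `SimulationConfig`.
#' @param seed Integer global seed.
#' @return List of class `SyntheticCohort`: `cfg`, `seed`, `lnc_expr`,
#'   `mrna_expr`, `immune_genes`, `clinical`, `fractions`, `gene_sets`,
#'   `pm_truth`, `truth` (including `risk_true`).
#' @export
simulate_cohort <- function(cfg = simulation_config(), seed = 1) {
  ex <- simulate_expression(cfg, seed)
  truth <- ex$truth
  tum <- cohort_samples(ex$lnc_expr, "tumor")

  pair_gene_ids <- unique(c(truth$true_pairs$gene_a, truth$true_pairs$gene_b))
  pm_truth <- if (length(pair_gene_ids) >= 2) {
    subset_pairs(build_pair_matrix(ex$lnc_expr, pair_gene_ids, samples = tum),
                 pairs = truth$true_pairs$pair)
  } else {
    structure(list(S = matrix(0L, 0, length(tum), dimnames = list(NULL, tum)),
                   pairs = data.frame(gene_a = character(), gene_b = character()),
                   one_frequency = numeric()),
              class = "PairIndicatorMatrix")
  }
  risk_true <- if (nrow(truth$true_pairs) > 0)
    drop(truth$true_pairs$beta %*% pm_truth$S[truth$true_pairs$pair, , drop = FALSE])
  else stats::setNames(rep(0, length(tum)), tum)
  truth$risk_true <- risk_true
  r_std <- if (stats::sd(risk_true) > 0) as.vector(scale(risk_true)) else rep(0, length(tum))

  # checkpoint panel: tumor expression pulled down with the true risk score
  set.seed(child_seed(seed, 3))
  mv <- expr_values(ex$mrna_expr)
  for (g in truth$checkpoint_genes) {
    base <- stats::runif(1, 3, 5)
    logx <- rep(base, ncol(mv))
    logx[colnames(mv) %in% tum] <- base - cfg$checkpoint_coupling * r_std +
      stats::rnorm(length(tum), sd = 0.5)
    logx[!colnames(mv) %in% tum] <- base + stats::rnorm(sum(!colnames(mv) %in% tum), sd = 0.5)
    mv[g, ] <- 2^logx
  }
  mrna_expr <- ExpressionMatrix(mv, expr_cohort(ex$mrna_expr))

  clinical <- simulate_survival(cfg, truth, pm_truth, seed)

  # cell fractions: Dirichlet-like draws; two designated cell types coupled
  # to the true risk score with opposite signs
  set.seed(child_seed(seed, 4))
  cell_types <- c("B.cells.naive", "T.cells.CD8", "T.cells.CD4.memory",
                  "NK.cells", "Monocytes", "Macrophages.M0", "Macrophages.M1",
                  "Macrophages.M2", "Dendritic.cells", "Neutrophils")
  base_shape <- stats::setNames(stats::runif(length(cell_types), 0.5, 2), cell_types)
  fractions <- matrix(0, nrow = length(tum), ncol = length(cell_types),
                      dimnames = list(tum, cell_types))
  for (i in seq_along(tum)) {
    shp <- base_shape
    shp["Macrophages.M2"] <- shp["Macrophages.M2"] * exp(cfg$fraction_coupling * r_std[i])
    shp["T.cells.CD8"] <- shp["T.cells.CD8"] * exp(-cfg$fraction_coupling * r_std[i])
    draw <- stats::rgamma(length(cell_types), shape = shp)
    fractions[i, ] <- draw / sum(draw)
  }

  # gene sets over coding genes: one concentrated in the immune genes of the
  # modules the true-pair lncRNAs load on, plus random background sets
  set.seed(child_seed(seed, 5))
  coding <- gene_ids(mrna_expr)
  truth_modules <- unique(truth$module_of_lnc[pair_gene_ids])
  truth_set <- names(truth$module_of_imm)[truth$module_of_imm %in% truth_modules]
  if (length(truth_set) == 0) truth_set <- truth$immune_mrna[1:5]
  gene_sets <- c(list(TRUTH_MODULE_GENES = truth_set),
                 stats::setNames(lapply(1:5, function(i) sample(coding, 25)),
                                 paste0("RANDOM_SET_", 1:5)))

  structure(list(cfg = cfg, seed = seed,
                 lnc_expr = ex$lnc_expr, mrna_expr = mrna_expr,
                 immune_genes = truth$immune_mrna,
                 clinical = clinical, fractions = fractions,
                 gene_sets = gene_sets, pm_truth = pm_truth, truth = truth),
            class = "SyntheticCohort")
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits everything the pipeline reads: combined expression TSV plus a
#' sample-to-cohort map, clinical TSV, immune gene list, a minimal GTF
#' annotating every simulated gene (lncRNA / protein_coding biotypes, parses
#' cleanly through [parse_gtf_biotypes()]), a CIBERSORT-style fraction table
#' (with a tolerated `P-value` column), a GMT collection, and the ground
#' truth as JSON. Refuses to write into a non-empty directory unless
#' `overwrite = TRUE`.
#'
#' @param cohort A `SyntheticCohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param overwrite Allow writing into a non-empty directory.
#' @return Named character vector of the files written, invisibly.
#' @export
emit_cohort <- function(cohort, dir, overwrite = FALSE) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stop("output directory not empty (use overwrite = TRUE): ", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             samples = file.path(dir, "samples.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             immune = file.path(dir, "immune_genes.txt"),
             gtf = file.path(dir, "genes.gtf"),
             fractions = file.path(dir, "cell_fractions.tsv"),
             gmt = file.path(dir, "gene_sets.gmt"),
             truth = file.path(dir, "truth.json"))

  lv <- expr_values(cohort$lnc_expr); mv <- expr_values(cohort$mrna_expr)
  combined <- ExpressionMatrix(rbind(lv, mv), expr_cohort(cohort$lnc_expr))
  write_expression(combined, paths["expression"])
  utils::write.table(data.frame(sample = sample_ids(combined),
                                cohort = unname(expr_cohort(combined))),
                     paths["samples"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(cohort$clinical), paths["clinical"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(cohort$immune_genes, paths["immune"])

  genes <- c(rownames(lv), rownames(mv))
  biotype <- c(rep("lncRNA", nrow(lv)), rep("protein_coding", nrow(mv)))
  start <- seq_along(genes) * 2000 + 1
  gtf <- sprintf(
    'chr1\tirlpsig_sim\tgene\t%d\t%d\t.\t+\t.\tgene_id "%s"; gene_type "%s"; gene_name "%s";',
    start, start + 999, genes, biotype, genes)
  writeLines(gtf, paths["gtf"])

  fr <- data.frame(Mixture = rownames(cohort$fractions), cohort$fractions,
                   `P-value` = 0.001, check.names = FALSE)
  utils::write.table(fr, paths["fractions"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(cohort$gene_sets, paths["gmt"])

  truth_doc <- list(
    seed = cohort$seed,
    config = unclass(cohort$cfg)[!vapply(unclass(cohort$cfg), is.function, logical(1))],
    immune_lnc = cohort$truth$immune_lnc,
    de = cohort$truth$de,
    true_pairs = cohort$truth$true_pairs,
    checkpoint_genes = cohort$truth$checkpoint_genes,
    risk_true = as.list(cohort$truth$risk_true))
  jsonlite::write_json(truth_doc, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
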