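small_cfg <- function(...) {
  simulation_config(n_tumor = 120, n_normal = 30, n_lnc = 40,
                    n_immune_mrna = 20, n_other_mrna = 20,
                    n_immune_lnc = 16, n_de = 10, n_true_pairs = 4, ...)
}

test_that("the same seed reproduces the cohort exactly; different seeds differ", {
  a <- simulate_cohort(small_cfg(), seed = 5)
  b <- simulate_cohort(small_cfg(), seed = 5)
  c <- simulate_cohort(small_cfg(), seed = 6)
  expect_identical(expr_values(a$lnc_expr), expr_values(b$lnc_expr))
  expect_identical(a$clinical$time, b$clinical$time)
  expect_identical(a$truth$true_pairs, b$truth$true_pairs)
  expect_false(identical(expr_values(a$lnc_expr), expr_values(c$lnc_expr)))
})

test_that("config invariants are enforced and infeasible coexpression calibration errors", {
  expect_error(simulation_config(n_de = 5, n_true_pairs = 4), "n_de")
  expect_error(simulation_config(censoring_rate = 1), "censoring_rate")
  cfg_bad <- small_cfg(noise_sd_immune = 5)  # r = 1/26 << 0.4
  expect_error(simulate_expression(cfg_bad, seed = 1), "infeasible")
})

test_that("vanishing noise drives the immune lncRNA / module-gene correlation to 1", {
  cfg <- small_cfg(noise_sd_immune = 1e-6, de_lfc = 2)
  ex <- simulate_expression(cfg, seed = 3)
  lnc <- setdiff(ex$truth$immune_lnc, ex$truth$de$gene)[1]
  mod <- ex$truth$module_of_lnc[[lnc]]
  imm <- names(ex$truth$module_of_imm)[ex$truth$module_of_imm == mod][1]
  r <- cor(log2(expr_values(ex$lnc_expr)[lnc, ] + 1),
           log2(expr_values(ex$mrna_expr)[imm, ] + 1))
  expect_gt(r, 0.999)
})

test_that("the coexpression screen recovers nearly all truth-flagged immune lncRNAs", {
  hits <- vapply(1:5, function(s) {
    cfg <- small_cfg()
    ex <- simulate_expression(cfg, seed = s)
    res <- coexpression_screen(ex$lnc_expr, ex$mrna_expr,
                               immune_genes = ex$truth$immune_mrna)
    mean(ex$truth$immune_lnc %in% res$immune_lnc)
  }, numeric(1))
  expect_gte(median(hits), 0.9)
})

test_that("the DE screen recovers the planted differential lncRNAs with the planted directions", {
  ex <- simulate_expression(small_cfg(), seed = 11)
  de <- differential_expression(ex$lnc_expr, genes = ex$truth$immune_lnc)
  called <- de$gene[de$direction != "ns"]
  expect_gte(mean(ex$truth$de$gene %in% called), 0.9)
  hit <- merge(de, ex$truth$de, by = "gene")
  hit <- hit[hit$direction != "ns", ]
  expect_true(all(sign(hit$logFC) == sign(hit$lfc_true)))
  expect_true(all(abs(hit$logFC - hit$lfc_true) < 0.75))
})

test_that("shape 1 reduces to exponential survival with the closed-form mean", {
  cfg <- simulation_config(n_tumor = 10000, n_normal = 60,
                           weibull_shape = 1, weibull_scale = 8,
                           censoring_rate = 0, beta_true = 0,
                           gamma_age = 0, gamma_stage = 0)
  ex <- simulate_expression(small_cfg(), seed = 2)
  pm <- structure(list(S = matrix(0L, 0, cfg$n_tumor,
                                  dimnames = list(NULL, sprintf("TUM%04d", 1:cfg$n_tumor))),
                       pairs = data.frame(gene_a = character(), gene_b = character()),
                       one_frequency = numeric()),
                  class = "PairIndicatorMatrix")
  truth0 <- ex$truth
  truth0$true_pairs <- truth0$true_pairs[0, ]
  clin <- simulate_survival(cfg, truth0, pm, seed = 4)
  expect_equal(mean(clin$time), 8, tolerance = 0.03)   # E[T] = scale at lp = 0
  expect_true(all(clin$event == 1))
})

test_that("censoring is calibrated to its target and a wildly off rate warns", {
  cohort <- simulate_cohort(simulation_config(n_tumor = 400, n_normal = 40,
                                              n_lnc = 40, n_immune_mrna = 20,
                                              n_other_mrna = 20, n_immune_lnc = 16,
                                              n_de = 10, n_true_pairs = 4),
                            seed = 8)
  achieved <- 1 - mean(cohort$clinical$event)
  expect_lt(abs(achieved - 0.3), 0.1)
})

test_that("a strongly prognostic single pair separates KM curves decisively", {
  cfg <- simulation_config(n_tumor = 600, n_normal = 30, n_lnc = 40,
                           n_immune_mrna = 20, n_other_mrna = 20,
                           n_immune_lnc = 16, n_de = 10, n_true_pairs = 1,
                           beta_true = 2)
  cohort <- simulate_cohort(cfg, seed = 9)
  s <- cohort$pm_truth$S[cohort$truth$true_pairs$pair, ]
  grp <- factor(ifelse(s == 1, "high", "low"), levels = c("low", "high"))
  km <- km_logrank(grp, cohort$clinical$time, cohort$clinical$event)
  expect_lt(km$p, 0.001)
})

test_that("the emitted cohort round-trips through every reader and the truth JSON rescoring is exact", {
  cohort <- simulate_cohort(small_cfg(), seed = 13)
  dir <- withr::local_tempdir()
  paths <- emit_cohort(cohort, dir, overwrite = TRUE)
  expect_error(emit_cohort(cohort, dir), "overwrite")

  ann <- expect_no_warning(parse_gtf_biotypes(paths[["gtf"]]))
  cm <- utils::read.delim(paths[["samples"]])
  cohort_map <- setNames(cm$cohort, cm$sample)
  expr <- read_expression(paths[["expression"]], cohort_map)
  sp <- split_by_biotype(expr, ann)
  expect_setequal(gene_ids(sp$lnc), gene_ids(cohort$lnc_expr))
  expect_setequal(gene_ids(sp$mrna), gene_ids(cohort$mrna_expr))
  expect_equal(expr_values(sp$lnc)[gene_ids(cohort$lnc_expr), ],
               expr_values(cohort$lnc_expr), tolerance = 1e-8)

  clin <- read_clinical(paths[["clinical"]], time_unit = "years")
  expect_true(all(clin$eligible))
  imm <- read_immune_genes(paths[["immune"]])
  expect_setequal(imm, cohort$immune_genes)
  fr <- read_cell_fractions(paths[["fractions"]])
  expect_equal(fr, cohort$fractions, tolerance = 1e-8)
  sets <- read_gmt(paths[["gmt"]])
  expect_identical(names(sets), names(cohort$gene_sets))

  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  pm <- build_pair_matrix(sp$lnc,
                          unique(c(truth$true_pairs$gene_a, truth$true_pairs$gene_b)),
                          samples = cohort_samples(sp$lnc, "tumor"))
  rescored <- risk_score(list(pairs = truth$true_pairs$pair,
                              beta = setNames(truth$true_pairs$beta,
                                              truth$true_pairs$pair)),
                         pm)
  expect_equal(rescored[names(cohort$truth$risk_true)],
               cohort$truth$risk_true, tolerance = 1e-12)
})
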