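---
title: "Immune-related lncRNA pair signatures: model, assumptions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune-related lncRNA pair signatures: model, assumptions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irlpsig)
```

## The problem and the statistic

Prognostic expression signatures built from absolute transcript abundances
inherit every normalization problem of RNA-seq: batch effects, library-size
differences, platform shifts. `irlpsig` implements a signature family that
sidesteps this by using only the *within-sample ordering* of gene pairs.
For two long noncoding RNAs (lncRNAs) $A < B$ (canonical lexicographic
order), the pair indicator in sample $j$ is

$$S_{AB}(j) = \mathbf{1}\{x_{Aj} > x_{Bj}\},$$

with ties scored 0. Because $S$ depends only on which member of the pair is
more abundant *inside one sample*, it is invariant to any strictly
increasing transformation applied per sample — FPKM, TPM, log, quantile
shifts all give the same matrix. This invariance is a tested property, not
an aspiration (see `test-pair-matrix.R` and the acceptance suite).

The pipeline narrows the pair universe in stages:

1. **Immune-related lncRNA screen.** Pearson correlation (Spearman
   available) between every lncRNA and every immune-related coding gene on
   `log2(x + 1)` abundances across tumor and normal samples jointly; a
   lncRNA is immune-related when some immune gene passes `r > 0.4` and
   `p < 0.001` (strict). The tumor+normal default reflects that
   coexpression is a property of the transcriptional program, not of the
   contrast; a tumor-only screen is available through the `samples`
   argument.
2. **Differential expression.** For the immune-related lncRNAs,
   `logFC = log2((mean_T + 0.001)/(mean_N + 0.001))` with a two-sided
   Wilcoxon rank-sum test and Benjamini–Hochberg FDR; called when
   `|logFC| > 1.5` and `FDR < 0.5`. The unusually permissive FDR bound is
   retained deliberately as the workflow's stated operating point (it is a
   screening stage, not an inference); both thresholds are arguments. The
   rank-sum test was chosen over a model-based test because the downstream
   statistic is itself rank-based and FPKM-like values have no natural
   count model. The `0.001` pseudo-count only guards unexpressed genes;
   results are insensitive to its magnitude at realistic abundances.
3. **Pair matrix and skew filter.** All $\binom{D}{2}$ pairs of the $D$
   differential lncRNAs are formed on *tumor* samples (survival modeling
   concerns tumors; normals would dilute the indicator distribution). A
   pair is kept only when both indicator values occur in more than 20% of
   samples (`0.2 < \bar S < 0.8`, strict at the boundary): a near-constant
   indicator cannot stratify anything.

## Signature selection and the risk score

Selection is the standard three-stage funnel used with high-dimensional
survival predictors:

- **Univariate Cox** per pair (Efron tie handling — many ties are
  guaranteed with a binary covariate), keeping Wald `p < 0.05`. Constant
  pairs carry no information and are skipped; non-convergent fits are
  dropped loudly, never silently.
- **Lasso-penalized Cox** over the survivors via `glmnet` with 10-fold
  cross-validated partial-likelihood deviance. Folds are stratified by
  event status and fixed by the seed, so the chosen penalty is
  reproducible. The `lambda.min` rule is the default: the signature family
  this package implements historically retains a few dozen pairs out of
  roughly a thousand, which matches the less sparse rule; `lambda.1se` is
  an argument. An empty active set falls back to the smallest penalty with
  one nonzero coefficient, with a message.
- **Bidirectional stepwise AIC** on the multivariate Cox model of the
  Lasso-selected pairs (`MASS::stepAIC` from the full model). Identical
  indicator rows are collapsed first and aliased covariates dropped, so
  collinearity cannot crash the refit. The final coefficients $\beta_i$
  come from the refitted multivariate model, and the risk score is

$$\mathrm{RS}(j) = \sum_{i=1}^k \beta_i\, S_i(j).$$

All three stages are recorded in the model's provenance (uni-Cox
survivors, Lasso set, penalty, seed), because the stages can disagree and
a reader of a serialized model should see the full funnel.

## Evaluation

The **time-dependent ROC** at horizon $t$ uses the cumulative-case /
dynamic-control definition: cases have an event by $t$, controls survive
past $t$, samples censored at or before $t$ are excluded. The AUC is the
Mann–Whitney probability with ties counted one half, and the cutoff is the
Youden maximizer ($\mathrm{TPR}-\mathrm{FPR}$), ties broken toward the
lower threshold. No inverse-probability-of-censoring weighting is applied:
the simple estimator is transparent, exactly oracle-checkable by
brute-force threshold scans, and adequate at the censoring levels the
package targets; an IPCW variant is a natural extension, not a default.
The cutoff is fixed once, on the 5-year ROC of the fitting cohort, and
reused by every downstream grouping — one source of truth for "high risk".

Kaplan–Meier curves and the two-group log-rank test (hypergeometric
variance) compare the groups overall and independently within each
molecular subtype; a stratum with an empty group is skipped with a
warning, because an impossible comparison is different from a null result.
Clinical association uses the unpaired Wilcoxon rank-sum for two-level
variables and Kruskal–Wallis beyond; the source workflows for this
signature family describe this step inconsistently (a paired t-test in one
place, a signed-rank test in another — both misnomers for independent
groups), so the package implements the defensible unpaired rank tests and
documents the choice here rather than guessing an intent. Uni- and
multivariate Cox models of the risk score with numerically coded clinical
covariates report HR, Wald CI and p; exactly collinear covariates are
dropped in listing order.

Immune associations are deliberately all rank-based (Wilcoxon, Spearman,
BH within stratum), which makes every output invariant to monotone
rescaling of the risk score. Cell-type fractions are *consumed*, never
computed: deconvolution engines are external tools with their own
licenses, and the module only requires a samples × cell-types fraction
table. Enrichment is the classic hypergeometric overrepresentation test
with the universe restricted to coding genes present in the expression
matrix — conditioning on what was measurable, not on the genome.

## What the synthetic cohorts emulate

`simulate_cohort()` generates the structure every stage assumes, with the
truth serialized beside the data:

- Latent per-sample immune-module scores $z_m \sim N(0,1)$ (4 modules);
  immune coding genes and immune lncRNAs load on them with unit loading
  and log-scale noise SD 0.5, giving a population lncRNA–gene correlation
  of about 0.8, comfortably above the 0.4 screening threshold. An
  infeasible calibration (noise too large for the requested correlation)
  is a hard error, not a silent miss.
- 30 of the 60 immune lncRNAs receive a tumor/normal shift of 2 log2
  units (about one third up-regulated), well past the 1.5 threshold.
  All DE genes share one tumor log2 mean, so every candidate pair has an
  indicator frequency near 0.5 and survives the skew filter.
- **Both members of a true pair load on the same immune module.** The
  shared module score cancels inside the within-sample comparison, so
  each true pair's indicator is an independent, gene-noise-driven rank
  flip. This is a deliberate design choice: the planted pairs are meant
  to be distinct prognostic factors. If pairs instead straddled two
  modules, different pairs would ride the same module contrast, their
  indicators would be strongly correlated, and opposite-sign effects
  would cancel in marginal screens — a confounded ground truth rather
  than a harder one.
- Survival follows $h(t) = h_0(t)\exp(\sum_i \beta_i S_i + \gamma^T z)$
  with a Weibull baseline (shape 1.5, scale 8 years; median ≈ 6.3 years
  at linear predictor 0), drawn by inverse-transform sampling; shape 1 is
  the exponential special case used as a closed-form oracle in the tests.
  Ten true pairs at $|\beta| = 0.8$ with alternating signs give a linear
  predictor SD of about 1.25. Independent exponential censoring is
  calibrated by root finding to a 30% target; age (SD 12 years,
  0.02/year) and stage (0.25/stage) add modest clinical structure.
  Subtype labels are drawn at proportions typical of a large
  breast-cancer cohort (LumA 0.49, LumB 0.22, Basal 0.19, Her2 0.10).
- The fraction table couples `Macrophages.M2` positively and
  `T.cells.CD8` negatively to the standardized true risk score (gamma
  draws scaled by $e^{\pm 0.8 r}$, then normalized), giving the immune
  module a known signed target; the four checkpoint genes are coupled
  negatively. Under the global null these couplings vanish by
  construction because the true score is constant.

What the generator does **not** emulate: negative-binomial count noise,
library-size and batch effects, correlated censoring, subtype-dependent
survival or expression differences, and inter-patient heterogeneity of
module structure. Passing the recovery study therefore demonstrates that
the pipeline's inference machinery is correct and well calibrated under
its own assumptions — not that any particular clinical cohort will yield a
signature of the same quality.

## Validation studies and problem sizes

The reference experiment (`score_synthetic_run()`) draws the default
cohort (600 tumors, 60 normals, 200 candidate lncRNAs, 10 true pairs,
$|\beta| = 0.8$, 30% censoring), fits on a 70% tumor split plus all
normals, and evaluates on the held-out 30%: true-pair recovery and
coefficient signs, Harrell's C, the 5-year AUC, and the log-rank p of the
training-derived cutoff. Medians over 10 seeds are the reported
quantities; typical values are full recovery, C ≈ 0.73, AUC ≈ 0.79. The
matched global-null study ($\beta = 0$) checks that held-out concordance
sits at 0.5 and that BH-significant cell types stay at the nominal rate;
when no signature can be established under the null — a legitimate
outcome — the run is scored with a constant score (concordance 0.5 by
construction) and the immune check falls back to a score-independent
split. Ten seeds per arm keep the full suite comfortably fast on one CPU
while making medians stable; the same studies are what
`scripts/acceptance.R` recomputes.

## Numerical choices and degenerate inputs

- Ties in the pair indicator score 0 (the "former" gene must be strictly
  higher); exact FPKM ties are rare and the rule is deterministic.
- All published-style thresholds are strict inequalities as printed
  (`r > 0.4`, `p < 0.001`, `|logFC| > 1.5`, `FDR < 0.5`, frequency
  strictly between 0.2 and 0.8, uni-Cox `p < 0.05`).
- Ensembl-style version suffixes are stripped before every identifier
  join; duplicate expression rows collapse by per-sample maximum
  (deterministic, favors detected signal; `mean`/`first` available).
- Correlations on constant profiles are undefined: such rows are skipped
  with warnings in screens and reported as `NA` in panel correlations.
- Youden ties break toward the lower threshold with a $10^{-9}$ guard
  against floating-point noise (distinct Youden values on $n$ samples
  differ by at least $1/n^2$).
- Samples with missing time or event are flagged ineligible and excluded
  from model fitting but never silently deleted from the table.

## Known limitations

Pairs are restricted to lncRNA–lncRNA comparisons; cross-biotype pairs,
elastic-net variants, stability selection, competing risks, IPCW-corrected
ROC and nomograms are out of scope. The coexpression and DE screens are
marginal (no covariate adjustment). The generator's idealizations listed
above bound what the validation studies can claim about real cohorts.
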