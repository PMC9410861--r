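# irlpsig

Prognostic signatures from **immune-related lncRNA pairs** (IRLPs) in tumor
expression cohorts, for researchers who want survival stratification that is
robust to normalization. Instead of modeling transcript abundances, the
signature is built from binary within-sample rank indicators: for two
lncRNAs `A < B`,

    S_AB(j) = 1  if  expr(A, j) > expr(B, j),   else 0,

so every downstream quantity depends only on which member of the pair is
more abundant inside each sample — invariant to FPKM/TPM choice, library
size and any per-sample monotone transformation. The risk score of a
signature of `k` selected pairs with multivariate Cox coefficients `β_i` is

    RS(j) = Σ_{i=1..k} β_i · S_i(j).

The pipeline: (1) screen lncRNAs for immune relatedness by coexpression with
a curated immune gene list (Pearson `r > 0.4`, `p < 0.001`); (2) keep those
differentially expressed between tumor and normal (`|log2 FC| > 1.5`,
`FDR < 0.5`, Wilcoxon + Benjamini–Hochberg); (3) form all candidate pairs
and drop near-constant ones (both indicator values in > 20% of samples);
(4) select pairs by univariate Cox (`p < 0.05`), Lasso-penalized Cox with
10-fold cross-validation (`glmnet`, `lambda.min`), and bidirectional
stepwise AIC refinement of the multivariate Cox model; (5) evaluate by
time-dependent ROC (1/3/5-year) with a Youden-optimal cutoff, Kaplan–Meier
and log-rank overall and per molecular subtype, clinical covariate Cox
models, immune cell-fraction and checkpoint-gene association, and
hypergeometric gene-set enrichment of coding genes correlated with the
signature lncRNAs (`|R| > 0.6`, `p < 0.05`). A synthetic cohort generator
with serialized ground truth makes every stage testable offline.

## Worked example

A compact synthetic cohort (300 tumors, 40 normals, 80 candidate lncRNAs,
5 true pairs planted at |β| = 0.8) run end to end:

```r
library(irlpsig)
cfg <- simulation_config(n_tumor = 300, n_normal = 40, n_lnc = 80,
                         n_immune_mrna = 30, n_other_mrna = 40,
                         n_immune_lnc = 30, n_de = 14, n_true_pairs = 5)
cohort <- simulate_cohort(cfg, seed = 101)
fit <- run_irlp_pipeline(cohort$lnc_expr, cohort$mrna_expr,
                         cohort$immune_genes, cohort$clinical, seed = 101)
```

which prints (stage sizes, final signature, ROC, risk-group survival and
checkpoint-panel association):

```
immune-related lncRNAs: 30 | DE: 13 | pairs kept: 78
SignatureModel: 5 pairs
             pair       beta        hr            p
1 LNC0006|LNC0057 -0.6970204 0.4980671 1.331854e-06
2 LNC0011|LNC0036  0.4981418 1.6456605 4.007272e-04
3 LNC0013|LNC0037 -0.3884865 0.6780824 5.313628e-03
4 LNC0056|LNC0071  0.7472038 2.1110887 1.976978e-07
5 LNC0074|LNC0080 -0.6501420 0.5219716 4.580800e-06
TimeROC at t = 5: AUC = 0.7675, Youden cutoff = -0.5405 (143 cases, 107 controls, 50 excluded)
log-rank chisq = 64.8, p = 8.41e-16; groups: low 128 / high 172
      gene        rho            p      p_group missing
1     LAG3 -0.6845390 8.241850e-43 1.560627e-23   FALSE
2    CTLA4 -0.7089576 4.157803e-47 1.137180e-25   FALSE
3    PDCD1 -0.6679618 3.987431e-40 1.748656e-22   FALSE
4 PDCD1LG2 -0.7129864 7.358721e-48 1.158744e-26   FALSE
true pairs recovered: 4 of 5
```

Reading it: the funnel kept 78 balanced pairs of 13 differential
immune-related lncRNAs and settled on a 5-pair signature (each row shows
the multivariate Cox coefficient, hazard ratio and Wald p). The risk score
separates 5-year outcomes with AUC 0.77; dichotomized at the Youden cutoff,
the high-risk group has markedly worse survival (log-rank p ≈ 8e-16), and
all four immunosuppression checkpoint genes correlate negatively with the
score — the structure the generator planted. Four of the five planted pairs
are recovered with correct coefficient signs; the fifth is replaced by a
correlated proxy pair, the expected failure mode of marginal screening.

For real data, start instead from `read_expression()` +
`parse_gtf_biotypes()` + `split_by_biotype()` + `read_immune_genes()` +
`read_clinical()`, and bring deconvolved cell fractions via
`read_cell_fractions()`; `emit_cohort()` shows the exact file formats.

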