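# editome

Survival-guided analysis of A-to-I RNA editing profiles in tumour cohorts.

Adenosine-to-inosine RNA editing, catalysed by ADAR enzymes, appears as A>G
substitutions in RNA-seq reads; at a known site the editing level of a
sample is G/(A+G). In glioma, editing profiles carry prognostic information
that is *sex-dependent*: hyper-editing associates with poor survival in
females but better survival in males. `editome` implements the full
analysis that establishes and exploits this:

1. **Site calling and QC** — a cell (site, sample) is accepted as edited
   when coverage ≥ 10, edited-G reads ≥ 3, and an exact binomial test
   against a 0.1% sequencing-error rate passes at BH-adjusted p < 0.05;
   discriminative sites must vary among patients
   (median(|x − Q3(x)|) > 0), and samples with > 20% low-coverage sites
   are dropped.
2. **Stratification** — UMAP embedding of editing profiles, HDBSCAN
   density clustering (implemented in-package) over a hyperparameter grid,
   selecting the labelling with the smallest log-rank p; survival is then
   evaluated per sex (Kaplan–Meier, log-rank, multivariate Cox with Efron
   ties).
3. **Differential editing** — per-comparison filter cascade (near-constant
   sites out; |Δmedian| ≤ 3% out), two-sided Mann–Whitney U with BH
   correction (DES: adjusted p < 0.05), signed gene ranking by
   sign(Δ)·(−log₁₀ p), and rank–rank hypergeometric overlap maps between
   comparisons.
4. **Regulation** — per-site OLS of log(expression + 0.5) on editing level
   controlling for age; genes with FDR < 10% correlations are
   editing-regulated if ADAR1 knockdown changed their expression
   (adjusted p < 0.05) opposite in sign to the regression coefficient;
   3'UTR enrichment (Fisher exact) and knockdown-direction (exact
   binomial) tests; age-adjusted per-sex Cox screen of prognostic sites
   at FDR < 0.15, with the sex-dependent 30%/70% dichotomization rule for
   per-site KM curves.
5. **Cross-cohort validation** — sex-specific random-forest classifiers on
   DES features (collinearity-pruned, tuned by five-fold CV with a pooled
   out-of-fold log-rank objective) transferred to an independent cohort.
6. **Synthetic cohorts** — `simulate_cohort()` generates full pipeline
   inputs with planted clusters, sex-opposite hazards, editing-coupled
   expression and knockdown response, so every stage is testable without
   any data download.

## Worked example

```r
library(editome)

sim  <- simulate_cohort(sim_config(seed = 7))     # 200 samples, 2000 sites
disc <- select_discriminative_sites(sim$mat)
fit  <- fit_editing_subtypes(disc, sim$meta, stratify_config(seed = 7))
print(fit)
for (s in c("female", "male")) {
  e <- fit$per_sex[[s]]
  cat(sprintf("%s: log-rank p = %.3g, direction = %s\n", s, e$p, e$direction))
}

cl  <- fit$labels
cmp <- comparison("F1", names(cl)[cl == 2], names(cl)[cl == 1], "female")
des <- test_des(prefilter_sites(sim$mat, cmp), cmp)
cat(sprintf("DESs: %d of %d tested sites\n", sum(des$is_des), nrow(des)))
```

prints

```
discriminative sites: kept 1997/2000 (2 no evidence, 1 constant)
editing_subtypes: 200 samples, 2 clusters (+0 noise), seed 7
  selection log-rank p = 0.00489 at grid point (mcs=10, eps=0, ms=5)
female: log-rank p = 0.0209, direction = cluster2_worse
male: log-rank p = 8.22e-07, direction = cluster2_better
DESs: 205 of 207 tested sites
```

The two recovered clusters coincide with the planted ones; cluster 2 (the
hyper-edited group) has worse survival among females and better survival
among males — the sexually dimorphic pattern the pipeline is designed to
detect. The DES step then recovers the sites separating the risk groups.
A full tour of the methods, their assumptions, and the tunable parameters
is in `vignettes/editing-survival-pipeline.Rmd`.

A thin command-line wrapper over the same functions is installed at
`inst/cli/editome.R` (subcommands `validate`, `simulate`, `filter`,
`stratify`), e.g.

```sh
Rscript inst/cli/editome.R simulate --seed 42 --out cohort/
Rscript inst/cli/editome.R stratify --seed 42 cohort/matrix.tsv cohort/meta.tsv out/
```

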