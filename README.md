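# imputeval

Evaluation of genotype imputation accuracy and quality in admixed study
populations.

Genome-wide association studies impute untyped SNPs from reference
haplotype panels. For admixed populations such as African Americans, the
panel choice is a genuine trade-off: diverse "cosmopolitan" panels add
reference haplotypes and SNP density, but also flood the output with
low-frequency SNPs that do not segregate in the study population's
ancestries and are imputed poorly. `imputeval` is an R package plus a
small analysis workflow for quantifying that trade-off with a masked-SNP
experiment: hide a fraction of genotyped SNPs, impute, score against the
hidden truth, stratify by minor allele frequency (MAF), and filter SNPs
that are monomorphic in a reference subpanel. It is aimed at statistical
geneticists benchmarking imputation strategies and at method developers
who need the metrics and the bookkeeping to be exactly reproducible.

## What it computes

For each masked SNP, with `N` the 3×3 table of true genotype (rows)
versus most-likely imputed genotype (columns) and `n = Σ N`:

* **Concordance** — observed agreement `P0 = tr(N)/n`.
* **IQS** (imputation quality score) — concordance corrected for chance
  agreement, Cohen's-kappa style:
  `IQS = (P0 − Pc) / (1 − Pc)` with `Pc = Σ_g N_g· N_·g / n²`,
  the agreement expected from the marginal genotype frequencies alone.
  Informative exactly where concordance is inflated: low-MAF SNPs.
* **r2hat** — the dosage variance-ratio estimate of the squared
  correlation between imputed and true genotype,
  `r̂² = Var(d) / (2 p̂ (1 − p̂))` with `p̂ = mean(d)/2`,
  computable for every imputed SNP (no truth needed) and averaged
  overall and in 1%-MAF bins. The literal squared Pearson correlation
  (`true_rsq`) is available for masked SNPs.

Around the metrics: strict SNP QC (MAF < 1%, call rate < 95%, exact
Hardy–Weinberg p < 1e-4), duplicate pruning by identity-by-state,
relatedness pruning with the stratification-robust kinship estimator
(0.0441 third-degree cutoff), ancestry-fraction filtering, nested
reference-panel composition (N = 234 / 625 / 1092), and pre- or
post-imputation removal of SNPs monomorphic in a subpanel, including the
conventional `r̂² ≥ 0.3` threshold filter.

A synthetic-data module (Balding–Nichols population divergence, two-way
admixture, a parameterized imputation channel with closed-form metric
expectations) exercises the whole pipeline end to end without any
external data. Real imputer output is consumed through standard formats:
VCF (GT / GP / DS), IMPUTE2-style GEN triplets, MaCH-style dosage text.

## Worked example

```r
library(imputeval)

sc <- scenario_three_panels(sim_config(seed = 1))
sc
#> imputation_scenario: 3000 SNPs (1000 planted), 200 samples, 3 panels, 10 mask reps
#>   close    N= 234  rsq_mean=0.647  maf<=2%: 48.9%
#>   afr_eur  N= 625  rsq_mean=0.539  maf<=2%: 59.1%
#>   all      N=1092  rsq_mean=0.461  maf<=2%: 65.9%

compare_summaries(sc$summaries)$table
#>     panel concordance   iqs rsq_mean rsq_le2 rsq_gt2 frac_maf_le2 n_polymorphic
#> 1   close       0.989 0.789    0.647   0.478   0.809        0.489          2000
#> 2 afr_eur       0.989 0.789    0.539   0.352   0.809        0.591          2500
#> 3     all       0.989 0.789    0.461   0.282   0.809        0.659          3000
```

Reading the table: masked-SNP accuracy (concordance 98.9%, IQS 0.789) is
identical across panels — the same SNPs are masked and the shared-SNP
channel is identical — but overall mean r2hat *falls* with panel
diversity (0.647 → 0.539 → 0.461) while the common-SNP stratum
(`rsq_gt2`, MAF > 2%) holds at 0.809. The drop is driven entirely by
low-frequency SNPs the diverse panels introduce: the MAF ≤ 2% fraction of
imputed SNPs rises from 48.9% to 65.9%, and a third of the cosmopolitan
panel's SNPs are monomorphic in the close panel. Filtering those SNPs
after imputation restores the close panel's quality exactly:

```r
pf <- post_impute_filter(sc$metrics$all, sc$panels$close, sc$plans)
pf$summary$rsq_mean
#> [1] 0.6471941
```

The `r̂² ≥ 0.3` threshold is the weaker mitigation — it reduces but does
not eliminate the population-specific SNPs (2.7% of survivors remain
monomorphic in the close panel under the default conditions).

## Analysis workflow

The numbered drivers under `analysis/` run the study end to end, writing
tables under `results/`:

```sh
Rscript analysis/01_simulate_study.R      # population freqs, admixed truth
Rscript analysis/02_quality_control.R     # SNP QC + subject-QC demonstration
Rscript analysis/03_masking_evaluation.R  # masking, metrics, per-panel summaries
Rscript analysis/04_panel_filters.R       # monomorphic / threshold filters
Rscript analysis/05_compare_panels.R      # comparison table, r2hat-vs-MAF profile
```

The methods vignette
(`vignettes/imputation-quality-evaluation.Rmd`) documents the model, the
averaging conventions, the synthetic generator's design and its
limitations.

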