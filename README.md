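# afprs

Case-control and post-cardioversion recurrence analysis of a small panel of
atrial-fibrillation (AF) risk variants, built around a population-tailored
**unweighted polygenic risk score** (PRS).

`afprs` is for biostatisticians and cardio-genetics researchers who work
with small candidate-SNV panels rather than genome-wide scores. It
implements, end to end:

* **Panel and data I/O** — an eight-SNV AF panel (*CAV1* rs3807989, *SOX5*
  rs11047543, *MYH7* rs28631169, *ZFHX3* rs2106261, *KCNN3* rs13376333,
  *KCNJ5* rs75190942, *PITX2* rs2200733 and rs6838973) with designated risk
  alleles and frequencies; genotype input from VCF or dosage CSV, with
  REF/ALT orientation resolved to risk-allele dosage at load time; a typed
  phenotype table with strict 0/1 booleans and explicit missingness.
* **Association machinery** — 2×2 odds ratios with Woolf 95% CIs
  (`exp(ln OR ± z₀.₉₇₅·√(1/a+1/b+1/c+1/d))`), uncorrected Pearson χ² tests,
  Haldane–Anscombe correction for zero cells, multivariate logistic models
  with Wald inference and separation flags, variance inflation factors, and
  the CHA2DS2-VASc / combined-comorbidity composite variables.
* **The score** — `PRS = Σ effective dosages` over the panel (range 0–16).
  A variant whose listed risk allele shows a *protective* trend in the
  per-SNV recurrence models (p < 0.1 **and** OR < 1) is **flipped**: the
  opposite allele is counted (`2 − dosage`), tailoring the score to the
  analysed population. The score is dichotomized strictly at `> 7`.
* **A seeded synthetic-cohort generator** — Hardy–Weinberg genotypes at the
  panel frequencies, a logistic occurrence model over carrier status, a
  logistic recurrence model driven by `PRS > 7` and AF duration, and
  covariate marginals matched to the emulated study population (259 cases /
  108 controls, 97 followed after cardioversion, 50 with echo data). All
  of it bit-reproducible from one seed.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` accessors, `autoplot()` for forest plots.

## Worked example

Simulate a cohort with the default (study-sized) configuration and run the
whole analysis:

```r
library(afprs)

study <- run_full_study(config = cohort_config(seed = 2021))
print(study)
#> <afprs_study> 259 cases / 108 controls
#> <afprs_flips> no variants flipped (alpha = 0.1)
#> PRS models fitted: occurrence_prs, recurrence_prs, echo

glance(study)
#> # A tibble: 1 × 8
#>   n_cases n_controls n_followed n_recurred recurrence_fraction n_flipped ...
#> 1     259        108         97         58               0.598         0
```

58 of 97 followed cases recurred (59.8%) — the recurrence marginal the
generator is calibrated to. The per-SNV occurrence models recover the one
injected genotype effect, the rs2200733 (*PITX2*) carrier odds ratio
(generating value 2.31):

```r
occ <- study$snv_occurrence
occ[occ$term == "rs2200733", c("term", "or", "ci_low", "ci_high", "p_value")]
#>   term         or ci_low ci_high p_value
#> 1 rs2200733  2.53   1.28    5.04 0.00797
```

At the study's size the dichotomized score is rare (4 subjects above 7
among the 97 followed cases here), and the recurrence-PRS model is flagged
rather than trusted:

```r
fit <- study$prs_models$recurrence_prs
fit[fit$term == "prs_above", c("term", "or", "p_value", "warning")]
#>   term             or p_value              warning
#> 1 prs_above 1.87e+09   0.999  possible_separation
```

That `possible_separation` flag is the package telling you the subgroup is
too small for a stable maximum-likelihood estimate — the same instability
that makes tiny-subgroup PRS odds ratios in this literature balloon with
huge confidence intervals. The methods vignette
(`vignettes/afprs-methods.Rmd`) quantifies when the full pipeline recovers
the generating PRS effect reliably and when it cannot.

Forest-plot data and figures:

```r
fd <- render_forest_data(study$snv_recurrence)  # flip markers: p<0.1 & OR<1
autoplot(fd)
plot_prs_distribution(study)
```

Real data go through the same surface — `run_full_study(genotypes =
"cohort.vcf", phenotypes = "phenotypes.csv")` — and a thin CLI wrapper
(`inst/exec/afprs`) exposes `simulate`, `descriptives` and `run-all`
subcommands.

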