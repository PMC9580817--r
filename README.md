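# endoprs

A tested R pipeline for small-panel polygenic risk score (PRS) analysis of
endometriosis in case-control cohorts. It covers the full path from genotype
quality control to association statistics, and ships a synthetic cohort
generator with a calibrated disease model so every stage can be verified
against known ground truth — no access to protected registry data required.

## The science

Endometriosis is a common, heritable gynecological disease. Genome-wide
association studies have identified a modest set of risk variants; a small
panel of such variants can be combined into a polygenic risk score

```
PRS_j = Σ_i  x_ij · w_i
```

where `x_ij` is the dosage (0, 1, 2) of the *effect allele* of variant `i`
in sample `j`, and `w_i` is the log-odds-ratio weight for that allele. The
raw score is standardized to mean 0, SD 1 within an analysis stratum, and
the primary association statistic is the **odds ratio per standard
deviation** of PRS from a logistic regression of case status on the
standardized score, accompanied by the Mann-Whitney AUC (with
Hanley-McNeil standard error), Nagelkerke's R², and a decile-based
odds-ratio table against a central reference decile.

Phenotypes are defined from ICD-10 N80 codes: any of N80.1-N80.9 (except
the invalid N80.7) classifies a sample as endometriosis, with subtypes
collapsed by a fixed severity ranking into *infiltrating* (N80.4, N80.5),
*ovarian* (N80.1), *peritoneal* (N80.2, N80.3), and *other* (N80.6, N80.8,
N80.9). N80.0 alone is adenomyosis, analyzed as a separate comparison
group; samples with no N80 code are controls.

The package includes the supporting machinery a real analysis needs:
Hardy-Weinberg exact tests, allele-swap detection against reference
frequencies, duplicate-sample concordance, within-cohort mean imputation
of sporadic missing calls, effect-allele harmonization when scoring, and a
subtype tabulation with the rounding conventions of a clinical Table 1.

## Worked example

Simulate a cohort at the scale of a combined clinical + registry study
(389 endometriosis cases, 664 controls, 25 adenomyosis samples) with a
generating odds ratio per SD of 1.57, then run the analysis by hand:

```r
library(endoprs)

cfg <- simulation_config(n_cases = 389, n_controls = 664,
                         n_adenomyosis = 25, seed = 7)
cohort <- simulate_case_control(cfg)
cohort
#> simulated_cohort: 25 adenomyosis, 664 control, 389 endometriosis (generating OR per SD 1.570, prevalence intercept -2.277)

gm  <- mean_impute(cohort$genotypes)
prs <- standardize_prs(compute_prs(gm, cfg$variants))
assignments <- phenotype_assignments(cohort$phenotypes)

keep <- assignments$status %in% c("endometriosis", "control")
or_per_sd(assignments$status[keep] == "endometriosis", prs$std_prs[keep])
#> PRS association: OR per SD = 1.713 (SE logOR 0.069, p = 5.08e-15)
#>   AUC = 0.644, Nagelkerke R2 = 0.0835, 389 cases / 664 controls

evaluate_associations(prs, assignments)
#>      population n_cases n_controls odds_ratio  se_log_or      p_value       auc r2_nagelkerke
#> 1 endometriosis     389        664   1.713237 0.06880322 5.077024e-15 0.6440189    0.08348430
#> 2  infiltrating     198        664   1.768231 0.08478601 1.785504e-11 0.6506100    0.08247127
#> 3       ovarian      84        664   1.720590 0.12136863 7.777072e-06 0.6415483    0.05351897
#> 4    peritoneal      60        664   1.466125 0.13932469 6.027721e-03 0.6053840    0.02375412
#> 5         other      47        664   1.802811 0.15976639 2.253095e-04 0.6699885    0.05012809
#> 6   adenomyosis      25        664   1.580164 0.20997829 2.933661e-02 0.6361446    0.02534561
```

The recovered OR per SD (1.71) sits within sampling error of the
generating value for a single cohort of this size. The adenomyosis arm is
generated with *no* PRS effect; its estimate here (OR 1.58 from only 25
samples, SE 0.21 on the log scale) is small-sample noise, a useful
reminder of how wide the error bars are at that n.

The same analysis runs end to end, with all tables written to disk and a
reproducibility manifest, via:

```r
report <- run_pipeline(run_config(simulation = cfg, output_dir = "my_run"))
```

or from the command line with the thin wrapper in `inst/cli/endoprs.R`
(subcommands `simulate`, `qc`, `score`, `phenotype`, `evaluate`,
`run-all`). Real data enter through a dosage TSV or a minimal VCF plus a
weight table (`rsID`, `effect_allele`, `other_allele`, `effect_weight`)
and a phenotype TSV of ICD-10 codes; `validate_inputs()` itemizes schema
problems before anything runs.

## Documentation

Function documentation lives in roxygen comments in `R/`. The methods
vignette (`vignettes/synthetic-validation.Rmd`) describes the generative
model, the calibration of its intercept, the default parameter choices,
and the numerical conventions used throughout.
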