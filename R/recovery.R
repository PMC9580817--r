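#' Parameter-recovery experiment for the per-SD odds ratio
#'
#' Repeatedly simulates an ascertained case-control cohort with a known
#' generating odds ratio per SD of PRS, runs the full analysis path on each
#' replicate (within-cohort mean imputation, scoring, standardization within
#' the analysis sample, logistic fit), and summarizes how well the
#' generating value is recovered. Because the logistic odds ratio is
#' invariant to outcome-dependent sampling, the mean recovered OR should
#' match the generating OR up to Monte-Carlo error.
#'
#' @param generating_or generating odds ratio per SD of standardized PRS.
#' @param n_cases,n_controls arm sizes per replicate.
#' @param replicates number of simulated cohorts.
#' @param seed integer root seed; each replicate derives its own sub-seed.
#' @param subtype `NULL` to compare all cases against controls, or one of
#'   `"infiltrating"`, `"ovarian"`, `"peritoneal"`, `"other"` to generate
#'   every case in that subtype and run the subtype-versus-all-controls
#'   comparison.
#' @param prevalence population disease probability.
#' @param variants variant panel used for generation and scoring.
#' @param multi_code_prob,missing_rate passed to [simulation_config()].
#' @return List with `mean_or` (mean recovered odds ratio), `mc_se`
#'   (Monte-Carlo standard error of that mean), `generating_or`,
#'   `replicates`, `n_per_cohort` and the per-replicate `ors`.
#' @export
prs_recovery_experiment <- function(generating_or, n_cases, n_controls,
                                    replicates = 200, seed = 1,
                                    subtype = NULL, prevalence = 0.10,
                                    variants = variant_panel(),
                                    multi_code_prob = 0.2,
                                    missing_rate = 0.003) {
  sub_probs <- if (is.null(subtype)) {
    formals(simulation_config)$subtype_probs
  } else {
    p <- c(infiltrating = 0, ovarian = 0, peritoneal = 0, other = 0)
    p[subtype] <- 1
    p
  }
  if (is.language(sub_probs)) sub_probs <- eval(sub_probs)
  ors <- vapply(seq_len(replicates), function(r) {
    cfg <- simulation_config(
      variants = variants, beta_per_sd = log(generating_or),
      prevalence = prevalence, n_cases = n_cases, n_controls = n_controls,
      subtype_probs = sub_probs, multi_code_prob = multi_code_prob,
      missing_rate = missing_rate,
      seed = stage_seed(seed, paste0("replicate", r)))
    cohort <- simulate_case_control(cfg)
    prs <- standardize_prs(compute_prs(mean_impute(cohort$genotypes),
                                       cfg$variants))
    assignments <- phenotype_assignments(cohort$phenotypes)
    if (is.null(subtype)) {
      keep <- assignments$status %in% c("endometriosis", "control")
      or_per_sd(assignments$status[keep] == "endometriosis",
                prs$std_prs[keep])$odds_ratio
    } else {
      res <- evaluate_associations(prs, assignments)
      res$odds_ratio[res$population == subtype]
    }
  }, numeric(1))
  list(mean_or = mean(ors), mc_se = stats::sd(ors) / sqrt(replicates),
       generating_or = generating_or, replicates = replicates,
       n_per_cohort = n_cases + n_controls, ors = ors)
}
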