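# Synthetic case-control cohort generator.
#
# Disease is generated from a logistic model on the population-standardized
# PRS: logit P(D=1 | z) = alpha + beta_per_sd * z, with alpha calibrated so
# the population prevalence matches the configured one. Cases and controls
# are then ascertained to fixed quotas, which leaves the logistic odds ratio
# estimable (outcome-dependent sampling only shifts the intercept).

#' Synthetic 14-variant scoring panel
#'
#' A stand-in panel of 14 independent biallelic variants with rsID-style
#' identifiers, risk-allele frequencies and per-allele log odds-ratio
#' weights of the magnitude typical for genome-wide significant hits of a
#' large case-control GWAS (per-allele ORs roughly 1.05-1.25). The
#' identifiers and weights are synthetic placeholders for testing and
#' simulation; real analyses must supply the published scoring file.
#'
#' @return Data frame: `variant_id`, `effect_allele`, `other_allele`,
#'   `risk_allele_freq`, `weight`.
#' @export
variant_panel <- function() {
  data.frame(
    variant_id = c("rs77294520", sprintf("rs9900%04d", 1:13)),
    effect_allele = c("A", "G", "T", "C", "A", "G", "T", "C",
                      "A", "G", "T", "C", "A", "G"),
    other_allele  = c("G", "A", "C", "T", "G", "A", "C", "T",
                      "G", "A", "C", "T", "G", "A"),
    risk_allele_freq = c(0.22, 0.35, 0.48, 0.61, 0.15, 0.72, 0.30, 0.55,
                         0.42, 0.27, 0.66, 0.38, 0.19, 0.50),
    weight = c(0.19, 0.11, 0.08, 0.06, 0.17, 0.09, 0.13, 0.07,
               0.10, 0.15, 0.05, 0.12, 0.20, 0.08),
    stringsAsFactors = FALSE
  )
}

validate_variants <- function(variants) {
  need <- c("variant_id", "effect_allele", "other_allele",
            "risk_allele_freq", "weight")
  if (!is.data.frame(variants) || !all(need %in% names(variants)) ||
      nrow(variants) == 0)
    stop("variants must be a non-empty data frame with columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(variants$variant_id))
    stop("variant_id values must be unique", call. = FALSE)
  if (any(variants$risk_allele_freq <= 0 | variants$risk_allele_freq >= 1))
    stop("risk_allele_freq must lie strictly in (0, 1)", call. = FALSE)
  if (any(variants$effect_allele == variants$other_allele))
    stop("effect and other allele must differ", call. = FALSE)
  if (!all(is.finite(variants$weight)))
    stop("weights must be finite", call. = FALSE)
  variants
}

# deterministic per-stage sub-seed from a single root seed, kept in 32-bit
# integer range so stages can be re-run independently
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 7919 + h) %% 2147483647)
}

#' Simulate panel genotypes under Hardy-Weinberg equilibrium
#'
#' Each call is an independent draw of the risk-allele count,
#' Binomial(2, risk_allele_freq), per variant; HWE holds by construction.
#'
#' @param variants variant panel (see [variant_panel()]).
#' @param n number of samples (at least 1).
#' @param seed optional integer seed (omit to draw from the current RNG
#'   stream).
#' @param cohort cohort label for all samples.
#' @return A [genotype_matrix()] whose counted allele is the effect allele.
#' @export
simulate_genotypes <- function(variants, n, seed = NULL, cohort = "sim") {
  variants <- validate_variants(variants)
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(variants)
  calls <- matrix(stats::rbinom(n * m, 2,
                                rep(variants$risk_allele_freq, each = n)),
                  nrow = n, ncol = m)
  genotype_matrix(calls,
                  sample_ids = sprintf("S%06d", seq_len(n)),
                  variant_ids = variants$variant_id,
                  counted_allele = variants$effect_allele,
                  other_allele = variants$other_allele,
                  cohort = cohort)
}

#' Population moments of the raw PRS
#'
#' With independent variants in HWE, the raw score `sum_i X_i w_i` has exact
#' moments `mean = sum_i 2 p_i w_i` and `var = sum_i w_i^2 2 p_i (1 - p_i)`.
#' Using these exact population moments for the generator's standardization
#' (rather than moments of the ascertained sample) avoids ascertainment-
#' induced shrinkage of the generating effect size.
#'
#' @param variants variant panel.
#' @return List with `mean` and `sd`.
#' @export
prs_population_moments <- function(variants) {
  variants <- validate_variants(variants)
  p <- variants$risk_allele_freq
  w <- variants$weight
  v <- sum(w^2 * 2 * p * (1 - p))
  if (v == 0) stop("panel has zero PRS variance", call. = FALSE)
  list(mean = sum(2 * p * w), sd = sqrt(v))
}

#' Calibrate the disease-model intercept to a target prevalence
#'
#' Solves `E_Z[plogis(alpha + beta * Z)] = prevalence` for `alpha`, with Z
#' standard normal, by Gauss quadrature ([stats::integrate()]) and root
#' finding ([stats::uniroot()]) to an absolute error below 1e-8.
#'
#' @param beta_per_sd log odds ratio per SD of standardized PRS.
#' @param prevalence target population disease probability in (0, 1).
#' @return The intercept `alpha` (log-odds scale).
#' @export
calibrate_intercept <- function(beta_per_sd, prevalence) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly in (0, 1)", call. = FALSE)
  if (beta_per_sd == 0) return(stats::qlogis(prevalence))
  marginal <- function(alpha) {
    stats::integrate(function(z) stats::dnorm(z) *
                       stats::plogis(alpha + beta_per_sd * z),
                     -Inf, Inf, rel.tol = 1e-12)$value - prevalence
  }
  lo <- -50; hi <- 50
  if (marginal(lo) > 0 || marginal(hi) < 0)
    stop("no intercept in [-50, 50] achieves the requested prevalence",
         call. = FALSE)
  root <- stats::uniroot(marginal, c(lo, hi), tol = 1e-12)
  alpha <- root$root
  if (abs(marginal(alpha)) > 1e-8)
    stop("intercept calibration did not reach the 1e-8 tolerance",
         call. = FALSE)
  alpha
}

#' Simulation configuration
#'
#' Bundles and validates everything the cohort generator needs. Defaults
#' follow the combined Danish case-control design: subtype mix proportional
#' to the pooled subtype counts of the two Danish cohorts, 10% population
#' prevalence, and per-genotype missingness of 0.3% (of the order seen on a
#' small directly genotyped panel).
#'
#' @param variants variant panel (see [variant_panel()]).
#' @param beta_per_sd generating log odds ratio per SD of standardized PRS.
#' @param prevalence population disease probability in (0, 1).
#' @param n_cases,n_controls,n_adenomyosis arm sizes (non-negative).
#' @param subtype_probs probabilities over infiltrating/ovarian/peritoneal/
#'   other, summing to 1.
#' @param multi_code_prob probability a case carries a second, strictly less
#'   severe N80 code.
#' @param missing_rate per-genotype missingness probability in \[0, 1).
#' @param seed integer root RNG seed; per-stage streams are derived from it.
#' @param cohort_label label attached to every sample.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(variants = variant_panel(),
                              beta_per_sd = log(1.57), prevalence = 0.10,
                              n_cases = 389, n_controls = 664,
                              n_adenomyosis = 0,
                              subtype_probs = c(infiltrating = 210 / 389,
                                                ovarian = 75 / 389,
                                                peritoneal = 60 / 389,
                                                other = 44 / 389),
                              multi_code_prob = 0.2, missing_rate = 0.003,
                              seed = 1, cohort_label = "sim") {
  variants <- validate_variants(variants)
  if (!is.finite(beta_per_sd)) stop("beta_per_sd must be finite", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly in (0, 1)", call. = FALSE)
  counts <- c(n_cases = n_cases, n_controls = n_controls,
              n_adenomyosis = n_adenomyosis)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("arm sizes must be non-negative integers", call. = FALSE)
  sub_names <- c("infiltrating", "ovarian", "peritoneal", "other")
  if (is.null(names(subtype_probs))) names(subtype_probs) <- sub_names
  if (!setequal(names(subtype_probs), sub_names))
    stop("subtype_probs must be named: ", paste(sub_names, collapse = ", "),
         call. = FALSE)
  subtype_probs <- subtype_probs[sub_names]
  if (any(subtype_probs < 0) || abs(sum(subtype_probs) - 1) > 1e-9)
    stop("subtype_probs must be non-negative and sum to 1 (within 1e-9)",
         call. = FALSE)
  if (multi_code_prob < 0 || multi_code_prob > 1)
    stop("multi_code_prob must lie in [0, 1]", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  if (length(seed) != 1 || seed != round(seed))
    stop("seed must be a single integer", call. = FALSE)
  structure(list(variants = variants, beta_per_sd = beta_per_sd,
                 prevalence = prevalence, n_cases = n_cases,
                 n_controls = n_controls, n_adenomyosis = n_adenomyosis,
                 subtype_probs = subtype_probs,
                 multi_code_prob = multi_code_prob,
                 missing_rate = missing_rate, seed = as.integer(seed),
                 cohort_label = cohort_label),
            class = "sim_config")
}

#' Assign ICD-10 N80 codes to simulated cases
#'
#' Each case draws a subtype from `subtype_probs` and a primary code
#' uniformly within that subtype's code group; with probability
#' `multi_code_prob` one extra code, strictly less severe under the clinical
#' severity order, is added (skipped when the primary code is already the
#' least severe). Collapsing the resulting code set by severity therefore
#' always returns the sampled subtype.
#'
#' @param n number of cases.
#' @param subtype_probs named probabilities over the four subtypes.
#' @param multi_code_prob probability of a second, less severe code.
#' @param seed optional integer seed.
#' @return Data frame: `subtype` (the sampled truth) and `icd_codes`
#'   (semicolon-joined).
#' @export
assign_icd_codes <- function(n, subtype_probs, multi_code_prob, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(subtype_probs < 0) || abs(sum(subtype_probs) - 1) > 1e-9)
    stop("subtype_probs must be a probability distribution", call. = FALSE)
  groups <- subtype_groups()
  subtype <- sample(names(groups), n, replace = TRUE,
                    prob = subtype_probs[names(groups)])
  codes <- vapply(subtype, function(s) {
    g <- groups[[s]]
    primary <- if (length(g) == 1) g else sample(g, 1)
    out <- primary
    if (stats::runif(1) < multi_code_prob) {
      rank_primary <- match(primary, SEVERITY_ORDER)
      milder <- SEVERITY_ORDER[seq_along(SEVERITY_ORDER) > rank_primary]
      if (length(milder))
        out <- c(out, if (length(milder) == 1) milder else sample(milder, 1))
    }
    paste(out, collapse = ";")
  }, character(1))
  data.frame(subtype = subtype, icd_codes = unname(codes),
             stringsAsFactors = FALSE)
}

#' Simulate an ascertained case-control cohort
#'
#' Population members are drawn (genotypes, raw PRS, standardization against
#' exact population moments, disease via the calibrated logistic model) and
#' accepted into the case or control arm until the quotas are met. The
#' adenomyosis arm is drawn with the PRS effect forced to zero — its
#' genotypes come straight from the population — encoding the finding that
#' this variant panel carries no adenomyosis signal. ICD codes are assigned
#' to cases via [assign_icd_codes()]; genotype missingness is injected last.
#'
#' @param config a [simulation_config()].
#' @return A list of class `simulated_cohort`: `genotypes` (a
#'   [genotype_matrix()], arm order cases, adenomyosis, controls),
#'   `phenotypes` (data frame `sample_id`, `cohort`, `icd_codes`,
#'   `self_report`), and `truth` (generating `beta_per_sd`, `intercept`,
#'   population PRS moments, per-sample `status`, `subtype` and `liability`).
#' @export
simulate_case_control <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("config must come from simulation_config()", call. = FALSE)
  variants <- config$variants
  mom <- prs_population_moments(variants)
  alpha <- calibrate_intercept(config$beta_per_sd, config$prevalence)

  set.seed(stage_seed(config$seed, "sampling"))
  case_calls <- control_calls <- list()
  case_z <- control_z <- list()
  n_case_have <- n_control_have <- 0
  attempts <- 0
  batch_n <- max(100, ceiling(1.2 * max(config$n_cases / config$prevalence,
                                        config$n_controls / (1 - config$prevalence))))
  while (n_case_have < config$n_cases || n_control_have < config$n_controls) {
    attempts <- attempts + 1
    if (attempts > 1000)
      stop("sampling error: case/control quota unreachable at the configured prevalence",
           call. = FALSE)
    g <- simulate_genotypes(variants, batch_n, cohort = config$cohort_label)
    z <- (as.numeric(g$calls %*% variants$weight) - mom$mean) / mom$sd
    d <- stats::rbinom(batch_n, 1, stats::plogis(alpha + config$beta_per_sd * z))
    need_case <- config$n_cases - n_case_have
    need_control <- config$n_controls - n_control_have
    take_case <- which(d == 1)[seq_len(min(need_case, sum(d == 1)))]
    take_control <- which(d == 0)[seq_len(min(need_control, sum(d == 0)))]
    if (length(take_case)) {
      case_calls[[attempts]] <- g$calls[take_case, , drop = FALSE]
      case_z[[attempts]] <- z[take_case]
      n_case_have <- n_case_have + length(take_case)
    }
    if (length(take_control)) {
      control_calls[[attempts]] <- g$calls[take_control, , drop = FALSE]
      control_z[[attempts]] <- z[take_control]
      n_control_have <- n_control_have + length(take_control)
    }
  }
  calls <- do.call(rbind, c(case_calls, control_calls))
  if (is.null(calls)) calls <- matrix(numeric(0), 0, nrow(variants))
  z_all <- c(unlist(case_z), unlist(control_z))
  status <- c(rep("endometriosis", config$n_cases),
              rep("control", config$n_controls))

  if (config$n_adenomyosis > 0) {
    # beta forced to 0 for this arm: PRS-independent, so genotypes are
    # straight population draws
    g_ad <- simulate_genotypes(variants, config$n_adenomyosis,
                               cohort = config$cohort_label)
    z_ad <- (as.numeric(g_ad$calls %*% variants$weight) - mom$mean) / mom$sd
    calls <- rbind(calls[seq_len(config$n_cases), , drop = FALSE],
                   g_ad$calls,
                   calls[config$n_cases + seq_len(config$n_controls), ,
                         drop = FALSE])
    z_all <- c(z_all[seq_len(config$n_cases)], z_ad,
               z_all[config$n_cases + seq_len(config$n_controls)])
    status <- c(rep("endometriosis", config$n_cases),
                rep("adenomyosis", config$n_adenomyosis),
                rep("control", config$n_controls))
  }

  n_total <- nrow(calls)
  ids <- sprintf("S%06d", seq_len(n_total))
  rownames(calls) <- ids

  subtype <- rep("none", n_total)
  icd <- rep("", n_total)
  icd[status == "adenomyosis"] <- "N80.0"
  if (config$n_cases > 0) {
    assigned <- assign_icd_codes(config$n_cases, config$subtype_probs,
                                 config$multi_code_prob,
                                 seed = stage_seed(config$seed, "icd"))
    subtype[status == "endometriosis"] <- assigned$subtype
    icd[status == "endometriosis"] <- assigned$icd_codes
  }

  if (config$missing_rate > 0) {
    set.seed(stage_seed(config$seed, "missing"))
    mask <- matrix(stats::runif(length(calls)) < config$missing_rate,
                   nrow = nrow(calls))
    calls[mask] <- NA_real_
  }

  genotypes <- genotype_matrix(calls,
                               variant_ids = variants$variant_id,
                               counted_allele = variants$effect_allele,
                               other_allele = variants$other_allele,
                               cohort = config$cohort_label)
  liability <- alpha + ifelse(status == "adenomyosis", 0,
                              config$beta_per_sd * z_all)
  structure(list(
    genotypes = genotypes,
    phenotypes = data.frame(sample_id = ids, cohort = config$cohort_label,
                            icd_codes = icd, self_report = 0L,
                            stringsAsFactors = FALSE),
    truth = list(beta_per_sd = config$beta_per_sd, intercept = alpha,
                 prs_mean = mom$mean, prs_sd = mom$sd,
                 status = stats::setNames(status, ids),
                 subtype = stats::setNames(subtype, ids),
                 std_prs_population = stats::setNames(z_all, ids),
                 liability = stats::setNames(liability, ids))
  ), class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  tb <- table(x$truth$status)
  cat(sprintf("simulated_cohort: %s (generating OR per SD %.3f, prevalence intercept %.3f)\n",
              paste(sprintf("%d %s", tb, names(tb)), collapse = ", "),
              exp(x$truth$beta_per_sd), x$truth$intercept))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits `genotypes.vcf` (minimal VCF 4.2), `dosages.tsv`, `phenotypes.tsv`
#' and `truth.json` into `dir`. Output contains no timestamps, so identical
#' configurations yield byte-identical files.
#'
#' @param cohort a [simulate_case_control()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the four paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             dosages = file.path(dir, "dosages.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "truth.json"))
  gm <- cohort$genotypes
  # VCF wants integer calls; keep missing entries as ./.
  write_genotypes_vcf(gm, paths["vcf"])
  write_dosage_tsv(gm, paths["dosages"])
  utils::write.table(cohort$phenotypes, paths["phenotypes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read a simulation configuration from YAML
#'
#' The YAML mirrors [simulation_config()] fields; `variants` may be either an
#' inline list of records or a path to a panel TSV with the same columns.
#' Unknown fields are rejected with an explicit message.
#'
#' @param path YAML file path.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- c("variants", "beta_per_sd", "prevalence", "n_cases",
               "n_controls", "n_adenomyosis", "subtype_probs",
               "multi_code_prob", "missing_rate", "seed", "cohort_label")
  unknown <- setdiff(names(y), allowed)
  if (length(unknown))
    stop(sprintf("unknown simulation config field(s): %s (allowed: %s)",
                 paste(unknown, collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
  if (!is.null(y$variants)) {
    y$variants <- if (is.character(y$variants))
      utils::read.delim(y$variants, stringsAsFactors = FALSE)
    else do.call(rbind, lapply(y$variants, as.data.frame,
                               stringsAsFactors = FALSE))
  }
  if (!is.null(y$subtype_probs)) y$subtype_probs <- unlist(y$subtype_probs)
  do.call(simulation_config, y[!vapply(y, is.null, logical(1))])
}
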