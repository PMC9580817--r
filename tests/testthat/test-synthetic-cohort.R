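test_that("genotype simulation draws binomial allelic counts deterministically", {
  panel1 <- data.frame(variant_id = "v1", effect_allele = "A",
                       other_allele = "G", risk_allele_freq = 1 - 1e-12,
                       weight = 0.1, stringsAsFactors = FALSE)
  gm <- simulate_genotypes(panel1, 100, seed = 1)
  expect_true(all(gm$calls == 2))

  panel2 <- panel1
  panel2$risk_allele_freq <- 0.5
  gm2 <- simulate_genotypes(panel2, 10000, seed = 2)
  emp <- mean(gm2$calls) / 2
  expect_lt(abs(emp - 0.5), 3 * sqrt(0.25 / 20000))

  expect_identical(simulate_genotypes(variant_panel(), 50, seed = 3)$calls,
                   simulate_genotypes(variant_panel(), 50, seed = 3)$calls)
  expect_error(simulate_genotypes(variant_panel()[0, ], 10, seed = 1),
               "non-empty")
  expect_error(simulate_genotypes(variant_panel(), 0, seed = 1), "at least 1")
})

test_that("panel validation rejects out-of-range frequencies and equal alleles", {
  bad <- variant_panel()
  bad$risk_allele_freq[1] <- 1
  expect_error(endoprs:::validate_variants(bad), "strictly in")
  bad2 <- variant_panel()
  bad2$other_allele[2] <- bad2$effect_allele[2]
  expect_error(endoprs:::validate_variants(bad2), "differ")
})

test_that("intercept calibration solves the marginal-prevalence equation", {
  expect_equal(calibrate_intercept(0, 0.10), qlogis(0.10))
  expect_equal(calibrate_intercept(0, 0.5), 0)
  beta <- log(1.57)
  alpha <- calibrate_intercept(beta, 0.10)
  # self-consistency against an independent quadrature of the marginal
  marg <- integrate(function(z) dnorm(z) * plogis(alpha + beta * z),
                    -Inf, Inf, rel.tol = 1e-12)$value
  expect_lt(abs(marg - 0.10), 1e-8)
  # a positive slope pulls the intercept below the beta = 0 solution
  expect_lt(alpha, qlogis(0.10))
  expect_error(calibrate_intercept(0.5, 1), "strictly in")
})

test_that("analytic PRS population moments match a large genotype draw", {
  panel <- variant_panel()
  mom <- prs_population_moments(panel)
  gm <- simulate_genotypes(panel, 50000, seed = 17)
  raw <- compute_prs(gm, endoprs:::as_weight_table(panel))$raw_prs
  expect_equal(mean(raw), mom$mean, tolerance = 0.01)
  expect_equal(sd(raw), mom$sd, tolerance = 0.01)
})

test_that("ICD code assignment round-trips through the severity collapser", {
  one <- assign_icd_codes(50, c(infiltrating = 0, ovarian = 1,
                                peritoneal = 0, other = 0),
                          multi_code_prob = 0, seed = 5)
  expect_true(all(one$icd_codes == "N80.1"))

  # round trip: the collapsed subtype always equals the sampled subtype
  many <- assign_icd_codes(10000, c(infiltrating = 0.4, ovarian = 0.25,
                                    peritoneal = 0.2, other = 0.15),
                           multi_code_prob = 0.5, seed = 6)
  codes <- parse_icd_codes(many$icd_codes)
  expect_equal(assign_severity_subtype(codes), many$subtype)
  # multi-code cases carry exactly one extra, strictly less severe code
  n_codes <- lengths(codes)
  expect_true(all(n_codes %in% 1:2))
  expect_gt(mean(n_codes == 2), 0.35)

  # degenerate distribution: every primary code is an infiltrating code
  inf <- assign_icd_codes(500, c(infiltrating = 1, ovarian = 0,
                                 peritoneal = 0, other = 0),
                          multi_code_prob = 0.5, seed = 7)
  primary <- vapply(parse_icd_codes(inf$icd_codes), function(cs) {
    endoprs:::SEVERITY_ORDER[endoprs:::SEVERITY_ORDER %in% cs][1]
  }, character(1))
  expect_true(all(primary %in% c("N80.4", "N80.5")))
})

test_that("simulated cohorts satisfy the code-set contracts per arm", {
  cfg <- simulation_config(n_cases = 120, n_controls = 200,
                           n_adenomyosis = 30, seed = 9)
  coh <- simulate_case_control(cfg)
  expect_equal(nrow(coh$genotypes$calls), nrow(coh$phenotypes))
  codes <- parse_icd_codes(coh$phenotypes$icd_codes)
  status <- coh$truth$status[coh$phenotypes$sample_id]
  endo_codes <- endoprs:::SEVERITY_ORDER
  for (i in seq_along(codes)) {
    if (status[i] == "endometriosis") {
      expect_true(any(codes[[i]] %in% endo_codes))
    } else if (status[i] == "adenomyosis") {
      expect_equal(codes[[i]], "N80.0")
    } else {
      expect_length(codes[[i]], 0)
    }
  }
  # classifier agrees with the generating truth everywhere
  a <- phenotype_assignments(coh$phenotypes)
  expect_equal(a$status, unname(status))
  # and the collapsed subtype equals the sampled one
  is_case <- a$status == "endometriosis"
  expect_equal(a$subtype[is_case],
               unname(coh$truth$subtype[coh$phenotypes$sample_id][is_case]))
  # missingness lands near the configured rate
  expect_lt(abs(mean(is.na(coh$genotypes$calls)) - cfg$missing_rate), 0.005)
})

test_that("a null PRS effect yields no case-control separation", {
  cfg <- simulation_config(beta_per_sd = 0, prevalence = 0.5,
                           n_cases = 2000, n_controls = 2000,
                           missing_rate = 0, seed = 13)
  coh <- simulate_case_control(cfg)
  prs <- standardize_prs(compute_prs(coh$genotypes, cfg$variants))
  status <- coh$truth$status[prs$sample_id] == "endometriosis"
  expect_lt(abs(mean(prs$std_prs[status]) - mean(prs$std_prs[!status])), 0.1)
  expect_lt(abs(auc_mann_whitney(prs$std_prs, status)$auc - 0.5), 0.02)
})

test_that("pre-ascertainment disease fraction matches the configured prevalence", {
  cfg <- simulation_config(seed = 19)
  alpha <- coh_alpha <- calibrate_intercept(cfg$beta_per_sd, cfg$prevalence)
  mom <- prs_population_moments(cfg$variants)
  set.seed(19)
  n <- 100000
  gm <- simulate_genotypes(cfg$variants, n)
  z <- (as.numeric(gm$calls %*% cfg$variants$weight) - mom$mean) / mom$sd
  d <- rbinom(n, 1, plogis(alpha + cfg$beta_per_sd * z))
  se <- sqrt(cfg$prevalence * (1 - cfg$prevalence) / n)
  expect_lt(abs(mean(d) - cfg$prevalence), 3 * se)
})

test_that("HWE holds in simulated genotypes at the nominal rejection rate", {
  set.seed(23)
  n <- 5000
  p <- 0.3
  reps <- 400
  rejected <- vapply(seq_len(reps), function(i) {
    g <- rbinom(n, 2, p)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2)) < 0.05
  }, logical(1))
  # binomial CI around the nominal level (the exact test is slightly
  # conservative, so the band is asymmetric-tolerant)
  expect_lt(abs(mean(rejected) - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("identical configurations produce byte-identical cohort files", {
  cfg <- simulation_config(n_cases = 40, n_controls = 60, n_adenomyosis = 5,
                           seed = 29)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_cohort(simulate_case_control(cfg), d1)
  p2 <- write_cohort(simulate_case_control(cfg), d2)
  for (k in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[k]])),
                     unname(tools::md5sum(p2[[k]])), label = k)
  }
  cfg2 <- simulation_config(n_cases = 40, n_controls = 60, n_adenomyosis = 5,
                            seed = 30)
  d3 <- withr::local_tempdir()
  p3 <- write_cohort(simulate_case_control(cfg2), d3)
  expect_false(identical(unname(tools::md5sum(p1[["dosages"]])),
                         unname(tools::md5sum(p3[["dosages"]]))))
})

test_that("simulation configs validate fields and read from YAML", {
  expect_error(simulation_config(prevalence = 0), "strictly in")
  expect_error(simulation_config(n_cases = -1), "non-negative")
  expect_error(simulation_config(subtype_probs = c(infiltrating = 0.5,
                                                   ovarian = 0.5,
                                                   peritoneal = 0.5,
                                                   other = -0.5)),
               "sum to 1|non-negative")
  expect_error(simulation_config(missing_rate = 1), "\\[0, 1\\)")

  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("beta_per_sd: 0.45", "prevalence: 0.1", "n_cases: 10",
               "n_controls: 20", "seed: 4"), tmp)
  cfg <- read_sim_config(tmp)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_cases, 10)

  writeLines(c("n_cases: 10", "bogus_field: 3"), tmp)
  expect_error(read_sim_config(tmp), "bogus_field")
})
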