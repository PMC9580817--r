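test_that("logistic fit on a binary predictor equals the 2x2 cross-product ratio", {
  status <- c(rep(1, 40), rep(0, 60))
  x <- c(rep(1, 30), rep(0, 10), rep(1, 20), rep(0, 40))
  fit <- logistic_fit(status, x)
  oracle <- woolf_2x2(30, 10, 20, 40)
  expect_equal(unname(exp(fit$coefficients[2])), 6.0, tolerance = 1e-8)
  expect_equal(unname(fit$se[2]), oracle$se, tolerance = 1e-6)
  # sqrt(1/30 + 1/10 + 1/20 + 1/40) = 0.45644
  expect_equal(oracle$se, 0.45644, tolerance = 1e-4)

  # swapping labels negates the slope exactly
  fit2 <- logistic_fit(1 - status, x)
  expect_equal(unname(fit2$coefficients[2]), -unname(fit$coefficients[2]),
               tolerance = 1e-8)
})

test_that("logistic fit handles degenerate predictors and separation", {
  status <- rep(c(1, 0), c(30, 70))
  fit <- logistic_fit(status, rep(2, 100))
  expect_equal(unname(fit$coefficients[2]), 0)
  expect_equal(unname(fit$coefficients[1]), qlogis(0.3), tolerance = 1e-8)
  expect_error(logistic_fit(rep(1, 10), rnorm(10)), "both outcome classes")
  expect_error(suppressWarnings(logistic_fit(c(rep(1, 20), rep(0, 20)),
                                             c(rnorm(20, 10), rnorm(20, -10)))),
               "separation")
})

test_that("pooled t-test matches the hand-computed statistic and is antisymmetric", {
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  tt <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3.67423, tolerance = 1e-5)
  expect_equal(tt$df, 4)
  expect_equal(tt$p_value, 0.02131, tolerance = 1e-4)

  rev_ <- two_sample_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rev_$t, -tt$t)
  expect_equal(rev_$p_value, tt$p_value)
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "zero pooled variance")
  # Welch variant available for unequal variances
  expect_lt(two_sample_t(c(1, 2, 3), c(4, 8, 20), welch = TRUE)$df, 4)
})

test_that("Mann-Whitney AUC matches brute force, ties and transformations", {
  expect_equal(auc_mann_whitney(c(5, 6, 1, 2), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(auc_mann_whitney(rep(3, 10), rep(c(1, 0), 5))$auc, 0.5)
  expect_equal(auc_mann_whitney(c(3, 1, 2, 0), c(1, 1, 0, 0))$auc, 0.75)
  expect_error(auc_mann_whitney(1:5, rep(1, 5)), "both classes")

  set.seed(31)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    scores <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)  # force ties
    status <- rbinom(n, 1, 0.4)
    if (length(unique(status)) < 2) next
    expect_equal(auc_mann_whitney(scores, status)$auc,
                 auc_bruteforce(scores, status), tolerance = 1e-12)
    # invariance under a strictly increasing transformation
    expect_equal(auc_mann_whitney(exp(scores), status)$auc,
                 auc_mann_whitney(scores, status)$auc)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(8)
  scores <- rnorm(200)
  status <- rbinom(200, 1, plogis(scores))
  ours <- auc_mann_whitney(scores, status)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(status, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("Nagelkerke R2 evaluates the rescaled Cox-Snell formula", {
  expect_equal(nagelkerke_r2(-50, -50, 80), 0)
  # CS = 1 - exp(2/100 * (-19.3147)) = 0.320424; max = 1 - exp(-1.386294)
  # = 0.75; ratio = 0.42723
  expect_equal(nagelkerke_r2(-69.3147, -50, 100), 0.42723, tolerance = 1e-4)
  # perfect fit reaches 1
  expect_equal(nagelkerke_r2(-69.3147, 0, 100), 1, tolerance = 1e-6)
  expect_error(nagelkerke_r2(-10, -20, 50), ">=")
  expect_error(nagelkerke_r2(0, 0, 50), "degenerate")
  # monotone non-decreasing in the full-model likelihood
  lls <- seq(-69, -10, by = 5)
  r2 <- vapply(lls, function(l) nagelkerke_r2(-69.3147, l, 100), numeric(1))
  expect_true(all(diff(r2) > 0))
})

test_that("decile odds ratios match per-bin 2x2 oracles with unit reference", {
  # 40 samples, 4 per decile; case counts per decile chosen so every bin is
  # mixed and the oracle cross-products are simple
  n_case_per_decile <- c(1, 1, 1, 2, 2, 2, 3, 3, 3, 3)
  status <- unlist(lapply(n_case_per_decile,
                          function(k) c(rep(1, k), rep(0, 4 - k))))
  scores <- seq_len(40) / 10
  dec <- decile_analysis(scores, status, reference = 5)
  expect_equal(dec$n, rep(4L, 10))
  expect_equal(dec$n_cases, n_case_per_decile)
  expect_equal(dec$odds_ratio[5], 1)
  expect_true(is.na(dec$se_log_or[5]))
  for (d in c(1, 3, 8, 10)) {
    oracle <- woolf_2x2(dec$n_cases[d], dec$n_controls[d],
                        dec$n_cases[5], dec$n_controls[5])
    expect_equal(dec$odds_ratio[d], oracle$or, tolerance = 1e-7)
    expect_equal(dec$se_log_or[d], oracle$se, tolerance = 1e-6)
  }
  expect_equal(dec$case_fraction, n_case_per_decile / 4)

  # bin sizes differ by at most one when n is not a multiple of 10
  set.seed(101)
  s47 <- rnorm(47)
  st47 <- integer(47)
  st47[order(s47)] <- rep(c(1L, 0L), length.out = 47)  # every bin mixed
  dec47 <- decile_analysis(s47, st47)
  expect_lte(diff(range(dec47$n)), 1)
  expect_equal(sum(dec47$n), 47)

  # a single-class reference bin is rejected with advice
  bad_status <- status
  bad_status[17:20] <- 0
  expect_error(decile_analysis(scores, bad_status, reference = 5),
               "different reference")
})

test_that("decile ORs stay near 1 when the score is uninformative", {
  set.seed(12)
  scores <- rnorm(5000)
  status <- rbinom(5000, 1, 0.3)
  dec <- decile_analysis(scores, status)
  nonref <- dec$decile != 5
  z <- abs(log(dec$odds_ratio[nonref])) / dec$se_log_or[nonref]
  expect_true(mean(z < 2) >= 8 / 9)  # allow one bin at the boundary
})

test_that("single-variant scan recovers the direction of simulated effects", {
  set.seed(44)
  n <- 4000
  g <- rbinom(n, 2, 0.4)
  status <- rbinom(n, 1, plogis(-1 + 0.3 * g))
  gm <- tiny_gm(cbind(v1 = g), counted = "A", other = "G")
  w <- weight_table(data.frame(rsID = "v1", effect_allele = "A",
                               other_allele = "G", effect_weight = 0.2))
  scan <- single_variant_scan(gm, status, w)
  expect_true(scan$direction_consistent)
  expect_gt(scan$odds_ratio, 1)
  # a zero-weight variant has no defined direction
  w0 <- weight_table(data.frame(rsID = "v1", effect_allele = "A",
                                other_allele = "G", effect_weight = 0))
  expect_true(is.na(single_variant_scan(gm, status, w0)$direction_consistent))
  # a null variant's log OR sits within 2 SE of zero
  status_null <- rbinom(n, 1, 0.3)
  scan_null <- single_variant_scan(gm, status_null, w)
  expect_lt(abs(log(scan_null$odds_ratio)), 2 * scan_null$se_log_or + 0.0)
})

test_that("or_per_sd bundles OR, AUC and Nagelkerke R2 consistently", {
  set.seed(52)
  z <- rnorm(1500)
  status <- rbinom(1500, 1, plogis(-1 + 0.5 * z))
  res <- or_per_sd(status, standardize_scores(z))
  expect_gt(res$odds_ratio, 1)
  expect_true(res$auc > 0.5 && res$auc < 1)
  expect_true(res$r2_nagelkerke > 0 && res$r2_nagelkerke < 1)
  expect_equal(res$n_cases + res$n_controls, 1500)
  # doubling the spread of raw scores changes nothing after re-standardization
  res2 <- or_per_sd(status, standardize_scores(2 * z))
  expect_equal(res2$odds_ratio, res$odds_ratio, tolerance = 1e-10)
})
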