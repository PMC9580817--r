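#' Logistic regression fit for case-control association
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()], convergence tolerance 1e-10, up to 100
#' iterations) with Wald standard errors from the observed information.
#' Coefficients larger than 30 in absolute value are treated as perfect
#' separation and rejected.
#'
#' @param status binary outcome vector (0/1 or logical); both classes must
#'   be present.
#' @param x predictor: a numeric vector, matrix, or factor (expanded to
#'   indicator columns).
#' @return List with `coefficients`, `se`, `p_value` (two-sided Wald),
#'   `loglik`, `loglik_null`, `n`, `n_cases`, `n_controls`.
#' @export
logistic_fit <- function(status, x) {
  status <- as.integer(status)
  if (!all(status %in% c(0L, 1L))) stop("status must be binary", call. = FALSE)
  if (length(unique(status)) < 2)
    stop("both outcome classes must be present", call. = FALSE)
  df <- data.frame(.y = status)
  df$.x <- x
  fit <- stats::glm(.y ~ .x, family = stats::binomial(), data = df,
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  if (!fit$converged)
    stop("logistic regression did not converge in 100 iterations",
         call. = FALSE)
  co <- stats::coef(fit)
  aliased <- is.na(co)
  co[aliased] <- 0            # constant/collinear predictors carry no effect
  # under (quasi-)separation the linear predictor diverges even when the
  # slope itself stays moderate on a wide predictor scale
  if (any(abs(co) > 30) || max(abs(stats::predict(fit))) > 30)
    stop("perfect separation detected (divergent coefficients)", call. = FALSE)
  sm <- summary(fit)$coefficients
  se <- stats::setNames(rep(NA_real_, length(co)), names(co))
  se[rownames(sm)] <- sm[, "Std. Error"]
  n <- length(status)
  n1 <- sum(status)
  p1 <- n1 / n
  ll_null <- n1 * log(p1) + (n - n1) * log(1 - p1)
  list(coefficients = co, se = se,
       p_value = 2 * stats::pnorm(-abs(co / se)),
       loglik = as.numeric(stats::logLik(fit)), loglik_null = ll_null,
       n = n, n_cases = n1, n_controls = n - n1)
}

#' Pooled-variance Student's t-test for group PRS means
#'
#' @param scores_cases,scores_controls numeric score vectors (each of length
#'   at least 2).
#' @param welch use Welch's unequal-variance correction instead of the
#'   pooled-variance Student's test.
#' @return List with `t`, `df`, `p_value`, `mean_cases`, `mean_controls`.
#' @export
two_sample_t <- function(scores_cases, scores_controls, welch = FALSE) {
  if (length(scores_cases) < 2 || length(scores_controls) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  if (!welch && stats::var(scores_cases) == 0 && stats::var(scores_controls) == 0)
    stop("zero pooled variance", call. = FALSE)
  tt <- stats::t.test(scores_cases, scores_controls, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       mean_cases = mean(scores_cases), mean_controls = mean(scores_controls))
}

#' AUC via the Mann-Whitney statistic
#'
#' The probability that a randomly chosen case outscores a randomly chosen
#' control (ties count one half), computed from ranks; the standard error is
#' the Hanley-McNeil approximation.
#'
#' @param scores numeric scores.
#' @param status binary case indicator.
#' @return List with `auc`, `se`, `n_cases`, `n_controls`.
#' @export
auc_mann_whitney <- function(scores, status) {
  status <- as.integer(status)
  n1 <- as.numeric(sum(status == 1))
  n0 <- as.numeric(sum(status == 0))
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[status == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
              (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  list(auc = auc, se = se, n_cases = n1, n_controls = n0)
}

#' Nagelkerke's pseudo R-squared
#'
#' Cox-Snell `R2 = 1 - exp((2/n) * (ll0 - ll1))` rescaled by its maximum
#' `1 - exp((2/n) * ll0)` so that a saturated model scores 1.
#'
#' @param loglik_null log-likelihood of the intercept-only model.
#' @param loglik_full log-likelihood of the fitted model (`>= loglik_null`).
#' @param n sample count.
#' @return Proportion in \[0, 1\].
#' @export
nagelkerke_r2 <- function(loglik_null, loglik_full, n) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (loglik_full < loglik_null - 1e-8)
    stop("loglik_full must be >= loglik_null", call. = FALSE)
  if (loglik_null == 0)
    stop("degenerate null model (loglik_null = 0)", call. = FALSE)
  r2_cs <- 1 - exp((2 / n) * (loglik_null - loglik_full))
  r2 <- r2_cs / (1 - exp((2 / n) * loglik_null))
  # guard only against floating-point undershoot/overshoot
  min(max(r2, 0), 1)
}

#' Association of a standardized PRS with case status
#'
#' Fits status on the standardized score by logistic regression and reports
#' the odds ratio per standard deviation of PRS together with the AUC and
#' Nagelkerke's R-squared for the same comparison.
#'
#' @param status binary case indicator.
#' @param std_prs scores standardized over the analysis stratum.
#' @return An object of class `prs_association`: list with `odds_ratio`,
#'   `se_log_or`, `p_value`, `auc`, `auc_se`, `r2_nagelkerke`, `n_cases`,
#'   `n_controls`.
#' @export
or_per_sd <- function(status, std_prs) {
  fit <- logistic_fit(status, std_prs)
  aucr <- auc_mann_whitney(std_prs, status)
  structure(list(
    odds_ratio = unname(exp(fit$coefficients[2])),
    se_log_or = unname(fit$se[2]),
    p_value = unname(fit$p_value[2]),
    auc = aucr$auc, auc_se = aucr$se,
    r2_nagelkerke = nagelkerke_r2(fit$loglik_null, fit$loglik, fit$n),
    n_cases = fit$n_cases, n_controls = fit$n_controls
  ), class = "prs_association")
}

#' @export
print.prs_association <- function(x, ...) {
  cat(sprintf(
    "PRS association: OR per SD = %.3f (SE logOR %.3f, p = %.3g)\n  AUC = %.3f, Nagelkerke R2 = %.4f, %d cases / %d controls\n",
    x$odds_ratio, x$se_log_or, x$p_value, x$auc, x$r2_nagelkerke,
    x$n_cases, x$n_controls))
  invisible(x)
}

#' Decile risk stratification of a PRS
#'
#' Samples are ranked by score (ties broken by stable input order) and split
#' into ten near-equal bins. Each bin's odds of disease are expressed
#' relative to the reference bin via logistic regression of status on decile
#' indicators; point estimates coincide with the per-bin 2x2 cross-product
#' ratios against the reference.
#'
#' @param std_prs standardized scores (at least 10 samples).
#' @param status binary case indicator; the reference decile must contain
#'   both classes.
#' @param reference reference decile (default 5, the middle of the
#'   distribution).
#' @return Data frame of class `decile_table`: `decile`, `n`, `n_cases`,
#'   `n_controls`, `case_fraction`, `odds_ratio`, `se_log_or` (`odds_ratio`
#'   is exactly 1 and `se_log_or` `NA` for the reference).
#' @export
decile_analysis <- function(std_prs, status, reference = 5) {
  n <- length(std_prs)
  if (n < 10) stop("decile analysis needs at least 10 samples", call. = FALSE)
  if (!reference %in% 1:10) stop("reference decile must be in 1..10", call. = FALSE)
  status <- as.integer(status)
  ord <- order(std_prs)                       # stable: ties keep input order
  decile <- integer(n)
  decile[ord] <- ceiling(seq_len(n) * 10 / n)
  ref_status <- status[decile == reference]
  if (length(unique(ref_status)) < 2)
    stop(sprintf(
      "reference decile %d contains a single outcome class; choose a different reference",
      reference), call. = FALSE)
  f <- stats::relevel(factor(decile, levels = 1:10), ref = as.character(reference))
  fit <- logistic_fit(status, f)
  lab <- paste0(".x", setdiff(as.character(1:10), as.character(reference)))
  out <- data.frame(decile = 1:10)
  out$n <- as.integer(table(factor(decile, levels = 1:10)))
  out$n_cases <- as.integer(tapply(status, factor(decile, levels = 1:10), sum,
                                   default = 0L))
  out$n_controls <- out$n - out$n_cases
  out$case_fraction <- ifelse(out$n > 0, out$n_cases / out$n, NA_real_)
  out$odds_ratio <- 1
  out$se_log_or <- NA_real_
  nonref <- setdiff(1:10, reference)
  out$odds_ratio[nonref] <- exp(unname(fit$coefficients[lab]))
  out$se_log_or[nonref] <- unname(fit$se[lab])
  class(out) <- c("decile_table", "data.frame")
  out
}

#' Per-variant logistic association scan
#'
#' Fits each panel variant's effect-allele dosage against case status and
#' flags whether the estimated direction of effect agrees with the sign of
#' its scoring weight (the directional-consistency check against the
#' discovery GWAS). Variants with weight zero have no defined direction and
#' get an `NA` flag.
#'
#' @param gm a [genotype_matrix()] with no missing calls.
#' @param status binary case indicator, one per sample.
#' @param weights a [weight_table()].
#' @return Data frame: `variant_id`, `odds_ratio`, `se_log_or`, `p_value`,
#'   `weight`, `direction_consistent`.
#' @export
single_variant_scan <- function(gm, status, weights) {
  weights <- as_weight_table(weights)
  if (anyNA(gm$calls))
    stop("genotype matrix has missing calls; run mean_impute() first",
         call. = FALSE)
  rows <- lapply(seq_len(nrow(weights)), function(k) {
    v <- weights$rsID[k]
    counted <- gm$counted_allele[v]
    dos <- if (is.na(counted) || counted == weights$effect_allele[k])
      gm$calls[, v] else 2 - gm$calls[, v]
    fit <- logistic_fit(status, dos)
    b <- unname(fit$coefficients[2])
    w <- weights$effect_weight[k]
    data.frame(variant_id = v, odds_ratio = exp(b),
               se_log_or = unname(fit$se[2]), p_value = unname(fit$p_value[2]),
               weight = w,
               direction_consistent = if (w == 0) NA else sign(b) == sign(w),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full association surface for a phenotyped, scored cohort
#'
#' Runs the per-SD PRS association for all endometriosis cases versus
#' controls, for each subtype versus all controls (cases of other subtypes
#' excluded), and for adenomyosis versus controls. Groups without cases are
#' skipped.
#'
#' @param prs a standardized `prs_vector` (see [standardize_prs()]).
#' @param assignments output of [phenotype_assignments()] for the same
#'   samples.
#' @return Data frame: `population`, `n_cases`, `n_controls`, `odds_ratio`,
#'   `se_log_or`, `p_value`, `auc`, `r2_nagelkerke`.
#' @export
evaluate_associations <- function(prs, assignments) {
  m <- merge(as.data.frame(prs), assignments, by = c("sample_id", "cohort"))
  if (nrow(m) != nrow(prs))
    stop("PRS and phenotype assignments do not cover the same samples",
         call. = FALSE)
  is_control <- m$status == "control"
  comparisons <- c("endometriosis", names(subtype_groups()), "adenomyosis")
  rows <- lapply(comparisons, function(g) {
    in_group <- if (g == "endometriosis") m$status == "endometriosis"
                else if (g == "adenomyosis") m$status == "adenomyosis"
                else m$subtype == g
    if (!any(in_group)) return(NULL)
    sel <- in_group | is_control
    res <- or_per_sd(in_group[sel], m$std_prs[sel])
    data.frame(population = g, n_cases = res$n_cases,
               n_controls = res$n_controls, odds_ratio = res$odds_ratio,
               se_log_or = res$se_log_or, p_value = res$p_value,
               auc = res$auc, r2_nagelkerke = res$r2_nagelkerke,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
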