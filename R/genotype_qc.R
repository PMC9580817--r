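#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on the heterozygote count given the allele counts:
#' the p-value is the sum of probabilities of all heterozygote configurations
#' whose conditional probability does not exceed that of the observed one.
#' Probabilities follow the standard recurrence over heterozygote counts,
#' anchored at the modal configuration, so the test is stable for the large
#' sample sizes seen in biobank cohorts. Monomorphic variants (minor allele
#' count zero) return p = 1 by convention, flagged via the `"monomorphic"`
#' attribute.
#'
#' @param n_hom_ref count of samples homozygous for one allele.
#' @param n_het count of heterozygous samples.
#' @param n_hom_alt count of samples homozygous for the other allele.
#' @return The exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers", call. = FALSE)
  n <- sum(counts)
  if (n < 1) stop("at least one genotyped sample is required", call. = FALSE)
  rare <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  if (rare == 0)
    return(structure(1, monomorphic = TRUE))

  # possible heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2 != rare %% 2) mid <- mid + 1
  mid_i <- match(mid, hets)
  probs[mid_i] <- 1
  if (mid_i > 1) {
    for (i in mid_i:2) {
      h <- hets[i]
      hom_r <- (rare - h) / 2
      hom_c <- n - h - hom_r
      probs[i - 1] <- probs[i] * h * (h - 1) / (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  if (mid_i < length(hets)) {
    for (i in mid_i:(length(hets) - 1)) {
      h <- hets[i]
      hom_r <- (rare - h) / 2
      hom_c <- n - h - hom_r
      probs[i + 1] <- probs[i] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  min(p, 1)
}

#' Observed allele frequency of the counted allele
#'
#' @param gm a [genotype_matrix()].
#' @param variant variant identifier (omit to get frequencies for the whole
#'   panel).
#' @return Frequency in \[0, 1\] (named vector when `variant` is omitted).
#'   Missing calls are excluded from the denominator.
#' @export
allele_frequency <- function(gm, variant = NULL) {
  calls <- gm$calls
  if (!is.null(variant)) {
    if (!variant %in% colnames(calls))
      stop(sprintf("variant '%s' not present", variant), call. = FALSE)
    calls <- calls[, variant, drop = FALSE]
  }
  n_obs <- colSums(!is.na(calls))
  if (any(n_obs == 0))
    stop(sprintf("allele frequency undefined for all-missing variant(s): %s",
                 paste(colnames(calls)[n_obs == 0], collapse = ", ")),
         call. = FALSE)
  freq <- colSums(calls, na.rm = TRUE) / (2 * n_obs)
  if (!is.null(variant)) unname(freq) else freq
}

#' Detect allele swaps against a reference population frequency
#'
#' A variant whose observed counted-allele frequency matches the complement
#' of the reference frequency, but not the reference itself, is flagged as a
#' swap (the counted allele is mislabelled). Near-0.5 frequencies are
#' intrinsically ambiguous.
#'
#' @param observed_freq observed frequency in \[0, 1\].
#' @param reference_freq reference-population frequency in \[0, 1\].
#' @param tolerance maximum absolute frequency difference treated as a match.
#' @return One of `"ok"`, `"swapped"`, `"ambiguous"` (vectorized).
#' @export
check_allele_swap <- function(observed_freq, reference_freq, tolerance = 0.15) {
  if (any(observed_freq < 0 | observed_freq > 1 |
          reference_freq < 0 | reference_freq > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  direct <- abs(observed_freq - reference_freq) <= tolerance
  flipped <- abs(observed_freq - (1 - reference_freq)) <= tolerance
  out <- rep("ambiguous", length(direct))
  out[direct & !flipped] <- "ok"
  out[flipped & !direct] <- "swapped"
  out[direct & flipped] <- "ambiguous"
  out
}

#' Concordance between duplicate genotyping runs
#'
#' @param calls_a,calls_b call vectors for the same sample genotyped twice;
#'   pairs where either call is missing are excluded.
#' @return Fraction of comparable pairs with identical calls.
#' @export
duplicate_concordance <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b))
    stop("duplicate call vectors must have equal length", call. = FALSE)
  ok <- !is.na(calls_a) & !is.na(calls_b)
  if (!any(ok))
    stop("concordance undefined: no pair with both calls observed",
         call. = FALSE)
  mean(calls_a[ok] == calls_b[ok])
}

#' Impute missing genotypes to the within-cohort mean
#'
#' Each missing call is replaced by the mean observed allelic count of the
#' same variant within the same cohort, so cohorts with different allele
#' frequencies do not contaminate each other. Imputed dosages are kept
#' fractional; observed calls are unchanged.
#'
#' @param gm a [genotype_matrix()].
#' @return A `genotype_matrix` with no missing calls and `imputed = TRUE`.
#' @export
mean_impute <- function(gm) {
  calls <- gm$calls
  if (!anyNA(calls))
    return(genotype_matrix(calls, counted_allele = gm$counted_allele,
                           other_allele = gm$other_allele, cohort = gm$cohort,
                           imputed = isTRUE(attr(gm, "imputed"))))
  for (co in unique(gm$cohort)) {
    rows <- gm$cohort == co
    block <- calls[rows, , drop = FALSE]
    miss_var <- colSums(is.na(block)) > 0
    for (v in colnames(calls)[miss_var]) {
      obs <- block[, v][!is.na(block[, v])]
      if (length(obs) == 0)
        stop(sprintf("cannot impute variant '%s' in cohort '%s': all calls missing",
                     v, co), call. = FALSE)
      block[is.na(block[, v]), v] <- mean(obs)
    }
    calls[rows, ] <- block
  }
  genotype_matrix(calls, counted_allele = gm$counted_allele,
                  other_allele = gm$other_allele, cohort = gm$cohort,
                  imputed = TRUE)
}

#' Genotype quality-control report
#'
#' Per (cohort, variant): genotype counts, observed allele frequency, exact
#' Hardy-Weinberg p-value, missingness, and (when reference frequencies are
#' supplied) an allele-swap flag. Fractional (imputed) calls are not
#' accepted: QC runs on raw calls.
#'
#' @param gm a [genotype_matrix()] with raw (non-imputed) calls.
#' @param reference_freq optional named vector of reference-population
#'   frequencies of the counted allele, keyed by variant id.
#' @param swap_tolerance tolerance passed to [check_allele_swap()].
#' @param by_cohort test each cohort separately (default) or pool all
#'   samples.
#' @return A data frame of class `qc_report`, one row per (cohort, variant),
#'   with the overall missing count/fraction in attributes `missing_count`
#'   and `missing_fraction`.
#' @export
qc_report <- function(gm, reference_freq = NULL, swap_tolerance = 0.15,
                      by_cohort = TRUE) {
  if (isTRUE(attr(gm, "imputed")))
    stop("qc_report requires raw (non-imputed) genotype calls", call. = FALSE)
  groups <- if (by_cohort) split(seq_along(gm$cohort), gm$cohort)
            else list(all = seq_along(gm$cohort))
  rows <- lapply(names(groups), function(co) {
    block <- gm$calls[groups[[co]], , drop = FALSE]
    do.call(rbind, lapply(colnames(block), function(v) {
      x <- block[, v]
      n0 <- sum(x == 0, na.rm = TRUE)
      n1 <- sum(x == 1, na.rm = TRUE)
      n2 <- sum(x == 2, na.rm = TRUE)
      n_miss <- sum(is.na(x))
      freq <- if (n0 + n1 + n2 > 0) (n1 + 2 * n2) / (2 * (n0 + n1 + n2)) else NA_real_
      p <- if (n0 + n1 + n2 > 0) hwe_exact_test(n0, n1, n2) else NA_real_
      data.frame(cohort = co, variant_id = v, n = length(x),
                 n_hom_ref = n0, n_het = n1, n_hom_alt = n2,
                 n_missing = n_miss, freq = freq,
                 hwe_p = as.numeric(p),
                 monomorphic = isTRUE(attr(p, "monomorphic")),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (!is.null(reference_freq)) {
    ref <- reference_freq[out$variant_id]
    out$reference_freq <- as.numeric(ref)
    out$swap <- ifelse(is.na(ref), NA_character_,
                       check_allele_swap(out$freq, as.numeric(ref),
                                         swap_tolerance))
  }
  rownames(out) <- NULL
  attr(out, "missing_count") <- sum(is.na(gm$calls))
  attr(out, "missing_fraction") <- sum(is.na(gm$calls)) / length(gm$calls)
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Write a QC report as TSV and JSON
#'
#' @param report a [qc_report()].
#' @param path_prefix files are written to `<path_prefix>.tsv` and
#'   `<path_prefix>.json`.
#' @return The two paths, invisibly.
#' @export
write_qc_report <- function(report, path_prefix) {
  tsv <- paste0(path_prefix, ".tsv")
  json <- paste0(path_prefix, ".json")
  utils::write.table(as.data.frame(report), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(variants = as.data.frame(report),
         missing_count = attr(report, "missing_count"),
         missing_fraction = attr(report, "missing_fraction")),
    json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(tsv, json))
}
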