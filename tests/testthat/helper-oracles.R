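# Independent oracles used to cross-check the package's statistics.

# Exact HWE test by direct enumeration: conditional probability of each
# possible heterozygote count given the allele counts, from log factorials.
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  na <- 2 * n_hom_alt + n_het              # alt allele count
  rare <- min(na, 2 * n - na)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (rare - h) / 2
    hc <- n - h - hr
    lfactorial(n) - lfactorial(h) - lfactorial(hr) - lfactorial(hc) +
      h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  min(sum(p[p <= obs * (1 + 1e-12)]), 1)
}

# AUC by brute force over all case-control pairs.
auc_bruteforce <- function(scores, status) {
  cases <- scores[status == 1]
  controls <- scores[status == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

# Woolf odds ratio and SE from a 2x2 table (exposed/unexposed x case/control).
woolf_2x2 <- function(case_exp, case_unexp, ctrl_exp, ctrl_unexp) {
  list(or = (case_exp * ctrl_unexp) / (case_unexp * ctrl_exp),
       se = sqrt(1 / case_exp + 1 / case_unexp + 1 / ctrl_exp + 1 / ctrl_unexp))
}

# Tiny genotype matrix builder for unit tests.
tiny_gm <- function(calls, counted = NULL, other = NULL, cohort = NULL,
                    imputed = FALSE) {
  calls <- as.matrix(calls)
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("v", seq_len(ncol(calls)))
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("s", seq_len(nrow(calls)))
  genotype_matrix(calls, counted_allele = counted, other_allele = other,
                  cohort = cohort, imputed = imputed)
}
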