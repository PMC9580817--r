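#' Read a PRS scoring weight table
#'
#' Tab-separated with header columns `rsID`, `effect_allele`, `other_allele`,
#' `effect_weight` (a compatible subset of PGS-Catalog scoring files). The
#' weight is the per-allele log odds ratio from the discovery GWAS.
#'
#' @param path TSV file path.
#' @return A validated weight table data frame.
#' @export
read_weight_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  weight_table(df)
}

#' Validate a weight table
#'
#' @param df data frame with columns `rsID`, `effect_allele`, `other_allele`,
#'   `effect_weight`.
#' @return The validated data frame.
#' @export
weight_table <- function(df) {
  need <- c("rsID", "effect_allele", "other_allele", "effect_weight")
  if (!all(need %in% names(df)))
    stop(sprintf("weight table must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  df <- df[, need]
  if (anyDuplicated(df$rsID))
    stop("weight table rsIDs must be unique", call. = FALSE)
  if (!all(is.finite(df$effect_weight)))
    stop("weights must be finite", call. = FALSE)
  bad <- df$effect_allele == df$other_allele
  if (any(bad))
    stop(sprintf("effect and other allele identical for: %s",
                 paste(df$rsID[bad], collapse = ", ")), call. = FALSE)
  df
}

#' Compute the weighted-allele polygenic risk score
#'
#' The raw score of a sample is the weighted sum of its effect-allele
#' dosages over the panel: `sum_i dosage_i * weight_i`, with the weight the
#' per-allele log odds ratio. Genotypes whose counted allele is the scoring
#' file's other allele are reoriented as `2 - count`; variants recorded
#' without allele labels (dosage TSVs) are assumed already effect-oriented.
#' A counted allele matching neither scoring allele is a harmonization error
#' (strand flips are not guessed for a directly genotyped panel).
#'
#' @param gm a [genotype_matrix()] with no missing calls (run [mean_impute()]
#'   first).
#' @param weights a [weight_table()] (or the `variants` data frame of a
#'   simulation config, which is converted automatically).
#' @return A `prs_vector` data frame: `sample_id`, `cohort`, `raw_prs`.
#' @export
compute_prs <- function(gm, weights) {
  weights <- as_weight_table(weights)
  if (anyNA(gm$calls))
    stop("genotype matrix has missing calls; run mean_impute() first",
         call. = FALSE)
  absent <- setdiff(weights$rsID, variant_ids(gm))
  if (length(absent))
    stop(sprintf("weight-table variant(s) absent from genotypes: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  dosage <- matrix(0, nrow(gm$calls), nrow(weights))
  for (k in seq_len(nrow(weights))) {
    v <- weights$rsID[k]
    counted <- gm$counted_allele[v]
    if (is.na(counted) || counted == weights$effect_allele[k]) {
      dosage[, k] <- gm$calls[, v]
    } else if (counted == weights$other_allele[k]) {
      dosage[, k] <- 2 - gm$calls[, v]
    } else {
      stop(sprintf(
        "cannot harmonize variant '%s': counted allele %s matches neither %s nor %s",
        v, counted, weights$effect_allele[k], weights$other_allele[k]),
        call. = FALSE)
    }
  }
  raw <- as.numeric(dosage %*% weights$effect_weight)
  out <- data.frame(sample_id = sample_ids(gm),
                    cohort = unname(gm$cohort),
                    raw_prs = raw, stringsAsFactors = FALSE)
  class(out) <- c("prs_vector", "data.frame")
  out
}

as_weight_table <- function(x) {
  if (all(c("rsID", "effect_weight") %in% names(x))) return(weight_table(x))
  if (all(c("variant_id", "weight") %in% names(x)))
    return(weight_table(data.frame(rsID = x$variant_id,
                                   effect_allele = x$effect_allele,
                                   other_allele = x$other_allele,
                                   effect_weight = x$weight,
                                   stringsAsFactors = FALSE)))
  stop("not a weight table", call. = FALSE)
}

#' Standardize scores within strata
#'
#' Z-scores each stratum with its own sample mean and sample standard
#' deviation (n-1 denominator), the convention used when a cohort's PRS is
#' standardized to mean zero and variance one before association testing.
#'
#' @param x numeric scores.
#' @param strata per-value stratum labels (a single label pools everything).
#' @return Numeric vector of standardized scores.
#' @export
standardize_scores <- function(x, strata = "combined") {
  strata <- rep_len(as.character(strata), length(x))
  out <- numeric(length(x))
  for (s in unique(strata)) {
    idx <- strata == s
    if (sum(idx) < 2)
      stop(sprintf("stratum '%s' has fewer than 2 samples", s), call. = FALSE)
    sdv <- stats::sd(x[idx])
    if (sdv == 0)
      stop(sprintf("stratum '%s' has zero score variance", s), call. = FALSE)
    out[idx] <- (x[idx] - mean(x[idx])) / sdv
  }
  out
}

#' Standardize a PRS vector
#'
#' @param prs a `prs_vector` from [compute_prs()].
#' @param strata `"combined"` (pool all samples, the combined-cohort
#'   analysis), `"cohort"` (each cohort uses its own moments), or an explicit
#'   per-sample label vector.
#' @return The `prs_vector` with `std_prs` and `stratum` columns added.
#' @export
standardize_prs <- function(prs, strata = "combined") {
  labels <- if (identical(strata, "combined")) rep("combined", nrow(prs))
            else if (identical(strata, "cohort")) prs$cohort
            else rep_len(as.character(strata), nrow(prs))
  prs$std_prs <- standardize_scores(prs$raw_prs, labels)
  prs$stratum <- labels
  prs
}

#' Write a PRS table as TSV
#'
#' Score columns are written with 17 significant digits so the doubles
#' round-trip losslessly; re-reading the file reproduces the in-memory
#' scores (and hence every rank-based statistic) exactly.
#'
#' @param prs a `prs_vector`, standardized or not.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_prs_tsv <- function(prs, path) {
  df <- as.data.frame(prs)
  for (col in names(df)) {
    if (is.double(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
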