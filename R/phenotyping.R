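# ICD-10 N80 phenotype engine.
#
# N80.0 is adenomyosis (uterine) and is handled as a distinct entity; N80.1
# through N80.9 are endometriosis by anatomical site. N80.7 is not part of
# the coding scheme used here and is rejected rather than silently binned.

# severity order, most severe first; N80.0 is never ranked
SEVERITY_ORDER <- c("N80.5", "N80.4", "N80.1", "N80.3", "N80.2",
                    "N80.9", "N80.8", "N80.6")

SUBTYPE_MAP <- c(N80.4 = "infiltrating", N80.5 = "infiltrating",
                 N80.1 = "ovarian",
                 N80.2 = "peritoneal", N80.3 = "peritoneal",
                 N80.6 = "other", N80.8 = "other", N80.9 = "other")

VALID_CODES <- c("N80.0", SEVERITY_ORDER)

#' Endometriosis subtype groups
#'
#' @return Named list mapping subtype to its ICD-10 N80 codes: infiltrating
#'   (N80.4, N80.5), ovarian (N80.1), peritoneal (N80.2, N80.3), other
#'   (N80.6, N80.8, N80.9).
#' @export
subtype_groups <- function() {
  split(names(SUBTYPE_MAP), unname(SUBTYPE_MAP))[
    c("infiltrating", "ovarian", "peritoneal", "other")]
}

#' Parse a semicolon-joined ICD-10 code string
#'
#' @param x character vector of semicolon-joined N80 codes (empty string or
#'   `NA` means no diagnosis).
#' @return A list of character vectors of validated codes.
#' @export
parse_icd_codes <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(character(0))
    codes <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    validate_icd_codes(codes)
  })
}

validate_icd_codes <- function(codes) {
  bad <- setdiff(codes, VALID_CODES)
  if (length(bad))
    stop(sprintf("unrecognized ICD-10 code(s): %s (valid: %s)",
                 paste(bad, collapse = ", "),
                 paste(VALID_CODES, collapse = ", ")), call. = FALSE)
  unique(codes)
}

#' Classify case-control status from N80 codes
#'
#' Any code in N80.1-N80.9 makes a sample an endometriosis case; N80.0 alone
#' makes it adenomyosis; samples with no N80 code are controls unless they
#' self-reported endometriosis, in which case they are excluded (the
#' biobank-style control definition).
#'
#' @param codes character vector of N80 codes for one sample, or a list of
#'   such vectors for many samples (see [parse_icd_codes()]).
#' @param self_reported logical, self-reported endometriosis without an N80
#'   code (recycled over samples).
#' @return `"endometriosis"`, `"adenomyosis"`, `"control"` or `"excluded"`.
#' @export
classify_status <- function(codes, self_reported = FALSE) {
  if (!is.list(codes)) codes <- list(codes)
  self_reported <- rep_len(as.logical(self_reported), length(codes))
  vapply(seq_along(codes), function(i) {
    cs <- validate_icd_codes(codes[[i]])
    if (any(cs %in% SEVERITY_ORDER)) return("endometriosis")
    if ("N80.0" %in% cs) return("adenomyosis")
    if (isTRUE(self_reported[i])) return("excluded")
    "control"
  }, character(1))
}

#' Collapse a case's codes to its most severe subtype
#'
#' Multi-code cases are assigned to the most severe category, severity
#' ranked N80.5 > N80.4 > N80.1 > N80.3 > N80.2 > N80.9 > N80.8 > N80.6
#' (N80.0 is ignored for ranking). The top-ranked code is then mapped to its
#' subtype group.
#'
#' @param codes character vector of N80 codes for one endometriosis case, or
#'   a list of such vectors.
#' @return Subtype: `"infiltrating"`, `"ovarian"`, `"peritoneal"` or
#'   `"other"`.
#' @export
assign_severity_subtype <- function(codes) {
  if (!is.list(codes)) codes <- list(codes)
  vapply(codes, function(cs) {
    cs <- validate_icd_codes(cs)
    ranked <- SEVERITY_ORDER[SEVERITY_ORDER %in% cs]
    if (!length(ranked))
      stop("subtype assignment requires an endometriosis case (a code in N80.1-N80.9)",
           call. = FALSE)
    unname(SUBTYPE_MAP[ranked[1]])
  }, character(1))
}

#' Phenotype a cohort table
#'
#' @param pheno data frame with columns `sample_id`, `cohort`, `icd_codes`
#'   (semicolon-joined) and optionally `self_report` (0/1; biobank-style
#'   control exclusion applies only when present).
#' @return Data frame `sample_id`, `cohort`, `status`, `subtype` (subtype is
#'   `"none"` for non-cases).
#' @export
phenotype_assignments <- function(pheno) {
  need <- c("sample_id", "cohort", "icd_codes")
  if (!all(need %in% names(pheno)))
    stop(sprintf("phenotype table must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  codes <- parse_icd_codes(pheno$icd_codes)
  self <- if ("self_report" %in% names(pheno)) pheno$self_report == 1 else FALSE
  status <- classify_status(codes, self)
  subtype <- rep("none", length(status))
  is_case <- status == "endometriosis"
  if (any(is_case)) subtype[is_case] <- assign_severity_subtype(codes[is_case])
  data.frame(sample_id = pheno$sample_id, cohort = pheno$cohort,
             status = status, subtype = subtype, stringsAsFactors = FALSE)
}

round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

format_percent <- function(count, total, style) {
  pct <- 100 * count / total
  if (style == "integer") return(round_half_up(pct, 0))
  out <- round_half_up(pct, 1)
  # counts too small for one decimal keep one significant figure (0.04%)
  small <- out == 0 & count > 0
  out[small] <- signif(pct[small], 1)
  out
}

#' Tabulate subtype and adenomyosis counts per cohort
#'
#' Reproduces the standard cohort-description table: per cohort, the number
#' (and percentage) of endometriosis cases, each subtype, and adenomyosis.
#' Percentages use the full classified cohort (cases + adenomyosis +
#' controls; excluded samples are dropped) as denominator. Rounding is
#' half-up; `percent_style = "integer"` prints whole percents (registry-size
#' cohorts), `"decimal"` one decimal, falling back to one significant figure
#' for non-zero fractions below 0.05% (biobank-size cohorts).
#'
#' @param assignments output of [phenotype_assignments()].
#' @param percent_style `"integer"` or `"decimal"`, a single value or one per
#'   cohort (named).
#' @return Data frame: `cohort`, `group`, `n`, `percent`, `total`.
#' @export
tabulate_subtypes <- function(assignments, percent_style = "integer") {
  if (!nrow(assignments)) stop("no assignments to tabulate", call. = FALSE)
  assignments <- assignments[assignments$status != "excluded", , drop = FALSE]
  cohorts <- unique(assignments$cohort)
  styles <- if (!is.null(names(percent_style))) percent_style[cohorts]
            else rep_len(percent_style, length(cohorts))
  groups <- c("endometriosis", names(subtype_groups()), "adenomyosis")
  rows <- lapply(seq_along(cohorts), function(i) {
    a <- assignments[assignments$cohort == cohorts[i], ]
    total <- nrow(a)
    n <- vapply(groups, function(g) {
      if (g == "endometriosis") sum(a$status == "endometriosis")
      else if (g == "adenomyosis") sum(a$status == "adenomyosis")
      else sum(a$subtype == g)
    }, numeric(1))
    data.frame(cohort = cohorts[i], group = groups, n = n,
               percent = format_percent(n, total, styles[i]),
               total = total, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
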