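#' Genotype matrix container
#'
#' Holds allelic counts for a panel of biallelic variants across samples,
#' together with the allele each column counts and a per-sample cohort label.
#' Counts are 0, 1 or 2 copies of the counted allele; `NA` marks a missing
#' call. After [mean_impute()] counts may be fractional (anywhere in
#' \[0, 2\]).
#'
#' @param calls numeric matrix, samples in rows and variants in columns.
#'   Non-missing entries must lie in \[0, 2\], and must be whole numbers
#'   unless `imputed = TRUE`.
#' @param sample_ids character vector of unique sample identifiers
#'   (defaults to the rownames of `calls`).
#' @param variant_ids character vector of unique variant identifiers
#'   (defaults to the colnames of `calls`).
#' @param counted_allele character vector, one single-base allele per variant:
#'   the allele whose copies `calls` counts. May be `NA` when the source
#'   format does not record alleles (dosage TSVs), in which case scoring
#'   assumes the counted allele is the effect allele.
#' @param other_allele character vector, the variant's other allele
#'   (optional; used when writing VCF).
#' @param cohort character vector of per-sample cohort labels.
#' @param imputed logical, `TRUE` when fractional (imputed) dosages are
#'   allowed.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `counted_allele`, `other_allele` and `cohort`.
#' @export
genotype_matrix <- function(calls, sample_ids = rownames(calls),
                            variant_ids = colnames(calls),
                            counted_allele = NULL, other_allele = NULL,
                            cohort = NULL, imputed = FALSE) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "double"
  if (is.null(sample_ids)) sample_ids <- sprintf("S%05d", seq_len(nrow(calls)))
  if (is.null(variant_ids)) stop("variant_ids are required", call. = FALSE)
  sample_ids <- as.character(sample_ids)
  variant_ids <- as.character(variant_ids)
  if (length(sample_ids) != nrow(calls))
    stop("length(sample_ids) must equal nrow(calls)", call. = FALSE)
  if (length(variant_ids) != ncol(calls))
    stop("length(variant_ids) must equal ncol(calls)", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique", call. = FALSE)
  if (anyDuplicated(variant_ids)) stop("variant_ids must be unique", call. = FALSE)
  obs <- calls[!is.na(calls)]
  if (length(obs) && (min(obs) < 0 || max(obs) > 2))
    stop("genotype calls must lie in [0, 2]", call. = FALSE)
  if (!imputed && length(obs) && any(obs != round(obs)))
    stop("non-imputed genotype calls must be whole allelic counts (0, 1, 2)",
         call. = FALSE)
  if (is.null(counted_allele)) counted_allele <- rep(NA_character_, ncol(calls))
  if (is.null(other_allele)) other_allele <- rep(NA_character_, ncol(calls))
  counted_allele <- rep_len(as.character(counted_allele), ncol(calls))
  other_allele <- rep_len(as.character(other_allele), ncol(calls))
  if (is.null(cohort)) cohort <- rep("cohort1", nrow(calls))
  cohort <- rep_len(as.character(cohort), nrow(calls))
  dimnames(calls) <- list(sample_ids, variant_ids)
  names(counted_allele) <- variant_ids
  names(other_allele) <- variant_ids
  names(cohort) <- sample_ids
  structure(
    list(calls = calls, counted_allele = counted_allele,
         other_allele = other_allele, cohort = cohort),
    class = "genotype_matrix", imputed = imputed
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%d cohort%s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$cohort)),
              if (length(unique(x$cohort)) == 1) "" else "s"))
  nm <- sum(is.na(x$calls))
  cat(sprintf("  missing calls: %d (%.2f%%)%s\n", nm,
              100 * nm / length(x$calls),
              if (isTRUE(attr(x, "imputed"))) "; imputed dosages" else ""))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

sample_ids <- function(gm) rownames(gm$calls)
variant_ids <- function(gm) colnames(gm$calls)

#' Subset a genotype matrix by samples
#'
#' @param gm a [genotype_matrix()].
#' @param keep logical or integer index over samples.
#' @return A `genotype_matrix` restricted to the selected samples.
#' @export
subset_samples <- function(gm, keep) {
  genotype_matrix(gm$calls[keep, , drop = FALSE],
                  counted_allele = gm$counted_allele,
                  other_allele = gm$other_allele,
                  cohort = gm$cohort[keep],
                  imputed = isTRUE(attr(gm, "imputed")))
}

#' Write genotypes as a minimal VCF 4.2 file
#'
#' Emits one record per variant on a single placeholder contig, with the
#' counted allele as ALT so that GT allele-1 counts equal the stored calls.
#' Missing calls are written as `./.`.
#'
#' @param gm a [genotype_matrix()] with integer calls and known alleles.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(gm, path) {
  if (isTRUE(attr(gm, "imputed")))
    stop("VCF output requires integer calls; write a dosage TSV instead",
         call. = FALSE)
  if (anyNA(gm$counted_allele) || anyNA(gm$other_allele))
    stop("VCF output requires counted and other alleles for every variant",
         call. = FALSE)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(gm)), collapse = "\t")
  )
  rows <- vapply(seq_len(ncol(gm$calls)), function(j) {
    gt <- ifelse(is.na(gm$calls[, j]), "./.",
                 gt_code[as.character(gm$calls[, j])])
    paste(c("1", j, variant_ids(gm)[j], gm$other_allele[j],
            gm$counted_allele[j], ".", ".", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Parses GT calls with [vcfR::read.vcfR()]; each call becomes the count of
#' ALT-allele copies, with `./.` mapped to missing. The ALT allele becomes
#' the counted allele.
#'
#' @param path VCF file path.
#' @param cohort per-sample cohort labels (single label recycled, or a named
#'   vector keyed by sample id).
#' @return A [genotype_matrix()].
#' @export
read_genotypes_vcf <- function(path, cohort = "cohort1") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  counts <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_real_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
  })
  fix <- vcfR::getFIX(vcf)
  calls <- t(counts)
  gm_cohort <- if (!is.null(names(cohort))) cohort[rownames(calls)] else cohort
  genotype_matrix(calls,
                  variant_ids = unname(fix[, "ID"]),
                  counted_allele = unname(fix[, "ALT"]),
                  other_allele = unname(fix[, "REF"]),
                  cohort = gm_cohort)
}

#' Write genotypes as a dosage TSV
#'
#' Layout: `sample_id`, `cohort`, then one column per variant with values
#' 0/1/2 (fractional after imputation) and `NA` for missing calls.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(gm, path) {
  df <- data.frame(sample_id = sample_ids(gm), cohort = gm$cohort, gm$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a dosage TSV
#'
#' Dosage TSVs carry no allele information; by convention their values count
#' copies of the scoring file's effect allele. Pass a weight table via
#' `weights` to record that orientation, otherwise the counted allele is
#' left unknown and scoring assumes effect-allele orientation.
#'
#' @param path TSV path with header `sample_id`, an optional `cohort`
#'   column, then one column per variant.
#' @param cohort per-sample cohort labels (single label recycled, or a named
#'   vector keyed by sample id); `NULL` (default) uses the file's `cohort`
#'   column when present, else the label `"cohort1"`.
#' @param weights optional weight table (see [read_weight_table()]) used to
#'   set counted/other alleles for variants it covers.
#' @return A [genotype_matrix()].
#' @export
read_dosage_tsv <- function(path, cohort = NULL, weights = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id")
    stop("dosage TSV must start with a 'sample_id' column", call. = FALSE)
  file_cohort <- NULL
  if (identical(names(df)[2], "cohort")) {
    file_cohort <- df$cohort
    df$cohort <- NULL
  }
  if (is.null(cohort)) {
    cohort <- if (!is.null(file_cohort)) file_cohort else "cohort1"
  }
  calls <- as.matrix(df[, -1, drop = FALSE])
  rownames(calls) <- df$sample_id
  counted <- other <- rep(NA_character_, ncol(calls))
  if (!is.null(weights)) {
    idx <- match(colnames(calls), weights$rsID)
    counted <- weights$effect_allele[idx]
    other <- weights$other_allele[idx]
  }
  gm_cohort <- if (!is.null(names(cohort))) cohort[df$sample_id] else cohort
  imputed <- any(calls[!is.na(calls)] != round(calls[!is.na(calls)]))
  genotype_matrix(calls, counted_allele = counted, other_allele = other,
                  cohort = gm_cohort, imputed = imputed)
}
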