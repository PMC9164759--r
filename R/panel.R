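#' Genotype panel
#'
#' Container for a rectangular dosage matrix (individuals x SNPs) holding
#' counts of the reference allele, together with SNP identifiers and
#' chromosome labels. Dosages must be complete (no missing values) and coded
#' 0/1/2 against a common reference allele across all populations that will
#' enter a meta-analysis.
#'
#' @param dosage numeric matrix, individuals in rows, SNPs in columns,
#'   entries in \{0, 1, 2\}.
#' @param snp_ids character vector of unique SNP identifiers; defaults to the
#'   column names of `dosage`.
#' @param chrom chromosome label per SNP; defaults to a single chromosome.
#'   Used to delimit LD blocks during summary-statistic imputation.
#' @param indiv_ids individual identifiers; defaults to the row names.
#'
#' @return An object of class `genotype_panel` with fields `dosage`,
#'   `snp_ids`, `chrom`, `indiv_ids`.
#' @seealso [allele_freq()], [center_genotypes()], [summarize_population()]
#' @export
genotype_panel <- function(dosage, snp_ids = colnames(dosage), chrom = NULL,
                           indiv_ids = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (anyNA(dosage)) stop("dosage matrix contains missing values")
  if (!all(dosage == 0 | dosage == 1 | dosage == 2))
    stop("dosage entries must be 0, 1 or 2 (counts of the reference allele)")
  m <- ncol(dosage)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
  snp_ids <- as.character(snp_ids)
  if (length(snp_ids) != m) stop("length(snp_ids) must equal ncol(dosage)")
  if (anyDuplicated(snp_ids)) stop("snp_ids must be unique")
  if (is.null(chrom)) chrom <- rep("1", m)
  chrom <- as.character(chrom)
  if (length(chrom) != m) stop("length(chrom) must equal ncol(dosage)")
  if (is.null(indiv_ids)) indiv_ids <- paste0("id", seq_len(nrow(dosage)))
  indiv_ids <- as.character(indiv_ids)
  if (length(indiv_ids) != nrow(dosage) || anyDuplicated(indiv_ids))
    stop("indiv_ids must be unique and match nrow(dosage)")
  dimnames(dosage) <- list(indiv_ids, snp_ids)
  structure(
    list(snp_ids = snp_ids, chrom = chrom, dosage = dosage,
         indiv_ids = indiv_ids),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$indiv_ids), "individuals x",
      length(x$snp_ids), "SNPs on", length(unique(x$chrom)),
      "chromosome(s)\n")
  invisible(x)
}

#' Phenotype records for a sire-model evaluation
#'
#' Phenotypes are daughter-average records corrected for all effects other
#' than the additive genetic effect captured by the SNPs; `n_daughters` is the
#' effective number of daughters contributing to each record, which sets the
#' residual precision of that record (residual variance `err_var / n_ik`).
#'
#' @param y numeric vector of corrected phenotypes (trait units).
#' @param n_daughters strictly positive effective daughter counts, same
#'   length as `y`.
#' @param indiv_ids optional identifiers matching a [genotype_panel()];
#'   if omitted the records are taken to be row-aligned with the panel.
#' @return An object of class `phenotype_records`.
#' @export
phenotype_records <- function(y, n_daughters, indiv_ids = NULL) {
  y <- as.numeric(y)
  n_daughters <- as.numeric(n_daughters)
  if (length(y) != length(n_daughters))
    stop("y and n_daughters must have the same length")
  if (anyNA(y) || anyNA(n_daughters)) stop("missing values not allowed")
  if (any(n_daughters <= 0)) stop("n_daughters must be strictly positive")
  if (!is.null(indiv_ids)) {
    indiv_ids <- as.character(indiv_ids)
    if (length(indiv_ids) != length(y) || anyDuplicated(indiv_ids))
      stop("indiv_ids must be unique and match length(y)")
  }
  structure(list(y = y, n_daughters = n_daughters, indiv_ids = indiv_ids),
            class = "phenotype_records")
}

#' @export
print.phenotype_records <- function(x, ...) {
  cat("phenotype_records:", length(x$y), "records, mean n_daughters",
      format(mean(x$n_daughters), digits = 4), "\n")
  invisible(x)
}

#' Reference-allele frequencies of a panel
#'
#' Frequencies are computed as mean dosage over the panel's genotyped
#' individuals divided by two.
#'
#' @param panel a [genotype_panel()].
#' @return Named numeric vector of per-SNP frequencies in \[0, 1\].
#' @export
allele_freq <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  colMeans(panel$dosage) / 2
}

# Align phenotype records with a panel: returns row indices into the panel's
# dosage matrix. Phenotyped individuals must be a subset of genotyped ones.
match_records <- function(panel, records) {
  if (is.null(records$indiv_ids)) {
    if (length(records$y) != nrow(panel$dosage))
      stop("records without indiv_ids must cover every panel individual")
    return(seq_along(records$y))
  }
  idx <- match(records$indiv_ids, panel$indiv_ids)
  if (anyNA(idx))
    stop("phenotyped individuals must be a subset of the genotyped panel; ",
         "missing: ", paste(utils::head(records$indiv_ids[is.na(idx)], 5),
                            collapse = ", "))
  idx
}
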