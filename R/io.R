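# On-disk formats
#
# dosage table:     TSV, header "indiv_id" + SNP ids, entries 0/1/2
# phenotype table:  TSV, columns indiv_id, y, n_daughters
# SNP map:          TSV, columns snp_id, chrom
# population summary (prefix-based):
#   <prefix>.snps.tsv   snp_id, allele_freq [, effect] [, rhs]
#   <prefix>.meta       "key: value" lines (dgv_var, err_var, n_pheno,
#                       n_geno, population, trait)
#   <prefix>.lhsbin     packed lower triangle of the precision matrix,
#                       row-major 8-byte little-endian doubles, after a
#                       16-byte header (8-byte magic "MGSLHS01", m as an
#                       8-byte little-endian integer)

LHS_MAGIC <- "MGSLHS01"

#' Write / read a dosage table
#'
#' Tab-separated: header row `indiv_id` followed by SNP ids; one row per
#' individual with 0/1/2 entries.
#'
#' @param panel a [genotype_panel()].
#' @param path file path.
#' @param snp_map optional path of a SNP map TSV (`snp_id`, `chrom`) giving
#'   chromosome labels on read; without it all SNPs land on one chromosome.
#' @return `read_dosage()` returns a [genotype_panel()];
#'   `write_dosage()` returns `path` invisibly.
#' @export
write_dosage <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  df <- data.frame(indiv_id = panel$indiv_ids,
                   panel$dosage, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage
#' @export
read_dosage <- function(path, snp_map = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (names(df)[1L] != "indiv_id")
    stop("dosage table must start with an 'indiv_id' column: ", path)
  mat <- as.matrix(df[-1L])
  chrom <- NULL
  if (!is.null(snp_map)) {
    map <- utils::read.table(snp_map, header = TRUE, sep = "\t",
                             colClasses = "character")
    chrom <- map$chrom[match(colnames(mat), map$snp_id)]
    if (anyNA(chrom)) stop("SNP map does not cover all dosage columns")
  }
  genotype_panel(mat, snp_ids = colnames(mat), chrom = chrom,
                 indiv_ids = df$indiv_id)
}

#' Write / read a phenotype table
#'
#' Tab-separated with columns `indiv_id`, `y`, `n_daughters`.
#'
#' @param records a [phenotype_records()].
#' @param path file path.
#' @return `read_phenotypes()` returns a [phenotype_records()].
#' @export
write_phenotypes <- function(records, path) {
  stopifnot(inherits(records, "phenotype_records"))
  ids <- records$indiv_ids
  if (is.null(ids)) ids <- paste0("id", seq_along(records$y))
  df <- data.frame(indiv_id = ids, y = sprintf("%.10g", records$y),
                   n_daughters = sprintf("%.10g", records$n_daughters))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("indiv_id", "y", "n_daughters")
  if (!all(need %in% names(df)))
    stop("phenotype table must have columns indiv_id, y, n_daughters: ", path)
  phenotype_records(df$y, df$n_daughters, indiv_ids = df$indiv_id)
}

#' Write a SNP map (snp_id, chrom)
#' @param panel a [genotype_panel()].
#' @param path file path.
#' @export
write_snp_map <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  utils::write.table(
    data.frame(snp_id = panel$snp_ids, chrom = panel$chrom),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# 8-byte little-endian nonnegative integer, written as two 4-byte words
# (dimensions here always fit the low word)
write_int64le <- function(con, x) {
  if (x >= 2^31) stop("dimension too large for this writer")
  writeBin(as.integer(c(x, 0L)), con, size = 4L, endian = "little")
}

read_int64le <- function(con) {
  w <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  if (length(w) != 2L) stop("truncated header")
  lo <- as.numeric(w[1L]); if (lo < 0) lo <- lo + 2^32
  lo + as.numeric(w[2L]) * 2^32
}

#' Write / read the packed binary lower triangle of a precision matrix
#'
#' Layout: 8 bytes magic `"MGSLHS01"`, 8 bytes little-endian integer m, then
#' m(m+1)/2 doubles - the lower triangle including the diagonal, row-major
#' (row i contributes columns 1..i). The round trip is bit-exact.
#'
#' @param lhs symmetric m x m matrix.
#' @param path file path.
#' @return `read_lhs_bin()` returns the full symmetric matrix.
#' @export
write_lhs_bin <- function(lhs, path) {
  lhs <- as.matrix(lhs)
  m <- nrow(lhs)
  if (ncol(lhs) != m) stop("lhs must be square")
  if (anyNA(lhs) || any(!is.finite(lhs)))
    stop("lhs contains non-finite values")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(LHS_MAGIC), con)
  write_int64le(con, m)
  writeBin(as.numeric(t(lhs)[upper.tri(lhs, diag = TRUE)]), con,
           size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_lhs_bin
#' @export
read_lhs_bin <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 16)
    stop("not a packed-triangle file (shorter than the 16-byte header): ",
         path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (!identical(magic, charToRaw(LHS_MAGIC)))
    stop("magic mismatch at byte 0 of ", path, ": expected '", LHS_MAGIC,
         "', found '", paste(as.character(magic), collapse = " "), "'")
  m <- read_int64le(con)
  ntri <- m * (m + 1) / 2
  expect_sz <- 16 + 8 * ntri
  if (sz != expect_sz)
    stop("dimension mismatch in ", path, ": header says m = ", m,
         " (", expect_sz, " bytes) but the file has ", sz, " bytes")
  vals <- readBin(con, "numeric", n = ntri, size = 8L, endian = "little")
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("non-finite values in packed triangle: ", path)
  out <- matrix(0, m, m)
  out[upper.tri(out, diag = TRUE)] <- vals   # row-major lower == col-major upper
  out <- t(out)
  out[upper.tri(out)] <- t(out)[upper.tri(out)]
  out
}

#' Write / read a population summary
#'
#' A summary occupies three files sharing one prefix: `<prefix>.snps.tsv`
#' (snp_id, allele_freq and, when present, effect and rhs columns, written
#' with 10 significant digits), `<prefix>.meta` (key-value metadata) and
#' `<prefix>.lhsbin` (binary packed triangle, see [write_lhs_bin()]).
#'
#' @param summary a `pop_summary`.
#' @param prefix path prefix for the three files.
#' @return `read_summary()` returns a `pop_summary`.
#' @export
write_summary <- function(summary, prefix) {
  stopifnot(inherits(summary, "pop_summary"))
  df <- data.frame(snp_id = summary$snp_ids,
                   allele_freq = sprintf("%.10g", summary$allele_freq))
  if (!is.null(summary$effects))
    df$effect <- sprintf("%.10g", summary$effects)
  if (!is.null(summary$rhs))
    df$rhs <- sprintf("%.10g", summary$rhs)
  utils::write.table(df, paste0(prefix, ".snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- c(population = summary$population, trait = summary$trait,
            dgv_var = sprintf("%.10g", summary$dgv_var),
            err_var = sprintf("%.10g", summary$err_var),
            n_pheno = summary$n_pheno, n_geno = summary$n_geno)
  writeLines(paste0(names(meta), ": ", meta), paste0(prefix, ".meta"))
  write_lhs_bin(summary$lhs, paste0(prefix, ".lhsbin"))
  invisible(prefix)
}

#' @rdname write_summary
#' @export
read_summary <- function(prefix) {
  snps <- utils::read.table(paste0(prefix, ".snps.tsv"), header = TRUE,
                            sep = "\t", colClasses = NA)
  meta_lines <- readLines(paste0(prefix, ".meta"))
  kv <- strsplit(meta_lines, ": ", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  lhs <- read_lhs_bin(paste0(prefix, ".lhsbin"))
  if (nrow(snps) != nrow(lhs))
    stop("dimension mismatch: ", nrow(snps), " SNP rows vs ", nrow(lhs),
         "-dimensional precision matrix under prefix ", prefix)
  structure(
    list(snp_ids = as.character(snps$snp_id),
         allele_freq = as.numeric(snps$allele_freq),
         lhs = lhs,
         rhs = if ("rhs" %in% names(snps)) as.numeric(snps$rhs),
         effects = if ("effect" %in% names(snps)) as.numeric(snps$effect),
         dgv_var = as.numeric(meta[["dgv_var"]]),
         err_var = as.numeric(meta[["err_var"]]),
         n_pheno = as.integer(meta[["n_pheno"]]),
         n_geno = as.integer(meta[["n_geno"]]),
         population = meta[["population"]], trait = meta[["trait"]]),
    class = "pop_summary"
  )
}
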