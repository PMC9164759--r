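#' Rescale a precision matrix by the phenotyped fraction
#'
#' A data holder computes Z'R^-1 Z once on all `n_geno` genotyped
#' individuals; for a trait phenotyped on only `n_pheno` of them, the matrix
#' is rescaled by `n_pheno / n_geno` so the population's contribution to the
#' meta-analysis is not overstated.
#'
#' @param lhs_full m x m precision matrix built from all genotyped
#'   individuals.
#' @param n_pheno number of phenotyped individuals (0 < n_pheno <= n_geno).
#' @param n_geno number of genotyped individuals behind `lhs_full`.
#' @return The rescaled matrix.
#' @export
rescale_lhs <- function(lhs_full, n_pheno, n_geno) {
  if (n_pheno <= 0 || n_geno <= 0) stop("counts must be positive")
  if (n_pheno > n_geno)
    stop("n_pheno (", n_pheno, ") exceeds n_geno (", n_geno, ")")
  as.matrix(lhs_full) * (n_pheno / n_geno)
}

#' Block-wise LD mapping from observed to complete SNPs
#'
#' On a reference panel genotyped for the complete SNP list, the genotypes of
#' the complete set relate to those of the observed subset by `Zc = Zi T`
#' with `T = (Zi'Zi)^-1 Zi'Zc` (least squares on centered genotypes). To keep
#' `Zi'Zi` invertible at realistic panel sizes, T is computed independently
#' within contiguous blocks of at most `block_size` adjacent SNPs per
#' chromosome, making the full T block-diagonal.
#'
#' @param ref_panel a [genotype_panel()] covering the complete SNP list.
#' @param observed_ids SNP ids present in the target population's summary.
#' @param complete_ids the complete (union) SNP list, a superset of
#'   `observed_ids`, in map order; defaults to all SNPs of the reference
#'   panel.
#' @param block_size maximum number of adjacent SNPs per block (default 200).
#' @param ridge nonnegative ridge added to Zi'Zi before inversion, or
#'   `"auto"`: zero when the block cross-product is well conditioned, else
#'   `1e-6 * mean(diag(Zi'Zi))` with a warning.
#' @return An object of class `imputation_map`: per-block T submatrices with
#'   index bookkeeping (`observed_idx` positions of observed SNPs in the
#'   complete list, `empty_blocks` blocks containing no observed SNP).
#' @export
build_imputation_map <- function(ref_panel, observed_ids,
                                 complete_ids = NULL, block_size = 200L,
                                 ridge = "auto") {
  stopifnot(inherits(ref_panel, "genotype_panel"))
  if (is.null(complete_ids)) complete_ids <- ref_panel$snp_ids
  complete_ids <- as.character(complete_ids)
  observed_ids <- as.character(observed_ids)
  if (block_size < 1L) stop("block_size must be at least 1")
  if (!all(observed_ids %in% complete_ids))
    stop("observed_ids must be a subset of complete_ids")
  panel_pos <- match(complete_ids, ref_panel$snp_ids)
  if (anyNA(panel_pos))
    stop("reference panel does not cover the complete SNP list")
  auto <- identical(ridge, "auto")
  if (!auto && (!is.numeric(ridge) || ridge < 0))
    stop("ridge must be nonnegative or \"auto\"")
  freq <- colMeans(ref_panel$dosage[, panel_pos, drop = FALSE]) / 2
  # SNPs monomorphic in the (possibly small) reference sample: clamp the
  # frequency so centering stays defined; such columns are constant and any
  # rank deficiency they cause is handled by the ridge below.
  eps <- 1 / (4 * nrow(ref_panel$dosage))
  freq <- pmin(pmax(freq, eps), 1 - eps)
  Zref <- center_genotypes(ref_panel$dosage[, panel_pos, drop = FALSE], freq)
  m_c <- length(complete_ids)
  is_obs <- complete_ids %in% observed_ids
  chrom <- ref_panel$chrom[panel_pos]
  # contiguous runs of <= block_size SNPs within each chromosome
  runs <- rle(chrom)
  starts <- cumsum(c(1L, utils::head(runs$lengths, -1L)))
  blocks <- list()
  empty <- integer(0)
  for (r in seq_along(runs$lengths)) {
    off <- starts[r] - 1L
    len <- runs$lengths[r]
    nb <- ceiling(len / block_size)
    for (b in seq_len(nb)) {
      cols <- off + ((b - 1L) * block_size + 1L):min(b * block_size, len)
      obs <- cols[is_obs[cols]]
      bl <- list(chrom = runs$values[r], cols = cols, obs = obs)
      if (length(obs) == 0L) {
        bl$T <- matrix(0, 0L, length(cols))
        bl$ridge <- 0
        empty <- c(empty, length(blocks) + 1L)
      } else {
        Zi <- Zref[, obs, drop = FALSE]
        Zc <- Zref[, cols, drop = FALSE]
        A <- crossprod(Zi)
        r_use <- if (auto) 0 else ridge
        ok <- length(obs) < nrow(Zref) && rcond(A) > 1e-10
        if (!ok && auto) {
          r_use <- 1e-6 * mean(diag(A))
          warning("block ", length(blocks) + 1L, " (", length(obs),
                  " observed SNPs, ", nrow(Zref), " reference individuals) ",
                  "is rank-deficient; using ridge ",
                  format(r_use, digits = 3), call. = FALSE)
        }
        if (!ok && !auto && r_use == 0)
          stop("block with ", length(obs), " observed SNPs is singular ",
               "given ", nrow(Zref), " reference individuals; supply a ",
               "positive ridge (or ridge = \"auto\")")
        bl$T <- solve(A + diag(r_use, length(obs)), crossprod(Zi, Zc))
        bl$ridge <- r_use
      }
      blocks[[length(blocks) + 1L]] <- bl
    }
  }
  structure(
    list(blocks = blocks, complete_ids = complete_ids,
         observed_ids = complete_ids[is_obs],
         observed_idx = which(is_obs), empty_blocks = empty,
         block_size = as.integer(block_size)),
    class = "imputation_map"
  )
}

#' @export
print.imputation_map <- function(x, ...) {
  cat("imputation_map:", length(x$observed_idx), "observed of",
      length(x$complete_ids), "SNPs in", length(x$blocks), "block(s)",
      if (length(x$empty_blocks))
        paste0("(", length(x$empty_blocks), " with no observed SNP)"),
      "\n")
  invisible(x)
}

# Full block-diagonal T as a dense (n observed) x (n complete) matrix.
# Rows follow the complete-list order of the observed SNPs.
full_T <- function(map) {
  m_c <- length(map$complete_ids)
  m_o <- length(map$observed_idx)
  Tm <- matrix(0, m_o, m_c)
  obs_row <- match(seq_len(m_c), map$observed_idx)  # NA for missing SNPs
  for (bl in map$blocks) {
    if (length(bl$obs) == 0L) next
    Tm[obs_row[bl$obs], bl$cols] <- bl$T
  }
  Tm
}

#' Impute the right-hand side onto the complete SNP list
#'
#' `rhs_c = T' rhs_i` applied block by block; blocks containing no observed
#' SNP receive zeros (their information enters the meta system only through
#' cross-block entries of the imputed precision matrix).
#'
#' @param map an [build_imputation_map()] result.
#' @param rhs_obs right-hand side aligned with `map$observed_ids`.
#' @return Right-hand side on the complete SNP list.
#' @export
impute_rhs <- function(map, rhs_obs) {
  stopifnot(inherits(map, "imputation_map"))
  rhs_obs <- as.numeric(rhs_obs)
  if (length(rhs_obs) != length(map$observed_idx))
    stop("rhs_obs must align with the map's observed SNP list (",
         length(map$observed_idx), " entries)")
  rhs_c <- numeric(length(map$complete_ids))
  obs_row <- match(seq_along(map$complete_ids), map$observed_idx)
  for (bl in map$blocks) {
    if (length(bl$obs) == 0L) next
    rhs_c[bl$cols] <- drop(crossprod(bl$T, rhs_obs[obs_row[bl$obs]]))
  }
  rhs_c
}

#' Impute the precision matrix onto the complete SNP list
#'
#' `lhs_c = T' lhs_i T` with the block-diagonal T: within-block products and
#' cross-block products `T_a' lhs[obs_a, obs_b] T_b` are both formed, so the
#' cross-block LD carried by the observed precision matrix is retained.
#'
#' @param map an [build_imputation_map()] result.
#' @param lhs_obs symmetric precision matrix on the observed SNP list.
#' @param tol relative asymmetry tolerance for the input.
#' @return Symmetric precision matrix on the complete SNP list.
#' @export
impute_lhs <- function(map, lhs_obs, tol = 1e-8) {
  stopifnot(inherits(map, "imputation_map"))
  lhs_obs <- as.matrix(lhs_obs)
  m_o <- length(map$observed_idx)
  if (!all(dim(lhs_obs) == m_o))
    stop("lhs_obs must be ", m_o, " x ", m_o,
         " (the map's observed SNP list)")
  if (max(abs(lhs_obs - t(lhs_obs))) > tol * max(1, max(abs(lhs_obs))))
    stop("lhs_obs is asymmetric beyond tolerance")
  Tm <- full_T(map)
  out <- crossprod(Tm, lhs_obs %*% Tm)
  (out + t(out)) / 2
}

#' Map complete-list solutions back to a population's own SNP list
#'
#' After the meta system has been solved on the complete SNP list, a
#' population recovers effects for its original SNPs by `g_i = T g_c`.
#'
#' @param map an [build_imputation_map()] result.
#' @param g_complete effect vector on the complete SNP list.
#' @return Effect vector aligned with `map$observed_ids`.
#' @export
map_solutions <- function(map, g_complete) {
  stopifnot(inherits(map, "imputation_map"))
  g_complete <- as.numeric(g_complete)
  if (length(g_complete) != length(map$complete_ids))
    stop("g_complete must align with the complete SNP list")
  g_i <- numeric(length(map$observed_idx))
  obs_row <- match(seq_along(map$complete_ids), map$observed_idx)
  for (bl in map$blocks) {
    if (length(bl$obs) == 0L) next
    g_i[obs_row[bl$obs]] <- drop(bl$T %*% g_complete[bl$cols])
  }
  g_i
}
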