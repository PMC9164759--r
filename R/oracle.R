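#' Joint multi-population SNP-BLUP on raw pooled data
#'
#' Ground-truth solver the summary-statistic meta-analysis must duplicate:
#' it pools the raw genotypes and phenotypes of all populations and solves
#' the full multi-trait mixed model equations directly, treating the same
#' trait in different populations as distinct correlated traits. Each
#' population's phenotypes inform only its own trait; the populations are
#' linked solely through the SNP-effect prior, whose cross-population
#' covariance per SNP is `corr[i,k] * sqrt(dgv_var_i * dgv_var_k) *
#' sqrt(theta_i * theta_k)`. A general mean is fitted per population.
#'
#' The assembly here is deliberately independent of [assemble_meta()] (no
#' shared code paths), so agreement between the two solvers is evidence, not
#' tautology.
#'
#' @param panels list of [genotype_panel()] objects, one per population, on
#'   an identical SNP list; individuals are disjoint across populations.
#' @param records list of [phenotype_records()] row-aligned with each panel.
#' @param dgv_var,err_var per-population variances.
#' @param corr across-population correlation matrix of SNP effects.
#' @return List with per-population `mu`, `effects` (list of vectors) and
#'   `gebv` (list of per-individual DGV using the population's own effects).
#' @export
solve_joint_mblup <- function(panels, records, dgv_var, err_var, corr) {
  c_ <- length(panels)
  stopifnot(length(records) == c_, length(dgv_var) == c_,
            length(err_var) == c_, all(dim(as.matrix(corr)) == c_))
  ids <- panels[[1L]]$snp_ids
  for (p in panels)
    if (!identical(p$snp_ids, ids))
      stop("all populations must share one identically ordered SNP list")
  m <- length(ids)
  corr <- as.matrix(corr)

  # per-population ingredients, built from raw data
  Zs <- vector("list", c_); ws <- vector("list", c_); ys <- vector("list", c_)
  theta <- numeric(c_)
  for (i in seq_len(c_)) {
    d <- panels[[i]]$dosage
    p <- colMeans(d) / 2
    if (any(p <= 0 | p >= 1)) stop("monomorphic SNPs in population ", i)
    theta[i] <- 1 / sum(2 * p * (1 - p))
    if (length(records[[i]]$y) != nrow(d))
      stop("records must be row-aligned with each panel")
    Zs[[i]] <- sweep(d, 2L, 2 * p, `-`)
    ws[[i]] <- records[[i]]$n_daughters / err_var[i]
    ys[[i]] <- records[[i]]$y
  }

  # SNP-effect prior precision: inverse of the c x c per-SNP covariance,
  # expanded SNP-wise
  sdv <- sqrt(dgv_var * theta)
  Sigma <- corr * tcrossprod(sdv)
  Pinv <- solve(Sigma)

  # unknowns: c means followed by c blocks of m SNP effects
  ntot <- c_ + c_ * m
  A <- matrix(0, ntot, ntot)
  b <- numeric(ntot)
  gblk <- function(i) c_ + (i - 1L) * m + seq_len(m)
  for (i in seq_len(c_)) {
    Zi <- Zs[[i]]; wi <- ws[[i]]; yi <- ys[[i]]
    Zw <- Zi * wi
    bi <- gblk(i)
    A[i, i] <- sum(wi)
    A[i, bi] <- colSums(Zw)
    A[bi, i] <- colSums(Zw)
    A[bi, bi] <- crossprod(Zi, Zw) + diag(Pinv[i, i], m)
    b[i] <- sum(wi * yi)
    b[bi] <- crossprod(Zw, yi)
    for (k in seq_len(c_)) {
      if (k != i) A[bi, gblk(k)] <- diag(Pinv[i, k], m)
    }
  }
  sol <- solve(A, b)
  effects <- lapply(seq_len(c_), function(i) as.numeric(sol[gblk(i)]))
  gebv <- lapply(seq_len(c_), function(i) drop(Zs[[i]] %*% effects[[i]]))
  list(mu = as.numeric(sol[seq_len(c_)]), effects = effects, gebv = gebv)
}
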