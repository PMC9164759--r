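#' Center a dosage matrix by allele frequency
#'
#' Translates 0/1/2 dosages into the design matrix Z of the SNP-BLUP model:
#' genotypes AA, AB and BB take values `2 - 2p`, `1 - 2p` and `0 - 2p`, with
#' `p` the reference-allele frequency of each SNP. With a general mean in the
#' model, the BLUP of the SNP effects is invariant to the frequencies used
#' here; the frequencies do affect the intercept.
#'
#' @param panel a [genotype_panel()] or a bare dosage matrix.
#' @param freq per-SNP frequencies in (0, 1), aligned with the panel columns.
#' @return Numeric matrix Z with `Z[k, j] = dosage[k, j] - 2 * freq[j]`.
#' @export
center_genotypes <- function(panel, freq) {
  dosage <- if (inherits(panel, "genotype_panel")) panel$dosage else as.matrix(panel)
  freq <- as.numeric(freq)
  if (length(freq) != ncol(dosage))
    stop("freq must have one entry per SNP column")
  if (anyNA(freq) || any(freq <= 0) || any(freq >= 1))
    stop("invalid frequency: all entries must lie strictly in (0, 1)")
  sweep(dosage, 2L, 2 * freq, `-`)
}

#' Residual precision of daughter-average records
#'
#' The residual of a sire's daughter-average phenotype has variance
#' `err_var / n_ik`, so the inverse residual covariance R^-1 is diagonal with
#' entries `n_ik / err_var`. The diagonal is returned as a vector.
#'
#' @param records a [phenotype_records()].
#' @param err_var residual (error) variance of the population, > 0.
#' @return Numeric vector: the diagonal of R^-1.
#' @export
residual_precision <- function(records, err_var) {
  stopifnot(inherits(records, "phenotype_records"))
  if (!is.numeric(err_var) || length(err_var) != 1L || err_var <= 0)
    stop("err_var must be a single positive number")
  if (any(records$n_daughters <= 0))
    stop("n_daughters must be strictly positive")
  records$n_daughters / err_var
}

#' Per-SNP variance scaling factor
#'
#' Converts the variance of direct genomic values into the common per-SNP
#' effect variance: `theta = 1 / sum_j 2 p_j (1 - p_j)`, so that
#' `var(g_j) = dgv_var * theta` for every SNP j.
#'
#' @param freq per-SNP allele frequencies, all strictly in (0, 1).
#' @return The scalar theta (> 0).
#' @export
compute_theta <- function(freq) {
  freq <- as.numeric(freq)
  if (length(freq) == 0L) stop("empty SNP list: theta is undefined")
  if (anyNA(freq) || any(freq <= 0) || any(freq >= 1))
    stop("theta requires all frequencies strictly in (0, 1)")
  1 / sum(2 * freq * (1 - freq))
}

# Cholesky solve of a symmetric positive-definite system with a condition
# estimate in the error message on failure.
chol_solve <- function(A, b, context = "mixed model equations") {
  R <- tryCatch(chol(A), error = function(e) {
    rc <- tryCatch(rcond(A), error = function(e2) NA_real_)
    stop("singular or indefinite ", context,
         " (reciprocal condition estimate ", format(rc, digits = 3), ")",
         call. = FALSE)
  })
  backsolve(R, backsolve(R, b, transpose = TRUE))
}

#' Solve the single-population SNP-BLUP mixed model equations
#'
#' Fits `y = mu * 1 + Z g + e` with `var(e) = R` diagonal and the ridge prior
#' `var(g) = dgv_var * theta * I`. The full (1 + m) system, mean included, is
#' solved by a direct symmetric factorization.
#'
#' @param Z centered genotype matrix (individuals x SNPs).
#' @param rinv diagonal of R^-1 (see [residual_precision()]), or a diagonal
#'   matrix.
#' @param y phenotype vector.
#' @param dgv_var variance of direct genomic values, > 0.
#' @param theta per-SNP variance scaling (see [compute_theta()]).
#' @return List with `mu` (fitted general mean) and `effects` (BLUP of the
#'   SNP effects).
#' @export
solve_single_pop <- function(Z, rinv, y, dgv_var, theta) {
  Z <- as.matrix(Z)
  w <- if (is.matrix(rinv)) diag(rinv) else as.numeric(rinv)
  y <- as.numeric(y)
  if (length(w) != nrow(Z) || length(y) != nrow(Z))
    stop("Z, rinv and y must agree on the number of individuals")
  if (dgv_var <= 0 || theta <= 0) stop("dgv_var and theta must be positive")
  m <- ncol(Z)
  lambda <- 1 / (dgv_var * theta)
  Zw <- Z * w
  A <- matrix(0, m + 1L, m + 1L)
  A[1L, 1L] <- sum(w)
  zw <- colSums(Zw)
  A[1L, -1L] <- zw
  A[-1L, 1L] <- zw
  A[-1L, -1L] <- crossprod(Z, Zw) + diag(lambda, m)
  b <- c(sum(w * y), crossprod(Zw, y))
  sol <- chol_solve(A, b, "single-population mixed model equations")
  list(mu = sol[1L], effects = as.numeric(sol[-1L]))
}

#' Direct genomic values
#'
#' The DGV of an individual is the sum of its SNP effects weighted by the
#' centered genotype: `DGV_k = z_k . g`.
#'
#' @param Z centered genotype rows.
#' @param effects SNP effect vector.
#' @return Numeric vector of per-individual DGV.
#' @export
compute_dgv <- function(Z, effects) {
  Z <- as.matrix(Z)
  effects <- as.numeric(effects)
  if (ncol(Z) != length(effects))
    stop("dimension mismatch between genotype columns and effects")
  drop(Z %*% effects)
}

#' Precision matrix Z'R^-1 Z of a panel
#'
#' The raw (no mean absorption) weighted cross-product of the centered
#' genotypes. This is the trait-agnostic LD summary a data holder can compute
#' once on all genotyped individuals and rescale per trait with
#' [rescale_lhs()].
#'
#' @param panel a [genotype_panel()] or a centered matrix.
#' @param weights per-individual diagonal of R^-1.
#' @param freq frequencies used for centering; defaults to the panel's own
#'   [allele_freq()]. Ignored when `panel` is already a centered matrix.
#' @return Symmetric m x m matrix.
#' @export
precision_matrix <- function(panel, weights, freq = NULL) {
  if (inherits(panel, "genotype_panel")) {
    if (is.null(freq)) freq <- allele_freq(panel)
    Z <- center_genotypes(panel, freq)
  } else {
    Z <- as.matrix(panel)
  }
  weights <- as.numeric(weights)
  if (length(weights) != nrow(Z))
    stop("weights must have one entry per individual")
  crossprod(Z * sqrt(weights))
}

#' Build the summary statistics one population shares
#'
#' Computes everything a data holder submits to the meta-analysis: allele
#' frequencies, the precision matrix Z'R^-1 Z, the right-hand side Z'R^-1 y,
#' the solved SNP effects, and the variance components. The general mean is
#' absorbed: y is centered by its precision-weighted mean and the precision
#' matrix is projected accordingly, which is algebraically identical to
#' fitting the mean in the full system and absorbing it afterwards. The
#' shared statistics therefore solve to exactly the same SNP effects as
#' [solve_single_pop()].
#'
#' @param panel a [genotype_panel()] of the population's genotyped
#'   individuals.
#' @param records a [phenotype_records()]; phenotyped individuals must be a
#'   subset of the panel (matched by id, or row-aligned when ids are absent).
#' @param err_var residual variance (trait units squared), > 0.
#' @param dgv_var variance of direct genomic values (trait units squared), > 0.
#' @param population,trait labels carried into the summary metadata.
#' @return An object of class `pop_summary` with fields `snp_ids`,
#'   `allele_freq`, `lhs`, `rhs`, `effects`, `dgv_var`, `err_var`, `n_pheno`,
#'   `n_geno`, `population`, `trait`.
#' @export
summarize_population <- function(panel, records, err_var, dgv_var,
                                 population = "pop", trait = "trait") {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(records, "phenotype_records"))
  if (err_var <= 0 || dgv_var <= 0)
    stop("err_var and dgv_var must be positive")
  freq <- allele_freq(panel)
  mono <- freq <= 0 | freq >= 1
  if (any(mono))
    stop("monomorphic SNPs in panel (fixed reference or alternative allele): ",
         paste(utils::head(panel$snp_ids[mono], 5), collapse = ", "),
         "; filter them before summarization")
  idx <- match_records(panel, records)
  Z <- center_genotypes(panel$dosage[idx, , drop = FALSE], freq)
  w <- residual_precision(records, err_var)
  sw <- sum(w)
  Zw <- Z * w
  zw <- colSums(Zw)                       # Z' R^-1 1
  ybar <- sum(w * records$y) / sw         # precision-weighted mean
  ytil <- records$y - ybar
  lhs <- crossprod(Z, Zw) - tcrossprod(zw) / sw
  lhs <- (lhs + t(lhs)) / 2
  rhs <- as.numeric(crossprod(Z, w * ytil))
  theta <- compute_theta(freq)
  lambda <- 1 / (dgv_var * theta)
  effects <- as.numeric(
    chol_solve(lhs + diag(lambda, ncol(Z)), rhs, "population summary system"))
  structure(
    list(snp_ids = panel$snp_ids, allele_freq = freq, lhs = lhs, rhs = rhs,
         effects = effects, dgv_var = dgv_var, err_var = err_var,
         n_pheno = length(records$y), n_geno = nrow(panel$dosage),
         population = population, trait = trait),
    class = "pop_summary"
  )
}

#' @export
print.pop_summary <- function(x, ...) {
  cat("pop_summary '", x$population, "' (", x$trait, "): ",
      length(x$snp_ids), " SNPs, n_pheno = ", x$n_pheno,
      ", n_geno = ", x$n_geno, "\n", sep = "")
  cat("  dgv_var = ", format(x$dgv_var, digits = 5),
      ", err_var = ", format(x$err_var, digits = 5),
      if (is.null(x$rhs)) ", rhs absent" else "",
      if (is.null(x$effects)) ", effects absent" else "", "\n", sep = "")
  invisible(x)
}

#' Recover the right-hand side from shared SNP effects
#'
#' A data holder may share the solved effects instead of the right-hand side.
#' Because the effects satisfy `(lhs + I / (dgv_var * theta)) g = rhs`, the
#' right-hand side is recovered by multiplying back.
#'
#' @param summary a `pop_summary` carrying `effects`, `lhs`, `dgv_var` and
#'   `allele_freq`.
#' @return Numeric right-hand-side vector, aligned with `summary$snp_ids`.
#' @export
recover_rhs <- function(summary) {
  stopifnot(inherits(summary, "pop_summary"))
  if (is.null(summary$effects))
    stop("summary carries no effects; cannot recover the right-hand side")
  theta <- compute_theta(summary$allele_freq)
  lambda <- 1 / (summary$dgv_var * theta)
  as.numeric(summary$lhs %*% summary$effects + lambda * summary$effects)
}
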