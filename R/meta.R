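#' Across-population SNP-effect covariance specification
#'
#' The SNP effects of the c populations are modelled as correlated: the
#' cross-population covariance of any SNP's effects is
#' `corr[i, k] * sqrt(dgv_var[i] * dgv_var[k])` on the DGV scale, scaled to
#' the per-SNP scale by `sqrt(theta[i] * theta[k])`.
#'
#' @param dgv_var per-population DGV variances (> 0).
#' @param corr c x c correlation matrix of SNP effects / breeding values
#'   across populations: symmetric, unit diagonal, entries in \[-1, 1\].
#'   Off-diagonal magnitudes above 0.999 are rejected as numerically
#'   degenerate rather than silently regularized.
#' @param theta per-population scaling factors (see [compute_theta()]).
#' @return An object of class `covariance_spec`.
#' @export
covariance_spec <- function(dgv_var, corr, theta) {
  dgv_var <- as.numeric(dgv_var)
  theta <- as.numeric(theta)
  corr <- as.matrix(corr)
  c_ <- length(dgv_var)
  if (length(theta) != c_ || !all(dim(corr) == c_))
    stop("dgv_var, theta and corr must agree on the number of populations")
  if (any(dgv_var <= 0) || any(theta <= 0))
    stop("dgv_var and theta must be positive")
  if (max(abs(corr - t(corr))) > 1e-12) stop("corr must be symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-12) stop("corr must have unit diagonal")
  if (any(abs(corr) > 1)) stop("correlations must lie in [-1, 1]")
  off <- corr[upper.tri(corr)]
  if (length(off) && any(abs(off) > 0.999))
    stop("correlation magnitude above 0.999: the covariance is numerically ",
         "singular; perturb the correlation instead of relying on silent ",
         "regularization")
  structure(list(dgv_var = dgv_var, corr = corr, theta = theta),
            class = "covariance_spec")
}

#' Per-SNP cross-population covariance matrix
#'
#' Builds the c x c matrix Sigma with
#' `Sigma[i, k] = corr[i, k] * sqrt(dgv_var[i] * dgv_var[k]) *
#' sqrt(theta[i] * theta[k])`. The full SNP-effect covariance across all
#' populations is `Sigma` expanded SNP-wise (each block a scalar multiple of
#' the identity), so Sigma is all that is ever materialized.
#'
#' @param spec a [covariance_spec()].
#' @return Symmetric c x c matrix.
#' @export
build_sigma <- function(spec) {
  stopifnot(inherits(spec, "covariance_spec"))
  ev <- eigen(spec$corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("corr is not positive semidefinite (smallest eigenvalue ",
         format(min(ev), digits = 4), ")")
  s <- sqrt(spec$dgv_var * spec$theta)
  Sigma <- spec$corr * tcrossprod(s)
  (Sigma + t(Sigma)) / 2
}

#' Scalar coefficients of the inverse SNP-effect covariance
#'
#' Because the cross-population covariance of the SNP effects is a Kronecker
#' product `Sigma (x) I`, its inverse is `Sigma^-1 (x) I`: block (i, k) of
#' the inverse equals `Sigma^-1[i, k] * I`. Only the c x c inverse is
#' computed; the SNP-expanded matrix is never formed.
#'
#' @param Sigma c x c covariance from [build_sigma()].
#' @return c x c matrix of block coefficients.
#' @export
invert_g <- function(Sigma) {
  Sigma <- as.matrix(Sigma)
  rc <- rcond(Sigma)
  if (!is.finite(rc) || rc < 1e-12)
    stop("cross-population covariance is singular (reciprocal condition ",
         format(rc, digits = 3), "); a correlation of magnitude 1 between ",
         "populations cannot be inverted - perturb the correlation")
  Sinv <- solve(Sigma)
  (Sinv + t(Sinv)) / 2
}

#' Assemble the meta-analysis mixed model equations
#'
#' Stacks the shared per-population summaries into the block system whose
#' solution is the meta-analysis SNP effects: diagonal block i is
#' `lhs_i + Sigma^-1[i, i] * I`, off-diagonal block (i, k) is
#' `Sigma^-1[i, k] * I`, and the right-hand side is the stacked per-population
#' right-hand sides (recovered from effects via [recover_rhs()] when absent).
#' Blocks are population-major: all SNPs of population 1 first, then 2, ...
#'
#' @param summaries list of `pop_summary` objects sharing one identically
#'   ordered SNP list.
#' @param spec a [covariance_spec()]; `theta` should normally be computed
#'   from each summary's allele frequencies (see [compute_theta()]).
#' @return An object of class `meta_system` with `block_lhs`, `block_rhs`,
#'   `m`, `n_pops`, `populations`, `snp_ids`.
#' @export
assemble_meta <- function(summaries, spec) {
  stopifnot(is.list(summaries), length(summaries) >= 1L,
            inherits(spec, "covariance_spec"))
  if (!all(vapply(summaries, inherits, TRUE, "pop_summary")))
    stop("summaries must be a list of pop_summary objects")
  c_ <- length(summaries)
  if (length(spec$dgv_var) != c_)
    stop("covariance_spec covers ", length(spec$dgv_var),
         " populations but ", c_, " summaries were given")
  ids <- summaries[[1L]]$snp_ids
  for (s in summaries) {
    if (!identical(s$snp_ids, ids))
      stop("summaries do not share an identical, identically ordered SNP ",
           "list; harmonize them first with the summary-statistic ",
           "imputation functions (build_imputation_map / impute_rhs / ",
           "impute_lhs)")
  }
  m <- length(ids)
  Sinv <- invert_g(build_sigma(spec))
  lhs <- matrix(0, c_ * m, c_ * m)
  rhs <- numeric(c_ * m)
  for (i in seq_len(c_)) {
    s <- summaries[[i]]
    ri <- if (!is.null(s$rhs)) s$rhs else recover_rhs(s)
    if (length(ri) != m) stop("right-hand side length mismatch")
    Li <- s$lhs
    asym <- max(abs(Li - t(Li)))
    if (asym > 1e-8 * max(1, max(abs(Li))))
      warning("precision matrix of population ", i,
              " is asymmetric beyond tolerance; symmetrizing (A + A')/2")
    Li <- (Li + t(Li)) / 2
    bi <- (i - 1L) * m + seq_len(m)
    lhs[bi, bi] <- Li + diag(Sinv[i, i], m)
    rhs[bi] <- ri
    for (k in seq_len(c_)) {
      if (k == i) next
      bk <- (k - 1L) * m + seq_len(m)
      lhs[bi, bk] <- diag(Sinv[i, k], m)
    }
  }
  structure(
    list(block_lhs = lhs, block_rhs = rhs, m = m, n_pops = c_,
         populations = vapply(summaries, function(s) s$population, ""),
         snp_ids = ids),
    class = "meta_system"
  )
}

#' @export
print.meta_system <- function(x, ...) {
  cat("meta_system:", x$n_pops, "populations x", x$m, "SNPs (",
      nrow(x$block_lhs), "equations )\n")
  invisible(x)
}

# Conjugate gradients with the block-diagonal part as preconditioner.
# Kept for systems too large for a dense factorization; tolerance is on the
# relative residual.
solve_meta_cg <- function(system, tol = 1e-8, maxit = 2000L) {
  A <- system$block_lhs
  b <- system$block_rhs
  m <- system$m
  c_ <- system$n_pops
  blocks <- lapply(seq_len(c_), function(i) {
    bi <- (i - 1L) * m + seq_len(m)
    chol(A[bi, bi])
  })
  precond <- function(r) {
    z <- numeric(length(r))
    for (i in seq_len(c_)) {
      bi <- (i - 1L) * m + seq_len(m)
      z[bi] <- backsolve(blocks[[i]],
                         backsolve(blocks[[i]], r[bi], transpose = TRUE))
    }
    z
  }
  x <- numeric(length(b))
  r <- b
  z <- precond(r)
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(x)
  for (it in seq_len(maxit)) {
    Ap <- drop(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) <= tol * bnorm) break
    z <- precond(r)
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  x
}

#' Solve the meta-analysis system
#'
#' @param system a `meta_system` from [assemble_meta()].
#' @param method `"direct"` (Cholesky; default) or `"cg"` (preconditioned
#'   conjugate gradients, for systems too large to factorize densely).
#' @param tol relative-residual tolerance for the CG path.
#' @return Named list of per-population SNP-effect vectors, in the order the
#'   summaries were supplied.
#' @export
solve_meta <- function(system, method = c("direct", "cg"), tol = 1e-8) {
  stopifnot(inherits(system, "meta_system"))
  method <- match.arg(method)
  x <- if (method == "direct") {
    as.numeric(chol_solve(system$block_lhs, system$block_rhs,
                          "meta-analysis mixed model equations"))
  } else {
    solve_meta_cg(system, tol = tol)
  }
  m <- system$m
  out <- lapply(seq_len(system$n_pops),
                function(i) x[(i - 1L) * m + seq_len(m)])
  names(out) <- system$populations
  out
}

#' Predict DGV and evaluate accuracy against phenotypes
#'
#' @param Z centered genotype rows of the validation individuals.
#' @param effects SNP effect vector.
#' @param phenotypes validation phenotypes (same order as rows of `Z`).
#' @return List with `dgv`, `correlation` (Pearson r between DGV and
#'   phenotype) and `slope` (regression of phenotype on DGV).
#' @export
predict_and_evaluate <- function(Z, effects, phenotypes) {
  dgv <- compute_dgv(Z, effects)
  phenotypes <- as.numeric(phenotypes)
  if (length(phenotypes) != length(dgv))
    stop("phenotypes must match the number of genotype rows")
  v <- stats::var(dgv)
  if (!is.finite(v) || v == 0)
    stop("DGV has zero variance; correlation with phenotypes is undefined")
  list(dgv = dgv,
       correlation = stats::cor(dgv, phenotypes),
       slope = stats::cov(dgv, phenotypes) / v)
}
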