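#' Scenario for the synthetic multi-population sire-model dataset
#'
#' Defines the study conditions the simulator emulates: two (or more) cattle
#' breeds genotyped on a shared SNP panel with block LD, per-SNP effects
#' correlated across breeds, and sire-model phenotypes (daughter averages
#' with effective daughter counts). Defaults give two populations of 800 and
#' 300 sires on 2,000 SNPs in 200-SNP LD blocks with cross-population effect
#' correlation 0.5 - a reduced-scale analogue of a two-breed 50k-chip
#' evaluation.
#'
#' @param n_pops number of populations.
#' @param n_indiv per-population individual counts.
#' @param n_snps number of SNPs simulated (before the joint MAF filter).
#' @param n_chrom chromosomes; SNPs are split evenly among them.
#' @param block_len LD block length in SNPs.
#' @param within_block_ld target magnitude of the pairwise dosage correlation
#'   within a block, in \[0, 1).
#' @param maf_min minor-allele-frequency floor, in (0, 0.5); SNPs below it in
#'   any population are dropped from all populations.
#' @param effect_corr c x c correlation matrix of per-SNP effects across
#'   populations (scalar shorthand: common off-diagonal value).
#' @param dgv_var,err_var per-population variances (recycled if scalar).
#' @param mu per-population general mean of the phenotypes.
#' @param daughter_count_range integer range the effective daughter counts
#'   are drawn from, uniformly.
#' @param seed RNG seed; every simulated object is deterministic given it.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_pops = 2L, n_indiv = c(800L, 300L),
                         n_snps = 2000L, n_chrom = 2L, block_len = 200L,
                         within_block_ld = 0.8, maf_min = 0.05,
                         effect_corr = 0.5, dgv_var = 1, err_var = 10,
                         mu = 1, daughter_count_range = c(20L, 100L),
                         seed = 20260923L) {
  n_pops <- as.integer(n_pops)
  n_indiv <- rep_len(as.integer(n_indiv), n_pops)
  if (any(n_indiv < 2L)) stop("each population needs at least 2 individuals")
  if (within_block_ld < 0 || within_block_ld >= 1)
    stop("within_block_ld must lie in [0, 1): a target of 1 or more is ",
         "infeasible for distinct SNPs")
  if (maf_min <= 0 || maf_min >= 0.5) stop("maf_min must lie in (0, 0.5)")
  if (length(effect_corr) == 1L) {
    ec <- matrix(effect_corr, n_pops, n_pops); diag(ec) <- 1
    effect_corr <- ec
  }
  effect_corr <- as.matrix(effect_corr)
  if (!all(dim(effect_corr) == n_pops) ||
      max(abs(effect_corr - t(effect_corr))) > 1e-12 ||
      max(abs(diag(effect_corr) - 1)) > 1e-12 ||
      any(abs(effect_corr) > 1))
    stop("effect_corr must be a valid correlation matrix")
  ev <- eigen(effect_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("effect_corr is not positive semidefinite")
  daughter_count_range <- as.integer(daughter_count_range)
  if (length(daughter_count_range) != 2L ||
      daughter_count_range[1L] < 1L ||
      daughter_count_range[2L] < daughter_count_range[1L])
    stop("daughter_count_range must be an increasing positive integer pair")
  structure(
    list(n_pops = n_pops, n_indiv = n_indiv, n_snps = as.integer(n_snps),
         n_chrom = as.integer(n_chrom), block_len = as.integer(block_len),
         within_block_ld = within_block_ld, maf_min = maf_min,
         effect_corr = effect_corr,
         dgv_var = rep_len(as.numeric(dgv_var), n_pops),
         err_var = rep_len(as.numeric(err_var), n_pops),
         mu = rep_len(as.numeric(mu), n_pops),
         daughter_count_range = daughter_count_range,
         seed = as.integer(seed)),
    class = "sim_scenario"
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("sim_scenario:", x$n_pops, "populations (",
      paste(x$n_indiv, collapse = "+"), "individuals ),", x$n_snps,
      "SNPs on", x$n_chrom, "chromosome(s), LD target",
      x$within_block_ld, "\n")
  invisible(x)
}

#' Simulate block-LD genotype panels for all populations
#'
#' Haplotypes are generated per LD block by copy-with-mutation from a small
#' founder pool shared across populations: each block carries a pair of
#' complementary founder haplotypes and a founder-choice weight; an
#' individual haplotype copies one founder (chosen with that weight) and
#' flips each allele independently with probability
#' `eps = (1 - sqrt(within_block_ld)) / 2`, so the magnitude of the dosage
#' correlation between any two SNPs of a block is approximately
#' `(1 - 2 eps)^2 = within_block_ld`; SNPs in different blocks are
#' independent. Dosage is the sum of two haplotypes. SNPs whose minor allele
#' frequency falls below `maf_min` in any population are dropped from all
#' populations, so the returned panels share one SNP list by construction.
#'
#' @param scenario a [sim_scenario()].
#' @return Named list of [genotype_panel()] objects (`pop1`, `pop2`, ...).
#' @export
simulate_genotypes <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  m <- scenario$n_snps
  per_chr <- diff(round(seq(0, m, length.out = scenario$n_chrom + 1L)))
  chrom <- rep(seq_len(scenario$n_chrom), times = per_chr)
  snp_ids <- sprintf("chr%d_snp%04d", chrom,
                     unlist(lapply(per_chr, seq_len)))
  eps <- (1 - sqrt(scenario$within_block_ld)) / 2
  # block boundaries: runs of block_len within each chromosome
  block_id <- integer(m)
  nb <- 0L
  for (ch in seq_len(scenario$n_chrom)) {
    pos <- which(chrom == ch)
    k <- ceiling(length(pos) / scenario$block_len)
    block_id[pos] <- nb + rep(seq_len(k), each = scenario$block_len,
                              length.out = length(pos))
    nb <- nb + k
  }
  founders <- lapply(seq_len(nb), function(b) {
    len <- sum(block_id == b)
    list(f = stats::rbinom(len, 1L, 0.5), w = stats::runif(1, 0.25, 0.75))
  })
  sim_pop <- function(n) {
    dos <- matrix(0, n, m)
    for (b in seq_len(nb)) {
      cols <- which(block_id == b)
      len <- length(cols)
      f <- founders[[b]]$f
      for (hap in 1:2) {
        pick <- stats::rbinom(n, 1L, founders[[b]]$w)
        base <- outer(pick, f, function(x, fj) x * fj + (1 - x) * (1 - fj))
        flip <- matrix(stats::rbinom(n * len, 1L, eps), n, len)
        dos[, cols] <- dos[, cols] + abs(base - flip)
      }
    }
    dos
  }
  panels <- lapply(scenario$n_indiv, sim_pop)
  keep <- rep(TRUE, m)
  for (d in panels) {
    p <- colMeans(d) / 2
    keep <- keep & pmin(p, 1 - p) >= scenario$maf_min
  }
  if (!any(keep)) stop("MAF filter removed every SNP; lower maf_min")
  out <- lapply(seq_along(panels), function(i) {
    genotype_panel(panels[[i]][, keep, drop = FALSE],
                   snp_ids = snp_ids[keep],
                   chrom = as.character(chrom[keep]),
                   indiv_ids = sprintf("pop%d_id%04d", i,
                                       seq_len(scenario$n_indiv[i])))
  })
  names(out) <- paste0("pop", seq_along(out))
  out
}

#' Simulate correlated SNP effects and sire-model phenotypes
#'
#' Per SNP, the vector of effects across populations is drawn from a
#' zero-mean multivariate normal with covariance
#' `effect_corr[i,k] * sqrt(dgv_var_i * dgv_var_k) * sqrt(theta_i * theta_k)`
#' where each `theta_i` comes from the realized allele frequencies, so the
#' realized DGV variance matches `dgv_var` in expectation. Phenotypes follow
#' the sire model directly: `y_k = mu + DGV_k + e_k` with
#' `var(e_k) = err_var / n_k` and effective daughter counts `n_k` uniform on
#' `daughter_count_range`.
#'
#' @param scenario a [sim_scenario()].
#' @param panels panels from [simulate_genotypes()].
#' @return Named list per population: `effects` (true per-SNP effects),
#'   `records` ([phenotype_records()]), `dgv` (true DGV).
#' @export
simulate_effects_and_phenotypes <- function(scenario, panels) {
  stopifnot(inherits(scenario, "sim_scenario"))
  c_ <- length(panels)
  set.seed(scenario$seed + 1L)
  m <- length(panels[[1L]]$snp_ids)
  theta <- vapply(panels, function(p) compute_theta(allele_freq(p)), 0)
  sdv <- sqrt(scenario$dgv_var * theta)
  Sigma <- scenario$effect_corr * tcrossprod(sdv)
  L <- chol_psd(Sigma)
  E <- matrix(stats::rnorm(m * c_), m, c_) %*% L   # m x c, row = one SNP
  out <- lapply(seq_len(c_), function(i) {
    panel <- panels[[i]]
    Z <- center_genotypes(panel, allele_freq(panel))
    g <- E[, i]
    dgv <- drop(Z %*% g)
    n <- nrow(Z)
    rng <- scenario$daughter_count_range
    nk <- rng[1L] + sample.int(rng[2L] - rng[1L] + 1L, n, replace = TRUE) - 1L
    e <- stats::rnorm(n, 0, sqrt(scenario$err_var[i] / nk))
    y <- scenario$mu[i] + dgv + e
    list(effects = g,
         records = phenotype_records(y, nk, indiv_ids = panel$indiv_ids),
         dgv = dgv)
  })
  names(out) <- names(panels)
  out
}

# Upper-triangular Cholesky factor tolerant of semidefinite matrices.
chol_psd <- function(S) {
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(out)) return(out)
  ed <- eigen(S, symmetric = TRUE)
  ev <- pmax(ed$values, 0)
  t(ed$vectors %*% (sqrt(ev) * t(ed$vectors)))
}

#' Simulate a complete multi-population dataset
#'
#' Convenience wrapper: genotypes, effects and phenotypes in one call.
#'
#' @param scenario a [sim_scenario()].
#' @return List with `scenario`, `panels` and `truth` (output of
#'   [simulate_effects_and_phenotypes()]).
#' @export
simulate_dataset <- function(scenario = sim_scenario()) {
  panels <- simulate_genotypes(scenario)
  truth <- simulate_effects_and_phenotypes(scenario, panels)
  list(scenario = scenario, panels = panels, truth = truth)
}
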