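#' Phenotype-masking experiment for precision-matrix rescaling
#'
#' Per replicate, a random fraction of individuals lose their phenotypes; the
#' precision matrix rebuilt from the phenotyped subset is compared with the
#' full-population matrix rescaled by `n_pheno / n_geno` (see
#' [rescale_lhs()]). Accuracy is the Pearson correlation of the lower
#' triangles (diagonal included) and the regression slope of subset entries
#' on rescaled entries.
#'
#' @param panel a [genotype_panel()].
#' @param n_daughters per-individual effective daughter counts (weights).
#' @param err_var residual variance.
#' @param mask_fraction fraction of individuals whose phenotypes are masked,
#'   in (0, 1).
#' @param n_replicates number of random masks.
#' @param seed RNG seed; the run is reproducible bit for bit.
#' @return List with `replicates` (data.frame: replicate, correlation,
#'   slope) and `summary` (means with normal-theory 95 percent intervals).
#' @export
rescaling_experiment <- function(panel, n_daughters, err_var,
                                 mask_fraction = 0.5, n_replicates = 100L,
                                 seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (mask_fraction <= 0 || mask_fraction >= 1)
    stop("mask_fraction must lie in (0, 1)")
  n <- nrow(panel$dosage)
  w <- as.numeric(n_daughters) / err_var
  if (length(w) != n) stop("n_daughters must cover every panel individual")
  freq <- allele_freq(panel)
  Z <- center_genotypes(panel, freq)
  full <- precision_matrix(Z, w)
  lt <- lower.tri(full, diag = TRUE)
  set.seed(seed)
  res <- vapply(seq_len(n_replicates), function(r) {
    keep <- sort(sample.int(n, n - floor(mask_fraction * n)))
    sub <- precision_matrix(Z[keep, , drop = FALSE], w[keep])
    scaled <- rescale_lhs(full, length(keep), n)
    x <- scaled[lt]; y <- sub[lt]
    c(stats::cor(x, y), stats::cov(x, y) / stats::var(x))
  }, numeric(2))
  reps <- data.frame(replicate = seq_len(n_replicates),
                     correlation = res[1L, ], slope = res[2L, ])
  list(replicates = reps, summary = summarize_replicates(reps[-1L]))
}

# Mean and normal-theory 95% interval per column of a replicate table.
summarize_replicates <- function(df) {
  do.call(rbind, lapply(names(df), function(nm) {
    x <- df[[nm]]
    se <- stats::sd(x) / sqrt(length(x))
    data.frame(metric = nm, mean = mean(x),
               lower95 = mean(x) - 1.96 * se,
               upper95 = mean(x) + 1.96 * se)
  }))
}

#' SNP-masking experiment for summary-statistic imputation
#'
#' Reproduces the three-way split protocol: per replicate the population is
#' divided into a reference third (builds the block-wise T), a training third
#' (its summary statistics are masked and imputed) and a validation third
#' (prediction accuracy). A random `mask_fraction` of SNPs is removed from
#' the training summary; the right-hand side and precision matrix are imputed
#' back onto the complete list, the single-population system is re-solved,
#' and imputed quantities are correlated with their full-data counterparts
#' over the masked entries only (masked rows/columns for the precision
#' matrix).
#'
#' @param panel a [genotype_panel()] of the whole population.
#' @param records [phenotype_records()] covering the panel.
#' @param err_var,dgv_var variance components of the population.
#' @param mask_fraction fraction of SNPs masked, in (0, 1).
#' @param n_replicates number of replicates.
#' @param seed RNG seed.
#' @param block_size,ridge passed to [build_imputation_map()].
#' @return List with `replicates` (data.frame: replicate, corr_lhs, corr_rhs,
#'   corr_g, acc_imputed, acc_full, n_empty_blocks) and `summary` (means with
#'   95 percent intervals).
#' @export
mask_and_evaluate <- function(panel, records, err_var, dgv_var,
                              mask_fraction, n_replicates = 20L, seed = 1L,
                              block_size = 200L, ridge = "auto") {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(records, "phenotype_records"))
  if (mask_fraction <= 0 || mask_fraction >= 1)
    stop("mask_fraction must lie in (0, 1)")
  idx <- match_records(panel, records)
  if (length(idx) != nrow(panel$dosage))
    stop("the masking experiment needs phenotypes for every panel individual")
  n <- nrow(panel$dosage)
  m <- length(panel$snp_ids)
  n_mask <- floor(mask_fraction * m)
  if (n_mask < 1L || n_mask >= m) stop("mask_fraction leaves no SNPs to test")
  set.seed(seed)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    thirds <- split(sample.int(n), rep_len(1:3, n))
    ref <- subset_panel(panel, thirds[[1L]])
    train_idx <- sort(thirds[[2L]])
    test_idx <- sort(thirds[[3L]])
    train_panel <- subset_panel(panel, train_idx)
    train_rec <- phenotype_records(records$y[idx][train_idx],
                                   records$n_daughters[idx][train_idx])
    full_sum <- summarize_population(train_panel, train_rec, err_var, dgv_var)
    masked <- sort(sample.int(m, n_mask))
    obs_ids <- panel$snp_ids[-masked]
    # summary the population would actually share: observed SNPs only
    obs_pos <- match(obs_ids, panel$snp_ids)
    lhs_obs <- full_sum$lhs[obs_pos, obs_pos, drop = FALSE]
    rhs_obs <- full_sum$rhs[obs_pos]
    map <- build_imputation_map(ref, obs_ids, panel$snp_ids,
                                block_size = block_size, ridge = ridge)
    rhs_imp <- impute_rhs(map, rhs_obs)
    lhs_imp <- impute_lhs(map, lhs_obs)
    theta <- compute_theta(full_sum$allele_freq)
    lambda <- 1 / (dgv_var * theta)
    g_imp <- as.numeric(chol_solve(lhs_imp + diag(lambda, m), rhs_imp,
                                   "imputed summary system"))
    g_full <- full_sum$effects
    mask_rc <- outer(seq_len(m) %in% masked, seq_len(m) %in% masked, `|`) &
      lower.tri(diag(m), diag = TRUE)
    Ztest <- center_genotypes(panel$dosage[test_idx, , drop = FALSE],
                              full_sum$allele_freq)
    y_test <- records$y[idx][test_idx]
    rows[[r]] <- data.frame(
      replicate = r,
      corr_lhs = stats::cor(lhs_imp[mask_rc], full_sum$lhs[mask_rc]),
      corr_rhs = stats::cor(rhs_imp[masked], full_sum$rhs[masked]),
      corr_g = stats::cor(g_imp[masked], g_full[masked]),
      acc_imputed = stats::cor(compute_dgv(Ztest, g_imp), y_test),
      acc_full = stats::cor(compute_dgv(Ztest, g_full), y_test),
      n_empty_blocks = length(map$empty_blocks))
  }
  reps <- do.call(rbind, rows)
  list(replicates = reps, summary = summarize_replicates(reps[-1L]))
}

#' Subset a genotype panel by individuals
#'
#' @param panel a [genotype_panel()].
#' @param rows integer row indices or individual ids to keep.
#' @return A new `genotype_panel`.
#' @export
subset_panel <- function(panel, rows) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.character(rows)) rows <- match(rows, panel$indiv_ids)
  genotype_panel(panel$dosage[rows, , drop = FALSE],
                 snp_ids = panel$snp_ids, chrom = panel$chrom,
                 indiv_ids = panel$indiv_ids[rows])
}
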