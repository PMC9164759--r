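test_that("cross-population covariance scales correlations by sd and theta", {
  spec <- covariance_spec(c(1, 1), diag(2), c(1, 1))
  expect_equal(build_sigma(spec), diag(2))
  # two breeds with milk-yield-like correlation 0.54
  spec2 <- covariance_spec(c(2, 3), matrix(c(1, 0.54, 0.54, 1), 2),
                           c(0.01, 0.02))
  S <- build_sigma(spec2)
  expect_equal(S[1, 2], 0.54 * sqrt(2 * 3) * sqrt(0.01 * 0.02))
  expect_equal(diag(S), c(2 * 0.01, 3 * 0.02))
  # arithmetic example
  spec3 <- covariance_spec(c(4, 1), matrix(c(1, 0.5, 0.5, 1), 2), c(2, 0.5))
  expect_equal(build_sigma(spec3)[1, 2], 0.5 * 2 * 1 * sqrt(2 * 0.5))
  # invalid correlation matrices are rejected
  bad <- matrix(c(1, 0.9, 0.2, 1), 2)
  expect_error(covariance_spec(c(1, 1), bad, c(1, 1)), "symmetric")
  expect_error(covariance_spec(c(1, 1), matrix(c(1, 0.9995, 0.9995, 1), 2),
                               c(1, 1)), "0.999")
})

test_that("inverse covariance blocks come from the c x c inverse", {
  expect_equal(invert_g(diag(2)), diag(2))
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(invert_g(S), matrix(c(4, -2, -2, 4) / 3, 2))
  set.seed(4)
  A <- crossprod(matrix(rnorm(9), 3))
  expect_equal(A %*% invert_g(A), diag(3), tolerance = 1e-10)
  expect_error(invert_g(matrix(c(1, 1, 1, 1), 2)), "singular")
})

test_that("assembled meta system matches brute-force construction", {
  ds <- small_dataset(n_indiv = c(60L, 50L), n_snps = 80L)
  summaries <- summaries_of(ds)
  spec <- spec_of(ds, summaries)
  sys <- assemble_meta(summaries, spec)
  m <- sys$m
  Sinv <- invert_g(build_sigma(spec))
  # brute force from raw data, without the package assembly path
  ref <- matrix(0, 2 * m, 2 * m)
  rhs <- numeric(2 * m)
  for (i in 1:2) {
    p <- ds$panels[[i]]; rec <- ds$truth[[i]]$records
    w <- rec$n_daughters / ds$scenario$err_var[i]
    Z <- sweep(p$dosage, 2, 2 * colMeans(p$dosage) / 2)
    L <- crossprod(Z * sqrt(w)) - tcrossprod(colSums(Z * w)) / sum(w)
    yt <- rec$y - sum(w * rec$y) / sum(w)
    bi <- (i - 1) * m + 1:m
    ref[bi, bi] <- L + diag(Sinv[i, i], m)
    ref[bi, setdiff(1:(2 * m), bi)] <- diag(Sinv[i, 3 - i], m)
    rhs[bi] <- crossprod(Z, w * yt)
  }
  expect_equal(sys$block_lhs, ref, tolerance = 1e-9)
  expect_equal(sys$block_rhs, rhs, tolerance = 1e-9)
  expect_equal(sys$block_lhs, t(sys$block_lhs))
})

test_that("meta solve reproduces the raw-data joint BLUP oracle", {
  ds <- small_dataset()
  summaries <- summaries_of(ds)
  sol <- solve_meta(assemble_meta(summaries, spec_of(ds, summaries)))
  orc <- solve_joint_mblup(ds$panels, lapply(ds$truth, `[[`, "records"),
                           ds$scenario$dgv_var, ds$scenario$err_var,
                           ds$scenario$effect_corr)
  scale <- max(abs(unlist(orc$effects)))
  expect_lt(max(abs(unlist(sol) - unlist(orc$effects))), 1e-6 * scale)
  gebv_meta <- unlist(lapply(1:2, function(i)
    compute_dgv(center_genotypes(ds$panels[[i]],
                                 allele_freq(ds$panels[[i]])), sol[[i]])))
  expect_gte(cor(gebv_meta, unlist(orc$gebv)), 0.9999)
})

test_that("zero correlation reduces the meta solve to per-population BLUP", {
  ds <- small_dataset(corr = 0)
  summaries <- summaries_of(ds)
  sol <- solve_meta(assemble_meta(summaries, spec_of(ds, summaries)))
  for (i in 1:2) {
    st <- summaries[[i]]$effects
    expect_lt(max(abs(sol[[i]] - st)) / max(abs(st)), 1e-8)
  }
})

test_that("a single population reduces to the single-population system", {
  ds <- one_pop_dataset(n = 120L, m = 100L)
  s <- summarize_population(ds$panels[[1]], ds$truth[[1]]$records, 10, 1)
  spec <- covariance_spec(1, matrix(1), compute_theta(s$allele_freq))
  sol <- solve_meta(assemble_meta(list(s), spec))
  expect_equal(sol[[1]], s$effects, tolerance = 1e-10)
})

test_that("zero right-hand sides give zero solutions", {
  ds <- small_dataset(n_indiv = c(40L, 30L), n_snps = 40L)
  summaries <- summaries_of(ds)
  summaries <- lapply(summaries, function(s) {
    s$rhs <- rep(0, length(s$rhs)); s$effects <- NULL; s
  })
  sol <- solve_meta(assemble_meta(summaries, spec_of(ds, summaries)))
  expect_equal(max(abs(unlist(sol))), 0)
})

test_that("effects-only summaries solve identically via rhs recovery", {
  ds <- small_dataset(n_indiv = c(60L, 40L), n_snps = 60L)
  summaries <- summaries_of(ds)
  spec <- spec_of(ds, summaries)
  ref <- solve_meta(assemble_meta(summaries, spec))
  no_rhs <- lapply(summaries, function(s) { s$rhs <- NULL; s })
  sol <- solve_meta(assemble_meta(no_rhs, spec))
  expect_equal(sol, ref, tolerance = 1e-8)
})

test_that("mismatched SNP lists point the user to imputation", {
  ds <- small_dataset(n_indiv = c(40L, 30L), n_snps = 40L)
  summaries <- summaries_of(ds)
  s2 <- summaries[[2]]
  keep <- seq_along(s2$snp_ids)[-1]
  s2$snp_ids <- s2$snp_ids[keep]; s2$allele_freq <- s2$allele_freq[keep]
  s2$lhs <- s2$lhs[keep, keep]; s2$rhs <- s2$rhs[keep]
  s2$effects <- s2$effects[keep]
  expect_error(assemble_meta(list(summaries[[1]], s2), spec_of(ds, summaries)),
               "imputation")
})

test_that("solutions are invariant to the order of populations", {
  ds <- small_dataset(n_indiv = c(60L, 40L), n_snps = 60L)
  summaries <- summaries_of(ds)
  spec <- spec_of(ds, summaries)
  sol12 <- solve_meta(assemble_meta(summaries, spec))
  theta <- vapply(summaries, function(s) compute_theta(s$allele_freq), 0)
  spec21 <- covariance_spec(rev(ds$scenario$dgv_var),
                            ds$scenario$effect_corr[2:1, 2:1], rev(theta))
  sol21 <- solve_meta(assemble_meta(summaries[2:1], spec21))
  expect_equal(sol12$pop1, sol21$pop1, tolerance = 1e-9)
  expect_equal(sol12$pop2, sol21$pop2, tolerance = 1e-9)
})

test_that("positive correlation pulls each population toward the other", {
  ds <- small_dataset(n_indiv = c(60L, 40L), n_snps = 60L, corr = 0.8)
  summaries <- summaries_of(ds)
  sol_cor <- solve_meta(assemble_meta(summaries, spec_of(ds, summaries)))
  st <- lapply(summaries, `[[`, "effects")  # corr = 0 solutions
  for (i in 1:2) {
    other <- st[[3 - i]]
    expect_lt(sqrt(sum((sol_cor[[i]] - other)^2)),
              sqrt(sum((st[[i]] - other)^2)))
  }
})

test_that("conjugate-gradient path agrees with the direct factorization", {
  ds <- small_dataset(n_indiv = c(60L, 40L), n_snps = 60L)
  summaries <- summaries_of(ds)
  sys <- assemble_meta(summaries, spec_of(ds, summaries))
  direct <- solve_meta(sys, method = "direct")
  cg <- solve_meta(sys, method = "cg", tol = 1e-10)
  expect_equal(cg, direct, tolerance = 1e-6)
})

test_that("prediction metrics behave on degenerate and permuted input", {
  set.seed(5)
  Z <- matrix(rnorm(200), 50, 4)
  g <- c(1, -2, 0.5, 0)
  y <- compute_dgv(Z, g)
  ev <- predict_and_evaluate(Z, g, y)
  expect_equal(ev$correlation, 1)
  expect_equal(ev$slope, 1)
  perm <- sample(50)
  ev_p <- predict_and_evaluate(Z[perm, ], g, y[perm])
  expect_equal(ev_p$correlation, ev$correlation)
  expect_equal(ev_p$slope, ev$slope)
  expect_error(predict_and_evaluate(Z, rep(0, 4), y), "zero variance")
  # uncorrelated noise: |r| bounded by sampling error
  n <- 4000
  Zbig <- matrix(rnorm(n * 2), n, 2)
  ev_n <- predict_and_evaluate(Zbig, c(1, 1), rnorm(n))
  expect_lt(abs(ev_n$correlation), 3 / sqrt(n))
})
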