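test_that("genotype centering subtracts twice the allele frequency", {
  Z <- center_genotypes(matrix(c(2, 1, 0), 3, 1), 0.5)
  expect_equal(drop(Z), c(1, 0, -1))
  expect_equal(drop(center_genotypes(matrix(0, 1, 1), 0.1)), -0.2)
  expect_error(center_genotypes(matrix(1, 1, 1), 1), "invalid frequency")
  expect_error(center_genotypes(matrix(1, 1, 1), 0), "invalid frequency")
})

test_that("residual precision is n_daughters over the error variance", {
  rec <- phenotype_records(y = c(0, 0), n_daughters = c(3, 6))
  expect_equal(residual_precision(rec, 3), c(1, 2))
  expect_equal(residual_precision(phenotype_records(0, 10), 2), 5)
  expect_equal(residual_precision(phenotype_records(0, 1), 1), 1)
  expect_error(residual_precision(rec, -1), "positive")
  expect_error(phenotype_records(0, 0), "strictly positive")
})

test_that("theta converts DGV variance to per-SNP variance", {
  expect_equal(compute_theta(0.5), 2)
  expect_equal(compute_theta(c(0.5, 0.5)), 1)
  expect_equal(compute_theta(c(0.1, 0.2)), 2)
  expect_error(compute_theta(numeric(0)), "empty")
  expect_error(compute_theta(c(0.5, 1)), "strictly in")
})

test_that("single-population solve matches a hand-built dense system", {
  # two individuals, one SNP: independently assemble the 2x2-blocked mixed
  # model equations and solve with base solve()
  Z <- matrix(c(1.5, -0.5), 2, 1)
  w <- c(2, 4)          # n_daughters / err_var
  y <- c(3, -1)
  dgv_var <- 0.8
  theta <- 2.5
  lam <- 1 / (dgv_var * theta)
  A <- rbind(c(sum(w), sum(w * Z)),
             c(sum(w * Z), sum(w * Z^2) + lam))
  b <- c(sum(w * y), sum(w * Z * y))
  ref <- solve(A, b)
  fit <- solve_single_pop(Z, w, y, dgv_var, theta)
  expect_equal(fit$mu, ref[1], tolerance = 1e-12)
  expect_equal(fit$effects, ref[2], tolerance = 1e-12)
})

test_that("null phenotypes give null mean and effects", {
  ds <- one_pop_dataset()
  p <- ds$panels[[1]]
  Z <- center_genotypes(p, allele_freq(p))
  fit <- solve_single_pop(Z, rep(1, nrow(Z)), rep(0, nrow(Z)), 1,
                          compute_theta(allele_freq(p)))
  expect_equal(fit$mu, 0)
  expect_equal(max(abs(fit$effects)), 0)
})

test_that("SNP effects are invariant to the centering frequency", {
  ds <- one_pop_dataset()
  p <- ds$panels[[1]]
  rec <- ds$truth[[1]]$records
  w <- residual_precision(rec, 10)
  theta <- compute_theta(allele_freq(p))
  base <- solve_single_pop(center_genotypes(p, allele_freq(p)), w, rec$y,
                           1, theta)
  set.seed(1)
  for (rep in 1:3) {
    freq <- runif(length(p$snp_ids), 0.05, 0.95)
    alt <- solve_single_pop(center_genotypes(p, freq), w, rec$y, 1, theta)
    expect_equal(alt$effects, base$effects, tolerance = 1e-8)
  }
})

test_that("DGV is the genotype-weighted sum of effects", {
  expect_equal(compute_dgv(matrix(c(1, -1), 1, 2), c(2, 3)), -1)
  expect_equal(compute_dgv(matrix(rnorm(12), 3, 4), rep(0, 4)), rep(0, 3))
  set.seed(2)
  Z <- matrix(rnorm(20), 4, 5); g <- rnorm(5)
  brute <- sapply(1:4, function(k) sum(Z[k, ] * g))
  expect_equal(compute_dgv(Z, g), brute)
  expect_error(compute_dgv(Z, g[-1]), "mismatch")
})

test_that("population summary matches hand arithmetic on one SNP", {
  # two individuals, one SNP; absorb the precision-weighted mean by hand
  dos <- matrix(c(2, 0), 2, 1)
  panel <- genotype_panel(dos, snp_ids = "s1", indiv_ids = c("a", "b"))
  rec <- phenotype_records(c(1.0, -0.5), c(4, 2), indiv_ids = c("a", "b"))
  err_var <- 2; dgv_var <- 1
  s <- summarize_population(panel, rec, err_var, dgv_var)
  p <- 0.5                       # mean dosage / 2
  z <- c(2, 0) - 2 * p
  w <- c(4, 2) / err_var
  ybar <- sum(w * c(1, -0.5)) / sum(w)
  yt <- c(1, -0.5) - ybar
  lhs <- sum(w * z^2) - sum(w * z)^2 / sum(w)
  rhs <- sum(w * z * yt)
  expect_equal(s$allele_freq, c(s1 = p))
  expect_equal(drop(s$lhs), lhs)
  expect_equal(s$rhs, rhs)
  theta <- 1 / (2 * p * (1 - p))
  expect_equal(s$effects, rhs / (lhs + 1 / (dgv_var * theta)))
})

test_that("summaries are deterministic and their lhs is symmetric PSD", {
  ds <- one_pop_dataset()
  s1 <- summarize_population(ds$panels[[1]], ds$truth[[1]]$records, 10, 1)
  s2 <- summarize_population(ds$panels[[1]], ds$truth[[1]]$records, 10, 1)
  expect_identical(s1, s2)
  expect_equal(s1$lhs, t(s1$lhs))
  ev <- eigen(s1$lhs, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
})

test_that("summary effects equal the explicit mean-fitted solve", {
  ds <- one_pop_dataset()
  p <- ds$panels[[1]]; rec <- ds$truth[[1]]$records
  s <- summarize_population(p, rec, 10, 1)
  fit <- solve_single_pop(center_genotypes(p, allele_freq(p)),
                          residual_precision(rec, 10), rec$y, 1,
                          compute_theta(allele_freq(p)))
  expect_equal(s$effects, fit$effects, tolerance = 1e-10)
})

test_that("recover_rhs inverts the summary solve", {
  ds <- one_pop_dataset()
  s <- summarize_population(ds$panels[[1]], ds$truth[[1]]$records, 10, 1)
  stripped <- s
  stripped$rhs <- NULL
  expect_equal(recover_rhs(stripped), s$rhs, tolerance = 1e-8)
  # null effects give null rhs
  z <- s; z$effects <- rep(0, length(s$effects))
  expect_equal(recover_rhs(z), rep(0, length(s$rhs)))
  # identity lhs, unit variances: rhs = (1 + 1) * g
  one <- structure(list(snp_ids = "s", allele_freq = 0.5,
                        lhs = matrix(1, 1, 1), effects = 1,
                        dgv_var = 0.5, err_var = 1),
                   class = "pop_summary")
  expect_equal(recover_rhs(one), 2)  # lhs*g + g/(0.5 * 2)
  z$effects <- NULL
  expect_error(recover_rhs(z), "no effects")
})

test_that("shrinkage vanishes as the residual precision grows", {
  set.seed(9)
  n <- 40; m <- 8
  dos <- matrix(rbinom(n * m, 2, 0.4), n, m)
  panel <- genotype_panel(dos)
  f <- allele_freq(panel)
  Z <- center_genotypes(panel, f)
  g_true <- rnorm(m, 0, 0.3)
  y <- drop(Z %*% g_true) + rnorm(n, 0, 0.1)
  theta <- compute_theta(f)
  # weighted least squares with the mean fitted (no prior): the target
  X <- cbind(1, Z)
  ols <- qr.solve(X, y)[-1]
  dist <- sapply(c(1, 10, 100, 1000), function(nd) {
    fit <- solve_single_pop(Z, rep(nd, n), y, 1, theta)
    sqrt(sum((fit$effects - ols)^2))
  })
  expect_true(all(diff(dist) < 0))
})

test_that("monomorphic SNPs are rejected at summarization", {
  dos <- cbind(c(2, 2, 2), c(1, 0, 2))
  panel <- genotype_panel(dos)
  rec <- phenotype_records(c(1, 2, 3), c(5, 5, 5))
  expect_error(summarize_population(panel, rec, 1, 1), "monomorphic")
})
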