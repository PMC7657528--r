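# The max-kernel U-statistic machinery.

test_that("ku_statistic matches the brute-force double-loop oracle", {
  # frozen hand case: n = 4, off-diagonals 1, residuals (1,-1,1,-1)
  k <- matrix(1, 4, 4); diag(k) <- 0
  e <- c(1, -1, 1, -1)
  st <- ku_statistic(k, e)
  expect_equal(st$t_n, -1 / 3)
  expect_equal(st$v_hat, 1 / 6)
  expect_equal(st$q, (-1 / 3) / sqrt(1 / 6))

  # random instances, n <= 20, all kernel families
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(6:20, 1)
    x <- matrix(sample(0:2, n * 5, TRUE), n, 5)
    e <- null_resid(n)
    for (spec in kernel_bundle()) {
      kc <- center_kernel(kernel_matrix(x, spec))
      st <- ku_statistic(kc, e)
      br <- ku_brute(kc$values, e)
      expect_equal(st$t_n, br$t_n, tolerance = 1e-10)
      expect_equal(st$v_hat, br$v_hat, tolerance = 1e-10)
    }
  }
})

test_that("Q is invariant to positive rescaling of kernel and residuals", {
  set.seed(32)
  x <- matrix(sample(0:2, 30 * 6, TRUE), 30, 6)
  kc <- center_kernel(kernel_matrix(x, kernel_spec("linear")))
  e <- null_resid(30)
  q1 <- ku_statistic(kc, e)$q
  q2 <- ku_statistic(structure(list(values = 10 * kc$values, spec = NULL,
                                    centered = TRUE),
                               class = "kernel_matrix"), 3 * e)$q
  expect_equal(q1, q2, tolerance = 1e-12)
})

test_that("degenerate kernels are rejected", {
  k0 <- diag(5)                                  # no off-diagonal signal
  expect_error(ku_statistic(k0, null_resid(5)), "degenerate")
  expect_error(ku_statistic(matrix(1, 4, 4), rep(0, 4)), "zero")
})

test_that("residualize produces OLS residuals orthogonal to the design", {
  set.seed(33)
  y <- rnorm(100)
  z <- cbind(a = rnorm(100), b = rnorm(100))
  e <- residualize(y, z)
  expect_lt(abs(sum(e)), 1e-8)
  expect_lt(max(abs(crossprod(cbind(1, z), e))), 1e-8)
  # intercept-only and perfect-fit edge cases
  expect_equal(residualize(y, NULL), y - mean(y))
  expect_equal(residualize(2 + 3 * z[, "a"], z), rep(0, 100),
               tolerance = 1e-10)
  zz <- cbind(z, c2 = 2 * z[, "a"])
  expect_error(residualize(y, zz), "collinear")
})

test_that("screening keeps the right SNPs under null and signal", {
  set.seed(34)
  g <- simulate_genotypes(400, 1000, ld_r = 0)
  y <- rnorm(400)
  # threshold 1 keeps everything polymorphic
  sc_all <- screen_snps(g, y, alpha_m = 1)
  expect_length(sc_all$kept_snp_ids, 1000)
  # independent label keeps about 5%
  sc <- screen_snps(g, y, alpha_m = 0.05)
  expect_equal(sc$label_type, "quantitative")
  expect_lt(abs(length(sc$kept_snp_ids) - 50),
            3 * sqrt(1000 * 0.05 * 0.95))
  expect_true(all(sc$per_snp_pvalues[sc$kept_snp_ids] < 0.05))
  expect_false(sc$fallback)

  # a strongly associated SNP survives screening with a binary label
  kept_hits <- vapply(1:40, function(r) {
    set.seed(1000 + r)
    gs <- simulate_genotypes(500, 5, maf_low = 0.3, maf_high = 0.3)
    eta <- -0.5 + 1.0 * gs$values[, 3]          # log-OR 1 at SNP 3
    lab <- rbinom(500, 1, plogis(eta))
    "snp3" %in% screen_snps(gs, lab, 0.05)$kept_snp_ids
  }, logical(1))
  expect_gte(mean(kept_hits), 0.95)

  # monomorphic SNPs get p = 1 and are never kept
  gm <- genotype_matrix(cbind(snpA = rep(1L, 50),
                              snpB = sample(0:2, 50, TRUE)))
  scm <- screen_snps(gm, rnorm(50), alpha_m = 1)
  expect_equal(unname(scm$per_snp_pvalues["snpA"]), 1)
  expect_false("snpA" %in% scm$kept_snp_ids)

  # empty selection falls back to the full pathway with a flag
  sc_fb <- screen_snps(gm, rnorm(50), alpha_m = 1e-12)
  expect_true(sc_fb$fallback)
  expect_length(sc_fb$kept_snp_ids, 2)
})

test_that("kernel correlation honours equality, scaling and orthogonality", {
  set.seed(35)
  x <- matrix(sample(0:2, 25 * 6, TRUE), 25, 6)
  e <- null_resid(25)
  kc <- center_kernel(kernel_matrix(x, kernel_spec("linear")))
  # identical and positively scaled kernels are perfectly correlated
  om <- kernel_correlation(list(kc, kc), e)
  expect_equal(om[1, 2], 1, tolerance = 1e-10)
  kc2 <- structure(list(values = 3.7 * kc$values, spec = NULL,
                        centered = TRUE), class = "kernel_matrix")
  om2 <- kernel_correlation(list(kc, kc2), e)
  expect_equal(om2[1, 2], 1, tolerance = 1e-10)
  # disjoint off-diagonal supports give zero correlation
  k1 <- matrix(0, 4, 4); k1[1, 2] <- k1[2, 1] <- 1
  k2 <- matrix(0, 4, 4); k2[3, 4] <- k2[4, 3] <- 1
  om3 <- kernel_correlation(
    list(structure(list(values = k1, spec = NULL, centered = TRUE),
                   class = "kernel_matrix"),
         structure(list(values = k2, spec = NULL, centered = TRUE),
                   class = "kernel_matrix")),
    c(1, -1, 2, 1))
  expect_equal(om3[1, 2], 0, tolerance = 1e-12)
  # estimated matrices are valid: unit diagonal, |rho| <= 1, PSD
  om4 <- kernel_correlation(
    lapply(kernel_bundle(), function(sp)
      center_kernel(kernel_matrix(x, sp))), e)
  expect_equal(diag(om4), rep(1, 3))
  expect_true(all(abs(om4) <= 1 + 1e-10))
  expect_gte(min(eigen(om4, symmetric = TRUE)$values), -1e-10)
})

test_that("max-statistic p-value matches normal and independence oracles", {
  q <- qnorm(0.95)
  expect_equal(max_statistic_pvalue(q, matrix(1, 1, 1)), 0.05,
               tolerance = 1e-6)
  expect_equal(max_statistic_pvalue(q, diag(2)), 1 - 0.95^2,
               tolerance = 1e-4)
  # perfectly correlated components collapse to the single-kernel case
  r1 <- matrix(1, 2, 2)
  expect_equal(max_statistic_pvalue(q, r1), 0.05, tolerance = 1e-3)
  # deterministic across calls
  om <- matrix(c(1, .6, .3, .6, 1, .5, .3, .5, 1), 3)
  expect_identical(max_statistic_pvalue(1.2, om),
                   max_statistic_pvalue(1.2, om))
  # calling it must not disturb the caller's RNG stream
  set.seed(77); r_before <- rnorm(1)
  set.seed(77); invisible(max_statistic_pvalue(1.2, om)); r_after <- rnorm(1)
  expect_identical(r_before, r_after)
})

test_that("msku_test is deterministic and invariant to nuisance transforms", {
  set.seed(36)
  g <- simulate_genotypes(120, 40)
  z <- simulate_covariates(120)
  y <- simulate_phenotypes(z, h = 0, t = 1, rho = 0)[, 1]
  r1 <- msku_test(g, y, covariates = z)
  r2 <- msku_test(g, y, covariates = z)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(r1$q_max, max(vapply(r1$per_kernel, `[[`, numeric(1), "q")))
  expect_true(r1$p_value >= 0 && r1$p_value <= 1)
  # adding a constant to the phenotype and affinely transforming the
  # covariates leaves Q untouched
  z2 <- cbind(Z1 = 2 * z[, "Z1"] - 5, Z2 = -3 * z[, "Z2"] + 1)
  r3 <- msku_test(g, y + 100, covariates = z2)
  expect_equal(vapply(r3$per_kernel, `[[`, numeric(1), "q"),
               vapply(r1$per_kernel, `[[`, numeric(1), "q"),
               tolerance = 1e-8)
  expect_error(msku_test(g, y, pathway_snp_ids = c("nope1", "nope2")),
               "none of the pathway")
})

test_that("monomorphic SNPs are dropped before kernel construction", {
  set.seed(37)
  x <- cbind(matrix(sample(0:2, 60 * 10, TRUE), 60, 10), mono = 0L)
  colnames(x) <- c(paste0("s", 1:10), "mono")
  y <- rnorm(60)
  expect_message(r <- msku_test(x, y), "monomorphic")
  expect_equal(r$snps_used, 10)
  expect_equal(r$snps_in_pathway, 11)
})

test_that("null p-values with independent-label screening are uniform", {
  # Screening with a label unrelated to the phenotype must not break
  # calibration; pathways are kept large enough for the asymptotics.
  b <- 600
  pv <- numeric(b)
  set.seed(38)
  for (r in seq_len(b)) {
    g <- simulate_genotypes(200, 1000, ld_r = 0.5)
    lab <- rnorm(200)
    sc <- screen_snps(g, lab, 0.05)
    xs <- g$values[, sc$kept_snp_ids, drop = FALSE]
    kp <- sim_kernels_with_products(xs)
    pv[r] <- msku_pvalue_fast(kp, null_resid(200))
  }
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
  # mild finite-sample inflation of the marginal test is tolerated, but
  # nothing beyond it
  expect_lt(mean(pv < 0.05), 0.095)
  expect_gt(mean(pv < 0.05), 0.02)
})
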