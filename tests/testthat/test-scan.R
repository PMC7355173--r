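# Per-SNP interaction scan: design construction, OLS against an
# independent oracle, degeneracy handling, null uniformity, invariances.

make_spec <- function(keller = FALSE) {
  scan_spec("support", keller_terms = keller, min_nonmissing = 10L)
}

test_that("design matrix has the documented columns", {
  set.seed(1)
  n <- 30
  g <- rbinom(n, 2, 0.3); e <- runif(n, 1, 5)
  C <- cbind(age = rnorm(n, 13.78), sex = rbinom(n, 1, 0.5))
  d0 <- build_design(g, e, C, make_spec(keller = FALSE))
  expect_equal(ncol(d0$X), 6)
  d1 <- build_design(g, e, C, make_spec(keller = TRUE))
  expect_equal(ncol(d1$X), 10)
  expect_identical(colnames(d1$X)[4], "g:e")
  # all-missing genotype is degenerate
  dm <- build_design(rep(NA_real_, n), e, C, make_spec())
  expect_true(dm$degenerate)
  # complete-case per SNP: a missing dosage drops exactly that row
  g2 <- g; g2[5] <- NA
  d2 <- build_design(g2, e, C, make_spec())
  expect_equal(nrow(d2$X), n - 1)
  expect_false(d2$mask[5])
})

test_that("noiseless outcome recovers the interaction coefficient exactly", {
  set.seed(2)
  n <- 50
  g <- rbinom(n, 2, 0.4); e <- runif(n, 1, 5)
  C <- cbind(age = rnorm(n, 13.78), sex = rbinom(n, 1, 0.5))
  d <- build_design(g, e, C, make_spec())
  y <- drop(d$X %*% c(1.5, 0.2, -0.1, 0.7, 0.05, -0.3))
  fit <- fit_snp_interaction(y, d)
  expect_equal(fit$beta_gxe, 0.7, tolerance = 1e-8)
  expect_lt(fit$p, 1e-12)
  expect_identical(fit$status, "ok")
})

test_that("rank-deficient designs are skipped as degenerate", {
  set.seed(3)
  n <- 40
  e <- runif(n, 1, 5)
  C <- cbind(age = rnorm(n, 13.78), sex = rbinom(n, 1, 0.5))
  d <- build_design(rep(1, n), e, C, make_spec())   # monomorphic SNP
  fit <- fit_snp_interaction(rnorm(n), d)
  expect_identical(fit$status, "skipped_degenerate")
  expect_true(is.na(fit$p))
})

test_that("scan estimates match the normal-equations + t oracle", {
  set.seed(4)
  n <- 40
  g <- rbinom(n, 2, 0.3); e <- runif(n, 1, 5)
  C <- cbind(age = rnorm(n, 13.78), sex = rbinom(n, 1, 0.5))
  y <- rnorm(n, 2, 0.6)
  for (keller in c(FALSE, TRUE)) {
    d <- build_design(g, e, C, make_spec(keller))
    fit <- fit_snp_interaction(y, d)
    orc <- ols_oracle(y, d$X)
    j <- d$gxe_col
    expect_equal(fit$beta_gxe, unname(orc$beta[j]), tolerance = 1e-8)
    expect_equal(fit$se, unname(orc$se[j]), tolerance = 1e-8)
    expect_equal(fit$t, unname(orc$t[j]), tolerance = 1e-8)
    expect_equal(fit$p, unname(orc$p[j]), tolerance = 1e-8)
    expect_equal(fit$t, fit$beta_gxe / fit$se, tolerance = 1e-10)
  }
})

test_that("scan_gxe returns one row per SNP in stable order", {
  cfg <- null_indep_config(n_genes = 6, n = 300, seed = 12)
  coh <- simulate_cohort(cfg)
  sc <- scan_gxe(coh, scan_spec("support"))
  expect_equal(nrow(sc), ncol(coh$genotypes))
  expect_identical(sc$snp_id, colnames(coh$genotypes))
})

test_that("jointly permuting sample order leaves every p unchanged", {
  cfg <- null_indep_config(n_genes = 4, n = 200, seed = 13)
  coh <- simulate_cohort(cfg)
  sc1 <- scan_gxe(coh, scan_spec("support"))
  set.seed(99)
  perm <- sample.int(nrow(coh$genotypes))
  coh2 <- coh
  coh2$genotypes <- coh$genotypes[perm, , drop = FALSE]
  coh2$pheno <- coh$pheno[perm, , drop = FALSE]
  sc2 <- scan_gxe(coh2, scan_spec("support"))
  expect_equal(sc2$p, sc1$p, tolerance = 1e-10)
})

test_that("affine rescaling of the exposure rescales beta, not p", {
  cfg <- null_indep_config(n_genes = 4, n = 200, seed = 14)
  coh <- simulate_cohort(cfg)
  sc1 <- scan_gxe(coh, scan_spec("support", keller_terms = FALSE))
  coh2 <- coh
  coh2$pheno$support <- 3 * coh$pheno$support + 2
  sc2 <- scan_gxe(coh2, scan_spec("support", keller_terms = FALSE))
  expect_equal(sc2$p, sc1$p, tolerance = 1e-8)
  expect_equal(sc2$beta_gxe, sc1$beta_gxe / 3, tolerance = 1e-8)
})

test_that("null interaction p-values are uniform", {
  cfg <- sim_config(n_individuals = 948,
                    genes = default_gene_panel(n_genes = 1000,
                                               n_snps_range = c(2L, 2L),
                                               ld_rho_range = c(0, 0),
                                               seed = 15),
                    seed = 151)
  coh <- simulate_cohort(cfg)
  sc <- scan_gxe(coh, scan_spec("harsh_punitive_control"))
  p <- sc$p[sc$status == "ok"]
  expect_gte(length(p), 2000)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
  for (a in c(0.05, 0.01)) {
    tol <- 3 * sqrt(a * (1 - a) / length(p))
    expect_lt(abs(mean(p < a) - a), tol)
  }
})
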