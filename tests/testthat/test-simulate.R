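# Synthetic-cohort generator: determinism, marginal frequencies, LD
# structure, HWE by construction, exposure shapes, phenotype model.

test_that("same configuration and seed give bit-identical cohorts", {
  cfg <- sim_config(genes = default_gene_panel(n_genes = 5, seed = 2),
                    seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$pheno, b$pheno)
})

test_that("marginal allele frequency matches the drawn MAF (binomial oracle)", {
  n <- 50000
  cfg <- sim_config(n_individuals = n,
                    genes = list(sim_gene("g", 4, ld_rho = 0,
                                          maf_range = c(0.3, 0.3))),
                    seed = 21)
  G <- simulate_genotypes(cfg)$genotypes
  f <- colSums(G) / (2 * n)
  se <- sqrt(0.3 * 0.7 / (2 * n))
  expect_true(all(abs(f - 0.3) < 4 * se))
})

test_that("higher ld_rho yields higher adjacent-SNP dosage correlation", {
  mk <- function(rho) {
    cfg <- sim_config(n_individuals = 50000,
                      genes = list(sim_gene("g", 5, ld_rho = rho,
                                            maf_range = c(0.2, 0.4))),
                      seed = 31)
    G <- simulate_genotypes(cfg)$genotypes
    mean(diag(cor(G)[-1, -ncol(G)]))
  }
  expect_gt(mk(0.9), mk(0.1))
})

test_that("genotype marginals satisfy HWE by construction", {
  cfg <- sim_config(n_individuals = 50000,
                    genes = default_gene_panel(n_genes = 20,
                                               n_snps_range = c(3L, 3L),
                                               seed = 5),
                    seed = 41)
  G <- simulate_genotypes(cfg)$genotypes
  pvals <- apply(G, 2, function(g)
    hwe_test(sum(g == 0), sum(g == 1), sum(g == 2), method = "chi2"))
  expect_gte(mean(pvals > 0.001), 0.99)
})

test_that("exposures respect their scale and shapes", {
  cfg <- sim_config(n_individuals = 10000, seed = 51)
  ph <- simulate_exposures_covariates(cfg)
  for (ex in c("support", "harsh_punitive_control")) {
    expect_true(all(ph[[ex]] >= 1 & ph[[ex]] <= 5))
  }
  # right-skewed dimension: strong skew, floor point mass, median at floor
  hp <- ph$harsh_punitive_control
  expect_gt(sample_skewness(hp), 1)
  expect_gte(mean(hp == 1), 0.5)
  expect_equal(median(hp), 1)
  # degenerate bounded normal collapses to its centre
  cfg2 <- sim_config(n_individuals = 100,
                     exposures = list(sim_exposure("e", "bounded_normal",
                                                   mean = 3, sd = 0)),
                     genes = list(sim_gene("g", 1)), seed = 52)
  expect_true(all(simulate_exposures_covariates(cfg2)$e == 3))
  # sex fraction: binomial oracle at the configured probability
  se <- sqrt(0.505 * 0.495 / 10000)
  expect_lt(abs(mean(ph$sex) - 0.505), 4 * se)
  # age moments
  expect_lt(abs(mean(ph$age) - 13.78), 4 * 0.92 / sqrt(10000))
})

test_that("null phenotype is pure noise, uncorrelated with every g:e product", {
  cfg <- sim_config(n_individuals = 2000,
                    genes = default_gene_panel(n_genes = 5, seed = 6),
                    seed = 61)
  coh <- simulate_cohort(cfg)
  e <- coh$pheno$support
  y <- coh$pheno$symptom_score
  r <- apply(coh$genotypes, 2, function(g) cor(y, g * e))
  expect_true(all(abs(r) < 4 / sqrt(2000)))
})

test_that("near-noiseless phenotype lets OLS recover the injected interaction", {
  genes <- list(sim_gene("tg", 1, ld_rho = 0, maf_range = c(0.3, 0.3)))
  eff <- sim_effect(target_gene = "tg", beta_gxe = 0.5, noise_sd = 1e-8)
  cfg <- sim_config(n_individuals = 500, genes = genes, effect = eff,
                    seed = 71)
  coh <- simulate_cohort(cfg)
  ph <- coh$pheno
  X <- cbind(1, coh$genotypes[, 1], ph$support,
             coh$genotypes[, 1] * ph$support, ph$age, ph$sex)
  fit <- ols_oracle(ph$symptom_score, X)
  expect_lt(abs(fit$beta[4] - 0.5), 1e-6)
})

test_that("phenotype generation is deterministic and checks alignment", {
  cfg <- sim_config(genes = default_gene_panel(n_genes = 3, seed = 8),
                    seed = 81)
  gen <- simulate_genotypes(cfg)
  ph <- simulate_exposures_covariates(cfg)
  y1 <- simulate_phenotype(gen$genotypes, gen$gene_map, ph, cfg$effect, 9)
  y2 <- simulate_phenotype(gen$genotypes, gen$gene_map, ph, cfg$effect, 9)
  expect_identical(y1, y2)
  expect_error(simulate_phenotype(gen$genotypes[-1, , drop = FALSE],
                                  gen$gene_map, ph, cfg$effect, 9),
               "aligned")
})

test_that("missingness injector hits the requested rate without breaking HWE inputs", {
  cfg <- sim_config(n_individuals = 2000,
                    genes = default_gene_panel(n_genes = 10, seed = 9),
                    missing_rate = 0.05, seed = 91)
  coh <- simulate_cohort(cfg)
  rate <- mean(is.na(coh$genotypes))
  expect_lt(abs(rate - 0.05), 0.01)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_gene("g", 0), "n_snps")
  expect_error(sim_gene("g", 2, maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_gene("g", 2, ld_rho = 1.2), "ld_rho")
  expect_error(sim_effect(noise_sd = 0), "noise_sd")
  expect_error(sim_config(n_individuals = 0,
                          genes = list(sim_gene("g", 1))), "positive")
  expect_error(sim_config(prob_male = 1.5,
                          genes = list(sim_gene("g", 1))), "prob_male")
})

test_that("calibrated interaction effect yields near-target single-SNP power", {
  genes <- c(default_gene_panel(n_genes = 2, seed = 10),
             list(sim_gene("tg", 1, ld_rho = 0, maf_range = c(0.25, 0.35))))
  cfg <- sim_config(n_individuals = 948, genes = genes,
                    effect = sim_effect(target_gene = "tg",
                                        exposure = "harsh_punitive_control"),
                    seed = 101)
  beta <- calibrate_gxe_effect(cfg, power = 0.8, n_cal = 20000)
  hits <- 0L
  reps <- 60L
  for (s in seq_len(reps)) {
    cfg_s <- cfg
    cfg_s$effect$beta_gxe <- beta
    cfg_s$seed <- 1000L + s
    coh <- simulate_cohort(cfg_s)
    sc <- scan_gxe(coh, scan_spec("harsh_punitive_control"))
    hits <- hits + (sc$p[sc$snp_id == "tg_snp01"] < 0.05)
  }
  # binomial(60, 0.8): 4 SD band around the target
  expect_gt(hits / reps, 0.8 - 4 * sqrt(0.8 * 0.2 / reps))
  expect_lt(hits / reps, 0.8 + 4 * sqrt(0.8 * 0.2 / reps))
})
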