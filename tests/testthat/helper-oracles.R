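# Independent oracles used across the suite. Deliberately written with
# different machinery than the package (explicit normal equations, direct
# chi-square survival calls, hand-rolled moments) so agreement is evidence.

# OLS by explicit normal equations + Student-t p-values
ols_oracle <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- drop(solve(XtX, t(X) %*% y))
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * diag(solve(XtX)))
  tt <- beta / se
  list(beta = beta, se = se, t = tt, p = 2 * pt(-abs(tt), df), df = df)
}

# Fisher's combination, closed form
fisher_oracle <- function(p) {
  T_stat <- -2 * sum(log(p))
  list(T = T_stat,
       p = pchisq(T_stat, df = 2 * length(p), lower.tail = FALSE))
}

# moment-based sample skewness
sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}

# small deterministic cohort built by hand (no generator involved)
tiny_cohort <- function() {
  G <- matrix(c(0, 1, 2, 1, 0, 2,
                1, 1, 0, 2, 1, 0,
                0, 0, 1, 1, 2, 2), nrow = 6,
              dimnames = list(paste0("s", 1:6), c("snpA", "snpB", "snpC")))
  gm <- data.frame(snp_id = c("snpA", "snpB", "snpC"),
                   gene_id = c("g1", "g1", "g2"),
                   chrom = 1L, pos = c(100L, 200L, 5000L),
                   stringsAsFactors = FALSE)
  ph <- data.frame(sample_id = paste0("s", 1:6),
                   symptom_score = c(2.1, 2.5, 3.0, 1.8, 2.2, 2.9),
                   support = c(3.5, 4.0, 2.5, 3.0, 4.5, 3.8),
                   age = c(13, 14, 13.5, 12.8, 14.2, 13.1),
                   sex = c(0, 1, 0, 1, 1, 0),
                   stringsAsFactors = FALSE)
  cohort_data(G, gm, ph, exposures = "support")
}

# null cohort with independent SNPs (no LD, no effects)
null_indep_config <- function(n_genes = 50, n = 948, seed = 1,
                              n_snps_range = c(2L, 4L)) {
  sim_config(n_individuals = n,
             genes = default_gene_panel(n_genes = n_genes,
                                        n_snps_range = n_snps_range,
                                        ld_rho_range = c(0, 0),
                                        seed = seed),
             seed = seed)
}
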