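# SNP quality control: MAF folding, HWE tests, filter thresholds and order.

test_that("compute_maf folds the allele frequency and handles missing", {
  expect_equal(compute_maf(c(0, 1, 1, 2)), 0.5)
  expect_equal(compute_maf(c(0, 0, 0, 1)), 0.125)
  expect_equal(compute_maf(c(2, 2, 2, 2)), 0)
  expect_equal(compute_maf(c(0, NA, 0, 1)), 1 / 6)
  expect_error(compute_maf(c(NA, NA)), "missing")
})

test_that("chi-square HWE test matches the 1-df survival oracle", {
  expect_equal(hwe_test(25, 50, 25, method = "chi2"), 1)
  # (30,40,30): expected (25,50,25) at p=0.5, chi2 = 1+2+1 = 4
  expect_equal(hwe_test(30, 40, 30, method = "chi2"),
               pchisq(4, df = 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(hwe_test(-1, 2, 3), "non-negative")
  expect_equal(hwe_test(10, 0, 0, method = "chi2"), 1)   # monomorphic
})

test_that("exact HWE test sums the conditional haploid-draw distribution", {
  # tiny case checked against full enumeration done inline
  exact_enum <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    nA <- 2 * nAA + nAa
    het <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
    pr <- vapply(het, function(h) {
      aa <- (nA - h) / 2
      choose(n, aa) * choose(n - aa, h) * 2^h /
        choose(2 * n, nA) * choose(2 * n - nA, 0)  # last factor = 1
    }, 0)
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[het == nAa] + 1e-12])
  }
  for (cnt in list(c(3, 4, 3), c(5, 2, 5), c(1, 8, 1), c(6, 0, 4))) {
    expect_equal(hwe_test(cnt[1], cnt[2], cnt[3], method = "exact"),
                 exact_enum(cnt[1], cnt[2], cnt[3]), tolerance = 1e-10)
  }
  # large-sample agreement with the chi-square test
  expect_lt(abs(hwe_test(3000, 4000, 3000, method = "exact") -
                hwe_test(3000, 4000, 3000, method = "chi2")), 0.02)
})

test_that("QC removes SNPs by strict call-rate and MAF thresholds", {
  n <- 1000
  mk_snp <- function(n_missing = 0, n_het = 100) {
    g <- rep(0, n)
    g[seq_len(n_het)] <- 1
    if (n_missing > 0) g[n - seq_len(n_missing) + 1] <- NA
    g
  }
  G <- cbind(cr97 = mk_snp(n_missing = 30),    # call rate 0.970 -> out
             cr98 = mk_snp(n_missing = 20),    # call rate 0.980 -> kept
             maf009 = mk_snp(n_het = 18),      # MAF 0.009 -> out
             maf012 = mk_snp(n_het = 24))      # MAF 0.012 -> kept
  rownames(G) <- sprintf("s%04d", 1:n)
  gm <- data.frame(snp_id = colnames(G), gene_id = "g1", chrom = 1L,
                   pos = 1:4, stringsAsFactors = FALSE)
  ph <- data.frame(sample_id = rownames(G), symptom_score = rnorm(n),
                   support = runif(n, 1, 5), age = rnorm(n, 13.78),
                   sex = rep(c(0, 1), n / 2), stringsAsFactors = FALSE)
  coh <- cohort_data(G, gm, ph, "support")
  res <- apply_qc(coh)
  rep <- res$report
  expect_identical(rep$reason[rep$snp_id == "cr97"], "call_rate")
  expect_true(rep$kept[rep$snp_id == "cr98"])
  expect_identical(rep$reason[rep$snp_id == "maf009"], "maf")
  expect_true(rep$kept[rep$snp_id == "maf012"])
  expect_identical(colnames(res$cohort$genotypes), c("cr98", "maf012"))
  expect_identical(res$cohort$gene_map$snp_id, c("cr98", "maf012"))
  # call-rate failure takes precedence in the reported reason
  expect_identical(rep$reason[rep$call_rate < 0.98], "call_rate")
})

test_that("HWE filter is applied only when enabled, and QC is idempotent", {
  n <- 500
  set.seed(7)
  hwe_ok <- rbinom(n, 1, 0.3) + rbinom(n, 1, 0.3)
  hwe_bad <- c(rep(0, 250), rep(2, 250))       # no heterozygotes at MAF 0.5
  G <- cbind(ok = hwe_ok, bad = hwe_bad)
  G <- matrix(as.numeric(G), ncol = 2,
              dimnames = list(sprintf("s%03d", 1:n), c("ok", "bad")))
  gm <- data.frame(snp_id = c("ok", "bad"), gene_id = "g1", chrom = 1L,
                   pos = 1:2, stringsAsFactors = FALSE)
  ph <- data.frame(sample_id = rownames(G), symptom_score = rnorm(n),
                   support = runif(n, 1, 5), age = rnorm(n, 13.78),
                   sex = rep(c(0, 1), n / 2), stringsAsFactors = FALSE)
  coh <- cohort_data(G, gm, ph, "support")
  res <- apply_qc(coh)
  expect_identical(res$report$reason, c("pass", "hwe"))
  off <- apply_qc(coh, hwe_alpha = 0)
  expect_true(all(off$report$kept))
  # idempotence: filtering a filtered cohort changes nothing
  twice <- apply_qc(res$cohort)
  expect_identical(twice$cohort$genotypes, res$cohort$genotypes)
  expect_true(all(twice$report$kept))
  # report partitions the input exactly
  expect_equal(nrow(res$report), ncol(G))
  expect_equal(sum(res$report$kept) + sum(!res$report$kept), ncol(G))
})

test_that("removing every SNP yields an empty cohort with a warning", {
  coh <- tiny_cohort()
  expect_warning(res <- apply_qc(coh, maf_min = 0.6), "all SNPs removed")
  expect_equal(ncol(res$cohort$genotypes), 0)
  expect_equal(nrow(res$report), 3)
})
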