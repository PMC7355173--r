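# SNP-level quality control: call rate, minor allele frequency,
# Hardy-Weinberg equilibrium.

#' Minor allele frequency of a dosage vector
#'
#' Alternate-allele frequency among non-missing alleles, folded to
#' \code{min(f, 1 - f)}.
#'
#' @param dosages numeric vector of 0/1/2 dosages, \code{NA} allowed.
#' @return MAF in [0, 0.5].
#' @export
compute_maf <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) stop("MAF undefined: all dosages missing")
  f <- sum(d) / (2 * length(d))
  min(f, 1 - f)
}

#' Hardy--Weinberg equilibrium test
#'
#' \code{chi2}: 1-df chi-square test of the observed genotype counts against
#' the HWE-expected counts at the sample allele frequency. \code{exact}:
#' exact test by enumeration over all heterozygote counts compatible with
#' the observed allele counts, summing the probabilities of all tables at
#' most as probable as the observed one under the conditional
#' haploid-sampling distribution.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total > 0).
#' @param method \code{"chi2"} or \code{"exact"}.
#' @return p-value in (0, 1].
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa, method = c("chi2", "exact")) {
  method <- match.arg(method)
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("total genotype count must be positive")
  if (method == "chi2") {
    p <- (2 * n_AA + n_Aa) / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    o <- c(n_AA, n_Aa, n_aa)
    if (any(e == 0)) return(1)      # monomorphic: nothing to test
    stat <- sum((o - e)^2 / e)
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    # conditional distribution of the heterozygote count given allele counts
    nA <- 2 * n_AA + n_Aa
    na <- 2 * n_aa + n_Aa
    if (nA == 0 || na == 0) return(1)
    het <- seq.int(nA %% 2, min(nA, na), by = 2)
    logp <- lgamma(n + 1) - lgamma((nA - het) / 2 + 1) - lgamma(het + 1) -
      lgamma((na - het) / 2 + 1) + het * log(2) +
      lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
    pr <- exp(logp - max(logp))
    pr <- pr / sum(pr)
    obs <- pr[match(n_Aa, het)]
    min(1, sum(pr[pr <= obs + 1e-12]))
  }
}

#' Apply SNP-level quality-control filters
#'
#' SNPs are removed, in order, for call rate below \code{call_rate_min}
#' (strict), folded MAF below \code{maf_min} (strict), and HWE exact-test
#' p-value below \code{hwe_alpha} (strict; \code{hwe_alpha = 0} disables the
#' HWE filter). The report records every input SNP with its first failure
#' reason; the gene map of the filtered cohort is pruned consistently.
#'
#' @param cohort a \code{\link{cohort_data}}.
#' @param call_rate_min minimum per-SNP call rate (fraction of non-missing
#'   individuals).
#' @param maf_min minimum folded MAF.
#' @param hwe_alpha HWE exact-test significance threshold (default 1e-6,
#'   the conventional GWAS value).
#' @return list with \code{cohort} (filtered) and \code{report}
#'   (data frame \code{snp_id}, \code{call_rate}, \code{maf}, \code{hwe_p},
#'   \code{kept}, \code{reason}).
#' @export
apply_qc <- function(cohort, call_rate_min = 0.98, maf_min = 0.01,
                     hwe_alpha = 1e-6) {
  stopifnot(inherits(cohort, "cohort_data"))
  G <- cohort$genotypes
  n <- nrow(G)
  call_rate <- colMeans(!is.na(G))
  maf <- apply(G, 2, function(g) {
    if (all(is.na(g))) NA_real_ else compute_maf(g)
  })
  hwe_p <- apply(G, 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_test(sum(g == 0), sum(g == 1), sum(g == 2), method = "exact")
  })
  reason <- rep("pass", ncol(G))
  reason[!is.na(hwe_p) & hwe_p < hwe_alpha] <- "hwe"
  reason[is.na(maf) | maf < maf_min] <- "maf"
  reason[call_rate < call_rate_min] <- "call_rate"
  kept <- reason == "pass"
  report <- data.frame(snp_id = colnames(G), call_rate = call_rate,
                       maf = maf, hwe_p = hwe_p, kept = kept,
                       reason = reason, row.names = NULL,
                       stringsAsFactors = FALSE)
  if (!any(kept)) {
    warning("all SNPs removed by QC; returning empty cohort")
  }
  keep_ids <- colnames(G)[kept]
  gm <- cohort$gene_map[cohort$gene_map$snp_id %in% keep_ids, , drop = FALSE]
  rownames(gm) <- NULL
  filtered <- cohort
  filtered$genotypes <- G[, kept, drop = FALSE]
  filtered$gene_map <- gm
  list(cohort = filtered, report = report)
}
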