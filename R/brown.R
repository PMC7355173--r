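# Brown's method: Fisher combination of dependent p-values with an
# LD-derived covariance, via a moment-matched scaled chi-square.

#' Covariance of \eqn{-2\ln p} for two correlated tests
#'
#' Cubic approximation (Kost--McDermott) to
#' \eqn{\mathrm{cov}(-2\ln p_i, -2\ln p_j)} as a function of the correlation
#' \eqn{\rho} of the underlying test statistics. By default the dosage
#' correlation enters through its absolute value (two-sided p-value
#' dependence is symmetric in the sign of the statistic correlation) and the
#' result is clamped to [0, 4], the theoretical range for \eqn{\chi^2_2}
#' margins. With \code{signed = TRUE} the polynomial is evaluated at the
#' signed \eqn{\rho} and clamped to [-4, 4].
#'
#' @param rho correlation(s) in [-1, 1].
#' @param signed use the signed correlation instead of \code{|rho|}.
#' @return covariance value(s).
#' @export
kost_covariance <- function(rho, signed = FALSE) {
  if (any(abs(rho) > 1 + 1e-9)) stop("|rho| must not exceed 1")
  rho <- pmin(pmax(rho, -1), 1)
  r <- if (signed) rho else abs(rho)
  v <- 3.263 * r + 0.710 * r^2 + 0.027 * r^3
  if (signed) pmin(pmax(v, -4), 4) else pmin(pmax(v, 0), 4)
}

#' Pool dependent p-values with Brown's method
#'
#' Computes the Fisher statistic \eqn{T = -2\sum_i \ln p_i} and refers
#' \eqn{T} to a scaled chi-square with moments matched to the dependent
#' null: \eqn{E[T] = 2k}, \eqn{\mathrm{Var}[T] = 4k +
#' 2\sum_{i<j}\mathrm{cov}(-2\ln p_i, -2\ln p_j)}, scale
#' \eqn{c = \mathrm{Var}/(2E)} and degrees of freedom
#' \eqn{f = 2E^2/\mathrm{Var}}. The (generally non-integer) df chi-square
#' upper tail is evaluated through the gamma distribution:
#' \eqn{p = P(\Gamma(f/2, \mathrm{scale}=2c) > T)}. With an identity LD
#' matrix this reduces exactly to Fisher's method (\eqn{c = 1},
#' \eqn{f = 2k}).
#'
#' @param p p-values in (0, 1].
#' @param ld \code{\link{ld_matrix}} (or plain correlation matrix) of the
#'   same dimension and order as \code{p}.
#' @param signed_rho pass the signed dosage correlation to
#'   \code{\link{kost_covariance}} instead of its absolute value.
#' @return list with \code{k}, \code{T}, \code{c}, \code{f},
#'   \code{p_pooled}.
#' @export
brown_pool <- function(p, ld, signed_rho = FALSE) {
  k <- length(p)
  if (k == 0) stop("no p-values to pool")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  ld <- as.matrix(ld)
  if (nrow(ld) != k || ncol(ld) != k)
    stop("LD matrix dimension does not match the number of p-values")
  T_stat <- -2 * sum(log(p))
  E <- 2 * k
  if (k == 1) {
    cc <- 1; f <- 2
  } else {
    off <- ld[upper.tri(ld)]
    V <- 4 * k + 2 * sum(kost_covariance(off, signed = signed_rho))
    V <- max(V, 1e-8)           # guard against signed-rho cancellation
    cc <- V / (2 * E)
    f <- 2 * E^2 / V
  }
  p_pooled <- stats::pgamma(T_stat, shape = f / 2, scale = 2 * cc,
                            lower.tail = FALSE)
  list(k = k, T = T_stat, c = cc, f = f,
       p_pooled = max(p_pooled, .Machine$double.xmin))
}

#' Pool SNP-level scan results to gene-level p-values
#'
#' Applies \code{\link{brown_pool}} per gene to the interaction p-values of
#' its usable (status \code{"ok"}) SNPs, using that gene's LD matrix
#' restricted to the same SNPs. Genes with fewer than \code{min_snps}
#' usable SNPs are excluded. Output order follows the input gene order.
#'
#' @param scan a scan result data frame (see \code{\link{scan_gxe}}).
#' @param ld_blocks named list of per-gene \code{\link{ld_matrix}}.
#' @param min_snps minimum usable SNPs per gene (default 2, the multi-SNP
#'   gene filter).
#' @param signed_rho see \code{\link{brown_pool}}.
#' @return data frame \code{gene_id}, \code{k}, \code{T}, \code{c},
#'   \code{f}, \code{p_pooled}, one row per retained gene.
#' @export
pool_genes <- function(scan, ld_blocks, min_snps = 2, signed_rho = FALSE) {
  genes <- unique(scan$gene_id)
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    sub <- scan[scan$gene_id == g & scan$status == "ok", , drop = FALSE]
    if (nrow(sub) < min_snps) next
    if (is.null(ld_blocks[[g]]))
      stop("gene '", g, "' present in scan but missing from LD blocks")
    ld <- ld_blocks[[g]]
    idx <- match(sub$snp_id, rownames(ld))
    if (anyNA(idx))
      stop("scan SNPs of gene '", g, "' absent from its LD matrix")
    b <- brown_pool(sub$p, ld[idx, idx, drop = FALSE],
                    signed_rho = signed_rho)
    rows[[i]] <- data.frame(gene_id = g, k = b$k, T = b$T, c = b$c,
                            f = b$f, p_pooled = b$p_pooled,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(gene_id = character(), k = integer(), T = numeric(),
                      c = numeric(), f = numeric(), p_pooled = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected per-gene significance threshold
#'
#' @param n_genes number of genes tested (>= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @return per-gene threshold \code{alpha / n_genes}; gene results are
#'   called significant when \code{p_pooled} falls strictly below it.
#' @export
bonferroni_threshold <- function(n_genes, alpha = 0.05) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  alpha / n_genes
}
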