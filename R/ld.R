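# Per-gene linkage-disequilibrium matrices from dosages.

#' Pearson correlation matrix of SNP dosages
#'
#' Signed Pearson r over pairwise-complete observations (the PLINK
#' \code{--r} convention), with the diagonal set to exactly 1.
#'
#' @param G sample x SNP dosage submatrix of one gene.
#' @return an \code{\link{ld_matrix}}.
#' @export
genotype_correlation_matrix <- function(G) {
  if (is.null(dim(G))) G <- matrix(G, ncol = 1,
                                   dimnames = list(NULL, "snp"))
  sds <- apply(G, 2, stats::sd, na.rm = TRUE)
  if (any(is.na(sds) | sds == 0))
    stop("zero-variance SNP(s): ",
         paste(colnames(G)[is.na(sds) | sds == 0], collapse = ", "),
         " (should have been removed by QC)")
  if (ncol(G) > 1) {
    nn <- crossprod(!is.na(G))
    if (any(nn[upper.tri(nn)] < 3))
      stop("fewer than 3 pairwise-complete observations for some SNP pair")
  }
  r <- suppressWarnings(stats::cor(G, use = "pairwise.complete.obs"))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  ld_matrix(r, colnames(G))
}

#' LD matrices for every gene of a cohort
#'
#' @param cohort a QC-passed \code{\link{cohort_data}}.
#' @param snps optional named list restricting each gene to a subset of its
#'   SNPs (in scan order); by default all mapped SNPs are used.
#' @return named list of \code{\link{ld_matrix}}, one per gene with at least
#'   one SNP, in gene-map order; SNP order within each matrix matches the
#'   genotype-column (scan) order.
#' @export
gene_ld_blocks <- function(cohort, snps = NULL) {
  stopifnot(inherits(cohort, "cohort_data"))
  genes <- .gene_order(cohort)
  out <- list()
  for (g in genes) {
    ids <- if (!is.null(snps)) snps[[g]] else .gene_snps(cohort, g)
    if (!length(ids)) next
    out[[g]] <- genotype_correlation_matrix(
      cohort$genotypes[, ids, drop = FALSE])
  }
  out
}
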