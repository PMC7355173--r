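#' Cohort container for gene-based G\eqn{\times}{x}E analysis
#'
#' Bundles an additive-dosage genotype matrix, a SNP-to-gene map and a
#' phenotype table into a validated container used by every downstream stage.
#'
#' @param genotypes numeric matrix, samples in rows and SNPs in columns, with
#'   dosages in \{0, 1, 2\} or \code{NA} for missing. Row names are sample
#'   ids, column names are SNP ids.
#' @param gene_map data frame with columns \code{snp_id}, \code{gene_id},
#'   \code{chrom}, \code{pos} (1-based positions; carried, never computed on).
#' @param pheno data frame with one row per sample: \code{sample_id},
#'   \code{symptom_score}, one column per exposure, \code{age}, \code{sex}
#'   (coded 0/1).
#' @param exposures character vector naming the exposure columns of
#'   \code{pheno}.
#'
#' @return An object of class \code{"cohort_data"}: a list with elements
#'   \code{genotypes}, \code{gene_map}, \code{pheno}, \code{exposures}.
#' @export
cohort_data <- function(genotypes, gene_map, pheno, exposures) {
  if (!is.matrix(genotypes) || !is.numeric(genotypes))
    stop("'genotypes' must be a numeric matrix")
  if (is.null(rownames(genotypes)) || is.null(colnames(genotypes)))
    stop("'genotypes' must carry sample ids (rownames) and SNP ids (colnames)")
  if (anyDuplicated(rownames(genotypes)))
    stop("duplicate sample ids in genotype matrix")
  if (anyDuplicated(colnames(genotypes)))
    stop("duplicate SNP ids in genotype matrix")
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("dosages must be 0, 1, 2 or NA")
  req <- c("snp_id", "gene_id", "chrom", "pos")
  if (!all(req %in% names(gene_map)))
    stop("gene_map must have columns: ", paste(req, collapse = ", "))
  if (!all(gene_map$snp_id %in% colnames(genotypes)))
    stop("gene_map refers to SNPs absent from the genotype matrix")
  if (anyDuplicated(gene_map$snp_id))
    stop("duplicate snp_id in gene_map")
  if (!"sample_id" %in% names(pheno))
    stop("pheno must have a 'sample_id' column")
  if (anyDuplicated(pheno$sample_id))
    stop("duplicate sample_id in pheno table")
  if (!setequal(pheno$sample_id, rownames(genotypes)))
    stop("pheno samples and genotype rows do not match")
  if (!all(exposures %in% names(pheno)))
    stop("exposure columns missing from pheno table")
  # align pheno rows to genotype row order once, here
  pheno <- pheno[match(rownames(genotypes), pheno$sample_id), , drop = FALSE]
  rownames(pheno) <- NULL
  structure(
    list(genotypes = genotypes, gene_map = gene_map, pheno = pheno,
         exposures = exposures),
    class = "cohort_data"
  )
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("cohort_data:", nrow(x$genotypes), "samples,",
      ncol(x$genotypes), "SNPs,",
      length(unique(x$gene_map$gene_id)), "genes\n")
  cat("exposures:", paste(x$exposures, collapse = ", "), "\n")
  miss <- mean(is.na(x$genotypes))
  if (miss > 0) cat(sprintf("missing dosages: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.cohort_data <- function(x) dim(x$genotypes)

# SNPs of one gene, in genotype-column (= scan) order
.gene_snps <- function(cohort, gene) {
  ids <- cohort$gene_map$snp_id[cohort$gene_map$gene_id == gene]
  colnames(cohort$genotypes)[colnames(cohort$genotypes) %in% ids]
}

# genes in first-appearance order of the gene map
.gene_order <- function(cohort) unique(cohort$gene_map$gene_id)
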