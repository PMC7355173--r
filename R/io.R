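# Readers and writers for every on-disk format the pipeline touches:
# PLINK .raw dosage tables, PLINK .ld square matrices, TSV phenotype and
# gene-map tables, minimal VCF 4.2 (GT only).

#' Construct and validate an LD matrix
#'
#' @param r square numeric matrix of Pearson correlations between SNP
#'   dosages.
#' @param snp_ids SNP ids in matrix order.
#' @return matrix of class \code{"ld_matrix"} with unit diagonal, entries in
#'   [-1, 1] and symmetry within 1e-12.
#' @export
ld_matrix <- function(r, snp_ids = rownames(r)) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square")
  if (is.null(snp_ids) || length(snp_ids) != nrow(r))
    stop("snp_ids must match the matrix dimension")
  if (any(abs(r) > 1 + 1e-9, na.rm = TRUE))
    stop("LD entries must lie in [-1, 1]")
  asym <- max(abs(r - t(r)))
  if (asym > 1e-6) stop("LD matrix is asymmetric (max deviation ",
                        format(asym), ")")
  r <- (r + t(r)) / 2
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(snp_ids, snp_ids)
  class(r) <- c("ld_matrix", class(r))
  r
}

#' Write genotypes as a PLINK .raw dosage table
#'
#' Header \code{FID IID PAT MAT SEX PHENOTYPE <snp>_<allele> ...}; dosages
#' 0/1/2, \code{NA} for missing. The counted-allele suffix written is
#' \code{_A}; it is stripped again on reading.
#'
#' @param genotypes sample x SNP dosage matrix with dimnames.
#' @param path output file.
#' @export
write_genotype_table <- function(genotypes, path) {
  snp_cols <- paste0(colnames(genotypes), "_A")
  df <- data.frame(FID = rownames(genotypes), IID = rownames(genotypes),
                   PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = -9L,
                   stringsAsFactors = FALSE, check.names = FALSE)
  dos <- as.data.frame(genotypes)
  names(dos) <- snp_cols
  utils::write.table(cbind(df, dos), path, sep = " ", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a PLINK .raw dosage table
#'
#' @param path file in the PLINK \code{.raw} dialect.
#' @return list with \code{genotypes} (numeric sample x SNP matrix, sample
#'   ids from the IID column, SNP ids with the allele suffix stripped) and
#'   \code{sample_ids}, \code{snp_ids}.
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- strsplit(readLines(path, n = 1L), "[ \t]+")[[1]]
  lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (length(hdr) < 6 || !identical(hdr[1:6], lead))
    stop("malformed .raw header: expected leading columns ",
         paste(lead, collapse = " "))
  df <- utils::read.table(path, header = TRUE, sep = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "NA",
                          colClasses = c(rep("character", 2),
                                         rep("numeric", length(hdr) - 2)))
  snp_cols <- hdr[-(1:6)]
  snp_ids <- sub("_[^_]*$", "", snp_cols)
  G <- as.matrix(df[, snp_cols, drop = FALSE])
  bad <- which(!is.na(G) & !(G %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid dosage %s at sample '%s', SNP '%s'",
                 format(G[bad[1, , drop = FALSE]]), df$IID[bad[1, 1]],
                 snp_ids[bad[1, 2]]))
  }
  dimnames(G) <- list(df$IID, snp_ids)
  if (anyDuplicated(df$IID)) stop("duplicate IID in .raw file")
  if (anyDuplicated(snp_ids)) stop("duplicate SNP id in .raw header")
  list(genotypes = G, sample_ids = df$IID, snp_ids = snp_ids)
}

#' Write an LD matrix in PLINK square format
#'
#' Whitespace-delimited reals, one row per SNP, no header (the PLINK
#' \code{--r --matrix} layout).
#'
#' @param ld an \code{\link{ld_matrix}} (or plain square matrix).
#' @param path output file.
#' @export
write_ld_square <- function(ld, path) {
  utils::write.table(format(unclass(ld), digits = 10, trim = TRUE,
                            scientific = FALSE),
                     path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a PLINK square LD matrix
#'
#' @param path whitespace-delimited square matrix file.
#' @param snp_ids SNP ids in row order; the file must have exactly this many
#'   rows and columns.
#' @return an \code{\link{ld_matrix}}. Asymmetry up to 1e-6 is symmetrized
#'   by averaging; beyond that it is an error, as are entries outside
#'   [-1, 1] (beyond 1e-9).
#' @export
read_ld_square <- function(path, snp_ids) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = ""))
  if (nrow(m) != length(snp_ids) || ncol(m) != length(snp_ids))
    stop("LD file dimension ", nrow(m), "x", ncol(m),
         " does not match ", length(snp_ids), " SNP ids")
  dimnames(m) <- NULL
  ld_matrix(m, snp_ids)
}

#' Write the phenotype/exposure/covariate table as TSV
#'
#' @param pheno data frame keyed by \code{sample_id}.
#' @param path output file.
#' @export
write_pheno_table <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read the phenotype/exposure/covariate table
#'
#' @param path TSV with at least \code{sample_id}, \code{symptom_score},
#'   \code{age}, \code{sex}; remaining numeric columns are treated as
#'   exposures.
#' @return data frame with \code{sex} validated to \{0, 1\} and unique
#'   sample ids; attribute \code{"exposures"} names the exposure columns.
#' @export
read_pheno_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  req <- c("sample_id", "symptom_score", "age", "sex")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("pheno table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in pheno table")
  sx <- df$sex[!is.na(df$sex)]
  if (!all(sx %in% c(0, 1)))
    stop("column 'sex' must be coded 0/1; found value ",
         format(sx[!sx %in% c(0, 1)][1]))
  df$sample_id <- as.character(df$sample_id)
  attr(df, "exposures") <- setdiff(names(df), req)
  df
}

#' Write the SNP-to-gene map as TSV
#' @param gene_map data frame \code{snp_id}, \code{gene_id}, \code{chrom},
#'   \code{pos}.
#' @param path output file.
#' @export
write_gene_map <- function(gene_map, path) {
  utils::write.table(gene_map[, c("snp_id", "gene_id", "chrom", "pos")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the SNP-to-gene map
#' @param path TSV with columns \code{snp_id}, \code{gene_id}, \code{chrom},
#'   \code{pos} (1-based).
#' @return typed data frame; duplicate SNP ids are an error.
#' @export
read_gene_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("snp_id", "gene_id", "chrom", "pos")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("gene map missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$snp_id)) stop("duplicate snp_id in gene map")
  df$snp_id <- as.character(df$snp_id)
  df$gene_id <- as.character(df$gene_id)
  df$pos <- as.integer(df$pos)
  df
}

#' Write genotypes as a minimal VCF 4.2
#'
#' One biallelic record per SNP (REF=A, ALT=G placeholders), GT as unphased
#' diploid calls; dosage counts the ALT allele. Missing dosage becomes
#' \code{./.}.
#'
#' @param genotypes sample x SNP dosage matrix.
#' @param gene_map map supplying \code{chrom} and \code{pos} per SNP.
#' @param path output file (plain text).
#' @export
write_vcf <- function(genotypes, gene_map, path) {
  gm <- gene_map[match(colnames(genotypes), gene_map$snp_id), ]
  gt_code <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(genotypes)),
                     collapse = "\t")),
             con)
  for (j in seq_len(ncol(genotypes))) {
    g <- genotypes[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1])
    writeLines(paste(c(gm$chrom[j], gm$pos[j], colnames(genotypes)[j],
                       "A", "G", ".", "PASS", ".", "GT", gt),
                     collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read genotypes from a VCF (GT field only)
#'
#' Biallelic records only; multiallelic records are skipped with a warning.
#' Parsing is delegated to \pkg{vcfR}; the ALT allele is counted, so GT
#' \code{0/0}, \code{0/1}, \code{1/1} map to dosages 0, 1, 2 and missing
#' calls to \code{NA}.
#'
#' @param path VCF file (plain or bgzipped).
#' @return list with \code{genotypes}, \code{sample_ids}, \code{snp_ids}.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped")
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0
  dos[clean == "0/1" | clean == "1/0"] <- 1
  dos[clean == "1/1"] <- 2
  G <- t(dos)
  list(genotypes = G, sample_ids = rownames(G), snp_ids = colnames(G))
}

#' Assemble a cohort from files on disk
#'
#' @param genotype_path PLINK \code{.raw} table (or VCF if
#'   \code{format = "vcf"}).
#' @param gene_map_path SNP-to-gene TSV.
#' @param pheno_path phenotype/exposure/covariate TSV.
#' @param format genotype file format.
#' @return a \code{\link{cohort_data}}.
#' @export
read_cohort <- function(genotype_path, gene_map_path, pheno_path,
                        format = c("raw", "vcf")) {
  format <- match.arg(format)
  g <- if (format == "raw") read_genotype_table(genotype_path)
       else read_vcf(genotype_path)
  gm <- read_gene_map(gene_map_path)
  gm <- gm[gm$snp_id %in% g$snp_ids, , drop = FALSE]
  ph <- read_pheno_table(pheno_path)
  cohort_data(g$genotypes, gm, ph, exposures = attr(ph, "exposures"))
}
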