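# Permutation validation of gene-level findings, genomic-control inflation,
# and the dichotomized-exposure sensitivity analysis.

#' Permutation test of gene-level pooled p-values
#'
#' Re-runs the scan-and-pool pipeline on permuted data and counts, per
#' gene, the permutations whose pooled p-value is at most as large as the
#' observed one. The default strategy permutes the outcome vector across
#' samples (valid under the complete null of no genetic association);
#' \code{strategy = "environment"} permutes the exposure instead, keeping
#' outcome-covariate linkage intact. Empirical p-values use the add-one
#' estimator \eqn{(1 + b)/(1 + B)}, which never returns zero. Deterministic
#' given \code{seed}.
#'
#' @param cohort a QC-passed \code{\link{cohort_data}}.
#' @param spec a \code{\link{scan_spec}}.
#' @param n_perm number of permutations (>= 1; default 1000 for desk runs;
#'   the full-scale choice is 100000).
#' @param strategy \code{"phenotype"} or \code{"environment"}.
#' @param seed RNG seed for the permutation draws.
#' @param min_snps,signed_rho pooling options, as in
#'   \code{\link{pool_genes}}.
#' @return data frame \code{gene_id}, \code{p_observed}, \code{n_perm},
#'   \code{n_as_extreme}, \code{p_empirical}, \code{strategy}.
#' @export
permutation_test <- function(cohort, spec, n_perm = 1000L,
                             strategy = c("phenotype", "environment"),
                             seed = 1L, min_snps = 2, signed_rho = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(n_perm >= 1)
  scan <- scan_gxe(cohort, spec)
  ld <- gene_ld_blocks(cohort)
  obs <- pool_genes(scan, ld, min_snps = min_snps, signed_rho = signed_rho)
  if (!nrow(obs)) stop("no genes to test after the multi-SNP filter")

  # per-gene moment constants are fixed across permutations (LD unchanged)
  usable <- lapply(obs$gene_id, function(g)
    scan$snp_id[scan$gene_id == g & scan$status == "ok"])
  consts <- lapply(seq_len(nrow(obs)), function(i) {
    ids <- usable[[i]]
    m <- ld[[obs$gene_id[i]]]
    idx <- match(ids, rownames(m))
    b <- brown_pool(rep(0.5, length(ids)), m[idx, idx, drop = FALSE],
                    signed_rho = signed_rho)
    list(c = b$c, f = b$f)
  })

  y <- cohort$pheno$symptom_score
  n <- length(y)
  counts <- integer(nrow(obs))

  if (strategy == "phenotype" && !anyNA(y)) {
    sp <- .scan_prep(cohort, spec)
    snp_idx <- lapply(usable, function(ids) match(ids, sp$snp_ids))
    chunk <- 250L
    .with_seed(seed, {
      done <- 0L
      while (done < n_perm) {
        B <- min(chunk, n_perm - done)
        Y <- vapply(seq_len(B), function(b) y[sample.int(n)],
                    numeric(n))
        P <- .scan_fast(sp, Y)
        for (i in seq_len(nrow(obs))) {
          Tb <- -2 * colSums(log(P[snp_idx[[i]], , drop = FALSE]))
          pp <- stats::pgamma(Tb, shape = consts[[i]]$f / 2,
                              scale = 2 * consts[[i]]$c,
                              lower.tail = FALSE)
          counts[i] <- counts[i] + sum(pp <= obs$p_pooled[i])
        }
        done <- done + B
      }
    })
  } else {
    .with_seed(seed, {
      for (b in seq_len(n_perm)) {
        perm <- sample.int(n)
        pc <- cohort
        if (strategy == "phenotype") {
          pc$pheno$symptom_score <- y[perm]
        } else {
          pc$pheno[[spec$exposure]] <- pc$pheno[[spec$exposure]][perm]
        }
        ps <- scan_gxe(pc, spec)
        pg <- pool_genes(ps, ld, min_snps = 1, signed_rho = signed_rho)
        for (i in seq_len(nrow(obs))) {
          row <- pg[pg$gene_id == obs$gene_id[i], , drop = FALSE]
          if (nrow(row) && row$p_pooled <= obs$p_pooled[i])
            counts[i] <- counts[i] + 1L
        }
      }
    })
  }
  data.frame(gene_id = obs$gene_id, p_observed = obs$p_pooled,
             n_perm = as.integer(n_perm), n_as_extreme = counts,
             p_empirical = (1 + counts) / (1 + n_perm),
             strategy = strategy, stringsAsFactors = FALSE)
}

#' Genomic-control inflation factor
#'
#' Converts each p-value to a 1-df chi-square quantile and divides the
#' median by the theoretical \eqn{\chi^2_1} median (0.4549364...). Values
#' near 1 indicate a well-calibrated test-statistic distribution; values
#' well above 1 indicate inflation.
#'
#' @param p p-values in (0, 1].
#' @return inflation factor \eqn{\lambda}.
#' @export
genomic_control_lambda <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stop("no p-values supplied")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Dichotomize an exposure
#'
#' \code{median_split}: 1 for values strictly above the sample median, 0
#' otherwise (ties at the median go to 0). \code{min_threshold}: 1 for any
#' value strictly above the scale floor -- the presence/absence contrast.
#' For a floor-massed variable whose median sits at the floor, the two
#' coincide.
#'
#' @param e numeric exposure vector (\code{NA} propagated).
#' @param method \code{"median_split"} or \code{"min_threshold"}.
#' @param scale_min scale floor for \code{min_threshold} (default 1).
#' @return binary 0/1 vector.
#' @export
dichotomize_exposure <- function(e, method = c("median_split",
                                               "min_threshold"),
                                 scale_min = 1) {
  method <- match.arg(method)
  thr <- if (method == "median_split") {
    m <- stats::median(e, na.rm = TRUE)
    if (isTRUE(m == max(e, na.rm = TRUE)))
      warning("median equals the maximum; dichotomized exposure is all zero")
    m
  } else scale_min
  out <- as.numeric(e > thr)
  out[is.na(e)] <- NA_real_
  out
}

#' Sensitivity analysis with a dichotomized exposure
#'
#' Replaces the named exposure by its binary version and re-runs the full
#' scan, pool and genomic-control pipeline unchanged.
#'
#' @param cohort a QC-passed \code{\link{cohort_data}}.
#' @param exposure exposure name to dichotomize.
#' @param method dichotomization method, see
#'   \code{\link{dichotomize_exposure}}.
#' @param ... further arguments passed to \code{\link{gxe_brown}}.
#' @return a \code{\link{gxe_brown}} fit on the dichotomized exposure.
#' @export
sensitivity_run <- function(cohort, exposure,
                            method = c("median_split", "min_threshold"),
                            ...) {
  method <- match.arg(method)
  cohort$pheno[[exposure]] <- dichotomize_exposure(
    cohort$pheno[[exposure]], method = method)
  fit <- gxe_brown(cohort, exposure, ...)
  fit$dichotomized <- method
  fit
}
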