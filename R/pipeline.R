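# Top-level interface: gxe_brown() fits the whole gene-based GxE analysis
# for one exposure and returns a classed object; run_pipeline() orchestrates
# simulate/read -> QC -> scan -> pool -> validate across exposures and
# writes every stage artifact to a run directory.

#' Gene-based G\eqn{\times}{x}E interaction analysis
#'
#' Fits the per-SNP linear interaction model for one exposure, pools the
#' SNP-level interaction p-values to gene-level p-values with Brown's
#' method using the genes' LD matrices, applies the multi-SNP gene filter
#' and the Bonferroni threshold over tested genes, and computes the
#' genomic-control inflation factor of the gene-level p-values.
#'
#' @param cohort a QC-passed \code{\link{cohort_data}}.
#' @param exposure exposure column name (E).
#' @param covariates covariate columns adjusted for.
#' @param keller_terms include covariate-by-G and covariate-by-E products
#'   (see \code{\link{scan_spec}}).
#' @param min_snps minimum usable SNPs per gene (default 2).
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param ld_blocks optional precomputed per-gene \code{\link{ld_matrix}}
#'   list (e.g. read from PLINK \code{.ld} files); computed from dosages by
#'   default.
#' @param signed_rho pass signed dosage correlations to the pooling
#'   covariance (default: absolute value).
#' @return object of class \code{"gxe_brown"}: list with \code{scan}
#'   (per-SNP results), \code{genes} (per-gene results with
#'   \code{significant} flag), \code{lambda}, \code{threshold},
#'   \code{n_genes}, \code{exposure}, \code{spec}, \code{call}.
#' @examples
#' cfg <- sim_config(genes = default_gene_panel(n_genes = 10, seed = 7),
#'                   seed = 7)
#' coh <- apply_qc(simulate_cohort(cfg))$cohort
#' fit <- gxe_brown(coh, "harsh_punitive_control")
#' fit
#' @export
gxe_brown <- function(cohort, exposure, covariates = c("age", "sex"),
                      keller_terms = TRUE, min_snps = 2, alpha = 0.05,
                      ld_blocks = NULL, signed_rho = FALSE) {
  spec <- scan_spec(exposure, covariates, keller_terms)
  scan <- scan_gxe(cohort, spec)
  if (is.null(ld_blocks)) ld_blocks <- gene_ld_blocks(cohort)
  genes <- pool_genes(scan, ld_blocks, min_snps = min_snps,
                      signed_rho = signed_rho)
  n_genes <- nrow(genes)
  threshold <- if (n_genes) bonferroni_threshold(n_genes, alpha) else NA_real_
  genes$significant <- if (n_genes) genes$p_pooled < threshold else logical()
  lambda <- if (n_genes) genomic_control_lambda(genes$p_pooled) else NA_real_
  structure(list(scan = scan, genes = genes, ld_blocks = ld_blocks,
                 lambda = lambda, threshold = threshold,
                 n_genes = n_genes, alpha = alpha, exposure = exposure,
                 spec = spec, signed_rho = signed_rho,
                 call = match.call()),
            class = "gxe_brown")
}

#' @export
print.gxe_brown <- function(x, ...) {
  cat("Gene-based GxE analysis (Brown pooling, LD-adjusted)\n")
  cat("exposure:", x$exposure,
      if (!is.null(x$dichotomized)) paste0("(dichotomized: ",
                                           x$dichotomized, ")"), "\n")
  cat(sprintf("SNPs scanned: %d (%d usable)  genes tested: %d\n",
              nrow(x$scan), sum(x$scan$status == "ok"), x$n_genes))
  cat(sprintf("Bonferroni threshold: %.3g   lambda: %.3f\n",
              x$threshold, x$lambda))
  sig <- x$genes[x$genes$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat("significant genes:\n")
    print(sig[, c("gene_id", "k", "p_pooled")], row.names = FALSE)
  } else cat("no gene passes the Bonferroni threshold\n")
  invisible(x)
}

#' @export
summary.gxe_brown <- function(object, n_top = 5, ...) {
  g <- object$genes[order(object$genes$p_pooled), , drop = FALSE]
  structure(list(exposure = object$exposure,
                 n_snps = nrow(object$scan),
                 n_degenerate = sum(object$scan$status != "ok"),
                 n_genes = object$n_genes,
                 threshold = object$threshold,
                 lambda = object$lambda,
                 n_significant = sum(object$genes$significant),
                 top = utils::head(g, n_top)),
            class = "summary.gxe_brown")
}

#' @export
print.summary.gxe_brown <- function(x, ...) {
  cat("Gene-based GxE analysis of exposure '", x$exposure, "'\n", sep = "")
  cat(sprintf("  SNPs: %d (%d degenerate)   genes: %d\n",
              x$n_snps, x$n_degenerate, x$n_genes))
  cat(sprintf("  Bonferroni threshold %.3g, %d significant gene(s)\n",
              x$threshold, x$n_significant))
  cat(sprintf("  genomic-control lambda: %.3f\n", x$lambda))
  cat("  top genes:\n")
  print(x$top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.gxe_brown <- function(x, ...) x$genes

#' Manhattan-style gene table
#'
#' @param fit a \code{\link{gxe_brown}} fit (or its \code{genes} data
#'   frame together with \code{threshold}).
#' @param threshold per-gene significance threshold (taken from the fit by
#'   default).
#' @return data frame \code{gene_id}, \code{k}, \code{p_pooled},
#'   \code{neg_log10_p} (underflow floored at 1e-300), \code{significant},
#'   in input gene order.
#' @export
manhattan_table <- function(fit, threshold = NULL) {
  g <- if (inherits(fit, "gxe_brown")) fit$genes else fit
  if (!nrow(g)) stop("no gene results")
  if (is.null(threshold))
    threshold <- if (inherits(fit, "gxe_brown")) fit$threshold else
      bonferroni_threshold(nrow(g))
  data.frame(gene_id = g$gene_id, k = g$k, p_pooled = g$p_pooled,
             neg_log10_p = -log10(pmax(g$p_pooled, 1e-300)),
             significant = g$p_pooled < threshold,
             stringsAsFactors = FALSE)
}

#' Manhattan bar plot of gene-level p-values
#'
#' One bar per gene at \eqn{-\log_{10} p}; the dashed line marks the
#' Bonferroni threshold.
#'
#' @param x a \code{\link{gxe_brown}} fit.
#' @param ... passed to \code{\link[graphics]{barplot}}.
#' @export
plot.gxe_brown <- function(x, ...) {
  mt <- manhattan_table(x)
  bp <- graphics::barplot(mt$neg_log10_p,
                          col = ifelse(mt$significant, "firebrick", "grey40"),
                          border = NA, ylab = expression(-log[10](p)),
                          xlab = "gene",
                          main = paste("Gene-based GxE:", x$exposure), ...)
  graphics::abline(h = -log10(x$threshold), lty = 2)
  invisible(bp)
}

#' Configure a full pipeline run
#'
#' Exactly one of \code{sim} (a \code{\link{sim_config}}) or \code{paths}
#' (named list \code{genotypes}, \code{gene_map}, \code{pheno}) must be
#' given.
#'
#' @param sim synthetic-cohort configuration.
#' @param paths input file paths.
#' @param exposures exposure columns to analyse (default: all configured /
#'   all found).
#' @param covariates,keller_terms scan options.
#' @param call_rate_min,maf_min,hwe_alpha QC thresholds.
#' @param min_snps,alpha,signed_rho pooling options.
#' @param n_perm permutations per exposure (0 disables the permutation
#'   stage).
#' @param perm_strategy \code{"phenotype"} or \code{"environment"}.
#' @param binary_exposure optional exposure name also analysed after
#'   median-split dichotomization (sensitivity analysis).
#' @param seed seed for every stochastic stage.
#' @return list of class \code{"run_config"}.
#' @export
run_config <- function(sim = NULL, paths = NULL, exposures = NULL,
                       covariates = c("age", "sex"), keller_terms = TRUE,
                       call_rate_min = 0.98, maf_min = 0.01,
                       hwe_alpha = 1e-6, min_snps = 2, alpha = 0.05,
                       signed_rho = FALSE, n_perm = 0L,
                       perm_strategy = "phenotype",
                       binary_exposure = NULL, seed = 1L) {
  if (is.null(sim) == is.null(paths))
    stop("exactly one of 'sim' or 'paths' must be provided")
  if (!is.null(paths)) {
    need <- c("genotypes", "gene_map", "pheno")
    if (!all(need %in% names(paths)))
      stop("paths must name: ", paste(need, collapse = ", "))
  }
  structure(list(sim = sim, paths = paths, exposures = exposures,
                 covariates = covariates, keller_terms = keller_terms,
                 call_rate_min = call_rate_min, maf_min = maf_min,
                 hwe_alpha = hwe_alpha, min_snps = min_snps, alpha = alpha,
                 signed_rho = signed_rho, n_perm = as.integer(n_perm),
                 perm_strategy = perm_strategy,
                 binary_exposure = binary_exposure,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline and write every stage artifact
#'
#' Stages: simulate (or read) the cohort, SNP QC, then per exposure the
#' interaction scan, Brown pooling, genomic control, Manhattan table and
#' (optionally) the permutation test; finally the median-split sensitivity
#' analysis for \code{binary_exposure} if configured. All tables are TSV;
#' a machine-readable YAML summary and a structured log with stage timings
#' and seeds are written alongside.
#'
#' @param config a \code{\link{run_config}} (or path to a YAML file with
#'   the same fields).
#' @param out_dir run directory (created if needed).
#' @return invisibly, a list with the QC report, the per-exposure
#'   \code{\link{gxe_brown}} fits and the summary.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  cat("", file = logf)
  logmsg <- function(...) cat(format(Sys.time(), "%H:%M:%S"), "|", ...,
                              "\n", file = logf, append = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    logmsg(sprintf("stage %-10s done in %.2fs", name,
                   proc.time()[["elapsed"]] - t0))
    r
  }
  logmsg("seed:", config$seed)

  cohort <- stage("input", {
    if (!is.null(config$sim)) {
      sc <- config$sim; sc$seed <- config$seed
      coh <- simulate_cohort(sc)
      write_genotype_table(coh$genotypes,
                           file.path(out_dir, "genotypes.raw"))
      write_gene_map(coh$gene_map, file.path(out_dir, "gene_map.tsv"))
      write_pheno_table(coh$pheno, file.path(out_dir, "pheno.tsv"))
      coh
    } else {
      read_cohort(config$paths$genotypes, config$paths$gene_map,
                  config$paths$pheno)
    }
  })

  qc <- stage("qc", apply_qc(cohort, config$call_rate_min, config$maf_min,
                             config$hwe_alpha))
  utils::write.table(qc$report, file.path(out_dir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cohort <- qc$cohort

  exposures <- config$exposures
  if (is.null(exposures)) exposures <- cohort$exposures
  fits <- list()
  perms <- list()
  for (ex in exposures) {
    fit <- stage(ex, gxe_brown(cohort, ex, covariates = config$covariates,
                               keller_terms = config$keller_terms,
                               min_snps = config$min_snps,
                               alpha = config$alpha,
                               signed_rho = config$signed_rho))
    fits[[ex]] <- fit
    utils::write.table(fit$scan, file.path(out_dir,
                                           paste0("scan_", ex, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gt <- fit$genes
    utils::write.table(gt, file.path(out_dir, paste0("genes_", ex, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(manhattan_table(fit),
                       file.path(out_dir, paste0("manhattan_", ex, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logmsg(sprintf("exposure %s: lambda=%.3f, %d significant gene(s)",
                   ex, fit$lambda, sum(gt$significant)))
    if (config$n_perm > 0) {
      pr <- stage(paste0(ex, "-perm"),
                  permutation_test(cohort, fit$spec, config$n_perm,
                                   strategy = config$perm_strategy,
                                   seed = config$seed,
                                   min_snps = config$min_snps,
                                   signed_rho = config$signed_rho))
      perms[[ex]] <- pr
      utils::write.table(pr, file.path(out_dir,
                                       paste0("perm_", ex, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(config$binary_exposure)) {
    bx <- config$binary_exposure
    fit <- stage(paste0(bx, "-binary"),
                 sensitivity_run(cohort, bx, method = "median_split",
                                 covariates = config$covariates,
                                 keller_terms = config$keller_terms,
                                 min_snps = config$min_snps,
                                 alpha = config$alpha,
                                 signed_rho = config$signed_rho))
    fits[[paste0(bx, "_binary")]] <- fit
    utils::write.table(fit$genes,
                       file.path(out_dir, paste0("genes_", bx,
                                                 "_binary.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    seed = config$seed,
    n_samples = nrow(cohort$genotypes),
    n_snps_in = nrow(qc$report),
    n_snps_kept = sum(qc$report$kept),
    exposures = lapply(fits, function(f) list(
      exposure = f$exposure,
      n_genes = f$n_genes,
      threshold = f$threshold,
      lambda = f$lambda,
      significant_genes = f$genes$gene_id[f$genes$significant])))
  yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"))
  logmsg("pipeline complete")
  invisible(list(qc = qc$report, fits = fits, perms = perms,
                 summary = summary))
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of \code{\link{run_config}}; the
#' \code{sim} block mirrors \code{\link{sim_config}} with \code{genes}
#' given either as a list of \code{(gene_id, n_snps, ld_rho, maf_range)}
#' entries or as a \code{panel} block passed to
#' \code{\link{default_gene_panel}}.
#'
#' @param path YAML file.
#' @return a \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$sim)) {
    s <- y$sim
    genes <- if (!is.null(s$panel)) do.call(default_gene_panel, s$panel)
             else lapply(s$genes, function(g) do.call(sim_gene, g))
    args <- list(genes = genes)
    if (!is.null(s$exposures)) args$exposures <-
      lapply(s$exposures, function(e) do.call(sim_exposure, e))
    for (f in c("n_individuals", "age_mean", "age_sd", "prob_male",
                "missing_rate", "seed"))
      if (!is.null(s[[f]])) args[[f]] <- s[[f]]
    if (!is.null(s$effect)) args$effect <- do.call(sim_effect, s$effect)
    sim <- do.call(sim_config, args)
  }
  args <- y[setdiff(names(y), "sim")]
  args$sim <- sim
  do.call(run_config, args)
}
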