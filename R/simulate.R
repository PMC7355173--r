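# Synthetic-cohort generator: block-LD genotypes in HWE, bounded skewed
# exposures, covariates and a linear phenotype with optional GxE signal.

#' Specify one simulated gene
#'
#' @param gene_id gene label.
#' @param n_snps number of SNPs in the gene (>= 1).
#' @param ld_rho latent AR(1) correlation between adjacent SNPs, in [0, 1].
#'   LD between SNPs i and j decays as \code{ld_rho^|i-j|} on the latent
#'   haplotype scale; the realized dosage correlation is attenuated by the
#'   allele-frequency thresholding.
#' @param maf_range minor-allele-frequency interval within (0, 0.5]; each
#'   SNP's MAF is drawn uniformly from it.
#' @return list of class \code{"sim_gene"}.
#' @export
sim_gene <- function(gene_id, n_snps, ld_rho = 0.6, maf_range = c(0.05, 0.5)) {
  stopifnot(length(n_snps) == 1, n_snps >= 1)
  if (ld_rho < 0 || ld_rho > 1) stop("ld_rho must be in [0, 1]")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an interval within (0, 0.5]")
  structure(list(gene_id = as.character(gene_id), n_snps = as.integer(n_snps),
                 ld_rho = ld_rho, maf_range = maf_range),
            class = "sim_gene")
}

#' Specify one simulated exposure dimension
#'
#' All exposures live on the 1--5 Likert scale. \code{bounded_normal} is a
#' Gaussian clipped to [1, 5]; \code{right_skewed} places a point mass at the
#' scale floor (1.0) and a gamma-shaped tail above it, so that the empirical
#' median can coincide with the minimum -- the structure of a rarely endorsed
#' harsh-parenting dimension.
#'
#' @param name exposure name (column name in the phenotype table).
#' @param distribution \code{"bounded_normal"} or \code{"right_skewed"}.
#' @param mean,sd location/scale of the Gaussian (bounded_normal only).
#' @param floor_mass probability of the exact floor value 1.0
#'   (right_skewed only; default 0.55 so the median equals the floor).
#' @param shape,scale gamma parameters for the positive part above the floor
#'   (right_skewed only).
#' @return list of class \code{"sim_exposure"}.
#' @export
sim_exposure <- function(name,
                         distribution = c("bounded_normal", "right_skewed"),
                         mean = 3, sd = 0.8,
                         floor_mass = 0.55, shape = 1.2, scale = 0.9) {
  distribution <- match.arg(distribution)
  if (floor_mass < 0 || floor_mass > 1) stop("floor_mass must be in [0, 1]")
  if (sd < 0) stop("sd must be non-negative")
  structure(list(name = name, distribution = distribution, mean = mean,
                 sd = sd, floor_mass = floor_mass, shape = shape,
                 scale = scale),
            class = "sim_exposure")
}

#' Specify the phenotype effect structure
#'
#' The symptom score is generated as
#' \deqn{y = \beta_0 + \sum_j (\beta_g g_j + \beta_{gxe} g_j e) +
#'   \beta_e e + \beta_{age} age + \beta_{sex} sex + \epsilon,\quad
#'   \epsilon \sim N(0, \sigma^2)}
#' where the genetic sums run over the SNPs of \code{target_gene} (none if
#' \code{NULL}) and \eqn{e} is the exposure named in \code{exposure}.
#'
#' @param target_gene gene id carrying the genetic effects, or \code{NULL}
#'   for a fully null genome.
#' @param exposure name of the exposure entering the main and interaction
#'   effects (default: the first configured exposure).
#' @param beta_g,beta_e,beta_gxe,beta_age,beta_sex regression coefficients.
#' @param intercept baseline symptom score.
#' @param noise_sd residual standard deviation (> 0).
#' @return list of class \code{"sim_effect"}.
#' @export
sim_effect <- function(target_gene = NULL, exposure = NULL,
                       beta_g = 0, beta_e = 0, beta_gxe = 0,
                       beta_age = 0, beta_sex = 0,
                       intercept = 2.2, noise_sd = 0.6) {
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  structure(list(target_gene = target_gene, exposure = exposure,
                 beta_g = beta_g, beta_e = beta_e, beta_gxe = beta_gxe,
                 beta_age = beta_age, beta_sex = beta_sex,
                 intercept = intercept, noise_sd = noise_sd),
            class = "sim_effect")
}

#' Draw a default panel of gene specifications
#'
#' Convenience generator of a desk-scale gene panel: SNP counts uniform on
#' \code{n_snps_range}, latent adjacent-SNP correlations uniform on
#' \code{ld_rho_range}, MAF interval shared by all genes. Deterministic
#' given \code{seed}.
#'
#' @param n_genes number of genes.
#' @param n_snps_range integer range of SNPs per gene.
#' @param ld_rho_range range of the per-gene latent AR(1) correlation.
#' @param maf_range minor-allele-frequency interval.
#' @param seed RNG seed for the panel draw.
#' @return list of \code{\link{sim_gene}} objects.
#' @export
default_gene_panel <- function(n_genes = 50, n_snps_range = c(2L, 8L),
                               ld_rho_range = c(0.3, 0.9),
                               maf_range = c(0.05, 0.5), seed = 1L) {
  stopifnot(n_genes >= 1)
  kpool <- seq.int(n_snps_range[1], n_snps_range[2])
  rs <- .with_seed(seed, {
    list(k = kpool[sample.int(length(kpool), n_genes, replace = TRUE)],
         rho = stats::runif(n_genes, ld_rho_range[1], ld_rho_range[2]))
  })
  lapply(seq_len(n_genes), function(i)
    sim_gene(sprintf("gene%03d", i), rs$k[i], rs$rho[i], maf_range))
}

#' Full parameterization of a synthetic cohort
#'
#' Defaults mirror the cohort structure the analysis is designed for:
#' 948 adolescents, age ~ N(13.78, 0.92^2), 50.5\% male, five parenting
#' dimensions on a 1--5 scale with one strongly right-skewed dimension
#' (harsh punitive control), and a continuous symptom score.
#'
#' @param n_individuals cohort size.
#' @param genes list of \code{\link{sim_gene}} specifications.
#' @param exposures list of \code{\link{sim_exposure}} specifications.
#' @param age_mean,age_sd age distribution (years).
#' @param prob_male probability of sex = 1.
#' @param effect \code{\link{sim_effect}} specification.
#' @param missing_rate fraction of dosages set missing completely at random
#'   (default 0; used to exercise call-rate QC).
#' @param seed integer seed; the same configuration and seed always yield a
#'   bit-identical cohort.
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_individuals = 948L,
                       genes = default_gene_panel(),
                       exposures = list(
                         sim_exposure("support", "bounded_normal", 3.8, 0.6),
                         sim_exposure("proactive_control", "bounded_normal", 3.2, 0.7),
                         sim_exposure("psychological_control", "bounded_normal", 2.0, 0.7),
                         sim_exposure("punitive_control", "bounded_normal", 1.9, 0.7),
                         sim_exposure("harsh_punitive_control", "right_skewed")),
                       age_mean = 13.78, age_sd = 0.92,
                       prob_male = 0.505,
                       effect = sim_effect(),
                       missing_rate = 0,
                       seed = 1L) {
  if (n_individuals < 1) stop("n_individuals must be a positive count")
  if (prob_male < 0 || prob_male > 1) stop("prob_male must be in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (age_sd < 0) stop("age_sd must be non-negative")
  if (!length(genes)) stop("at least one gene must be specified")
  genes <- lapply(genes, function(g) {
    if (!inherits(g, "sim_gene")) stop("genes must be sim_gene objects")
    g
  })
  exposures <- lapply(exposures, function(e) {
    if (!inherits(e, "sim_exposure")) stop("exposures must be sim_exposure objects")
    e
  })
  if (is.null(effect$exposure)) effect$exposure <- exposures[[1]]$name
  enames <- vapply(exposures, `[[`, "", "name")
  if (anyDuplicated(enames)) stop("duplicate exposure names")
  if (!effect$exposure %in% enames)
    stop("effect exposure '", effect$exposure, "' is not a configured exposure")
  if (!is.null(effect$target_gene) &&
      !effect$target_gene %in% vapply(genes, `[[`, "", "gene_id"))
    stop("effect target_gene is not a configured gene")
  structure(list(n_individuals = as.integer(n_individuals), genes = genes,
                 exposures = exposures, age_mean = age_mean, age_sd = age_sd,
                 prob_male = prob_male, effect = effect,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# evaluate expr under a private RNG state, restoring the caller's
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate block-LD genotypes in Hardy--Weinberg equilibrium
#'
#' Each individual receives two independent haplotypes per gene. A haplotype
#' is a thresholded draw from a latent Gaussian vector with AR(1) correlation
#' \code{ld_rho} across the gene's SNPs; the threshold is the normal quantile
#' of the SNP's MAF, so the marginal allele frequency equals the MAF exactly
#' and dosages (haplotype sums) are in HWE by construction.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{genotypes} (sample x SNP dosage matrix) and
#'   \code{gene_map} (data frame \code{snp_id}, \code{gene_id}, \code{chrom},
#'   \code{pos}).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  .with_seed(config$seed, {
    blocks <- vector("list", length(config$genes))
    maps <- vector("list", length(config$genes))
    pos0 <- 0L
    for (i in seq_along(config$genes)) {
      g <- config$genes[[i]]
      k <- g$n_snps
      maf <- stats::runif(k, g$maf_range[1], g$maf_range[2])
      thr <- stats::qnorm(maf)
      if (g$ld_rho >= 1 - 1e-12) {
        z <- matrix(stats::rnorm(2L * n), 2L * n, 1L)[, rep(1L, k), drop = FALSE]
      } else if (g$ld_rho <= 0) {
        z <- matrix(stats::rnorm(2L * n * k), 2L * n, k)
      } else {
        R <- g$ld_rho^abs(outer(seq_len(k), seq_len(k), "-"))
        z <- matrix(stats::rnorm(2L * n * k), 2L * n, k) %*% chol(R)
      }
      hap <- z < rep(thr, each = 2L * n)      # allele indicator, P = maf
      dos <- hap[seq_len(n), , drop = FALSE] +
        hap[n + seq_len(n), , drop = FALSE]
      storage.mode(dos) <- "double"
      snp_ids <- sprintf("%s_snp%02d", g$gene_id, seq_len(k))
      colnames(dos) <- snp_ids
      blocks[[i]] <- dos
      maps[[i]] <- data.frame(snp_id = snp_ids, gene_id = g$gene_id,
                              chrom = ((i - 1L) %% 22L) + 1L,
                              pos = pos0 + seq_len(k) * 1000L,
                              stringsAsFactors = FALSE)
      pos0 <- pos0 + k * 1000L + 100000L
    }
    genotypes <- do.call(cbind, blocks)
    rownames(genotypes) <- sprintf("S%05d", seq_len(n))
    list(genotypes = genotypes, gene_map = do.call(rbind, maps))
  })
}

#' Simulate exposures and covariates
#'
#' @param config a \code{\link{sim_config}}.
#' @return data frame with \code{sample_id}, one column per exposure,
#'   \code{age}, \code{sex}. Exposure values never leave [1, 5].
#' @export
simulate_exposures_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  .with_seed(config$seed + 1L, {
    out <- data.frame(sample_id = sprintf("S%05d", seq_len(n)),
                      stringsAsFactors = FALSE)
    for (ex in config$exposures) {
      v <- if (ex$distribution == "bounded_normal") {
        pmin(pmax(stats::rnorm(n, ex$mean, ex$sd), 1), 5)
      } else {
        at_floor <- stats::runif(n) < ex$floor_mass
        v <- 1 + stats::rgamma(n, shape = ex$shape, scale = ex$scale)
        v[at_floor] <- 1
        pmin(v, 5)
      }
      out[[ex$name]] <- v
    }
    out$age <- stats::rnorm(n, config$age_mean, config$age_sd)
    out$sex <- as.numeric(stats::runif(n) < config$prob_male)
    out
  })
}

#' Simulate the symptom score
#'
#' Applies the linear data-generating model of \code{\link{sim_effect}} to
#' sample-aligned genotypes, exposures and covariates. When a target gene is
#' set, its per-SNP genetic main effects and interactions are summed.
#'
#' @param genotypes sample x SNP dosage matrix (complete for the target gene).
#' @param gene_map SNP-to-gene map (needed only when a target gene is set).
#' @param pheno data frame with the exposures, \code{age} and \code{sex}.
#' @param effect a \code{\link{sim_effect}}.
#' @param seed RNG seed for the residual noise.
#' @return numeric symptom-score vector, one value per sample.
#' @export
simulate_phenotype <- function(genotypes, gene_map, pheno, effect, seed) {
  stopifnot(inherits(effect, "sim_effect"))
  n <- nrow(pheno)
  if (!is.null(genotypes) && nrow(genotypes) != n)
    stop("genotypes and phenotype table are not sample-aligned")
  e <- pheno[[effect$exposure]]
  if (is.null(e)) stop("exposure '", effect$exposure, "' not found")
  mu <- effect$intercept + effect$beta_e * e +
    effect$beta_age * pheno$age + effect$beta_sex * pheno$sex
  if (!is.null(effect$target_gene)) {
    snps <- gene_map$snp_id[gene_map$gene_id == effect$target_gene]
    if (!length(snps)) stop("target gene has no SNPs in the gene map")
    G <- genotypes[, snps, drop = FALSE]
    if (anyNA(G)) stop("target-gene dosages must be complete")
    mu <- mu + effect$beta_g * rowSums(G) + effect$beta_gxe * rowSums(G * e)
  }
  .with_seed(seed, mu + stats::rnorm(n, 0, effect$noise_sd))
}

#' Simulate a complete cohort
#'
#' Runs genotype, exposure/covariate and phenotype generation under the
#' configuration's seed and assembles a \code{\link{cohort_data}}. Missing
#' dosages (if \code{missing_rate > 0}) are injected after the phenotype is
#' generated, so the phenotype always reflects the true genotypes.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{\link{cohort_data}}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gen <- simulate_genotypes(config)
  pheno <- simulate_exposures_covariates(config)
  pheno$symptom_score <- simulate_phenotype(gen$genotypes, gen$gene_map,
                                            pheno, config$effect,
                                            seed = config$seed + 2L)
  if (config$missing_rate > 0) {
    gen$genotypes[] <- .with_seed(config$seed + 3L, {
      m <- stats::runif(length(gen$genotypes)) < config$missing_rate
      gg <- gen$genotypes
      gg[m] <- NA_real_
      gg
    })
  }
  enames <- vapply(config$exposures, `[[`, "", "name")
  cohort_data(gen$genotypes, gen$gene_map, pheno, exposures = enames)
}

#' Calibrate an interaction effect size for a target power
#'
#' Returns the interaction coefficient \code{beta_gxe} at which a single
#' SNP of the target gene, analysed alone with the standard scan model,
#' reaches approximately the requested two-sided power at the configured
#' cohort size. The residual standard deviation of the g:e design column
#' (after projection on the remaining columns) is estimated once from a
#' large calibration cohort drawn under the same generator settings; the
#' normal approximation \eqn{ncp = z_{1-\alpha/2} + z_{power}} then gives
#' \eqn{\beta = ncp\,\sigma / (s_{g:e}\sqrt{n})}.
#'
#' @param config a \code{\link{sim_config}} whose effect names the target
#'   gene and exposure.
#' @param power target per-SNP power (default 0.8).
#' @param alpha two-sided test level (default 0.05).
#' @param n_cal calibration cohort size (default 20000).
#' @param seed seed of the calibration draw.
#' @return the calibrated \code{beta_gxe}.
#' @export
calibrate_gxe_effect <- function(config, power = 0.8, alpha = 0.05,
                                 n_cal = 20000L, seed = 424242L) {
  stopifnot(inherits(config, "sim_config"))
  target <- config$effect$target_gene
  if (is.null(target)) stop("config$effect must name a target_gene")
  big <- config
  big$n_individuals <- as.integer(n_cal)
  big$seed <- as.integer(seed)
  big$genes <- Filter(function(g) g$gene_id == target, config$genes)
  big$missing_rate <- 0
  big$effect <- sim_effect(exposure = config$effect$exposure,
                           intercept = config$effect$intercept,
                           noise_sd = config$effect$noise_sd)
  coh <- simulate_cohort(big)
  spec <- scan_spec(config$effect$exposure)
  g <- coh$genotypes[, 1]
  e <- coh$pheno[[spec$exposure]]
  C <- as.matrix(coh$pheno[, spec$covariates, drop = FALSE])
  des <- build_design(g, e, C, spec)
  X <- des$X
  j <- des$gxe_col
  other <- X[, -j, drop = FALSE]
  resid <- X[, j] - other %*% solve(crossprod(other),
                                    crossprod(other, X[, j]))
  s_ge <- sqrt(sum(resid^2) / nrow(X))
  ncp <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  ncp * config$effect$noise_sd / (s_ge * sqrt(config$n_individuals))
}
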