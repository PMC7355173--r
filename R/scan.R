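# Per-SNP linear GxE interaction scan: y ~ g + e + g:e + covariates
# (optionally + covariate:g + covariate:e), OLS with a Student-t p-value on
# the interaction coefficient.

#' Scan model specification
#'
#' @param exposure name of the exposure column used as E.
#' @param covariates covariate column names adjusted for (default age and
#'   sex).
#' @param keller_terms also include covariate-by-G and covariate-by-E
#'   product terms (default \code{TRUE}); recommended so that a confounder
#'   of the interaction cannot masquerade as G\eqn{\times}{x}E.
#' @param min_nonmissing minimum number of complete-case rows required to
#'   fit a SNP (default 30).
#' @return list of class \code{"scan_spec"}.
#' @export
scan_spec <- function(exposure, covariates = c("age", "sex"),
                      keller_terms = TRUE, min_nonmissing = 30L) {
  if (exposure %in% covariates)
    stop("exposure and covariates must be distinct columns")
  structure(list(exposure = exposure, covariates = covariates,
                 keller_terms = isTRUE(keller_terms),
                 min_nonmissing = as.integer(min_nonmissing)),
            class = "scan_spec")
}

#' Build the per-SNP design matrix
#'
#' Columns: intercept, g, e, g:e, covariates, and (with
#' \code{keller_terms}) covariate-by-g and covariate-by-e products. Rows
#' with any missing value among y, g, e or the covariates are dropped
#' (complete-case per SNP).
#'
#' @param g dosage vector.
#' @param e exposure vector.
#' @param covariates data frame (or matrix) of covariate columns.
#' @param spec a \code{\link{scan_spec}}.
#' @param y optional outcome vector included in the completeness mask.
#' @return list with \code{X} (design matrix on complete rows),
#'   \code{mask} (logical used-sample mask), \code{gxe_col} (index of the
#'   g:e column), \code{degenerate} (TRUE when fewer than
#'   \code{min_nonmissing} complete rows remain).
#' @export
build_design <- function(g, e, covariates, spec, y = NULL) {
  C <- as.matrix(covariates)
  mask <- !is.na(g) & !is.na(e) & stats::complete.cases(C)
  if (!is.null(y)) mask <- mask & !is.na(y)
  if (sum(mask) < spec$min_nonmissing)
    return(list(X = NULL, mask = mask, gxe_col = NA_integer_,
                degenerate = TRUE))
  gm <- g[mask]; em <- e[mask]; Cm <- C[mask, , drop = FALSE]
  X <- cbind(1, gm, em, gm * em, Cm)
  cn <- c("(Intercept)", "g", "e", "g:e", colnames(C))
  if (spec$keller_terms && ncol(C)) {
    X <- cbind(X, Cm * gm, Cm * em)
    cn <- c(cn, paste0(colnames(C), ":g"), paste0(colnames(C), ":e"))
  }
  colnames(X) <- cn
  list(X = X, mask = mask, gxe_col = 4L, degenerate = FALSE)
}

# OLS fit returning the g:e coefficient, its SE, t and two-sided p.
# Rank deficiency is detected by a relative singular-value tolerance.
.fit_design <- function(y, X, gxe_col, sv_tol = 1e-10) {
  n <- nrow(X); q <- ncol(X)
  if (n <= q) return(NULL)
  d <- svd(X, nu = 0, nv = 0)$d
  if (d[length(d)] < sv_tol * d[1]) return(NULL)
  XtX <- crossprod(X)
  A <- chol2inv(chol(XtX))
  Xty <- crossprod(X, y)
  beta <- drop(A %*% Xty)
  rss <- sum(y^2) - sum(beta * Xty)
  df <- n - q
  s2 <- max(rss, 0) / df
  se <- sqrt(s2 * diag(A))
  tval <- beta / se
  list(beta = beta[gxe_col], se = se[gxe_col], t = tval[gxe_col],
       p = 2 * stats::pt(-abs(tval[gxe_col]), df), df = df, n = n,
       A = A, coef = beta)
}

#' Fit the interaction model for one SNP
#'
#' Ordinary least squares on the design from \code{\link{build_design}};
#' the two-sided p-value of the g:e coefficient comes from a Student-t with
#' \code{n_used - n_columns} degrees of freedom. A rank-deficient design
#' (monomorphic SNP, constant exposure, ...) yields status
#' \code{"skipped_degenerate"}.
#'
#' @param y outcome vector (full length; the design's mask is applied).
#' @param design result of \code{\link{build_design}}.
#' @param snp_id,gene_id labels copied into the result.
#' @return one-row data frame: \code{snp_id}, \code{gene_id},
#'   \code{n_used}, \code{beta_gxe}, \code{se}, \code{t}, \code{p},
#'   \code{status}.
#' @export
fit_snp_interaction <- function(y, design, snp_id = "snp", gene_id = NA) {
  skip <- function(n) data.frame(
    snp_id = snp_id, gene_id = gene_id, n_used = n,
    beta_gxe = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
    status = "skipped_degenerate", stringsAsFactors = FALSE)
  if (design$degenerate) return(skip(sum(design$mask)))
  ym <- y[design$mask]
  fit <- .fit_design(ym, design$X, design$gxe_col)
  if (is.null(fit)) return(skip(nrow(design$X)))
  data.frame(snp_id = snp_id, gene_id = gene_id, n_used = fit$n,
             beta_gxe = fit$beta, se = fit$se, t = fit$t,
             p = max(fit$p, .Machine$double.xmin), status = "ok",
             stringsAsFactors = FALSE)
}

#' Scan every SNP of a cohort for G\eqn{\times}{x}E interaction
#'
#' @param cohort a QC-passed \code{\link{cohort_data}}.
#' @param spec a \code{\link{scan_spec}}.
#' @return data frame of class \code{"gxe_scan"}, one row per mapped SNP in
#'   genotype-column order; degenerate SNPs carry status
#'   \code{"skipped_degenerate"} and are excluded from pooling downstream.
#' @export
scan_gxe <- function(cohort, spec) {
  stopifnot(inherits(cohort, "cohort_data"), inherits(spec, "scan_spec"))
  ph <- cohort$pheno
  e <- ph[[spec$exposure]]
  if (is.null(e)) stop("exposure '", spec$exposure, "' not in pheno table")
  miss_cov <- setdiff(spec$covariates, names(ph))
  if (length(miss_cov)) stop("covariate(s) not in pheno table: ",
                             paste(miss_cov, collapse = ", "))
  C <- as.matrix(ph[, spec$covariates, drop = FALSE])
  y <- ph$symptom_score
  snp_ids <- colnames(cohort$genotypes)
  snp_ids <- snp_ids[snp_ids %in% cohort$gene_map$snp_id]
  gene_of <- cohort$gene_map$gene_id[match(snp_ids, cohort$gene_map$snp_id)]
  rows <- vector("list", length(snp_ids))
  for (i in seq_along(snp_ids)) {
    g <- cohort$genotypes[, snp_ids[i]]
    des <- build_design(g, e, C, spec, y = y)
    rows[[i]] <- fit_snp_interaction(y, des, snp_id = snp_ids[i],
                                     gene_id = gene_of[i])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gxe_scan", class(out))
  attr(out, "spec") <- spec
  out
}

# Precompute per-SNP design inverses for the fast phenotype-permutation
# path. Requires a complete outcome vector (mask independent of y).
.scan_prep <- function(cohort, spec) {
  ph <- cohort$pheno
  e <- ph[[spec$exposure]]
  C <- as.matrix(ph[, spec$covariates, drop = FALSE])
  snp_ids <- colnames(cohort$genotypes)
  snp_ids <- snp_ids[snp_ids %in% cohort$gene_map$snp_id]
  gene_of <- cohort$gene_map$gene_id[match(snp_ids, cohort$gene_map$snp_id)]
  prep <- vector("list", length(snp_ids))
  for (i in seq_along(snp_ids)) {
    g <- cohort$genotypes[, snp_ids[i]]
    des <- build_design(g, e, C, spec)
    if (des$degenerate) next
    X <- des$X
    d <- svd(X, nu = 0, nv = 0)$d
    if (d[length(d)] < 1e-10 * d[1]) next
    A <- chol2inv(chol(crossprod(X)))
    prep[[i]] <- list(Xt = t(X), A = A, a_jj = A[des$gxe_col, des$gxe_col],
                      j = des$gxe_col, mask = des$mask,
                      df = nrow(X) - ncol(X))
  }
  list(snp_ids = snp_ids, gene_of = gene_of, prep = prep)
}

# p-value matrix (SNP x B) for B outcome columns Y under precomputed designs
.scan_fast <- function(sp, Y) {
  m <- length(sp$snp_ids)
  B <- ncol(Y)
  P <- matrix(NA_real_, m, B)
  for (i in seq_len(m)) {
    pr <- sp$prep[[i]]
    if (is.null(pr)) next
    Ym <- Y[pr$mask, , drop = FALSE]
    XtY <- pr$Xt %*% Ym
    Bmat <- pr$A %*% XtY
    rss <- colSums(Ym^2) - colSums(Bmat * XtY)
    s2 <- pmax(rss, 0) / pr$df
    tv <- Bmat[pr$j, ] / sqrt(s2 * pr$a_jj)
    P[i, ] <- 2 * stats::pt(-abs(tv), pr$df)
  }
  P[P < .Machine$double.xmin] <- .Machine$double.xmin
  P
}
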