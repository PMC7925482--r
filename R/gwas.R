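# Spectral two-component REML: y = Xb + u + e, u ~ N(0, K s2u), e ~ N(0, s2e I).
# Eigendecomposition of K reduces the restricted likelihood to a 1-D profile
# in the variance ratio lambda = s2u / s2e.
spectral_reml <- function(y, X, K, ridge = 1e-6) {
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(K) == n)
  if (qr(X)$rank < ncol(X)) stop("covariates are collinear")
  eig <- eigen((K + t(K)) / 2 + diag(ridge, n), symmetric = TRUE)
  if (min(eig$values) < -1e-6) stop("kinship matrix is not PSD after ridge")
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  p <- ncol(X)
  rll <- function(log_lambda) {
    lam <- exp(log_lambda)
    w <- 1 / (lam * d + 1)
    XtW <- Xt * w
    XX <- crossprod(Xt, XtW)
    Xy <- crossprod(XtW, yt)
    beta <- solve(XX, Xy)
    r <- yt - Xt %*% beta
    rss <- sum(w * r^2)
    s2e <- rss / (n - p)
    -0.5 * ((n - p) * log(2 * pi * s2e) + sum(log(lam * d + 1)) +
              determinant(XX, logarithm = TRUE)$modulus[1] + (n - p))
  }
  opt <- optimize(rll, interval = c(-12, 12), maximum = TRUE, tol = 1e-8)
  lam <- exp(opt$maximum)
  w <- 1 / (lam * d + 1)
  XtW <- Xt * w
  XX <- crossprod(Xt, XtW)
  beta <- solve(XX, crossprod(XtW, yt))
  r <- yt - Xt %*% beta
  s2e <- sum(w * r^2) / (n - p)
  list(lambda = lam, sigma2_u = lam * s2e, sigma2_e = s2e,
       beta = as.numeric(beta), U = U, d = d, yt = as.numeric(yt), Xt = Xt,
       loglik = opt$objective, rll = rll, eigK = eig)
}

#' Fit the null mixed linear model for association scanning
#'
#' REML fit of `y = Xb + u + e` with `u ~ N(0, K sigma2_u)` via
#' eigendecomposition of the kinship matrix and one-dimensional optimization
#' of the variance ratio; the spectral rotation is cached so the subsequent
#' per-marker scan (P3D: variance components fixed at the null estimates) is
#' a set of weighted regressions.
#'
#' @param y named line-level response (e.g. BLUPs), aligned with `K`.
#' @param covariates optional matrix of covariates (e.g. PC scores); an
#'   intercept is always added.
#' @param K kinship / genomic relationship matrix.
#' @param ridge diagonal ridge added to `K` before decomposition.
#' @return List of class `mlm_null`: variance components `sigma2_u`,
#'   `sigma2_e`, ratio `lambda_e_u` (= sigma2_e / sigma2_u), restricted
#'   log-likelihood, profile function `rll(log_ratio)`, and the spectral
#'   cache.
#' @export
fit_null_mlm <- function(y, covariates = NULL, K, ridge = 1e-6) {
  if (!is.null(names(y)) && !is.null(rownames(K))) {
    stopifnot(all(names(y) %in% rownames(K)))
    K <- K[names(y), names(y)]
  }
  X <- cbind(`(Intercept)` = rep(1, length(y)), covariates)
  fit <- spectral_reml(y, X, K, ridge)
  structure(c(fit, list(lambda_e_u = 1 / fit$lambda, n = length(y))),
            class = "mlm_null")
}

#' Single-marker association scan
#'
#' Per-marker generalized-least-squares t-test of the additive dosage
#' effect. `method = "MLM"` uses the spectral cache of a fitted null model
#' (P3D: the variance ratio is fixed from the null fit; the residual
#' variance of each marker model is re-estimated from its own residual sum
#' of squares, so with `K = I` the test reduces exactly to ordinary
#' regression). `method = "GLM"` is the same test with the kinship omitted
#' (structure correction through the covariates only).
#'
#' @param y named line-level response.
#' @param geno imputed [geno_matrix()] over the same lines.
#' @param covariates optional covariate matrix (PC scores).
#' @param K kinship matrix (MLM only).
#' @param method `"MLM"` or `"GLM"`.
#' @param null optional pre-fitted [fit_null_mlm()] object to reuse.
#' @return data.frame of class `gwas_result`: `marker`, `chrom`, `pos`,
#'   `maf`, `beta` (alt-dosage effect), `se`, `p`; attributes `method`,
#'   `lambda_e_u`, `n_pcs`, `skipped` (zero-variance markers).
#' @export
gwas_scan <- function(y, geno, covariates = NULL, K = NULL,
                      method = c("MLM", "GLM"), null = NULL) {
  method <- match.arg(method)
  ids <- names(y)
  if (is.null(ids)) stop("y must be named by line id")
  stopifnot(all(ids %in% line_ids(geno)))
  M <- impute_dosage(geno[ids, ]$values)
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  p <- ncol(X)
  if (method == "MLM") {
    if (is.null(null)) {
      if (is.null(K)) stop("MLM requires K or a pre-fitted null model")
      null <- fit_null_mlm(y, covariates, K)
    }
    w <- 1 / (null$lambda * null$d + 1)
    sw <- sqrt(w)
    ys <- null$yt * sw
    Xs <- null$Xt * sw
    Ms <- crossprod(null$U, M) * sw
  } else {
    ys <- y
    Xs <- X
    Ms <- M
  }
  # residualize on the covariates once
  qrX <- qr(Xs)
  ry <- qr.resid(qrX, ys)
  rM <- qr.resid(qrX, Ms)
  Smm <- colSums(rM^2)
  skipped <- Smm < 1e-10
  Smy <- colSums(rM * ry)
  beta <- Smy / Smm
  rss <- sum(ry^2) - beta * Smy
  df <- n - p - 1L
  s2 <- rss / df
  se <- sqrt(s2 / Smm)
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df = df, lower.tail = FALSE)
  freq <- colMeans(M) / 2
  out <- data.frame(marker = geno$map$marker, chrom = geno$map$chrom,
                    pos = geno$map$pos, maf = pmin(freq, 1 - freq),
                    beta = beta, se = se, p = pval)
  out[skipped, c("beta", "se", "p")] <- NA
  attr(out, "alt_freq") <- freq
  attr(out, "method") <- method
  attr(out, "lambda_e_u") <- if (method == "MLM") null$lambda_e_u else NA_real_
  attr(out, "n_pcs") <- if (is.null(covariates)) 0L else ncol(covariates)
  attr(out, "skipped") <- sum(skipped)
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Genomic-control inflation factor
#'
#' Median chi-square statistic of the scan divided by the null median; 1
#' indicates a well-calibrated test.
#'
#' @param res a [gwas_scan()] result (or numeric p-values).
#' @return lambda_GC (scalar).
#' @export
lambda_gc <- function(res) {
  p <- if (is.data.frame(res)) res$p else res
  p <- p[!is.na(p)]
  stats::median(qnorm(p / 2)^2) / stats::qchisq(0.5, 1)
}

#' Quantile-quantile table for a scan
#'
#' @param res a [gwas_scan()] result.
#' @return data.frame `expected`, `observed` (-log10 p, both sorted
#'   ascending).
#' @export
qq_table <- function(res) {
  p <- sort(res$p[!is.na(res$p)], decreasing = TRUE)
  data.frame(expected = -log10(sort(ppoints(length(p)), decreasing = TRUE)),
             observed = -log10(p))
}

#' Select significant association hits
#'
#' Markers with p strictly below the trait-appropriate threshold, with the
#' effect re-oriented to the minor allele.
#'
#' @param res a [gwas_scan()] result (needs a `geno` for allele labels only
#'   if `alleles` supplied).
#' @param threshold significance threshold (e.g. `2e-6` for the resistance
#'   traits, `5.6e-6` for yield, or `alpha / n_effective_tests` from
#'   [ld_decay()]).
#' @param alleles optional data.frame `ref`, `alt` per marker.
#' @return data.frame: `snp`, `chrom`, `pos`, `p`, `effect_minor` (effect of
#'   the minor allele), `maf`, `alleles` (minor/major).
#' @export
significant_hits <- function(res, threshold = 2e-6, alleles = NULL) {
  sel <- !is.na(res$p) & res$p < threshold
  d <- res[sel, , drop = FALSE]
  if (nrow(d) == 0)
    return(data.frame(snp = character(), chrom = integer(), pos = integer(),
                      p = numeric(), effect_minor = numeric(), maf = numeric(),
                      alleles = character()))
  # beta is the alt-dosage effect; flip the sign when alt is the major allele
  freq <- attr(res, "alt_freq")
  freq <- if (is.null(freq)) d$maf else freq[sel]   # unknown: alt already minor
  alt_is_minor <- freq <= 0.5
  eff <- ifelse(alt_is_minor, d$beta, -d$beta)
  lab <- if (!is.null(alleles)) {
    a <- alleles[sel, , drop = FALSE]
    ifelse(alt_is_minor, paste0(a$alt, "/", a$ref), paste0(a$ref, "/", a$alt))
  } else NA_character_
  data.frame(snp = paste0("S", d$chrom, "_", d$pos), chrom = d$chrom,
             pos = d$pos, p = d$p, effect_minor = eff, maf = d$maf,
             alleles = lab, row.names = NULL)
}

#' Variance explained by the detected hits
#'
#' Adjusted R-squared of the joint ordinary regression of the response on
#' all hit dosages (aliased columns dropped), and the fraction of genotypic
#' variance explained, `p_G = R2_adj / h2` (flagged when > 1).
#'
#' @param y named line-level response.
#' @param hits a [significant_hits()] table (column `snp`).
#' @param geno imputed [geno_matrix()] providing the hit dosages.
#' @param h2 entry-mean heritability of the response.
#' @return List: `R2_adj`, `p_G`, `n_hits_fitted`, `flagged`.
#' @export
variance_explained <- function(y, hits, geno, h2) {
  if (is.null(hits) || nrow(hits) == 0)
    return(list(R2_adj = 0, p_G = 0, n_hits_fitted = 0L, flagged = FALSE))
  sel <- match(hits$snp, geno$map$marker)
  if (anyNA(sel)) stop("hit markers absent from the genotype matrix")
  M <- impute_dosage(geno[names(y), sel]$values)
  if (ncol(M) >= length(y)) stop("more hits than lines: joint fit is unidentified")
  fit <- lm(y ~ M)
  r2 <- max(0, summary(fit)$adj.r.squared)
  n_fitted <- sum(!is.na(coef(fit))) - 1L
  pg <- r2 / h2
  list(R2_adj = r2, p_G = pg, n_hits_fitted = n_fitted, flagged = pg > 1)
}
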