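# ---- REML engines -----------------------------------------------------------

# maximize a restricted log-likelihood over 1 or 2 log-variance-ratio params
optim_reml <- function(rll, npar) {
  if (npar == 1L) {
    o <- optimize(rll, c(-12, 12), maximum = TRUE, tol = 1e-8)
    list(par = o$maximum, value = o$objective, convergence = 0L)
  } else {
    optim(rep(log(0.5), npar), rll, method = "Nelder-Mead",
          control = list(fnscale = -1, maxit = 500, reltol = 1e-10))
  }
}

# Multi-environment REML on balanced line x environment data via double
# diagonalization: eigenvectors of G across lines, and the mean/contrast
# rotation across environments. Model (env means fixed):
#   y_le = E_e + g_l + ge_le + eps,  g ~ N(0, G s2G), ge ~ N(0, (G x I) s2GE)
# In the rotated basis the covariance is diagonal with elements
#   v = s2e * (1 + gG * E * d_j * [mean dir] + gGE * d_j).
reml_multienv_balanced <- function(Y, G, model = c("G+GE", "G"), ridge = 1e-6) {
  model <- match.arg(model)
  L <- nrow(Y); E <- ncol(Y)
  stopifnot(E >= 2, !anyNA(Y))
  eig <- eigen((G + t(G)) / 2 + diag(ridge, L), symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  H <- qr.Q(qr(cbind(rep(1 / sqrt(E), E), diag(E))))[, seq_len(E)]
  yt <- as.vector(crossprod(U, Y) %*% H)        # ordered (rotated env c) blocks
  a <- as.numeric(crossprod(U, rep(1, L)))
  Xt <- kronecker(t(H), matrix(a, ncol = 1))    # columns = original env means
  is_mean <- rep(seq_len(E) == 1L, each = L)    # block c = 1 carries the mean dir
  dvec <- rep(d, E)
  n <- L * E; p <- E
  rll <- function(par) {
    gG <- exp(par[1]); gGE <- if (model == "G+GE") exp(par[2]) else 0
    v <- 1 + gGE * dvec + gG * E * dvec * is_mean
    w <- 1 / v
    XtW <- Xt * w
    XX <- crossprod(Xt, XtW)
    beta <- solve(XX, crossprod(XtW, yt))
    r <- yt - Xt %*% beta
    rss <- sum(w * r^2)
    s2e <- rss / (n - p)
    -0.5 * ((n - p) * (log(2 * pi * s2e) + 1) + sum(log(v)) +
              determinant(XX, logarithm = TRUE)$modulus[1])
  }
  npar <- if (model == "G+GE") 2L else 1L
  opt <- optim_reml(rll, npar)
  gG <- exp(opt$par[1]); gGE <- if (model == "G+GE") exp(opt$par[2]) else 0
  v <- 1 + gGE * dvec + gG * E * dvec * is_mean
  w <- 1 / v
  XtW <- Xt * w
  XX <- crossprod(Xt, XtW)
  beta <- as.numeric(solve(XX, crossprod(XtW, yt)))
  r <- yt - Xt %*% beta
  s2e <- sum(w * r^2) / (n - p)
  names(beta) <- colnames(Y)
  list(sigma2_G = gG * s2e, sigma2_GE = gGE * s2e, sigma2_e = s2e,
       env_means = beta, loglik = opt$value, converged = opt$convergence == 0,
       model = model)
}

# Dense REML for (possibly unbalanced) observed cells. obs: data.frame with
# integer line index `l` (into G), env factor `env`, response `y`.
reml_multienv_dense <- function(obs, G, model = c("G+GE", "G"), ridge = 1e-6) {
  model <- match.arg(model)
  n <- nrow(obs)
  A <- G[obs$l, obs$l] + diag(ridge, n)
  same_env <- outer(obs$env, obs$env, "==")
  B <- A * same_env
  X <- model.matrix(~ 0 + env, data = obs)
  p <- ncol(X)
  rll <- function(par) {
    gG <- exp(par[1]); gGE <- if (model == "G+GE") exp(par[2]) else 0
    Hm <- gG * A + gGE * B
    diag(Hm) <- diag(Hm) + 1
    ch <- tryCatch(chol(Hm), error = function(e) NULL)
    if (is.null(ch)) return(-1e10)
    logdet <- 2 * sum(log(diag(ch)))
    Xi <- backsolve(ch, forwardsolve(t(ch), X))
    yi <- backsolve(ch, forwardsolve(t(ch), obs$y))
    XX <- crossprod(X, Xi)
    beta <- solve(XX, crossprod(Xi, obs$y))
    r <- obs$y - X %*% beta
    ri <- backsolve(ch, forwardsolve(t(ch), r))
    rss <- sum(r * ri)
    s2e <- rss / (n - p)
    -0.5 * ((n - p) * (log(2 * pi * s2e) + 1) + logdet +
              determinant(XX, logarithm = TRUE)$modulus[1])
  }
  npar <- if (model == "G+GE") 2L else 1L
  opt <- optim_reml(rll, npar)
  gG <- exp(opt$par[1]); gGE <- if (model == "G+GE") exp(opt$par[2]) else 0
  Hm <- gG * A + gGE * B
  diag(Hm) <- diag(Hm) + 1
  ch <- chol(Hm)
  Xi <- backsolve(ch, forwardsolve(t(ch), X))
  XX <- crossprod(X, Xi)
  beta <- as.numeric(solve(XX, crossprod(Xi, obs$y)))
  r <- obs$y - X %*% beta
  ri <- backsolve(ch, forwardsolve(t(ch), r))
  s2e <- sum(r * ri) / (n - p)
  names(beta) <- sub("^env", "", colnames(X))
  list(sigma2_G = gG * s2e, sigma2_GE = gGE * s2e, sigma2_e = s2e,
       env_means = beta, loglik = opt$value, converged = opt$convergence == 0,
       model = model)
}

# ---- GBLUP ------------------------------------------------------------------

#' Fit a GBLUP model (single- or multi-environment)
#'
#' Single-environment mode fits \eqn{y = \mu + g + e}, \eqn{g \sim N(0, G_1
#' \sigma^2_G)}, by spectral REML. Multi-environment mode fits the model
#' with environment main effects (fixed means), a genomic main effect shared
#' across environments and, for `model = "G+GE"`, an
#' environment-specific genomic interaction with covariance
#' \eqn{G_1 \otimes I \, \sigma^2_{GE}}. Balanced complete line x
#' environment data use a fast double-diagonalization REML; unbalanced data
#' (or `vc_lines` subsets) fall back to a dense REML on the observed cells.
#' Optional SNP dosage covariates (GWAS-hit augmentation) enter the fixed
#' part.
#'
#' @param y response: for `mode = "single"` a named numeric vector; for
#'   `mode = "multi"` a data.frame `line`, `env`, `value` (one record per
#'   cell) or a lines x environments matrix (NA = unobserved).
#' @param G1 genomic relationship matrix covering all lines involved.
#' @param mode `"single"` or `"multi"`.
#' @param model `"G+GE"` or `"G"` (multi-environment only).
#' @param snp_covariates optional lines x markers dosage matrix of fixed
#'   marker covariates (rownames = line ids).
#' @param vc_lines optional character vector: estimate variance components
#'   on this (typically balanced) subset of lines, then compute BLUPs from
#'   all observed records.
#' @param ridge diagonal ridge added to `G1`.
#' @return Object of class `gblup_fit`: variance components, fixed effects,
#'   REML log-likelihood, random-effect solutions, and everything
#'   [predict.gblup_fit()] needs.
#' @export
fit_gblup <- function(y, G1, mode = c("single", "multi"),
                      model = c("G+GE", "G"), snp_covariates = NULL,
                      vc_lines = NULL, ridge = 1e-6) {
  mode <- match.arg(mode)
  model <- match.arg(model)
  if (mode == "single") {
    stopifnot(!is.null(names(y)), all(names(y) %in% rownames(G1)))
    ids <- names(y)
    K <- G1[ids, ids]
    X <- cbind(`(Intercept)` = rep(1, length(y)),
               if (!is.null(snp_covariates)) snp_covariates[ids, , drop = FALSE])
    fit <- spectral_reml(y, X, K, ridge)
    # alpha = V^{-1} (y - X beta) in the original basis
    w <- 1 / (fit$sigma2_u * fit$d + fit$sigma2_e)
    r <- fit$yt - fit$Xt %*% fit$beta
    alpha <- as.numeric(fit$U %*% (w * r))
    u <- fit$sigma2_u * as.numeric(K %*% alpha)
    obj <- list(mode = "single", model = "G",
                sigma2_G = fit$sigma2_u, sigma2_GE = 0, sigma2_e = fit$sigma2_e,
                beta = setNames(fit$beta, colnames(X)), loglik = fit$loglik,
                alpha = setNames(alpha, ids), obs_lines = ids, obs_env = NULL,
                u = setNames(u, ids), G1 = G1, snp_covariates = snp_covariates,
                converged = TRUE)
    return(structure(obj, class = "gblup_fit"))
  }
  # ---- multi-environment ----
  if (is.matrix(y)) {
    obs_df <- data.frame(line = rep(rownames(y), ncol(y)),
                         env = rep(colnames(y), each = nrow(y)),
                         value = as.vector(y))
    obs_df <- obs_df[!is.na(obs_df$value), ]
  } else obs_df <- y[!is.na(y$value), c("line", "env", "value")]
  stopifnot(all(obs_df$line %in% rownames(G1)))
  envs <- sort(unique(obs_df$env))
  if (length(envs) < 2) stop("multi-environment mode requires >= 2 environments")
  if (!is.null(snp_covariates))
    return(fit_gblup_dense_cov(obs_df, G1, model, snp_covariates, ridge))
  # variance-component estimation
  vc_src <- obs_df
  if (!is.null(vc_lines)) vc_src <- obs_df[obs_df$line %in% vc_lines, ]
  tab <- table(vc_src$line, vc_src$env)
  balanced <- all(tab == 1) && ncol(tab) == length(envs)
  if (balanced) {
    ids <- rownames(tab)
    Y <- matrix(NA_real_, length(ids), length(envs),
                dimnames = list(ids, envs))
    Y[cbind(match(vc_src$line, ids), match(vc_src$env, envs))] <- vc_src$value
    vc <- reml_multienv_balanced(Y, G1[ids, ids], model, ridge)
  } else {
    o <- data.frame(l = match(vc_src$line, rownames(G1)),
                    env = factor(vc_src$env, levels = envs), y = vc_src$value)
    vc <- reml_multienv_dense(o, G1, model, ridge)
  }
  # BLUP machinery on ALL observed cells at the estimated components
  ol <- match(obs_df$line, rownames(G1))
  n <- nrow(obs_df)
  A <- G1[ol, ol]
  V <- vc$sigma2_G * A +
    vc$sigma2_GE * (A * outer(obs_df$env, obs_df$env, "==")) +
    diag(vc$sigma2_e + ridge, n)
  ch <- chol(V)
  X <- model.matrix(~ 0 + factor(env, levels = envs), data = obs_df)
  colnames(X) <- envs
  Xi <- backsolve(ch, forwardsolve(t(ch), X))
  beta <- as.numeric(solve(crossprod(X, Xi), crossprod(Xi, obs_df$value)))
  names(beta) <- envs
  r <- obs_df$value - X %*% beta
  alpha <- as.numeric(backsolve(ch, forwardsolve(t(ch), r)))
  obj <- list(mode = "multi", model = model,
              sigma2_G = vc$sigma2_G, sigma2_GE = vc$sigma2_GE,
              sigma2_e = vc$sigma2_e, beta = beta, loglik = vc$loglik,
              alpha = alpha, obs_lines = obs_df$line, obs_env = obs_df$env,
              envs = envs, G1 = G1, snp_covariates = NULL,
              converged = vc$converged)
  structure(obj, class = "gblup_fit")
}

# multi-env fit with fixed SNP covariates: dense path throughout
fit_gblup_dense_cov <- function(obs_df, G1, model, snp_covariates, ridge) {
  envs <- sort(unique(obs_df$env))
  ol <- match(obs_df$line, rownames(G1))
  n <- nrow(obs_df)
  A <- G1[ol, ol]
  same_env <- outer(obs_df$env, obs_df$env, "==")
  S <- snp_covariates[obs_df$line, , drop = FALSE]
  Xf <- cbind(model.matrix(~ 0 + factor(env, levels = envs), data = obs_df), S)
  colnames(Xf) <- c(envs, colnames(snp_covariates) %||%
                      paste0("snp", seq_len(ncol(S))))
  qrX <- qr(Xf)
  Xf <- Xf[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]   # drop aliased dosages
  p <- ncol(Xf)
  rll <- function(par) {
    gG <- exp(par[1]); gGE <- if (model == "G+GE") exp(par[2]) else 0
    Hm <- gG * A + gGE * (A * same_env)
    diag(Hm) <- diag(Hm) + 1
    ch <- tryCatch(chol(Hm), error = function(e) NULL)
    if (is.null(ch)) return(-1e10)
    Xi <- backsolve(ch, forwardsolve(t(ch), Xf))
    XX <- crossprod(Xf, Xi)
    beta <- solve(XX, crossprod(Xi, obs_df$value))
    r <- obs_df$value - Xf %*% beta
    ri <- backsolve(ch, forwardsolve(t(ch), r))
    s2e <- sum(r * ri) / (n - p)
    -0.5 * ((n - p) * (log(2 * pi * s2e) + 1) + 2 * sum(log(diag(ch))) +
              determinant(XX, logarithm = TRUE)$modulus[1])
  }
  npar <- if (model == "G+GE") 2L else 1L
  opt <- optim_reml(rll, npar)
  gG <- exp(opt$par[1]); gGE <- if (model == "G+GE") exp(opt$par[2]) else 0
  Hm <- gG * A + gGE * (A * same_env)
  diag(Hm) <- diag(Hm) + 1
  ch <- chol(Hm)
  Xi <- backsolve(ch, forwardsolve(t(ch), Xf))
  beta <- as.numeric(solve(crossprod(Xf, Xi), crossprod(Xi, obs_df$value)))
  names(beta) <- colnames(Xf)
  r <- obs_df$value - Xf %*% beta
  ri <- backsolve(ch, forwardsolve(t(ch), r))
  s2e <- sum(r * ri) / (n - p)
  alpha <- as.numeric(ri) / s2e          # V^{-1} r = H^{-1} r / s2e
  obj <- list(mode = "multi", model = model, sigma2_G = gG * s2e,
              sigma2_GE = gGE * s2e, sigma2_e = s2e,
              beta = beta, loglik = opt$value, alpha = alpha,
              obs_lines = obs_df$line, obs_env = obs_df$env, envs = envs,
              G1 = G1, snp_covariates = snp_covariates,
              converged = opt$convergence == 0)
  structure(obj, class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("GBLUP fit (%s, %s): sigma2_G = %.4g, sigma2_GE = %.4g, sigma2_e = %.4g\n",
              x$mode, x$model, x$sigma2_G, x$sigma2_GE, x$sigma2_e))
  cat(sprintf("  REML log-likelihood = %.4f\n", x$loglik))
  invisible(x)
}

#' Predict line values from a GBLUP fit
#'
#' Out-of-sample genomic prediction: the genomic (and genotype-by-
#' environment) effect of any line in `G1` is the covariance-weighted
#' combination of the observed records,
#' \eqn{\hat g = \sigma^2_G G_1[new, obs] V^{-1} (y - X\hat\beta)}.
#' For an environment that was never observed the environment mean is
#' replaced by the average of the fitted environment means and the
#' interaction BLUP is 0.
#'
#' @param object a [fit_gblup()] result.
#' @param lines character vector of line ids (must appear in `G1`).
#' @param env environment id(s) (multi-environment fits), recycled against
#'   `lines`.
#' @param snp_covariates dosage matrix for the predicted lines when the fit
#'   was augmented.
#' @param ... unused.
#' @return Numeric vector of predicted values.
#' @export
predict.gblup_fit <- function(object, lines, env = NULL,
                              snp_covariates = NULL, ...) {
  x <- object
  stopifnot(all(lines %in% rownames(x$G1)))
  P <- x$G1[lines, x$obs_lines, drop = FALSE]
  main <- x$sigma2_G * as.numeric(P %*% x$alpha)
  if (x$mode == "single") {
    xb <- x$beta[["(Intercept)"]]
    if (!is.null(x$snp_covariates)) {
      S <- (snp_covariates %||% x$snp_covariates)[lines, , drop = FALSE]
      extra <- names(x$beta)[-1]
      xb <- xb + as.numeric(S[, extra, drop = FALSE] %*% x$beta[extra])
    }
    return(setNames(xb + main, lines))
  }
  env <- rep_len(env %||% x$envs[1], length(lines))
  envmean <- ifelse(env %in% x$envs,
                    unname(x$beta[match(env, x$envs)]),
                    mean(x$beta[x$envs]))
  ge <- numeric(length(lines))
  if (x$model == "G+GE" && x$sigma2_GE > 0) {
    for (e in unique(env)) {
      if (!e %in% x$obs_env) next
      idx <- which(x$obs_env == e)
      tgt <- which(env == e)
      ge[tgt] <- x$sigma2_GE *
        as.numeric(P[tgt, idx, drop = FALSE] %*% x$alpha[idx])
    }
  }
  snp <- 0
  if (!is.null(x$snp_covariates)) {
    S <- (snp_covariates %||% x$snp_covariates)[lines, , drop = FALSE]
    extra <- setdiff(names(x$beta), x$envs)
    snp <- as.numeric(S[, extra, drop = FALSE] %*% x$beta[extra])
  }
  setNames(envmean + main + ge + snp, paste(lines, env, sep = ":"))
}
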