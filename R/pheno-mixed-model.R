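#' Fit the stage-1 phenotypic mixed model
#'
#' Fits the standard multi-environment trial decomposition by REML:
#' \deqn{Y = \mu + G + E + GE + R(E) + B(R.E) + e}
#' with environments and replicates-within-environment as fixed effects and
#' genotype, genotype-by-environment and incomplete block as random effects
#' (`scope = "across"`), or the within-environment reduction
#' \eqn{Y = \mu + G + R + B(R) + e} (`scope = "single"`). With
#' `genotype_as = "fixed"` the genotype enters the fixed part and the
#' adjusted line means are BLUEs; with `"random"` line values are shrunken
#' BLUPs. Sum-to-zero contrasts are used for the fixed design factors so
#' that line summaries are centered on the grand mean.
#'
#' Random terms whose grouping factor has no replication (e.g. a trial
#' without incomplete blocks) are dropped automatically. Variance components
#' estimated at the REML boundary (zero) are reported as 0 and flagged in
#' the log.
#'
#' @param pheno long plot table (`line`, `env`, `rep`, `block`, `trait`,
#'   `value`).
#' @param trait trait name to analyse.
#' @param scope `"across"` (all environments; requires >= 2) or `"single"`.
#' @param env environment id, required when `scope = "single"`.
#' @param genotype_as `"random"` (BLUPs) or `"fixed"` (BLUEs).
#' @return List of class `pheno_fit`: `vc` (variance components with `E`,
#'   `R` counts), `lines` (data.frame `line`, `blup` or `blue`), `log`
#'   (convergence info), `fit` (the underlying lme4 object).
#' @export
fit_mixed_model <- function(pheno, trait,
                            scope = c("across", "single"), env = NULL,
                            genotype_as = c("random", "fixed")) {
  scope <- match.arg(scope)
  genotype_as <- match.arg(genotype_as)
  d <- pheno[pheno$trait == trait & !is.na(pheno$value), , drop = FALSE]
  if (nrow(d) == 0) stop("trait not found: ", trait)
  if (scope == "single") {
    if (is.null(env)) stop("scope = 'single' requires env")
    d <- d[d$env == env, , drop = FALSE]
    if (nrow(d) == 0) stop("no records for environment ", env)
  }
  d$line <- factor(d$line)
  d$env <- factor(d$env)
  d$rep <- factor(d$rep)
  n_env <- nlevels(d$env)
  n_rep <- nlevels(d$rep)
  if (scope == "across" && n_env < 2) stop("across-environment fit requires >= 2 environments")
  if (n_rep < 2) stop("fit requires >= 2 replicates")
  has_block <- !all(is.na(d$block)) && length(unique(na.omit(d$block))) > 1
  d$block_uid <- if (has_block)
    factor(paste(d$env, d$rep, d$block, sep = ":")) else factor(1)
  if (n_env > 1) contrasts(d$env) <- stats::contr.sum(n_env)
  if (n_rep > 1) contrasts(d$rep) <- stats::contr.sum(n_rep)

  fixed <- if (scope == "across") "env + env:rep" else "rep"
  rand <- character()
  if (genotype_as == "random") rand <- c(rand, "(1 | line)")
  if (scope == "across") rand <- c(rand, "(1 | line:env)")
  if (has_block) rand <- c(rand, "(1 | block_uid)")
  lhs <- if (genotype_as == "fixed") paste("value ~ 0 + line +", fixed)
         else paste("value ~", fixed)
  form <- as.formula(paste(c(lhs, rand), collapse = " + "))
  fit <- suppressMessages(lme4::lmer(form, data = d,
                                     control = lme4::lmerControl(
                                       check.nobs.vs.nlev = "ignore",
                                       check.nobs.vs.nRE = "ignore",
                                       calc.derivs = TRUE)))
  vc_tab <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(name) {
    i <- match(name, vc_tab$grp)
    if (is.na(i)) 0 else vc_tab$vcov[i]
  }
  vc <- list(sigma2_G = get_vc("line"),
             sigma2_GE = get_vc("line:env"),
             sigma2_block = get_vc("block_uid"),
             sigma2_rep = NA_real_,           # replicates are fixed effects
             sigma2_e = get_vc("Residual"),
             E = n_env, R = n_rep)
  boundary <- lme4::isSingular(fit, tol = 1e-5)
  ll <- list(converged = length(fit@optinfo$conv$lme4) == 0,
             singular = boundary,
             boundary_components = if (boundary)
               vc_tab$grp[vc_tab$vcov < 1e-8] else character(),
             n_iter = fit@optinfo$feval,
             message = paste(unlist(fit@optinfo$conv$lme4$messages),
                             collapse = "; "))
  lines_df <- if (genotype_as == "random") {
    re <- lme4::ranef(fit)$line
    mu_hat <- unname(lme4::fixef(fit)["(Intercept)"])
    data.frame(line = rownames(re), blup = mu_hat + re[, 1])
  } else {
    cf <- lme4::fixef(fit)
    sel <- grepl("^line", names(cf))
    data.frame(line = sub("^line", "", names(cf)[sel]),
               blue = unname(cf[sel]))
  }
  rownames(lines_df) <- NULL
  structure(list(vc = vc, lines = lines_df, log = ll, fit = fit),
            class = "pheno_fit")
}

#' @export
print.pheno_fit <- function(x, ...) {
  cat("Stage-1 mixed-model fit (", x$vc$E, "env x", x$vc$R, "rep )\n")
  cat(sprintf("  sigma2_G = %.4g  sigma2_GE = %.4g  sigma2_block = %.4g  sigma2_e = %.4g\n",
              x$vc$sigma2_G, x$vc$sigma2_GE, x$vc$sigma2_block, x$vc$sigma2_e))
  if (x$vc$E > 1)
    cat(sprintf("  entry-mean h2 = %.3f\n", entry_mean_heritability(x$vc)))
  invisible(x)
}

#' Entry-mean heritability
#'
#' \deqn{h^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{GE}/E + \sigma^2_e/(ER))}
#' the heritability of line means across `E` environments and `R`
#' replicates.
#'
#' @param vc list with `sigma2_G`, `sigma2_GE`, `sigma2_e`, `E`, `R` (e.g.
#'   the `vc` element of [fit_mixed_model()]).
#' @return Heritability in `[0, 1]`.
#' @export
entry_mean_heritability <- function(vc) {
  stopifnot(all(c("sigma2_G", "sigma2_GE", "sigma2_e", "E", "R") %in% names(vc)))
  if (any(unlist(vc[c("sigma2_G", "sigma2_GE", "sigma2_e")]) < 0))
    stop("variance components must be >= 0")
  den <- vc$sigma2_G + vc$sigma2_GE / vc$E + vc$sigma2_e / (vc$E * vc$R)
  if (den <= 0) stop("heritability undefined: all variance components are zero")
  vc$sigma2_G / den
}

#' Area under the disease (Striga number) progress curve
#'
#' Trapezoidal area
#' \eqn{\sum_i \frac{y_i + y_{i+1}}{2} (t_{i+1} - t_i)} of repeated
#' measurements over time; applied to emerged-parasite counts this is the
#' AUSNPC.
#'
#' @param values measurements at each timepoint.
#' @param times strictly increasing timepoints (days).
#' @return The area (value units x days).
#' @export
audpc <- function(values, times) {
  if (length(values) != length(times)) stop("values and times differ in length")
  if (length(times) < 2) stop("need >= 2 timepoints")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  sum((head(values, -1) + values[-1]) / 2 * diff(times))
}

#' Derive plot-level AUSNPC rows from count traits
#'
#' Applies [audpc()] per plot to the `nStr_<t>WAP` trait columns, with times
#' in days (weeks after planting x 7), and returns the new trait rows.
#'
#' @param pheno long plot table containing the count traits.
#' @param count_traits names of the count traits, in time order.
#' @param times_days timepoints in days.
#' @param trait_name name of the derived trait.
#' @return data.frame of new rows (same columns as `pheno`).
#' @export
derive_ausnpc <- function(pheno,
                          count_traits = c("nStr_8WAP", "nStr_10WAP", "nStr_12WAP"),
                          times_days = c(56, 70, 84),
                          trait_name = "AUSNPC") {
  d <- pheno[pheno$trait %in% count_traits, , drop = FALSE]
  if (nrow(d) == 0) stop("count traits not found")
  d$trait <- factor(d$trait, levels = count_traits)
  key <- interaction(d$line, d$env, d$rep, sep = "\r", drop = TRUE)
  Y <- matrix(NA_real_, nlevels(key), length(count_traits))
  Y[cbind(as.integer(key), as.integer(d$trait))] <- d$value
  first <- match(levels(key), key)
  area <- apply(Y, 1L, audpc, times = times_days)
  data.frame(line = d$line[first], env = d$env[first], rep = d$rep[first],
             block = d$block[first], trait = trait_name,
             value = as.numeric(area))
}

#' Pairwise trait correlations with significance cutoffs
#'
#' Pearson correlations between line-level trait summaries
#' (pairwise-complete), with two-sided p-values from the t distribution and
#' the |r| cutoffs corresponding to p = 0.05 and 0.01 at the common sample
#' size.
#'
#' @param summaries data.frame: `line` column plus one numeric column per
#'   trait (e.g. BLUEs).
#' @param traits trait columns to correlate (default: all numeric columns).
#' @return List: `r` (correlation matrix), `p` (p-value matrix), `n`
#'   (pairwise counts), `cutoff_05`, `cutoff_01` (|r| significance cutoffs
#'   at the median pairwise n), `flagged` (constant traits, correlations
#'   emitted as NA).
#' @export
trait_correlations <- function(summaries, traits = NULL) {
  num <- vapply(summaries, is.numeric, TRUE)
  if (is.null(traits)) traits <- names(summaries)[num & names(summaries) != "line"]
  X <- as.matrix(summaries[, traits, drop = FALSE])
  constant <- apply(X, 2L, function(x) sd(x, na.rm = TRUE) == 0 ||
                      sum(!is.na(x)) < 3)
  r <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(X))
  if (any(n[upper.tri(n)] < 3)) warning("some trait pairs have < 3 complete pairs")
  tt <- r * sqrt(pmax(n - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tt), df = pmax(n - 2, 1), lower.tail = FALSE)
  diag(p) <- 0
  r[constant, ] <- NA; r[, constant] <- NA; diag(r) <- 1
  n_med <- stats::median(n[upper.tri(n)])
  cutoff <- function(alpha) {
    tc <- qt(1 - alpha / 2, df = n_med - 2)
    tc / sqrt(n_med - 2 + tc^2)
  }
  list(r = r, p = p, n = n,
       cutoff_05 = if (is.na(n_med)) NA_real_ else cutoff(0.05),
       cutoff_01 = if (is.na(n_med)) NA_real_ else cutoff(0.01),
       flagged = traits[constant])
}

#' Remove outlying plot records
#'
#' Standardized residuals from a preliminary fixed-effects fit
#' (`value ~ line + env + env:rep`, reduced to the terms the data support);
#' records with |z| > `z_max` are dropped.
#'
#' @param pheno long plot table.
#' @param trait trait to screen (other traits pass through untouched).
#' @param z_max positive threshold (default 3.5); `Inf` is a no-op.
#' @return The filtered table; attribute `n_removed` gives the count.
#' @export
remove_outliers <- function(pheno, trait, z_max = 3.5) {
  stopifnot(z_max > 0)
  sel <- which(pheno$trait == trait & !is.na(pheno$value))
  d <- pheno[sel, , drop = FALSE]
  if (is.infinite(z_max) || nrow(d) < 3) {
    attr(pheno, "n_removed") <- 0L
    return(pheno)
  }
  terms <- "line"
  if (length(unique(d$env)) > 1) terms <- c(terms, "env")
  if (length(unique(d$rep)) > 1) terms <- c(terms, "env:rep")
  fit <- lm(as.formula(paste("value ~", paste(terms, collapse = " + "))), data = d)
  z <- rstandard(fit)
  drop_rows <- sel[!is.na(z) & abs(z) > z_max]
  out <- if (length(drop_rows)) pheno[-drop_rows, , drop = FALSE] else pheno
  attr(out, "n_removed") <- length(drop_rows)
  out
}

#' Within-environment repeatability screen
#'
#' Repeatability (line-mean heritability within one environment,
#' \eqn{\sigma^2_G / (\sigma^2_G + \sigma^2_e / R)}) per environment, plus a
#' likelihood-ratio test of the genotype variance; environments pass the
#' screen when repeatability >= `min_rep` and the LRT p-value < `alpha`.
#'
#' @param pheno long plot table.
#' @param trait trait name.
#' @param min_rep repeatability threshold (default 0.1).
#' @param alpha LRT significance level (default 0.05).
#' @return data.frame per environment: `env`, `repeatability`, `p_lrt`,
#'   `keep`.
#' @export
screen_environments <- function(pheno, trait, min_rep = 0.1, alpha = 0.05) {
  envs <- unique(pheno$env[pheno$trait == trait])
  out <- lapply(envs, function(e) {
    f1 <- fit_mixed_model(pheno, trait, scope = "single", env = e)
    rep_ <- with(f1$vc, if (sigma2_G + sigma2_e / R <= 0) 0 else
      sigma2_G / (sigma2_G + sigma2_e / R))
    d <- pheno[pheno$trait == trait & pheno$env == e & !is.na(pheno$value), ]
    d$line <- factor(d$line); d$rep <- factor(d$rep)
    null_fit <- lm(value ~ rep, data = d)
    ll0 <- as.numeric(stats::logLik(null_fit))
    ll1 <- as.numeric(stats::logLik(f1$fit, REML = FALSE))
    # refit alternative by ML for a comparable LRT
    ml1 <- suppressMessages(stats::update(f1$fit, REML = FALSE))
    lrt <- max(0, 2 * (as.numeric(stats::logLik(ml1)) - ll0))
    p <- 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)  # boundary mixture
    data.frame(env = e, repeatability = rep_, p_lrt = p,
               keep = rep_ >= min_rep & p < alpha)
  })
  do.call(rbind, out)
}
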