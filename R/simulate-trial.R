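#' Simulate a multi-environment alpha-lattice trial
#'
#' Generates plot-level phenotypes for an inbred panel following the standard
#' multi-environment mixed-model decomposition: genomic main effect (variance
#' `sigma2_G`, built from additive QTL effects), environment-specific genetic
#' deviations (variance `sigma2_GE`, giving cross-environment genetic
#' correlation `sigma2_G / (sigma2_G + sigma2_GE)`), fixed-size environment
#' effects, replicate-within-environment and incomplete-block-within-replicate
#' effects, and i.i.d. residuals. QTL effects are rescaled after drawing so
#' the realized genetic variance in the panel equals the target exactly.
#'
#' Several traits can be generated at once; `trait_cor` sets the genetic
#' correlation of their QTL effects (shared for the main and the
#' environment-specific parts), which is how correlated trait families (e.g.
#' emerged-parasite counts, damage scores and yield) arise in the generator.
#'
#' @param geno a [geno_matrix()] (no missing values are required; missing
#'   dosages are mean-imputed internally for the QTL model).
#' @param n_env,n_rep number of environments / replicates per environment.
#' @param block_size incomplete-block size (entries per block); blocks are
#'   assigned by consecutive plot order within each replicate, the last block
#'   is padded (shorter) with a warning when `block_size` does not tile the
#'   panel.
#' @param mu trait intercept(s), recycled over traits.
#' @param sigma2_G,sigma2_GE,sigma2_e genetic, genotype-by-environment and
#'   residual variances (recycled over traits).
#' @param sigma2_env,sigma2_rep,sigma2_block variances of environment,
#'   replicate and block effects.
#' @param n_qtl number of causal markers (sampled without replacement).
#' @param traits character vector of trait names.
#' @param trait_cor genetic correlation between traits: scalar or correlation
#'   matrix (ignored for a single trait).
#' @param seed integer seed.
#' @return A list with `pheno` (long data.frame `line`, `env`, `rep`,
#'   `block`, `trait`, `value`) and `truth` (list: `qtl_indices`,
#'   `qtl_effects_main`, `qtl_effects_env`, `tbv` lines x envs x traits
#'   array, `env_effects`, `variance_components_true`, `env_correlation`).
#' @export
simulate_trial <- function(geno, n_env = 3, n_rep = 2, block_size = 5,
                           mu = 0, sigma2_G = 1, sigma2_GE = 0.25,
                           sigma2_e = 1, sigma2_env = 1, sigma2_rep = 0.05,
                           sigma2_block = 0.1, n_qtl = 100,
                           traits = "trait", trait_cor = 0, seed = NULL) {
  stopifnot(n_env >= 1, n_rep >= 1, block_size >= 1)
  n_tr <- length(traits)
  sigma2_G <- rep_len(sigma2_G, n_tr)
  sigma2_GE <- rep_len(sigma2_GE, n_tr)
  sigma2_e <- rep_len(sigma2_e, n_tr)
  mu <- rep_len(mu, n_tr)
  vcs <- c(sigma2_G, sigma2_GE, sigma2_e, sigma2_env, sigma2_rep, sigma2_block)
  if (any(vcs < 0)) stop("variance components must be >= 0")
  ids <- line_ids(geno)
  n <- length(ids)
  if (n %% block_size != 0)
    warning("block_size does not tile n_lines; last block is padded (smaller)")
  if (n_tr > 1L) {
    R <- if (is.matrix(trait_cor)) trait_cor else {
      m <- matrix(trait_cor, n_tr, n_tr); diag(m) <- 1; m
    }
    stopifnot(nrow(R) == n_tr, all(abs(R) <= 1))
    Lc <- chol(R + diag(1e-10, n_tr))
  }
  draw_effects <- function(k) {
    # k x n_tr matrix of standard normal effects with trait correlation R
    E <- matrix(rnorm(k * n_tr), k, n_tr)
    if (n_tr > 1L) E <- E %*% Lc
    E
  }
  with_seed(seed, {
    Z <- impute_dosage(geno$values)
    Z <- scale(Z, center = TRUE, scale = FALSE)
    qtl <- sort(sample.int(ncol(Z), min(n_qtl, ncol(Z))))
    Zq <- Z[, qtl, drop = FALSE]
    b_main <- draw_effects(length(qtl))
    g_main <- matrix(0, n, n_tr)
    for (t in seq_len(n_tr)) {
      sg <- scale_to_var(Zq %*% b_main[, t], sigma2_G[t])
      g_main[, t] <- sg
      f <- attr(sg, "scale_factor")
      if (!is.null(f)) b_main[, t] <- b_main[, t] * f
    }
    b_env <- vector("list", n_env)
    tbv <- array(0, dim = c(n, n_env, n_tr),
                 dimnames = list(ids, paste0("E", seq_len(n_env)), traits))
    for (e in seq_len(n_env)) {
      b_env[[e]] <- draw_effects(length(qtl))
      for (t in seq_len(n_tr)) {
        d <- scale_to_var(Zq %*% b_env[[e]][, t], sigma2_GE[t])
        tbv[, e, t] <- g_main[, t] + d
      }
    }
    env_eff <- rnorm(n_env, 0, sqrt(sigma2_env))
    rep_eff <- matrix(rnorm(n_env * n_rep, 0, sqrt(sigma2_rep)), n_env, n_rep)
    n_blocks <- ceiling(n / block_size)
    rows <- vector("list", n_env * n_rep * n_tr)
    i <- 0L
    for (e in seq_len(n_env)) for (r in seq_len(n_rep)) {
      ord <- sample.int(n)                       # randomize entries to plots
      blk <- ceiling(seq_len(n) / block_size)    # consecutive plot order
      blk_eff <- rnorm(n_blocks, 0, sqrt(sigma2_block))
      for (t in seq_len(n_tr)) {
        res <- rnorm(n, 0, sqrt(sigma2_e[t]))
        val <- mu[t] + env_eff[e] + tbv[ord, e, t] + rep_eff[e, r] +
          blk_eff[blk] + res
        i <- i + 1L
        rows[[i]] <- data.frame(line = ids[ord], env = paste0("E", e),
                                rep = paste0("R", r), block = blk,
                                trait = traits[t], value = as.numeric(val))
      }
    }
    pheno <- do.call(rbind, rows)
    rownames(pheno) <- NULL
    dimnames(g_main) <- list(ids, traits)
    truth <- list(
      qtl_indices = qtl,
      g_main = g_main,
      qtl_effects_main = b_main,
      qtl_effects_env = b_env,
      tbv = tbv,
      env_effects = env_eff,
      variance_components_true = list(sigma2_G = sigma2_G,
                                      sigma2_GE = sigma2_GE,
                                      sigma2_e = sigma2_e,
                                      sigma2_env = sigma2_env,
                                      sigma2_rep = sigma2_rep,
                                      sigma2_block = sigma2_block),
      env_correlation = sigma2_G / (sigma2_G + sigma2_GE))
    list(pheno = pheno, truth = truth)
  })
}

# rescale a vector so its sample variance is exactly v (0 allowed)
scale_to_var <- function(x, v) {
  x <- as.numeric(x)
  if (v == 0) return(rep(0, length(x)))
  s <- var(x)
  if (s == 0) stop("cannot scale a constant genetic value to positive variance")
  x_c <- x - mean(x)
  out <- x_c * sqrt(v / s)
  attr(out, "scale_factor") <- sqrt(v / s)
  out
}

#' Simulate emerged Striga counts at successive scoring dates
#'
#' Draws plot-level emerged-parasite counts at the canonical scoring dates
#' (8, 10 and 12 weeks after planting) from a negative-binomial model whose
#' log-mean is the timepoint baseline plus a scaled per-line genetic
#' liability. The half-variance lognormal correction keeps the marginal
#' grand mean at each timepoint equal to `baseline_means` when the liability
#' is (approximately) Gaussian. `overdispersion = 0` gives Poisson counts.
#'
#' @param liability per-line genetic liability: named numeric vector, or a
#'   lines x environments matrix for environment-specific liabilities.
#'   Standardized internally to mean 0, sd 1 (if non-constant).
#' @param timepoints_wap scoring times in weeks after planting.
#' @param baseline_means expected count at each timepoint (non-decreasing).
#' @param overdispersion negative-binomial overdispersion (variance =
#'   mean + overdispersion * mean^2); 0 = Poisson.
#' @param n_env,n_rep trial layout for which to emit plot counts.
#' @param liability_scale multiplier of the standardized liability on the
#'   log-mean scale.
#' @param seed integer seed.
#' @return Long data.frame (`line`, `env`, `rep`, `block = NA`, `trait`,
#'   `value`) with one trait per timepoint, named `nStr_<t>WAP`.
#' @export
simulate_striga_counts <- function(liability, timepoints_wap = c(8, 10, 12),
                                   baseline_means = c(6.2, 30, 65),
                                   overdispersion = 0.3, n_env = 3, n_rep = 2,
                                   liability_scale = 0.3, seed = NULL) {
  if (any(baseline_means < 0)) stop("baseline_means must be non-negative")
  if (any(diff(baseline_means) < 0)) stop("baseline_means must be non-decreasing")
  if (overdispersion < 0) stop("overdispersion must be >= 0")
  stopifnot(length(baseline_means) == length(timepoints_wap))
  L <- if (is.matrix(liability)) liability else
    matrix(liability, nrow = length(liability), ncol = n_env,
           dimnames = list(names(liability), NULL))
  if (is.null(rownames(L))) stop("liability must carry line ids as names/rownames")
  n <- nrow(L)
  s <- liability_scale
  if (sd(L) > 0) L <- (L - mean(L)) / sd(L) else s <- 0
  # with s = 0 the lognormal mean correction exp(-s^2/2) vanishes, so a flat
  # liability yields counts centered exactly on the baselines
  with_seed(seed, {
    rows <- list(); i <- 0L
    for (e in seq_len(n_env)) for (r in seq_len(n_rep)) {
      for (t in seq_along(timepoints_wap)) {
        mu <- baseline_means[t] * exp(s * L[, e] - s^2 / 2)
        cnt <- if (overdispersion == 0) rpois(n, mu) else
          rnbinom(n, size = 1 / overdispersion, mu = mu)
        i <- i + 1L
        rows[[i]] <- data.frame(line = rownames(L), env = paste0("E", e),
                                rep = paste0("R", r), block = NA_integer_,
                                trait = paste0("nStr_", timepoints_wap[t], "WAP"),
                                value = as.numeric(cnt))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a complete Striga-panel dataset
#'
#' Composes [simulate_genotypes()], [simulate_trial()] and
#' [simulate_striga_counts()] into the canonical synthetic dataset the rest
#' of the package is exercised on: an inbred panel phenotyped for grain
#' yield (GY), Striga damage rating (SDR) and days to anthesis (AD) in a
#' multi-environment alpha-lattice trial, plus emerged-Striga counts at
#' 8/10/12 weeks after planting driven by the SDR genetic liability, and the
#' derived area under the Striga number progress curve (AUSNPC). Default
#' variance components and trait means are the published entry-mean
#' components of a tropical maize association panel evaluated under
#' artificial Striga infestation in three environments with two replicates.
#'
#' @param n_lines,n_markers,n_env,n_rep,block_size design dimensions.
#' @param seed integer master seed (fanned out per stage via [child_seed()]).
#' @param ... passed on to [simulate_genotypes()].
#' @return List with `geno`, `pheno` (long plot table incl. count traits and
#'   AUSNPC), `truth`.
#' @export
simulate_striga_panel <- function(n_lines = 380, n_markers = 2000, n_env = 3,
                                  n_rep = 2, block_size = 5, seed = 1, ...) {
  geno <- simulate_genotypes(n_lines, n_markers, seed = child_seed(seed, "geno"), ...)
  trial <- simulate_trial(
    geno, n_env = n_env, n_rep = n_rep, block_size = block_size,
    traits = c("GY", "SDR", "AD"),
    mu = c(1.52, 4.17, 73),
    sigma2_G = c(0.28, 0.78, 15.26),
    sigma2_GE = c(0.11, 0.10, 1.45),
    sigma2_e = c(0.53, 0.72, 4.93),
    trait_cor = matrix(c(1, -0.4, -0.3,
                         -0.4, 1, 0.3,
                         -0.3, 0.3, 1), 3, 3),
    seed = child_seed(seed, "trial"))
  liab <- trial$truth$tbv[, , "SDR"]
  counts <- simulate_striga_counts(liab, n_env = n_env, n_rep = n_rep,
                                   seed = child_seed(seed, "counts"))
  pheno <- rbind(trial$pheno, counts)
  pheno <- rbind(pheno, derive_ausnpc(pheno))
  list(geno = geno, pheno = pheno, truth = trial$truth)
}

#' Canonical small fixture dataset
#'
#' 100 lines x 500 markers x 3 environments, used throughout the test suite.
#'
#' @param seed integer seed.
#' @return Same structure as [simulate_striga_panel()].
#' @export
striga_fixture <- function(seed = 1) {
  simulate_striga_panel(n_lines = 100, n_markers = 500, seed = seed)
}

#' Write / read a plot-level phenotype table as CSV
#'
#' Long format with header `line,env,rep,block,trait,value`.
#'
#' @param pheno long-format data.frame.
#' @param path CSV path.
#' @return `path` invisibly (writer); data.frame (reader).
#' @export
write_pheno_csv <- function(pheno, path) {
  write.csv(pheno[, c("line", "env", "rep", "block", "trait", "value")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pheno_csv
#' @export
read_pheno_csv <- function(path) {
  df <- read.csv(path, colClasses = c(line = "character", env = "character",
                                      rep = "character", trait = "character"))
  need <- c("line", "env", "rep", "block", "trait", "value")
  if (!all(need %in% names(df))) stop("phenotype CSV must have columns ",
                                      paste(need, collapse = ","))
  df
}
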