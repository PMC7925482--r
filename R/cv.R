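#' Cross-validated genomic prediction accuracy (CV0 / CV1 / CV2)
#'
#' Implements the three multi-environment cross-validation schemes used to
#' benchmark genomic prediction, plus an across-environment scheme on BLUEs:
#' \describe{
#'   \item{CV0}{leave-one-environment-out: every line is predicted in the
#'     held-out environment from the remaining environments (new
#'     environments for known lines). Deterministic; one result per
#'     environment.}
#'   \item{CV1}{random five-fold partition of lines; test-fold lines are
#'     masked in all environments (entirely new lines).}
#'   \item{CV2}{same line partition as CV1 (paired comparison), but each
#'     test line is masked only in a uniformly drawn non-empty proper
#'     subset of environments (incomplete field trials).}
#'   \item{across}{five-fold prediction of across-environment BLUEs with a
#'     single-environment GBLUP.}
#' }
#' Accuracy is the Pearson correlation between predicted and observed
#' values in the test partition, per environment and repetition; folds with
#' fewer than 3 test observations in an environment are skipped. Variance
#' components are re-estimated per fold on the fully observed training
#' lines; predictions use all observed cells.
#'
#' Augmentation with association hits adds their dosages as fixed
#' covariates: `"whole-panel"` takes hits detected on the full panel
#' (deliberately reproducing the optimistic information leakage of
#' panel-wide hit selection), `"training-only"` re-scans within each
#' training fold.
#'
#' @param data lines x environments matrix of line-level values (e.g.
#'   per-environment BLUEs), or for `scheme = "across"` a named vector /
#'   one-column matrix of across-environment BLUEs.
#' @param G1 genomic relationship matrix.
#' @param scheme `"CV0"`, `"CV1"`, `"CV2"` or `"across"`.
#' @param model `"G+GE"` or `"G"` (multi-environment schemes).
#' @param k_folds folds (default 5, i.e. 80/20).
#' @param n_repetitions repetitions of the random fold draw.
#' @param seed master seed; fold partitions are drawn from a per-repetition
#'   child stream so CV1 and CV2 at the same seed share line partitions.
#' @param augment `"none"`, `"whole-panel"` or `"training-only"`.
#' @param hits_dosage lines x hits dosage matrix (required for
#'   `"whole-panel"`).
#' @param geno,gwas_threshold,n_pcs genotype data and scan settings for
#'   `"training-only"` augmentation.
#' @return data.frame of class `cv_result`: `scheme`, `model`, `env`,
#'   `rep`, `cor`, `n_test`.
#' @export
run_cv <- function(data, G1, scheme = c("CV1", "CV2", "CV0", "across"),
                   model = c("G+GE", "G"), k_folds = 5, n_repetitions = 10,
                   seed = 1, augment = c("none", "whole-panel", "training-only"),
                   hits_dosage = NULL, geno = NULL, gwas_threshold = 2e-6,
                   n_pcs = 3) {
  scheme <- match.arg(scheme)
  model <- match.arg(model)
  augment <- match.arg(augment)
  if (augment == "whole-panel" && is.null(hits_dosage))
    stop("whole-panel augmentation requires hits_dosage")
  if (augment == "training-only" && is.null(geno))
    stop("training-only augmentation requires geno")
  if (scheme == "across") {
    y <- if (is.matrix(data)) setNames(data[, 1], rownames(data)) else data
    return(cv_across(y, G1, k_folds, n_repetitions, seed, augment,
                     hits_dosage, geno, gwas_threshold, n_pcs))
  }
  Y <- as.matrix(data)
  stopifnot(!is.null(rownames(Y)), ncol(Y) >= 2, all(rownames(Y) %in% rownames(G1)))
  envs <- colnames(Y) %||% paste0("E", seq_len(ncol(Y)))
  colnames(Y) <- envs
  n <- nrow(Y); E <- ncol(Y)
  res <- list()
  if (scheme == "CV0") {
    for (e in seq_len(E)) {
      train <- Y[, -e, drop = FALSE]
      fit <- fit_gblup(train, G1, mode = "multi", model = model)
      pred <- predict(fit, rownames(Y), env = rep(envs[e], n))
      obs <- Y[, e]
      ok <- !is.na(obs)
      res[[length(res) + 1L]] <- data.frame(
        scheme = scheme, model = model, env = envs[e], rep = 1L,
        cor = cor(pred[ok], obs[ok]), n_test = sum(ok))
    }
  } else {
    for (r in seq_len(n_repetitions)) {
      folds <- with_seed(child_seed(seed, paste0("fold", r)),
                         sample(rep_len(seq_len(k_folds), n)))
      masks <- with_seed(child_seed(seed, paste0("mask", r)), {
        # per line: non-empty proper env subset (>= 1 observed env kept)
        lapply(seq_len(n), function(i) {
          k <- sample.int(E - 1L, 1L)
          sort(sample.int(E, k))
        })
      })
      for (f in seq_len(k_folds)) {
        test <- which(folds == f)
        if (length(test) < 3) next
        Ytr <- Y
        if (scheme == "CV1") {
          Ytr[test, ] <- NA
        } else {
          for (i in test) Ytr[i, masks[[i]]] <- NA
        }
        train_lines <- rownames(Y)[-test]
        aug <- cv_augmentation(augment, Y, Ytr, train_lines, hits_dosage,
                               geno, G1, gwas_threshold, n_pcs)
        fit <- fit_gblup(Ytr, G1, mode = "multi", model = model,
                         vc_lines = train_lines, snp_covariates = aug)
        for (e in seq_len(E)) {
          tl <- if (scheme == "CV1") test else
            test[vapply(test, function(i) e %in% masks[[i]], TRUE)]
          tl <- tl[!is.na(Y[tl, e])]
          if (length(tl) < 3) next
          pred <- predict(fit, rownames(Y)[tl], env = rep(envs[e], length(tl)))
          res[[length(res) + 1L]] <- data.frame(
            scheme = scheme, model = model, env = envs[e], rep = r,
            cor = cor(pred, Y[tl, e]), n_test = length(tl))
        }
      }
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("cv_result", "data.frame")
  out
}

cv_augmentation <- function(augment, Y, Ytr, train_lines, hits_dosage,
                            geno, G1, gwas_threshold, n_pcs) {
  if (augment == "none") return(NULL)
  if (augment == "whole-panel") return(hits_dosage)
  # training-only: MLM scan of the training lines' across-environment mean
  ytr <- rowMeans(Y[train_lines, , drop = FALSE], na.rm = TRUE)
  gsub_ <- impute_missing(geno[train_lines, ])
  pcs <- pca_genotypes(gsub_$values, n_pc = n_pcs)$scores
  scan <- gwas_scan(ytr, gsub_, covariates = pcs,
                    K = G1[train_lines, train_lines], method = "MLM")
  hits <- significant_hits(scan, threshold = gwas_threshold)
  if (nrow(hits) == 0) return(NULL)
  sel <- match(hits$snp, geno$map$marker)
  D <- impute_dosage(geno$values)[, sel, drop = FALSE]
  colnames(D) <- hits$snp
  D
}

cv_across <- function(y, G1, k_folds, n_repetitions, seed, augment,
                      hits_dosage, geno, gwas_threshold, n_pcs) {
  n <- length(y)
  res <- list()
  for (r in seq_len(n_repetitions)) {
    folds <- with_seed(child_seed(seed, paste0("fold", r)),
                       sample(rep_len(seq_len(k_folds), n)))
    for (f in seq_len(k_folds)) {
      test <- which(folds == f)
      if (length(test) < 3) next
      aug <- if (augment == "whole-panel") hits_dosage else if
        (augment == "training-only") {
        Ym <- matrix(y, ncol = 1, dimnames = list(names(y), "across"))
        cv_augmentation(augment, Ym, NULL, names(y)[-test], hits_dosage,
                        geno, G1, gwas_threshold, n_pcs)
      } else NULL
      fit <- fit_gblup(y[-test], G1, mode = "single", snp_covariates = aug)
      pred <- predict(fit, names(y)[test], snp_covariates = aug)
      res[[length(res) + 1L]] <- data.frame(
        scheme = "across", model = "G", env = "across", rep = r,
        cor = cor(pred, y[test]), n_test = length(test))
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("cv_result", "data.frame")
  out
}

#' Summarize cross-validation accuracy
#'
#' Mean of the per-repetition correlations (repetition means are averaged,
#' not pooled predictions), per environment.
#'
#' @param res a [run_cv()] result (rows may be pooled across schemes).
#' @return data.frame `scheme`, `model`, `env`, `mean_cor`, `sd_cor`,
#'   `n_rep`.
#' @export
summarize_cv <- function(res) {
  key <- interaction(res$scheme, res$model, res$env, drop = TRUE)
  # average within repetition first, then across repetitions
  agg <- do.call(rbind, lapply(split(res, key), function(d) {
    per_rep <- tapply(d$cor, d$rep, mean, na.rm = TRUE)
    data.frame(scheme = d$scheme[1], model = d$model[1], env = d$env[1],
               mean_cor = mean(per_rep), sd_cor = sd(per_rep),
               n_rep = length(per_rep))
  }))
  rownames(agg) <- NULL
  agg
}
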