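#' Build a lines x (trait, environment) matrix
#'
#' Assembles line-level trait values (e.g. per-environment line means or
#' BLUEs) into the wide "users x items" matrix of the collaborative
#' filtering predictor: rows are lines, columns are trait-environment
#' combinations named `trait@env`.
#'
#' @param values long data.frame `line`, `env`, `trait`, `value` (one row
#'   per line-item; plot-level tables should be averaged to line level
#'   first, e.g. via [line_means()]).
#' @return Numeric matrix with `line` rownames and `trait@env` colnames;
#'   class `trait_env_matrix`.
#' @export
trait_env_matrix <- function(values) {
  stopifnot(all(c("line", "env", "trait", "value") %in% names(values)))
  item <- paste0(values$trait, "@", values$env)
  lines <- sort(unique(values$line))
  items <- unique(item)
  M <- matrix(NA_real_, length(lines), length(items),
              dimnames = list(lines, items))
  M[cbind(match(values$line, lines), match(item, items))] <- values$value
  class(M) <- c("trait_env_matrix", class(M))
  M
}

#' Line-level means of a plot table
#'
#' @param pheno long plot table (`line`, `env`, `rep`, `trait`, `value`).
#' @param by_env average within environment (`TRUE`) or across all records.
#' @return Long data.frame `line`, `env` (or `"across"`), `trait`, `value`.
#' @export
line_means <- function(pheno, by_env = TRUE) {
  f <- if (by_env) list(line = pheno$line, env = pheno$env, trait = pheno$trait)
       else list(line = pheno$line, trait = pheno$trait)
  agg <- stats::aggregate(list(value = pheno$value), f, mean, na.rm = TRUE)
  if (!by_env) agg$env <- "across"
  agg[, c("line", "env", "trait", "value")]
}

#' Standardize the item columns
#'
#' Each observed column is centered and scaled by its sample mean and
#' standard deviation (computed on observed cells; sample SD, n-1
#' denominator, the convention matching the Pearson weights); missing cells
#' stay missing. Constant columns (or columns with < 3 observations) are
#' dropped with a warning.
#'
#' @param M a [trait_env_matrix()].
#' @return List: `z` (standardized matrix), `mu`, `sigma` (per retained
#'   column), `dropped` (column names).
#' @export
ibcf_standardize <- function(M) {
  mu <- apply(M, 2L, mean, na.rm = TRUE)
  sigma <- apply(M, 2L, sd, na.rm = TRUE)
  n_obs <- colSums(!is.na(M))
  bad <- n_obs < 3 | is.na(sigma) | sigma == 0
  if (any(bad)) warning("dropping constant/sparse item column(s): ",
                        paste(colnames(M)[bad], collapse = ", "))
  keep <- which(!bad)
  z <- sweep(sweep(M[, keep, drop = FALSE], 2L, mu[keep]), 2L, sigma[keep], `/`)
  list(z = z, mu = mu[keep], sigma = sigma[keep],
       dropped = colnames(M)[bad])
}

#' Item-item similarity weights
#'
#' Pairwise-complete Pearson correlations between the standardized item
#' columns; pairs with fewer than `min_pairs` complete observations get a
#' missing weight.
#'
#' @param Z standardized matrix (the `z` element of [ibcf_standardize()]).
#' @param min_pairs minimum complete pairs per item pair (default 3).
#' @return Symmetric item x item weight matrix with unit diagonal.
#' @export
ibcf_similarity <- function(Z, min_pairs = 3) {
  W <- suppressWarnings(cor(Z, use = "pairwise.complete.obs"))
  np <- crossprod(!is.na(Z))
  W[np < min_pairs] <- NA
  diag(W) <- 1
  W
}

#' Predict missing cells by item-based collaborative filtering
#'
#' For a missing cell (line i, item j) the standardized prediction is the
#' weight-normalized sum over the neighborhood \eqn{N_i(j)} of items
#' observed for line i:
#' \deqn{\hat z_{ij} = \sum_{j' \in N_i(j)} z_{ij'} w_{jj'} \big/
#'       \sum_{j' \in N_i(j)} w_{jj'}}
#' de-standardized with the target column's mean and SD. The signed weight
#' sum in the denominator follows the printed collaborative-filtering
#' formula; `denominator = "abs"` switches to the absolute-value variant.
#' Predictions whose weight sum is below `1e-8` in absolute value are
#' returned as NA and flagged.
#'
#' @param M a [trait_env_matrix()].
#' @param neighborhood `"all"` observed items (default) or `"top-k"`.
#' @param k neighborhood size for `"top-k"` (by |w|).
#' @param restrict_to_other_envs only use neighbor items from environments
#'   other than the target item's.
#' @param denominator `"signed"` (default) or `"abs"`.
#' @param drop_negative drop negative-weight neighbors.
#' @param cells optional 2-column matrix / data.frame (line, item) of cells
#'   to predict; default: all missing cells.
#' @return data.frame `line`, `item`, `trait`, `env`, `predicted`,
#'   `flagged` (degenerate weight sum).
#' @export
ibcf_predict <- function(M, neighborhood = c("all", "top-k"), k = 10,
                         restrict_to_other_envs = FALSE,
                         denominator = c("signed", "abs"),
                         drop_negative = FALSE, cells = NULL) {
  neighborhood <- match.arg(neighborhood)
  denominator <- match.arg(denominator)
  std <- ibcf_standardize(M)
  Z <- std$z
  W <- ibcf_similarity(Z)
  items <- colnames(Z)
  item_env <- sub("^.*@", "", items)
  if (is.null(cells)) {
    idx <- which(is.na(M[, items, drop = FALSE]), arr.ind = TRUE)
    cells <- data.frame(line = rownames(M)[idx[, 1]], item = items[idx[, 2]])
  } else {
    cells <- as.data.frame(cells)
    names(cells)[1:2] <- c("line", "item")
  }
  pred <- rep(NA_real_, nrow(cells))
  flag <- rep(FALSE, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    li <- cells$line[i]; it <- cells$item[i]
    if (!it %in% items) next
    zrow <- Z[li, ]
    nb <- which(!is.na(zrow) & items != it & !is.na(W[it, ]))
    if (restrict_to_other_envs)
      nb <- nb[item_env[nb] != sub("^.*@", "", it)]
    w <- W[it, nb]
    if (drop_negative) { nb <- nb[w > 0]; w <- w[w > 0] }
    if (neighborhood == "top-k" && length(nb) > k) {
      ord <- order(abs(w), decreasing = TRUE)[seq_len(k)]
      nb <- nb[ord]; w <- w[ord]
    }
    if (!length(nb)) { flag[i] <- TRUE; next }
    den <- if (denominator == "signed") sum(w) else sum(abs(w))
    if (abs(den) < 1e-8) { flag[i] <- TRUE; next }
    zhat <- sum(zrow[nb] * w) / den
    pred[i] <- std$mu[it] + std$sigma[it] * zhat
  }
  data.frame(line = cells$line, item = cells$item,
             trait = sub("@.*$", "", cells$item),
             env = sub("^.*@", "", cells$item),
             predicted = pred, flagged = flag)
}

#' Hold-out evaluation of the collaborative-filtering predictor
#'
#' Incomplete-field-trial (CV2-style) evaluation: lines are split into
#' `k_folds` folds; each fold's target-trait cells in the target
#' environment are masked in turn and predicted from all remaining items
#' (the lines' records in the other environments plus the training lines'
#' records everywhere, from which the column statistics and item-item
#' weights are re-estimated). Every line is predicted exactly once; the
#' report is the per-trait Pearson correlation between the pooled
#' predictions and the held-out observations. Supplying `folds` (a list of
#' line-id vectors) instead reuses an external partition so the evaluation
#' can be paired with a GBLUP cross-validation on identical folds.
#'
#' @param M a [trait_env_matrix()].
#' @param target_env environment whose cells are held out.
#' @param target_traits traits to evaluate (default: all traits present in
#'   the target environment).
#' @param k_folds number of line folds (default 5, i.e. 80/20).
#' @param folds optional list of character vectors of line ids overriding
#'   the internal fold draw.
#' @param seed seed for the fold draw.
#' @param ... passed to [ibcf_predict()].
#' @return data.frame `trait`, `env`, `cor`, `n`; attribute `predictions`
#'   holds the pooled per-cell table.
#' @export
ibcf_cv2_evaluate <- function(M, target_env, target_traits = NULL,
                              k_folds = 5, folds = NULL, seed = 1, ...) {
  items <- colnames(M)
  envs <- sub("^.*@", "", items)
  if (length(setdiff(unique(envs), target_env)) < 2)
    stop("need >= 2 non-target environments")
  tgt_items <- items[envs == target_env]
  if (!is.null(target_traits))
    tgt_items <- tgt_items[sub("@.*$", "", tgt_items) %in% target_traits]
  if (!length(tgt_items)) stop("target column absent: ", target_env)
  if (is.null(folds)) {
    f <- with_seed(child_seed(seed, "ibcf_fold"),
                   sample(rep_len(seq_len(k_folds), nrow(M))))
    folds <- split(rownames(M), f)
  }
  preds <- list()
  for (fl in folds) {
    Mm <- M
    held <- which(!is.na(M) &
                    (col(M) %in% match(tgt_items, items)) &
                    (rownames(M)[row(M)] %in% fl))
    if (!length(held)) next
    Mm[held] <- NA
    cells <- data.frame(line = rownames(M)[row(M)[held]],
                        item = items[col(M)[held]])
    pr <- ibcf_predict(Mm, cells = cells, ...)
    pr$observed <- M[held]
    preds[[length(preds) + 1L]] <- pr
  }
  if (!length(preds)) stop("nothing to hold out: target cells are all missing")
  pr <- do.call(rbind, preds)
  out <- do.call(rbind, lapply(split(pr, pr$trait), function(d) {
    ok <- !is.na(d$predicted)
    data.frame(trait = d$trait[1], env = target_env,
               cor = if (sum(ok) >= 3) cor(d$predicted[ok], d$observed[ok])
                     else NA_real_,
               n = sum(ok))
  }))
  rownames(out) <- NULL
  attr(out, "predictions") <- pr
  out
}
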