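tem <- function(M) { class(M) <- c("trait_env_matrix", class(M)); M }

hand_matrix <- function() {
  # 6 lines x 4 items with two missing cells; values chosen by hand
  M <- matrix(c(1.0, 2.0, 3.0, 4.0, 5.0, 6.0,
                2.1, 3.9, 6.1, 8.0, 9.9, NA,
                5.0, 4.0, 3.2, 2.1, 1.0, 0.2,
                0.5, 1.8, NA, 4.2, 4.8, 6.3), 6, 4,
              dimnames = list(paste0("L", 1:6),
                              c("A@E1", "A@E2", "B@E1", "B@E2")))
  tem(M)
}

test_that("column standardization uses observed-cell sample moments and round-trips exactly", {
  M <- tem(matrix(c(1, 2, 3, 4, 10, 20, 30, NA), 4, 2,
                  dimnames = list(paste0("L", 1:4), c("A@E1", "A@E2"))))
  std <- ibcf_standardize(M)
  expect_equal(unname(std$z[, "A@E1"]), (1:4 - 2.5) / sd(1:4))
  expect_equal(unname(std$mu), c(2.5, 20))
  expect_equal(unname(std$sigma), c(sd(1:4), 10))
  expect_true(is.na(std$z[4, "A@E2"]))
  # inverse transform restores the observed cells exactly
  back <- sweep(sweep(std$z, 2L, std$sigma, `*`), 2L, std$mu, `+`)
  expect_equal(back[!is.na(M)], M[!is.na(M)])
  # an already-standardized column is unchanged
  z2 <- ibcf_standardize(tem(std$z))$z
  expect_equal(z2[, "A@E1"], std$z[, "A@E1"])
  # constant columns are dropped with a warning
  Mc <- tem(cbind(M, `C@E1` = c(7, 7, 7, 7)))
  expect_warning(stdc <- ibcf_standardize(Mc), "constant")
  expect_false("C@E1" %in% colnames(stdc$z))
})

test_that("item weights equal brute-force Pearson correlations on the hand matrix", {
  M <- hand_matrix()
  Z <- ibcf_standardize(M)$z
  W <- ibcf_similarity(Z)
  brute <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  for (i in 1:4) for (j in 1:4)
    expect_equal(W[i, j], brute(Z[, i], Z[, j]), tolerance = 1e-12)
  expect_equal(unname(diag(W)), rep(1, 4))
  # identical and negated columns
  M2 <- tem(cbind(M, `A2@E3` = M[, 1], `An@E3` = -M[, 1]))
  W2 <- ibcf_similarity(ibcf_standardize(M2)$z)
  expect_equal(W2["A@E1", "A2@E3"], 1, tolerance = 1e-12)
  expect_equal(W2["A@E1", "An@E3"], -1, tolerance = 1e-12)
})

test_that("predictions reproduce the weighted-neighborhood formula to machine precision", {
  M <- hand_matrix()
  pr <- ibcf_predict(M)
  std <- ibcf_standardize(M)
  W <- ibcf_similarity(std$z)
  # brute-force recomputation for every missing cell
  for (k in seq_len(nrow(pr))) {
    li <- pr$line[k]; it <- pr$item[k]
    zrow <- std$z[li, ]
    nb <- names(zrow)[!is.na(zrow) & names(zrow) != it]
    w <- W[it, nb]
    zhat <- sum(zrow[nb] * w) / sum(w)
    expect_equal(pr$predicted[k], std$mu[[it]] + std$sigma[[it]] * zhat,
                 tolerance = 1e-12)
  }
})

test_that("a single perfectly correlated neighbor transfers its standardized value", {
  # A@E2 = 2 * A@E1 + 1 exactly -> w = 1; L4 observed only at A@E1
  M <- tem(matrix(c(1, 2, 3, 1.2,
                    3, 5, 7, NA), 4, 2,
                  dimnames = list(paste0("L", 1:4), c("A@E1", "A@E2"))))
  pr <- ibcf_predict(M)
  std <- ibcf_standardize(M)
  expect_equal(pr$predicted[1],
               std$mu[["A@E2"]] + std$sigma[["A@E2"]] * std$z["L4", "A@E1"],
               tolerance = 1e-10)
})

test_that("equal weights average the neighbors and degenerate weight sums are flagged", {
  # three identical items (pairwise w = 1) and one target column
  base <- c(1, 2, 3, 4, 5)
  M <- tem(matrix(c(base, base, base, 2 * base + c(0, 0, 0, 0, NA)), 5, 4,
                  dimnames = list(paste0("L", 1:5),
                                  c("A@E1", "A@E2", "A@E3", "B@E1"))))
  pr <- ibcf_predict(M)
  std <- ibcf_standardize(M)
  zmean <- mean(std$z["L5", c("A@E1", "A@E2", "A@E3")])
  expect_equal(pr$predicted[1], std$mu[["B@E1"]] + std$sigma[["B@E1"]] * zmean,
               tolerance = 1e-10)
  # +1 and -1 weights cancel under the signed denominator -> flagged NA
  M2 <- tem(matrix(c(base, -base, 2 * base + c(0, 0, 0, 0, NA)), 5, 3,
                   dimnames = list(paste0("L", 1:5),
                                   c("A@E1", "An@E2", "B@E1"))))
  pr2 <- ibcf_predict(M2)
  expect_true(pr2$flagged[1])
  expect_true(is.na(pr2$predicted[1]))
  # the absolute-value denominator variant recovers a prediction
  pr3 <- ibcf_predict(M2, denominator = "abs")
  expect_false(pr3$flagged[1])
})

test_that("predictions are equivariant under affine transforms of the target column", {
  M <- hand_matrix()
  pr <- ibcf_predict(M)
  M2 <- M
  M2[, "A@E2"] <- 3 * M2[, "A@E2"] - 5
  pr2 <- ibcf_predict(M2)
  k <- pr$item == "A@E2"
  expect_equal(pr2$predicted[k], 3 * pr$predicted[k] - 5, tolerance = 1e-10)
})

test_that("the CV2-style evaluation guards its preconditions and recovers correlated structure", {
  g <- fx_geno_clean()
  tr <- simulate_trial(g, sigma2_G = 0.9, sigma2_GE = 0.1, sigma2_e = 0.25,
                       sigma2_rep = 0, sigma2_block = 0, seed = 121)
  pm <- line_means(tr$pheno)
  M <- trait_env_matrix(pm)
  ev <- ibcf_cv2_evaluate(M, target_env = "E1", seed = 9)
  expect_gt(ev$cor[ev$trait == "trait"], 0.5)
  # guard: fewer than 2 non-target environments
  M2 <- M[, 1:2]
  class(M2) <- class(M)
  expect_error(ibcf_cv2_evaluate(M2, target_env = "E1"), "non-target")
  expect_error(ibcf_cv2_evaluate(M, target_env = "E9"), "non-target|absent")
})

test_that("an independent target column transfers no signal", {
  set.seed(11)
  n <- 120
  shared <- rnorm(n)
  M <- tem(cbind(`A@E1` = shared + rnorm(n, 0, 0.3),
                 `A@E2` = shared + rnorm(n, 0, 0.3),
                 `B@E3` = rnorm(n)))
  rownames(M) <- paste0("L", seq_len(n))
  ev <- ibcf_cv2_evaluate(M, target_env = "E3", seed = 10)
  expect_lt(abs(ev$cor), 0.25)
})
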