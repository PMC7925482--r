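toy_geno <- function(values, chrom = NULL, pos = NULL) {
  m <- ncol(values)
  geno_matrix(values,
              data.frame(marker = paste0("m", seq_len(m)),
                         chrom = chrom %||% rep(1L, m),
                         pos = pos %||% (seq_len(m) * 100L)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the QC filter applies each rule strictly and reports the reasons", {
  # 40 lines; marker 2 has MAF 0.025, marker 4 has 50% missing, marker 5 is het-heavy
  v <- matrix(2L, 40, 5, dimnames = list(paste0("L", 1:40), NULL))
  v[1:16, 1] <- 0L                     # MAF 0.4: keep
  v[1, 2] <- 0L                        # MAF 0.025: drop
  v[1:12, 3] <- 0L                     # MAF 0.3: keep
  v[1:20, 4] <- NA_integer_            # 50% missing: drop regardless of MAF
  v[1:20, 5] <- 1L                     # 50% het: drop
  g <- toy_geno(v)
  gq <- filter_snps(g)
  expect_identical(gq$map$marker, c("m1", "m3"))
  rep_ <- attr(gq, "filter_report")
  expect_equal(unname(rep_["n_retained"]), 2)
  # a matrix already satisfying the thresholds passes unchanged
  g2 <- toy_geno(v[, c(1, 3)])
  expect_identical(filter_snps(g2)$values, g2$values)
  # monomorphic markers always go
  g3 <- toy_geno(cbind(v[, 1, drop = FALSE], matrix(2L, 40, 1)))
  expect_identical(ncol(filter_snps(g3)$values), 1L)
  expect_error(filter_snps(toy_geno(matrix(2L, 40, 1,
    dimnames = list(paste0("L", 1:40), NULL)))), "all markers")
})

test_that("mean imputation fills 2p, preserves marker means, and is the identity without missingness", {
  v <- matrix(c(0L, 2L, NA, 2L, 0L, 0L), 3, 2,
              dimnames = list(c("a", "b", "c"), NULL))
  g <- impute_missing(toy_geno(v))
  expect_equal(g$values[3, 1], 1.0)            # {0,2,NA}, p = 0.5 -> 1
  expect_equal(colMeans(g$values), colMeans(v, na.rm = TRUE),
               ignore_attr = TRUE)
  v2 <- matrix(c(0L, 1L, 2L, 2L), 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_equal(impute_missing(toy_geno(v2))$values, v2,
               ignore_attr = TRUE)
})

test_that("the VanRaden GRM matches the hand-computed 3x2 example and its invariances", {
  v <- matrix(c(0L, 2L, 2L, 2L, 0L, 2L), 3, 2,
              dimnames = list(c("a", "b", "c"), NULL))
  G <- vanraden_grm(v)
  expect_equal(unname(G),
               matrix(c(2.5, -2, -0.5, -2, 2.5, -0.5, -0.5, -0.5, 1), 3, 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(G, "denominator"), 8 / 9, tolerance = 1e-12)
  # duplicated line: identical rows/columns
  v2 <- rbind(v, d = v["a", ])
  G2 <- vanraden_grm(v2)
  expect_equal(G2["a", ], G2["d", ], ignore_attr = TRUE)
  # invariant to marker order and allele-label swap (0 <-> 2)
  g <- fx_geno_clean()
  w <- g$values[1:60, 1:100]
  Ga <- vanraden_grm(w)
  set.seed(7)
  expect_equal(unname(vanraden_grm(w[, sample(100)])), unname(Ga),
               tolerance = 1e-10, ignore_attr = TRUE)
  w2 <- w; w2[, 1:50] <- 2L - w2[, 1:50]
  expect_equal(unname(vanraden_grm(w2)), unname(Ga), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("GRM diagonal of a fully inbred panel averages 1 + f with f near 1", {
  g <- simulate_genotypes(400, 800, n_subpops = 1, fst = 0, het_rate = 0,
                          missing_rate = 0, seed = 51)
  G <- vanraden_grm(g$values)
  expect_equal(mean(diag(G)), 2, tolerance = 0.1)
})

test_that("genotype PCA has ordered spectra, orthogonal scores, and separates subpopulations", {
  g <- fx_geno_qc()
  pc <- pca_genotypes(g$values, n_pc = 4)
  expect_true(all(diff(pc$varexp) <= 1e-12))
  expect_lte(sum(pc$varexp), 1)
  cp <- crossprod(pc$scores)
  expect_lt(max(abs(cp[upper.tri(cp)])) / max(diag(cp)), 1e-8)
  # two well-separated subpopulations split on PC1 by sign
  g2 <- simulate_genotypes(200, 400, n_subpops = 2, fst = 0.3,
                           het_rate = 0, missing_rate = 0, seed = 55)
  pc2 <- pca_genotypes(g2$values, n_pc = 2)
  sp <- attr(g2, "subpop")
  s <- sign(pc2$scores[, 1])
  acc <- max(mean(s[sp == 1] > 0) + mean(s[sp == 2] < 0),
             mean(s[sp == 1] < 0) + mean(s[sp == 2] > 0)) / 2
  expect_gte(acc, 0.95)
  expect_error(pca_genotypes(g2$values, n_pc = 200), "n_pc")
})

test_that("PCA scores agree with the GRM eigenvectors at matching eigenvalues up to sign", {
  g <- fx_geno_clean()
  v <- g$values[1:80, ]
  pc <- pca_genotypes(v, n_pc = 3)
  W <- scale(v, center = TRUE, scale = FALSE)
  ei <- eigen(tcrossprod(W), symmetric = TRUE)
  for (k in 1:3) {
    sc <- ei$vectors[, k] * sqrt(ei$values[k])
    expect_equal(abs(cor(pc$scores[, k], sc)), 1, tolerance = 1e-6)
  }
})

test_that("LD decay bins track the chain oracle and the effective-test rule is genome/d0.1", {
  g <- simulate_genotypes(400, 1200, n_chrom = 4, n_subpops = 1, fst = 0,
                          ld_rho = 0.9, het_rate = 0, missing_rate = 0,
                          seed = 61)
  ld <- ld_decay(g, max_dist_bp = 20000)
  # per-lag binned means against the analytic per-pair expectation
  for (lag in 1:3) {
    ana <- c()
    for (ch in unique(g$map$chrom)) {
      ix <- which(g$map$chrom == ch)
      a <- ix[seq_len(length(ix) - lag)]
      ana <- c(ana, sapply(a, function(j) ld_markov_r(g, j, j + lag)^2))
    }
    b <- ld$bins[which.min(abs(ld$bins$distance - lag * 1000)), ]
    expect_lt(abs(b$r2 - mean(ana)), 0.03)
  }
  expect_gte(ld$d_r2_0.1, ld$d_r2_0.2)
  expect_equal(ld$n_effective_tests, ld$genome_length_bp / ld$d_r2_0.1,
               tolerance = 1e-12)
  expect_equal(ld$threshold, 0.05 / ld$n_effective_tests, tolerance = 1e-12)
})

test_that("a duplicated marker contributes r2 = 1 at its distance", {
  set.seed(3)
  base <- matrix(as.integer(2 * rbinom(40 * 3, 1, 0.5)), 40, 3,
                 dimnames = list(paste0("L", 1:40), NULL))
  v <- cbind(base[, 1], base[, 1], base[, 2], base[, 3])
  storage.mode(v) <- "integer"
  rownames(v) <- paste0("L", 1:40)
  g <- toy_geno(v, pos = c(100L, 200L, 300L, 400L))
  ld <- ld_decay(g, max_dist_bp = 1000, bin_width = 100)
  b1 <- ld$bins[ld$bins$distance == 100, ]
  expect_gte(b1$r2, 1 / b1$n)          # the duplicate pair contributes r2 = 1
  expect_true(any(ld$pairs$r2[ld$pairs$distance == 100] == 1))
})

test_that("filter -> impute -> GRM is idempotent on its own output", {
  g <- fx_geno_qc()
  g2 <- impute_missing(filter_snps(geno_matrix(round(g$values), g$map),
                                   maf_min = 0.05))
  expect_identical(dim(g2$values), dim(filter_snps(geno_matrix(round(g2$values), g2$map))$values))
})
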