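test_that("AUDPC reproduces hand trapezoid sums and is linear in the measurements", {
  expect_equal(audpc(c(5, 5, 5), c(56, 70, 84)), 140)
  expect_equal(audpc(c(0, 10), c(0, 14)), 70)
  expect_equal(audpc(c(6.2, 30, 65), c(56, 70, 84)), 918.4)
  # linearity on a common time grid
  t <- c(56, 70, 84)
  y1 <- c(1, 4, 2); y2 <- c(3, 0, 5)
  expect_equal(audpc(2 * y1 + 3 * y2, t),
               2 * audpc(y1, t) + 3 * audpc(y2, t))
  expect_error(audpc(c(1, 2), c(3, 3)), "increasing")
  expect_error(audpc(c(1, 2, 3), c(1, 2)), "length")
})

test_that("entry-mean heritability follows the variance-component formula and its invariances", {
  vc <- function(G, GE, e, E = 3, R = 2)
    list(sigma2_G = G, sigma2_GE = GE, sigma2_e = e, E = E, R = R)
  expect_equal(entry_mean_heritability(vc(1, 0, 0)), 1)
  # invariant to rescaling all components by a positive constant
  h <- entry_mean_heritability(vc(0.78, 0.10, 0.72))
  expect_equal(entry_mean_heritability(vc(7.8, 1.0, 7.2)), h)
  expect_true(h >= 0 && h <= 1)
  expect_error(entry_mean_heritability(vc(0, 0, 0)), "undefined")
  expect_error(entry_mean_heritability(vc(-1, 0, 1)), ">= 0")
})

test_that("BLUEs equal arithmetic line means on a balanced two-environment trial without blocks", {
  set.seed(2)
  lines <- paste0("L", 1:8)
  d <- expand.grid(line = lines, env = c("E1", "E2"), rep = c("R1", "R2"),
                   stringsAsFactors = FALSE)
  d$block <- NA
  d$trait <- "y"
  d$value <- rnorm(nrow(d)) + rep(seq(0, 3.5, by = 0.5), 4) +
    ifelse(d$env == "E2", 2, 0)
  fit <- fit_mixed_model(d, "y", scope = "across", genotype_as = "fixed")
  m <- tapply(d$value, d$line, mean)
  expect_equal(fit$lines$blue, as.numeric(m[fit$lines$line]),
               tolerance = 1e-6)
})

test_that("BLUPs are shrunken towards the grand mean relative to BLUEs", {
  g <- fx_geno_clean()
  tr <- simulate_trial(g, sigma2_G = 0.5, sigma2_e = 1.5, seed = 17)
  fr <- fit_mixed_model(tr$pheno, "trait", genotype_as = "random")
  fb <- fit_mixed_model(tr$pheno, "trait", genotype_as = "fixed")
  expect_lt(var(fr$lines$blup), var(fb$lines$blue))
  # shrinkage keeps the ordering broadly intact
  expect_gt(cor(fr$lines$blup, fb$lines$blue[match(fr$lines$line, fb$lines$line)]),
            0.95)
})

test_that("a noise-free balanced trial yields a near-zero residual variance and BLUEs = raw means", {
  g <- fx_geno_clean()
  tr <- simulate_trial(g, sigma2_G = 1, sigma2_GE = 0, sigma2_e = 0,
                       sigma2_rep = 0, sigma2_block = 0, seed = 23)
  fit <- fit_mixed_model(tr$pheno, "trait", genotype_as = "fixed")
  expect_lt(fit$vc$sigma2_e, 1e-6)
  m <- tapply(tr$pheno$value, tr$pheno$line, mean)
  expect_equal(fit$lines$blue, as.numeric(m[fit$lines$line]),
               tolerance = 1e-4)
})

test_that("REML on duplicated records leaves the genotypic variance essentially unchanged", {
  g <- fx_geno_clean()
  tr <- simulate_trial(g, seed = 29)
  f1 <- fit_mixed_model(tr$pheno, "trait")
  f2 <- fit_mixed_model(rbind(tr$pheno, tr$pheno), "trait")
  expect_equal(f2$vc$sigma2_G, f1$vc$sigma2_G, tolerance = 0.15)
})

test_that("trait correlations carry unit diagonal, antisymmetry, and t-based significance cutoffs", {
  set.seed(5)
  df <- data.frame(line = paste0("L", 1:380), a = rnorm(380))
  df$b <- -df$a
  df$c <- rnorm(380)
  tc <- trait_correlations(df)
  expect_equal(unname(diag(tc$r)), rep(1, 3))
  expect_equal(tc$r["a", "b"], -1)
  # at n = 380, |r| = 0.12 is significant at 5% and 0.16 at 1% (t oracle)
  p_of_r <- function(r, n) 2 * pt(abs(r) * sqrt((n - 2) / (1 - r^2)),
                                  df = n - 2, lower.tail = FALSE)
  expect_lte(p_of_r(0.12, 380), 0.05)
  expect_lte(p_of_r(0.16, 380), 0.01)
  expect_lt(tc$cutoff_05, 0.12)
  expect_lt(tc$cutoff_01, 0.16)
  expect_gt(tc$cutoff_01, tc$cutoff_05)
  # constant trait is flagged and emitted as missing
  df$d <- 1
  tc2 <- suppressWarnings(trait_correlations(df))
  expect_true("d" %in% tc2$flagged)
  expect_true(all(is.na(tc2$r["d", c("a", "b", "c")])))
})

test_that("outlier removal drops exactly the injected aberrant record and nothing else in bulk", {
  g <- fx_geno_clean()
  tr <- simulate_trial(g, seed = 31)
  ph <- tr$pheno
  # z_max = Inf is the identity
  same <- remove_outliers(ph, "trait", z_max = Inf)
  expect_identical(nrow(same), nrow(ph))
  # clean Gaussian data: near-null removal at 3.5 SD
  cl <- remove_outliers(ph, "trait", z_max = 3.5)
  expect_lte(attr(cl, "n_removed"), ceiling(0.005 * nrow(ph)))
  # inject a +10 SD record
  i <- 17L
  ph2 <- ph
  ph2$value[i] <- ph2$value[i] + 10 * sd(ph$value)
  out <- remove_outliers(ph2, "trait", z_max = 3.5)
  expect_false(any(rownames(out) == rownames(ph2)[i]))
  expect_gte(attr(out, "n_removed"), 1L)
})

test_that("derived AUSNPC rows equal the per-plot trapezoid of the count traits", {
  sim <- fx_panel()
  ph <- sim$pheno
  aus <- ph[ph$trait == "AUSNPC", ]
  expect_equal(nrow(aus), 100 * 3 * 2)
  one <- aus[aus$line == "L001" & aus$env == "E1" & aus$rep == "R1", ]
  y <- sapply(c("nStr_8WAP", "nStr_10WAP", "nStr_12WAP"), function(tr)
    ph$value[ph$line == "L001" & ph$env == "E1" & ph$rep == "R1" & ph$trait == tr])
  expect_equal(one$value, audpc(y, c(56, 70, 84)))
})

test_that("the environment screen keeps environments with real genotypic signal and flags junk", {
  g <- fx_geno_clean()
  tr <- simulate_trial(g, sigma2_G = 1, sigma2_e = 0.5, seed = 37)
  sc <- screen_environments(tr$pheno, "trait")
  expect_true(all(sc$keep))
  # destroy the genetic signal in one environment by shuffling lines
  set.seed(99)
  ph <- tr$pheno
  e1 <- ph$env == "E1"
  ph$value[e1] <- sample(ph$value[e1])
  sc2 <- screen_environments(ph, "trait")
  expect_false(sc2$keep[sc2$env == "E1"])
  expect_true(all(sc2$keep[sc2$env != "E1"]))
})
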