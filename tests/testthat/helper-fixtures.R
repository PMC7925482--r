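# Shared fixtures, built once per test run and memoized.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# canonical small panel: 100 lines x 500 markers x 3 env
fx_panel <- function() memo("panel", striga_fixture(seed = 1))

# QC'd + imputed genotypes and the GRM of the canonical panel
fx_geno_qc <- function() memo("geno_qc", impute_missing(filter_snps(fx_panel()$geno)))
fx_grm <- function() memo("grm", vanraden_grm(fx_geno_qc()$values))

# clean mid-sized genotype panel without het/missing (oracle tests)
fx_geno_clean <- function() memo("geno_clean",
  simulate_genotypes(n_lines = 150, n_markers = 400, n_chrom = 5,
                     n_subpops = 1, fst = 0, ld_rho = 0.5,
                     het_rate = 0, missing_rate = 0, seed = 42))

# line x environment means for one trait of a simulated trial
trait_env_means <- function(pheno, trait) {
  pm <- line_means(pheno[pheno$trait == trait, , drop = FALSE])
  Y <- trait_env_matrix(pm)
  colnames(Y) <- sub("^.*@", "", colnames(Y))
  unclass(Y)
}
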