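test_that("a hand-written toy VCF is transcribed exactly and round-trips", {
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "L1", "L2", "L3", sep = "\t"),
    paste(1, 100, "s1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste(1, 200, "s2", "C", "T", ".", "PASS", ".", "GT",
          "1/1", "./.", "0/0", sep = "\t"),
    paste(2, 150, "s3", "G", "A", ".", "PASS", ".", "GT",
          "0|1", "1/1", "0/0", sep = "\t"))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines, f)
  g <- read_vcf(f)
  expect_equal(unname(g$values),
               matrix(c(0L, 1L, 2L, 2L, NA, 0L, 1L, 2L, 0L), 3, 3),
               ignore_attr = TRUE)
  expect_identical(rownames(g$values), c("L1", "L2", "L3"))
  expect_identical(g$map$pos, c(100L, 200L, 150L))
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, f2)
  g2 <- read_vcf(f2)
  expect_identical(g$values, g2$values)
  expect_identical(g$map, g2$map)
})

test_that("HapMap readers accept IUPAC single-letter and two-letter het codes as dosage 1", {
  hm <- c(paste("rs", "alleles", "chrom", "pos", "L1", "L2", "L3", sep = "\t"),
          paste("s1", "A/G", "1", "100", "A", "R", "GG", sep = "\t"),
          paste("s2", "C/T", "1", "200", "CT", "N", "C", sep = "\t"))
  f <- withr::local_tempfile(fileext = ".hmp.txt")
  writeLines(hm, f)
  g <- read_hapmap(f)
  expect_equal(unname(g$values),
               matrix(c(0L, 1L, 2L, 1L, NA, 0L), 3, 2),
               ignore_attr = TRUE)
  # writer -> reader round trip on simulated data with missing + het calls
  gg <- simulate_genotypes(12, 30, n_chrom = 2, het_rate = 0.05,
                           missing_rate = 0.05, seed = 131)
  f2 <- withr::local_tempfile(fileext = ".hmp.txt")
  write_hapmap(gg, f2)
  g2 <- read_hapmap(f2)
  expect_identical(unname(gg$values), unname(g2$values))
})

test_that("dosage CSV export round-trips values, ids and map", {
  gg <- simulate_genotypes(10, 25, n_chrom = 2, seed = 133)
  f <- withr::local_tempfile(fileext = ".csv")
  write_geno_csv(gg, f)
  g2 <- read_geno_csv(f)
  expect_identical(unname(gg$values), unname(g2$values))
  expect_identical(rownames(gg$values), rownames(g2$values))
  expect_equal(gg$map$pos, g2$map$pos)
})

test_that("the pipeline completes on the fixture panel and is byte-reproducible", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- list(seed = 11, out_dir = out1,
              simulate = list(n_lines = 80, n_markers = 300, n_env = 3,
                              n_rep = 2),
              predict = list(trait = "GY", schemes = c("CV1", "CV2"),
                             models = "G+GE", n_repetitions = 2),
              ibcf = list(target_envs = "E1"))
  r1 <- suppressMessages(run_pipeline(do.call(default_config, cfg)))
  expect_true(r1$ok)
  expect_true(all(file.exists(file.path(out1,
    c("variance_components.csv", "blues.csv", "grm.tsv", "cv_accuracy.csv",
      "ibcf_cv2.csv", "gwas_hits.csv")))))
  cfg$out_dir <- out2
  r2 <- suppressMessages(run_pipeline(do.call(default_config, cfg)))
  for (fn in c("variance_components.csv", "cv_accuracy.csv", "ibcf_cv2.csv")) {
    expect_identical(readLines(file.path(out1, fn)),
                     readLines(file.path(out2, fn)))
  }
  # every emitted CSV re-parses with a header
  for (fn in list.files(out1, pattern = "\\.csv$")) {
    df <- read.csv(file.path(out1, fn))
    expect_gt(ncol(df), 0)
  }
})

test_that("missing input files raise clean errors naming the path", {
  expect_error(read_genotypes("/no/such/file.vcf"), "no/such/file")
  cfg <- default_config(genotype_file = "/no/such/file.vcf",
                        phenotype_file = "/no/such/pheno.csv")
  expect_error(suppressMessages(run_pipeline(cfg)), "file")
})

test_that("stage seeds derive stably from the master seed and differ across stages", {
  expect_identical(child_seed(42, "gwas"), child_seed(42, "gwas"))
  expect_false(child_seed(42, "gwas") == child_seed(42, "predict"))
  expect_false(child_seed(42, "gwas") == child_seed(43, "gwas"))
  expect_true(child_seed(2147483646, "x") < 2^31)
})

test_that("YAML configuration files are honored", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(seed = 7, simulate = list(n_lines = 30)), f)
  cfg <- strigapanel:::read_config(f)
  expect_equal(cfg$seed, 7)
  expect_equal(cfg$simulate$n_lines, 30)
  expect_equal(cfg$simulate$n_markers, 500)   # default preserved
})
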