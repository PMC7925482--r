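#' Default pipeline configuration
#'
#' Returns the full configuration list of [run_pipeline()] with the package
#' defaults; any element can be overridden by the supplied list / YAML.
#'
#' @param ... named overrides (nested lists merged shallowly per stage).
#' @return Named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    out_dir = NULL,
    genotype_file = NULL,          # VCF / HapMap TSV / dosage CSV; NULL = simulate
    phenotype_file = NULL,         # long CSV; NULL = simulate
    stages = c("pheno", "qc", "gwas", "predict", "ibcf"),
    simulate = list(n_lines = 100, n_markers = 500, n_env = 3, n_rep = 2),
    qc = list(maf_min = 0.05, missing_max = 0.05, het_max = 0.05,
              n_pcs = 3, ld_window_bp = 50000),
    pheno = list(traits = NULL, z_max = 3.5),
    gwas = list(traits = NULL, threshold_traits = 2e-6, threshold_gy = 5.6e-6,
                use_ld_threshold = FALSE),
    predict = list(trait = NULL, schemes = c("CV0", "CV1", "CV2"),
                   models = c("G", "G+GE"), k_folds = 5, n_repetitions = 10,
                   augment = "none"),
    ibcf = list(target_envs = NULL))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  class(cfg) <- "run_config"
  cfg
}

read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(default_config, cfg)
}

#' Load genotypes from any supported format
#'
#' Dispatches on file extension: `.vcf`/`.vcf.gz` (VCF GT field),
#' `.hmp.txt`/`.hapmap`/`.tsv` (HapMap-like TSV), `.csv` (dosage matrix with
#' `<file>.map.csv` alongside).
#'
#' @param path genotype file.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path)) return(read_vcf(path))
  if (grepl("\\.(hmp\\.txt|hapmap|tsv|txt)$", path)) return(read_hapmap(path))
  if (grepl("\\.csv$", path)) return(read_geno_csv(path))
  stop("unrecognized genotype format: ", path)
}

#' Run the end-to-end panel analysis
#'
#' Executes the requested stages in order on user data or on a freshly
#' simulated panel: stage-1 phenotypic mixed models (variance components,
#' entry-mean heritability, BLUEs/BLUPs, trait correlations), marker QC /
#' GRM / PCA / LD decay, association scans, genomic-prediction
#' cross-validation, and the collaborative-filtering comparison. Each
#' stage's tables are written as CSV into `out_dir` (if set) and returned.
#' A stage failure is caught, logged, and dependent stages are skipped.
#'
#' @param config a [default_config()] list, a YAML path, or NULL.
#' @param ... overrides passed to [default_config()] when `config` is NULL.
#' @return Named list with one element per executed stage plus `log`;
#'   element `ok` is FALSE when any stage failed.
#' @export
run_pipeline <- function(config = NULL, ...) {
  cfg <- if (is.null(config)) default_config(...)
         else if (is.character(config)) read_config(config)
         else do.call(default_config, unclass(config))
  out <- list(config = cfg, log = character(), ok = TRUE)
  say <- function(...) {
    msg <- sprintf(...)
    out$log <<- c(out$log, msg)
    message(msg)
  }
  emit <- function(df, name) {
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      write.csv(df, file.path(cfg$out_dir, paste0(name, ".csv")),
                row.names = FALSE)
    }
  }
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(unclass(cfg)[!vapply(cfg, is.null, TRUE)],
                     file.path(cfg$out_dir, "config.yaml"))
  }
  # ---- inputs ----
  if (is.null(cfg$genotype_file) || is.null(cfg$phenotype_file)) {
    say("simulate: %d lines x %d markers x %d env",
        cfg$simulate$n_lines, cfg$simulate$n_markers, cfg$simulate$n_env)
    sim <- simulate_striga_panel(n_lines = cfg$simulate$n_lines,
                                 n_markers = cfg$simulate$n_markers,
                                 n_env = cfg$simulate$n_env,
                                 n_rep = cfg$simulate$n_rep,
                                 seed = child_seed(cfg$seed, "simulate"))
    geno <- sim$geno; pheno <- sim$pheno
  } else {
    geno <- read_genotypes(cfg$genotype_file)
    pheno <- read_pheno_csv(cfg$phenotype_file)
  }
  say("inputs: %d lines, %d markers, %d phenotype records",
      nrow(geno$values), ncol(geno$values), nrow(pheno))
  traits <- cfg$pheno$traits %||% unique(pheno$trait)

  run_stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    t0 <- Sys.time()
    r <- tryCatch(fun(), error = function(e) {
      say("stage %s FAILED: %s", name, conditionMessage(e))
      out$ok <<- FALSE
      NULL
    })
    if (!is.null(r)) say("stage %s done (%.1fs)", name,
                         as.numeric(Sys.time() - t0, units = "secs"))
    r
  }

  blues <- NULL; blups <- NULL
  out$pheno <- run_stage("pheno", function() {
    vc_rows <- list(); line_tabs <- list(); blup_tabs <- list()
    for (tr in traits) {
      ph <- remove_outliers(pheno, tr, cfg$pheno$z_max)
      fr <- fit_mixed_model(ph, tr, scope = "across", genotype_as = "random")
      fb <- fit_mixed_model(ph, tr, scope = "across", genotype_as = "fixed")
      h2 <- entry_mean_heritability(fr$vc)
      vc_rows[[tr]] <- data.frame(trait = tr, sigma2_G = fr$vc$sigma2_G,
                                  sigma2_GE = fr$vc$sigma2_GE,
                                  sigma2_e = fr$vc$sigma2_e, E = fr$vc$E,
                                  R = fr$vc$R, h2 = h2)
      line_tabs[[tr]] <- setNames(fb$lines, c("line", tr))
      blup_tabs[[tr]] <- setNames(fr$lines, c("line", tr))
    }
    vc_tab <- do.call(rbind, vc_rows); rownames(vc_tab) <- NULL
    blues <<- Reduce(function(a, b) merge(a, b, by = "line", all = TRUE),
                     line_tabs)
    blups <<- Reduce(function(a, b) merge(a, b, by = "line", all = TRUE),
                     blup_tabs)
    corr <- trait_correlations(blues)
    emit(vc_tab, "variance_components")
    emit(blues, "blues")
    emit(blups, "blups")
    emit(data.frame(trait = rownames(corr$r), corr$r, check.names = FALSE),
         "trait_correlations")
    list(vc = vc_tab, blues = blues, blups = blups, correlations = corr)
  })

  geno_qc <- NULL; G <- NULL; pcs <- NULL; ld <- NULL
  out$qc <- run_stage("qc", function() {
    gq <- filter_snps(geno, cfg$qc$maf_min, cfg$qc$missing_max, cfg$qc$het_max)
    gq <- impute_missing(gq)
    geno_qc <<- gq
    G <<- vanraden_grm(gq)
    pcs <<- pca_genotypes(gq$values, n_pc = cfg$qc$n_pcs)
    ld <<- ld_decay(gq, max_dist_bp = cfg$qc$ld_window_bp)
    say("qc: retained %d/%d markers; LD d(r2=0.1) = %.0f bp; %.0f effective tests",
        ncol(gq$values), ncol(geno$values), ld$d_r2_0.1, ld$n_effective_tests)
    if (!is.null(cfg$out_dir)) write_grm(G, file.path(cfg$out_dir, "grm.tsv"))
    emit(data.frame(line = rownames(pcs$scores), pcs$scores), "pcs")
    emit(ld$bins, "ld_decay_bins")
    list(geno = gq, report = attr(gq, "filter_report"), grm = G, pca = pcs,
         ld = ld)
  })

  out$gwas <- run_stage("gwas", function() {
    if (is.null(G)) stop("qc stage required before gwas")
    if (is.null(blups)) stop("pheno stage required before gwas")
    gtraits <- cfg$gwas$traits %||% intersect(traits, names(blups))
    scans <- list(); hit_rows <- list()
    for (tr in gtraits) {
      y <- setNames(blups[[tr]], blups$line)
      y <- y[!is.na(y)]
      null <- fit_null_mlm(y, pcs$scores[names(y), , drop = FALSE],
                           G[names(y), names(y)])
      sc <- gwas_scan(y, geno_qc[names(y), ],
                      covariates = pcs$scores[names(y), , drop = FALSE],
                      null = null, method = "MLM")
      thr <- if (cfg$gwas$use_ld_threshold) ld$threshold
             else if (tr == "GY") cfg$gwas$threshold_gy
             else cfg$gwas$threshold_traits
      hits <- significant_hits(sc, threshold = thr, alleles = geno_qc$alleles)
      ve <- if (nrow(hits)) {
        h2 <- entry_mean_heritability(
          fit_mixed_model(pheno, tr, scope = "across")$vc)
        variance_explained(y, hits, geno_qc, h2)
      } else list(R2_adj = 0, p_G = 0)
      if (nrow(hits))
        hit_rows[[tr]] <- cbind(trait = tr, hits, R2_adj = ve$R2_adj,
                                p_G = ve$p_G)
      scans[[tr]] <- sc
      emit(sc, paste0("gwas_", tr))
    }
    hit_tab <- if (length(hit_rows)) do.call(rbind, hit_rows) else
      data.frame(trait = character(), snp = character(), chrom = integer(),
                 pos = integer(), p = numeric(), effect_minor = numeric(),
                 maf = numeric(), alleles = character(), R2_adj = numeric(),
                 p_G = numeric())
    emit(hit_tab, "gwas_hits")
    list(scans = scans, hits = hit_tab)
  })

  out$predict <- run_stage("predict", function() {
    if (is.null(G)) stop("qc stage required before predict")
    tr <- cfg$predict$trait %||% traits[1]
    pm <- line_means(pheno[pheno$trait == tr, ])
    Y <- trait_env_matrix(pm)
    colnames(Y) <- sub("^.*@", "", colnames(Y))
    res <- list()
    for (sc in cfg$predict$schemes) for (md in cfg$predict$models) {
      if (sc == "across" && md == "G+GE") next
      res[[paste(sc, md)]] <- run_cv(
        unclass(Y), G, scheme = sc, model = md,
        k_folds = cfg$predict$k_folds,
        n_repetitions = cfg$predict$n_repetitions,
        seed = child_seed(cfg$seed, "predict"),
        augment = cfg$predict$augment)
    }
    cv <- do.call(rbind, res); rownames(cv) <- NULL
    emit(cv, "cv_accuracy")
    emit(summarize_cv(cv), "cv_summary")
    list(trait = tr, cv = cv, summary = summarize_cv(cv))
  })

  out$ibcf <- run_stage("ibcf", function() {
    pm <- line_means(pheno)
    M <- trait_env_matrix(pm)
    envs <- cfg$ibcf$target_envs %||% unique(sub("^.*@", "", colnames(M)))
    comp <- do.call(rbind, lapply(envs, function(e)
      ibcf_cv2_evaluate(M, target_env = e)))
    emit(comp, "ibcf_cv2")
    list(matrix = M, cv2 = comp)
  })

  out$geno <- geno
  out$pheno_table <- pheno
  invisible(out)
}
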