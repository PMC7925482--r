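#' Marker quality-control filter
#'
#' Retains markers with minor allele frequency strictly above `maf_min`,
#' missing fraction strictly below `missing_max` and heterozygosity strictly
#' below `het_max`; monomorphic markers are always dropped.
#'
#' @param geno a [geno_matrix()].
#' @param maf_min,missing_max,het_max thresholds (defaults 0.05 / 0.05 /
#'   0.05, the standard GBS panel filter).
#' @return Filtered [geno_matrix()]; attribute `filter_report` counts
#'   markers dropped by each rule.
#' @export
filter_snps <- function(geno, maf_min = 0.05, missing_max = 0.05,
                        het_max = 0.05) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, missing_max >= 0, missing_max <= 1,
            het_max >= 0, het_max <= 1)
  st <- marker_stats(geno)
  mono <- st$maf == 0 | is.nan(st$maf)
  keep <- !mono & st$maf > maf_min & st$missing < missing_max & st$het < het_max
  if (!any(keep)) stop("all markers removed by QC filters")
  out <- geno[, which(keep)]
  attr(out, "filter_report") <- c(
    n_in = nrow(st), n_retained = sum(keep), monomorphic = sum(mono),
    low_maf = sum(!mono & st$maf <= maf_min),
    high_missing = sum(st$missing >= missing_max),
    high_het = sum(st$het >= het_max, na.rm = TRUE))
  out
}

# marker-mean imputation on a raw dosage matrix
impute_dosage <- function(v) {
  miss <- is.na(v)
  if (!any(miss)) return(v)
  mu <- colMeans(v, na.rm = TRUE)
  if (anyNA(mu)) stop("fully-missing marker cannot be imputed")
  idx <- which(miss, arr.ind = TRUE)
  v <- matrix(as.numeric(v), nrow(v), ncol(v), dimnames = dimnames(v))
  v[idx] <- mu[idx[, 2L]]
  v
}

#' Mean-impute missing genotype calls
#'
#' Missing entries are replaced by the marker mean dosage (2p). The output
#' matrix is numeric (imputed values are fractional) with no missing values;
#' per-marker means are preserved exactly.
#'
#' @param geno a [geno_matrix()].
#' @return The imputed genotype object; `$values` becomes numeric.
#' @export
impute_missing <- function(geno) {
  geno$values <- impute_dosage(geno$values)
  geno
}

#' VanRaden genomic relationship matrix
#'
#' \deqn{G = W W^T / (2 \sum_k p_k (1 - p_k))} with `W` the
#' allele-frequency-centered dosage matrix (`genotype - 2p` per marker) and
#' `p` estimated from the sample.
#'
#' @param geno a [geno_matrix()] (or plain dosage matrix) without missing
#'   values (run [impute_missing()] first).
#' @return lines x lines relationship matrix with attributes `denominator`
#'   and `allele_freqs`.
#' @export
vanraden_grm <- function(geno) {
  v <- if (inherits(geno, "geno_matrix")) geno$values else as.matrix(geno)
  if (anyNA(v)) stop("GRM requires imputed genotypes (no missing values)")
  p <- colMeans(v) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2) stop("need >= 2 polymorphic markers")
  den <- 2 * sum(p * (1 - p))
  if (den <= 0) stop("zero denominator: all markers monomorphic")
  W <- sweep(v, 2L, 2 * p)
  G <- tcrossprod(W) / den
  attr(G, "denominator") <- den
  attr(G, "allele_freqs") <- p
  G
}

#' Identity-by-state kinship
#'
#' Proportion of shared alleles between lines, `1 - mean(|x - y|) / 2` over
#' markers; the simple alternative kinship for MLM association scans.
#'
#' @inheritParams vanraden_grm
#' @return lines x lines IBS similarity matrix in `[0, 1]`.
#' @export
ibs_kinship <- function(geno) {
  v <- if (inherits(geno, "geno_matrix")) geno$values else as.matrix(geno)
  if (anyNA(v)) stop("IBS kinship requires imputed genotypes")
  n <- nrow(v)
  D <- as.matrix(dist(v, method = "manhattan")) / (2 * ncol(v))
  K <- 1 - D
  dimnames(K) <- list(rownames(v), rownames(v))
  K
}

#' Principal components of the genotype matrix
#'
#' PCA of the column-centered (optionally standardized) dosage matrix, the
#' standard population-structure covariates for association scans.
#'
#' @param geno imputed [geno_matrix()] or dosage matrix.
#' @param n_pc number of components to return.
#' @param scale standardize markers to unit variance first?
#' @return List: `scores` (lines x n_pc), `varexp` (fraction of variance
#'   explained per returned component, non-increasing).
#' @export
pca_genotypes <- function(geno, n_pc = 3, scale = FALSE) {
  v <- if (inherits(geno, "geno_matrix")) geno$values else as.matrix(geno)
  if (anyNA(v)) stop("PCA requires imputed genotypes")
  if (n_pc >= min(dim(v))) stop("n_pc must be < min(lines, markers)")
  keep <- apply(v, 2L, sd) > 0
  pr <- prcomp(v[, keep, drop = FALSE], center = TRUE, scale. = scale)
  varexp <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = pr$x[, seq_len(n_pc), drop = FALSE],
       varexp = varexp[seq_len(n_pc)])
}

#' Linkage-disequilibrium decay and the effective number of tests
#'
#' Computes squared dosage correlations (composite r-squared, appropriate
#' for unphased inbred data) for all marker pairs within `max_dist_bp` on
#' the same chromosome, bins them by physical distance, locates the decay
#' distances where the binned mean first crosses r-squared 0.1 and 0.2
#' (linear interpolation between bin centers), and derives the effective
#' number of independent tests as total mapped genome length divided by the
#' r-squared = 0.1 decay distance, with the corresponding Bonferroni-style
#' significance threshold `alpha / n_effective_tests`.
#'
#' @param geno imputed [geno_matrix()].
#' @param max_dist_bp maximum pair distance considered.
#' @param bin_width bin width in bp (default: median adjacent spacing).
#' @param alpha genome-wide error rate for the derived threshold.
#' @return List of class `ld_decay`: `pairs` (distance, r2), `bins`
#'   (distance, mean r2, n), `d_r2_0.1`, `d_r2_0.2`, `genome_length_bp`,
#'   `n_effective_tests`, `threshold`.
#' @export
ld_decay <- function(geno, max_dist_bp = 50000, bin_width = NULL,
                     alpha = 0.05) {
  v <- if (inherits(geno, "geno_matrix")) geno$values else stop("need a geno_matrix")
  if (anyNA(v)) stop("ld_decay requires imputed genotypes")
  map <- geno$map
  dists <- numeric(0); r2s <- numeric(0)
  for (ch in unique(map$chrom)) {
    ix <- which(map$chrom == ch)
    if (length(ix) < 2) { warning("chromosome ", ch, " has < 2 markers; skipped"); next }
    X <- v[, ix, drop = FALSE]
    pos <- map$pos[ix]
    sds <- apply(X, 2L, sd)
    Z <- sweep(X, 2L, colMeans(X))
    Z <- sweep(Z, 2L, ifelse(sds > 0, sds, 1), `/`)
    m <- length(ix); n <- nrow(X)
    for (lag in seq_len(m - 1L)) {
      a <- seq_len(m - lag); b <- a + lag
      d <- pos[b] - pos[a]
      ok <- d <= max_dist_bp
      if (!any(ok)) break
      r <- colSums(Z[, a[ok], drop = FALSE] * Z[, b[ok], drop = FALSE]) / (n - 1)
      r[sds[a[ok]] == 0 | sds[b[ok]] == 0] <- NA
      dists <- c(dists, d[ok]); r2s <- c(r2s, r^2)
    }
  }
  keep <- !is.na(r2s)
  dists <- dists[keep]; r2s <- r2s[keep]
  if (!length(r2s)) stop("no marker pairs within the window")
  if (is.null(bin_width)) {
    sp <- unlist(lapply(split(map$pos, map$chrom), diff), use.names = FALSE)
    bin_width <- max(1, stats::median(sp))
  }
  bin <- ceiling(dists / bin_width)
  bdist <- tapply(dists, bin, mean)
  br2 <- tapply(r2s, bin, mean)
  bn <- tapply(r2s, bin, length)
  ord <- order(bdist)
  bins <- data.frame(distance = as.numeric(bdist[ord]),
                     r2 = as.numeric(br2[ord]), n = as.numeric(bn[ord]))
  decay_at <- function(thr) {
    below <- which(bins$r2 < thr)
    if (!length(below)) return(max(bins$distance))     # never decays in window
    i <- below[1L]
    if (i == 1L) return(bins$distance[1L])
    # linear interpolation between the flanking bins
    x0 <- bins$distance[i - 1L]; y0 <- bins$r2[i - 1L]
    x1 <- bins$distance[i]; y1 <- bins$r2[i]
    x0 + (y0 - thr) / (y0 - y1) * (x1 - x0)
  }
  d01 <- decay_at(0.1); d02 <- decay_at(0.2)
  glen <- sum(vapply(split(map$pos, map$chrom),
                     function(p) diff(range(p)), 0))
  neff <- max(1, glen / d01)
  structure(list(pairs = data.frame(distance = dists, r2 = r2s),
                 bins = bins, d_r2_0.1 = d01, d_r2_0.2 = d02,
                 genome_length_bp = glen, n_effective_tests = neff,
                 threshold = alpha / neff, alpha = alpha),
            class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  cat(sprintf("LD decay: d(r2=0.2) = %.0f bp, d(r2=0.1) = %.0f bp\n",
              x$d_r2_0.2, x$d_r2_0.1))
  cat(sprintf("effective tests = %.1f over %.0f bp; threshold = %.3g (alpha = %g)\n",
              x$n_effective_tests, x$genome_length_bp, x$threshold, x$alpha))
  invisible(x)
}

#' Write a GRM as TSV with line-id header
#' @param G relationship matrix with dimnames.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_grm <- function(G, path) {
  df <- data.frame(line_id = rownames(G), as.data.frame(G), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
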