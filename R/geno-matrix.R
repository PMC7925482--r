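#' Genotype matrix container
#'
#' A `geno_matrix` holds an inbred panel's marker data as a lines x markers
#' integer dosage matrix coded 0/1/2 (count of the alternate allele, `NA` =
#' missing call) together with a marker map (chromosome, 1-based bp position).
#'
#' @param values integer matrix, lines in rows (rownames = line ids), markers
#'   in columns (colnames = marker ids); entries in `{0, 1, 2, NA}`.
#' @param map data.frame with columns `marker`, `chrom`, `pos` (bp), one row
#'   per column of `values`, positions strictly increasing within chromosome.
#' @param alleles optional data.frame with columns `ref`, `alt` per marker.
#' @return An object of class `geno_matrix` (list with elements `values`,
#'   `map`, `alleles`).
#' @export
geno_matrix <- function(values, map, alleles = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(rownames(values))) stop("values must have line ids as rownames")
  if (anyDuplicated(rownames(values))) stop("line ids must be unique")
  if (is.null(colnames(values))) colnames(values) <- map$marker
  stopifnot(is.data.frame(map), all(c("marker", "chrom", "pos") %in% names(map)),
            nrow(map) == ncol(values))
  bad <- !(values %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (is.null(alleles)) {
    alleles <- data.frame(ref = rep("A", nrow(map)), alt = rep("G", nrow(map)))
  }
  structure(list(values = values, map = map, alleles = alleles),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d lines x %d markers on %d chromosome(s); %.2f%% missing\n",
              nrow(x$values), ncol(x$values), length(unique(x$map$chrom)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$values)

#' Line identifiers of a genotype matrix
#' @param geno a [geno_matrix()].
#' @return Character vector of line ids.
#' @export
line_ids <- function(geno) rownames(geno$values)

#' Subset a genotype matrix
#'
#' @param x a [geno_matrix()].
#' @param i line index (ids, logical or integer); missing keeps all.
#' @param j marker index; missing keeps all.
#' @param ... unused.
#' @return A `geno_matrix` restricted to the selected lines/markers.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  geno_matrix(x$values[i, j, drop = FALSE],
              x$map[j, , drop = FALSE],
              x$alleles[j, , drop = FALSE])
}

marker_allele_freq <- function(geno) {
  colMeans(geno$values, na.rm = TRUE) / 2
}

#' Per-marker summary statistics
#'
#' @param geno a [geno_matrix()].
#' @return data.frame with `marker`, `freq` (alt-allele frequency), `maf`,
#'   `missing` (fraction), `het` (fraction of heterozygous calls).
#' @export
marker_stats <- function(geno) {
  v <- geno$values
  freq <- colMeans(v, na.rm = TRUE) / 2
  data.frame(marker = geno$map$marker,
             freq = freq,
             maf = pmin(freq, 1 - freq),
             missing = colMeans(is.na(v)),
             het = colMeans(v == 1L, na.rm = TRUE))
}

# ---- I/O -------------------------------------------------------------------

#' Write a genotype matrix to VCF
#'
#' Minimal VCFv4.2 writer: one biallelic SNP per row, unphased diploid GT
#' (0/0, 0/1, 1/1, ./.), samples = lines.
#'
#' @param geno a [geno_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  v <- geno$values
  header <- c("##fileformat=VCFv4.2",
              "##source=strigapanel",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(v)), collapse = "\t"))
  gt <- matrix("./.", nrow = ncol(v), ncol = nrow(v))
  for (k in 0:2) gt[t(v) == k] <- gt_code[[as.character(k)]]
  body <- paste(geno$map$chrom, geno$map$pos, geno$map$marker,
                geno$alleles$ref, geno$alleles$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a genotype matrix from VCF
#'
#' Reads the GT field of a (possibly gzipped) VCF via the vcfR parser.
#' Multi-allelic sites are dropped with a warning; `./.` becomes `NA`.
#'
#' @param path VCF file path.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warning(sum(multi), " multi-allelic site(s) dropped")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  gt_clean <- gsub("\\|", "/", gt)
  dose[gt_clean %in% "0/0"] <- 0L
  dose[gt_clean %in% c("0/1", "1/0")] <- 1L
  dose[gt_clean %in% "1/1"] <- 2L
  id <- fix$ID
  if (any(is.na(id) | id == ".")) id <- paste0("S", fix$CHROM, "_", fix$POS)
  map <- data.frame(marker = id,
                    chrom = suppressWarnings(as.integer(fix$CHROM)),
                    pos = as.integer(fix$POS))
  if (anyNA(map$chrom)) map$chrom <- fix$CHROM
  geno_matrix(t(dose), map, data.frame(ref = fix$REF, alt = fix$ALT))
}

iupac_het <- c(AG = "R", GA = "R", CT = "Y", TC = "Y", GC = "S", CG = "S",
               AT = "W", TA = "W", GT = "K", TG = "K", AC = "M", CA = "M")

#' Write a genotype matrix as HapMap-like TSV
#'
#' Columns: `rs`, `alleles`, `chrom`, `pos`, then one single-letter IUPAC
#' genotype column per line (hets as ambiguity codes, `N` = missing).
#'
#' @param geno a [geno_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hapmap <- function(geno, path) {
  v <- geno$values
  ref <- geno$alleles$ref
  alt <- geno$alleles$alt
  het <- iupac_het[paste0(ref, alt)]
  het[is.na(het)] <- "N"   # identical ref/alt cannot occur for biallelic SNPs
  m <- ncol(v)
  code <- matrix("N", nrow = m, ncol = nrow(v))
  for (k in seq_len(m)) {
    g <- v[, k]
    out <- rep("N", length(g))
    out[g == 0L] <- ref[k]
    out[g == 1L] <- het[k]
    out[g == 2L] <- alt[k]
    code[k, ] <- out
  }
  df <- data.frame(rs = geno$map$marker,
                   alleles = paste0(ref, "/", alt),
                   chrom = geno$map$chrom, pos = geno$map$pos,
                   code, check.names = FALSE)
  names(df)[-(1:4)] <- rownames(v)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a HapMap-like TSV genotype file
#'
#' Accepts single-letter IUPAC calls (`A/C/G/T`, het ambiguity codes, `N`)
#' or two-letter calls (`AA`, `AG`, `NN`). Dosage is the count of the file's
#' alternate allele (second allele of the `alleles` column).
#'
#' @param path TSV file path.
#' @return A [geno_matrix()].
#' @export
read_hapmap <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  al <- strsplit(df$alleles, "/", fixed = TRUE)
  ref <- vapply(al, `[`, "", 1L)
  alt <- vapply(al, `[`, "", 2L)
  het1 <- iupac_het[paste0(ref, alt)]
  samp_cols <- setdiff(names(df), c("rs", "alleles", "chrom", "pos", "strand",
                                    "assembly", "center", "protLSID",
                                    "assayLSID", "panelLSID", "QCcode"))
  m <- nrow(df)
  dose <- matrix(NA_integer_, nrow = length(samp_cols), ncol = m,
                 dimnames = list(samp_cols, df$rs))
  for (k in seq_len(m)) {
    g <- toupper(unlist(df[k, samp_cols], use.names = FALSE))
    d <- rep(NA_integer_, length(g))
    d[g %in% c(ref[k], strrep(ref[k], 2L))] <- 0L
    d[g %in% c(alt[k], strrep(alt[k], 2L))] <- 2L
    d[g %in% c(het1[k], paste0(ref[k], alt[k]), paste0(alt[k], ref[k]))] <- 1L
    dose[, k] <- d
  }
  map <- data.frame(marker = df$rs,
                    chrom = suppressWarnings(as.integer(df$chrom)),
                    pos = as.integer(df$pos))
  if (anyNA(map$chrom)) map$chrom <- df$chrom
  geno_matrix(dose, map, data.frame(ref = ref, alt = alt))
}

#' Write / read a genotype matrix as a dosage CSV pair
#'
#' `write_geno_csv` emits `<path>` (line_id, then one 0/1/2 column per
#' marker) plus `<path>.map.csv` (marker, chrom, pos); `read_geno_csv`
#' reverses it.
#'
#' @param geno a [geno_matrix()].
#' @param path CSV file path.
#' @return `path` invisibly (writer); a [geno_matrix()] (reader).
#' @export
write_geno_csv <- function(geno, path) {
  df <- data.frame(line_id = rownames(geno$values), geno$values,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  write.csv(geno$map, paste0(path, ".map.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_geno_csv
#' @export
read_geno_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  map <- read.csv(paste0(path, ".map.csv"))
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$line_id
  geno_matrix(v, map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
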