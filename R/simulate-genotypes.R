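#' Simulate an inbred SNP panel with structure and linkage disequilibrium
#'
#' Generates near-fully-homozygous inbred genotypes (doubled haplotypes) for a
#' structured panel. Ancestral allele frequencies are uniform on (0.1, 0.9);
#' subpopulation frequencies are Balding-Nichols draws with divergence `fst`;
#' haplotypes follow a first-order Markov chain along each chromosome whose
#' adjacent-allele correlation targets `ld_rho`. Because two Bernoulli
#' variables with unequal frequencies cannot be correlated beyond
#' \eqn{r_{max} = \sqrt{\min(p_1 q_2 / (q_1 p_2),\; p_2 q_1 / (q_2 p_1))}},
#' the realized per-step correlation is `min(ld_rho, r_max)`; the chain keeps
#' every marker's subpopulation frequency exact. The closed-form correlation
#' between two markers k steps apart is the product of the intervening
#' per-step correlations (see [ld_markov_r()]), which the LD oracle tests use.
#'
#' Heterozygous calls are injected at rate `het_rate` (residual
#' heterozygosity of inbreds) and calls are masked at rate `missing_rate`.
#' Marker positions are equally spaced at `spacing_bp` within chromosomes.
#'
#' @param n_lines,n_markers,n_chrom panel dimensions (markers split as evenly
#'   as possible across chromosomes).
#' @param n_subpops number of subpopulations (lines split evenly).
#' @param fst Balding-Nichols divergence in `[0, 1)`; 0 = panmictic.
#' @param ld_rho target adjacent-allele correlation in `[0, 1)`.
#' @param het_rate,missing_rate injection rates, each `<= 0.05`.
#' @param spacing_bp distance between adjacent markers (bp).
#' @param seed integer seed; the function is a pure function of its arguments.
#' @return A [geno_matrix()]; attributes `subpop` (per-line assignment),
#'   `subpop_freqs` (markers x subpops), and `step_r` (per-step realized
#'   correlations per subpop) support the analytic LD oracle.
#' @export
simulate_genotypes <- function(n_lines, n_markers, n_chrom = 10,
                               n_subpops = 3, fst = 0.1, ld_rho = 0.9,
                               het_rate = 0.005, missing_rate = 0.01,
                               spacing_bp = 1000, seed = NULL) {
  stopifnot(n_lines >= 1, n_markers >= 1, n_chrom >= 1, n_subpops >= 1,
            fst >= 0, fst < 1, ld_rho >= 0, ld_rho < 1)
  if (het_rate < 0 || het_rate > 0.05) stop("het_rate must be in [0, 0.05]")
  if (missing_rate < 0 || missing_rate > 0.05) stop("missing_rate must be in [0, 0.05]")
  with_seed(seed, {
    chrom <- sort(rep_len(seq_len(n_chrom), n_markers))
    pos <- unlist(lapply(split(seq_along(chrom), chrom),
                         function(ix) seq_along(ix) * spacing_bp),
                  use.names = FALSE)
    p_anc <- runif(n_markers, 0.1, 0.9)
    pf <- matrix(0, n_markers, n_subpops)
    if (fst == 0 || n_subpops == 1L) {
      pf[] <- p_anc
    } else {
      a <- (1 - fst) / fst
      for (s in seq_len(n_subpops)) {
        pf[, s] <- rbeta_safe(p_anc * a, (1 - p_anc) * a)
      }
      # keep frequencies usable for the Markov transitions and QC-realistic
      pf <- pmin(pmax(pf, 0.02), 0.98)
    }
    subpop <- rep_len(seq_len(n_subpops), n_lines)
    hap <- matrix(0L, n_lines, n_markers)
    step_r <- matrix(0, n_markers, n_subpops)   # r between marker k-1 and k
    for (s in seq_len(n_subpops)) {
      rows <- which(subpop == s)
      ns <- length(rows)
      if (ns == 0L) next
      p <- pf[, s]
      x <- rbinom(ns, 1L, p[1L])
      H <- matrix(0L, ns, n_markers)
      H[, 1L] <- x
      for (k in 2L:n_markers) {
        if (chrom[k] != chrom[k - 1L]) {           # new chromosome: restart
          x <- rbinom(ns, 1L, p[k])
        } else {
          p1 <- p[k - 1L]; p2 <- p[k]
          q1 <- 1 - p1; q2 <- 1 - p2
          rmax <- sqrt(min(p1 * q2 / (q1 * p2), p2 * q1 / (q2 * p1)))
          r <- min(ld_rho, rmax)
          step_r[k, s] <- r
          pr <- ifelse(x == 1L,
                       p2 + r * sqrt(p2 * q2 * q1 / p1),
                       p2 - r * sqrt(p2 * q2 * p1 / q1))
          x <- rbinom(ns, 1L, pmin(pmax(pr, 0), 1))
        }
        H[, k] <- x
      }
      hap[rows, ] <- H
    }
    g <- 2L * hap
    if (het_rate > 0) {
      flip <- matrix(runif(length(g)) < het_rate, nrow(g))
      g[flip] <- 1L
    }
    if (missing_rate > 0) {
      g[matrix(runif(length(g)) < missing_rate, nrow(g))] <- NA_integer_
    }
    rownames(g) <- sprintf("L%03d", seq_len(n_lines))
    map <- data.frame(marker = paste0("S", chrom, "_", pos),
                      chrom = chrom, pos = pos)
    colnames(g) <- map$marker
    out <- geno_matrix(g, map)
    attr(out, "subpop") <- subpop
    attr(out, "subpop_freqs") <- pf
    attr(out, "step_r") <- step_r
    attr(out, "p_anc") <- p_anc
    out
  })
}

# Balding-Nichols beta draw that tolerates extreme shape values
rbeta_safe <- function(a, b) {
  x <- rgamma(length(a), shape = a, rate = 1)
  y <- rgamma(length(b), shape = b, rate = 1)
  x / (x + y)
}

#' Analytic haplotype-allele correlation for the simulated Markov chain
#'
#' Closed-form Pearson correlation between the alleles at two markers of the
#' chain used by [simulate_genotypes()]: the product of the realized
#' per-step correlations between them (0 across chromosome boundaries).
#'
#' @param geno a [geno_matrix()] produced by [simulate_genotypes()].
#' @param j,k marker column indices (`j < k`).
#' @param subpop subpopulation whose chain is evaluated.
#' @return The expected allele correlation (scalar).
#' @export
ld_markov_r <- function(geno, j, k, subpop = 1L) {
  step_r <- attr(geno, "step_r")
  if (is.null(step_r)) stop("geno was not produced by simulate_genotypes()")
  stopifnot(j < k)
  if (geno$map$chrom[j] != geno$map$chrom[k]) return(0)
  prod(step_r[(j + 1L):k, subpop])
}
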