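---
title: "Models and methods behind strigapanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind strigapanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strigapanel)
```

# The analysis problem

Resistance of maize to the parasitic weed *Striga hermonthica* is screened
in artificially infested field trials: an inbred panel is grown in several
environments in an alpha-lattice design with two replications, and plots are
scored for emerged parasites at 8, 10 and 12 weeks after planting (WAP), a
1-9 host-damage rating (SDR), grain yield (GY) and standard agronomic
traits. `strigapanel` implements the full quantitative-genetic analysis of
such a panel — stage-1 mixed models, genome-wide association with structure
and kinship correction, GBLUP genomic prediction with genotype-by-
environment (G×E) interaction under three cross-validation schemes, and an
item-based collaborative-filtering (IBCF) multi-trait predictor — together
with a synthetic-data generator that emulates the trial so that every stage
is testable without external data.

# Stage-1 phenotypic model

Plot values are decomposed as

$$Y_{ijko} = \mu + G_i + E_j + (GE)_{ij} + R(E)_{kj} + B(R.E)_{ojk} + e_{ijko}$$

with environments and replicates-within-environment fixed and genotype,
G×E and incomplete block random. The REML fit is delegated to `lme4`
(`fit_mixed_model()`); sum-to-zero contrasts on the fixed factors center
the line summaries on the grand mean. With genotype random the line values
are shrunken BLUPs (used downstream by the association scan); with genotype
fixed they are BLUEs (used by genomic prediction), which for balanced data
equal arithmetic line means — a property the test suite checks exactly.

Entry-mean heritability is
$$h^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{GE}/E + \sigma^2_e/(ER)},$$
the repeatability of line means across $E$ environments and $R$ replicates.
Repeated parasite counts are condensed into the area under the *Striga*
number progress curve (AUSNPC) by the trapezoidal AUDPC rule; we measure
time in days (WAP × 7, so 56/70/84), an arbitrary unit choice that rescales
AUSNPC by a constant and therefore cancels in correlations and
heritability. Outlier screening (`remove_outliers()`) drops records whose
standardized residual from a preliminary fixed-effects fit exceeds 3.5 (a
conventional bulk-screening threshold; the rule is configurable), and
`screen_environments()` implements the usual gate for across-location
analysis: keep an environment if its within-environment repeatability is at
least 0.1 and the genotype-variance likelihood-ratio test (boundary-mixture
p-value) is significant at 5%.

# Marker tools

QC follows the standard GBS panel filter: minor allele frequency strictly
above 0.05, missingness strictly below 5%, heterozygosity strictly below 5%
(inbred lines), monomorphic markers always dropped. Remaining missing calls
are mean-imputed (dosage $2p_k$), which preserves marker means exactly.
The genomic relationship matrix is VanRaden's
$G = WW^\top / (2\sum_k p_k(1-p_k))$ with $W$ the frequency-centered dosage
matrix; for a fully homozygous panel its diagonal averages $1+f \approx 2$,
which matters when converting the variance ratio of a kinship model into a
heritability. An identity-by-state kinship (`ibs_kinship()`) is provided as
the alternative MLM kinship, with VanRaden as the default for both the
association and prediction stages. Population structure covariates are the
first three principal components of the centered dosage matrix.

Linkage disequilibrium is summarized as the squared Pearson correlation of
dosages (composite LD, appropriate for unphased inbreds) for marker pairs
within a window, binned by physical distance. The decay distances at
$r^2 = 0.2$ and $0.1$ are located by the first downward crossing of the
binned means (linear interpolation); the effective number of independent
tests is genome length divided by the $r^2 = 0.1$ distance, and the
genome-wide significance threshold is $\alpha$ over that number. The fixed
thresholds $2\times10^{-6}$ (resistance traits) and $5.6\times10^{-6}$
(yield) are available as defaults in the pipeline configuration.

# Association scan

The mixed linear model $y = X\beta + u + e$, $u \sim N(0, K\sigma^2_u)$, is
fitted by spectral REML: one eigendecomposition of $K$ reduces the
restricted likelihood to a one-dimensional profile in the variance ratio.
The per-marker scan holds the variance components at their null-model
estimates (the standard P3D speed-up) and performs generalized-least-squares
t-tests of the additive dosage effect; the residual variance of each marker
model is re-estimated from its own residual sum of squares, so with
$K = I$ the test reduces *exactly* to simple regression — an oracle the
tests verify to $10^{-8}$. The GLM path is the same test with the kinship
omitted. Hits (p strictly below the trait threshold) are reported with the
effect oriented to the minor allele; their joint contribution is the
adjusted $R^2$ of an ordinary regression on all hit dosages, and the share
of genotypic variance is $p_G = R^2_{adj}/h^2$, flagged when it exceeds 1.

# Genomic prediction

Within one environment GBLUP is $y_j = \mu + g_j + e_j$ with
$g \sim N(0, G_1\sigma^2_G)$, fitted by the same spectral REML. Across
environments the model adds fixed environment means and an interaction with
Kronecker covariance:
$$y_{ij} = E_i + g_j + (gE)_{ij} + e_{ij}, \qquad
  gE \sim N(0,\; G_1 \otimes I\,\sigma^2_{GE}).$$
Environment means are treated as fixed effects rather than draws from a
random environment distribution: with three environments a variance is
barely estimable, and predictions in a new environment then use the average
fitted mean, which leaves correlation-based accuracy untouched. Estimation
is REML throughout (deterministic, testable, and identical in expectation to
the Bayesian GBLUP point predictions); for balanced complete line ×
environment tables a double diagonalization (eigenvectors of $G_1$ across
lines; the mean/contrast rotation across environments) makes the
two-parameter profile likelihood closed-form per evaluation, and a dense
Cholesky REML handles unbalanced records. The two paths agree on balanced
data (tested), and the single-environment solutions agree with the
generalized-least-squares closed form to $10^{-6}$.

Prediction of any line, observed or not, is the covariance-weighted
combination $\hat g = \sigma^2_G\, G_1[\text{new}, \text{obs}]\,
V^{-1}(y - X\hat\beta)$, with the interaction BLUP added when the target
environment was observed.

## Cross-validation schemes

* **CV0** — leave one environment out; predict all lines there (new
  environments for known lines). Deterministic.
* **CV1** — five-fold random partition of lines; test lines masked in all
  environments (entirely new lines).
* **CV2** — same line partition (so CV1/CV2 comparisons are paired), each
  test line masked in a uniformly drawn non-empty proper subset of
  environments (incomplete field trials); at least one observed environment
  per test line is guaranteed.
* **across** — five-fold prediction of across-environment BLUEs by
  single-environment GBLUP.

Variance components are re-estimated per fold on the fully observed
training lines (balanced, hence fast); BLUPs then use all observed cells,
including the test lines' unmasked environments. Accuracy is the Pearson
correlation of predicted and observed test values per environment,
averaged over repetitions (means of repetition means, not pooled
predictions). Augmentation with association hits adds their dosages as
fixed covariates; the `"whole-panel"` mode reuses hits detected on the full
panel — deliberately reproducing the optimistic bias of panel-wide marker
selection — while `"training-only"` re-scans within each training fold.

# The collaborative-filtering predictor

The lines × (trait, environment) matrix is standardized column-wise
($z_{ij} = (y_{ij} - \mu_j)/\sigma_j$, sample SD, matching the Pearson
convention of the weights), item-item weights are pairwise-complete Pearson
correlations, and a missing cell is predicted as

$$\hat z_{ij} = \frac{\sum_{j' \in N_i(j)} z_{ij'} w_{jj'}}
                     {\sum_{j' \in N_i(j)} w_{jj'}}, \qquad
  \hat y_{ij} = \mu_j + \sigma_j \hat z_{ij}$$

over the neighborhood of items observed for that line. The signed weight
sum is the printed form of the method; because single-neighbor predictions
then depend on the weight only through its sign, and opposite weights can
cancel, the implementation guards near-zero denominators (flagged missing)
and offers the absolute-value variant and a top-k / positive-only
neighborhood as options. All observed items are used by default. The
CV2-style evaluation masks the target environment's cells fold-by-fold over
lines (every line predicted exactly once) so that the column statistics and
weights are always estimated from observed data.

When does IBCF beat single-trait GBLUP? In a world where all genetic signal
flows through the markers, the single-trait G×E GBLUP is the generating
model and cannot be beaten on average. IBCF wins exactly when a *companion
trait* measured in the target environment shares the target's
environment-specific signal — the situation of a correlated resistance-trait
family (emerged-parasite counts, AUSNPC, damage scores), and the pattern the
package's acceptance suite reproduces: with a companion trait sharing 90% of
the QTL signal (item correlations around 0.8 within environment) and
GE-dominant variance components, IBCF clearly exceeds GBLUP; with an
independent companion it clearly falls below. Maturity-type traits measured
alongside but genetically unrelated play the role of the independent case.

# The synthetic-data generator

`simulate_genotypes()` produces doubled-haploid-style inbred genotypes:
ancestral allele frequencies uniform on (0.1, 0.9), subpopulation
frequencies by Balding–Nichols draws (default three subpopulations,
F~ST~ = 0.1), haplotypes from a first-order Markov chain along each
chromosome, residual heterozygosity 0.5% and missingness 1% — rates below
the QC thresholds, so generator output passes the default filters. The
chain targets an adjacent-allele correlation `ld_rho` (default 0.9) while
keeping every marker's frequency exact; because two binary variables with
unequal frequencies cannot exceed the correlation bound
$\sqrt{\min(p_1q_2/(q_1p_2),\, p_2q_1/(q_2p_1))}$, the realized per-step
correlation is capped at that bound and the exact correlation between any
two markers is the product of the intervening per-step values
(`ld_markov_r()`). The LD tests therefore compare measured $r^2$ to this
closed-form oracle; the uncapped geometric value `ld_rho`^2k^ is only an
upper envelope, which heterogeneous frequencies keep out of reach — a
mathematical constraint of binary chains, not an implementation choice.

`simulate_trial()` builds plot phenotypes from additive QTL effects
(default 100 causal markers), rescaled after drawing so the realized
genetic variances hit their targets exactly in the founder sample — this
makes variance-recovery tests sharp. Environment-specific QTL deviations
give the G×E component, so the implied cross-environment genetic
correlation is $\sigma^2_G/(\sigma^2_G + \sigma^2_{GE})$. Multiple traits
can share QTL effects with a chosen genetic correlation (both the main and
the environment-specific parts), which is how the generator produces a
correlated resistance-trait family. Environment, replicate and
incomplete-block effects (blocks of five consecutive plot entries within
each replicate, mirroring the 5 × 76 lattice) and Gaussian residuals
complete the plot value.

`simulate_striga_counts()` draws emerged-parasite counts from a negative
binomial whose log-mean is the timepoint baseline plus a scaled,
standardized genetic liability, with the half-variance lognormal correction
so the marginal means stay on the baselines (defaults 6.2, 30 and 65 at
8/10/12 WAP, matching the reported grand means; overdispersion 0.3 and
liability scale 0.3 are this package's calibration — the raw count
distribution of the original trials is not published, so defaults are tied
only to the reported means and ranges). Counts are emitted raw, because the
downstream stage-1 analysis models raw counts with Gaussian mixed models.
`simulate_striga_panel()` composes everything into the canonical dataset
(GY, SDR, AD with the published variance components and means as defaults,
negatively correlated GY, plus counts driven by the SDR liability and the
derived AUSNPC).

What the generator does *not* emulate: coalescent genealogy, dominance and
epistasis, spatial field trend, and count distributions beyond the
negative-binomial family. Tests passing on this generator show the
estimators recover the generating structure; they do not certify behavior
under model misspecification present in real fields.

# Numerical choices

* REML optimizations run on log-variance-ratio scales: Brent search on
  [-12, 12] for one ratio, Nelder–Mead for two; the residual variance is
  always profiled out analytically.
* `1e-6` ridge on relationship matrices before decomposition or inversion
  (numerical PSD guarantee); eigenvalues clipped at zero.
* Variance components estimated at the REML boundary are reported as zero
  and flagged in the fit log.
* Zero-variance markers are skipped in scans (logged); aliased hit dosages
  are dropped from the joint fit.
* All generators are pure functions of their arguments including `seed`;
  the pipeline fans a master seed into per-stage streams by stable string
  hashing (`child_seed()`), so toggling one stage never shifts another's
  draws, and CV1/CV2 share line partitions at equal seeds.

# Problem sizes used by the test and acceptance harnesses

The package's own verification runs at desk scale, chosen so the whole
suite completes in about a minute: the canonical fixture is 100 lines × 500
markers × 3 environments; variance-component recovery uses 20 independent
trials of 300 lines; cross-validation structure uses 250–300 lines with 10
repetitions of five folds (the pipeline default; 100 repetitions, as used
in full-scale studies, is a configuration switch); null calibration pools
five permutation scans of 2 000 markers. These sizes are the package's
choices for sharp-but-fast statistical checks; all of them scale up through
function arguments.

# Known limitations

* The multi-environment REML treats environment means as fixed; a random
  environment main effect is not fitted separately (its variance is not
  identifiable apart from the intercept with few environments).
* Per-marker exact REML (non-P3D) is not implemented; P3D is the
  documented approximation, standard in MLM association tooling.
* IBCF evaluation requires at least two non-target environments and at
  least three observed values per item column.
* Mean imputation only; no LD-aware genotype imputation.
* The heritability worked examples reproduce published two-decimal tables
  only as precisely as those tables' own rounding allows: components
  printed to two decimals can shift the recomputed heritability by one
  unit in the second decimal for ratios near a rounding boundary.
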