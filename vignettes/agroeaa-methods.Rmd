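---
title: "Methods: environment association analysis for landrace collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: environment association analysis for landrace collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agroeaa)
```

## The problem

Crop landraces are locally adapted populations maintained by farmers; their
genomes carry the footprints of the selection pressures met along their
historical distribution. Given (i) daily gridded weather at the collection
sites of a panel of inbred landrace accessions, (ii) a biallelic SNP matrix
with a genetic map, and (iii) group-membership probabilities from a
population-structure analysis, `agroeaa` asks two questions at two levels of
genetic organisation:

* which environmental gradients explain the geographic distribution of the
  germplasm *groups* (redundancy analysis on the Q matrix, population
  differentiation scans), and
* which individual SNPs track environmental gradients *beyond* what shared
  ancestry predicts (Bayes-factor and latent-factor association).

Because the interesting quantities are all susceptible to confounding by
population structure and by spatial autocorrelation, the package is built
around explicit null machinery: a drift covariance matrix, simulated-neutral
calibration for the differentiation scan, and spatially correlated dummy
variables for empirical association thresholds.

## Agroclimatic variables

Daily minimum/maximum temperature, precipitation and reference
evapotranspiration per site are summarised into a catalogue of 147 named
agroclimatic variables: monthly and seasonal precipitation, mean/max/min
temperature, thermal amplitude and frost-day counts (6 families x 12 months
+ 4 seasons), monthly potential vernalization, days from sowing to 10/20/30/40
vernalization days, the late-frost probability day, and monthly, seasonal and
annual reference evapotranspiration and climatic water balance
(`bal = cumulative pcp - cumulative ET0`).

**Vernalization.** Effectiveness is piecewise linear in temperature: zero at
or below 0 degC, rising to 1 at 4 degC, full on the 4-8 degC plateau, falling
linearly to zero at 15 degC. The within-day temperature course is a sine
curve between `tmin` and `tmax` (the CERES-Wheat tradition); a day's
vernalization fraction is the mean effectiveness over that curve. We sample
the diurnal curve at 96 points (15-minute resolution): the piecewise-linear
response composed with a sine has quadrature error that falls quadratically
in the step count, and 96 steps keep the error below about 3e-4 vernalization
days, comfortably within the 1e-3 tolerance our tests enforce against a
10,000-step oracle. `verna_Nd` counts days from a 15 November sowing
(inclusive) until N vernalization days accumulate, with accumulation starting
five days after sowing to allow for seed imbibition; season-years that never
reach the target are excluded with a warning.

**Late frost (`pfrost`).** We read "first day of year where P(tmin < 0) <=
0.10" as a return-period statement: `q(d)` is the fraction of years with at
least one frost on or after day `d` (searching January-June), and `pfrost`
is the smallest `d` with `q(d) <= 0.10` - a one-in-ten-year late-frost risk.
A pointwise alternative (per-day frost frequency) is available behind
`method = "pointwise"`; the return-period estimator is the default because it
matches the stated return-period interpretation and is robust to the
day-to-day noise of daily series.

**Seasons.** Winter is DJF, autumn SON, spring MAM, summer JJA. A two-month
(March-April) spring is sometimes used for naming spring composites; because
spring-named composites elsewhere span May, we treat the two-month reading as
a documentation slip and keep MAM as the default, configurable in
`season_spec()`. Multi-month composites (`pcp_mar_apr`, `bal_mar_apr_may`,
`frost_jan_feb`, ...) are declared as named month groups and aggregated by
the family rule: totals are summed, temperatures averaged. Summer aggregates
and July-October months are dropped from the analysis subset - they have no
bearing on an autumn-sown winter cereal.

Variable selection follows the published workflow: Ward-D2 clustering of the
scaled variables into 10 groups, with a shipped default of 20 representative
variables (three geographic plus 17 agroclimatic), and a PCA of the scaled
catalogue whose leading scores can themselves be used as environmental
variables.

## Spatially correlated dummy variables

Testing spatial environmental variables against an unstructured permutation
null inflates type-I error, so empirical thresholds are built from dummy
variables that are spatially smooth but genetically meaningless: zero-mean
Gaussian random fields simulated unconditionally from a semivariogram model
(spherical/exponential/gaussian; dense Cholesky factorisation of the grid
covariance - grids here are small, so no circulant embedding is needed),
sampled at the sites by nearest-cell lookup and standardised.
`fit_semivariogram()` (binned empirical semivariogram, Cressie-weighted
least squares) lets the dummy smoothness be matched to a real climate
surface. Our tests verify simulation-refit round trips recover the range
within +/-30%.

A consequence worth stating explicitly: because the dummies are site-level
and spatially smooth, their Bayes-factor null distribution is *heavier-tailed*
than an accession-level permutation null, even under the covariance model.
That is not a defect - it is the reason the dummy design exists - and the
test suite asserts both halves: site-level permutations match non-spatial
(nugget) dummies, and smooth dummies dominate the permutation null in the
upper tail. Thresholds derived from the dummies (the 99.99th percentile of
pooled dummy Bayes factors) are therefore conservative in exactly the right
way for spatial predictors.

## Genotype handling

Inbred accessions are haploid-coded (`{0, 1, NA}`). The deposited two-line
allele-counts format (one line of allele-1 counts, one of allele-2 counts
per SNP; `0/0` = missing) round-trips byte-identically. Filters: loci with
more than 10% missing calls are dropped, then MAF > 0.05 retained (strict
inequality, configurable). Missing calls are imputed by k-nearest-neighbour
majority (k = 5) over genotype-mismatch distance, with global-major-allele
tie-breaks - a transparent stand-in for specialised homozygous-panel
imputation, pinned by tests. LD is the squared Pearson correlation of call
vectors; the structure-corrected `r_S^2` correlates the residuals of both
loci after projection on the intercept and the Q-matrix columns, so LD that
merely reflects co-membership in a group is removed. The nonredundant marker
shortlist used for covariance estimation keeps, in map order, loci with
unique genetic positions whose `r^2` against previously kept loci within a
five-marker window stays below 0.2 (greedy, deterministic, first-kept-wins
on cM ties).

## Population differentiation

Per-locus gene diversity is `H = 2p(1-p)`. Pairwise Fst uses a haploid
analysis-of-variance estimator of the Weir-Cockerham family, combined across
loci as a ratio of sums; the matrix diagonal reports within-group mean `H`.
On Balding-Nichols simulations the estimator recovers the generating `F`
within +/-0.05 at 2,000 loci across `F` in {0.05, 0.2, 0.4}.

**The covariance matrix Omega.** For each locus the population frequency
vector is centred and scaled by `sqrt(pbar(1-pbar))`; Omega is the mean
outer product across shortlisted loci (optionally averaged over bootstrap
replicates), projected to the PSD cone. Because centring uses the locus's
own mean, this estimator cannot see variance shared by *all* populations
(it is rank-deficient along the all-ones vector); everything downstream is
defined consistently with that fact.

**XtX.** The differentiation statistic is the Mahalanobis form
`(theta - eps)' [eps(1-eps) Omega]^{-1} (theta - eps)` with `eps` the
GLS ancestral-frequency estimate (with the ridge-regularised moment Omega
this reduces to the plain mean), rescaled by `P/(P-1)`. The rescaling is a
degrees-of-freedom accounting choice: estimating `eps` absorbs one degree of
freedom, so the raw quadratic form has neutral expectation `P-1`, whereas
formulations that integrate ancestral-frequency uncertainty (as the MCMC
samplers do) centre neutral loci at `P`. With the rescaling, neutral
Balding-Nichols data centre at `P` (the test suite asserts the mean within
+-0.2 at 5,000 loci; the acceptance script reports the measured value), and the
statistic is invariant to population relabelling.

**Significance by pseudo-observed data.** Neutral loci are simulated from
the fitted model - ancestral frequencies resampled from the observed
spectrum, deviations multivariate normal from Omega completed by an
exchangeable shared-drift component (mean of the contrast-space eigenvalues
along the all-ones direction), clipped to [0, 1] - and then *re-analysed
with their own re-estimated moment Omega*, exactly as the observed data
were. This re-analysis step is what makes the threshold calibrated: the
observed XtX uses an Omega estimated from the observed loci, so the POD XtX
must do the same. Under the Gaussian model's own null, about 1% of neutral
loci exceed the 99th-percentile threshold; under Balding-Nichols data the
beta-distributed drift is heavier-tailed than the Gaussian working model and
the threshold is conservative, which we accept and state rather than tune
away.

Scan results are reported per SNP and in 4 cM sliding windows on the
cumulative map position (half-open `[c-2, c+2)`, never crossing a
chromosome), with reference lines at the windowed 95th/5th and single-SNP
99th/1st percentiles.

## SNP-environment association

Each accession is treated as a population of haploid sample size one, per
the published design. The hierarchical model: observed frequencies
`p_hat ~ N(eps 1 + beta e, eps(1-eps)(Omega + diag(1/n)))`, where `Omega`
is the accession-level covariance (or the identity for the
structure-uncorrected "null model") and `e` the standardised environment.
The Bayes factor integrates `beta` over a uniform prior on [-0.3, 0.3]
evaluated on a 61-point grid - for standardised environments, frequency
shifts beyond 0.3 per SD are already implausible - and integrates ancestral
-frequency uncertainty by Monte Carlo draws from its profile posterior
(default 50 draws, seeded). Runs differ only through those seeded draws, so
everything is deterministic per seed and the five-run median mimics the
replicate structure of MCMC-based analyses without opaque convergence
questions. A monomorphic locus has no evidence either way and gets BF = 1
with a flag. No numerical agreement with MCMC implementations is claimed -
agreement is at the rank/threshold level.

The accompanying nonparametric statistic is Spearman's rho. Under the
covariance model it is computed on the structure-standardised frequencies
(Cholesky-whitened residuals after removing the fitted ancestral component,
against the whitened environment): a raw rank correlation measures mostly
structure when environment and ancestry are confounded, and could never
agree with a structure-corrected Bayes factor. Under the null model the raw
frequencies are used. The consensus rule flags (locus, variable) pairs in
the pooled top 1% of median Bayes factors whose |rho| also sits in the
pooled top 1% in *every* run; top-x% membership is computed by average rank
so that wide ties below the cutoff can never flood the selection.

The latent-factor route estimates K factors (default 6) from the centred
genotype matrix by a seeded randomized truncated SVD (run-to-run variation
enters through the random range-finder, mimicking independently started
solvers), regresses each locus on the environment adjusted for the factors,
combines the per-run z-scores by Stouffer's rule `sum(z)/sqrt(m)`, and
controls FDR per variable by Benjamini-Hochberg at Q = 0.01. With K at the
true group count, p-values are uniform under a structured null with a
structure-confounded environment (the test suite asserts the KS p-value
above 0.01 and the acceptance script reports it), while K = 0 is grossly
anti-conservative - the package's own demonstration of why the adjustment
matters.

## Redundancy analysis

The Q matrix (which is compositional: rows sum to one, so one column is
redundant - the projection tolerates this via rank-revealing QR) is the
response; agroclimatic and geographic variables are predictors. `R^2` is
the trace of fitted variance over total variance; the adjustment is
Ezekiel's formula with the predictor *rank* as the effective count, and
negative adjusted values are reported as-is. Partial models residualise the
response and focal predictors on the conditioning set; the variance
partition reports unique and common fractions which sum to the combined
model's adjusted `R^2` by construction. Significance is a permutational
pseudo-F test on (residualised) response rows with
`p = (1 + #{F* >= F}) / (n_perm + 1)`. Forward selection adds the candidate
with the largest adjusted-`R^2` gain; flagged dummy candidates compete
equally, and the reported stop index is the number of real variables
entered before a dummy first ranks best - the "stop at the first dummy"
reading of model capacity. Our implementation is plain linear algebra;
tests cross-check `R^2`, adjusted `R^2` and permutation verdicts against
both a brute-force per-column OLS oracle and vegan.

## The synthetic-data module

Everything above is exercised end to end on seeded synthetic data with known
truth, generated by the package itself:

* **Weather**: seasonal sinusoids for daily mean temperature (coldest
  mid-January) and diurnal range, AR(1) Gaussian anomalies, a 6.5 degC/km
  lapse rate and a poleward cooling gradient; Bernoulli-gamma precipitation
  with monthly occurrence probabilities; evapotranspiration as a smooth
  seasonal curve coupled to the site's temperature. This is the minimal
  structure supporting every catalogue variable; it makes no attempt to
  reproduce real spell structure, extremes or inter-variable dependence
  beyond the temperature coupling.
* **Genotypes**: Balding-Nichols - per-locus ancestral frequencies uniform
  on (0.05, 0.95), per-group frequencies Beta-distributed around them with
  group-specific `F`, haploid Bernoulli calls, 5% missing at random. The
  default fixture has 120 accessions in four groups (15/10/45/50 scaled
  proportions), per-group `F` of 0.35/0.4/0.2/0.25, and 3,000 loci on seven
  chromosomes. Real LD decay and site-frequency spectra are out of scope.
* **Clines**: causal loci get accession-level allele probabilities
  `plogis(qlogis(p_group) + beta * env)`. Causal loci are drawn among loci
  with mean group frequency in (0.2, 0.8): a locus near fixation cannot
  carry a cline, and truth labels must mean what they claim. The default
  effect size is beta = 2 on the standardised late-frost gradient.
* **Geography**: groups occupy latitudinal bands with overlap, so
  environment and ancestry are genuinely confounded - the hard case the
  covariance model exists for.

Passing tests on this fixture show the machinery is correct and calibrated
under the model's assumptions; they do not show that real barley data meet
those assumptions (no isolation-by-distance, no LD, Gaussian working
likelihood at haploid sample size one).

## Problem sizes and numerical conventions

The test suite runs the planted-cline power study at the fixture's full
size (3,000 loci, 120 accessions, 20 causal loci, beta = 2) over 20 seeds
with 3 association runs and 30 Monte Carlo draws per Bayes factor; the
acceptance script uses 8 seeds. Differentiation checks use 5,000 loci and
P = 4; Fst recovery uses 2,000 loci. Ridge regularisation is `1e-6 I`
before any covariance inversion; PSD projection clips negative eigenvalues
at zero; the BF working likelihood truncates ancestral frequencies to
[1e-3, 1-1e-3]. Physical positions are 1-based at interfaces; candidate
windows are half-open internally. All generators and samplers take explicit
integer seeds, and equal seeds give bit-identical output.

## Known limitations

* The Bayes factor uses a Gaussian working likelihood for binomial data;
  with haploid sample size one this is a coarse approximation whose
  absolute scale should not be compared with MCMC implementations.
* The moment Omega cannot estimate drift shared by all populations; the
  POD generator restores it only through an exchangeability assumption.
* The POD threshold is conservative for data with heavier-than-Gaussian
  drift (e.g. Balding-Nichols at moderate F).
* kNN imputation ignores linkage: neighbours are genome-wide, not local.
* The weather generator is not a stochastic weather model of record; it is
  a fixture with the right marginal structure for the catalogue.
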