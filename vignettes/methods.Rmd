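---
title: "Detecting incidental local adaptation and GxE in clonal multi-environment trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting incidental local adaptation and GxE in clonal multi-environment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envgxe)
```

## The problem

Potato breeding programs select intensely for the first three field years in
a single small geographic region before promising clones enter a national
multi-location trial. Because genotype-by-environment interaction (GxE) is a
large share of genetic variance for yield in potato, this early selection can
incidentally favour alleles adapted to the home environment. `envgxe`
implements a framework for asking three questions of such a trial:

1. **Is there allele-frequency structure along the selection environment?**
   Environmental GWAS (envGWAS) regresses allele dosage on a descriptor of
   each clone's selection environment — its home program (case-control), the
   latitude/longitude of the selection site, or 3-year growing-season
   averages of minimum temperature, maximum temperature and precipitation.
   The regression is "reverse" (the environment is the response, dosage the
   regressor); this is defensible because dosages are measured essentially
   without error.
2. **Which loci shift environmental sensitivity of yield?** Per-clone
   reaction-norm slopes of normalized yield on trial-environment variables
   are scanned as a quantitative trait (regression GWAS).
3. **Are any of these alleles rising in frequency over time?** Generation
   proxy selection mapping (GPSM) scans the first submission year of each
   clone as the response, detecting directional allele-frequency change
   while kinship absorbs drift and relatedness.

A synthetic-data generator with planted ground truth stands in for the real
trial, so the whole pipeline is testable end to end.

## The yield model and variance decomposition

Plot yield (kg) follows

$$\gamma = \mu + Y + L + YL + g + gY + gL + gYL + \varepsilon,$$

with year (Y), location (L) and their interaction fixed, and genotype (g),
genotype-by-year (gY), genotype-by-location (gL) and
genotype-by-year-by-location (gYL) independent random effects.
`partition_variance()` fits this by REML via `lme4::lmer` and reports each
genetic component as a percentage of the summed genetic variance
(g + gY + gL + gYL); shares of total phenotypic variance (including the
residual) are reported alongside, since the denominator convention matters
when comparing studies. Components are non-negative by construction of the
REML boundary. The fit is validated two ways: parameter recovery on
simulated trials (a planted 1:1 split of g and gYL is recovered as 50/50
within 5 points at 500 clones by 8 trials), and agreement with a dense
profile-likelihood oracle on tiny instances — the REML log-likelihood,
evaluated with explicit covariance matrices, is maximal at the fitted
components against factor-wise perturbations.

The decomposition uses raw plot yield. Normalized yield — each plot divided
by its trial (location-year) mean and log-transformed, so the within-trial
mean of the back-transformed values is exactly 1 — feeds only the reaction
norms and the GWAS layers, where cross-trial comparability matters and plot
spacing differs between locations.

## The mixed-model scan

All scans share one engine. With kinship
$K = ZZ^\top / c$ (column-centred dosages, $c$ scaling the mean diagonal to
1), the null model $y = X\beta + u + e$, $u \sim N(0, \sigma^2_{poly} K)$,
$e \sim N(0, \sigma^2_e I)$ is fitted by REML with a one-dimensional search
over $\delta = \sigma^2_e / \sigma^2_{poly}$ after eigen-decomposing $K$.
The rotation is cached and reused for every marker (the P3D approximation),
so each marker test is a weighted least squares in the rotated basis:
additive dosage effect, Wald SE, $t$-test p-value and LOD $= -\log_{10} p$.
Correctness is pinned by two oracles: on panels of up to 20 clones the scan
reproduces a dense-matrix GLS (built from an explicit inverse of
$\sigma^2_{poly} K + \sigma^2_e I$) to $|\Delta p| < 10^{-6}$, and with
$K = I$ it collapses to textbook OLS to $10^{-8}$.

Binary program membership is scanned with the same linear engine — a
first-order approximation to the logistic model that is adequate for
localization and robust to misspecification.

**Multiple testing.** The genome-wide threshold is
$-\log_{10}(\alpha / M_{eff})$ with $\alpha = 0.05$. $M_{eff}$, the
effective number of independent markers, is computed per chromosome from
the eigenvalues of the marker correlation matrix as the number of leading
eigenvalues needed to capture 99.5 % of the variance, summed over
chromosomes. This estimator was chosen over the Li–Ji fractional rule
because it satisfies both boundary contracts exactly: mutually independent
markers count fully ($M_{eff} \approx M$), and duplicating every marker
leaves $M_{eff}$ unchanged, whereas the fractional rule inflates the count
by up to 50 % on duplicated panels when sampling noise pushes paired
eigenvalues just below integer boundaries. Calibration under the null
(polygenic heritable response, no planted QTL, 300 clones by 2,000
markers, 200 replicates) gives a family-wise error rate close to the
nominal 5 % and uniform p-values.

**PVE.** For the significant set, all markers enter one GLS model under the
null covariance; each marker's percent variance explained is the drop in
model $R^2$ (whitened scale, against the covariate-only model) when that
marker alone is removed, and the cumulative PVE is the joint-model $R^2$.
Result tables print the cumulative value as the 1-dp rounded sum of the
per-marker values, matching the additive convention of published tables.
Collinear markers are eliminated smallest-effect-first with a warning.

## Environmental summaries

Daily weather is reduced to growing-season summaries: maxTemp and minTemp
are means of daily maxima/minima over the season window (inclusive of both
endpoint days, window configurable per program — the true program windows
are not public, so the defaults are explicit assumptions), precipitation is
the seasonal sum in cm. Missing station-days are filled from fallback
stations in proximity order, with per-day provenance; a day absent from
every station is an error, never a silent interpolation. The selection
environment of a clone is the mean of exactly the three seasons preceding
its submission year (equal weighting; the source convention is unstated),
and latitude/longitude of the home site ride along as "general environment"
responses.

## The synthetic generator

The generator emulates the trial's structure, not its biology in detail:

* **Sites** carry the real trial/selection coordinates; climate parameters
  follow a simple latitudinal gradient (cooler, later seasons northward;
  wetter eastward) so environmental variables correlate across programs the
  way real ones do.
* **Genotypes** are Binomial(4, p) dosages per marker and clone
  (autotetraploid Hardy–Weinberg — the simplest defensible model, since the
  source data do not constrain one), with a U-shaped Beta(0.8, 0.8) base
  frequency spectrum, markers independent within and across 12
  chromosomes. Env-QTL markers get per-program frequencies
  $p = p_0 + c \cdot z$ with $z$ the population-standardized program value
  of the environmental variable — a linear cline whose strength $c$ is the
  power dial. Frequencies are clipped to [0.005, 0.995] and markers are
  redrawn if a realized frequency leaves that band.
* **Yields** follow the variance-component model above, with defaults at
  the reported genetic split (27.6 / 5.56 / 22.7 / 34.1 % for
  g / gY / gL / gYL) and location effects spread so per-trial means differ
  several-fold. Planted reaction-norm QTL act multiplicatively,
  $\exp(\sum d \cdot \beta \cdot E_c)$, so that $\beta$ is exactly the
  per-dosage-copy slope of normalized log yield on the (centred) trial
  environmental value — the scale on which the downstream regression GWAS
  measures effects. A positivity floor at 1 % of the trial mean guards the
  log step; truncations are counted and flagged.
* **Submission years** are uniform over 2010–2022; GPSM markers are redrawn
  with $p(\text{year}) = p_0 + \Delta(\text{year} - \text{year}_0)$,
  clipped with a warning.

What the generator does *not* emulate — linkage disequilibrium beyond
duplicated markers, pedigree structure, the selection funnel itself,
spatial field trends — bounds what passing tests show: power and
calibration statements hold for independent markers and hold only
approximately where real data have long-range LD (potato LD decays slowly,
so real peaks are wider and effective marker counts lower than simulated
ones).

## Numerical choices and degenerate inputs

* REML search over $\log \delta \in [-6\ln 10, 6\ln 10]$; eigenvalues of
  $K$ clipped at zero; the scan flags monomorphic markers with $p = 1$
  rather than dropping rows, so marker indices stay aligned.
* LOD at the threshold counts as significant (inclusive boundary), and
  overlap windows are inclusive at both ends with chromosome labels
  compared as strings.
* Zero-variance responses (single submission year, constant latitude),
  all-case program responses, confounded trial designs (no clone in two
  trials), empty MAF-filtered panels and days missing from all stations are
  hard errors with typed conditions (`envgxe_config_error`,
  `envgxe_data_error`), not warnings.
* Per-genotype reaction norms are independent OLS fits (for balanced data
  this is equivalent to the joint model with genotype-specific slopes);
  clones with fewer than 3 distinct trial-environment values, or none, are
  excluded and listed. The slope table keeps SEs and 95 % CIs because in
  realistic settings most intervals cross zero — `slope_summary()` reports
  that fraction, and treating slope error as response measurement error is
  what justifies scanning noisy slopes at all.

## Problem sizes

Tests and the acceptance script run at a deliberate 1/3–1/5 of the real
panel: power suites use 500–800 clones by 1,000 markers with 50 replicates,
null calibration 300 clones by 2,000 markers with 200 replicates,
transience checks 400 clones by 800 markers with 20 replicates, and the
variance decomposition 500 clones by 8 trials with two replicate plots.
These sizes keep every statement statistically meaningful (binomial error
on a 50-replicate power estimate is about 7 points) while the full suite
completes in minutes; the generator scales to the full trial size by
argument.

## Known limitations

Independent markers mean $M_{eff}$ is nearly the marker count — real panels
with LD will have materially lower thresholds. The case-control PVE is
inflated by small case counts (the Beavis effect), so cumulative PVE from
program scans should be read qualitatively. The linear reaction norm is an
assumption, not a finding; curvature in real responses loads into the
residual and costs power. GPSM's generation proxy is coarse wherever
parents span generations, which attenuates true frequency trends.
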