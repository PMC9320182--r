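---
title: "Heavy-metal water-quality indices and ingestion risk: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heavy-metal water-quality indices and ingestion risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquarisk)
```

aquarisk assesses heavy-metal(loid) contamination of domestic drinking water
— water-refilling stations (WRS), groundwater (GW) and tap water (TW) — from
a per-sample table of concentrations of As, Ba, Cu, Fe, Pb, Mn, Ni and Zn.
This vignette explains the models, their assumptions, the tunable parameters,
and the design choices made where the methodology was genuinely open.

## Pollution indices

All indices compare a concentration $C_i$ (mg/L) with the permissible limit
$S_i$ (mg/L) of one authority, by default the Philippine National Standards
for Drinking Water (PNSDW 2017); WHO guideline limits are selectable. Mixing
authorities within one computation is not possible: limits always come from a
single `standard_limits()` call.

* **Single-factor index** $SFPI_i = C_i / S_i$; a value above 1 means the
  metal exceeds its standard.
* **Quality rating** $Q_i = 100\, C_i / S_i$, i.e. $SFPI$ in percent.
* **Heavy-metal pollution index** is the weighted arithmetic mean
  $MPI = \sum_i Q_i W_i / \sum_i W_i$ with $W_i = 1/S_i$, so stricter limits
  get proportionally larger weight.
* **Nemerow index**
  $NPI = \sqrt{(SFPI_{\max}^2 + SFPI_{ave}^2)/2}$ emphasises the single
  worst pollutant; algebraically $NPI$ always lies in
  $[SFPI_{\max}/\sqrt 2,\; SFPI_{\max}]$.

Two decisions deserve note. Metals recorded as 0 (below the detection limit)
are *kept* with $Q_i = 0$ rather than dropped: dropping would change
$\sum W_i$ and silently reweight the rest. And because "the average MPI of a
group" is ambiguous, `group_indices()` reports both aggregation orders —
the index of the mean concentrations and the mean of per-sample indices.
For MPI the two coincide exactly (the index is linear in concentration);
for NPI they differ, and both are reported.

Classification scales (MPI low/medium/high at 90 and 180; NPI four classes
at 1, 2.5, 7; total cancer risk five classes at powers of ten; CV
low/intermediate/high at 15% and 35%) follow the printed inequality signs of
their sources. Where a boundary is claimed by both neighbouring classes or
by neither, the more-polluted class wins: a conservative tie-break, so
CV = 35% is "high" and TCR = $10^{-3}$ is "Very high".

## Ingestion-pathway exposure and risk

The USEPA ingestion chain is, per metal,

$$CDI = \frac{C \cdot IR \cdot EF \cdot ED}{BW \cdot AT}, \qquad
  HQ = \frac{CDI}{RfD}, \qquad HI = \sum HQ,$$
$$CR = CDI \cdot SF, \qquad TCR = \sum_{\text{As, Pb, Ni}} CR,$$

with cohort defaults: adults IR = 2.2 L/day, ED = 70 y, BW = 70 kg,
AT = 25,550 d; children IR = 1.0 L/day, ED = 10 y, BW = 25 kg, AT = 3,650 d;
EF = 365 d/y for both. Note that with these defaults $EF \times ED = AT$,
so the chain collapses algebraically to $CDI = C \cdot IR / BW$ — the
implementation reproduces this collapse to machine precision, which is a
useful internal consistency check (`cdi()` is exactly linear in $C$).

Concentrations are mg/L throughout. Source texts for this chain sometimes
state µg/L, but every published intake value in this line of work is only
consistent with mg/L inputs; the package standardises on mg/L and leaves
unit conversion to the caller.

Oral reference doses and slope factors are compiled in: only As (SF 1.5),
Pb (SF $8.5\times10^{-3}$) and Ni (SF 0.84) carry slope factors. Pb's
carcinogen status is contested between agencies; the package follows the
convention of including it. `risk_table()` computes risk from group-mean
concentrations by default (the convention for survey tables) and offers a
per-sample mode, since within-group ranges are informative when samples are
available. Internally everything is full precision; any rounding to
3 significant figures is presentation only.

## Monte Carlo uncertainty and sensitivity

`run_mc()` propagates input uncertainty through the CR equation with
independent draws (no correlation structure is assumed), a fixed seed, and
a deterministic alphabetical draw order over the variables `AT, BW, ED, EF,
IR, conc` so seeds are portable across configurations. Percentiles are the
linear-interpolation empirical quantile (R type 7). Concentration
distributions are lognormal, moment-matched to the positive observed values
($\sigma^2 = \ln(1+s^2/m^2)$, $\mu = \ln m - \sigma^2/2$); zeros are
excluded from the fit, and a zero spread degenerates to a point mass.
Exposure variables are point masses by default; an `"uncertain-exposure"`
profile (body weight normal with 15% CV truncated at 0; ingestion rate
uniform ±30%) exists for sensitivity studies and is labelled illustrative —
those two distributions are this package's choices, not published values.

Sensitivity is contribution-to-variance in the convention of spreadsheet
risk tools: the signed squared Spearman rank correlation of each varying
input with the output, normalised to 100%. Numerator variables
(concentration, IR, EF, ED, SF) therefore report non-negative
contributions and denominator variables (BW, AT) non-positive ones. The
published means and percentiles of comparable spreadsheet analyses are not
reproduction targets here: their distributional assumptions are
unpublished. The test suite instead pins the machinery with properties —
degenerate inputs reproduce the closed-form risk to $10^{-12}$, the MC mean
error decays as $1/\sqrt n$, and single-input runs give ±100%
contributions.

## Descriptive statistics, correlation, clustering

`describe()` uses the $n-1$ standard deviation and CV = sd/mean × 100 with
the CV classes above; a single observation reports sd 0 with a warning, and
a non-positive mean yields an undefined CV labelled `"n/a"`. The term
"Pearson rank-order correlation" seen in applied water-quality work
conflates two methods, so `correlation_matrix()` implements both, Pearson
by default, with two-sided p-values from the t transform on
pairwise-complete observations and no multiplicity correction
(stars at 0.05/0.01). `cluster_metals()` standardises variables to
z-scores, takes Euclidean distances between variable profiles and applies
Ward's criterion (`hclust` method `ward.D2`; average linkage optional);
zero-variance variables are excluded with a warning, and determinism
follows `hclust`'s lowest-index tie-break.

## Synthetic campaigns

The generator emulates the three-source-type survey design the package
targets: 25/26/21 samples (WRS/GW/TW; the counts are config), per-metal
lognormal concentrations moment-matched to stored per-source mean/SD
targets, physicochemical fields from truncated normals, and uniform planar
coordinates over a 40 × 25 km domain. Lognormality is an assumption, chosen
because environmental concentrations are non-negative and right-skewed and
because CVs above 300% are incompatible with normality. Below-detection
readings are stored as 0 with probability `p_lod` (default 0, so the
generated moments match the targets; an LOD/2 substitution switch exists
but is off because no substitution rule is standard). The generator does
*not* emulate instrument error or between-metal correlation beyond the
shared spatial field, so passing tests demonstrate correctness of the
computations, not realism of any particular survey.

One caveat worth stating: at CV ≈ 366% (the As tap-water target) the sample
mean of 21 draws is extremely variable and the sample SD converges very
slowly (the lognormal's kurtosis is of order $10^4$). Realised campaign
moments therefore scatter widely around their targets at survey-scale n —
that is a property of the model, and of real surveys under it, not a bug.
Moment-recovery tests run at $n = 10^4$ and check the heavy-tail case on
the log scale.

In spatial mode a smooth latent field — a first-order polynomial trend plus
12 random cosine modes of wavelength equal to the correlation length,
normalised to unit variance — shifts the chosen metal's log-concentration.
The default correlation length is 12 km: roughly 2–3 wavelengths across the
domain, comfortably above twice the ~2.6 km mean site spacing of a
~100-site campaign, so the field is resolvable by interpolation and the
generator can expose a recoverable ground truth (`latent_field()`), which
is exactly what the mapping tests need. Broad gradients of this scale are
also what point-source contamination across an island province looks like.

## MLGI mapping

`build_surface()` composes two layers. The **trend** is a single-hidden-layer
network ($2 \to h \to 1$, tanh hidden, linear output; $k = 4h+1$ weights)
fitted to standardised coordinates by global-best particle swarm
optimisation with constriction coefficients (inertia 0.729, cognitive =
social = 1.494), a 70/15/15 train/validation/test split, and a recorded
best-so-far MSE trace that is non-increasing by construction. The
hidden-layer size can be chosen by
$AIC = n\ln(MSE_{\text{train}}) + 2k$ over a candidate range (1–30), ties
to the smaller $k$; training reports carry hidden neurons, particles,
iterations, elapsed seconds, MSE and Pearson R on validation and test sets.
The **residual** layer is ordinary kriging of the trend residuals under an
exponential variogram $\gamma(h) = c_0 + c_1(1 - e^{-h/a})$ fitted by
weighted least squares with Cressie weights $N_j/h_j^2$ — short lags drive
kriging accuracy, and count-only weights let long-range waviness inflate
the nugget. With a zero nugget the predictor interpolates the residuals
exactly, so trend + residual reproduces the site values. The kriging system
is solved in sill units (weights are invariant to rescaling the
semivariance), which keeps it well conditioned when index values are large;
a residual singularity is handled by escalating diagonal jitter with a
warning.

An optional "EBK-flavoured" mode refits the variogram on bootstrap
subsamples (default B = 20, 80% of sites) and averages predictions,
retaining the idea of variogram-uncertainty averaging from empirical
Bayesian kriging with fully open math; true EBK is a proprietary
implementation and is not reproduced. Coordinates must be planar;
`project_lonlat()` supplies a local equirectangular projection for lon/lat
inputs. Grid cells outside the convex hull of the sites are flagged
extrapolated and should be read with caution.

Published MSE/R tables for comparable NN-PSO mapping runs are not
reproduction targets: they depend on per-site data that is not released,
and on stochastic training. Parity here is structural (same report columns)
and property-based: affine surfaces are recovered with validation R ≥
0.999, AIC selects small architectures on data from small generators, and
the full stack recovers a 150-site synthetic smooth field with R ≥ 0.9
against the generator's ground truth.

## Problem sizes and numerical choices

The shipped tests and drivers use sizes chosen to make the statistics
meaningful at interactive cost: moment recovery at $n = 10^4$ draws,
MC convergence over $n = 10^2\ldots10^4$ with 40–60 replicates per size,
mapping with 150 sites, a 40 × 40 grid, 25–30 particles and 150–300 PSO
iterations. Degenerate inputs are handled explicitly rather than by
accident: zero-SD targets produce exact constants, constant fields produce
constant models with zero training MSE, all-zero concentration vectors fit
a warned point mass, empty index collections and empty groups error.

## Known limitations

Only the ingestion pathway is modelled (no dermal/inhalation parameters),
with fixed cohort parameters rather than age-interpolated ones. Monte Carlo
draws are independent — no rank correlation between inputs. The variogram
is isotropic exponential only. The latent field gives one metal at a time a
spatial pattern. None of these restrictions affect the deterministic index
and risk chains, which are exact arithmetic on their inputs.
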