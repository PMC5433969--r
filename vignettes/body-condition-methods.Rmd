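---
title: "Methods: morphometric condition indices and blubber cortisol in small cetaceans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometric condition indices and blubber cortisol in small cetaceans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cetacond)
```

# The problem

Body condition — the size of an animal's energy reserves relative to its
structural size — predicts survival and reproductive success, but there is
no consensus on how to measure it in cetaceans. `cetacond` implements a
complete evaluation framework for stranded small cetaceans (the harbor
porpoise is the motivating system): ten candidate morphometric condition
indices, the allometric diagnostics needed to choose among them, a
ground-truthing procedure that ranks them against a-priori biological
expectations, and a parallel tool chain that quantifies and models blubber
cortisol as a physiological condition marker usable on biopsy samples from
free-ranging animals.

Because strandings datasets of this kind are rarely deposited, the package
ships a first-class synthetic-data generator whose defaults are calibrated
to published group-level values for Scottish male harbor porpoises. Every
analysis stage can therefore be exercised, tested and benchmarked without
any external data.

# Condition indices and allometry

The ten indices are: ventral blubber thickness (mm); blubber/girth and
blubber/length (mm/cm); girth/length; mass/length (kg/cm); Fulton's
K = mass/length^3; Quetelet's index (BMI) = mass/length^2; relative
condition Kn = M / (a L^b) with (a, b) from OLS of ln M on ln L; the
residual index (residuals of that same log-log regression); and the scaled
mass index M-hat = M (L0 / L)^b_SMA, where b_SMA = b_OLS / r is the
standardized major axis slope and L0 the arithmetic mean length. Units are
kg, cm and mm throughout; this reproduces the conventional magnitude of
mass/length^2 for porpoises (about 0.0018–0.0022 kg/cm^2).

Two fitting identities are load-bearing and are asserted in the tests: the
residual index has mean zero over the fitting set, and Kn has geometric
mean one when the power law is fitted on the log scale. "OLS regression of
M against L" for Kn is therefore implemented on the log scale
(back-transformed), keeping Kn and the residual index mutually consistent.

The size-independence diagnostic rests on the nonlinear allometry
`mass = delta + alpha * length^beta`, fitted by Levenberg–Marquardt least
squares. Numerical notes:

* Starting values come deterministically from the log-log fit
  (`delta = 0`, `alpha = a`, `beta = b`).
* The model is fitted with lengths scaled by their geometric mean L0, i.e.
  `mass = delta + alpha0 * (L/L0)^beta`, and `alpha = alpha0 / L0^beta` is
  recovered afterwards (delta-method standard error). With raw lengths the
  Jacobian columns `L^beta` and `alpha L^beta ln L` are nearly collinear,
  because ln L spans barely one unit across the biological range; the
  centred parameterization removes that near-singularity.
* A start that lands exactly on a zero-residual solution (possible with
  noise-free data) trips the singular-gradient guard of the optimizer; the
  fit retries from small deterministic nudges.
* Confidence intervals are asymptotic (Wald) by default, with a seeded
  nonparametric bootstrap available. The choice matters little at n ≈ 300.

An index of the form mass/length^k compares animals of different sizes
fairly only if k matches the actual scaling exponent. `size_independence()`
reports the Pearson correlation of an index with length; with beta ≈ 2.33,
mass/length correlates strongly with length while mass/length^2 is far
closer to size-free, which is the heart of the argument for Quetelet's
index in this species.

# The ground-truthing framework

Each index is regressed on cause-of-death class (acute trauma vs chronic
debilitation), age class (calf ≤ 90 cm, adult ≥ 135 cm, juvenile between —
cutoffs live in configuration, not code), season (breeding = June–August),
and an age-by-season interaction. Model selection is an exhaustive
enumeration of all marginality-respecting term subsets ranked by AIC (AICc
for small samples), with Akaike weights `w_i ∝ exp(-delta_i/2)` and a
delta < 2 equivalence rule — the same procedure popularized by `dredge`,
reimplemented here as explicit enumeration. Effect sizes are partial
eta-squared, `SS_term / (SS_term + SS_error)`, with Type II sums of squares
by default (Types I and III available); reference levels are acute, adult
and nonbreeding so that each hypothesized deficit appears as a negative
coefficient.

Three directional assumptions score each index: chronic cases should be in
poorer condition; adults should be in the best condition; breeding-season
condition should be lower. The ranking procedure then (i) discards indices
with a contrary age-class pattern or an empty best model, (ii) carries
adjusted R^2 and the cause-of-death effect size for the survivors,
(iii) applies the size-independence override — when mass/length correlates
with length beyond |r| = 0.3 (no published numeric threshold exists; 0.3
is this package's default and is configurable), only the surviving
mass/length^k candidate with k nearest the fitted beta stays in contention
— and (iv) recommends the surviving index with the highest adjusted R^2.
The override deliberately operates on the *surviving* candidates: an
exponent already discarded for a contrary age pattern is no longer a
candidate, so a noisy beta-hat near 2.5 still selects between mass/length
and mass/length^2 rather than abandoning the family. Every step is
recorded in an audit trace.

Inside `evaluate_indices()` each index is standardized to unit variance
before model fitting. Partial eta-squared, adjusted R^2, verdict signs and
criterion deltas are all invariant to this rescaling, and it keeps the
sums of squares of the smallest-magnitude index (Fulton's K, ~1e-5
kg/cm^3) away from floating-point underflow guards in the ANOVA
decomposition.

No multiple-testing correction is applied across indices, and selection is
information-criterion based rather than p-value based, matching standard
practice for this design.

# The blubber cortisol chain

Quantification follows the competitive-ELISA convention: the standard
curve (0–800 ng/ml, sensitivity 2.5 ng/ml) is a four-parameter logistic
`response = d + (a - d) / (1 + (x/c)^b)` with `a > d` (response falls as
concentration rises), fitted per plate by Levenberg–Marquardt with
deterministic self-derived starts. Inversion is closed-form, duplicates
are averaged after inversion, and concentrations below the sensitivity are
flagged, never imputed. Tissue concentration is
`ng/g = ng/ml × volume / mass / efficiency` with a 0.5 ml resuspension
volume by default; extraction efficiency is a per-sample scalar (default
1) because published efficiency-versus-mass coefficients are not
available. Quality gates are the conventional mean intra-assay CV < 10%
(duplicate pairs) and inter-assay CV < 20% (control extracts across
plates); failures flag, they do not drop data.

Modelling uses gamma distributions with a log link throughout — blubber
hormone concentrations are strictly positive and right-skewed — with a
per-individual random intercept where individuals contribute repeated
measures (body-site and layer analyses) and plain GLMs for the
one-sample-per-animal covariate analysis. The mixed models are estimated
by maximum likelihood with a Laplace approximation (glmmTMB); the
estimator is a contract, not an algorithm — any estimator passing the
recovery tests (fixed effects within 2 SE of generating values in ≥ 90% of
replicates at 500 individuals) would be acceptable, and the one used is
recorded in each fit object. Candidate sets mirror the scientific
questions: {site, condition, site:condition} for the around-the-girth
analysis, plus layer terms for the stratification analysis, and
{sex, age class, cause of death, mass/length^2} for the outer-dorsal
biopsy-proxy analysis, all selected by AICc with the same enumeration
engine as the morphometric stage. Non-positive-definite or non-converged
candidates are excluded from the weight normalization and listed as
failed, which is routine for overparameterized members of small-sample
candidate sets.

# What the generator emulates

`synth_config()` holds the full generative parameterization; the defaults
*are* the published group values, and the same seed and configuration give
byte-identical output.

Morphometrics: age classes are drawn with mixture 0.10 / 0.45 / 0.45
(calf / juvenile / adult) — combined with the published per-age acute
proportions (25%, 47.8%, 49.1%) this reproduces an overall acute rate near
46% — and lengths per class as truncated normal N(75, 8) on [55, 90],
uniform on [90, 135], and truncated normal N(145, 8) above 135 cm (only
the cutoffs are published; the within-class shapes are this package's
choice of realistic values). Mass follows
`delta + alpha L^beta` (defaults −3.17, 4e-4, 2.33) times a lognormal
cause-of-death condition factor. Two calibration details matter:

* The condition factors are derived at configuration time by numerical
  integration of baseline mass/length^2 over the age-mixture conditional
  on cause of death, so the group means hit the configured targets
  (0.0022 acute, 0.0018 chronic) exactly in expectation.
* The configured group SDs (0.00035, 0.00050) are *total* within-group
  spreads; the lognormal noise is sized to supply only the variance that
  the systematic age/length structure does not already produce. Sizing
  the noise at the full printed SD would double-count variance and
  inflate the spread of the fitted scaling exponent.

Girth and blubber thicknesses are plumbing (no published targets): girth
is 0.62 L scaled by condition^0.5 with 15% lognormal noise, ventral
blubber 14 mm scaled by condition^1.2 with 35% noise. The noise levels
were set so the resulting index models reproduce the *published ordering*
of explanatory power (girth/length adj R^2 ≈ 0.19, blubber ≈ 0.22, both
well below mass/length^2 ≈ 0.5 at the study scale); with unrealistically
precise girth, girth/length would outrank every mass-based index, which
contradicts the reported structure. The season effect defaults to zero
because season was never retained in the published selections; it is
switchable for power studies.

Cortisol: the field is parameterized directly by stratum means on the log
scale — full-depth site means 69.09 / 90.48 / 83.22 ng/g (dorsal /
lateral / ventral), layer means 77.84 / 156.28 / 180.02 ng/g (outer /
middle / inner), outer-dorsal sex means 111.37 / 66.77 ng/g (female /
male), a juvenile log-effect of 0.35, and a condition slope of −400 per
kg/cm^2 — with a normal per-individual random intercept (sd 0.25) and
gamma draws. All centred effects carry exact moment-generating-function
corrections, so empirical stratum means are calibrated, not merely
approximate. In the layer design the per-site full-depth means are set to
the printed site means; their marginal (80.93 ng/g) therefore sits about
9% below the layer-study's printed full-depth mean of 88.65 ng/g. The two
published subsets are mutually inconsistent at this level and the site
means were given priority; the discrepancy stays inside the 10%
calibration band.

The gamma shape is per sampling design — 4 (site study), 1.2 (layer
study), 6 (outer-dorsal covariate study) — because the published
dispersions differ by subset: the layer strata show CVs near 1.0 while the
outer-dorsal sex groups show CVs near 0.5, and a sex effect of the
reported size is statistically detectable at n = 20 (consistent with the
reported p = .02) only under the latter. A single common shape cannot
satisfy both; a scalar shape is still accepted and applies everywhere.

Assay plates: duplicate responses are generated by pushing lognormally
perturbed concentrations through the 4PL curve, with the perturbation sd
set from the intra-assay target via the expected two-replicate CV
(`tau = target / sqrt(2/pi)`), and a lognormal plate shift sized so control
extracts across plates reproduce the inter-assay target
(`sigma_p^2 = CV^2 - tau^2/2`). Defaults target the published 5.65% and
10.84%. The efficiency curve rises to a plateau at 0.15–0.2 g and declines
beyond it; this shape is an assumption (plausible for solvent-limited
extraction, consistent with the published recommendation of 0.15–0.2 g
subsamples) and is flagged as such. An optional additive progesterone
cross-reactivity bias for females exists in the generator only; no
correction is applied in estimation.

What the generator does *not* emulate: measurement rounding, carcass
decomposition, spatial or temporal stranding structure, female
reproductive status (all animals in the morphometric design are male), and
any between-plate drift beyond a single multiplicative shift. Passing
tests therefore demonstrate that the estimators recover the structure this
generative model encodes at the published magnitudes — not that the model
captures every feature of real strandings data.

# Problem sizes and open choices

The test suite exercises the framework at the study scales the analyses
target: 291 animals for the morphometric stage (20–50 replicates for
selection-frequency checks), 2000 animals for moment-calibration checks,
500 individuals × 100 replicates for mixed-model coverage, 200 plates for
CV recovery, and 1000 replicates for the homogeneity-test calibration.
These sizes make every simulation-based check stable at its stated
tolerance while keeping a full run in the minutes range.

Choices that were genuinely open, and how they were settled:

* Sums-of-squares type for partial eta-squared: Type II, matching the
  common default for additive linear models; configurable.
* Criterion: AIC at the n ≈ 300 morphometric stage, AICc for the n ≈ 20
  cortisol stage; both available everywhere.
* Levene center: mean (the classical test); median (Brown–Forsythe)
  optional.
* The intercept reported for the nonlinear allometry can be negative on
  real-scale data (lack of very small calves); it is reported as fitted,
  with the interval, and no constraint is imposed.
* Below-LOD assay values are retained with a flag.
* Reports are tables (CSV/JSON), not figures; every published figure this
  package addresses is reproduced as its underlying table.

# Known limitations

Exact published fit statistics (per-index adjusted R^2 of 0.72/0.50, exact
partial eta-squared values, absolute AICc values) depend on the raw data,
which are not public; the package treats them as recovery-order targets
(orderings, signs, calibrated group means) rather than equalities. The
random-intercept variance in the covariate design is not identifiable with
one sample per individual and simply thickens the marginal noise. The
layer/site inconsistency noted above is inherited from the published
values themselves.
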