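---
title: "Estimating angling-induced selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating angling-induced selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`anglesel` estimates how a passive hook-and-line fishery selects on the
phenotype of its target fish. The setting it models is a replicated pond
experiment on juvenile common carp: three ponds stocked with 40
PIT-tagged fish each, a six-day undisturbed observation period in which
antennae at a shelter and two feeding spots record individual boldness, a
20-day standardized angling period (four rod-hours per pond per day), and a
final draining in which growth increments are measured. This vignette
explains each model in the chain, the choices behind its defaults, and what
the synthetic-data generator can and cannot tell you about real data.

## Boldness from detection logs

Raw PIT reads are turned into three boldness measures per fish: visits per
hour at the close and at the distant feeding spot, and minutes per hour
spent sheltering. A *visit* is a maximal run of reads at one antenna
separated by less than a debounce window (default 60 s); a shelter *stay*
is the analogous merged presence interval, credited with its duration plus
half a debounce window so that an isolated read counts half a window. The
debounce default is a judgment call — PIT hardware emits bursts of reads per
pass — so it is configurable, and the package's own validation relies only on
properties that are robust to this choice. Daily rates use the full 24-h day
as the observation window, and period means average over *all* days in the
period, so a fish with no reads scores zero rather than missing.

Consistency of boldness is quantified two ways, both on week-level means
(observation week vs first angling week): Spearman rank correlation (midranks
for ties, t-approximation with n − 2 df), and the Lessells–Boag repeatability,
i.e. the intraclass correlation from a one-way ANOVA with individuals as
groups:

  s²_W = MS_W,  n₀ = (Σnᵢ − Σnᵢ²/Σnᵢ)/(a − 1),
  s²_A = (MS_A − MS_W)/n₀,  r = s²_A/(s²_A + s²_W).

Negative estimates are reported as computed (flagged, never clamped):
clamping at zero would bias the estimator exactly where its sampling
distribution straddles zero.

## Shape from landmarks

Sixteen landmarks per fish (left side, fixed anatomical order) are read from
TPS files; the y-axis is negated on read because image coordinates run
downward (configurable). The morphometric chain is:

1. **Generalized Procrustes superimposition** — translate to centroid
   origin, scale to unit centroid size, iteratively rotate to the consensus
   (SVD-based optimal rotation, reflections disallowed because all
   photographs show the same side) until the consensus changes by less than
   `tol` (default 1e-10, at most 100 iterations). The superimposed set is
   then rotated once more so the consensus lies along its principal axes,
   with the 180° ambiguity resolved by the skewness of landmark projections;
   this makes the output invariant to the arbitrary orientation of the
   input photographs, and therefore bit-reproducible.
2. **Arching removal (Burnaby projection)** — fish photographed with a
   dorsoventrally bent body contaminate shape variation. A pure bend
   displaces every landmark in y by approximately a quadratic function of
   its position along the body axis, so the nuisance direction is built
   geometrically from the consensus: the y-pattern `(x − mean x)²`,
   orthogonalized against the similarity modes the superimposition has
   already removed. Data are projected onto its orthogonal complement,
   `X(I − F(FᵀF)⁻¹Fᵀ)`. An alternative construction — regressing aligned
   coordinates on a per-fish midline bend score — was evaluated and
   rejected as the default: when shape variation is concentrated in a few
   directions, any finite-sample correlation between the score and a real
   shape factor makes the regression basis collapse onto that factor and
   the projection then removes genuine signal. The per-fish bend scores
   (quadratic coefficient of the midline landmarks 1, 14, 16, 8 and the
   peduncle midpoint, evaluated against consensus abscissae) are retained as
   a diagnostic, and a user-supplied basis overrides the default. The
   `arching_diagnostic()` reports how much the PC1 explained-variance
   fraction changes under projection; when no real arching is present the
   change should be well under 5 percentage points.
3. **PCA** — covariance eigendecomposition of the projected coordinates;
   eigenvector signs are fixed (largest-magnitude loading positive) for
   cross-platform reproducibility. Body shape SB is the first PC of the full
   16-landmark analysis; head shape SH is the first PC of a separate
   superimposition of the six head landmarks (1, 2, 12, 13, 15, 16). The
   head analysis is not Burnaby-projected: across the short head region a
   bend is nearly affine, and the head-subset superimposition removes affine
   nuisance on its own.
4. **Size correction** — both PC1 scores are replaced by their OLS residuals
   on total length, making the shape traits uncorrelated with TL by
   construction.

No tangent-space projection is applied after superimposition: shape
variation in a single-age, single-population sample is small enough that
the difference is negligible, and the reference software used in this
literature behaves the same way.

## The survival model and selection gradients

Fitness is survival of the fishery: a fish first captured within the
horizon (7 or 20 days) is coded s = 0, otherwise s = 1; recaptures are
ignored. Six predictors enter z-standardized (sample SD, n − 1): boldness BP
(distant-spot visits, week 1), total length TL, growth residual G (growth
increment residualized on BP, separating selection on growth from selection
via behavior), body shape SB, head shape SH, shelter use SP, plus quadratic
terms BP² and G² to probe stabilizing/disruptive selection.

Nine nested candidate models per horizon — from the full starting model down
to the intercept-only NULL — are fit by maximum-likelihood logistic
regression with a pond random intercept (Laplace approximation; `fixed` and
`none` pond modes are available for sensitivity). Models are ranked by

  AICc = −2ℓ + 2k + 2k(k + 1)/(n − k − 1),

with Akaike weights wᵢ = exp(−Δᵢ/2)/Σ exp(−Δⱼ/2). The parameter count k is
the number of fixed effects including the intercept (NULL ⇒ k = 1); the
random-effect variance is deliberately not counted, matching how the model
set is indexed in this literature. The *final* model used for gradients is
the richest model within ΔAICc < 1 of the minimum.

Logistic coefficients are linearized with the Janzen–Stern average-gradient
transformation,

  β_SD,j = α_j · [ (1/n) Σᵢ Ŵᵢ(1 − Ŵᵢ) ] / W̄,

where Ŵᵢ are fitted survival probabilities and W̄ the mean observed fitness.
Because predictors are z-scored these are SD-standardized gradients; the
tests pin this semantics against a numerical derivative of mean relative
fitness, independent of the closed form. Mean-standardized gradients are
β_μ,j = β_SD,j · μ_j/σ_j, the proportional fitness change from doubling the
trait — the unit-free quantity that makes selection on traits with different
units comparable. For derived zero-mean traits this scaling needs care: the
pipeline uses the raw growth increment's mean for G (a doubling of growth is
meaningful; a doubling of a zero-mean residual is not), while SB and SH keep
their zero means, so their β_μ are reported as ≈ 0 — any nonzero |β_μ| for
shape would be an artifact of the score's arbitrary origin. Model fit is
summarized by Nagelkerke's pseudo-R².

p-values are Wald; no multiplicity correction is applied (none is in the
design being emulated). Tied AICc minima are broken toward fewer parameters,
then model order.

## What the simulator emulates

`sim_config()` encodes the study conditions: 3 ponds × 40 fish; trait means
and SDs (TL 199 ± 9.2 mm, BP 4.6 ± 1.5 visits/hr, SP 6.3 ± 2.6 min/hr,
growth 7.8 ± 5.4 mm) and the six-trait correlation matrix of the pond
experiment (boldness–growth 0.31, boldness–shelter −0.52), repaired to
positive definiteness by eigenvalue clipping at 1e-6 should a user-edited
matrix need it; 6 observation days, 20 angling days with 4 one-hour
sessions per day.

**Detections.** Each fish's expected daily distant-spot rate equals its BP
trait value; daily rates are lognormal around that expectation and counts
are Poisson. The day-to-day variance is solved analytically so that the
intraclass correlation of weekly mean rates equals a target (default 0.65,
the middle of the 0.53–0.74 range the experiment reported). The close spot
shares each fish's boldness with correlation 0.9 (the two spots were nearly
interchangeable in the field, r ≈ 0.89). Visits are emitted as bursts of 1–5
reads within 10 s on a jittered within-day grid with at least 80 s between
visit starts, so a ≤ 60 s debounce recovers counts exactly; shelter stays
are emitted as reads every 45 s. The event-free `simulate_daily_activity()`
level exposes the same generative process without read emission for
replication-heavy validation.

**Angling.** Every session, every fish is landed with probability
`plogis(intercept + Σ coef·z + frailty·u)` and released (recaptures are
logged; the analysis uses first captures). The trait coefficients
(BP 1.0, TL 0.74, G 0.70 per SD, per session) and the lognormal-frailty
SD (2.817) with the intercept (−4.753) were calibrated jointly so that
three observed features of the fishery hold simultaneously: ~40% of fish
ever captured within 7 days, ~52% within 20 days, and fitted 7-day survival
coefficients of about −0.5/−0.4/−0.4 per SD of BP/TL/G. The flattening of
the capture curve (40% in the first week, only 12 points more in the next
13 days) cannot arise from a homogeneous hazard; the frailty term carries
the required individual catchability heterogeneity, a well-documented
feature of angling vulnerability. `calibrate_capture_intercept()` re-solves
the intercept for any other target by bisection on an analytic Monte-Carlo
expectation.

**Landmarks.** Configurations are the template carp shape deformed along two
orthonormal directions (trunk depth for SB, head elongation for SH, 0.030
and 0.025 body lengths per SD), bent along a quadratic arching direction by
a per-fish standard-normal posture score (0.020 body lengths per SD),
perturbed by isotropic digitizing noise (0.002 body lengths), scaled by TL
and randomly rotated/translated as a photograph would be.

**Attrition.** Each fish independently ends the experiment `predated`
(p = 11/120), `tag_lost` (p = 15/120) or `complete` — mutually exclusive
fates, so 78.3% of the stock is expected to yield complete records.
Attrition is applied at the end of the experiment (losses concentrated in
the final weeks in the field), so it censors records without altering
behavior or capture risk.

**What it does not emulate.** No water-temperature dynamics (the drop during
the long fishery is absorbed into the frailty-driven hazard flattening
rather than modelled), no hook avoidance learning, no trait-dependent
predation (whether bolder fish were predated more in the ponds is unknown;
attrition is trait-independent), no multi-generation response. Measured BP
attenuates latent correlations by roughly the square root of the
repeatability, so sample correlations among *measured* traits sit slightly
below the latent targets. Passing recovery tests on these simulations shows
the estimators are consistent under the stated generative model — not that
the model captures every feature of real pond telemetry.

## Determinism and numerical conventions

Every `simulate_*` operation derives a private RNG stream from the
configuration seed (and restores the caller's RNG state), so a fixed
configuration yields bit-identical data, and a fixed pipeline seed yields
byte-identical report files; wall-clock timings go to a separate log file.
Logistic fits converge on a log-likelihood change below 1e-8 (max 100
IRLS iterations); separation and rank deficiency are hard errors naming the
offending model or terms, and a failed candidate model is recorded while the
comparison continues. GPA convergence is 1e-10 on the consensus; Burnaby
projection tolerances are exact to ~1e-10 by construction.

## Validation problem sizes

The test-suite and acceptance checks use sizes chosen to keep Monte-Carlo
error well inside the asserted tolerances: 10⁴ fish for trait-correlation
convergence (tolerance 0.03), 500 replicate fisheries at the experiment's
sample size for gradient sign recovery, 200 replicates of 94 fish for
repeatability recovery (mean within ±0.05 of the 0.6 target), one
60 000-fish mega-replicate as the large-sample reference for gradient
consistency, and 200-specimen landmark sets for shape-recovery checks.

## Known limitations

- With three ponds and no simulated pond effect, the pond random-intercept
  variance is usually estimated at zero (a boundary fit); this is expected
  and benign, but with so few groups the random-intercept mode cannot be
  meaningfully stress-tested against strong pond heterogeneity.
- CPUE is reported as captures divided by accumulated rod-hours; published
  effort accounting can differ in rounding, so CPUE is a descriptive output,
  not a validated one.
- The arching basis is a single quadratic-bend direction; stronger or
  asymmetric posture artifacts would need a user-supplied multi-column
  basis.
- β_μ is computed per final model; when several near-best models contain a
  trait, gradients are not model-averaged.
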