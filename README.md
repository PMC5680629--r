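# anglesel

Tools for estimating **angling-induced phenotypic selection** from
replicated pond experiments on PIT-tagged fish. Recreational hook-and-line
fisheries do not capture fish at random: bolder, faster-growing and larger
individuals take baits more readily, so a fishery acts as a selective agent
on behavior, morphology and growth — the mechanism behind the hypothesized
"timidity syndrome" of exploited stocks. `anglesel` implements the complete
analysis chain for quantifying that selection in a controlled pond fishery
on juvenile common carp, together with an individual-based simulator of the
whole experiment so that every stage is runnable and testable without field
data.

The package is aimed at behavioral ecologists and fisheries scientists
working with passive telemetry (PIT antennae), landmark morphometrics and
capture-based fitness data.

## The analysis chain

1. **Boldness metrics** (`summarize_behavior`) — raw antenna reads are
   debounced into feeding-spot visits (visits/hr) and shelter stays
   (min/hr); consistency across observation weeks is quantified by Spearman
   rank correlation (`spearman_consistency`) and by the Lessells–Boag
   repeatability, the intraclass correlation from a one-way ANOVA
   (`lessells_boag_repeatability`):
   `r = s²_A / (s²_A + s²_W)`, `s²_A = (MS_A − MS_W)/n₀`.
2. **Shape traits** (`read_tps`, `generalized_procrustes`,
   `estimate_arching_basis`, `burnaby_project`, `shape_pca`,
   `size_correct`) — 16-landmark configurations are Procrustes-superimposed,
   cleaned of dorsoventral arching by Burnaby's orthogonal projection
   `X(I − F(FᵀF)⁻¹Fᵀ)`, and summarized by PCA: body shape SB (full
   configuration) and head shape SH (landmark subset), both residualized on
   total length.
3. **Survival models** (`assign_fitness`, `run_model_set`) — capture within
   an angling horizon codes fitness s = 0/1; nine nested logistic
   regressions of survival on the z-standardized traits
   (BP, TL, G, SB, SH, SP, BP², G²) with a pond random intercept are ranked
   by `AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1)` and Akaike weights
   `wᵢ = exp(−Δᵢ/2)/Σ exp(−Δⱼ/2)`.
4. **Selection gradients** (`janzen_stern`,
   `mean_standardized_gradients`) — logistic coefficients of the final model
   are linearized via the average-gradient transformation
   `β_SD = α · mean(Ŵ(1−Ŵ)) / W̄` and mean-standardized,
   `β_μ = β_SD · μ/σ`, the proportional fitness change from doubling a
   trait — comparable across traits with different units.
5. **Simulator** (`sim_config`, `simulate_experiment`, `write_fixture`) —
   correlated traits, Poisson foraging with a tunable intraclass
   correlation, a per-session capture hazard with catchability frailty
   calibrated to the experiment's 40% (7-day) and 52% (20-day) capture
   fractions, landmark generation with injected shape/arching effects, and
   end-of-experiment attrition (78.3% complete records expected).

See the methods vignette (`vignettes/angling-selection-methods.Rmd`) for
model details, assumptions and design choices.

## Worked example

```r
library(anglesel)
run <- run_pipeline(run_config(seed = 1))
print(run)
```

```
Angling-induced selection: pipeline summary
seed: 1
stocked fish: 120; complete records: 98 (81.7%)

Repeatability of boldness measures (week 1 vs week 2):
  bp_close    rho=0.716  F=7.653  r=0.769
  bp_distant  rho=0.620  F=4.769  r=0.653
  sp          rho=0.687  F=5.143  r=0.674

Arching diagnostic: PC1 explained 41.1% -> 50.5% (change -9.48 pp)

--- 7-day horizon ---
captured: 38/98 (38.8%), CPUE 0.452 fish/hr
final model: M4 (Nagelkerke R2 = 0.379)
  BP   alpha=  -1.004  beta_SD=  -0.275  beta_mu=  -0.646
  TL   alpha=  -0.423  beta_SD=  -0.116  beta_mu=  -2.405
  SB   alpha=   0.206  beta_SD=   0.056  beta_mu=   0.000
  SH   alpha=   0.789  beta_SD=   0.216  beta_mu=   0.000
  G    alpha=  -0.840  beta_SD=  -0.230  beta_mu=  -0.361

--- 20-day horizon ---
captured: 49/98 (50.0%), CPUE 0.204 fish/hr
final model: M6 (Nagelkerke R2 = 0.308)
  BP   alpha=  -1.159  beta_SD=  -0.442  beta_mu=  -1.037
  SB   alpha=  -0.365  beta_SD=  -0.139  beta_mu=  -0.000
  G    alpha=  -0.670  beta_SD=  -0.255  beta_mu=  -0.401
```

Reading the output: of 120 simulated fish, 98 yield complete records after
predation and tag loss. The three boldness measures are repeatable across
weeks (r ≈ 0.65–0.77) — fish have consistent personalities. In the 7-day
fishery 38.8% of fish are captured; the best-supported survival model shows
that bolder (negative α for BP), larger and faster-growing fish are more
likely to be removed. On the doubling scale, total length carries the
strongest short-term selection (β_μ = −2.4: doubling TL would cut relative
survival drastically), while over 20 days boldness dominates
(β_μ = −1.04). Shape traits have β_μ ≈ 0 because their scores are
zero-mean residuals. Negative gradients mean the fishery selects *against*
the trait — survivors are shyer, smaller and slower-growing, the raw
material for a timidity syndrome.

Setting `out_dir` in `run_config()` additionally writes tidy CSV tables
(model comparisons, gradients, repeatability, correlation matrix,
descriptives) plus a human-readable `summary.txt`; runs with the same seed
are byte-identical. A thin command-line wrapper is included at
`inst/cli/anglesel.R` (`simulate` and `run` subcommands).

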