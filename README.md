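# encmediate

Mediation analysis of women's empowerment, skilled antenatal care and
essential newborn care practice, for clustered (DHS-style) survey data.

## The problem

Essential newborn care (ENC) is the WHO bundle of five immediate newborn
practices — clean cord cutting, nothing (or only chlorhexidine) applied to
the cord, drying within 5 minutes, bathing delayed at least 72 hours,
breastfeeding within 1 hour. A newborn received *good* ENC only if all
five were practiced. Among home births this is rare, and a central policy
question is whether women's empowerment raises it — directly, and
indirectly by increasing skilled antenatal care (SANC: eight or more
pregnancy check-ups from skilled personnel, the WHO 2016 guideline).

`encmediate` is for epidemiologists and biostatisticians who want that
analysis as a tested, reproducible pipeline:

* **Empowerment index.** An Alkire–Foster style multidimensional
  empowerment index over five equally weighted dimensions (22 binary
  indicators by default),
  `Z_i = (1/m) Σ_j (1/p_j) Σ_k y_ijk ∈ [0, 1]`,
  categorised low / average / high at 0.50 and 0.75. The schema is data
  (YAML), validated against the nested equal-weight invariants.
* **Structural model.** Two cluster random-intercept logistic equations
  (adaptive Gauss–Hermite quadrature):
  `logit P(SANC) = α_m + a·MEI + x'γ_m + u_med` and
  `logit P(goodENC) = α_y + c·MEI + b·SANC + x'γ_y + u_out`,
  with latent-scale ICC `σ²_u / (σ²_u + π²/3)` and a boundary-corrected
  (½χ²₀ + ½χ²₁) likelihood-ratio test for the cluster effect.
* **Mediation.** Product of coefficients per exposure level: indirect
  effect `ME = a·b`, total effect `TE = ab + c` if ME is significant
  (else `TE = c`), proportion mediated `PME = 100·ME/TE`; odds ratios are
  `exp(·)` of each effect. Inference by cluster bootstrap with
  bias-corrected (BC) percentile intervals.
* **Synthetic generator.** Clustered populations drawn from exactly this
  model with known ground truth (including the published path
  coefficients and ICCs as defaults), so the whole pipeline is testable
  without access to restricted survey microdata.

## Worked example

```r
library(encmediate)

cfg <- synthetic_config(seed = 1)           # 672 clusters x 4 women
pc  <- pipeline_config(synthetic = cfg, B = 500, seed = 2, verbose = FALSE)
res <- run_pipeline(pc)
print(res)
```

```
ENC mediation pipeline result
   2688 women in 672 clusters; config c91f3356 
  good ENC 7.22%, SANC 4.69%
  ICC: mediator 0.172, outcome 0.093
Mediation result: 500 bootstrap resamples (cluster unit, seed 2)
Reference exposure level: low 

  average  direct    +0.18 (0.22)  OR 1.20 [0.81-1.95] 
  average  indirect  +0.55 (0.36)  OR 1.74 [1.07-4.64] * 
  average  total     +0.73 (0.41)  OR 2.08 [1.09-5.15] * 
  high     direct    +0.82 (0.25)  OR 2.27 [1.44-3.65] * 
  high     indirect  +1.19 (0.50)  OR 3.28 [1.55-11.79] * 
  high     total     +2.01 (0.52)  OR 7.45 [3.35-23.34] * 
  mediator->outcome b = +0.92 (0.29)  OR 2.51 [1.42-4.33] *
  PME average  75.57%
  PME high     59.10%
```

Reading the output: this synthetic population was generated with
`a_high = 1.52`, `b = 0.72`, `c_high = 0.53`, so the true high-level
indirect effect is `1.52 × 0.72 = 1.09` and the true total effect
`1.09 + 0.53 = 1.62`; the fitted values (+1.19 and +2.01, with bootstrap
SEs 0.50 and 0.52) are one draw from the estimator's sampling
distribution around those targets. Each row shows the log-odds effect,
its cluster-bootstrap SE, the odds ratio and the 95% bias-corrected
interval (`*` = interval excludes 0). `PME high = 59.1%` says that at
this draw about three-fifths of the total high-empowerment effect on good
ENC runs through skilled antenatal care. Prevalences (7.22% good ENC,
4.69% SANC) echo the rates the generator was calibrated to (7.6% and
5.28%). The marginal ICC estimates sit inside the published interval
estimates for a survey of this design.

Individual stages are exported too: `compute_mei()`, `categorize_mei()`,
`derive_good_enc()`, `derive_sanc()`, `fit_relogit()`,
`cluster_effect_lrt()`, `fit_mediation_sem()`, `bootstrap_mediation()`,
`screen_covariates()`, `association_table()`, `write_results()` — see the
help pages and the methods vignette (`vignettes/mei-enc-mediation.Rmd`)
for the model, its assumptions and the design decisions.

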