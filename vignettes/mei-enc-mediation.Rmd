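---
title: "Methods: empowerment, skilled antenatal care and newborn-care mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: empowerment, skilled antenatal care and newborn-care mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(encmediate)
```

## The scientific question

Essential newborn care (ENC) bundles five WHO-recommended practices for the
first hours of life: cutting the cord with a clean instrument, applying
nothing (or only chlorhexidine) to the cord, drying the baby within five
minutes, delaying the first bath at least 72 hours, and initiating
breastfeeding within one hour. A newborn received *good* ENC only when all
five were practiced. Among home births in settings like Bangladesh, good ENC
is rare, and a natural policy question is whether women's empowerment
improves it — directly, and indirectly by increasing the use of skilled
antenatal care (SANC, defined by the WHO 2016 guideline as eight or more
pregnancy check-ups from skilled health personnel).

`encmediate` implements that analysis end to end: a multidimensional
empowerment index (MEI), derivation of the binary mediator and outcome,
two multilevel logistic structural equations, product-of-coefficients
mediation with cluster-bootstrap bias-corrected inference, and a synthetic
generator of clustered survey data with known ground truth so the whole
pipeline is testable without restricted survey records.

## The empowerment index

The MEI follows the Alkire–Foster nested equal-weighting convention. With
$m$ dimensions and $p_j$ binary indicators in dimension $j$ ($y_{ijk} \in
\{0,1\}$, 1 = empowered on that indicator), woman $i$'s score is

$$Z_i = \frac{1}{m} \sum_{j=1}^{m} \frac{1}{p_j} \sum_{k=1}^{p_j} y_{ijk},
\qquad Z_i \in [0, 1].$$

The default schema has five dimensions — household decision-making autonomy
(4 indicators), attitude towards intimate partner violence (5), health
access barriers (4), social independence (8), asset ownership (1) — each
carrying weight 0.20 split equally across its indicators, so the score is
identically a weighted sum of the 22 indicators with Table-style weights
(0.050, 0.040, 0.050, 0.025, 0.200). `validate_mei_schema()` enforces the
weight identities; the schema is data (YAML), not code, so alternative
dimension sets run unchanged.

Scores are categorised low ($Z < 0.50$), average ($0.50 \le Z < 0.75$) and
high ($Z \ge 0.75$). The source phrasing makes 0.75 inclusive-high
explicit; exactly 0.50 is resolved as average, consistent with "scores
below 0.50" being low. Both cut points are arguments, so the opposite
resolution is one keystroke away. Missing or non-binary indicators are
errors, never imputed zeros, which would bias $Z$ downward.

## The structural model

Let $M_i$ be SANC (1 = eight-plus skilled visits) and $Y_i$ good ENC, for
woman $i$ in cluster (enumeration area) $c(i)$. Two random-intercept
logistic equations are fitted:

$$\operatorname{logit} P(M_i = 1) = \alpha_m + a_{\text{avg}} A_i +
a_{\text{high}} H_i + x_i'\gamma_m + u^{med}_{c(i)},$$

$$\operatorname{logit} P(Y_i = 1) = \alpha_y + c_{\text{avg}} A_i +
c_{\text{high}} H_i + b M_i + x_i'\gamma_y + u^{out}_{c(i)},$$

with $A_i, H_i$ the average/high MEI dummies (low is the reference),
$x_i$ screened covariates and $u_c \sim N(0, \sigma^2_u)$ independent
between equations. Estimation is maximum likelihood with the random
intercept integrated out by adaptive Gauss–Hermite quadrature
(`lme4::glmer`); the default is 7 quadrature points with the `bobyqa`
optimiser, and a test requires estimates to move by less than $10^{-3}$
when the point count doubles. Within-cluster dependence is summarised by
the latent-threshold intraclass correlation
$\mathrm{ICC} = \sigma^2_u / (\sigma^2_u + \pi^2/3)$, the standard
convention for binary multilevel models (the level-1 logistic residual has
variance $\pi^2/3$). The cluster effect is tested by a likelihood-ratio
statistic against the ordinary logistic fit; because $\sigma^2_u = 0$ sits
on the boundary of its parameter space the reference distribution is the
50:50 mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, i.e. the p-value is
half the $\chi^2_1$ tail (0.5 at a statistic of 0).

Candidate covariates (age group, birth order, residence, region) enter the
equations when the chi-square test of their unadjusted association with
good ENC has $p < 0.30$. The screening basis is the outcome association
(the descriptive-table column); this is one of several readings of a
loosely specified rule, so both the threshold and the candidate list are
arguments.

## Mediation and bootstrap inference

Effects are combined on the log-odds scale by the product-of-coefficients
rule, per non-reference MEI level: indirect effect $\mathrm{ME} = a b$,
total effect $\mathrm{TE} = ab + c$ *if* the indirect effect is
significant, otherwise $\mathrm{TE} = c$; proportion mediated
$\mathrm{PME} = 100\,\mathrm{ME}/\mathrm{TE}$, reported only when the
indirect effect is significant and $\mathrm{TE} \neq 0$. Reported odds
ratios are $\exp(\cdot)$ of each effect. A caveat inherited from the
method: logistic coefficients are non-collapsible, so $a b$ from two
differently conditioned equations is a model-scale summary, not a
counterfactual indirect effect; the package reports the method's own
quantity and does not attempt a counterfactual-scale estimator.

Inference is by bootstrap. The default resampling unit is the cluster
(respecting the two-stage design): each of $B$ resamples draws the
original number of clusters with replacement, refits both equations and
recomputes every effect. The standard error is the resample standard
deviation; intervals are bias-corrected (BC) percentile intervals — the
percentile interval shifted by $z_0 = \Phi^{-1}(\hat F(\hat\theta))$
estimated from the fraction of resample statistics below the point
estimate, with no acceleration term (plain "bias-corrected", not BCa).
Significance means the 95% BC interval excludes 0. Resample refits default
to the ordinary-logistic fast path: cluster resampling already carries the
between-cluster variability into the intervals, and refitting the
quadrature likelihood for every resample buys little for its cost;
`boot_engine = "glmer"` (Laplace by default) is available when the
random-intercept likelihood is wanted inside the loop. Failed resamples
(non-convergence, separation — flagged as coefficients beyond ±15 — or
lost factor levels) are dropped and counted, with a warning beyond 10%.
The resample index sequences are drawn up front from the seed, so
`(seed, B, unit)` reproduce every interval bit for bit.

Ties in the BC correction use a half-count, and the empirical fraction is
clamped to $[1/(B+1), B/(B+1)]$ so $z_0$ stays finite; a degenerate
bootstrap distribution (every resample identical) collapses the interval
to the point estimate with SE 0.

## The synthetic generator

`generate_population()` draws from exactly the model above, so every
downstream stage has known ground truth. Defaults are the study
conditions:

* 672 clusters of 4 women (the home-birth analysis subsample an
  enumeration area of ~30 sampled households contributes, not the full
  household listing); a Poisson cluster-size option reflects varying
  realised counts.
* Indicator prevalences at the observed dimension means (decision 68.6%,
  anti-violence attitude 92.7%, health access 60%, social independence
  42.3%, assets 40%), drawn independently by default; an optional shared
  Gaussian factor (`latent_loading`) induces positive dependence through
  a Gaussian copula that preserves the marginals, widening the score
  distribution towards the survey's category split.
* Path coefficients $a_{\text{avg}} = 0.73$, $a_{\text{high}} = 1.52$,
  $b = 0.72$, $c_{\text{avg}} = -0.01$, $c_{\text{high}} = 0.53$;
  random-intercept variances solving ICC 0.26 (mediator) and 0.13
  (outcome); covariate effects 0 (no published values exist for them).
* Intercepts $\alpha_m = -4.19$, $\alpha_y = -2.86$, calibrated once by
  Gauss–Hermite integration over the random intercepts so the marginal
  prevalences under the defaults echo the survey's headline rates (5.28%
  SANC, 7.6% good ENC).
* ENC component base probabilities at the observed component rates
  (86.3%, 47.1%, 62.8%, 47.2%, 69.0%). Components are made consistent
  with the drawn outcome: all five are 1 when good ENC = 1; otherwise
  they are drawn at base rates and, should all five come up 1, one
  uniformly chosen component is forced to 0 — the simplest scheme that
  preserves the good-ENC definition exactly.
* Visit counts: non-SANC women draw from 0–7 with Poisson(2) weights,
  SANC women from 8 + Poisson(2) — plumbing so the ≥8 dichotomisation is
  exercised from counts.

One root seed spawns a per-cluster substream seed, so output is
byte-identical under a fixed config and earlier clusters are untouched
when clusters are added.

What the generator does **not** emulate: sampling weights (emitted as 1 —
whether the original models were weighted is unstated, so the unweighted
likelihood is the default and a pseudo-likelihood weight option exists),
probability-proportional-to-size selection, stratification by division,
real correlation structure among indicators, or any exposure–mediator
interaction. Passing recovery tests therefore shows the estimator is
correct *under the stated model*, not that the model captures every
feature of real survey data.

## Verification problem sizes

The test suite verifies, among other properties: exhaustive agreement of
the score formula with a weighted-sum oracle on a reduced 6-indicator
schema (all 64 assignments); equivalence of the quadrature fit with
ordinary logistic regression on 2,000 women in 50 clusters generated
without a cluster effect (coefficients within $10^{-3}$); recovery of all
five paths (mean absolute bias < 0.1) and both ICCs (within 0.05) over 50
replicates of 150 clusters × 20 women at the published generating values;
bootstrap SE stability across seeds at $B = 500$ on a 150 × 20 dataset
(sized so each SE's own Monte-Carlo noise is well below the stability
band); and 90–98% empirical
coverage of the 95% BC interval for the indirect effect over 200
replicated no-cluster-effect populations (100 clusters × 15, the
ordinary-logistic path). These sizes are deliberate: large enough for the
asymptotics the checks rely on, small enough to run routinely.

## Known limitations

* Descriptive intervals are plain Wald (with a cluster-bootstrap option),
  and chi-square tests are uncorrected Pearson; design-based
  (Taylor-linearised) variance estimation for the two-stage design is out
  of scope, so descriptive CIs and p-values will differ somewhat from
  fully design-adjusted ones.
* The log-odds product method ignores non-collapsibility (above) and
  assumes no exposure–mediator interaction and a single mediator.
* Whether exactly 0.50 is low or average empowerment, the screening basis
  for covariates, and the reference distribution of the variance LRT are
  all under-determined by the source method; each choice is documented
  above and configurable where it matters.
* With rare outcomes and modest cluster counts, resample refits can
  separate; failure counts are reported rather than hidden, but heavy
  failure rates signal that $B$-resample inference is fragile for that
  data size.
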