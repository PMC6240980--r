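---
title: "Testing emotional mediation of music-to-color associations"
author: "emomediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing emotional mediation of music-to-color associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emomediate)
```

## The scientific question

When people pick colors that "go with" music, two mechanisms could drive
the systematic choices they make. Under a *direct-link* account, perceptual
properties of the sound map straight onto perceptual properties of color
(loud → dark, high-pitched → light). Under *emotional mediation*, music and
colors are linked through shared emotional content: agitated-sounding music
goes with agitated-looking colors. The two accounts make distinct
statistical predictions about what happens to music-perceptual ↔
color-appearance correlations once the emotional associations are
partialled out: mediation predicts they collapse; a direct channel predicts
some survive. This package implements that test chain and a synthetic
study generator with a planted ground truth for both regimes.

## The data model

The study design has five tables:

* color-emotion ratings: 37 colors × 10 bipolar scales × 30 subjects;
* music-emotion ratings: 34 excerpts × the same 10 scales × the same
  subjects;
* music-perceptual ratings: 34 excerpts × 15 features × 15 musicians;
* color-appearance ratings: 37 colors × 4 dimensions × 48 raters;
* a best/worst choice table: per subject and excerpt, the three best- and
  three worst-fitting colors, in choice order, all six distinct.

Bipolar ratings live on a line-mark scale encoded on [−bound, +bound]
(default bound 100), positive pole positive. `RatingsTensor` enforces no
missing cells and the bound; `ChoiceTable` enforces the six-distinct-slots
structure. Long CSV is the interchange format; loading is declaration-
ordered, so file row order never matters.

## MCA scoring

For each (subject, excerpt), the six chosen colors are aggregated over any
per-color attribute table:

$$\mathrm{score}(attr) = \frac{\sum_s w_s \, attr(color_s)}{\sum_s |w_s|},
\qquad w = (+3,+2,+1,-3,-2,-1)$$

over (best1..best3, worst1..worst3). The weights sum to zero, giving
translation invariance (shifting all attribute values changes nothing);
normalizing by $\sum|w|$ keeps scores on the attribute's own scale; and
weight magnitudes decrease in choice order within the best and within the
worst triple, so first choices matter most. Swapping best and worst slots
negates every score, and the across-subject level is the plain mean of
per-subject scores (the two operations commute with the formula above).
The weights are configurable; whether worst choices should instead be
weighted in reverse order is not settled by the design itself, so it is a
config decision, with the symmetric ordering as default.

With the four appearance dimensions as attributes these are perceptual
MCAs (PMCAs); with the ten across-subject color-emotion averages,
emotional MCAs (EMCAs); with latent color factor weights, Parafac-based
EMCAs.

## The joint Parafac model

Emotion ratings of colors and excerpts by the same subjects on the same
scales are stacked along the stimulus mode (colors first) and fitted with
the trilinear CP model

$$z_{ijk} \approx \sum_{r=1}^R a_{ir}\, b_{jr}\, c_{kr},$$

which, unlike a two-mode factor analysis of averages, retains
subject-specific factor saliences $c_{kr}$ and is identified up to factor
order and paired sign flips under mild conditions.

Numerical choices, all exposed as options:

* **Standardization.** Default: each (scale, subject) fiber is centered
  and scaled to SD 1 across stimuli (sample SD), removing per-subject
  response-style offsets and spread differences per scale. Alternatives:
  per-scale global z-scoring, or none. A zero-variance fiber is an error
  naming the scale and subject. Whether to additionally equalize the two
  modality blocks' total variance before joining is an option
  (`equalizeModalityVariance`, default off) — with per-fiber z-scoring the
  blocks are already on comparable scales, their totals differing only by
  their stimulus counts.
* **Fitting.** Multi-start alternating least squares: 10 random starts
  (B, C uniform(−1, 1)), exact per-mode least-squares updates, so SSE is
  non-increasing within a start by construction (the per-iteration trace
  is retained on the model and asserted in tests); convergence when the
  SSE decrease falls below 1e-8 of the total sum of squares, at most 500
  iterations; best-of-starts by SSE; fully seeded and deterministic.
* **Normalization.** B and C columns unit-norm, scale absorbed into A;
  factors ordered by stimulus-weight mass; signs fixed by making the
  largest-magnitude B and C loadings positive. Substantive orientation is
  a separate, fit-preserving step: `alignFactors()` permutes and flips so
  anchor scales (default: *agitated/calm* → factor 1 = arousal,
  *happy/sad* → factor 2 = valence) load positively.
* **Constraints.** None by default. Subject weights typically come out
  positive anyway; a nonnegative-C option (sign-resolved projected
  update) is provided but not default, since imposing it is a modeling
  assertion the data can make on their own.
* **Rank selection.** `screeCp()` tabulates SSE, variance explained and
  CORCONDIA for a factor range. CORCONDIA solves the least-squares Tucker
  core G given the CP factors and reports
  $100\,(1 - \sum(g-t)^2/\sum t^2)$ against the superdiagonal target; 100
  means the CP structure is adequate, collapse (possibly far negative)
  means over-factoring. On exact-rank tensors it is 100 to numerical
  precision; an independent normal-equations oracle (explicit Kronecker
  solve) checks the implementation in the tests. When over-factoring
  makes factor columns nearly collinear the core is ill-identified; the
  implementation raises an error on a singular factor cross-product
  rather than returning noise.

The pipeline always proceeds at R = 2 — interpretable as **arousal** and
**valence**, consistent with the two qualitative clusters of the emotion
scales and with the scree/CORCONDIA behavior on generated data — while
emitting the scree table for inspection.

## Inference machinery

All correlations are Spearman's rho (mid-ranks, Pearson on ranks) with
t-approximation p-values on n−2 df; at the study's n of 34 stimuli the
approximation is standard, and one- or two-tailed versions are explicit
arguments. Partial Spearman correlations rank-transform x, y and every
covariate, residualize the ranked x and y on the ranked covariates by OLS
with intercept, and correlate the residuals (n−q−2 df). Residualization
rather than recursive partial-correlation formulas is used because the
mediation test partials ten EMCAs at once. Exactly collinear covariates
are an error at the primitive level; the pipeline pre-drops covariate
columns whose rank transforms are linearly dependent (near-synonymous
scales do occasionally produce identical rank orderings), which leaves the
projection space — and hence the partial correlations — unchanged.

Family conventions mirror the reported figures: each correlation matrix
(15×4 features, 10×4 emotions, 2×4 factors) is one Holm family, two-tailed;
the ten matched-scale EMCA mediation tests are one-tailed (positive) under
Bonferroni (α = .05/10). Holm and Bonferroni go through `stats::p.adjust`
behind a validated wrapper. Inter-rater agreement per scale is Cronbach's
alpha with sample variances. The MLR comparison enters factor 1 first and
partitions R² by increments; the total is order-invariant, the split is
not, and both facts are asserted in tests.

## The synthetic-data generator

`makeGenerativeTruth()` plants: color and excerpt positions in the
arousal–valence plane, uniform on ±0.6·bound; fixed unit-norm loadings of
the 10 emotion scales at angles mimicking the two qualitative clusters
(an arousal-aligned set including reversed-polarity members near 180°, and
a valence-aligned set); analogous loadings for the 15 music-perceptual
features; strictly positive subject saliences, log-normal with median 1
(sdlog 0.4) and the arousal column scaled ×1.3 to mimic the tendency to
weight arousal more heavily; an affect → appearance map (arousal: more
saturated, darker, redder; valence: lighter, yellower, slightly more
saturated); and affect-independent "unique" components for the feature
and appearance tables (sd 0.15·bound and 0.2·bound) — real feature and
appearance profiles are not pure functions of affect, and without such
components the two regimes would be statistically indistinguishable.

Ratings follow the trilinear model plus i.i.d. Gaussian noise (default
sd 0.15·bound) and are clipped at the bound, mirroring a bounded line-mark
response; clipping rather than resampling keeps the error model simple and
only touches the distribution tails. Choices add Gumbel noise (temperature
10 against utility ranges of order 100, so choices are signal-driven but
not deterministic) to one of two utilities:

* **mediated**: minus the salience-weighted Euclidean distance between the
  excerpt's and the color's affect positions;
* **direct**: the inner product of the color's appearance vector with a
  unit-normalized target obtained by pushing the excerpt's feature vector
  through a perceptual map — affect plays no role. The default map is
  sparse (each feature feeds one appearance dimension, round-robin,
  alternating sign), and four "marker" features — one per appearance
  dimension — carry a larger idiosyncratic sd (0.4·bound vs 0.15·bound).
  The concentration matters for power: a direct channel spread thinly over
  15 features would be undetectable per-feature at 34 excerpts, whereas
  marker features give the regime a realistic, detectable signature.

Everything is a deterministic function of the config and seed; identical
seeds give bit-identical bundles.

### What the generator does and does not emulate

It emulates the latent-factor-plus-noise structure of the rating tasks,
individual salience differences, bounded responses, and the two competing
choice mechanisms. It does not emulate genre-specific semantics, real
colorimetric coordinates, cultural effects, non-Gaussian rating
idiosyncrasies, or subject-level correlations between tasks beyond the
shared saliences. Passing tests on synthetic bundles therefore
demonstrates that the pipeline recovers planted structure and separates
the two regimes under this model — not that real data satisfy the model.

### A structural asymmetry worth knowing

On mediated bundles, partialling the **ten EMCAs** removes every
feature × PMCA correlation essentially always: the EMCAs are themselves
functions of the same choices, so they absorb even the nonlinear part of
the affect-driven variation. Partialling only the **two latent factor
scores** leaves an occasional survivor (a rank-linear adjustment cannot
fully remove a nonlinear function of affect at n = 34). Conversely, on
direct bundles the EMCAs — being choice-derived — soak up part of the
direct channel as well, so the channel's survival is most reliably read
off the latent-factor partialling. The package runs both analyses; the
regime classification in the acceptance checks uses the EMCA partialling
for the mediation side and the factor partialling for the direct side,
which is also how the corresponding reported analyses divide the labor.

## Problem sizes used in the checks

Unit tests run on reduced designs (about 12 colors, 16 excerpts, 6
subjects) where the property under test does not depend on the study's n;
regime discrimination uses the full design over 20 seeds, factor recovery
(Tucker congruence ≥ 0.95 per factor at noise sd ≤ 0.1·bound) over 10
seeds, and the Holm family-wise error check uses 1000 null replicates —
sizes chosen to keep Monte-Carlo error small relative to the asserted
margins.

## Known limitations

* Tensor-level statistics of the real study (e.g. its variance-explained
  figure) depend on subject-level raw data that are not publicly
  deposited; they are covered here by recovery properties on synthetic
  data, not by numeric reproduction.
* CP degeneracy: over-factored fits can produce diverging correlated
  factors; CORCONDIA flags them, but the ALS itself does not regularize.
* The t-approximation for Spearman p-values is mildly liberal at small n;
  an exact permutation option would be a reasonable extension for n ≤ 10.
* The choice model is a single-temperature Gumbel ranking; real choice
  processes may have position effects or lapses the generator does not
  model.
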