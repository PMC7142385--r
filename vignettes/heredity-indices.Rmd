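---
title: "Heredity indices under the polygenic liability-threshold model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heredity indices under the polygenic liability-threshold model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyherit)
```

## The model

`polyherit` works with the simplest additive polygenic model that still
yields Mendelian transmission. Each parent carries two chromosome-level
effect scores, drawn independently from N(μ, σ²) (defaults μ = 100,
σ = 30; every correlation and conditional incidence in the package is
invariant to this affine scale, and the tests check that). An individual's
genetic liability is the sum of the two scores they carry: father A + B,
mother C + D. A child inherits one chromosome from each parent uniformly at
random, so its liability is one of A+C, A+D, B+C, B+D with probability 1/4
each. A second sibling of the pair whose first sibling is A + B likewise
draws one of A+B, A+C, B+D, C+D, sharing 2, 1, 1 or 0 chromosomes with the
first.

Two modelling points deserve emphasis.

**Transmission is a random selection, not an average.** The child's
liability could be written as a "1/4-weighted" combination of the four
gamete sums, which invites a deterministic reading — child =
(A+B+C+D)/2. That reading is wrong for this model: it would make the
parent–child correlation 1/√2 ≈ 0.707, whereas Mendelian segregation (and
the observable parent–offspring resemblance the model is calibrated to)
gives 0.5. Random one-of-four selection delivers exactly
Cov(child, A+B) = σ² over Var = 2σ², i.e. r = 0.5, and simulated cohorts
here reproduce it (e.g. 0.503 at n = 10,000, seed 20200326). The sibling
construction is the same selection; its mixture algebra
(1/4)·2σ² + (1/2)·σ² + (1/4)·0 = σ² again gives marginal correlation 0.5.

**Thresholding is rank-based.** A threshold trait with prevalence
("nature incidence") K marks the top round(n·K) liabilities affected, ties
broken toward the lower index. Observed incidence is therefore exact, the
operation is deterministic, and it commutes with any strictly increasing
transform of liability — which is why phi on the dichotomized pair equals
the Spearman correlation and why no distributional assumption leaks into
the dichotomization step.

## The analytic oracle

The package's expectation module has two routes to every quantity. The
simulation route dichotomizes a simulated cohort. The analytic route uses
the bivariate-normal upper-quadrant probability
P11(K, ρ) = P(X > z, Y > z), z = Φ⁻¹(1 − K), evaluated by adaptive
quadrature of dnorm(x)·Φ((ρx − z)/√(1 − ρ²)) over (z, ∞) with absolute
tolerance below 1e−10 (`stats::integrate`; the boundary cases ρ ∈ {0, 1}
return K² and K in closed form). Anchors with exact values pin the
quadrature: P11(0.5, ρ) = 1/4 + arcsin(ρ)/2π, so P11(0.5, 0.5) = 1/3,
expected phi 1/3 for a parent–child pair and 5/12 for siblings at K = 0.5.

Everything downstream is arithmetic on P11:

* conditional incidences: onset P11/K, no-disease (K − P11)/(1 − K);
* expected correlation Re = (P11 − K²)/(K(1 − K));
* sibling mixture P11 = K/4 + P11(K, 0.5)/2 + K²/4.

The oracle exists because a single simulated table at n = 10,000 carries
visible Monte-Carlo noise, and without an independent referee that noise is
indistinguishable from implementation error. Two consequences in the
published reference table shipped as `re_table_published()` are worth
knowing. First, the parent–child entries at K = 0.01 rest on only ~100
affected relatives, so their sampling SD is ≈ 0.034; the printed onset
value 0.170 sits 1.2 SD above the analytic 0.1294, and the well-known
"17% child risk at 1% prevalence" lookup inherits that noise (the analytic
risk is 12.9%). Second, the sibling table's K = 0.125 row (onset 0.298) is
more than 3 SD below the analytic 0.459 and breaks monotonicity against
the K = 0.0625 row — a flagged outlier; acceptance of the sibling table is
therefore judged against the analytic band, with the published row kept
verbatim for the lookup workflow. For the same reason the published hammer
example divides Ro = 0.293 by the tabulated Re = 0.272 yet reports 1.10;
the division gives 1.077, and the package reports the division (`print`
shows 1.08) while retaining full precision internally.

## The indices

`heredity_index()` is the central estimator. For a continuous trait it
computes the Pearson correlation Ro of relative–proband pairs and returns
HIC = Ro/0.5; for a binary trait it forms the 2×2 status table, computes
phi (identical to Pearson and Spearman on 0/1 indicators — no rank
machinery is needed or used) and returns HIB = Ro/Re(K). Re can come from
three sources, always recorded in the result: `analytic` (default —
noise-free, at the exact K), `simulation` (a seeded cohort), or
`paper_table` (the published table, nearest tabulated prevalence; this is
how a ~15% trait is served by the K = 0.125 row). Indices are kept at full
precision and only rounded to two decimals in printing. Negative Ro is
allowed but warned about, since the model presumes positive familial
resemblance; no confidence intervals are attached because the index is
defined as a point ratio.

### Heritability as a special case

The published model is purely genetic. As a deliberate extension, a
`heritability` parameter h² ∈ (0, 1] adds independent environmental noise
e ~ N(0, 2σ²(1 − h²)/h²) to every individual, so the genetic share of
observed-liability variance is h² and the parent–child correlation
attenuates to h²/2. This makes HIC an estimator of h² under the model —
HIC = 2·(h²/2) = h² — and the package's parameter-recovery tests exploit
exactly that: across h² ∈ {0.2, …, 1.0} at n = 100,000, estimated HIC is
within ±0.03 of h².

## Recurrence risk

`recurrence_risk()` turns a population prevalence and one first-degree
relative's status into the proband's risk: the onset conditional incidence
if the relative is affected, the no-disease one otherwise. The analytic
method is the default; `paper_table` reproduces the printed lookup
workflow (17% / 34% / 0.8% at K = 0.01) exactly as a table read-out. Risks
are deliberately not attenuated by an estimated HIC/HIB: the lookup is
defined under pure polygenic inheritance, and mixing an estimated index
into it would change the quantity's meaning. Parent and sibling risks are
reported separately (the sibling mixture's perfect-sharing component makes
sibling risk the larger one at every K; at K = 0.01 their unaffected-
relative ceilings are 0.88% and 0.69%).

## Synthetic data and what the tests do (and do not) show

The simulator's defaults are the study conditions: n = 10,000 families,
effect scores 100 ± 30, h² = 1. Test cohorts use one fixed seed (20200326)
chosen up front; Monte-Carlo tolerances are 3 delta-method standard errors
(for phi with fixed margins, SE = √(p11(1 − p11)/n)/(K(1 − K)) — at rare
prevalences this is several times larger than 1/√n, which matters when
judging the published K = 0.01 rows). Where a decisive rather than
statistical check is wanted (table regeneration within ±0.03 of printed
values), the suite also runs n = 10⁶ cohorts, which cost well under a
second each; the acceptance script uses n = 400,000 for the K = 0.01
conditional incidences for the same reason.

`fixture_lunula_synthetic()` generates demonstration data shaped like a
fingertip lunula count: simulated liabilities standardized and mapped
monotonically onto integers 0–10 (mean 5, SD 2.2, rounded, clipped). The
mapping preserves ranks, so the parent–child correlation survives up to a
small discretization attenuation (~3% at h² = 1), and the mean child count
rises with the father's count as in the published group-means table. It is
labelled synthetic because the original 370-family raw pairs were never
published — only group means — so the observed lunula correlation 0.549 is
*not* recomputable; the package reproduces only the HIC step
(0.549/0.5 = 1.10). Passing tests on synthetic cohorts validate the
machinery under the model's assumptions; they say nothing about
ascertainment, reporting error, assortative mating, shared environment or
dominance in real family data, all of which the model excludes.

## Known limitations

* Single-generation, two-chromosome genomes: no linkage, recombination,
  dominance, epistasis or multi-relative conditioning.
* Re for binary traits is phi at the trait's own prevalence, not a
  tetrachoric/liability-scale correlation; HIB is therefore
  prevalence-specific by design.
* The indices are descriptive ratios, not unbiased heritability
  estimators; HIC equals h² only under the model's assumptions (random
  mating, no shared environment, normal additive liability).
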