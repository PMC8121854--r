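---
title: "Methods: SC-RRB balance subtyping and replicable connectome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SC-RRB balance subtyping and replicable connectome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrrb)
```

This vignette documents the statistical procedures implemented in `scrrb`,
the modelling assumptions behind them, the design choices that were
genuinely open and how they were fixed, and what the synthetic-data
generators do and do not emulate.

## ADI-R scoring model

The ADI-R yields item-level codes where 0–3 express increasing symptom
severity and 6–9 are dummy codes with no severity meaning. The scoring
chain keeps 0–3 unchanged — in particular a code of 3 is retained rather
than truncated to 2 as the classic diagnostic algorithm would do, because
the 2-vs-3 distinction carries severity information that the downstream
difference score should see. Dummy and missing items are excluded, and
each subscale percentage divides by `3 × n_usable` so subjects with
different numbers of scoreable items (item sets vary with age and
verbal status) are comparable on a 0–1 scale. Domain scores average the
available subscale percentages ("available-mean"); a domain with no
usable item drops the subject, with the reason logged.

Two points are configuration, not code:

* **The item→subscale mapping is data.** The bundled
  `adir_item_mapping.csv` is *schematic* — structurally correct (every
  item in exactly one of A1–A3/B1–B4, realistic item counts) but not the
  instrument's age-dependent item table, which is licensed content. Real
  analyses must supply a mapping configured from the instrument via
  `read_item_mapping()`.
* **`min_items`** (default 1): the minimum usable items for a subscale to
  contribute. The default follows the principle that the denominator
  varies with the number of scoreable items.

Scoring is checked against a brute-force re-computation on 1,000 random
synthetic subjects, and property tests cover monotonicity (raising any
item never lowers the domain score), permutation invariance, and bounds.

## Subtyping model

With domain scores in hand, `d = SC − RRB` is z-normalized,
`z = (d − μ)/σ`, and thresholded at τ: `z > τ` ⇒ SC>RRB, `z < −τ` ⇒
RRB>SC, else SC=RRB. Decisions that the procedure description leaves
open, fixed here:

* **Boundary tie-break**: `|z| = τ` is assigned to SC=RRB. The outer
  labels use strict inequalities ("above the cutoff"), which makes labels
  a deterministic function of `(z, τ)`.
* **SD convention**: sample SD (n−1 denominator). At n ≈ 900 the
  difference from the population SD is negligible, but one convention
  must be fixed for bit-reproducibility.
* **Reference norms**: `ndar_combined_norms()` ships
  μ = 0.01045243, σ = 0.19482749 — the pooled-reference constants used to
  label new cohorts without refitting.
* **Threshold sweep**: τ ∈ {0.5, 0.6, 0.7, 0.8, 0.9, 1.0}. No single τ is
  privileged; downstream connectivity claims are restricted to effects
  present at *every* τ (consensus), which is the package's guard against
  an arbitrary cutoff.
* **Small subtypes**: groups under `min_group` (default 20) are excluded
  from edge models; at realistic prevalence the RRB>SC group is typically
  far too small for group comparisons.

`split_discovery_replication()` halves a cohort within site × sex strata
(singletons assigned by a seeded coin flip, logged) and optionally
age-matches a comparison group by greedy nearest-neighbour matching
without replacement.

## Edge-wise connectivity analysis

Per subject, direct connectivity between K components is the
ridge-regularized partial correlation (netmats convention): standardize
columns, compute covariance C, rescale by `1/sqrt(mean(diag(C)^2))`, add
ρ·I (ρ = 1 by default), invert, and read
`r_ij = −P_ij / sqrt(P_ii P_jj)`. The rescaling step is part of the
published netmats recipe this estimator follows; with standardized
columns it is nearly a no-op but is kept so ρ is on the documented scale.
With ρ = 0 and well-conditioned data the estimator agrees with the
textbook partial correlation from the precision matrix, which is the
oracle test. Edge values are Fisher-z (`atanh`, no small-sample scaling
factor) and the lower triangle is vectorized row-major (i > j), giving
171 edges for K = 19; components are reported 1-based as IC01…IC19.

Each edge is modelled as
`connectivity ~ group + sex + age, random = ~1 | site` (`nlme::lme`,
REML). With fewer than three sites, or if the mixed fit fails, the model
falls back to fixed site dummies, and with one site and no covariates it
reduces exactly to the pooled-variance two-sample t-test (tested).
p-values use the t distribution with `n − rank(X)` residual degrees of
freedom; the procedure source does not state a df method, so the simplest
defensible one is declared. The dimensional variant swaps the group
factor for a continuous predictor (SC, RRB, or the z-difference) and
reports the slope t.

### Replication Bayes factor

Evidence of replication is quantified as
`repBF = ∫ f(t_rep | δ√n_rep, df_rep) π(δ | t_orig) dδ / f(t_rep | 0, df_rep)`,
where f is the noncentral-t density and π is the discovery posterior of
the standardized effect δ under a flat prior. Fixed variants: flat prior,
two-sided likelihoods, with the sign-consistency requirement applied at
the consensus step rather than inside the BF; effective n for a
two-sample contrast is `n₁n₂/(n₁+n₂)` (the standard noncentrality
parameterization), and `n − rank` for continuous predictors. The
integral is evaluated by adaptive quadrature over a window covering both
likelihood bumps (±15 posterior SDs); non-convergence or a non-finite
integrand raises an error rather than returning silently. The quadrature
is validated against a self-normalized importance-sampling Monte-Carlo
oracle to within 2% across a grid of (t_orig, t_rep, n).

An edge *replicates* when Discovery p < 0.05, repBF > 10, and the two
halves agree in sign; a *consensus edge* replicates at every τ in the
sweep (set intersection, tested as such). No additional FDR is applied
across the 171 edges — the discovery-plus-replication rule is the primary
filter; `fdr_bh()` is available for sensitivity analyses.

## Gene-expression decoding

For a network map and a 6-donor atlas tabulated at shared sample
locations, analysis is restricted to cortical samples. Per donor and
gene, expression and map are z-scored across those samples and the slope
of expression on map — equal to the Pearson correlation after
standardization, which makes the regression-direction choice immaterial —
measures spatial similarity. The six slopes feed a one-sample t (df = 5),
BH-FDR across all genes for that map, and retention requires q < 0.05
with t > 0 (consistent *positive* coupling). Genes with slopes estimable
in fewer than two donors are dropped and counted. Decoding is invariant
to affine rescaling of the map or of any gene's expression (tested).

Subtype-specific sets are pure set algebra over retained-gene lists: the
SC>RRB set is genes unique to IC17, the SC=RRB set the union of
IC03/IC07/IC13 minus IC12 and IC17. "Unique to" is ambiguous between
"not in the other implicated networks" and "not in any of the 19"; the
functions take explicit `targets`/`exclude` arguments so either reading
is one call, and the pipeline default excludes the other *implicated*
networks.

## Enrichment

Over-representation of a network set in an annotation list uses the
upper hypergeometric tail `P(X ≥ a)` in a background universe of 20,787
genes (the decoding service's gene count; configurable), with the odds
ratio from the 2×2 table. Zero-cell convention: OR = 0 when the overlap
is empty; Inf when a margin cell is empty with a > 0; an optional
Haldane–Anscombe +0.5 correction behind a flag. Gene symbols are matched
exactly after upper-casing — alias resolution is annotation-version
dependent and out of scope. One BH-FDR family spans the entire
network × annotation grid, and only q < 0.05 cells are flagged.

## Synthetic data: what it emulates, and what it does not

The generators produce inputs with the statistical structure each stage
assumes, each bit-reproducible given a seed, with the planted truth
returned alongside the data. One master seed fans out to per-stage child
seeds (`child_seeds()`, a seeded `sample.int` draw), so any stage can be
regenerated independently.

* **ADI-R cohorts**: latent (SC, RRB) pairs from a bivariate normal
  truncated to the unit square. Marginal SD 0.15 with means near 0.33/0.32
  (plausible for a mixed-severity referral population); the between-domain
  correlation is solved from `var(diff) = 2σ²(1−ρ)` so the difference
  score matches the shipped reference norms, and a few seeded
  moment-matching iterations absorb the small shrinkage that truncation
  causes. Item codes are Binomial(3, severity), making the expected
  subscale percentage equal the latent severity; 5% of entries become
  dummy codes by default.
* **Connectomes**: in edge mode, Fisher-z edge values are Gaussian with
  unit residual SD, group-mean offsets equal to the planted standardized
  differences, and per-(site, edge) intercepts (SD 0.1, three sites).
  Default group sizes are the realistic Discovery 77/50/121 and
  Replication 83/49/122, and the default planted effects are the three
  consensus-edge effect sizes (0.51, −0.36, −0.41). In time-series mode,
  draws come from group-specific precision matrices whose implied partial
  correlations equal the planted values, for round-tripping the ridge
  estimator.
* **Expression atlas**: maps are smooth random fields (low-order Fourier
  basis with random coefficients) over ordered sample locations; coupled
  genes are `β·map + donor intercept + N(0,1)` with β = 1 by default
  (slope signal-to-noise 1), null genes pure noise; 10% of samples are
  flagged non-cortical to exercise the restriction.
* **Annotation lists**: biased-urn sampling without replacement with a
  planted weight multiplier on network-set genes.

What the generators do **not** emulate: real fMRI acquisition (motion,
physiological noise, hemodynamics), spatial autocorrelation between
edges, heavy-tailed or skewed severity distributions, item-level
age-dependence of the ADI-R, donor-specific sample locations in the
atlas, or gene–gene co-expression structure. Passing tests therefore
demonstrate correctness of the estimators and decision rules under their
own assumptions — not robustness of the scientific findings to the many
ways real data violate them.

## Problem sizes and numerical choices

Simulation-based tests run at sizes chosen to keep Monte-Carlo error
well below the tolerances they assert: 1,000 subjects for the scoring
oracle; 100 replicate pairs of n = 890 cohorts for the prediction-
agreement study; 2,000 replicates for effect-size recovery (MC error on
a mean d at n = 83/122 is ≈0.003); 200 replicates for the
replication-evidence study; T = 10⁵ timepoints for the precision-matrix
oracle; 3 × 10⁵ importance-sampling draws per point for the repBF oracle.
Degenerate inputs error loudly by design: constant difference scores
(norms), constant time-series columns, singular covariance at ρ = 0,
rank-deficient designs (naming the aliased columns), empty or oversized
gene lists.

## Known limitations

* The bundled item mapping is schematic; results on real ADI-R data
  depend on supplying the instrument's own item table.
* The mixed-model df convention (`n − rank`) is deliberately simple;
  Satterthwaite-style approximations would change p-values slightly near
  the significance boundary.
* The replication Bayes factor fixes one variant (flat prior, two-sided);
  one-sided or informed-prior variants would change the numeric values,
  which is why threshold behaviour rather than printed BF values is what
  the test suite pins down.
* Consensus edges are defined by intersection across thresholds on the
  same subjects, so per-threshold results are highly dependent; the
  consensus rule guards against threshold choice, not against sampling
  variability, which is the replication rule's job.
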