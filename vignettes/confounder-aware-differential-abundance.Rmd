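---
title: "Confounder-aware differential abundance: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confounder-aware differential abundance: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microconfound)
```

## The problem

A taxon can differ between patients and controls for two very different
reasons: the disease itself, or a lifestyle/diet variable that both shapes
the microbiota and is unbalanced across the study groups. `microconfound`
operationalizes the distinction with two vocabulary items:

* a **confounder** is a variable whose distribution differs across the
  target groups (detected by a Kruskal–Wallis test for numeric variables
  and Fisher's exact test for categorical ones, flagged at p < 0.05);
* a **covariate** is a variable that explains between-sample microbiota
  variation, whether or not it is unbalanced (detected by marginal-effect
  PERMANOVA on β-diversity matrices with per-metric backward elimination,
  retained at p < 0.05 in at least one metric).

Both kinds enter the adjusted ("IBDCC") per-taxon model; the contrast with
the unadjusted ("IBD") model, and the per-variable attribution of taxa
whose significance differs between the two, is the scientific payload.

## Count model and testing

Counts for one taxon are modeled with a log link and an offset
`log(s_j)`, where `s_j` are median-of-ratios size factors. We model raw
counts with offsets rather than dividing counts by `s_j` and rounding:
count likelihoods are defined on integers, and the offset reproduces the
normalization's intent exactly on the mean scale.

Four families are fitted:

* **Poisson** — `V(μ) = μ`;
* **negative binomial** (NB2) — `V(μ) = μ + μ²/θ`;
* **zero-inflated NB** — a structural-zero mass `π` (intercept-only)
  mixed with NB2. Intercept-only inflation is a parsimony choice: with
  cohort-scale `n` per taxon, a covariate-rich zero model is frequently
  inestimable, and the inflation parameter is a nuisance here, not a
  target of inference;
* **hurdle** — a binomial zero/nonzero part sharing the count-part
  design, plus a zero-truncated NB2 count part (offset applied to the
  count part, where sequencing depth acts multiplicatively).

The ZINB and truncated-NB likelihoods are maximized by `nlminb` with
analytic gradients; `θ` and `π` are optimized on log/logit scales with
box constraints at ±8 to keep degenerate fits flagged rather than
divergent. Fits that do not converge are excluded from selection; if no
family converges the taxon is skipped with a recorded reason.

**Family selection.** For each taxon the family is chosen by BIC
(`−2ℓ + k log n`; ties within 1e-9 resolve to the simplest family in the
fixed order Poisson < NB < ZINB < hurdle), and the likelihood-ratio test
of the target then compares full and reduced designs within that single
family. The BIC is evaluated on the *reduced* design — the one that
excludes the tested term. This is a deliberate design choice: selecting
on the full design couples the family choice to the very term being
tested — in null simulations the hurdle family wins the BIC precisely
when the target explains the zero pattern by chance, and the subsequent
LRT then fires almost inevitably — while selection on the reduced design
keeps the choice independent of the target under the null and gives
near-nominal calibration (the calibration suite checks the type-I error
at α = 0.05 against a [0.03, 0.07] band) without measurable loss of
power in the planted-effect scenarios. If the selected family fails to converge on
the full design, the next-best converged family is used and the fallback
recorded.

LRT statistics are clipped at zero with df equal to the parameter-count
difference (for the hurdle family the target sits in both parts, so df
doubles). Benjamini–Hochberg correction is applied across taxa within
each model run separately.

## PERMANOVA and covariate selection

The marginal-effect PERMANOVA Gower-centers `−D²/2` and measures each
term's sum of squares as the drop in explained trace when the term leaves
the full model; the pseudo-F compares it with the full-model residual.
p-values use whole-row-and-column permutations of the distance matrix
under a seeded RNG and the add-one estimator
`(1 + #{F* ≥ F})/(1 + n_perm)`, so they are never exactly zero and have
resolution `1/(n_perm + 1)`. With a single binary term and Euclidean
distances on one-dimensional data the pseudo-F equals the classical
one-way ANOVA F — one of the package's oracle tests.

Backward elimination runs per metric: starting from target + candidates,
the non-target term with the largest marginal p is dropped (ties broken
toward the term later in the candidate order, deterministically) until
all remaining non-target terms fall below α. The target is never
eliminated. The covariate set is the union of survivors across metrics;
the full elimination trace is kept so the automated procedure can be
audited the way a manual one would be. Elimination is per metric rather
than joint because the metrics deliberately weight different features of
the community (presence/absence vs abundance vs lineage depth), and a
variable that shapes any one view of the community is worth adjusting
for.

## Diversity choices

Chao1 is computed on raw integer counts: its singleton/doubleton
frequencies are meaningless after fractional normalization. Shannon and
Simpson are scale-invariant and are computed on normalized proportions.
Both Canberra and generalized UniFrac are available as the "fourth"
metric; the pipeline default follows the Bray–Curtis / Canberra /
unweighted / weighted UniFrac set, configurable. Generalized UniFrac
defaults to α = 0.5, the customary compromise between rare- and
abundant-lineage emphasis; at α = 1 it equals the normalized weighted
form (an analytic identity the tests assert to 1e-10). Unrooted input
trees are midpoint-rooted, since UniFrac needs a root. The α-diversity
group test is Kruskal–Wallis, chosen for consistency with the
non-parametric screening stage.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults are the study
conditions the rest of the package assumes: three groups of 42/52/58
samples (control group first), subgroup splits 27/22/3 and 9/18/28,
ages truncated-normal in [19, 72], 16 binary questionnaire variables with
per-group `P(yes)` (imbalance is planted by making these differ), and
counts drawn as ZINB — with probability `π_t` a structural zero,
otherwise NB with mean
`library_size_j × exp(β0_t + Σ active effects)` and size `θ_t`. Library
sizes are log-normal (sdlog 0.35 by default) and enter as multiplicative
offsets so normalization is non-trivial. Where no study value exists the
defaults are drawn once from realistic ranges: baselines uniform on
`log(2)`–`log(200)` counts, dispersions 0.3–3, zero-inflation 0–0.25. A
hurdle switch replaces the mixture zeros with a hurdle zero mass so the
BIC stage can be exercised against all four families. Every realized
parameter is recorded in a ground-truth ledger used as the oracle by the
validation suite.

What the generator does **not** emulate: compositionality constraints
(taxa are drawn independently given the design), taxon–taxon
correlations, phylogenetic signal in abundances (the tree is random and
independent of the counts), batch effects, and longitudinal structure.
Passing tests therefore demonstrate the statistical machinery under the
model's own assumptions — calibration, planted-effect recovery,
confounder attribution — not robustness to every feature of real 16S
data.

**Scenario used for confounded-taxon validation.** One taxon carries a
log-fold-change of 1.2 on a diet variable whose prevalence is 0.15 in
controls and 0.85 in cases, with NB size 4, 50 samples per group, and no
direct group effect. The effect size matters in both directions: a much
larger one makes within-group counts a bimodal mixture whose inflated
dispersion destroys the power of the *marginal* group test, so the
pattern the scenario exists to exhibit would itself become undetectable;
a much smaller one is invisible to either model. A small power study
across log-fold-changes 1.0–1.5 and imbalances 0.7–0.8 showed the joint
recovery rate stable around 0.9, so the scenario is not knife-edge.

## Numerical and validation details

* Problem sizes in the test suite: the calibration study uses 500 null
  cohorts of 60 samples × 40 taxa; confounded-taxon recovery uses 100
  cohorts of 150 samples × 12 taxa; PERMANOVA oracles use n = 6 with the
  exhaustive 20-relabelling set; parameter recovery uses n = 300.
* Exact-test screen p-values are discrete and conservative, so their
  uniformity check is one-sided (the empirical CDF must not materially
  exceed the uniform's); continuous p-values get a two-sided KS bound.
* `size_factors` uses the arithmetic median of count/geometric-mean
  ratios (the contract definition); this coincides with the
  median-on-the-log-scale variant whenever the number of reference taxa
  is odd.
* Agglomeration groups by the full lineage prefix, so identical family
  names under different higher ranks stay distinct; missing rank values
  collapse into `unclassified-<parent>` bins and per-sample totals are
  conserved exactly.
* Categorical metadata levels keep first-appearance order; the reference
  level of the target is the first level in the file — reproducible
  design matrices without hidden alphabetical reordering.
* All randomized stages derive per-stage child seeds from one global
  seed, so the pipeline is reproducible end to end and stages are
  individually replayable.

## Known limitations

* The hurdle zero part shares the count-part design; separation in small
  or extreme subgroups is flagged, not resolved.
* PERMANOVA permutes rows freely; restricted/Freedman–Lane schemes are
  not implemented.
* Attribution probes variables one at a time; a taxon driven by a
  combination of variables (the pattern the two-direction rule leaves
  unattributed) is reported with its full p-value table but no flag.
* Compositional methods (e.g. ratio-based transforms) are out of scope;
  inference is on expected counts given sequencing depth.
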