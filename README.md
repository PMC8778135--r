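# microconfound

Confounder- and covariate-aware differential abundance analysis of
microbiome feature tables.

Case–control microbiome studies routinely report taxa whose abundance
differs between patients and healthy controls. But lifestyle and diet
shape the gut microbiota too, and when such a variable is also unbalanced
across the study groups (patients eat differently than controls), a taxon
that responds only to the diet variable masquerades as a disease marker.
`microconfound` implements, as a tested and reusable R pipeline, an
analysis strategy that separates these cases for taxa-by-sample count
tables (16S ASV/OTU tables agglomerated to a taxonomic rank):

1. **Preprocessing** — `tax_glom`-style agglomeration to a rank,
   prevalence filtering (keep taxa present in ≥ 10% of samples,
   boundary inclusive), and median-of-ratios size factors
   (`poscounts` variant for sparse tables).
2. **Diversity** — α-diversity (Chao1 `S_obs + F1(F1−1)/(2(F2+1))`,
   Shannon `−Σ p_i log p_i`, Gini–Simpson `1 − Σ p_i²`) with
   Kruskal–Wallis group tests; β-diversity as Bray–Curtis, Canberra, and
   unweighted / weighted-normalized / generalized (exponent α) UniFrac on
   a rooted phylogeny.
3. **Confounder screen** — variables unbalanced across groups
   (Kruskal–Wallis for numeric, Fisher's exact for categorical;
   p < 0.05 flags a potential confounder).
4. **Covariate selection** — marginal-effect PERMANOVA
   (`SS_t = tr(H_full G) − tr(H_−t G)` on the Gower-centered distance
   matrix, whole-row permutations, add-one p estimator) with per-metric
   backward elimination; covariates are the union of terms significant in
   at least one metric.
5. **Differential abundance** — per taxon, a count GLM with log link and
   log-size-factor offset under the best of four families (Poisson,
   negative binomial, zero-inflated NB, hurdle; chosen by BIC), testing
   the disease target by likelihood-ratio test under two competing
   models: `Taxon ~ target` (unadjusted, "IBD") versus
   `Taxon ~ target + covariates + confounders` against its nested
   reduction (adjusted, "IBDCC"); Benjamini–Hochberg correction across
   taxa within each model.
6. **Attribution** — taxa significant under exactly one model are probed
   variable by variable: does adding the single variable to the
   unadjusted model kill the target's significance (approach 1), and does
   removing it from the adjusted model restore it (approach 2)? A
   variable flagged by both directions is the attributed driver.
7. **Subgroup reanalysis** — the same machinery with a multi-level
   clinical subgroup (e.g. disease extent E1–E3 or behaviour B1–B3) as
   the target.

A synthetic-cohort generator with planted ground truth (group effects,
single-variable effects, group-imbalanced variable prevalences,
zero-inflated overdispersed counts, log-normal sequencing depths) makes
every stage testable end to end.

## Worked example

```r
library(microconfound)

# a cohort in which taxon fam001 responds only to the diet variable
# "cereals", whose prevalence is unbalanced across groups
vars <- default_variables(c("HC", "CD", "UC"))[c("cereals", "bread")]
vars$cereals <- c(HC = 0.15, CD = 0.85, UC = 0.85)
cfg <- synthetic_config(
  groups = c(HC = 50, CD = 50, UC = 50), n_taxa = 12,
  dispersion = 4, zero_inflation = 0.05, variables = vars,
  effects = data.frame(taxon = "fam001", variable = "cereals",
                       level = NA, lfc = 1.2),
  seed = 500042)
co  <- generate_cohort(cfg)
tab <- prevalence_filter(co$counts, 0.10)
s   <- size_factors(tab)

ibd   <- run_model_suite(tab, co$metadata, s = s, mode = "IBD")
ibdcc <- run_model_suite(tab, co$metadata, s = s, mode = "IBDCC",
                         covariates = c("age", "gender", "cereals", "bread"))
identify_nofs(ibd, ibdcc)$ibd_only
#> [1] "fam001"

att <- attribute_nof("fam001", tab, co$metadata,
                     variables = c("age", "gender", "cereals", "bread"),
                     s = s)
att[, c("variable", "p_approach1", "p_approach2", "attributed")]
#>   variable  p_approach1  p_approach2 attributed
#> 1      age 2.076312e-11 5.050531e-02      FALSE
#> 2   gender 4.043983e-11 6.613906e-02      FALSE
#> 3  cereals 5.779765e-02 3.652664e-11       TRUE
#> 4    bread 8.194543e-12 6.733479e-02      FALSE
```

Read: `fam001` looks strongly disease-associated in the unadjusted model
(adding `age`, `gender` or `bread` alone leaves approach-1 p below
1e-10), but adding `cereals` alone removes the signal (approach-1
p = 0.058 ≥ 0.05), while removing `cereals` from the otherwise fully
adjusted model restores it (approach-2 p < 1e-10) — the abundance shift
is attributable to the diet variable, exactly as planted.

The full workflow (diversity, screening, PERMANOVA selection, both model
suites, attribution, subgroup runs) is orchestrated by
`run_pipeline(run_config(...))`, configurable from YAML; a thin CLI lives
at `inst/cli/microconfound.R`.

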