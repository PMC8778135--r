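Package: microconfound
Title: Confounder- and Covariate-Aware Differential Abundance Analysis of
    Microbiome Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for confounder- and covariate-aware
    analysis of taxa-by-sample count tables: taxonomic agglomeration,
    prevalence filtering and median-of-ratios normalization; alpha diversity
    (Chao1, Shannon, Simpson) with non-parametric group testing; beta
    diversity (Bray-Curtis, Canberra, unweighted, weighted and generalized
    UniFrac); screening of group-unbalanced variables (Kruskal-Wallis and
    Fisher's exact tests); marginal-effect PERMANOVA with backward
    elimination to select microbiota-shaping covariates; per-taxon count GLM
    differential abundance under competing models with and without
    covariates and confounders (Poisson, negative binomial, zero-inflated
    negative binomial and hurdle families selected by BIC, nested
    likelihood-ratio tests, Benjamini-Hochberg correction); identification
    of taxa whose significance depends on the model and attribution of such
    taxa to single lifestyle or diet variables. Includes a synthetic cohort
    generator with planted ground truth for validation and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    ape,
    phangorn,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phyloseq,
    DESeq2,
    glmmTMB,
    optparse
Config/testthat/edition: 3
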