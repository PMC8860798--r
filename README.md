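# twinmed

Multilevel twin variance-components mediation modeling: do traumatic
events (TEs) in childhood relate to post-traumatic stress symptoms
(PTSDsx) directly, or indirectly through brain region-of-interest (ROI)
volumes — and how much of each phenotype's variance is genetic,
family-environmental, person-specific, or attributable to the data
collection site?

The package is aimed at behavior-genetics and developmental-neuroimaging
analysts working with family-and-site clustered cohorts (monozygotic and
dizygotic twin pairs, siblings and singletons nested in study sites). Its
core is a trivariate mediation structural equation model with A/C/E/S
variance components,

    M_j = a_j X + u_Mj        (exposure -> mediator)
    Y   = c X + sum_j b_j M_j + u_Y     (direct + mediated outcome)

where each residual u splits into additive-genetic (A, correlated 1.0 in
MZ and 0.5 in DZ/sibling pairs), shared-environmental (C, per family),
unique-environmental (E, per person) and site (S, per site) components.
The model is estimated by full-information maximum likelihood over site
blocks (missing cells are marginalized, the shared site term is handled
exactly by a low-rank Woodbury update), mediators are pre-selected from
hundreds of ROI columns by an elastic net (coordinate descent,
family-stratified 10-fold cross-validation, the 1-SE rule), binary
symptom items are measured with a 2PL item factor model, and competing
causal directions are compared with likelihood-ratio tests and
`AIC = -2lnL - 2 df`. A seeded synthetic-cohort generator with known
ground truth makes every stage testable end to end.

## Worked example

```r
library(twinmed)

tr  <- truth_record(mediators = "roi_1", a = 0.2, b = 0.25, c = 0.5,
                    te_mix = c(0.3, 0.3, 0.38, 0.02),
                    mediator_mix = c(0.5, 0.25, 0.23, 0.02),
                    ptsdsx_mix = c(0.3, 0.2, 0.48, 0.02))
sp  <- cohort_spec(n_mz_pairs = 400, n_dz_pairs = 400, n_singletons = 800,
                   n_sites = 6, seed = 605)
cfg <- run_config(spec = sp, truth = tr, seed = 2001, max_mediators = 1,
                  en = en_config(alpha_grid = c(0.5, 1), k_folds = 4,
                                 nlambda = 25), n_starts = 1)
res <- run_pipeline(cfg)

res$chosen
#> [1] "uniDir"
res$comparison[, c("diff_ll", "diff_df", "p")]
#>     diff_ll diff_df         p
#> 1 0.9182835       1 0.3379261
round(subset(res$variance_proportions, phenotype == "roi_1")[, -1], 3)
#>      VA  VC    VE    VS
#> 2 0.454 0.3 0.221 0.025
res$indirect
#>   mediator    estimate        lower       upper
#> 1    roi_1 0.004062917 0.0004750929 0.007650741
```

Reading: the bidirectional model (adding a reverse PTSDsx-to-TEs path)
does not fit significantly better than the unidirectional one
(Δχ²(1) = 0.92, p = 0.34), so the more parsimonious `uniDir` variant is
selected — matching the generating structure, which had no reverse path.
The ROI's variance decomposition recovers the generating mix (0.5 A /
0.25 C / 0.23 E / 0.02 S) within sampling error, and the mediator's
indirect effect `a*b` is positive with an interval excluding zero
(attenuated relative to the generating 0.05 because the analysis scores
are coarse ordinal levels of rare binary items, not the latent
liabilities). The written report bundle contains the comparison,
indirect-effect, twin-correlation and variance-proportion tables as TSV
plus a JSON run log.

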