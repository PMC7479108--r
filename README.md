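# exprevo

Gene expression does not evolve freely: when a gene's organ of primary
expression shifts, where it lands depends strongly on where it was.
`exprevo` is an R package for studying that question on vertebrate-scale
data. It amalgamates heterogeneous bulk RNA-seq samples into per-species
organ expression profiles, dates gene family trees against a known species
tree, detects shifts of optimal expression under multi-optima
Ornstein–Uhlenbeck (OU) models, classifies each shift by the branching
event that preceded it — speciation (S), DNA-based duplication (D), or
retrotransposition (R) — and quantifies the resulting organ-to-organ flow
of expressed genes. A synthetic-data module generates truth-known inputs
with the same statistical structure, so the entire pipeline is testable
without any downloads.

## The model in brief

Each organ's log2 expression evolves along the gene tree as an OU process
with organ-specific selection strength α (1/MY) and diffusion σ² (the
stationary variance is γ = σ²/2α). Regime shifts move the optima of all
six organs (brain, heart, kidney, liver, ovary, testis) jointly at branch
starts. Shifts are found by a group-Lasso over candidate branches on
whitened data followed by unpenalized refits scored with a
multiplicity-adjusted AICc, and only shifts detected with both expression
metrics (TPM and TMM-FPKM) are kept. Per shift, the package reports organ
specificity τ = Σ(1 − x_i/max)/5 (0 uniform … 1 single-organ), expression
complementarity TEC = 1 − Σ min(p_i, q_i) against the sister branch
(0 identical … 1 mutually exclusive), the change in maximum expression
Δμ_max, and the ancestral/derived primary-expressed organ (PEO).
PEO-transition matrices are tested against margin-preserving permutation
nulls; the global polarity Σ|N_ij − N_ji|/ΣN_ij is bootstrapped; ω (dN/dS)
on shift branches is compared with unshifted sisters.

## A worked example

```r
library(exprevo)

cfg <- pipeline_config(
  n_species = 12, root_age = 400, n_families = 8,
  family_params = family_sim_params(dup_rate = 2e-3, loss_rate = 5e-4,
                                    retro_rate = 3e-4),
  expr_params = expr_sim_params(alpha = 0.05, sigma2 = 0.2, theta0 = 6,
                                shift_prob = c(S = 0.02, D = 0.15,
                                               R = 0.3),
                                shift_size_sd = 6),
  sample_params = sample_sim_params(projects_per_organ = 3,
                                    samples_per_project = 2,
                                    project_effect_sd = 0.3,
                                    noise_sd = 0.3),
  stats = stats_config(n_perm = 1000, n_boot = 200, seed = 7),
  n_scaling_genes = 200, min_tips = 6, seed = 7)
out <- run_pipeline(cfg)

out$stats$rates$table
#>   category branches shifts  frequency  rate_per_my
#> S        S      246      0 0.00000000 0.0000000000
#> D        D      102      4 0.03921569 0.0005705745
#> R        R        8      1 0.12500000 0.0012226004

out$records[, c("family_id", "branch", "category", "peo_anc", "peo_der",
                "d_tau", "tec")]
#>   family_id  branch category peo_anc peo_der      d_tau       tec
#> 1    fam001      N9        D  testis   heart 0.07685059 0.9269230
#> 2    fam001 sp05_g2        D  testis  kidney 0.04642178 0.8479373
#> 3    fam002     N23        D   brain   liver 0.19160327 0.9020648
#> 4    fam002     N47        D   brain  testis 0.19083126 0.7062367
#> 5    fam006 sp11_g4        R  testis   brain 0.78540224 0.8055474
```

Eight simulated gene families pass through sample simulation, TMM scaling,
curation, SVA correction, per-metric shift detection, cross-metric
consensus, and branch annotation. The rates table counts consensus shifts
per branch category: none of 246 speciation branches shifted, against
3.9% of duplication branches (5.7 × 10⁻⁴ shifts/MY) and 12.5% of
retrotransposition branches — the duplication-biased pattern the method is
designed to resolve (in this run every consensus shift is also a true
planted shift). Each record carries the shift's ancestral and derived
primary organ, the change in organ specificity (`d_tau`), and the
expression complementarity against its sister branch (`tec`); `out$stats`
adds the transition matrices, permutation enrichments, polarity, and ω
comparisons.

Individual stages are plain functions: `tmm_factors()`,
`iterative_removal()`, `sva_correct()`, `root_tree()`, `date_tree()`,
`skim_tree()`, `detect_shifts()`, `consensus_shifts()`,
`ancestral_binary()`, `classify_branches()`, `tau()`, `tec()`,
`transition_matrix()`, `permutation_enrichment()`, `polarity()`,
`omega_analysis()`. The methods vignette
(`vignettes/expression-evolution.Rmd`) documents the models, defaults,
and validation-study conditions.

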