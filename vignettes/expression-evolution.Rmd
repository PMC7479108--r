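---
title: "Detecting organ-level expression regime shifts on gene family trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting organ-level expression regime shifts on gene family trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

exprevo studies how organ-wise gene expression evolves along gene family
trees that include speciations, DNA-based duplications, and
retrotranspositions. This vignette is the package's account of the models
and procedures it implements, the choices behind their defaults, and what
the synthetic-data experiments do and do not establish.

```{r setup}
library(exprevo)
```

## The model

Each gene family is a rooted, dated, binary tree whose tips are genes in
extant species. Every tip carries a 6-vector of log~2~ expression levels in
brain, heart, kidney, liver, ovary, and testis. Expression in each organ
evolves as an Ornstein–Uhlenbeck (OU) process: a diffusion with variance
rate $\sigma^2$ pulled toward an optimum $\theta$ with strength $\alpha$
(both per MY). The stationary variance $\gamma = \sigma^2/(2\alpha)$
summarizes the long-run spread; the phylogenetic half-life is
$\ln 2/\alpha$. $\alpha$ and $\sigma^2$ are organ-specific but constant
across the tree; what changes along the tree is the optimum. A *regime
shift* moves the optima of all six organs jointly at the start of a branch,
so a shift is attributed to the branching event that precedes the branch:
speciation (S), DNA-based duplication (D), or retrotransposition (R; a
duplication whose new copy lost all introns).

Under a fixed root (the root value tied to the ancestral optimum), tip $i$
has expectation
$\theta_0 + \sum_b \delta_b\,[b \prec i]\,(1 - e^{-\alpha (T - t_b)})$,
where $b \prec i$ means branch $b$ is ancestral to tip $i$, $t_b$ is the
age of the branch start, and $T$ the tree depth; the covariance is
$V_{ij} = \tfrac{\sigma^2}{2\alpha} e^{-\alpha d_{ij}}
(1 - e^{-2\alpha t_{ij}})$ with $d_{ij}$ the patristic distance and
$t_{ij}$ the root-to-MRCA time. `ou_design()` builds both; as
$\alpha \to 0$, $V_{ij} \to \sigma^2 t_{ij}$, the Brownian limit. A
`root_mode = "stationary"` variant drops the $(1 - e^{-2\alpha t_{ij}})$
factor; the fixed-root form is the default because it is the form whose
Brownian limit and design interpretation are exact.

## Shift detection

`detect_shifts()` proceeds in stages:

1. **Skimming.** Clades whose tips have pairwise Pearson correlation of
   the 6-organ vectors above 0.99 are collapsed to a single tip carrying
   the clade's Brownian-motion phylogenetic mean (`skim_tree()`). This
   keeps large families tractable and removes exactly the clades within
   which no shift is resolvable.
2. **Null fit.** Per organ, $(\alpha, \sigma^2, \theta_0)$ are estimated
   by profiled maximum likelihood: $\alpha$ on a 32-point log grid
   spanning half-lives from 0.1% to 1000% of tree depth, refined by golden
   search; $\theta_0$ and $\sigma^2$ by closed-form GLS.
3. **Group-Lasso screening.** Each organ's data and candidate branch
   columns are whitened by the Cholesky inverse of its covariance and
   scaled by its $\sigma$; the per-organ intercept is projected out. The
   six organ coefficients of one branch form a group, so shifts are
   selected jointly across organs. A 50-value geometric penalty path (down
   to $10^{-3}\lambda_{max}$) is solved by block coordinate descent
   (compiled); distinct supports along the path become candidates, capped
   at $\max[\min(N/2, 100), \sqrt{N}]$ shifts (floored; `max_shifts()`),
   with a per-family override for exceptionally large trees.
4. **Refits and selection.** Every candidate support is refitted without
   penalty (per-organ GLS with $\alpha$ re-optimized by warm-started
   golden search) and scored. The default score is AICc over the $6N$
   trait observations with 3 parameters per organ plus 6 per shift,
   **plus a multiplicity adjustment**: each shift must additionally beat
   $\chi^2_6$'s family-wise $5\%$ critical value of a best-of-$p$ search,
   $q_{\chi^2_6}(1 - 0.05/p)$, where $p$ is the number of candidate
   branches. The adjustment is essential: the plain per-shift AICc cost
   (~12) lies below the expected maximum spurious likelihood gain over
   $\approx 2N$ branches (~22 at $N = 64$), so unadjusted AICc accepts
   several false shifts per tree. The adjusted rule holds the per-tree
   false-shift probability near 5% at any tree size; plain AICc remains
   available (`shift_search_config(criterion = "aicc")`).
5. **Backward pass.** The best few candidate supports are pruned to their
   score fixpoints (dropping any shift whose removal improves the score;
   supports larger than 12 are first trimmed to their 12 largest-effect
   groups), and the overall best model wins. Ties break toward fewer
   shifts, then lexicographic branch IDs.

Because a shift on one child of the root is indistinguishable from a shift
on the other child combined with a change of intercept, root-child shifts
are reported as whichever parameterization the search selects; studies
that plant shifts avoid root children for this reason.

Two expression metrics (TPM- and TMM-FPKM-derived organ means) are modeled
independently; `consensus_shifts()` keeps the intersection of the two shift
sets, which is the shift set used downstream.

## Amalgamation

Heterogeneous per-sample tables become per-species organ means in four
steps. `tmm_factors()` computes trimmed-mean-of-M-values scaling factors
across samples from single-copy orthologs (reference column by the
75th-percentile rule, 30% M-trim, 5% A-trim, precision weights — the
method's canonical defaults), normalized to geometric mean 1; because the
amalgamated FPKM columns are compared directly rather than via library
sizes, the factors absorb depth as well as composition.
`log_transform()` applies $\log_2(x + 1)$. `iterative_removal()` assumes
any sample correlates best with its own organ's mean computed from other
projects; per iteration it removes the project with the most violating
samples (ties by violating fraction, then project ID) until no violations
remain, skipping species with fewer than two projects. Ties in correlation
count as violations (the conservative reading). `sva_correct()` estimates
surrogate variables as the leading principal directions of the residuals
of the organ-mean model; the number of directions is chosen by
Buja–Eyuboglu permutation parallel analysis (20 row permutations,
$(b+1)/(B+1)$ p-values forced monotone, $\alpha = 0.05$) and their
contribution is removed with the organ design protected
(`limma::removeBatchEffect`). The permutation selection is implemented in
the package because the widely used implementation fixes the level at 0.1
with uncorrected p-values, which mislabels pure noise as a surrogate
variable in roughly a quarter of null datasets — incompatible with a
calibrated pipeline. `organ_means()` finishes with arithmetic means on the
log scale, flagging organs that lost all samples.

## Dating gene trees

Gene trees arrive with substitution-scale branch lengths.
`classify_species_overlap()` labels a node a duplication when its child
subtrees share a species — note this is deliberately *not* the
LCA-mapping rule: species overlap implies an LCA-mapping duplication, but
the converse fails for discordant topologies. `root_tree()` scores every
branch as a rooting candidate by its duplication–loss reconciliation cost
(duplication score 1.5, loss score 1.0) and also computes the midpoint and
minimal-ancestor-deviation (MAD) candidates; the final root is the MAD
branch if it is DL-minimal, else the midpoint branch if it is, else the
DL-minimal branch topologically nearest the MAD branch.

`build_constraints()` pins speciation nodes to their species-tree ages and
bounds duplication nodes below by the oldest nearest-descendant speciation
and above by the nearest-ancestral speciation (1105 MY — the
animal–fungus split — when none exists). `date_tree()` minimizes the
weighted lack-of-clock objective
$\sum_b (\ell_b - r\, t_b)^2 / \max(\ell_b, 10^{-6})$ over free node ages
and the rate(s) by coordinate descent (each free age is a clamped
quadratic minimum), starting both from a clock-anchored initialization
(rate estimated at the fixed nodes, ages from substitution depths) and
from interval midpoints, keeping the better optimum. More than one rate
category groups branches by fitted rate with shrinkage toward the global
rate; the default single category is a strict clock, appropriate for the
Gaussian surrogate when alignment lengths are unavailable. Infeasible
bounds are widened stepwise by 10% of the species-tree root age (up to 5
steps) and then dropped, with every step logged.

## Branch annotation

Intron counts are collapsed to binary states. Marginal ancestral
posteriors are computed exactly by inside–outside pruning under fixed
asymmetric rates (loss $10^{-3}$, gain $10^{-4}$ per gene per MY; the
transitions are rare on vertebrate timescales, so the rates act as weak
priors rather than estimated quantities), with a stationary root prior.
Chromosome states (autosome/X/Y) use a symmetric $10^{-3}$ rate with
missing data marginalized. A duplication-descended branch is relabeled R
when the maximum-a-posteriori intron state switches from containing to
intronless across it with both endpoint posteriors above 0.5; the sister
(original copy) stays D. Translocation is flagged when the MAP chromosome
differs across a branch.

## Downstream statistics

For every consensus shift, `build_shift_records()` takes the ancestral
regime from the parent branch and the derived regime from the shift
branch, unlogs the optima ($2^x - 1$, clamped at 0) for $\tau$
($\sum_i(1 - x_i/\max)/5$), TEC ($1 - \sum_i \min(p_i, q_i)$ on
sum-normalized vectors, against the sister branch), and the
primary-expressed organ (PEO; ties excluded and counted), while
$\Delta\mu_{max}$ stays on the log scale. `shift_rates()` reports
per-category frequencies and per-MY rates with a $\chi^2$ test.
`transition_matrix()` counts PEO switches; `permutation_enrichment()`
shuffles derived against ancestral labels (both margins preserved;
identity pairings excluded to mirror the structural zero diagonal) and
reports two-sided $(b+1)/(n+1)$ p-values, 10,000 permutations by default.
`polarity()` is $\sum_{i<j}|N_{ij} - N_{ji}| / \sum_{i \ne j} N_{ij}$ with
a 1000-resample bootstrap over records and Kolmogorov–Smirnov comparisons
between categories. `brunner_munzel()` implements the rank-based
Brunner–Munzel test (used for stationary-variance and $\omega$
comparisons). `omega_analysis()` compares $\omega$ on shift branches
against unshifted sisters (pairs with shifted sisters are excluded — no
clean baseline), classifies pairs as higher/undifferentiated/lower with a
±5% band on the raw ratio, and regresses $\log_2(\omega_+/\omega_-)$ on
$\Delta\tau$, $\Delta\mu_{max}$ (split by sign) and TEC with two-sided
t-tests on slopes.

## The synthetic-data module

The generator supplies truth-known inputs with the statistical structure
the analysis assumes:

* **Gene families** (`simulate_gene_family()`): a branch-wise Gillespie
  process along a dated species tree with per-lineage duplication, loss
  and retrotransposition rates; retrotransposition is a duplication whose
  new copy loses all introns and relocates chromosome. Defaults
  (5×10⁻⁴, 5×10⁻⁴, 5×10⁻⁵ events/gene/MY) give vertebrate-scale families
  a handful of duplications over ~400 MY; the absolute rates are chosen
  for test power, as empirical per-gene rates are not established.
* **Expression** (`simulate_ou_expression()`): exact OU transitions per
  branch; shifts planted at branch starts with category-specific
  probabilities defaulting to the per-branch frequencies measured on real
  vertebrate data (S 2.2%, D 9.0%, R 37.3%); the shift's target organ is
  drawn from a propensity row indexed by the current PEO and is boosted
  above the previous maximum, so the derived PEO is the target.
  Defaults: $\alpha = 0.02$/MY (half-life ≈ 35 MY), $\sigma^2 = 0.5$,
  $\theta_0 = 4$ (log~2~), shift scale 2 log~2~ units.
* **Samples** (`simulate_samples()`): organ truth means plus a rank-one
  project batch effect (gene loadings × project scores), i.i.d. noise, a
  lognormal library factor on the FPKM variant, and organ-deranged labels
  in planted anomalous projects.
* **ω** (`simulate_omega()`): lognormal around category medians with a
  multiplier on shift branches.

What the generator does *not* emulate: read-level sampling noise,
transcript-length and mappability biases, incomplete lineage sorting and
gene-tree estimation error, correlated evolution between organs, and
branch-wise $\alpha$/$\sigma^2$ variation. Passing tests therefore
establish internal correctness and calibration of the pipeline under its
own model class, not robustness to every artifact of real RNA-seq
compendia.

## Study sizes and conditions used by the test suite

The validation studies (also run by the test suite) use these sizes,
chosen to give stable pass/fail decisions on a single CPU:

* Detection calibration and power: 200 no-shift and 200 single-shift
  64-tip coalescent trees (root age 300 MY), OU defaults above. The
  planted shift moves every organ's optimum by 4 stationary SDs with
  random signs and sits on a long branch (at least the median internal
  length) deep enough that the tips have had ≥ 2 phylogenetic half-lives
  to express the new regime, and not on a root child (see above). The two
  metrics are two observations of the same realization with independent
  N(0, 0.2) organ-mean noise, the scale implied by the sample generator's
  defaults after averaging. A family "detects" a shift when it is in the
  cross-metric consensus. A shift planted closer to the present than one
  half-life is unrecoverable in principle — its regime is not yet
  expressed in any tip — which is why the power study conditions on
  expressed shifts.
* Parameter recovery: 100 replicates at 128 tips, $\alpha = 0.05$,
  $\sigma^2 = 1$.
* Dating: 15 clock-like simulated families on an 8-species, 400-MY tree.
* S/D/R recovery: 40 families with retrotransposition at 8×10⁻⁴/gene/MY,
  branches shorter than 5 MY excluded from the tally.
* Curation: 100 replicates with one organ-deranged project among five.
* Statistics calibration: 500 symmetric-null transition matrices of 120
  switches, 199 permutations each.
* Propensity recovery: 50 runs of ≥ 300 switching shifts from generator
  truth under a propensity matrix with three 3-fold-enriched cells
  (brain→testis, testis→ovary, kidney→liver), 2000 permutations.

## Numerical choices and degenerate inputs

Zero-variance trait vectors correlate 1 when equal within $10^{-12}$ and 0
otherwise (skimming); constant traits yield a zero-shift model with
$\sigma^2$ floored at $10^{-12}$ and a boundary flag. Zero branch
durations get $10^{-9}$ MY in character models. Rank-deficient whitened
designs are resolved by pivoted least squares with aliased coefficients
set to 0. Permutation and bootstrap p-values use the $(b+1)/(n+1)$
estimator. All generators and analyses derive their RNG streams
deterministically from user seeds, so every output is bit-reproducible.

## A worked end-to-end example

```{r, eval = FALSE}
cfg <- pipeline_config(
  n_species = 12, root_age = 400, n_families = 8,
  family_params = family_sim_params(dup_rate = 2e-3, loss_rate = 5e-4,
                                    retro_rate = 3e-4),
  expr_params = expr_sim_params(alpha = 0.05, sigma2 = 0.2, theta0 = 6,
                                shift_prob = c(S = 0.02, D = 0.15,
                                               R = 0.3),
                                shift_size_sd = 6),
  stats = stats_config(n_perm = 1000, n_boot = 200),
  n_scaling_genes = 200, min_tips = 6, seed = 7)
out <- run_pipeline(cfg)
out$manifest
out$stats$rates$table
```

The demonstration parameters use more conserved expression dynamics
(stationary SD ~1.4 log~2~ units) than the generator's defaults, so that
6-log~2~-unit shifts are both biologically plausible and resolvable on
families of 10-50 genes; the TPM variant is sensitive to genes whose
simulated expression dwarfs the synthetic transcriptome mass, which the
200 highly expressed single-copy scaling genes prevent.

## Known limitations

Shift placement is resolved only to the branch (not within-branch
position); root-child shifts are inherently ambiguous; $\omega$ values are
consumed, never estimated; the dating objective is a Gaussian surrogate
for a penalized likelihood, adequate for constraint-respecting point
estimates but not for credible intervals; and the consensus rule trades
recall for precision exactly as intended — shifts detected under only one
normalization are discarded.
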