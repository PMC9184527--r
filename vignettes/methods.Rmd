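---
title: "Dissecting long-term genetic gain in maize era panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting long-term genetic gain in maize era panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Commercial maize breeding has raised grain yield for decades by selecting,
directly or genomically, on yield itself. An *era panel* — a set of
successful hybrids released over a long period, here emulating 60 hybrids
released 1950–2015 — lets one ask three linked questions:

1. **How fast was the gain, and was it environment-dependent?** The genetic
   gain is the slope of a trait (yield, grain number) on year of release,
   and its interaction with environmental scenario measures whether old and
   new hybrids rank differently in favourable vs stressed fields.
2. **Through which traits did the gain flow?** Phenology (vegetative phase
   duration), reproductive development (silk number) and plant architecture
   (the vertical position of leaf area, `rh_PAD`, which controls how much
   light reaches the ear layer) are candidate mediators between year of
   release and grain number.
3. **Which genomic regions did selection move?** Loci whose allele
   frequencies trend with year of release — beyond the drift expected from
   the panel's population structure — are *regions under selection* (RUS),
   and their colocalization with published QTL intervals tells which trait
   classes breeding actually exploited.

`gainscan` implements this whole chain as testable, reusable components,
exercised end-to-end on synthetic panels whose ground truth (trending loci,
true trait DAG, true scenario labels, true QTL effects) is known. Every
statistical claim made below is checked by the test suite or recomputed by
`scripts/acceptance.R`; nothing is asserted from the literature alone.

# The synthetic era panel

`sim_config()` fixes the study conditions; `simulate_panel()`,
`simulate_environments()` and `simulate_trial()` generate the data.

**Genotypes.** Hybrids are modelled directly as additive allele-count
vectors (0/1/2), because every downstream method consumes counts only.
Neutral allele frequencies follow a two-ancestry Balding–Nichols model
(differentiation `ancestry_fst = 0.15`) whose mixture weight is a logistic
function of year of release (`structure_mix`: logit slope 0.06/yr, hybrid
noise SD 0.8). This one mechanism reproduces the two structural phenomena
an era panel shows: a leading genotype-PCA axis correlated with year
(R² ≈ 0.7 at the defaults) and era-dependent frequency drift at *every*
differentiated locus — the confound the kinship-controlled scan must
overcome. Selected loci (default 50 of 10,000) instead follow a
logit-linear frequency trend of `trend_slope = 0.05` per year. Missingness
is missing-completely-at-random (2%), adequate because QC is its only
consumer. Positions are uniform on ten chromosomes with maize-like lengths;
no linkage disequilibrium between loci is simulated, so "regions" in the
synthetic genome are single markers and merge windows are exercised with
planted coordinates.

**Environments.** Each of the six scenarios (cool/warm/hot × WW/WD)
contributes `n_experiments_per_scenario = 4` experiments, i.e. 24 fields.
Flowering-phase temperatures centre on Tmin 15/17/18 °C and Tmax
25/28/30 °C for cool/warm/hot; soil water potential centres at −0.05 MPa
(WW) or −0.4 MPa (WD), never crossing the −0.1 MPa class boundary.
Within-scenario dispersions are not reported for the real experiments and
are free parameters here; the defaults (0.35–0.6 °C for temperatures,
about 3% for phase light sums, hotter scenarios receiving more cumulated
light) place scenario classes 3–5 SD apart, matching the premise that the
scenarios are *consistent*, i.e. recoverable by clustering. `env_dispersion`
scales all of them at once.

**Trial.** Yield per (hybrid × experiment) is built as
intercept (9 t/ha) + genotypic effect + environment effect + QTL term +
year×scenario heterogeneity + G×E noise + residual, with grain number =
yield / 0.30 g. The genotypic year trend (`gain_per_year = 101` kg/ha/yr)
flows through the mediating traits along the known DAG
year → {veg, silk, rh_pad}, rh_pad → ear_light, {veg, silk, ear_light} → gn,
with slope shares 20% (veg), 20% (silk), 48% (ear light) and a 12% direct
residual year effect. Because the QTLs themselves sit on loci whose
frequencies drift with era, they carry part of the year trend; the direct
term is reduced by the realised QTL-borne slope so that `gain_per_year` is
the *total* expected trend — this is what makes the slope-recovery check
sharp. Variance components default to genetic 5, environment 2.25 (76% of
it between scenarios), G×E 0.25 and residual 0.25 (t/ha)²; the genetic
total of 5 makes the year covariate carry ≈74% of the genetic sum of
squares at the default gain. The year×scenario slope heterogeneity (SD
0.2 × gain across scenarios) is carved out of the G×E budget and amounts
to ≈1% of total variance. With one record per hybrid × experiment the G×E
and residual variances are confounded in a two-way ANOVA, so the
variance-recovery test checks genetic and environment individually and
G×E + residual as a sum.

# Scenario typing

`cluster_temperature()` standardises the nine phase-wise covariates
(cumulated intercepted light, mean daily Tmin and Tmax for the vegetative,
flowering and grain-filling phases), projects them on principal components
retaining ≥90% of variance, and runs PAM (k-medoids, BUILD + SWAP,
Euclidean) — a deterministic algorithm, which is why no seed is consumed.
Classes are renamed cool/warm/hot by ascending mean Tmax. `k = 3` is the
default because three temperature classes are the documented outcome; a
different `k` can be forced and the labels fall back to `T1..Tk`. Water
status is thresholded separately by `classify_water()`: WW strictly above
−0.1 MPa, so the boundary value itself is WD — the wording "above −0.1 MPa"
for WW forces that choice. The two-step design (cluster temperature, then
threshold water) follows the two-step description of the procedure rather
than folding Ψ into the clustering. `assign_scenario()` projects new
fields onto the stored PCA basis and takes the nearest medoid's class,
warning (but not failing) beyond 10× the training covariate range.

# Genotype means, gain, and the variance partition

`genotype_means()` fits, per group, the two-stage plant-breeding workhorse:
fixed hybrid effects, random experiment effects. The single variance ratio
is profiled out of the REML likelihood and minimised by golden-section
search (tolerance 1e-8 on log10 of the ratio; the ratio-to-zero boundary,
the ordinary-least-squares limit, is checked explicitly). Because the
marginal covariance is block-diagonal by experiment, all quadratic forms
reduce to per-experiment sums and no n×n matrix is ever formed. `lme4`
reproduces these BLUEs to 4 decimals in the test suite but is not a
runtime dependency. Spatial adjustment within experiments is out of scope,
and the synthetic trials carry no spatial trend accordingly.

`genetic_gain()` is ordinary least squares of a per-hybrid trait value on
year of release with a two-sided t-test; numerically exact fits are
special-cased (a constant trait has p = 1, an exact line p = 0).

`partition_variance()` fits the grain-number model with terms in the fixed
order: optional trait covariates, year (`G_year`), hybrid (`G_res`),
scenario (`Scen`), experiment (`E_res`), year×scenario, and converts
*sequential* (type-I) sums of squares into proportions of the total. The
sequential decomposition is the default because the narrative is nested —
"how much of the genetic effect does year capture, how much of that do the
traits capture" — and only type-I proportions are guaranteed to sum to 1;
a `type = "III"` flag reports drop1 sums of squares for comparison, without
that guarantee. Note that year is a linear function of hybrid, and scenario
of experiment: the later term in each pair is the *residual* effect, which
is exactly the quantity of interest. Forward selection and backward
elimination (`selection = "forward-backward"`, F tests at α = 0.05 — a
conventional default, as no threshold is printed in the source analyses)
respect the main-effects-before-interaction hierarchy; excluded terms
report proportion 0.

`factorial_regression()` estimates genotypic sensitivities β1 (to mean
soil water potential at flowering, GN per MPa) and β2 (to intercepted
radiation in the vegetative phase, GN per MJ m⁻²) by classical two-stage
factorial regression: the response is double-centred (hybrid and
experiment means removed) and each genotype's interaction residuals are
regressed on the centred indices. This is equivalent to sum-to-zero
genotype-specific slopes inside the full model and sidesteps the exact
aliasing of the *mean* sensitivity with the experiment main effect — so
the reported β's are deviations from the panel-mean sensitivity, which is
what group contrasts and rankings need. Indices are admitted sequentially
by a pooled F test at α = 0.05; a constant index is never admitted and
its sensitivities are NA.

# Constrained Gaussian Bayesian networks

`bge_score()` implements the Bayesian Gaussian equivalent (BGe) score: the
log marginal likelihood of centred, scaled data under a DAG with a
normal-Wishart prior. The hyperparameters are the standard
minimal-information choice: zero prior mean, prior-mean precision
`alpha_mu = 1`, Wishart imaginary sample size `iss = n_vars + 2`, and
prior scale `t·I` with `t = alpha_mu (iss − n_vars − 1)/(alpha_mu + 1)`,
which makes the implied prior marginal variances unity on standardised
data. The score decomposes into per-node family terms computed from
Cholesky factors of submatrices of a single posterior matrix, with a
per-dataset cache. Two properties pin the implementation down in tests:
score equality across entire Markov-equivalence classes (enumerated over
all 543 four-node DAGs, tolerance 1e-10), and agreement to 1e-9 with an
independent oracle that evaluates the same marginal likelihood as a
sequential product of multivariate-Student posterior-predictive densities.

`learn_structure()` is a tabu search over add/delete/reverse moves:
steepest ascent with a visited-structure tabu list (length 10), up to ten
non-improving escape steps, hard blacklists/whitelists, and lexicographic
tie-breaking so the search is deterministic given the column order. The
canonical constraint set (`year_trait_blacklist()`) encodes the two
biological assumptions: year of release is exogenous (no arcs into it),
and traits determined during the vegetative and flowering periods cannot
depend on grain number, which is fixed only at the start of grain filling.
Further constraints are user-editable.

`bootstrap_average()` learns on `B = 500` nonparametric row resamples and
tabulates arc strengths (fraction of networks containing the arc in either
direction) and directions. The averaged network keeps arcs above a
threshold chosen, by default, as the L1-minimising significance threshold
over the empirical strength distribution — the strengths are modelled as a
mixture of "noise" arcs near 0 and "real" arcs near 1, and the cut point
minimises the L1 distance between the empirical CDF and that ideal shape;
a fixed cutoff (e.g. 0.5) is available. Kept arcs are oriented by majority
direction and inserted in decreasing strength, skipping any that would
close a cycle. `cv_predict()` evaluates the averaged network by
ten-times-repeated five-fold cross-validation, predicting each node from
its fitted linear-Gaussian parents; root nodes report NA. Consensus across
per-scenario networks is the arc intersection (`consensus_network()`).

# Genome scans for regions under selection

`temporal_mlm_scan()` regresses year of release on per-SNP allele counts
while controlling relatedness: the null model `year = μ + u + e` with
`u ~ N(0, σg² K)` is fitted once by REML in the eigenbasis of the
intercept-projected kinship matrix (the restricted transformation; this
also removes the exact null vector that VanRaden centring gives the GRM,
which otherwise receives a near-infinite GLS weight), and every SNP is then
tested by generalised least squares with the variance ratio held fixed —
the standard fast approximation, roughly two orders of magnitude cheaper
than per-SNP REML and indistinguishable from it at these sample sizes
(an `exact = TRUE` flag re-profiles the ratio per SNP). Wald p-values use
n−2 degrees of freedom; with `K = NULL` the scan reduces *exactly* to
ordinary per-SNP regression, which is how the calibration contrast
(kinship control matters) is demonstrated. SNPs with −log10 p > 3.5 are
flagged.

`xtx_scan()` contrasts the 22 oldest with the 22 most recent hybrids
(group sizes are parameters). The published form of this statistic is a
Bayesian MCMC estimator; here it is replaced by a documented moment-based
analogue that preserves its defining property — covariance-standardised
differentiation. Per group, `z = (p̂_group − π̂)/√(π̂(1−π̂))` with π̂ the
pooled frequency; the 2×2 covariance Ω of `(z_old, z_recent)` is estimated
over an LD-pruned SNP subset, and `XtX = zᵀΩ⁻¹z`. With equal group sizes
the two z's are exactly opposite, so Ω is singular by construction and a
1e-6 ridge (with a warning) effectively reduces the statistic to a
standardised squared frequency difference — the intended behaviour for a
two-group design. Monomorphic pooled SNPs score 0 and are flagged
uninformative. Markers above the empirical 99.95th quantile are flagged;
`call_rus()` merges flagged positions within 500 kb (configurable) on the
same chromosome, union over methods by default since the combination rule
is not fully specified, and records which methods contributed.

LD pruning (`ld_prune()`) is greedy and windowed (50 SNPs, step 5,
r² ≤ 0.2 — conventional settings; only the resulting subset size is
reported for the real data), with an optional seeded subsample to a target
size. QC (`qc_and_impute()`) removes SNPs with MAF strictly below 0.05 or
missingness strictly above 20%, then imputes the per-SNP modal genotype —
deterministic and adequate at ≤20% missingness, in place of the external
haplotype-based imputation the real pipeline cites but does not describe.

# Colocalization enrichment

`enrichment_test()` counts QTL regions overlapping at least one RUS
(0-based half-open intervals; abutment is not overlap), then samples, 1e5
times by default, random region sets matching the QTL set in number and
physical lengths — chromosome chosen proportionally to the number of valid
start positions, start uniform, overlaps among random regions allowed, as
the simplest null consistent with "random regions of the same size". RUS
stay fixed. The permutation p-value uses the add-one correction
`(b + 1)/(m + 1)` and is the primary result; a chi-square statistic
comparing the observed count with the null-mean expectation is reported
alongside because both summaries are conventional, but the two can
disagree and the permutation p is authoritative. One-sided enrichment is
the default, depletion a flag. `freq_shift_contrast()` applies the same
null to a different statistic: the mean absolute old-vs-recent frequency
difference over SNPs inside the QTL space. The overlap engine is sorted
merged intervals with `findInterval` arithmetic, vectorised over all
`m × |QTL|` placements; a naive O(n²) oracle verifies it on 1,000 fuzzed
interval sets per run. Genetic-scale (cM) matching is not implemented;
physical matching is the default and only scale.

# Scenario-conditional allelic effects

`predict_field_effects()` is a pure lookup: each field's predicted allelic
effect for a QTL is the effect estimated in that field's scenario, with
per-QTL summaries over fields. Per-QTL means are therefore convex
combinations of the six scenario effects weighted by scenario frequencies
among the fields — an identity the tests check exactly. Summaries are
unweighted over fields. `favorable_freq_shift()` reports the favorable
allele's frequency (the allele with the positive effect in the cool/WW
scenario) in the oldest and most recent `n = 22` hybrids, with groups
formed by a stable sort on year, ties broken by hybrid id — tie handling
at equal release years being otherwise unspecified. The default
ground-truth effect table carries three constitutive QTLs (stable effects
0.10–0.24 t/ha, mean ≈ +0.18) and three adaptive QTLs (sign-flipping
between WW and WD, or cool and hot, spanning ≈ −0.16 to +0.17 t/ha);
constitutive QTLs are planted on trending loci and adaptive QTLs on
neutral ones, reproducing the observed contrast that favorable-allele
frequencies rise only at stable-effect QTLs.

# Numerical choices and degenerate inputs

- Boundary QC values: MAF exactly 0.05 and missingness exactly 20% are
  retained (both thresholds are strict).
- Modal-imputation ties go to the smaller genotype; PAM ties to the lowest
  index; tabu ties to lexicographic move order — all for determinism.
- The GRM gets a 1e-8 ridge before eigendecomposition; eigenvalues are
  floored at 1e-9; Ω gets a 1e-6 ridge when singular.
- Every stochastic operation takes a seed and restores the caller's RNG
  state; equal seeds give bit-identical output.
- `enrichment_test` warns below m = 100 (p resolution) and short-circuits
  with p = 1 and a flag on empty inputs.

# Problem sizes

The test suite and the acceptance script run the panel analyses at
60 hybrids × 10,000 SNPs (the study scale) and the scan calibration/power
analyses at 200 hybrids × 10,000 SNPs with 50 planted trending loci;
enrichment nulls use 1e4–1e5 permutations and 200 replicate seeds for the
uniformity check; networks use 500 bootstraps per scenario. The full test
suite completes in about two minutes, the acceptance script in about two.

# What passing tests do and do not show

The generator reproduces the statistical structure the methods assume —
era-correlated admixture, logit-linear selected-locus trends, scenario-
structured environments, a known trait DAG, variance components by design —
but not linkage disequilibrium, pedigree structure, spatial field trends,
genotype-specific phenology, or assay artefacts. Passing the planted-truth
checks therefore demonstrates the *methods* are correct and calibrated
under their stated assumptions; it does not by itself validate conclusions
on any real panel. The Tier-2 quantities that depend on the deposited
600k-array data (the exact retained-SNP count, the exact PC1–year R², the
published gain and partition percentages) are reported by the acceptance
script as the synthetic-panel analogues of those figures.
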