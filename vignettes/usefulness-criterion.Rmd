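---
title: "Predicting the usefulness criterion of donor x elite crosses in a BC1S2 bridging population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the usefulness criterion of donor x elite crosses in a BC1S2 bridging population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucbridge)
```

## The problem

Elite maize breeding pools are genetically narrow. A standard way to widen
them is a *bridging population*: genetic-resource donor lines are crossed to
elite recipient lines, the F1 is backcrossed once to the recipient, and the
BC1 progeny are selfed twice by single-seed descent (BC1S2). Progeny carry
on expectation three quarters of the recipient genome and one quarter of the
donor genome, so new diversity enters with a limited performance penalty.

Two decisions drive such a program:

1. **Which of the possible donor x recipient crosses is worth making?**
   The value of a cross is not just its expected progeny mean but also its
   progeny variance, because selection operates within the family. The
   *usefulness criterion* (UC) combines both.
2. **Which new donor should be incorporated next**, given the donors a
   recipient has already been crossed with? Here complementarity matters:
   a donor is valuable if it carries favorable haplotypes the current pool
   lacks. The *H criterion* scores exactly that.

`ucbridge` implements both decision tools, the genomic-prediction machinery
underneath them, and a synthetic-data generator that reproduces the
statistical structure of a multiparental BC1S2 bridging design so the whole
pipeline can be exercised and validated without any proprietary data.

## Models

### Per-family mean and additive variance (REML)

For each family $k$ the observed "truth" is estimated from its own progeny
with the mixed model

$$Y_{hk} = \mu_k + A_{hk} + E_{hk}, \qquad
  \mathbf A_k \sim N(0, \mathbf K_k \sigma^2_{Ak}), \quad
  \mathbf E \sim N(0, \mathbf I \sigma^2_E),$$

fitted by REML (`fit_family_gblup()`). $\mathbf K_k$ is a marker-based
additive kinship built with the Natural and Orthogonal Interaction Approach
(NOIA): for genotype frequencies $p_{Bb}, p_{bb}$ *computed on the exact
subset of individuals being analyzed*, the additive coefficient of an
individual with dosage $d \in \{0,1,2\}$ is $-(d - p_{Bb} - 2 p_{bb})$, and

$$\mathbf K = \frac{\mathbf H_A \mathbf H_A'}{\mathrm{tr}(\mathbf H_A
  \mathbf H_A')/n},$$

so $\mathrm{tr}(\mathbf K) = n$ (`kinship_noia()`).

The two-variance REML problem is reduced to a one-dimensional profile over
the ratio $\lambda = \sigma^2_A/\sigma^2_E$ by rotating the data into an
orthonormal basis of the intercept's orthogonal complement and
diagonalizing the rotated kinship there. One implementation point deserves
emphasis: the contrast basis is built explicitly (QR of the intercept
column, completed), *not* from the eigenvectors of the projected kinship.
With a family of $n$ individuals genotyped at $m < n$ markers the kinship is
rank-deficient, its null space mixes the intercept direction with genuine
contrasts, and eigenvectors of the projected matrix are then an invalid
contrast basis; the explicit construction is correct for any rank.
Convergence tolerance is $10^{-8}$ on the log-ratio; estimated variances
below $10^{-10}$ are reported as 0. Degenerate input (constant phenotypes)
returns $\sigma^2_A = \sigma^2_E = 0$ with $\mu$ the constant.

### Within- and inter-family GBLUP (cross-validation)

`gblup_predict()` fits the same model on a training set (TS) and
back-solves BLUPs for all individuals in the kinship subset; the kinship and
its NOIA frequencies are computed on TS plus validation set (VS) jointly.
`within_family_cv()` and `evaluate_ts_pa()` implement the repeated
two-thirds-VS / one-third-TS evaluation, with VS draws shared across TS
compositions so that compositions are compared on identical targets.
Training-set compositions are defined on the crossing design
(`build_training_set()`): `F` (rest of the target family), `OFO` (all other
families), `R` / `D` (families sharing the recipient / donor), `RD` (their
union) and `Disc` (families sharing neither parent), optionally augmented
with the non-VS third of the target family. For the inter-family types
without augmentation the TS does not depend on the CV repetition, so the
model is fitted once per (family, type) and only the validation
correlations vary across repetitions — the estimator is unchanged, only
redundant refits are avoided. Variance components are re-estimated whenever
the TS changes.

### Marker effects: Bayesian ridge regression

Cross-level predictions need marker effects. `fit_brr()` implements
Gaussian ridge regression with scaled-inverse-$\chi^2$ priors on both
variances, sampled by single-site Gibbs updates with the intercept as an
unpenalized column. Default hyperparameters follow the usual rule: degrees
of freedom 5 for both priors, scales set so the prior modes split the
phenotypic variance 50/50 between markers and error,
$\tau_E = \mathrm{Var}(y)(1-R^2)(\nu+2)$ and
$\tau_\beta = \mathrm{Var}(y) R^2 / \sum_j \mathrm{Var}(x_j) \cdot (\nu+2)$
(`default_hyperparameters()`). The default chain uses 20,000 iterations,
5,000 burn-in, and keeps every fifth post-burn-in draw: $S = 3000$ retained
samples. Chains are bit-reproducible under a fixed seed. Genotypes enter as
dosages 0/1/2 and are not centered by default (both recorded in the fit
metadata); progeny of a BC1S2 design are genuinely heterozygous at rate
about 1/8, so collapsing heterozygotes is deliberately not the default.

### Predicting an untested cross

For a recipient $R$ and donor $D$ with genotype vectors $x_R, x_D$ (coded
0/2) and posterior-mean effects $\hat\beta$:

* **Mean** — expected parental genome proportions after one backcross give
  $\hat\mu = \tfrac34 x_R'\hat\beta + \tfrac14 x_D'\hat\beta$ (the fitted
  intercept is added once).
* **Variance** — the progeny marker covariance is
  $\Sigma_{ij} = D^p_{ij}\,(1-2c_{ij})(3-2c_{ij})$, where
  $D^p = \tfrac1{16}(x_R-x_D)(x_R-x_D)'$ is the parental linkage
  disequilibrium (entries $0, \pm 0.25$) and $c_{ij}$ is the expected
  BC1S2 recombination obtained from the Haldane rate
  $c^1 = \tfrac12(1-e^{-2d})$ through
  $c = \frac{2c^1}{1+2c^1}\bigl(1-\tfrac14(1-2c^1)^2\bigr)
       + \tfrac12\bigl(\tfrac12(1-2c^1)\bigr)^2.$
  $\Sigma$ is assembled and multiplied per chromosome block; entries across
  chromosomes are exactly zero because $c = \tfrac12$ there.
  Two estimators are provided: **VPM**, the quadratic form
  $\hat\beta'\Sigma\hat\beta$ in the posterior means, and **PMV**, the
  average of $\beta^{(s)\prime}\Sigma\beta^{(s)}$ over posterior samples.
  Algebraically PMV $-$ VPM $= \mathrm{tr}(\Sigma\,\mathrm{Cov}(\beta))
  \ge 0$ for positive semi-definite $\Sigma$, so PMV is systematically the
  larger of the two; on data with finite training sets it tends to
  overshoot the REML-observed variances, which is why VPM is the default
  in the donor-ranking tools.
* **UC** — $UC = \hat\mu + i\,h\,\hat\sigma^2$ with selection intensity
  $i = 2.07$ (5% selection rate) and accuracy $h = 1$ by default.

A note on the UC scale: the classical definition uses the progeny standard
deviation, while the working equations this package follows apply the
intensity directly to the variance. Both are available
(`uc_scale = "variance"` is the default, `"sd"` the alternative), and the
scale used is recorded in every output row. Rankings are unaffected
whenever variances are monotone in standard deviations, but absolute UC
values differ.

### A deliberate discrepancy in the variance formula

The printed BC1S2 recombination expectation gives $c = 1/8$ at distance
zero, hence a per-locus variance contribution of
$\Sigma_{ii} = \tfrac14 (1 - \tfrac14)(3 - \tfrac14) = 33/64 \approx 0.516$
for a segregating locus — whereas
direct genotype-frequency algebra for BC1S2 (genotype probabilities
$11/16, 1/8, 3/16$ for 0/1/2 donor dosage) gives
$\mathrm{Var}(\text{dosage}) = 5/8 = 0.625$. The package implements the
covariance formula exactly as printed and exposes a brute-force Monte-Carlo
oracle (`empirical_progeny_variance()`) that simulates BC1S2 progeny and
computes the realized variance. The discrepancy is close to a constant
factor, so cross *rankings* — what the UC machinery consumes — are
preserved; the test suite asserts rank correlation $\ge 0.9$ between
analytic and simulated variances over batches of synthetic crosses rather
than absolute agreement.

### Fixed parental effects

As a benchmark for the mean prediction, `fit_parental_fixed_effects()` fits
$Y = \mu + \gamma_{donor} + \rho_{recipient} + E$ by OLS under sum-to-zero
contrasts, and `predict_parental_mean()` returns $\mu + \gamma_i + \rho_j$.
The identifiability constraint is a presentation choice only: predicted
cross means are constraint-invariant. Disconnected designs (aliased
parental levels) raise an error naming the aliased effects rather than
silently dropping them.

### The H criterion and donor prioritization

`build_windows()` tiles each chromosome with overlapping haplotype windows
of 100 markers advanced by 20 (defaults). Window starts run
$1, 21, 41, \dots$; a window is truncated at the chromosome end and window
generation stops at the first window reaching the last marker, so every
marker is covered, no window spans a chromosome boundary, and no nested
trailing windows are generated. The scaling factor
$\lambda = \text{step}/\text{window size} = 0.2$ compensates the
overlap.

`hebv()` computes the haplotypic estimated breeding values
$\mathrm{HEBV} = [X \circ (1\hat\beta')]Z$ — the genetic value each line's
haplotype contributes per window, with $\hat\beta$ from a ridge fit
calibrated on **all** individuals. For a recipient, its incorporated donors
and a candidate, the H criterion is

$$H = \lambda \sum_h \max\{\mathrm{HEBV}_{cand,h},\,
      \mathrm{HEBV}_{rec,h},\, \max_{D}\mathrm{HEBV}_{D,h}\},$$

the value of the best doubled haploid assembled from the pool's best
segments. `forward_select_donors()` incorporates candidates greedily,
reporting $H$ and the percent gain over the recipient-plus-initial-donors
baseline at each step; trajectories are non-decreasing by construction and
ties are broken lexicographically by donor id (determinism). UC-based
ranking of the same candidates (`rank_donors_by_uc()`, RD-type training set
and VPM variance recommended) is reported side by side; the two orders
legitimately disagree — UC rewards a donor's own performance and realistic
recombination, H rewards complementary haplotypes — and the test suite
contains a constructed instance where they must disagree.

## The synthetic-data generator

`simulate_dataset()` produces map, parents, crossing design, BC1S2
progeny and adjusted-mean phenotypes in one call. Its defaults are fixed
to the reference design shape: 7 recipients, 9 donors, 20 families of
38–66 progeny with 2–3 donors per recipient, 10 chromosomes of 1.7 Morgan.
The default panel of 200 markers per chromosome is a desk-scale stand-in
for a mid-density (about 19k SNP) array: dense enough that adjacent markers
are a few centimorgans apart, small enough that the full pipeline runs in
minutes.

Meiosis follows the Haldane model — Poisson crossover counts with uniform
positions and no interference, matching the map function used throughout
the analytic machinery — and the pedigree is simulated literally: F1,
backcross to the recipient, then two selfing generations advancing a single
seed each. Closed-form checks fall out of the pedigree: donor-allele
frequency $1/4$, heterozygosity $1/8$, per-locus dosage variance $5/8$ at
segregating markers; the test suite verifies all three by Monte Carlo.

Two structural choices matter for what the generator can and cannot show:

* **Hidden QTL.** By default each chromosome carries 20 causal loci
  interleaved with the panel but excluded from the delivered genotype
  matrices (`n_qtl_per_chromosome`, set 0 to make panel markers causal).
  This is not a detail: if panel markers are themselves the QTL, marker
  effects estimated in *any* family transfer to any other, and
  disconnected training sets are nearly as informative as related ones —
  unlike every empirical result in this literature. With hidden QTL, panel
  markers tag causal loci only through within-family co-segregation;
  marker–QTL phase is consistent across families sharing a parent and
  arbitrary across unrelated families, which is exactly the mechanism that
  makes training-set relatedness matter on real array data. Under this
  default the package reproduces the qualitative composition result
  ({OFO, RD} $\ge$ {R, D} $\ge$ Disc in mean predictive ability) across
  replicate designs.
* **Parental allele sharing.** Each marker has a consensus allele;
  recipients deviate with probability 0.3 and donors with probability 0.5.
  Recipients are thus distinct from one another (pairwise difference at
  about 42% of loci) yet more similar to each other than to the donor pool
  — the elite-versus-genetic-resource contrast. Making recipients too
  similar (near-clones) voids the information content of "same recipient"
  training sets and is avoided deliberately.

Phenotypes are simulated directly at the adjusted-hybrid-mean level: one
record per individual, additive genetic value plus Gaussian noise scaled to
a target heritability (default 0.5 — the real trait architectures are
unknown, so this is an explicit placeholder, config-exposed). The
generator does **not** emulate: multi-trial or tester structure,
genotype-by-environment interaction, dominance, founder linkage
disequilibrium beyond allele sharing, marker ascertainment bias, or
selection during family development. Consequences: passing tests
demonstrate the estimators and the relatedness mechanism, not robustness
to non-additive variation or to G×E; and absolute predictive abilities on
synthetic data should not be read as forecasts for field data.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_dataset(
  n_chromosomes = 5, length_morgan = 1.2, markers_per_chromosome = 40,
  n_recipients = 4, n_donors = 5, n_families = 10, family_sizes = 30:40,
  traits = list(GY = list(heritability = 0.5)),
  n_qtl_per_chromosome = 10, seed = 42)

y <- setNames(sim$pheno$value, sim$pheno$individual_id)
fam <- sim$design$family_id[1]

# observed family parameters (REML + NOIA kinship)
ids <- sim$individuals$individual_id[sim$individuals$family_id == fam]
vc <- fit_family_gblup(y[ids], kinship_noia(sim$progeny[ids, ]))

# predict the same cross as if it had never been made: RD training set
ts <- build_training_set(sim$design, sim$individuals, fam, "RD")
fit <- fit_brr(y[ts$member_ids], sim$progeny[ts$member_ids, ],
               n_iter = 6000, burn_in = 1000, thin = 5, seed = 1)
k <- match(fam, sim$design$family_id)
predict_cross(sim$parents[sim$design$recipient_id[k], ],
              sim$parents[sim$design$donor_id[k], ], fit, map = sim$map)
```

## Numerical choices and problem sizes

* Symmetry/trace assertions use a relative tolerance of $10^{-8}$;
  kinship eigenvalues are floored at 0 before simulation use.
* $\Sigma$ is stored per chromosome; dense assembly is available via
  `as.matrix()` for inspection.
* The test suite runs REML parameter recovery on 200 simulated families of
  300 individuals, marker-effect recovery on noiseless 400 x 100 data with
  the full default chain, the variance rank-fidelity check on 20 crosses
  with $10^4$ simulated progeny each, meiosis Monte Carlo at $10^5$
  gametes, and the training-set composition comparison on ten replicate
  15-family designs with 20 CV repetitions — sizes chosen so the whole
  suite completes in minutes on a single core while keeping Monte-Carlo
  standard errors well inside the asserted tolerances.
* `run_pipeline()` writes every table as TSV plus a manifest with the
  config hash and seeds; re-running any stage from the persisted inputs
  reproduces it exactly.

## Known limitations

* The BC1S2 covariance formula is implemented as printed, including its
  distance-zero behavior discussed above; users comparing analytic and
  simulated variances should expect a near-constant scale offset.
* Only additive effects are modeled end to end, so any dominance or
  epistatic variance present in real hybrids is absorbed into the error.
* $\Sigma$ coefficients are specific to BC1S2; other generation schemes
  (DH, RIL, further selfing) are out of scope.
* The Gibbs sampler reports no convergence diagnostics beyond the retained
  draws; the default chain length is generous for the desk-scale problems
  the package targets, but users fitting much larger panels should inspect
  the draws.
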