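---
title: "From fluorescence spectra and co-occurrence networks to carbon mineralization: methods and design"
author: "soilCNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From fluorescence spectra and co-occurrence networks to carbon mineralization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Organic amendments (green manure, biochar) change both the quality of
dissolved organic carbon (DOC) and the structure of soil microbial
communities, and both changes feed back on how fast soil organic carbon
mineralizes to CO2. `soilCNet` implements the analysis chain that ties
these three observations together in incubation studies: fluorescence
spectroscopy characterizes DOC composition, co-occurrence networks
summarize community organization, alkali-trap titration measures
mineralization, and attribution methods (permutation random forests,
variance partitioning) ask which block of drivers matters.

This vignette documents the models, the tunable parameters, the
numerical choices, and the limits of what the package's synthetic tests
demonstrate.

# Mineralization arithmetic

A jar of `soilMassKg` soil (default 0.030 kg) sits in a closed vessel
with a vial of NaOH (default 20 mL of 0.5 mol L⁻¹) trapping CO2. At each
sampling day (1, 3, 5, 7, 10, 15, 20, 25, 30) the residual alkali is
titrated to pH 7 with HCl (default 0.4 mol L⁻¹) after BaCl2
precipitation of the carbonate. Because each mole of CO2 consumes two
moles of NaOH, and titration measures residual NaOH 1:1,

$$\mathrm{CO_2\text{-}C\ (mg\,kg^{-1})} =
  (V_\mathrm{blank} - V_\mathrm{sample})\,\frac{M_\mathrm{HCl}}{2}\,
  \frac{12.01}{m_\mathrm{soil}}.$$

The factor-of-two stoichiometry and the 12.01 g mol⁻¹ carbon molar mass
are package conventions (the molar mass is configurable); blank
correction uses the mean blank volume of the same sampling day, so any
additive offset applied to every jar cancels exactly. Interval values
that come out negative (sample titration above blank) are clipped to
zero with a warning. Daily rates divide interval CO2-C by the days since
the previous sampling (day 0 origin); cumulative mineralization (*Cum*)
is the running sum through day 30 and is non-decreasing by construction.
Headspace carryover between jar openings is not corrected.

# EEM correction and fluorescence indices

Excitation–emission matrices are measured on a fixed lattice: excitation
200–450 nm in 5 nm steps (51 columns), emission 250–600 nm in 1 nm steps
(351 rows). Correction proceeds in the standard order:

1. **Raman normalization.** Sample cube and blank are divided by the
   blank's Raman peak area — the trapezoidal integral of the blank
   emission scan at ex 350 nm over em 371–428 nm. Only the excitation
   wavelength of the Raman line is a community constant; the emission
   window is a convention and is exposed as a parameter. Corrected
   intensities are therefore in Raman units and invariant to common
   rescaling of sample and blank.
2. **Blank subtraction** removes the Raman band and most scatter.
3. **Scatter excision.** Residual first- and second-order Rayleigh bands
   (em within ±10 nm of ex and of 2·ex) are set to missing, not
   interpolated — interpolation can fabricate trilinear structure that
   PARAFAC would then "recover". Excised cells are down-weighted to zero
   in the PARAFAC loss instead.
4. **Clipping.** Remaining negative cells (noise around zero) are
   clipped to 0, with the count reported, because the decomposition is
   non-negative.

Correction is guarded against double application.

Indices, from the corrected cube:

* **BIX** = F(em 380)/F(em 430) at ex 310; values > 0.8 flag
  autochthonous (microbially derived) DOC.
* **HIX** = ΣF(em 435–480) / (ΣF(em 300–345) + ΣF(em 435–480)) at ex
  254. This form is a proportion, so HIX ∈ [0, 1] for any non-negative
  EEM. Ex 254 nm lies off the 5-nm lattice and is linearly interpolated
  between the 250 and 255 nm columns; nearest-neighbour assignment
  would bias HIX systematically in one direction.
* **FI** = F(em 450)/F(em 500) at ex 370, the McKnight-style
  fluorescence index; the exact definition varies across the literature,
  so this choice is a documented package assumption.

Zero denominators yield missing indices with a warning, never an error:
one bad sample should not kill a batch.

# Non-negative PARAFAC

The corrected cube is modeled trilinearly,
$x_{ijk} \approx \sum_{r=1}^{R} a_{ir} b_{jr} c_{kr}$, with all three
modes non-negative. Fitting is alternating least squares: each mode's
rows are exact non-negative least-squares problems on R unknowns, solved
by enumerating the 2^R possible supports (exact for the small ranks used
here; R = 3 by default). Missing cells carry zero weight — the
scatter-excision mask depends only on wavelengths, so it is shared
across samples, which keeps the per-mode normal equations cheap. The
implementation is compiled (RcppArmadillo).

Choices that matter:

* **Initialization.** `nStarts` random non-negative draws plus one
  SVD-magnitude start; the best final loss wins. The seed controls all
  draws, so fits are bit-reproducible.
* **Convergence.** Relative loss change below `tol` (default 1e-8) or
  2,500 sweeps. On exact-rank data the loss decays geometrically toward
  zero and a relative-change rule alone can never fire, so an absolute
  floor (loss below 1e-14 of the data sum of squares) also counts as
  convergence.
* **Identifiability conventions.** Loading columns are normalized to
  unit Euclidean norm with magnitude pushed to the scores, and
  components are ordered by ascending emission peak (ties by excitation
  peak), so C1 < C2 < C3 in emission.
* **Diagnostics.** The ALS loss is non-increasing by construction and
  asserted in tests; a warning flags degenerate solutions (two
  components with mutual Tucker congruence > 0.98 on both modes) and
  non-convergence.

**Fmax** quantifies component r in sample i as
`score · max(exLoading) · max(emLoading)` (Raman units); row-normalized
Fmax gives the component's relative abundance.

**Split-half validation** partitions samples into random halves
(`nSplits` repetitions, 4 by default), fits each half, matches
components between halves by the bijection maximizing summed Tucker
congruence (TCC — the cosine between loading vectors), and passes when
every matched pair exceeds 0.95 on both modes. The split scheme and
repetition count are package conventions, exposed as parameters.
**Library matching** applies the same > 0.95-on-both-modes rule against
a local reference table (the shipped default holds synthetic Gaussian
templates of one microbial humic acid-like component at ex/em 280/401 nm
and two terrestrial humic acid-like components at 355/443 and
275/468 nm); no online database is queried.

# Community composition

Relative abundances aggregate counts at a chosen taxonomic rank (raw
counts, no rarefaction — a subsampling flag is the user's choice, not a
default), with unassigned taxa pooled into "unclassified" so columns
keep summing to one. Bray–Curtis distances feed classical principal
coordinates (double-centering + eigendecomposition; negative eigenvalues
are reported and excluded from axis fractions) and a one-way PERMANOVA:
R² = SS_between/SS_total from the Gower-centered partition, p =
(1 + #{F* ≥ F})/(nPerm + 1) under free label permutation (a
single-factor pot design has no strata).

# Co-occurrence networks

* **Prevalence filter:** keep OTUs present in strictly more than half
  of the samples (fraction configurable).
* **Edges:** all pairwise Spearman correlations (average ranks on ties;
  two-sided p by t-approximation for n ≥ 10, exact below),
  Benjamini–Hochberg adjustment over the upper triangle, and an edge
  wherever adjusted p < 0.01. No additional |ρ| cutoff is applied by
  default — significance is the only published filter — and
  constant-abundance OTUs are excluded with a logged count.
* **Nodes** are the endpoints of retained edges. Filtered-but-isolated
  OTUs are not nodes, which is why node counts sit far below the
  filtered OTU counts.
* **Subnetworks:** per treatment, the induced subgraph on OTUs present
  in more than half of that treatment's replicates; the membership rule
  is an interpretation (exposed as a parameter) since only the existence
  of subnetworks is conventionally reported.
* **Topology:** average degree 2E/N; local clustering coefficient
  2·triangles/(k(k−1)) on the unsigned simple graph, with degree < 2
  nodes contributing 0 (the most common convention; verified against
  brute-force triangle enumeration in tests). The average clustering
  coefficient (ACC) is the package's network-complexity proxy.
* **Modules:** Louvain modularity maximization on |ρ| weights under a
  fixed seed, labels ordered by descending module size.
* **Module eigengenes:** first principal component of the z-scored
  member abundances, sign-oriented to correlate non-negatively with the
  module mean (when that mean is flat — e.g. two exactly anti-correlated
  members — the orientation is left as PCA returns it). Associations
  with environmental variables use Pearson r with both analytic and
  seeded permutation p-values (stars at p < 0.05 / p < 0.01). A true
  Mantel test on distance matrices is also provided; the plain Pearson
  form drives the association table because eigengenes and soil
  variables are per-sample vectors, not distances.

# Driver attribution

The driver table holds, per sample: *Cum* (response), the DOC block
(component relative abundances C1–C3, BIX, HIX, FI) and the network
block (BACC and FACC, the bacterial and fungal subnetwork ACCs). ACC is
one number per treatment network, so it is broadcast to that treatment's
samples; the resulting pseudo-replication is flagged in the run report
rather than hidden.

* **Random forest:** regression forest (500 trees by default), %IncMSE
  importance normalized by its standard deviation. Per-predictor
  p-values permute that predictor and refit (`nPerm` times, seeded);
  the whole-model p permutes the response and compares out-of-bag
  pseudo-R². Constant predictors get zero importance.
* **Variance partitioning:** R² of the response on X1, X2, and X1∪X2 via
  least-squares projection (for a univariate response this is
  linear-model R²; a multivariate response uses the redundancy-analysis
  explained-inertia fraction — the "constrained ordination" degenerates
  to regression for one response). Fractions: unique_X1 = R²(both) −
  R²(X2), unique_X2 = R²(both) − R²(X1), shared = R²(X1) + R²(X2) −
  R²(both), residual = 1 − R²(both); they sum to one exactly, and a
  negative shared fraction (suppression) is reported with a flag, not
  silently floored. Unadjusted R² is the default at these small n;
  Ezekiel-adjusted R² is a flag.
* **Within-block shares:** both the standalone-R² share (each
  predictor's solo R² over the block's sum) and hierarchical
  partitioning (average sequential R² increment over all orderings) are
  emitted, clearly labeled, because the literature rarely states which
  decomposition produced a reported percentage.

# The synthetic world

`synthDesign()` fixes the study conditions: three treatments (NPK, GM,
GMC) × 8 replicates.

* **EEMs.** Components are Gaussians on the wavelength lattice (peaks at
  ex/em 280/401, 355/443, 275/468 nm; widths 15–20 nm excitation,
  28–38 nm emission) — matching the unimodal humic-like peak shapes
  without claiming spectral realism. Scores are log-normal (positive,
  right-skewed) times per-treatment multipliers chosen so the microbial
  humic-like C1 rises under GMC and C3 falls. Samples carry the full
  water-scatter pattern (Rayleigh ridges at em ≈ ex and em ≈ 2·ex,
  Raman band at the 3400 cm⁻¹ shift) so correction has real work to do;
  blanks carry scatter only. Default noise is 0.5% of the maximum
  noiseless signal; instrument inner-filter effects and detector
  saturation are not emulated.
* **Community.** Taxa in each of 4 planted modules (25 taxa each of 300)
  share a latent Gaussian factor on the log-abundance scale — a monotone
  association Spearman correlation detects regardless of marginal
  transforms. The latent weight (1.2), taxon noise (sd 0.5), median
  count scale (100) and dropout strength (0.3) are calibrated so the
  realized count-level within-module Spearman correlation is ≈ 0.8 with
  24 samples. Dropout is abundance-dependent
  (P(zero) = 0.3·e^(−λ/10)), concentrating zeros in rare observations as
  real OTU tables do — uniform random dropout would cap the attainable
  rank correlation well below the target. Counts are Poisson;
  overdispersion beyond the log-normal mixing is not needed to exercise
  rank correlations. Forty background taxa respond to treatment
  (multipliers 1 / 1.5 / 2.2) to create the compositional shift the
  ordination stage tests. Phylogenetic structure is not simulated.
* **Treatment-graded network complexity.** Per-treatment subnetwork
  differences are created by silencing planted modules in chosen
  treatments (the module's taxa drop below the within-treatment
  prevalence rule there). The default pipeline world silences two fungal
  modules under NPK and one under GM — fungal complexity rises
  NPK < GM < GMC — and one bacterial module under GMC, so bacterial
  complexity dips under co-amendment.
* **Mineralization.** Per-treatment 30-day cumulative targets default to
  2592 / 2934 / 3434 mg kg⁻¹ (NPK / GM / GMC) with a first-order decay
  of the daily rate (k = 0.05 d⁻¹; k = 0 gives a constant rate and an
  exactly linear *Cum*). In the default pipeline world each jar's total
  is additionally multiplied by exp(2·Δ), where Δ is the sample's C1
  proportion centered within its treatment — the within-treatment
  DOC-composition signal the driver stage is meant to detect — leaving
  treatment means at their targets. Titration noise (sd 0.05 mL) maps
  through the trap stoichiometry to ≈ 4 mg kg⁻¹ per interval.

**What passing tests show — and what they do not.** The generator
produces exactly trilinear fluorescence, monotone module associations,
and exchangeable noise. Recovery there demonstrates the implementation
is correct (the estimators find planted truth at the stated noise), not
that the methods are robust to inner-filter distortion, compositional
artifacts of relative abundances, overdispersed counts, or confounded
designs. In particular, Spearman co-occurrence networks are not
compositionality-aware (SparCC/SPIEC-EASI-style inference is out of
scope), and ACC broadcast to samples remains pseudo-replicated however
well the tests behave.

# Reproducibility and problem sizes

One global seed drives everything; per-stage seeds are derived by
hashing the stage name (FNV-1a folded into the seed modulo 2³¹−1), so
stages are decoupled but fully determined. Two runs with the same
configuration produce byte-identical reports (the run report records an
md5 of its own JSON).

Default analysis sizes used throughout the documentation and tests:
24-sample EEM cubes (51 × 351 grid), 300-taxon bacterial and 120-taxon
fungal tables, 999 PERMANOVA permutations, 199 association
permutations, 300–500 trees and 30–50 importance permutations for the
forest. Calibration studies in the test suite use 800 null simulations
per permutation test at 199 permutations each, enough to pin the
nominal 5% rejection rate within about one percentage point.

# Known limitations

* Rank selection is the user's (default 3); core-consistency diagnostics
  are not implemented.
* No inner-filter correction or absorbance-based indices (SUVA254).
* Networks are undirected, unsigned in topology, and built from rank
  correlations; keystone metrics beyond degree and ACC are out of scope.
* The VPA's "CCA-based" lineage degenerates, for a univariate response,
  to ordinary regression R²; with 8 predictors and 24 samples the
  unadjusted fractions are optimistic — the adjusted flag exists for a
  reason.
* Significance letters for per-treatment topology tables (which require
  replicate networks or bootstrapping) are not produced.
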