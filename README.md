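# soilCNet

Linking dissolved organic matter (DOM) fluorescence composition and
microbial co-occurrence network complexity to soil carbon
mineralization.

`soilCNet` is an R package for soil biogeochemists and microbial
ecologists analyzing incubation studies of the common
fertilization-treatment type (e.g. inorganic NPK vs green manure vs
green manure + biochar, with replicated pots). It implements the full
analysis chain from raw instrument output to driver attribution:

1. **Alkali-trap titration → CO2-C.** Residual-NaOH titration volumes
   are converted to interval CO2-C by
   `CO2-C (mg kg⁻¹) = (V_blank − V_sample) · M_HCl / 2 · 12.01 / m_soil`
   (BaCl2 precipitation means 2 mol NaOH per mol CO2), and cumulative
   mineralization *Cum* is the running sum over the 1, 3, 5, 7, 10, 15,
   20, 25, 30 d sampling schedule.
2. **EEM correction and indices.** Excitation–emission matrices (ex
   200–450 nm / 5 nm, em 250–600 nm / 1 nm) are Raman-normalized to the
   blank's Raman peak area (ex 350 nm), blank-subtracted, and
   scatter-excised. Scalar indices: BIX = F₍em380₎/F₍em430₎ at ex 310
   (autochthonous DOC above 0.8), HIX = Σ F₍em435–480₎ / (Σ F₍em300–345₎ +
   Σ F₍em435–480₎) at ex 254 (a proportion in [0, 1]), and FI =
   F₍em450₎/F₍em500₎ at ex 370.
3. **Non-negative PARAFAC.** The corrected cube is decomposed as
   X₍ijk₎ ≈ Σᵣ aᵢᵣ bⱼᵣ cₖᵣ with non-negativity on all three modes,
   missing (excised) cells carrying zero weight, multi-start alternating
   least squares (exact small-rank NNLS in C++), split-half validation
   by Tucker congruence (pass: TCC > 0.95 on both modes), Fmax
   quantification, and local spectral-library matching.
4. **Community structure.** Relative abundance at any taxonomic rank,
   Bray–Curtis distances, principal coordinates, and one-way PERMANOVA
   (Adonis) with permutation p-values.
5. **Co-occurrence networks.** Prevalence filter (present in > half the
   samples), all pairwise Spearman correlations, Benjamini–Hochberg FDR
   (edges at adjusted p < 0.01), per-treatment subnetworks, topology
   (nodes, edges, signed edge counts, average degree, average clustering
   coefficient — the network-complexity proxy), Louvain modules, module
   eigengenes (first PC of z-scored member abundances), and
   eigengene–environment Pearson/Mantel tests.
6. **Driver attribution.** Permutation random-forest importance
   (%IncMSE with per-predictor and whole-model permutation p-values)
   and variance partitioning of *Cum* between a DOC block and a
   network-complexity block (unique/shared/residual fractions), plus
   per-predictor shares within each block.

A seeded synthetic-data generator (`synthDesign()`, `simulateEEMs()`,
`simulateCommunity()`, `simulateTitration()`) emulates the 3-treatment ×
8-replicate design with known ground truth — component spectra, sample
scores, planted correlation modules, emission curves — so every stage is
testable against truth.

## Worked example

```r
library(soilCNet)
report <- runPipeline(pipelineConfig(seed = 1))
print(report)
```

```
soilCNet run report (seed 1 )
- cumulative mineralization (mg/kg):
 treatment n  meanCum    seCum
        GM 8 2951.238 90.11829
       GMC 8 3450.507 97.63939
       NPK 8 2596.989 55.21966
- PARAFAC: 3 components, explained variance 0.9993
  split-half pass: TRUE
- bacteria network: 130 nodes, 1163 edges, ACC 0.750, Q 0.750
- fungi network: 75 nodes, 339 edges, ACC 0.583, Q 0.681
- drivers: top RF predictor C1; VPA unique DOC 0.280 / unique net 0.020 / shared 0.697
```

Reading the output: cumulative mineralization is highest under the
co-amended treatment (GMC > GM > NPK, mean ± SE over 8 jars); the
3-component PARAFAC model explains 99.9% of the fluorescence variance
and passes split-half validation; both co-occurrence networks are
summarized by their topology (ACC = average clustering coefficient,
Q = modularity); and the driver stage attributes *Cum* variation mostly
to the shared effect of DOC composition and network complexity, with
the microbial humic-like component (C1) the top random-forest
predictor.

Individual stages are exported and composable, e.g.

```r
d    <- synthDesign(seed = 1)
sim  <- simulateEEMs(d)
corr <- correctEEMs(sim$cube, sim$blank)
fluorescenceIndices(corr)          # BIX / HIX / FI per sample
m    <- fitParafac(corr, nComponents = 3, seed = 1)
computeFmax(m, relative = TRUE)    # component proportions per sample
```

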