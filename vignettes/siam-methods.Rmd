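---
title: "Models and methods behind siampeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind siampeat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siampeat)
```

`siampeat` analyses stable isotope-assisted metabolomics (SIAM) experiments
in which ¹³C-labeled plant litter is incubated with peat, together with the
CO₂ flux partitioning that accompanies such incubations. This vignette
documents the models, their assumptions, the tunable parameters, and the
numerical decisions, in the order the pipeline runs them.

## The labeling model

Every molecule is treated as a string of carbon atoms that are
independently heavy (¹³C) or light. A compound with `nC` carbons and
per-carbon heavy probability `q` therefore shows a **binomial isotopologue
envelope**: the proportion of molecules carrying `k` heavy atoms is
`Binomial(nC, q)` at `k`, and the k-th isotopologue sits at the neutral
mass plus `k × 1.0033548` Da. Uniform labeling is an assumption — real
biosynthesis can label positions unevenly — but it is the standard SIAM
working model and it is what makes enrichment identifiable from the
envelope mean.

Two probabilities must not be confused:

- the **tracer probability** `p` (a litter compound grown under ¹³CO₂ has
  `p = 0.524`, i.e. 52.4 atom percent);
- the **observable probability** `q = p + (1 − p) · p_nat`, because
  non-tracer positions still carry natural-abundance ¹³C
  (`p_nat = 0.0107`). `total_heavy_probability()` performs this
  composition.

Natural-abundance correction removes the `p_nat` part again: the observed
envelope satisfies `f_obs = C f_corr` with
`C[i, j] = Binomial(nC − j, p_nat)` evaluated at `i − j` (a molecule with
`j` tracer atoms picks up `i − j` natural heavy atoms among its remaining
positions). `C` is lower-triangular and column-stochastic, and the
composition is exact: convolving `Binomial(nC, p)` with natural abundance
gives `Binomial(nC, q)`. Correction solves the linear system by
**non-negative least squares** (`pracma::lsqnonneg`) rather than plain
inversion, so corrected envelopes can never go negative under noise; the
solution is renormalized to sum to 1. The round trip
forward-convolve → correct is exact to ≈ 10⁻⁸ across the `(nC, p)` grid
the tests sweep.

Fractional enrichment is then `100 · Σ k f_corr,k / nC` atom percent —
exactly `100 p` on a noiseless envelope.

## Estimating the carbon count

The correction needs `nC`, which annotation would normally supply. Without
annotation it must come from the envelope itself, and the two labeling
regimes behave very differently:

- **Labeled envelopes** concentrate mass near `k ≈ nC·q`, so the envelope
  *shape* pins `nC` down. `estimate_n_carbon()` grid-searches the
  chemically plausible range (between mass/30 and mass/12 carbons,
  bounded below by the largest observed shift) and picks the count whose
  corrected envelope is closest to a binomial at its own mean probability.
  A raw deconvolution residual cannot do this — any `nC` at least the
  largest observed shift fits the data essentially exactly — which is why
  the residual is defined against the binomial shape.
- **Natural envelopes** are in the Poisson limit (`nC·p_nat` small), where
  only the product `nC·p_nat` is identifiable. `analyze_clusters()`
  therefore tests the natural hypothesis first: a least-squares fit of the
  natural envelope over the observed isotopologue support (restricted and
  renormalized, so tails truncated by the intensity threshold do not bias
  it). If the best-fitting natural count is chemically admissible — with a
  20 % + 2 allowance above the mass/12 cap for fit noise; any tracer level
  that allowance could absorb sits below the 2 % call threshold anyway —
  and the relative residual is ≤ 0.15, the cluster is treated as
  unlabeled-consistent and corrected at that count (choosing, within ±4 of
  the fit, the count that leaves the least residual tracer mass: the most
  parsimonious explanation). Otherwise the heavy excess is beyond anything
  natural and the labeled-shape estimator takes over.

The cluster envelope itself is estimated robustly: per-sample envelope
proportions are averaged over *complete* samples (none of the cluster's
members zeroed by missingness), falling back to a per-sample median. A
single missing cell in a high-abundance sample otherwise corrupts an
intensity-summed envelope badly enough to flip label calls.

A cluster is **called labeled** when the corrected envelope carries at
least `min_incorporation = 2 %` of its mass above `k = 0` and the cluster
has at least two members. On the generator's default tables this call
matches ground truth exactly without noise and reaches ≥ 0.95 sensitivity
and specificity at default noise.

## Flux partitioning

Total CO₂ flux from an amended jar is modeled as a two-end-member mixture.
With `R_net` the observed ¹³CO₂/CO₂ atom fraction, `R_soil` the mean ratio
of the unamended jars that day, and `R_litter` the litter ratio (taken as
a parameter; the bulk litter enrichment 0.524 by default, since the data
to derive a CO₂-specific value is not part of the pipeline):

- litter respiration `= F_net (R_net − R_soil)/(R_litter − R_soil)`,
- peat respiration `= F_net −` litter respiration,
- priming `=` PL peat respiration `−` mean PO total flux that day.

All ratios are atom fractions of total carbon; δ-valued inputs are
converted at the IO boundary (`delta_to_atom_fraction()`, VPDB ratio
0.0111802). `R_soil` is computed **per sampling day**, not pooled, because
priming is a time-resolved claim. Mixtures that fall outside `[0, F_net]`
are clamped with a warning instead of rejected — replicate noise around
pure end-members is expected. Days with no PO observation are flagged and
skipped, never interpolated. Cumulative components use trapezoidal
integration over the sampling days (1, 3, 5, then every 5 days to 40).
Fluxes carry the unit µmol CO₂ g⁻¹ dry peat d⁻¹ in file headers and are
never silently converted.

## Multivariate and discriminant statistics

Compound-level abundances (cluster member intensities summed per sample —
at this level labeled and unlabeled jars are genuine analytical
replicates, because the tracer only redistributes intensity across a
compound's isotopologues) are median-normalized per sample (nonzero
median, rescaled by the grand median), Pareto-scaled per feature
(centered, divided by √SD with the n−1 SD; constant features map to 0),
and compared by Manhattan distances. Zeros are kept as true zeros.

PCoA is classical metric scaling (Gower double-centering,
eigendecomposition, coordinates scaled by √eigenvalue); negative
eigenvalues — expected for Manhattan distances — are reported but excluded
from variance proportions, with no Cailliez correction. Hierarchical
clustering defaults to average linkage (the linkage is configurable; no
single convention dominates for this data type). PERMANOVA uses Anderson's
distance-based pseudo-F with the `(1 + b)/(1 + m)` permutation estimator so
p is never 0; `vegan::adonis2` does the computation behind the
`permanova()` surface, and the tests verify it against a direct
sums-of-squares oracle and exhaustive enumeration on a 4-sample case. The
pipeline exposes one-way tests per factor (sample type, time, and their
combination).

The discriminant stage couples the LC-MS and NMR blocks to a PO/PL class
outcome by multiblock sparse PLS-DA (`mixOmics::block.splsda` behind
`fit_multiblock_splsda()`): blocks are scaled internally, data blocks are
coupled to each other with `design_weight = 0.1` and to the outcome with
weight 1, sparsity keeps the `keep_per_block = c(20, 6)`
largest-magnitude loadings per component, blocks are deflated by
regression on their own scores, and initialization is the leading singular
vector of each block's cross-covariance with the outcome, making the fit
deterministic. Two components are fitted by default; discriminants are
ranked by absolute component-1 loading with alphabetical tie-break.
Fold-change trajectories are `log2((mean + ε)/(ref mean + ε))` against
peat-only at T0, with ε = half the smallest nonzero value.

## What the generator emulates — and what it does not

The generator reproduces the incubation design: 28 samples (litter-only at
T0; peat-only, unlabeled, at T0–T3; peat+litter at T0–T3; labeled and
unlabeled amendments each in duplicate — the harvested subset matches the
18 incubated jars), litter at 52.4 atom-% tracer, feature masses 100–1200
Da, an NMR-style block of 45 metabolites (32–355 Da, 40 % labeled), and
flux sampling on days 1, 3, 5, …, 40.

Abundance dynamics per origin pool: litter compounds decay exponentially
in PL jars (default 0.05 d⁻¹, a ~14-day half-life, so litter metabolites
persist to day 40); microbial products pulse as `A·(t/τ)·exp(1 − t/τ)`
(amplitude 10, τ = 5 d — peaking just before the day-7 harvest and largely
decayed by day 18), which is what makes the amended samples at T1 stand
apart in ordination; peat-native compounds are constant; peat-primed
compounds decline in PL only (0.05 d⁻¹), falling below their T0 level by
day 40. Base abundances are log-normal around 2×10⁸ — the emulated pool
is the *detected* features, which by construction sit above the 2×10⁶
detection threshold even after the envelope spreads intensity across many
isotopologues. The flux series uses baseline 2, litter component
8·exp(−0.1 t), and a priming pulse `0.4·t·exp(−t/7)` (peak ≈ 1 µmol g⁻¹
d⁻¹, ~13 % of peak flux: a transient positive pulse resolvable at the
default 10 % observation noise with two jars per treatment). Flux noise is
applied per component as mean-preserving log-normal before the mixture is
formed, so the mixing model is exact in expectation and unbiasedness is a
meaningful property.

An isotopologue becomes a feature row when its expected proportion exceeds
10⁻⁴ (an emission floor standing in for detector dynamic range); noise
rows, ppm mass error, RT jitter, intensity CV and per-cell missingness
(missing = zero, the sparse-table convention) are configurable. An
enrichment SD across litter compounds is exposed but defaults to 0: field
labeling is certainly heterogeneous, but no value is available to
calibrate it, so uniformity is the documented default rather than a
guess.

What the generator does **not** emulate: chromatographic peak shapes,
adducts and in-source fragments, correlated (batch) intensity error,
annotation databases, and NMR spectra (the NMR block enters as a
concentration table only). Passing tests therefore demonstrate the
*algorithms* recover known truth under the stated noise model — not that
real palsa peat behaves like the generator.

## Numerical choices and degenerate inputs

- Mass filter inclusive on both bounds; S/N strictly greater than 3.
- RT pairing window 0.2 min (tight against a 70-min gradient); 5 ppm mass
  tolerance, evaluated on the heavier feature's mass; greedy clustering
  seeds at the lowest unassigned mass, a member matching several k values
  takes the smallest ppm error, and duplicate k candidates start their own
  cluster.
- The labeled/unlabeled call threshold (2 % incorporation) is a documented
  stand-in: the vendor workflow's diagnostic-ratio rule is proprietary and
  no numeric criterion is published.
- Percentages in detection summaries round half-up to 2 decimals.
- Empty tables filter to empty tables; an empty feature set aborts the
  pipeline at the clustering stage by name; a sample with no nonzero
  values fails median normalization explicitly; `nC = 0` with a
  multi-member envelope signals an inconsistent carbon count; masses below
  12 Da are rejected as non-organic.
- All randomness flows from one root seed, split per pipeline stage
  (`stage_seed()`); manifests record per-stage seeds and output checksums,
  and two runs with the same seed are checksum-identical.

## Problem sizes

The test suite and the acceptance script run at deliberately desk-friendly
sizes chosen to keep every statistical check sharp: 40–120 synthetic
species per table, 200 envelopes at 10⁴ ions for enrichment recovery, 10
seeds for flux unbiasedness, 1000 null datasets × 199 permutations for
PERMANOVA calibration, and 8–10 planted-effect fits for discriminant
recovery. The planted effect for those fits is a +2 SD mean shift on 20
MS and 6 NMR features — "moderate noise" quantified once and used
throughout.

## Known limitations

- Carbon counts of unlabeled compounds are fundamentally unidentifiable
  from their envelopes (Poisson limit); the reported estimate for such
  clusters is the natural-fit value clamped to the chemical range and
  should not be over-interpreted.
- Enrichment estimates for clusters pooled across labeled *and* unlabeled
  jars are mixture means, not per-jar tracer levels; use labeled-sample
  subsets when per-jar enrichment matters.
- The two-pool flux model assumes exactly two end-members with known,
  constant ratios; a CO₂-specific litter ratio, if measured, should be
  passed as `r_litter`.
- `fit_multiblock_splsda()` supports two classes; keep values are
  parameters, not tuned by cross-validation.
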