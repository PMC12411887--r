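# siampeat

Stable isotope-assisted metabolomics (SIAM) and CO₂ flux partitioning for
litter-amendment incubation experiments in peat.

## The problem

When ¹³C-labeled plant litter is incubated with soil or peat, every
litter-derived metabolite shows up in LC-MS data as an *isotopologue
cluster*: a set of co-eluting features at exact mass shifts of
k × 1.0033548 Da whose intensity envelope encodes how much tracer carbon the
molecule carries. In parallel, the ¹³CO₂/CO₂ ratio of the headspace
partitions total respiration between the labeled litter and the unlabeled
native peat, which is what makes *priming* (amendment-induced change in
native organic-matter decomposition) quantifiable. `siampeat` implements
this entire analysis as composable, tested R functions for:

- **Feature filtering** — masses 100–1200 Da, minimum intensity 2×10⁶,
  signal-to-noise > 3.
- **Isotopologue detection** — greedy RT + exact-mass-shift clustering
  (5 ppm), natural-abundance correction by non-negative least squares
  (solving `f_obs = C f_corr`, where `C[i,j] = Binom(nC−j, p_nat)` at
  `i−j`), carbon-count estimation, and fractional ¹³C enrichment
  `100 · Σ k f_corr,k / nC` in atom percent, with a labeled/unlabeled call
  per cluster.
- **Two-pool flux partitioning** — litter respiration
  `F_net (R_net − R_soil)/(R_litter − R_soil)`, peat respiration as the
  complement, and priming as PL peat-derived flux minus the PO total flux,
  with per-day `R_soil` from the unamended jars and trapezoid-integrated
  cumulative components.
- **Multivariate statistics** — median normalization, Pareto scaling,
  Manhattan-distance PCoA, average-linkage hierarchical clustering, and
  one-way PERMANOVA with the (1+b)/(1+m) permutation p-value.
- **Multiblock sparse PLS-DA** — N-integration of the LC-MS and NMR blocks
  against a PO/PL class outcome, ranked discriminant features, and log₂
  fold-change trajectories relative to peat-only at T0.
- **A synthetic-data generator** with full ground truth (species, per-sample
  abundances, envelope parameters, flux decomposition) emulating the
  incubation design — 3 treatments (LO litter-only, PO peat-only, PL
  peat+litter), timepoints T0/T1/T2/T3 = days 0/7/18/40, labeled and
  unlabeled amendments in duplicate, litter at 52.4 atom-% ¹³C, and gas
  sampling on days 1, 3, 5, then every 5 days to day 40 — so the whole
  pipeline is testable without instrument data.

## Worked example

```r
library(siampeat)

cfg <- run_config(seed = 1, n_species = 120, outdir = "siam_demo")
man <- run_pipeline(cfg)
```

The run writes every stage's tables under `siam_demo/`. Highlights from this
exact run:

```
# detection_summary.csv
  category count   pct
     total  1023 100.0
   labeled   710  69.4
```

1023 isotopologue features survive the filters; 710 of them belong to
clusters called isotopically labeled (69.4 % — high, because each labeled
compound contributes many isotopologue rows).

```
# permanova.csv
               factor  pseudo_f p_value n_permutations
            treatment 15.511184   0.001            999
            timepoint  6.568586   0.001            999
  treatment_timepoint 52.001543   0.001            999
```

Sample type and time both structure the compound-level metabolome
(Manhattan distances on median-normalized, Pareto-scaled abundances).

```
# flux_partition.csv (jar PL_J1, first days)
  day r_soil r_litter f_net litter_flux peat_flux priming_flux
    1 0.0108    0.524 9.995       7.255     2.739       0.6092
    3 0.0108    0.524 8.460       5.852     2.607       0.6415
    5 0.0108    0.524 6.882       4.206     2.675       0.6435
   10 0.0108    0.524 6.325       3.117     3.208       1.2397
```

Early respiration is litter-dominated; the peat-derived component exceeds
the unamended baseline around the pulse (positive priming), and
`flux_cumulative.csv` integrates each component over the 40-day incubation
(here ≈ 72 µmol g⁻¹ litter-derived vs ≈ 18 µmol g⁻¹ priming per jar).

The thin CLI wrapper does the same from a shell:

```sh
Rscript inst/cli/siam-pipeline.R run-all --seed 1 --outdir siam_demo
```

## Package layout

- `R/` — generator (`generate_species`, `generate_feature_table`,
  `generate_nmr_block`, `simulate_flux_series`), SIAM core
  (`filter_features`, `cluster_isotopologues`, `natural_abundance_correct`,
  `estimate_n_carbon`, `estimate_enrichment`, `classify_labeled`,
  `analyze_clusters`, `summarize_detection`), flux module
  (`delta_to_atom_fraction`, `litter_respiration`, `partition_series`),
  statistics (`median_normalize`, `pareto_scale`, `manhattan_distance`,
  `pcoa`, `hierarchical_cluster`, `permanova`, `fit_multiblock_splsda`,
  `rank_discriminants`, `log2_fold_change`), and IO/pipeline
  (`read_feature_table`, `run_config`, `run_pipeline`, `write_report`).
- `vignettes/siam-methods.Rmd` — the model, its assumptions, and the
  numerical choices.
- `tests/testthat/` — unit, property and end-to-end suites with brute-force
  oracles.
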