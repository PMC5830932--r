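# tfchrono

Time-resolved analysis of pioneer-transcription-factor-driven chromatin
and expression dynamics.

A pioneer factor (EBF1 in early B-cell development is the motivating
system) binds target sites in closed chromatin and sets off a local
cascade: chromatin opening, histone-mark remodelling, delayed CpG
demethylation, recruitment of secondary factors such as Pax5, and
reprogramming of nearby genes. Given time-course assays — TF ChIP-seq
peaks, ATAC-seq Tn5 cut counts, WGBS methylation calls and FPKM
expression tables over 0 h / 24 h / 72 h / pro-B (plus an optional 6-h
point) — `tfchrono` answers, as tested R functions:

* **Which sites are bound when?** Replicate-consensus peaks are unified
  into a site catalog; each site gets one of five temporal classes:
  `preexisting` (accessible before induction, occupied from 24 h),
  `gain24` / `gain72` / `gainproB` (persistent, by gain time), or
  `transient` (occupied at 24/72 h, lost at pro-B).
* **How does accessibility follow binding?** RPKM signal matrices
  (±3 kb, 50-bp bins; RPKM = count × 10⁹ / (bin · total fragments)),
  five-cluster accessibility classification, central-dip profiles, and
  the fraction of TF sites inside ATAC-peak clusters.
* **When is DNA demethylated?** Low-methylated regions (runs of ≥4 CpGs
  at 10–50% methylation), ±100-bp site methylation, and per-class medians
  of the 72h−0h and proB−72h changes (cloud-map tables).
* **Who else binds?** A strand-aware Tn5 protection score
  (−log10 p_fwd − log10 p_rev from binomial lower tails of footprint vs
  shoulder cuts at p₀ = w/(w+s)), shuffle-calibrated footprint calls,
  PWM motif scanning, footprint-anchored motif occupancy over time, and
  pairwise motif co-occurrence enrichment (Fisher, BH) between time
  points.
* **Which genes respond, and how?** Differential genes (fold change > 2,
  p < 0.01 from a moderated t-test on log2(FPKM+0.1), FPKM ≥ 1 at either
  end), ±25-kb nearest-TSS site–gene links, >10-fold vs 2–10-fold
  amplitude strata, and short-time-series clustering against integer-step
  model trajectories with permutation significance.
* **Which secondary-factor sites need the pioneer?** The four-way
  classification of Pax5-like sites by pro-B co-occupancy × occupancy in
  a pioneer-free induction sample, with accessibility summaries.

A synthetic multi-omic generator (`generate_genome()` and friends) plants
all of the above with known truth at toy-genome scale (2 Mb, 500 sites,
200 genes by default), so the entire chain runs and is validated end to
end with no external data.

## Worked example

```r
library(tfchrono)

genome <- generate_genome(n_sites = 500, seed = 2024)
noise  <- noise_model(peak_dropout_prob = 0.05)
chip <- generate_timecourse_peaks(genome, noise, n_replicates = 2, seed = 2025)
atac <- generate_timecourse_peaks(genome, noise, assay = "atac",
                                  n_replicates = 2, seed = 2026)
catalog <- classify_temporal(
  build_site_catalog(lapply(chip, replicate_consensus)),
  accessible_0h = replicate_consensus(atac[["0h"]]))
print(catalog)
#> site_catalog: 451 sites x 4 time points (0h, 24h, 72h, proB)
#>      gain24      gain72    gainproB preexisting   transient
#>          99          83          92          85          92
```

451 of the 500 planted sites survive 5% per-replicate dropout and the
two-replicate consensus; the recovered class counts track the planted 100
per class. Methylation dynamics at LMR-associated sites then show the
expected contrast — pronounced pro-B demethylation only where occupancy
persists:

```r
meth <- generate_methylome(genome, noise, seed = 2027)
lmrs <- call_lmrs(meth[["proB"]])
dyn <- methylation_dynamics(lapply(meth, site_methylation, catalog = catalog),
                            catalog, lmrs)
print(dyn$summary, digits = 2)
#>         class  n median_delta_72h_0h median_delta_proB_72h
#> 1      gain24 98              -0.136               -0.4294
#> 2      gain72 83              -0.151               -0.4360
#> 3    gainproB 92              -0.140               -0.4367
#> 4 preexisting 63              -0.028               -0.0163
#> 5   transient 59              -0.143                0.0069
```

Persistent classes lose ~0.43 methylation between 72 h and pro-B (planted
0.65 → 0.20), transient sites stay flat (planted 0.65 → 0.65), and
pre-existing sites were hypomethylated all along.

## Analysis workflow

The `analysis/` directory holds the full narrative as numbered drivers
over the package functions; each regenerates its inputs deterministically
and writes tables under `results/analysis/`:

```sh
Rscript analysis/00_run_all.R        # or any single step:
Rscript analysis/02_occupancy_classes.R
```

1. `01_simulate` — toy genome and multi-omic time course, truth tables
2. `02_occupancy_classes` — site catalog, five temporal classes, 6-h overlap
3. `03_accessibility_signal` — signal matrices, accessibility clusters, motif fractions, ATAC-cluster site frequencies
4. `04_methylation_dynamics` — LMRs, cloud-map table, per-class deltas
5. `05_footprints_cooccurrence` — footprint calls, motif occupancy over time, co-occurrence enrichment
6. `06_expression_clusters` — differential genes, strata, site–gene links, trajectory clusters
7. `07_dependency` — pioneer-dependence classification of secondary-factor sites

An end-to-end configurable run with a manifest is also available as
`run_pipeline(default_config(seed = 1), "outdir")`.

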