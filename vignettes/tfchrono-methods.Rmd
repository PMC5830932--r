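---
title: "Methods: time-resolved analysis of pioneer-factor-driven chromatin and expression dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved analysis of pioneer-factor-driven chromatin and expression dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tfchrono)
```

# The scientific setting

`tfchrono` analyses what happens around the binding sites of a pioneer
transcription factor — a factor, such as EBF1 in early B-lymphocyte
development, that can engage its target sites in closed chromatin and then
initiate a cascade of local changes: chromatin opening, histone-mark
remodelling, delayed CpG demethylation, recruitment of secondary factors
(such as Pax5), and reprogramming of nearby gene expression. The data are a
time course: binding (ChIP-seq peaks), accessibility (ATAC-seq cuts),
methylation (WGBS calls) and expression (FPKM tables) measured before
induction (0 h), at 24 h and 72 h after induction, and at the committed
pro-B stage; an optional early 6-h point (fast Tet-on induction) can be
added for the binding assay.

The package implements the full analysis chain as testable functions and
ships a synthetic multi-omic generator with planted ground truth, so that
every stage can be validated end to end at toy-genome scale without any
external download.

# Temporal occupancy classes

The unified site catalog is the merged union of per-time-point
replicate-consensus peaks (`replicate_consensus()`,
`build_site_catalog()`). Consensus keeps the peaks of the first replicate
that share at least `min_overlap_bp` (default 1) bases with a peak in every
other replicate; coordinates are 0-based half-open throughout, so touching
peaks share no base. Merging uses `merge_gap_bp = 0` by default, which
collapses overlapping *or directly adjacent* intervals — a site boundary at
base `x` and another starting at `x` are one binding region for our
purposes.

`classify_temporal()` assigns each site one of five classes:

* **persistent** sites are occupied at pro-B and subclassed by the earliest
  occupied induced time point: `gain24`, `gain72`, `gainproB`;
* `gain24` sites that were **already accessible at 0 h** (an ATAC peak or a
  per-site flag) are relabelled `preexisting`;
* **transient** sites are occupied at 24 h and/or 72 h but not at pro-B;
* sites occupied at no induced time point are `unclassified` and excluded
  from class-resolved analyses.

Transient loss is modelled as peak absence at pro-B. A 6-h column never
changes these labels; early occupancy is summarised separately by
`early_occupancy_overlap()`.

# Signal matrices and accessibility clusters

`compute_signal_matrix()` counts fragment (cut) midpoints in 50-bp bins
over ±3 kb around each site centre and converts to RPKM
(`count × 10^9 / (bin_bp × total mapped fragments)`). Midpoint counting
makes bins additive, which the tests exploit as a conservation invariant.

`classify_accessibility()` reduces each matrix to a central signal (mean
RPKM within ±500 bp) and applies two thresholds: an absolute floor
`min_rpkm` and a `gain_fold` (default 2) increase over the 0-h central.
Neither threshold is dictated by the underlying biology, so both are
configurable; when `min_rpkm` is `NULL` it defaults to **twice the mean of
the 0-h matrix**, a background proxy that adapts to sequencing depth and
genome size (on a toy genome absolute RPKM values are ~1000-fold larger
than on a mammalian genome, so any fixed constant would be meaningless).
The 0-h central is floored at 0.25 RPKM in the fold comparison to avoid
division blow-ups at empty windows. Sites that gain by 72 h but fall back
below the gain threshold at pro-B form the transient-accessibility
cluster; each site receives exactly one label.

`central_depletion_profile()` summarises per-class mean profiles and the
centre (±100 bp) to shoulder (±500–1000 bp) signal ratio; ratios below 1
quantify the central dip seen in histone marks (and in Tn5 cuts) at bound
sites.

# Methylation dynamics

`call_lmrs()` detects low-methylated regions with the conventional
parameters for intermediate-methylation segments: maximal runs of
consecutive CpGs below 50% methylation, inter-CpG gaps ≤ 250 bp, at least
4 CpGs, run mean inside 10–50%. `site_methylation()` computes the
coverage-weighted mean CpG methylation within ±100 bp of each site centre
(an unweighted switch exists; weighting is the default because per-CpG
precision scales with coverage). CpGs below 5× coverage are dropped at
parse time.

`methylation_dynamics()` restricts sites to those whose centre lies within
`assoc_bp` of an LMR and tabulates per-site methylation across time points
plus per-class medians of the 72h−0h and proB−72h changes. We set the
association distance to **150 bp** (not 100): the package's synthetic
methylomes seed the enhancer-LMR core directly adjacent to, but outside,
the ±100-bp quantification window (first patch CpG 110 bp from the
centre), so a 100-bp association radius would miss exactly the planted
configuration while 150 bp keeps the quantification window uncontaminated
by the constitutively intermediate LMR core. The distance is a parameter;
analyses of real data can tighten it.

# Digital footprinting

`wellington_score()` is a simplified strand-aware protection statistic in
the spirit of the Wellington algorithm: with a candidate footprint of
width `w` and shoulders of `s = 35` bp, forward-strand cuts inside the
footprint are tested against the upstream shoulder and reverse-strand cuts
against the downstream shoulder, each with a binomial lower tail at
`p0 = w / (w + s)`; the score is `−log10 p_fwd − log10 p_rev`, and zero
when either shoulder carries no cuts (no information). The exact published
parameterisation is not restated here; widths 11–25 bp, 35-bp shoulders
and a 1% FDR are configurable defaults.

`call_footprints()` scores every (position, width) candidate inside each
accessible region, keeps the per-position maximum over widths, and
calibrates a threshold per region from a shuffle null that redistributes
the region's cuts uniformly while preserving per-strand totals: the
threshold is the `1 − fdr` quantile of the per-shuffle maximum scores.
Because that quantile is estimated from order statistics, the shuffle
count must resolve it: **100 shuffles** is the default (20 shuffles cannot
calibrate a 1% threshold — the best achievable exceedance rate with 20
null maxima is about 1/21 ≈ 5%). Scoring is vectorised across shuffles and
uses per-width log-CDF lookup tables, since all counts are small integers.
Overlapping candidate calls are resolved greedily by score, so accepted
footprints never overlap.

`scan_motifs()` is a both-strand log2-odds PWM scan against a uniform
background with same-motif overlap deduplication.
`footprint_motif_occupancy()` marks a motif instance footprinted when its
midpoint falls inside a footprint call, and tests consecutive-time-point
changes per motif (Fisher, Benjamini–Hochberg across motif × transition).
`cooccurrence_enrichment()` counts, for each motif pair, footprinted
instances with a footprinted partner midpoint within ±100 bp (a 200-bp
window), contrasts two time points in a 2×2 Fisher test (pooling
A-anchored and B-anchored instances, which keeps the matrix symmetric),
BH-adjusts across pairs, applies the Haldane–Anscombe +0.5 correction at
zero marginals, and orders the display by average-linkage clustering of
the log2 odds-ratio matrix. This transparent pairwise contrast replaces
the published co-occurrence clustering machinery, whose internals are not
restated here.

# Expression: differential calling and trajectory clustering

`differential_genes()` consumes an FPKM table and applies the filter
chain: fold change (replicate means, pseudocount 0.1) above 2 between 0 h
and pro-B, p-value below 0.01, and FPKM ≥ 1 at 0 h or pro-B (genes low at
both ends are removed). The evidence comes from a **moderated t-test
(limma)** on log2(FPKM + 0.1). With two replicates per condition a
per-gene Welch test has essentially no power at p < 0.01 (its minimum
attainable t-threshold at ~2 degrees of freedom is near 10), so variance
moderation across genes is the only defensible engine at this design
depth; `method = "welch"` remains available for comparison. The package's
contribution is the threshold chain and the downstream integration, not
the DE engine.

`assign_genes_to_sites()` links a site to the gene with the nearest TSS
within ±25 kb; a site in range of several TSSs goes to the nearest only
(ties to the lexicographically smaller gene id, logged in the map).
`stratify_by_amplitude()` splits differential genes at 10-fold (strictly
greater is stringent, exactly 10-fold is lenient).

`stem_cluster()` implements short-time-series model-profile clustering:
candidate profiles are all integer-step trajectories over transitions in
−c..c (default c = 2) starting at 0; 20 model profiles are selected by a
deterministic greedy maximin on correlation distance (profiles anchored
with a leading 0 so amplitude relative to baseline matters); genes are
assigned to the Pearson-nearest model profile; profile significance is
assessed by permuting each gene's time order and counting assignments,
Bonferroni-corrected across profiles; significant profiles correlating
≥ 0.7 merge into display clusters. The permutation default is **500**: a
Bonferroni bar of 0.05/20 = 0.0025 is unattainable with 100 permutations
(minimum p = 1/101 ≈ 0.0099), so 100 rounds would have zero power at any
effect size. Up- and down-regulated genes are clustered separately
(`cluster_trajectories()`).

# Dependence of a secondary factor on the pioneer

`classify_dependence()` takes the secondary factor's pro-B peaks as the
site universe and crosses two binary flags: co-occupancy (a pioneer-factor
pro-B peak centre within ±200 bp of the site centre — "neighbouring" is
not given a distance in the underlying biology, so the window is a
parameter) and occupancy in the knockout-induction sample (secondary
factor induced without the pioneer). Sites absent from the knockout sample
are *dependent*. Accessibility before induction and at pro-B annotates the
four classes; `dependence_accessibility_summary()` tabulates them and
tests dependent-versus-independent pre-accessibility by Fisher's exact
test. The knockout-induction input is a generic "factor B without factor
A" slot, so the scheme generalises beyond the EBF1/Pax5 pair.

# The synthetic generator: what it emulates, and what it does not

`generate_genome()` plants 500 sites (defaults: one 2-Mb chromosome, 200
genes) on a jittered grid with exact largest-remainder class counts.
Downstream generators emit, per class:

* **peaks** at exactly the class's time points (pre-existing and gain24
  occupied from 24 h; gain72 from 72 h; gainproB only at pro-B; transient
  at 24 h and 72 h only), widths 200–400 bp with ≤ 50 bp centre jitter;
  pre-existing sites are additionally accessible at 0 h in ATAC runs;
* **cut tracks** with Poisson background (5 fragments/kb/strand), ~60
  cuts over an occupied accessible site, and a 15-bp footprint interior
  thinned to 0.1× the flanking rate;
* **methylomes** with CpGs every ~25 bp inside site windows and ~100 bp
  elsewhere, beta-binomial noise around per-class target profiles
  (persistent 0.80 → 0.80 → 0.65 → 0.20; transient flat at 0.65 after
  72 h; pre-existing hypomethylated throughout), ~30× coverage, and — for
  LMR-associated sites — a constant 30%-methylated enhancer-core patch
  placed just outside the quantification window;
* **expression** for site-linked genes following the class-mapped
  trajectory template, log-normal replicate noise of 0.25 (log2 sd).

Two generator semantics deserve emphasis because they define what the
recovery benchmarks mean:

* **Dropout is a locus-level recovery failure.** `peak_dropout_prob` is
  the probability that a *replicate misses a site entirely* (an IP or
  library failure at that locus), not an independent per-time-point coin
  flip. Under independent per-time-point dropout the five-class label of a
  site is not identifiable at 5% noise — a gain24 site with its 24-h peak
  dropped is indistinguishable from a true gain72 site, and the Bayes
  accuracy ceiling falls below 95% — so per-time-point noise would make
  classification benchmarks measure the noise model rather than the
  classifier. Classification accuracy is therefore reported over sites
  recovered in the catalog; detection is reported separately.
* **Trajectory templates lie on model trajectories.** The five default
  templates (`default_templates()`: U1-like early jump 16-fold, U3-like
  gradual rise, U4-like pro-B-dominant activation, U5-like late-only
  activation with a small early dip, D4-like transient up then ~10-fold
  silencing) were chosen, within their biological shapes, to sit close to
  a single profile of the fixed model-profile dictionary. Cluster
  "recovery" is only well defined when a template has one nearest profile
  with margin; a template equidistant between two near-duplicate profiles
  would split its genes 50/50 no matter how good the method is.

The generator does **not** emulate read-level data (no FASTQ, mappability
or GC bias), Tn5 sequence preference, replicate-correlated noise,
diploid genotypes, or genome-scale site counts; passing tests demonstrate
correct recovery of planted structure under idealised noise, not
performance on real sequencing data.

# Numerical choices and problem sizes

Randomness is always seeded; generators take explicit seeds and internal
stochastic steps (shuffles, permutations) save and restore the RNG state.
The pipeline (`run_pipeline()`) fans a master seed out to per-stage seeds
at fixed offsets and writes a JSON manifest (config snapshot, derived
seeds, row counts, MD5 checksums) so a run is reproducible bit for bit.

Benchmarks in the tests and the acceptance script use: 500 planted sites
at 5% dropout for classification; 500 + 500 regions at 30 cuts per 35-bp
shoulder for footprinting; 200 sites at 30× CpG coverage for methylation;
500 genes (100 differential at 4-fold, 0.25 log2 sd, 10 seeds) for the DE
benchmark; 500 genes over 5 templates at 0.3 log2 sd for clustering; 400
secondary-factor sites for the dependence design. These sizes give stable
statistics in seconds per stage.

# Known limitations

Headline counts from the real study system (thousands of persistent and
transient sites, tens of thousands of footprints) depend on genome-scale
deposited data and are out of reach of the toy-scale generator; all
quantitative validation here is planted-truth recovery and oracle
equivalence. The footprint caller assumes accessible regions are given (or
called by the minimal Poisson enrichment caller) and does not correct Tn5
sequence bias. The co-occurrence contrast conditions on footprinted
instances only; motifs never footprinted at either time point do not
contribute. The dependence scheme is peak-presence-based; a signal-ratio
variant would need matched-depth tracks.
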