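#!/usr/bin/env Rscript
# Step 6: differential expression between 0 h and pro-B (fold change > 2,
# p < 0.01, FPKM >= 1 at either end), the +/-25-kb nearest-TSS link between
# binding sites and genes, the >10-fold / 2-10-fold amplitude strata, and
# model-profile trajectory clustering of the differential genes.

suppressPackageStartupMessages(library(tfchrono))
outdir <- "results/analysis"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

SEED <- 2024L
genome <- generate_genome(n_sites = 500, n_genes = 200, seed = SEED)
noise <- noise_model(peak_dropout_prob = 0.05)
chip <- generate_timecourse_peaks(genome, noise, n_replicates = 2,
                                  seed = SEED + 1)
catalog <- classify_temporal(
  build_site_catalog(lapply(chip, replicate_consensus)))
expr <- generate_expression(genome, noise, seed = SEED + 7)

de <- differential_genes(expr)
message(sprintf("%d differential genes of %d (planted %d)", sum(de$de),
                nrow(de), sum(expr$truth$template != "flat")))
strata <- stratify_by_amplitude(de)
message(sprintf("amplitude strata: stringent (>10-fold) %d (%.0f%%), lenient %d (%.0f%%)",
                sum(strata$stratum == "stringent"),
                100 * mean(strata$stratum == "stringent"),
                sum(strata$stratum == "lenient"),
                100 * mean(strata$stratum == "lenient")))

map <- assign_genes_to_sites(catalog, expr$genes)
reg <- regulated_genes(map, de)
message(sprintf("%d differential genes have a binding site within 25 kb of the TSS",
                length(reg)))

clust <- cluster_trajectories(de, seed = SEED + 8)
for (dir in c("up", "down")) {
  if (is.null(clust[[dir]])) next
  st <- clust[[dir]]$profile_stats
  used <- st[st$count > 0, ]
  message(sprintf("%s-regulated: %d genes over %d used profiles (%d significant)",
                  dir, nrow(clust[[dir]]$assignment), nrow(used),
                  sum(st$significant)))
}

summ <- site_count_and_distance_summary(map, de)
message("site count / TSS distance comparisons vs unchanged genes:")
for (i in seq_len(nrow(summ$tests))) {
  t <- summ$tests[i, ]
  message(sprintf("  %-5s %-12s adj.p=%.3g", t$group, t$measure,
                  t$adjusted_p))
}

write.table(de, file.path(outdir, "differential_genes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(strata, file.path(outdir, "amplitude_strata.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(map, file.path(outdir, "site_gene_map.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (dir in c("up", "down")) {
  if (!is.null(clust[[dir]])) {
    write.table(clust[[dir]]$assignment,
                file.path(outdir, sprintf("trajectory_clusters_%s.tsv", dir)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
}
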