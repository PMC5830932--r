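#!/usr/bin/env Rscript
# Step 1: simulate the study system — a toy genome with 500 planted
# pioneer-factor binding sites (100 per temporal class), 200 genes, and the
# full multi-omic time course over 0 h / 24 h / 72 h / pro-B. Exports the
# planted truth and example raw-format files so every later step (and any
# external tool) can read them.

suppressPackageStartupMessages(library(tfchrono))
outdir <- "results/analysis"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
datadir <- "results/synthetic_data"
dir.create(datadir, recursive = TRUE, showWarnings = FALSE)

SEED <- 2024L
genome <- generate_genome(n_sites = 500, n_genes = 200, seed = SEED)
noise <- noise_model(peak_dropout_prob = 0.05)

truth <- genome$sites
write.table(truth, file.path(outdir, "planted_sites.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(genome$genes, file.path(outdir, "gene_models.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# example raw exports: pro-B ChIP peaks (BED), pro-B methylome (TSV)
chip <- generate_timecourse_peaks(genome, noise, n_replicates = 2,
                                  seed = SEED + 1)
write_bed(chip[["proB"]][[1]], file.path(datadir, "chip_proB_rep1.bed"))
meth <- generate_methylome(genome, noise, timepoints = "proB",
                           seed = SEED + 3)
write_methylation(meth[["proB"]], file.path(datadir, "methylome_proB.tsv"))

message(sprintf("planted %d sites (%s)", nrow(truth),
                paste(sprintf("%s=%d", names(table(truth$true_class)),
                              table(truth$true_class)), collapse = ", ")))
message(sprintf("%d/%d genes linked to a binding site",
                sum(!is.na(truth$linked_gene_id)), nrow(genome$genes)))
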