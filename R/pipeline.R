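# End-to-end orchestration: a single config carries every threshold, the
# run directory gets one sub-folder per stage, and the manifest records the
# config, seeds, row counts and output checksums so a run is reproducible
# bit for bit.

#' Default pipeline configuration
#'
#' Every tunable of every stage, with the documented defaults: +/-3-kb
#' signal windows, +/-100-bp methylation windows, +/-25-kb TSS association,
#' 200-bp co-occurrence windows, fold change > 2 at p < 0.01 with the
#' FPKM >= 1 filter, the > 10-fold stringent stratum, footprint widths
#' 11--25 with 35-bp shoulders at 1% FDR, and the 10--50% LMR band.
#'
#' @param seed master seed; per-stage seeds are derived at fixed offsets.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    timepoints = CORE_TIMEPOINTS,
    synthetic = list(enabled = TRUE, n_chroms = 1, chrom_len = 2e6,
                     n_genes = 200, n_sites = 500, n_replicates = 2,
                     peak_dropout_prob = 0.02, signal_depth = 60,
                     background_rate = 5, meth_coverage = 30,
                     expr_dispersion = 0.25),
    peaks = list(min_overlap_bp = 1, merge_gap_bp = 0),
    signal = list(window_bp = 3000, bin_bp = 50, center_bp = 500,
                  gain_fold = 2, min_rpkm = NULL),
    methylation = list(min_coverage = 5, window_bp = 100,
                       low_band = c(0.10, 0.50), min_cpgs = 4,
                       max_gap_bp = 250, assoc_bp = 150),
    footprints = list(widths = seq(11, 25, 2), shoulder_bp = 35,
                      fdr = 0.01, n_shuffles = 100, cooccur_window_bp = 200),
    expression = list(fc_threshold = 2, p_threshold = 0.01, min_fpkm = 1,
                      cutoff_fold = 10, stem_c = 2, n_model_profiles = 20,
                      n_permutations = 500),
    dependency = list(cooccupancy_window_bp = 200, n_secondary_sites = 400,
                      cobound_frac = 0.5, dependent_frac_cobound = 0.5),
    inputs = list()  # per-assay file paths for non-synthetic runs
  )
}

#' Validate a pipeline configuration
#'
#' @param config configuration list (see \code{\link{default_config}}).
#' @return character vector of issues (length 0 when valid).
#' @export
validate_config <- function(config) {
  issues <- character(0)
  flag <- function(msg) issues <<- c(issues, msg)
  need <- c("seed", "timepoints", "peaks", "signal", "methylation",
            "footprints", "expression", "dependency")
  for (k in need) if (is.null(config[[k]])) flag(sprintf("missing section '%s'", k))
  if (length(issues)) return(issues)
  if (!all(config$timepoints %in% TIMEPOINTS)) {
    flag(sprintf("unknown time point label(s): %s",
                 paste(setdiff(config$timepoints, TIMEPOINTS), collapse = ", ")))
  }
  pos <- c(signal_window = config$signal$window_bp,
           signal_bin = config$signal$bin_bp,
           center = config$signal$center_bp,
           meth_window = config$methylation$window_bp,
           shoulder = config$footprints$shoulder_bp,
           cooccur = config$footprints$cooccur_window_bp)
  for (k in names(pos)) {
    if (!is.numeric(pos[[k]]) || pos[[k]] <= 0) {
      flag(sprintf("%s must be a positive number", k))
    }
  }
  if (config$expression$fc_threshold < 1) flag("fc_threshold must be >= 1")
  if (config$expression$p_threshold <= 0 || config$expression$p_threshold > 1) {
    flag("p_threshold must be in (0, 1]")
  }
  if (config$footprints$fdr <= 0 || config$footprints$fdr >= 1) {
    flag("footprint fdr must be in (0, 1)")
  }
  lb <- config$methylation$low_band
  if (length(lb) != 2 || lb[1] >= lb[2]) flag("low_band must be (lo, hi)")
  syn <- isTRUE(config$synthetic$enabled)
  if (!syn) {
    for (assay in names(config$inputs)) {
      paths <- unlist(config$inputs[[assay]])
      missing <- paths[!file.exists(paths)]
      for (m in missing) flag(sprintf("input file missing (%s): %s", assay, m))
    }
  }
  issues
}

#' Read/write a configuration as YAML
#' @param path file path.
#' @param config configuration list.
#' @export
read_config <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stopf("cannot parse config %s: %s",
                                            path, conditionMessage(e)))
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 12, trim = TRUE,
                                                scientific = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes peaks -> signal -> methylation -> footprints -> expression ->
#' dependency on synthetic data (default) or user-supplied inputs, writing
#' per-stage tables under `outdir` and a JSON manifest capturing the config
#' snapshot, derived seeds, per-stage row counts and output checksums.
#' Stages whose inputs are absent are skipped and logged.
#'
#' @param config configuration list; see \code{\link{default_config}}.
#' @param outdir output directory (created).
#' @return invisibly, a list with the manifest and the per-stage results.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("run_")) {
  issues <- validate_config(config)
  if (length(issues)) {
    stopf("invalid config:\n- %s", paste(issues, collapse = "\n- "))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  seed <- config$seed
  counts <- list()
  report <- list()

  if (!isTRUE(config$synthetic$enabled)) {
    stopf("non-synthetic runs require per-assay inputs; stage '%s' has none",
          "peaks")
  }
  syn <- config$synthetic
  noise <- noise_model(peak_dropout_prob = syn$peak_dropout_prob,
                       signal_depth = syn$signal_depth,
                       background_rate = syn$background_rate,
                       meth_coverage = syn$meth_coverage,
                       expr_dispersion = syn$expr_dispersion)
  genome <- generate_genome(n_chroms = syn$n_chroms, chrom_len = syn$chrom_len,
                            n_genes = syn$n_genes, n_sites = syn$n_sites,
                            seed = derive_seed(seed, 1))
  log("simulate: %d sites, %d genes on %d chrom(s)", nrow(genome$sites),
      nrow(genome$genes), length(genome$chrom_sizes))

  ## --- peaks ---------------------------------------------------------
  tps <- config$timepoints
  chip <- generate_timecourse_peaks(genome, noise, timepoints = tps,
                                    n_replicates = syn$n_replicates,
                                    assay = "chip",
                                    seed = derive_seed(seed, 2))
  atac <- generate_timecourse_peaks(genome, noise, timepoints = tps,
                                    n_replicates = syn$n_replicates,
                                    assay = "atac",
                                    atac_site_frequency = DEFAULT_ATAC_SITE_FREQUENCY,
                                    seed = derive_seed(seed, 3))
  chip_cons <- lapply(chip, replicate_consensus,
                      min_overlap_bp = config$peaks$min_overlap_bp)
  atac_cons <- lapply(atac, replicate_consensus,
                      min_overlap_bp = config$peaks$min_overlap_bp)
  catalog <- build_site_catalog(chip_cons,
                                merge_gap_bp = config$peaks$merge_gap_bp)
  catalog <- classify_temporal(catalog, accessible_0h = atac_cons[["0h"]])
  class_counts <- table(catalog$classes)
  counts$catalog_sites <- nrow(catalog$sites)
  report$temporal_classes <- as.list(class_counts)
  log("peaks: %d catalog sites (%s)", nrow(catalog$sites),
      paste(sprintf("%s=%d", names(class_counts), class_counts),
            collapse = ", "))
  write_bed(catalog$sites, file.path(outdir, "site_catalog.bed"))
  occ_df <- data.frame(site_id = catalog$sites$site_id,
                       catalog$occupancy * 1L,
                       class = catalog$classes, check.names = FALSE)
  write_tsv(occ_df, file.path(outdir, "site_occupancy.tsv"))

  ## --- signal --------------------------------------------------------
  cuts <- generate_cut_counts(genome, noise, timepoints = tps,
                              seed = derive_seed(seed, 4))
  mats <- lapply(cuts, compute_signal_matrix, catalog = catalog,
                 window_bp = config$signal$window_bp,
                 bin_bp = config$signal$bin_bp)
  acc_labels <- classify_accessibility(mats, catalog,
                                       center_bp = config$signal$center_bp,
                                       gain_fold = config$signal$gain_fold,
                                       min_rpkm = config$signal$min_rpkm)
  report$accessibility_clusters <- as.list(table(acc_labels))
  atac_freq <- atac_peak_site_frequency(atac_cons, catalog)
  report$atac_site_frequency <- setNames(as.list(atac_freq$fraction),
                                         atac_freq$cluster)
  write_tsv(data.frame(site_id = names(acc_labels), label = acc_labels),
            file.path(outdir, "accessibility_clusters.tsv"))
  write_tsv(atac_freq, file.path(outdir, "atac_site_frequency.tsv"))
  counts$accessibility_labeled <- sum(acc_labels != "unclassified")
  log("signal: %d/%d sites accessibility-labeled",
      counts$accessibility_labeled, length(acc_labels))

  ## --- methylation ---------------------------------------------------
  meth <- generate_methylome(genome, noise, timepoints = tps,
                             window_bp = config$methylation$window_bp,
                             seed = derive_seed(seed, 5))
  lmrs <- call_lmrs(meth[["proB"]], low_band = config$methylation$low_band,
                    min_cpgs = config$methylation$min_cpgs,
                    max_gap_bp = config$methylation$max_gap_bp)
  site_meth <- lapply(meth, site_methylation, catalog = catalog,
                      window_bp = config$methylation$window_bp)
  dyn <- methylation_dynamics(site_meth, catalog, lmrs,
                              assoc_bp = config$methylation$assoc_bp)
  counts$lmrs <- nrow(lmrs)
  counts$lmr_associated_sites <- nrow(dyn$table)
  report$methylation_deltas <- dyn$summary
  write_tsv(dyn$table, file.path(outdir, "methylation_cloud.tsv"))
  write_tsv(dyn$summary, file.path(outdir, "methylation_deltas.tsv"))
  log("methylation: %d LMRs, %d LMR-associated classified sites",
      nrow(lmrs), nrow(dyn$table))

  ## --- footprints ----------------------------------------------------
  # accessible-chromatin regions per time point, called from the coverage
  fps <- lapply(tps, function(tp) {
    regions <- call_enrichment_peaks(cuts[[tp]])
    call_footprints(cuts[[tp]], regions,
                    widths = config$footprints$widths,
                    shoulder_bp = config$footprints$shoulder_bp,
                    fdr = config$footprints$fdr,
                    n_shuffles = config$footprints$n_shuffles,
                    seed = derive_seed(seed, 6))
  })
  names(fps) <- tps
  counts$footprints <- vapply(fps, nrow, integer(1))
  log("footprints: %s",
      paste(sprintf("%s=%d", tps, counts$footprints), collapse = ", "))
  for (tp in tps) {
    write_tsv(fps[[tp]], file.path(outdir, sprintf("footprints_%s.tsv", tp)))
  }

  ## --- expression ----------------------------------------------------
  expr <- generate_expression(genome, noise, timepoints = tps,
                              n_replicates = syn$n_replicates,
                              seed = derive_seed(seed, 7))
  de <- differential_genes(expr,
                           fc_threshold = config$expression$fc_threshold,
                           p_threshold = config$expression$p_threshold,
                           min_fpkm = config$expression$min_fpkm)
  strata <- stratify_by_amplitude(de,
                                  cutoff_fold = config$expression$cutoff_fold)
  map <- assign_genes_to_sites(catalog, expr$genes)
  reg <- regulated_genes(map, de)
  clust <- cluster_trajectories(de,
                                c = config$expression$stem_c,
                                n_model_profiles = config$expression$n_model_profiles,
                                n_permutations = config$expression$n_permutations,
                                seed = derive_seed(seed, 8))
  counts$de_genes <- sum(de$de)
  counts$regulated_genes <- length(reg)
  report$expression <- list(de_genes = sum(de$de),
                            regulated = length(reg),
                            stringent = sum(strata$stratum == "stringent"),
                            lenient = sum(strata$stratum == "lenient"))
  write_tsv(de, file.path(outdir, "differential_genes.tsv"))
  write_tsv(map, file.path(outdir, "site_gene_map.tsv"))
  for (dir in c("up", "down")) {
    if (!is.null(clust[[dir]])) {
      write_tsv(clust[[dir]]$assignment,
                file.path(outdir, sprintf("expression_clusters_%s.tsv", dir)))
    }
  }
  log("expression: %d DE genes (%d bound within +/-25 kb)", sum(de$de),
      length(reg))

  ## --- dependency ----------------------------------------------------
  dep_design <- generate_secondary_sites(
    n_sites = config$dependency$n_secondary_sites,
    cobound_frac = config$dependency$cobound_frac,
    dependent_frac_cobound = config$dependency$dependent_frac_cobound,
    seed = derive_seed(seed, 9))
  depcls <- classify_dependence(
    dep_design$pax5_sites_proB, dep_design$pax5_peaks_knockout,
    dep_design$ebf1_peaks_proB, dep_design$accessible_pre,
    dep_design$accessible_proB,
    cooccupancy_window_bp = config$dependency$cooccupancy_window_bp)
  dep_sum <- dependence_accessibility_summary(depcls)
  counts$secondary_sites <- nrow(depcls)
  report$dependence <- as.list(table(depcls$label))
  write_tsv(depcls, file.path(outdir, "dependence_classification.tsv"))
  write_tsv(dep_sum$table, file.path(outdir, "dependence_summary.tsv"))
  log("dependency: %s",
      paste(sprintf("%s=%d", names(report$dependence),
                    unlist(report$dependence)), collapse = ", "))

  ## --- manifest ------------------------------------------------------
  outputs <- sort(list.files(outdir, full.names = FALSE))
  outputs <- setdiff(outputs, "manifest.json")
  checksums <- tools::md5sum(file.path(outdir, outputs))
  names(checksums) <- outputs
  manifest <- list(
    package_version = as.character(packageVersion("tfchrono")),
    seed = seed,
    derived_seeds = setNames(lapply(1:9, function(i) derive_seed(seed, i)),
                             c("genome", "chip", "atac", "cuts", "methylome",
                               "footprints", "expression", "stem",
                               "dependency")),
    config = config,
    counts = counts,
    checksums = as.list(checksums),
    log = log_lines)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(manifest = manifest, report = report, catalog = catalog,
                 accessibility = acc_labels, methylation = dyn, de = de,
                 strata = strata, clusters = clust, footprints = fps,
                 dependence = depcls, outdir = outdir))
}
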