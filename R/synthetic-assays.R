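# Assay-level synthetic generators: time-course peak sets, strand-specific
# Tn5 cut tracks, methylomes and expression tables, all driven by the
# planted truth in a `synthetic_genome`.

DEFAULT_SIXH_PROB <- c(preexisting = 0.44, gain24 = 0.44, gain72 = 0.44,
                       gainproB = 0.44, transient = 0.57)

# Fraction of ATAC peaks in each first-accessible cluster that contain a
# planted binding site. The 24 h and pro-B values mirror the study design
# (~90% and ~42%); the others are interpolations.
DEFAULT_ATAC_SITE_FREQUENCY <- c("0h" = 0.9, "24h" = 0.9, "72h" = 0.8,
                                 "proB" = 0.42, "transient" = 0.8)

ATAC_DEPTH_SCALE <- c(preexisting = 1, gain24 = 1, gain72 = 1,
                      gainproB = 0.6, transient = 1)

#' Generate per-time-point, per-replicate peak sets
#'
#' Each planted site emits a peak (width 200--400 bp, centre jitter <= 50 bp)
#' at exactly the time points dictated by its temporal class; ChIP emission
#' follows occupancy, ATAC emission follows accessibility (pre-existing sites
#' are accessible at 0 h although unoccupied). Dropout removes a site from a
#' replicate's peak calls with probability `noise$peak_dropout_prob`.
#'
#' For ATAC runs, "orphan" accessible regions without a planted binding site
#' are added so that each first-accessible peak cluster contains sites at the
#' configured frequency.
#'
#' @param genome a `synthetic_genome`.
#' @param noise a `noise_model`.
#' @param timepoints ordered subset of `c("0h","6h","24h","72h","proB")`.
#' @param n_replicates replicates per time point (>= 1).
#' @param assay `"chip"` (occupancy) or `"atac"` (accessibility).
#' @param six_hour_prob per-class probability that a site is already
#'   detectable at 6 h (used only when "6h" is requested; ChIP only).
#' @param atac_site_frequency named per-cluster site frequency for ATAC
#'   orphan-peak planting, or NULL to emit site peaks only.
#' @param seed integer seed.
#' @return named list per time point, each a list of interval data frames
#'   (one per replicate) with the emitting site id in `name`.
#' @export
generate_timecourse_peaks <- function(genome, noise,
                                      timepoints = CORE_TIMEPOINTS,
                                      n_replicates = 2,
                                      assay = c("chip", "atac"),
                                      six_hour_prob = DEFAULT_SIXH_PROB,
                                      atac_site_frequency = NULL,
                                      seed = genome$seed + 1) {
  assay <- match.arg(assay)
  timepoints <- order_timepoints(timepoints)
  if (n_replicates < 1) stopf("n_replicates must be >= 1")
  sites <- genome$sites

  with_seed(seed, {
    emit_fun <- if (assay == "chip") chip_emission_timepoints else
      atac_emission_timepoints
    emits <- lapply(sites$true_class, emit_fun)
    # 6 h occupancy is probabilistic (drawn once per site)
    if ("6h" %in% timepoints && assay == "chip") {
      at6 <- runif(nrow(sites)) < six_hour_prob[sites$true_class]
      emits <- lapply(seq_along(emits), function(i) {
        if (at6[i]) union(emits[[i]], "6h") else setdiff(emits[[i]], "6h")
      })
    }
    # locus-level recovery failure per (site, replicate)
    dropped <- matrix(runif(nrow(sites) * n_replicates) <
                        noise$peak_dropout_prob,
                      nrow = nrow(sites))

    orphan <- NULL
    if (assay == "atac" && !is.null(atac_site_frequency)) {
      orphan <- plan_atac_orphans(genome, atac_site_frequency)
    }

    out <- lapply(timepoints, function(tp) {
      live <- vapply(emits, function(e) tp %in% e, logical(1))
      lapply(seq_len(n_replicates), function(rep) {
        keep <- which(live & !dropped[, rep])
        n <- length(keep)
        if (n == 0L && is.null(orphan)) {
          return(genomic_intervals(character(), integer(), integer()))
        }
        halfw <- round(runif(n, 100, 200))
        jit <- round(runif(n, -50, 50))
        ctr <- sites$center[keep] + jit
        df <- genomic_intervals(sites$chrom[keep],
                                pmax(0L, as.integer(ctr - halfw)),
                                as.integer(ctr + halfw),
                                name = sites$site_id[keep])
        if (!is.null(orphan)) {
          o <- orphan[vapply(orphan$first_tp, function(ft)
            tp %in% orphan_emission(ft), logical(1)) , , drop = FALSE]
          if (nrow(o)) {
            ohw <- round(runif(nrow(o), 100, 200))
            df <- rbind(df, genomic_intervals(
              o$chrom, pmax(0L, as.integer(o$center - ohw)),
              as.integer(o$center + ohw), name = o$orphan_id))
          }
        }
        df[order(df$chrom, df$start), , drop = FALSE]
      })
    })
    names(out) <- timepoints
    attr(out, "assay") <- assay
    out
  })
}

orphan_emission <- function(first_tp) {
  switch(first_tp,
         "0h" = c("0h", "6h", "24h", "72h", "proB"),
         "24h" = c("24h", "72h", "proB"),
         "72h" = c("72h", "proB"),
         "proB" = "proB",
         "transient" = c("24h", "72h"))
}

# Lay out ATAC orphan (site-free) accessible regions so that each
# first-accessible cluster has the requested site frequency.
plan_atac_orphans <- function(genome, freq) {
  sites <- genome$sites
  cluster_of <- c(preexisting = "0h", gain24 = "24h", gain72 = "72h",
                  gainproB = "proB", transient = "transient")
  n_by_cluster <- table(factor(cluster_of[sites$true_class],
                               levels = names(freq)))
  n_orphans <- round(as.numeric(n_by_cluster) * (1 / freq - 1))
  names(n_orphans) <- names(freq)
  total <- sum(n_orphans)
  if (total == 0) return(NULL)
  # slots halfway between site grid positions, guaranteed clear of site peaks
  slots <- data.frame(chrom = sites$chrom, center = sites$center + 2000L,
                      stringsAsFactors = FALSE)
  if (total > nrow(slots)) {
    slots <- rbind(slots, data.frame(chrom = sites$chrom,
                                     center = sites$center - 1500L))
  }
  if (total > nrow(slots)) stopf("too many orphan ATAC peaks requested")
  idx <- seq_len(total)
  data.frame(orphan_id = sprintf("orphan_%04d", idx),
             chrom = slots$chrom[idx],
             center = slots$center[idx],
             first_tp = rep(names(n_orphans), times = n_orphans),
             stringsAsFactors = FALSE)
}

#' Generate strand-specific Tn5 cut-count tracks
#'
#' Background cuts are Poisson at `noise$background_rate` per kb per strand.
#' At each site accessible at a given time point, on average
#' `noise$signal_depth` additional cuts (both strands) are laid down over the
#' accessible region, with the planted footprint interior thinned to
#' `fp_depletion` times the flanking rate.
#'
#' @param genome a `synthetic_genome`.
#' @param noise a `noise_model`.
#' @param timepoints time points to emit.
#' @param accessible_halfwidth half-width (bp) of the accessible region.
#' @param fp_depletion interior-to-shoulder cut-rate ratio (<= 0.2).
#' @param seed integer seed.
#' @return named list per time point of `cut_track` objects.
#' @export
generate_cut_counts <- function(genome, noise, timepoints = CORE_TIMEPOINTS,
                                accessible_halfwidth = 150,
                                fp_depletion = 0.1,
                                seed = genome$seed + 2) {
  timepoints <- order_timepoints(timepoints)
  sites <- genome$sites
  if (any(sites$footprint_width >= 2 * accessible_halfwidth)) {
    stopf("footprint_width must be smaller than the accessible span")
  }
  with_seed(seed, {
    out <- lapply(timepoints, function(tp) {
      cuts <- list()
      # background
      for (chrom in names(genome$chrom_sizes)) {
        len <- genome$chrom_sizes[[chrom]]
        for (strand in c("+", "-")) {
          n <- rpois(1, noise$background_rate / 1000 * len)
          if (n > 0) {
            cuts[[length(cuts) + 1L]] <- data.frame(
              chrom = chrom, pos = as.integer(floor(runif(n, 0, len))),
              strand = strand, stringsAsFactors = FALSE)
          }
        }
      }
      # site-driven cuts (class-gated: only when accessible at tp)
      live <- vapply(sites$true_class,
                     function(cl) tp %in% atac_emission_timepoints(cl),
                     logical(1))
      for (i in which(live)) {
        depth <- noise$signal_depth * ATAC_DEPTH_SCALE[[sites$true_class[i]]]
        fw <- sites$footprint_width[i]
        for (strand in c("+", "-")) {
          n <- rpois(1, depth / 2)
          if (n == 0) next
          pos <- floor(runif(n, sites$center[i] - accessible_halfwidth,
                             sites$center[i] + accessible_halfwidth))
          if (fw > 0) {
            interior <- abs(pos - sites$center[i]) < fw / 2
            keep <- !interior | (runif(n) < fp_depletion)
            pos <- pos[keep]
          }
          if (length(pos)) {
            cuts[[length(cuts) + 1L]] <- data.frame(
              chrom = sites$chrom[i], pos = as.integer(pos),
              strand = strand, stringsAsFactors = FALSE)
          }
        }
      }
      cuts <- if (length(cuts)) do.call(rbind, cuts) else
        data.frame(chrom = character(), pos = integer(), strand = character())
      cuts <- cuts[order(cuts$chrom, cuts$pos), , drop = FALSE]
      rownames(cuts) <- NULL
      cut_track(cuts, genome$chrom_sizes)
    })
    names(out) <- timepoints
    out
  })
}

#' Construct a cut-count track
#'
#' @param cuts data frame with columns `chrom`, `pos` (0-based base of the
#'   insertion), `strand` ("+" or "-"), one row per cut.
#' @param chrom_sizes named lengths.
#' @return object of class `cut_track`; `total` is the mapped-fragment count
#'   used for RPKM normalization.
#' @export
cut_track <- function(cuts, chrom_sizes) {
  stopifnot(all(c("chrom", "pos", "strand") %in% names(cuts)))
  structure(list(cuts = cuts, chrom_sizes = chrom_sizes,
                 total = nrow(cuts)),
            class = "cut_track")
}

#' @export
print.cut_track <- function(x, ...) {
  cat(sprintf("cut_track: %d cuts on %d chrom(s)\n", x$total,
              length(x$chrom_sizes)))
  invisible(x)
}

#' Generate per-time-point methylomes
#'
#' CpGs are laid out densely (25-bp mean spacing) inside site windows and the
#' seeded LMR patches, sparsely (100 bp) elsewhere. Per-CpG methylation is a
#' beta-binomial draw around the site's planted demethylation profile at each
#' time point; background CpGs sit at 85--95% methylation; LMR-associated
#' sites carry an adjacent constant intermediate-methylation (30%) patch, the
#' planted enhancer LMR core.
#'
#' @param genome a `synthetic_genome`.
#' @param noise a `noise_model` (`meth_coverage` is the mean CpG coverage).
#' @param timepoints time points to emit (profiles are defined on the core
#'   grid).
#' @param window_bp half-width of the dynamic site window.
#' @param beta_conc concentration of the beta noise around the target.
#' @param seed integer seed.
#' @return named list per time point of `methylation_track` objects.
#' @export
generate_methylome <- function(genome, noise, timepoints = CORE_TIMEPOINTS,
                               window_bp = 100, beta_conc = 50,
                               seed = genome$seed + 3) {
  timepoints <- order_timepoints(timepoints)
  timepoints <- setdiff(timepoints, "6h")
  sites <- genome$sites
  with_seed(seed, {
    # CpG layout (shared across time points)
    layout <- list()
    for (chrom in names(genome$chrom_sizes)) {
      len <- genome$chrom_sizes[[chrom]]
      n_bg <- round(len / 100)
      bg_pos <- sort(sample.int(len, n_bg))  # 1-based
      on_chrom <- sites[sites$chrom == chrom, , drop = FALSE]
      keep <- rep(TRUE, length(bg_pos))
      for (i in seq_len(nrow(on_chrom))) {
        keep <- keep & abs(bg_pos - 1L - on_chrom$center[i]) > 260
      }
      layout[[length(layout) + 1L]] <- data.frame(
        chrom = chrom, pos = bg_pos[keep], kind = "bg",
        site_id = NA_character_,
        target0 = runif(sum(keep), 0.85, 0.95), stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(sites))) {
      win <- seq(sites$center[i] - window_bp + 8, sites$center[i] + window_bp - 8,
                 by = 25)
      layout[[length(layout) + 1L]] <- data.frame(
        chrom = sites$chrom[i], pos = as.integer(win) + 1L, kind = "site",
        site_id = sites$site_id[i], target0 = NA_real_,
        stringsAsFactors = FALSE)
      if (sites$lmr_associated[i]) {
        patch <- seq(sites$center[i] + window_bp + 10,
                     sites$center[i] + window_bp + 150, by = 25)
        layout[[length(layout) + 1L]] <- data.frame(
          chrom = sites$chrom[i], pos = as.integer(patch) + 1L, kind = "lmr",
          site_id = sites$site_id[i], target0 = 0.30,
          stringsAsFactors = FALSE)
      }
    }
    cpgs <- do.call(rbind, layout)
    cpgs <- cpgs[order(cpgs$chrom, cpgs$pos), , drop = FALSE]
    cpgs <- cpgs[!duplicated(cpgs[, c("chrom", "pos")]), , drop = FALSE]
    rownames(cpgs) <- NULL

    out <- lapply(timepoints, function(tp) {
      target <- cpgs$target0
      is_site <- cpgs$kind == "site"
      target[is_site] <- genome$meth_profiles[cpgs$site_id[is_site], tp]
      target <- pmin(pmax(target, 0.02), 0.98)
      p <- rbeta(length(target), beta_conc * target, beta_conc * (1 - target))
      cov <- rpois(length(target), noise$meth_coverage)
      meth <- rbinom(length(target), cov, p)
      keep <- cov > 0
      methylation_track(data.frame(chrom = cpgs$chrom[keep],
                                   pos = cpgs$pos[keep],
                                   frac = meth[keep] / cov[keep],
                                   cov = cov[keep],
                                   stringsAsFactors = FALSE))
    })
    names(out) <- timepoints
    out
  })
}

#' Default trajectory templates (log2 fold change vs 0 h)
#'
#' Shapes mirror the canonical expression-cluster archetypes: a marked
#' early jump that is maintained (U1), a gradual sequential rise (U3),
#' early induction with full activation only at the committed stage (U4),
#' late-only activation (U5), and transient up-regulation followed by sharp
#' silencing at the committed stage (D4, ~10-fold down). Each template lies
#' close to a single model trajectory of the default profile dictionary so
#' that cluster recovery is identifiable (see the methods vignette).
#'
#' @param timepoints induced time points the templates span.
#' @return named list of numeric vectors.
#' @export
default_templates <- function(timepoints = INDUCED_TIMEPOINTS) {
  tpl <- list(U1 = c(4, 5, 4),
              U3 = c(1.5, 3, 4.5),
              U4 = c(2, 1, 4),
              U5 = c(-1, 0, 3),
              D4 = c(2, 0, -3.3))
  lapply(tpl, function(x) setNames(x[seq_along(timepoints)], timepoints))
}

CLASS_TEMPLATE_MAP <- c(preexisting = "U1", gain24 = "U3", gain72 = "U4",
                        gainproB = "U5", transient = "D4")

#' Generate an expression table with planted trajectory clusters
#'
#' Genes linked to a planted site inherit the trajectory template mapped to
#' the site's temporal class; unlinked genes are flat. A fraction of unlinked
#' genes is planted at sub-threshold abundance (FPKM < 1 everywhere) to
#' exercise the low-expression filter.
#'
#' @param genome a `synthetic_genome`.
#' @param noise a `noise_model` (`expr_dispersion` is the replicate log2 sd).
#' @param timepoints ordered time points (must include "0h").
#' @param n_replicates replicates per time point.
#' @param cluster_templates named list of log2-fold-change vectors over the
#'   induced time points.
#' @param low_expr_frac fraction of unlinked genes planted below 1 FPKM.
#' @param seed integer seed.
#' @return an `expression_table` (list with `abundance`, `samples`, `genes`,
#'   `truth`).
#' @export
generate_expression <- function(genome, noise, timepoints = CORE_TIMEPOINTS,
                                n_replicates = 2,
                                cluster_templates = default_templates(),
                                low_expr_frac = 0.1,
                                seed = genome$seed + 4) {
  timepoints <- order_timepoints(setdiff(timepoints, "6h"))
  if (!"0h" %in% timepoints) stopf("timepoints must include '0h'")
  induced <- setdiff(timepoints, "0h")
  bad <- names(cluster_templates)[vapply(cluster_templates, length,
                                         integer(1)) != length(induced)]
  if (length(bad)) {
    stopf("template '%s' has length != number of induced time points", bad[1])
  }
  genes <- genome$genes
  sites <- genome$sites
  with_seed(seed, {
    template_of <- setNames(rep("flat", nrow(genes)), genes$gene_id)
    linked <- sites[!is.na(sites$linked_gene_id), , drop = FALSE]
    tpl_name <- CLASS_TEMPLATE_MAP[linked$true_class]
    ok <- tpl_name %in% names(cluster_templates)
    template_of[linked$linked_gene_id[ok]] <- tpl_name[ok]

    unlinked <- names(template_of)[template_of == "flat"]
    n_low <- round(low_expr_frac * length(unlinked))
    low_genes <- sample(unlinked, n_low)
    baseline <- rlnorm(nrow(genes), log(8), 0.8)
    names(baseline) <- genes$gene_id
    baseline[low_genes] <- runif(n_low, 0.05, 0.4)

    samples <- expand.grid(replicate = seq_len(n_replicates),
                           timepoint = timepoints,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    samples <- samples[, c("timepoint", "replicate")]
    samples$sample_id <- sprintf("%s_rep%d", samples$timepoint,
                                 samples$replicate)

    lfc <- matrix(0, nrow(genes), length(timepoints),
                  dimnames = list(genes$gene_id, timepoints))
    for (g in seq_len(nrow(genes))) {
      tn <- template_of[g]
      if (tn != "flat") lfc[g, induced] <- cluster_templates[[tn]]
    }
    ab <- matrix(0, nrow(genes), nrow(samples),
                 dimnames = list(genes$gene_id, samples$sample_id))
    for (s in seq_len(nrow(samples))) {
      tp <- samples$timepoint[s]
      ab[, s] <- baseline * 2^(lfc[, tp] +
                                 rnorm(nrow(genes), 0, noise$expr_dispersion))
    }
    truth <- data.frame(gene_id = genes$gene_id,
                        template = unname(template_of),
                        low_expressed = genes$gene_id %in% low_genes,
                        stringsAsFactors = FALSE)
    expression_table(ab, samples, genes, truth)
  })
}

#' Construct an expression table
#'
#' @param abundance genes x samples matrix of FPKM-scale abundances.
#' @param samples data frame with `sample_id`, `timepoint`, `replicate`.
#' @param genes data frame with `gene_id`, `chrom`, `strand`, `tss`.
#' @param truth optional planted-truth sidecar.
#' @return object of class `expression_table`.
#' @export
expression_table <- function(abundance, samples, genes, truth = NULL) {
  stopifnot(ncol(abundance) == nrow(samples),
            nrow(abundance) == nrow(genes),
            all(abundance >= 0),
            all(!is.na(samples$timepoint)))
  structure(list(abundance = abundance, samples = samples, genes = genes,
                 truth = truth), class = "expression_table")
}

#' Simulate a flat DE benchmark table
#'
#' A genome-free expression table for benchmarking the differential caller:
#' `n_de` genes change `effect_fold`-fold between 0 h and pro-B (linear ramp
#' across the grid, half up / half down), `n_low` genes carry the same effect
#' at sub-threshold abundance (FPKM < 1 at both ends), and the rest are flat.
#'
#' @param n_genes,n_de,n_low gene counts.
#' @param effect_fold planted fold change between 0 h and pro-B.
#' @param sigma replicate log2 standard deviation.
#' @param n_replicates replicates per time point.
#' @param seed integer seed.
#' @return an `expression_table` with truth columns `de` and `low_expressed`.
#' @export
simulate_de_table <- function(n_genes = 500, n_de = 100, n_low = 20,
                              effect_fold = 4, sigma = 0.25,
                              n_replicates = 2, seed = 1) {
  with_seed(seed, {
    timepoints <- CORE_TIMEPOINTS
    gene_id <- sprintf("gene_%04d", seq_len(n_genes))
    status <- rep("null", n_genes)
    status[sample.int(n_genes, n_de + n_low)] <- "de"
    low_idx <- sample(which(status == "de"), n_low)
    status[low_idx] <- "low"
    baseline <- rlnorm(n_genes, log(10), 0.6)
    baseline[status == "low"] <- runif(n_low, 0.05, 0.2)
    direction <- ifelse(runif(n_genes) < 0.5, 1, -1)
    amp <- log2(effect_fold)
    ramp <- c("0h" = 0, "24h" = 1 / 3, "72h" = 2 / 3, "proB" = 1)
    samples <- expand.grid(replicate = seq_len(n_replicates),
                           timepoint = timepoints, stringsAsFactors = FALSE)
    samples <- samples[, c("timepoint", "replicate")]
    samples$sample_id <- sprintf("%s_rep%d", samples$timepoint,
                                 samples$replicate)
    ab <- matrix(0, n_genes, nrow(samples),
                 dimnames = list(gene_id, samples$sample_id))
    for (s in seq_len(nrow(samples))) {
      tp <- samples$timepoint[s]
      shift <- ifelse(status %in% c("de", "low"),
                      direction * amp * ramp[[tp]], 0)
      ab[, s] <- baseline * 2^(shift + rnorm(n_genes, 0, sigma))
    }
    genes <- data.frame(gene_id = gene_id, chrom = "chrT1", strand = "+",
                        tss = seq_len(n_genes) * 1000L,
                        stringsAsFactors = FALSE)
    truth <- data.frame(gene_id = gene_id, de = status == "de",
                        low_expressed = status == "low",
                        direction = ifelse(status == "null", 0, direction),
                        stringsAsFactors = FALSE)
    expression_table(ab, samples, genes, truth)
  })
}

#' Simulate footprint benchmark regions
#'
#' Tiles `n_true + n_null` accessible regions along one toy chromosome. True
#' regions carry a central protected footprint (interior cut rate
#' `depletion` times the flanks); null regions are uniform. The per-strand
#' flank rate is `shoulder_depth / 35` cuts per bp, so `shoulder_depth` is
#' the expected cut count in a 35-bp shoulder.
#'
#' @param n_true,n_null region counts.
#' @param shoulder_depth expected per-strand cuts per 35-bp shoulder.
#' @param fp_width planted footprint width (bp).
#' @param region_width accessible-region width (bp).
#' @param depletion interior/flank rate ratio.
#' @param seed integer seed.
#' @return list with `track` (a `cut_track`), `regions` (intervals with
#'   `name` true_/null_), and `truth` (planted footprint intervals).
#' @export
simulate_footprint_regions <- function(n_true = 500, n_null = 500,
                                       shoulder_depth = 30, fp_width = 15,
                                       region_width = 200, depletion = 0.1,
                                       seed = 1) {
  with_seed(seed, {
    n <- n_true + n_null
    spacing <- 1000L
    starts <- seq_len(n) * spacing
    is_true <- sample(rep(c(TRUE, FALSE), times = c(n_true, n_null)))
    rate <- shoulder_depth / 35
    cuts <- vector("list", 2L * n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      lo <- starts[i]
      fp_lo <- lo + (region_width - fp_width) %/% 2
      fp_hi <- fp_lo + fp_width
      for (strand in c("+", "-")) {
        m <- rpois(1, rate * region_width)
        pos <- floor(runif(m, lo, lo + region_width))
        if (is_true[i]) {
          interior <- pos >= fp_lo & pos < fp_hi
          pos <- pos[!interior | runif(m) < depletion]
        }
        if (length(pos)) {
          cuts[[2L * (i - 1L) + (strand == "-") + 1L]] <-
            data.frame(chrom = "chrF", pos = as.integer(pos), strand = strand,
                       stringsAsFactors = FALSE)
        }
      }
      if (is_true[i]) {
        truth[[i]] <- data.frame(chrom = "chrF", start = fp_lo, end = fp_hi,
                                 stringsAsFactors = FALSE)
      }
    }
    cuts <- do.call(rbind, cuts[!vapply(cuts, is.null, logical(1))])
    cuts <- cuts[order(cuts$pos), , drop = FALSE]
    rownames(cuts) <- NULL
    regions <- genomic_intervals("chrF", starts, starts + region_width,
                                 name = sprintf("%s_%04d",
                                                ifelse(is_true, "true", "null"),
                                                seq_len(n)))
    truth <- do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
    list(track = cut_track(cuts, c(chrF = (n + 2L) * spacing)),
         regions = regions, truth = truth)
  })
}

#' Simulate a secondary-factor (Pax5-like) dependence design
#'
#' Plants a universe of secondary-factor pro-B binding sites of which a fixed
#' fraction is co-bound by the pioneer factor; among co-bound sites a fixed
#' fraction is pioneer-dependent (not bound in the knockout-induction
#' sample). Dependent sites are planted inaccessible before induction and
#' accessible at pro-B; independent sites are mostly pre-accessible.
#'
#' @param n_sites number of secondary-factor sites.
#' @param cobound_frac fraction with a neighbouring pioneer-factor peak.
#' @param dependent_frac_cobound fraction of co-bound sites that are
#'   pioneer-dependent (exact, stratified).
#' @param dependent_frac_solo Bernoulli probability that a solo site is
#'   dependent.
#' @param acc_pre_prob_independent probability an independent site is
#'   accessible before induction.
#' @param seed integer seed.
#' @return list of peak sets, accessibility flags and the planted truth.
#' @export
generate_secondary_sites <- function(n_sites = 400, cobound_frac = 0.5,
                                     dependent_frac_cobound = 0.5,
                                     dependent_frac_solo = 0.1,
                                     acc_pre_prob_independent = 0.9,
                                     seed = 1) {
  with_seed(seed, {
    centers <- seq_len(n_sites) * 3000L + 10000L
    chrom <- "chrS1"
    n_cb <- round(cobound_frac * n_sites)
    cobound <- sample(rep(c(TRUE, FALSE), times = c(n_cb, n_sites - n_cb)))
    dependent <- logical(n_sites)
    cb_idx <- which(cobound)
    n_dep_cb <- round(dependent_frac_cobound * length(cb_idx))
    dependent[sample(cb_idx, n_dep_cb)] <- TRUE
    solo_idx <- which(!cobound)
    dependent[solo_idx] <- runif(length(solo_idx)) < dependent_frac_solo
    acc_pre <- ifelse(dependent, FALSE,
                      runif(n_sites) < acc_pre_prob_independent)
    acc_proB <- rep(TRUE, n_sites)

    site_id <- sprintf("pax_%04d", seq_len(n_sites))
    pax5_proB <- genomic_intervals(chrom, centers - 150L, centers + 150L,
                                   name = site_id)
    ko_idx <- which(!dependent)
    jit <- round(runif(length(ko_idx), -30, 30))
    pax5_ko <- genomic_intervals(chrom, centers[ko_idx] - 150L + jit,
                                 centers[ko_idx] + 150L + jit,
                                 name = site_id[ko_idx])
    eb_idx <- which(cobound)
    off <- round(runif(length(eb_idx), -80, 80))
    ebf1_proB <- genomic_intervals(chrom, centers[eb_idx] + off - 150L,
                                   centers[eb_idx] + off + 150L,
                                   name = sprintf("ebf1_%04d",
                                                  seq_along(eb_idx)))
    truth <- data.frame(site_id = site_id, center = centers,
                        cobound = cobound, dependent = dependent,
                        accessible_pre = acc_pre, accessible_proB = acc_proB,
                        stringsAsFactors = FALSE)
    list(pax5_sites_proB = pax5_proB, pax5_peaks_knockout = pax5_ko,
         ebf1_peaks_proB = ebf1_proB, accessible_pre = acc_pre,
         accessible_proB = acc_proB, truth = truth)
  })
}
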