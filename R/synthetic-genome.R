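# Synthetic toy genome with planted binding sites, genes and ground truth.
# The generator exists so that every downstream stage of the pipeline can be
# exercised against known truth at desk scale; it emulates the shape of the
# real assays (peak sets, cut-count tracks, methylomes, expression tables),
# not their genome-scale statistics.

DEFAULT_MOTIF_PROB <- c(preexisting = 0.70, gain24 = 0.71, gain72 = 0.67,
                        gainproB = 0.22, transient = 0.70)

# Per-class target methylation fraction on the 0h/24h/72h/proB grid.
# Persistent classes: modest loss at 72 h, pronounced loss at pro-B.
# Transient: modest loss at 72 h, flat afterwards. Pre-existing sites sit in
# already-hypomethylated accessible chromatin.
DEFAULT_METH_PROFILES <- list(
  preexisting = c("0h" = 0.15, "24h" = 0.15, "72h" = 0.12, "proB" = 0.10),
  gain24      = c("0h" = 0.80, "24h" = 0.80, "72h" = 0.65, "proB" = 0.20),
  gain72      = c("0h" = 0.80, "24h" = 0.80, "72h" = 0.65, "proB" = 0.20),
  gainproB    = c("0h" = 0.80, "24h" = 0.80, "72h" = 0.65, "proB" = 0.20),
  transient   = c("0h" = 0.80, "24h" = 0.80, "72h" = 0.65, "proB" = 0.65)
)

#' Noise model for the synthetic generators
#'
#' @param peak_dropout_prob probability that a replicate fails to recover a
#'   planted site in its peak calls (applied per site and replicate; a
#'   locus-level recovery failure, see the methods vignette).
#' @param signal_depth mean Tn5 cut count deposited over an occupied,
#'   accessible site (both strands together).
#' @param background_rate background cut rate, fragments per kb per strand.
#' @param meth_coverage mean read coverage per CpG.
#' @param expr_dispersion replicate standard deviation of log2 expression.
#' @return a list of class `noise_model`.
#' @export
noise_model <- function(peak_dropout_prob = 0, signal_depth = 60,
                        background_rate = 5, meth_coverage = 30,
                        expr_dispersion = 0.25) {
  if (peak_dropout_prob < 0 || peak_dropout_prob > 1) {
    stopf("peak_dropout_prob must be in [0, 1]")
  }
  if (signal_depth < 0 || background_rate < 0 || meth_coverage < 0 ||
      expr_dispersion < 0) {
    stopf("noise rates and depths must be nonnegative")
  }
  structure(list(peak_dropout_prob = peak_dropout_prob,
                 signal_depth = signal_depth,
                 background_rate = background_rate,
                 meth_coverage = meth_coverage,
                 expr_dispersion = expr_dispersion),
            class = "noise_model")
}

#' Generate a toy genome with planted binding sites
#'
#' Sites are placed on a jittered grid (guaranteeing that neighbouring sites
#' never merge during catalog construction) and assigned one of the five
#' temporal occupancy classes in exactly the requested proportions
#' (largest-remainder rounding). A subset of sites is linked to genes whose
#' TSS is placed within the site's regulatory window.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_len length of each chromosome (bp).
#' @param n_genes number of genes.
#' @param n_sites number of planted binding sites (>= 5).
#' @param class_proportions named numeric over the five classes, summing to 1.
#' @param seed integer seed; identical seeds give identical genomes.
#' @param motif_prob per-class probability that a site carries a canonical
#'   motif.
#' @param lmr_prob per-class probability that a site is LMR-associated.
#' @param linked_frac fraction of genes linked to a planted site.
#' @param footprint_width protected width (bp) planted at occupied sites.
#' @return a list of class `synthetic_genome` with elements `chrom_sizes`,
#'   `genes`, `sites`, `meth_profiles` and `seed`.
#' @export
generate_genome <- function(n_chroms = 1, chrom_len = 2e6, n_genes = 200,
                            n_sites = 500,
                            class_proportions = NULL, seed = 1,
                            motif_prob = DEFAULT_MOTIF_PROB,
                            lmr_prob = c(preexisting = 0.5, gain24 = 0.8,
                                         gain72 = 0.8, gainproB = 0.8,
                                         transient = 0.8),
                            linked_frac = 0.75,
                            footprint_width = 15) {
  if (is.null(class_proportions)) {
    class_proportions <- setNames(rep(1 / 5, 5), SITE_CLASSES)
  }
  class_proportions <- class_proportions[SITE_CLASSES]
  class_proportions[is.na(class_proportions)] <- 0
  names(class_proportions) <- SITE_CLASSES
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stopf("class_proportions must sum to 1 (got %.12f)", sum(class_proportions))
  }
  if (n_sites < 5) stopf("n_sites must be >= 5")

  with_seed(seed, {
    chroms <- sprintf("chrT%d", seq_len(n_chroms))
    chrom_sizes <- setNames(rep(as.integer(chrom_len), n_chroms), chroms)

    # largest-remainder apportionment: exact class counts
    raw <- class_proportions * n_sites
    counts <- floor(raw)
    rem <- n_sites - sum(counts)
    if (rem > 0) {
      extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    classes <- sample(rep(SITE_CLASSES, times = counts))

    # site centers: even grid with jitter, margin for +/-3 kb windows
    per_chrom <- diff(round(seq(0, n_sites, length.out = n_chroms + 1)))
    site_chrom <- rep(chroms, times = per_chrom)
    centers <- unlist(lapply(per_chrom, function(k) {
      if (k == 0) return(integer(0))
      margin <- 10000
      grid <- seq(margin, chrom_len - margin, length.out = k)
      jit <- round(runif(k, -500, 500))
      as.integer(round(grid) + jit)
    }), use.names = FALSE)

    sites <- data.frame(
      site_id = sprintf("site_%04d", seq_len(n_sites)),
      chrom = site_chrom,
      center = centers,
      true_class = classes,
      has_canonical_motif = runif(n_sites) < motif_prob[classes],
      lmr_associated = runif(n_sites) < lmr_prob[classes],
      footprint_width = as.integer(footprint_width),
      linked_gene_id = NA_character_,
      stringsAsFactors = FALSE
    )

    meth_profiles <- do.call(rbind, DEFAULT_METH_PROFILES[classes])
    rownames(meth_profiles) <- sites$site_id

    # genes: a linked subset near sites, the rest on their own grid
    n_linked <- min(round(linked_frac * n_genes), n_sites)
    linked_sites <- sample(seq_len(n_sites), n_linked)
    gene_id <- sprintf("gene_%04d", seq_len(n_genes))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    tss <- integer(n_genes)
    gchrom <- character(n_genes)
    tss[seq_len(n_linked)] <- sites$center[linked_sites] +
      round(runif(n_linked, -15000, 15000))
    gchrom[seq_len(n_linked)] <- sites$chrom[linked_sites]
    n_free <- n_genes - n_linked
    if (n_free > 0) {
      fchrom <- sample(chroms, n_free, replace = TRUE)
      tss[n_linked + seq_len(n_free)] <-
        round(runif(n_free, 5000, chrom_len - 5000))
      gchrom[n_linked + seq_len(n_free)] <- fchrom
    }
    tss <- pmin(pmax(tss, 1000L), as.integer(chrom_len - 1000L))
    genes <- data.frame(gene_id = gene_id, chrom = gchrom, strand = strand,
                        tss = as.integer(tss),
                        length = as.integer(round(runif(n_genes, 2000, 20000))),
                        stringsAsFactors = FALSE)
    sites$linked_gene_id[linked_sites] <- gene_id[seq_len(n_linked)]

    structure(list(chrom_sizes = chrom_sizes, genes = genes, sites = sites,
                   meth_profiles = meth_profiles, seed = as.integer(seed)),
              class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic_genome: %d chrom(s), %s bp total, %d genes, %d sites\n",
              length(x$chrom_sizes), format(sum(x$chrom_sizes), big.mark = ","),
              nrow(x$genes), nrow(x$sites)))
  print(table(x$sites$true_class))
  invisible(x)
}

#' Match catalog sites back to planted sites
#'
#' For each catalog site, the index of the nearest planted site on the same
#' chromosome, or NA when none lies within `max_dist` bp of the catalog
#' centre.
#'
#' @param catalog a `site_catalog`.
#' @param genome the `synthetic_genome` the data came from.
#' @param max_dist maximum centre-to-centre distance (bp).
#' @return integer vector of row indices into `genome$sites`.
#' @export
match_sites_to_truth <- function(catalog, genome, max_dist = 300) {
  vapply(seq_len(nrow(catalog$sites)), function(i) {
    same <- which(genome$sites$chrom == catalog$sites$chrom[i])
    if (!length(same)) return(NA_integer_)
    d <- abs(genome$sites$center[same] - catalog$sites$center[i])
    k <- which.min(d)
    if (d[k] <= max_dist) same[k] else NA_integer_
  }, integer(1))
}

# Time points at which a site of a given class carries a ChIP peak.
chip_emission_timepoints <- function(class) {
  switch(class,
         preexisting = c("24h", "72h", "proB"),
         gain24      = c("24h", "72h", "proB"),
         gain72      = c("72h", "proB"),
         gainproB    = "proB",
         transient   = c("24h", "72h"),
         stopf("unknown site class '%s'", class))
}

# Time points at which a site of a given class is accessible (ATAC).
atac_emission_timepoints <- function(class) {
  switch(class,
         preexisting = c("0h", "6h", "24h", "72h", "proB"),
         gain24      = c("24h", "72h", "proB"),
         gain72      = c("72h", "proB"),
         gainproB    = "proB",
         transient   = c("24h", "72h"),
         stopf("unknown site class '%s'", class))
}
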