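# RPKM-normalized signal matrices around site centres, five-cluster
# accessibility classification, central-depletion profiles, ATAC-cluster
# site frequencies, and a minimal Poisson enrichment peak caller for
# synthetic coverage.

#' Compute an RPKM signal matrix around site centres
#'
#' Bins the window `[-window_bp, +window_bp)` around each site centre into
#' `bin_bp` bins and counts cut/fragment midpoints per bin; values are
#' RPKM: count x 1e9 / (bin_bp x total mapped fragments). Bins truncated at
#' chromosome edges are zero and flagged in `edge_clipped`.
#'
#' @param track a `cut_track` (or any list with a `cuts` data frame of
#'   midpoint positions and a `total` count).
#' @param catalog a `site_catalog` (or data frame with `chrom` and `center`).
#' @param window_bp half-window (bp), divisible by `bin_bp`.
#' @param bin_bp bin width (bp).
#' @return object of class `signal_matrix`: `values` (sites x bins RPKM),
#'   `bin_centers` (bp relative to site centre), `site_ids`, `window_bp`,
#'   `bin_bp`, `edge_clipped`.
#' @export
compute_signal_matrix <- function(track, catalog, window_bp = 3000,
                                  bin_bp = 50) {
  if (window_bp %% bin_bp != 0) stopf("window_bp must be divisible by bin_bp")
  sites <- if (inherits(catalog, "site_catalog")) catalog$sites else catalog
  n_bins <- 2L * window_bp %/% bin_bp
  bin_centers <- seq(-window_bp + bin_bp / 2, window_bp - bin_bp / 2,
                     by = bin_bp)
  values <- matrix(0, nrow(sites), n_bins,
                   dimnames = list(sites$site_id, NULL))
  edge <- rep(FALSE, nrow(sites))
  total <- track$total
  if (total == 0) {
    warning("empty signal track: all-zero matrix")
  } else {
    cuts <- track$cuts
    sizes <- track$chrom_sizes
    for (chrom in unique(sites$chrom)) {
      idx <- which(sites$chrom == chrom)
      pos <- cuts$pos[cuts$chrom == chrom]
      len <- if (!is.null(sizes) && chrom %in% names(sizes))
        sizes[[chrom]] else Inf
      for (i in idx) {
        lo <- sites$center[i] - window_bp
        hi <- sites$center[i] + window_bp
        if (lo < 0 || hi > len) edge[i] <- TRUE
        if (length(pos) == 0L) next
        inwin <- pos >= max(lo, 0) & pos < min(hi, len)
        if (!any(inwin)) next
        b <- (pos[inwin] - lo) %/% bin_bp + 1L
        tb <- tabulate(b, nbins = n_bins)
        values[i, ] <- tb * 1e9 / (bin_bp * total)
      }
    }
  }
  structure(list(values = values, bin_centers = bin_centers,
                 site_ids = sites$site_id, window_bp = window_bp,
                 bin_bp = bin_bp, edge_clipped = edge),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal_matrix: %d sites x %d bins (+/-%d bp, %d-bp bins)\n",
              nrow(x$values), ncol(x$values), x$window_bp, x$bin_bp))
  invisible(x)
}

central_signal <- function(mat, center_bp = 500) {
  sel <- abs(mat$bin_centers) <= center_bp
  rowMeans(mat$values[, sel, drop = FALSE])
}

#' Five-cluster accessibility classification
#'
#' Central signal is the mean RPKM within `center_bp` of the site centre. A
#' site is accessible at a time point when its central signal reaches
#' `min_rpkm`. Pre-existing sites are accessible at 0 h and occupied (per
#' the catalog) at 24 h. Other sites are classified by the first time point
#' whose central signal reaches both `min_rpkm` and `gain_fold` times the
#' 0-h central (floored at `pseudo_floor` to avoid division blow-ups);
#' sites that gain by 72 h but fall back below the gain threshold at pro-B
#' are transient. Everything else is unclassified.
#'
#' @param matrices_by_timepoint named list of `signal_matrix` over the core
#'   grid (must include "0h" and share the catalog's binning).
#' @param catalog a `site_catalog` with occupancy (for the 24-h condition).
#' @param center_bp central half-window (bp).
#' @param gain_fold fold gain over the 0-h central required to call a gain.
#' @param min_rpkm absolute accessibility threshold; `NULL` sets it to twice
#'   the mean matrix value at 0 h (a background proxy: most bins are
#'   background, so the matrix mean sits near the genome-wide rate).
#' @param pseudo_floor floor on the 0-h central in the fold comparison.
#' @return named character vector of labels per site.
#' @export
classify_accessibility <- function(matrices_by_timepoint, catalog,
                                   center_bp = 500, gain_fold = 2,
                                   min_rpkm = NULL, pseudo_floor = 0.25) {
  tps <- order_timepoints(names(matrices_by_timepoint))
  if (!"0h" %in% tps) stopf("need a 0h matrix")
  mats <- matrices_by_timepoint[tps]
  cen <- vapply(mats, central_signal, numeric(nrow(catalog$sites)),
                center_bp = center_bp)
  cen <- matrix(cen, nrow = nrow(catalog$sites), dimnames = list(
    catalog$sites$site_id, tps))
  if (is.null(min_rpkm)) min_rpkm <- 2 * mean(mats[["0h"]]$values)

  base <- pmax(cen[, "0h"], pseudo_floor)
  induced <- intersect(c("24h", "72h", "proB"), tps)
  gained <- sweep(cen[, induced, drop = FALSE], 1, base, "/") >= gain_fold &
    cen[, induced, drop = FALSE] >= min_rpkm

  occ24 <- if ("24h" %in% colnames(catalog$occupancy))
    catalog$occupancy[, "24h"] else rep(FALSE, nrow(cen))

  labels <- rep("unclassified", nrow(cen))
  first_gain <- apply(gained, 1, function(g) {
    w <- which(g)
    if (length(w)) induced[w[1]] else NA_character_
  })
  early_gain <- first_gain %in% c("24h", "72h")
  drops_proB <- if ("proB" %in% induced) {
    early_gain & !gained[, "proB"]
  } else {
    rep(FALSE, nrow(cen))
  }
  labels[early_gain & drops_proB] <- "transient"
  labels[early_gain & !drops_proB] <-
    paste0("gain", sub("h$", "", first_gain[early_gain & !drops_proB]))
  labels[!early_gain & first_gain %in% "proB"] <- "gainproB"
  pre <- cen[, "0h"] >= min_rpkm & occ24
  labels[pre] <- "preexisting"
  setNames(labels, catalog$sites$site_id)
}

#' Per-class mean profile and centre-to-shoulder ratio
#'
#' Column means per class plus the ratio of the mean signal within
#' `center_bp` of the centre to the mean over the shoulders
#' (`shoulder_bp[1]`--`shoulder_bp[2]` on both sides). A ratio below 1
#' indicates a central dip (e.g. reduced H3K4me2 at the bound site centre).
#'
#' @param matrix a `signal_matrix`.
#' @param class_labels character vector per site (NA / "unclassified"
#'   dropped).
#' @param center_bp central half-window.
#' @param shoulder_bp two-element range of shoulder distances.
#' @return list with `profiles` (class x bin means) and `ratio` (named
#'   numeric; NA with a warning when a class's shoulder mean is zero).
#' @export
central_depletion_profile <- function(matrix, class_labels, center_bp = 100,
                                      shoulder_bp = c(500, 1000)) {
  if (ncol(matrix$values) < 3L) stopf("matrix needs >= 3 bins")
  keep <- !is.na(class_labels) & class_labels != "unclassified"
  vals <- matrix$values[keep, , drop = FALSE]
  cls <- class_labels[keep]
  classes <- sort(unique(cls))
  profiles <- t(vapply(classes, function(cl)
    colMeans(vals[cls == cl, , drop = FALSE]), numeric(ncol(vals))))
  rownames(profiles) <- classes
  cen_sel <- abs(matrix$bin_centers) <= center_bp
  sh_sel <- abs(matrix$bin_centers) >= shoulder_bp[1] &
    abs(matrix$bin_centers) <= shoulder_bp[2]
  ratio <- vapply(classes, function(cl) {
    p <- profiles[cl, ]
    sh <- mean(p[sh_sel])
    if (sh == 0) {
      warning(sprintf("class %s: zero shoulder signal, ratio undefined", cl))
      return(NA_real_)
    }
    mean(p[cen_sel]) / sh
  }, numeric(1))
  list(profiles = profiles, ratio = ratio,
       bin_centers = matrix$bin_centers)
}

#' Site frequency within ATAC-peak clusters
#'
#' Builds an ATAC-peak catalog across time points, clusters peaks by their
#' first accessible time point (peaks accessible at 24 h/72 h but closed
#' again at pro-B form the "transient" cluster), and reports the fraction of
#' peaks in each cluster that contain at least one binding site from the
#' catalog.
#'
#' @param atac_peak_sets_by_timepoint named list of consensus ATAC peak sets.
#' @param catalog a `site_catalog` of binding sites.
#' @return data frame with cluster, peak count, site-containing count and
#'   fraction.
#' @export
atac_peak_site_frequency <- function(atac_peak_sets_by_timepoint, catalog) {
  acat <- build_site_catalog(atac_peak_sets_by_timepoint, merge_gap_bp = 0)
  occ <- acat$occupancy
  tps <- colnames(occ)
  first_tp <- apply(occ, 1, function(o) {
    w <- which(o)
    if (length(w)) tps[w[1]] else NA_character_
  })
  cluster <- first_tp
  if (all(c("24h", "72h", "proB") %in% tps)) {
    closed <- !occ[, "proB"] & (occ[, "24h"] | occ[, "72h"]) &
      !(if ("0h" %in% tps) occ[, "0h"] else FALSE)
    cluster[closed] <- "transient"
  }
  has_site <- overlaps_any(acat$sites, catalog$sites)
  keep <- !is.na(cluster)
  agg <- tapply(has_site[keep], cluster[keep], function(x)
    c(n = length(x), with_site = sum(x)))
  out <- do.call(rbind, agg)
  data.frame(cluster = rownames(out), n_peaks = out[, "n"],
             n_with_site = out[, "with_site"],
             fraction = out[, "with_site"] / out[, "n"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Minimal Poisson enrichment peak caller
#'
#' Scans fixed windows, keeps those whose cut count clears a Poisson
#' upper-tail test against the (estimated or supplied) background rate,
#' merges them, and drops merged peaks narrower than `min_width`. A
#' stand-in for a full peak caller so synthetic coverage can be taken end
#' to end; real analyses may supply externally called peak files instead.
#'
#' @param track a `cut_track`.
#' @param background_rate cuts per bp (both strands); `NULL` estimates the
#'   genome-wide mean.
#' @param p_threshold Poisson upper-tail p-value cutoff.
#' @param min_width minimum merged peak width (bp).
#' @param window_bp scan window width.
#' @param step_bp scan step.
#' @return interval data frame of peaks.
#' @export
call_enrichment_peaks <- function(track, background_rate = NULL,
                                  p_threshold = 1e-5, min_width = 100,
                                  window_bp = 100, step_bp = 50) {
  empty <- genomic_intervals(character(), integer(), integer())
  if (track$total == 0) return(empty)
  if (is.null(background_rate)) {
    background_rate <- track$total / sum(track$chrom_sizes)
  }
  if (background_rate <= 0) stopf("background_rate must be > 0")
  hits <- list()
  for (chrom in names(track$chrom_sizes)) {
    len <- track$chrom_sizes[[chrom]]
    pos <- track$cuts$pos[track$cuts$chrom == chrom]
    if (length(pos) == 0L) next
    starts <- seq(0L, max(0L, len - window_bp), by = step_bp)
    counts <- findInterval(starts + window_bp, sort(pos)) -
      findInterval(starts, sort(pos))
    p <- ppois(counts - 1, background_rate * window_bp, lower.tail = FALSE)
    sig <- which(p < p_threshold)
    if (length(sig)) {
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = chrom, start = starts[sig], end = starts[sig] + window_bp,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) return(empty)
  merged <- granges_to_df(GenomicRanges::reduce(
    as_granges(do.call(rbind, hits)), min.gapwidth = 1L))
  merged <- merged[merged$end - merged$start >= min_width, , drop = FALSE]
  genomic_intervals(merged$chrom, merged$start, merged$end)
}
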