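# Replicate consensus, the unified site catalog across time points, and
# temporal occupancy classification (persistent subclassed by gain time
# versus transient).

#' Replicate-consensus peaks
#'
#' Keeps the peaks of the first replicate that overlap a peak in every other
#' replicate by at least `min_overlap_bp` bases (half-open intervals, so
#' touching peaks share no base). A single replicate is returned unchanged.
#'
#' @param replicate_peak_sets list of interval data frames, one per replicate.
#' @param min_overlap_bp minimum shared bases (>= 1).
#' @return interval data frame.
#' @export
replicate_consensus <- function(replicate_peak_sets, min_overlap_bp = 1) {
  if (length(replicate_peak_sets) == 0L) stopf("need >= 1 replicate set")
  if (min_overlap_bp < 1) stopf("min_overlap_bp must be >= 1")
  ref <- replicate_peak_sets[[1]]
  if (length(replicate_peak_sets) == 1L || nrow(ref) == 0L) return(ref)
  keep <- rep(TRUE, nrow(ref))
  for (other in replicate_peak_sets[-1]) {
    keep <- keep & overlaps_any(ref, other, min_overlap_bp)
  }
  ref[keep, , drop = FALSE]
}

#' Build a unified site catalog across time points
#'
#' Merges the union of per-time-point consensus peaks (overlapping peaks, or
#' peaks within `merge_gap_bp`, collapse into one site) and records, per
#' merged site and time point, whether it overlaps a consensus peak there.
#' The site centre is the midpoint of the merged interval.
#'
#' @param consensus_sets_by_timepoint named list (time point -> interval data
#'   frame) covering >= 2 time points.
#' @param merge_gap_bp maximum gap (bp) between peaks merged into one site;
#'   0 merges overlapping or directly adjacent peaks.
#' @return object of class `site_catalog`: `sites` (intervals with `site_id`
#'   and `center`), logical `occupancy` matrix (sites x time points),
#'   `timepoints`, and `classes` (NA until \code{\link{classify_temporal}}).
#' @export
build_site_catalog <- function(consensus_sets_by_timepoint, merge_gap_bp = 0) {
  tps <- order_timepoints(names(consensus_sets_by_timepoint))
  if (length(tps) < 2L) stopf("need >= 2 time points")
  sets <- consensus_sets_by_timepoint[tps]
  all_peaks <- do.call(rbind, lapply(sets, function(df)
    df[, c("chrom", "start", "end")]))
  if (nrow(all_peaks) == 0L) {
    sites <- data.frame(site_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        center = integer(), stringsAsFactors = FALSE)
    occ <- matrix(FALSE, 0, length(tps), dimnames = list(NULL, tps))
    return(structure(list(sites = sites, occupancy = occ, timepoints = tps,
                          classes = character(0)), class = "site_catalog"))
  }
  merged <- granges_to_df(GenomicRanges::reduce(
    as_granges(all_peaks), min.gapwidth = as.integer(merge_gap_bp) + 1L))
  merged <- merged[order(merged$chrom, merged$start), , drop = FALSE]
  sites <- data.frame(site_id = sprintf("cat_%05d", seq_len(nrow(merged))),
                      chrom = merged$chrom, start = merged$start,
                      end = merged$end,
                      center = as.integer(floor((merged$start + merged$end) / 2)),
                      stringsAsFactors = FALSE)
  occ <- vapply(tps, function(tp) overlaps_any(sites, sets[[tp]]),
                logical(nrow(sites)))
  occ <- matrix(occ, nrow = nrow(sites), dimnames = list(sites$site_id, tps))
  structure(list(sites = sites, occupancy = occ, timepoints = tps,
                 classes = setNames(rep(NA_character_, nrow(sites)),
                                    sites$site_id)),
            class = "site_catalog")
}

#' @export
print.site_catalog <- function(x, ...) {
  cat(sprintf("site_catalog: %d sites x %d time points (%s)\n",
              nrow(x$sites), length(x$timepoints),
              paste(x$timepoints, collapse = ", ")))
  if (!all(is.na(x$classes))) print(table(x$classes, useNA = "ifany"))
  invisible(x)
}

#' Assign temporal occupancy classes
#'
#' Persistent sites are occupied at the pro-B stage and are subclassed by the
#' earliest occupied time point (gain24 / gain72 / gainproB); persistent
#' sites first occupied at 24 h that were already accessible before
#' induction are labelled pre-existing when 0 h accessibility is supplied.
#' Transient sites are occupied at 24 h and/or 72 h but not at pro-B. Sites
#' occupied at no induced time point are `unclassified`. A 6-h column, if
#' present, never changes labels.
#'
#' @param catalog a `site_catalog` whose last core time point is pro-B.
#' @param accessible_0h optional: logical vector per site, or an interval
#'   data frame of 0 h accessible regions (a site is pre-accessible when it
#'   overlaps one).
#' @return the catalog with `classes` filled in.
#' @export
classify_temporal <- function(catalog, accessible_0h = NULL) {
  occ <- catalog$occupancy
  if (!"proB" %in% colnames(occ)) stopf("pro-B time point missing from catalog")
  have <- intersect(c("24h", "72h"), colnames(occ))
  at24 <- if ("24h" %in% have) occ[, "24h"] else rep(FALSE, nrow(occ))
  at72 <- if ("72h" %in% have) occ[, "72h"] else rep(FALSE, nrow(occ))
  atPB <- occ[, "proB"]

  pre_acc <- rep(FALSE, nrow(occ))
  if (!is.null(accessible_0h)) {
    if (is.data.frame(accessible_0h)) {
      pre_acc <- overlaps_any(catalog$sites, accessible_0h)
    } else {
      stopifnot(length(accessible_0h) == nrow(occ))
      pre_acc <- as.logical(accessible_0h)
    }
  }

  cls <- rep("unclassified", nrow(occ))
  cls[atPB & at24] <- "gain24"
  cls[atPB & !at24 & at72] <- "gain72"
  cls[atPB & !at24 & !at72] <- "gainproB"
  cls[!atPB & (at24 | at72)] <- "transient"
  cls[cls == "gain24" & pre_acc] <- "preexisting"
  catalog$classes <- setNames(cls, catalog$sites$site_id)
  catalog
}

#' Fraction of sites containing a canonical motif, per temporal class
#'
#' A site contains a motif hit when the hit midpoint lies within the site
#' interval.
#'
#' @param catalog a classified `site_catalog`.
#' @param motif_hits interval data frame of motif hits.
#' @return named numeric fraction in [0, 1] per class present in the catalog.
#' @export
motif_fraction_by_class <- function(catalog, motif_hits) {
  mids <- interval_midpoint(motif_hits)
  has_hit <- if (nrow(motif_hits) == 0L) rep(FALSE, nrow(catalog$sites)) else {
    hit_df <- data.frame(chrom = motif_hits$chrom, start = mids,
                         end = mids + 1L, stringsAsFactors = FALSE)
    overlaps_any(catalog$sites, hit_df)
  }
  cls <- catalog$classes
  keep <- !is.na(cls) & cls != "unclassified"
  tapply(has_hit[keep], cls[keep], mean)
}
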