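# Four-way classification of secondary-factor binding sites by dependence
# on the pioneer factor: co-occupancy in pro-B cells crossed with occupancy
# in the pioneer-factor-free induction sample, annotated with chromatin
# accessibility before induction and at pro-B.

#' Classify secondary-factor sites by pioneer-factor dependence
#'
#' The site universe is the secondary factor's pro-B peak set. A site is
#' co-bound when a pioneer-factor pro-B peak centre lies within
#' `cooccupancy_window_bp` of the site centre; it is independent when it
#' overlaps a peak from the knockout-induction sample (secondary factor
#' induced without the pioneer factor), else dependent. Accessibility flags
#' may be supplied as logical vectors (aligned to the site universe) or as
#' interval sets of accessible regions.
#'
#' @param pax5_sites_proB secondary-factor pro-B peaks (site universe).
#' @param pax5_peaks_in_knockout knockout-induction peak set.
#' @param ebf1_peaks_proB pioneer-factor pro-B peak set.
#' @param atac_0h,atac_proB logical per-site flags, interval data frames of
#'   accessible regions, or NULL.
#' @param cooccupancy_window_bp centre-to-centre co-occupancy window.
#' @return data frame per site: flags `ebf1_cooccupied`,
#'   `bound_without_ebf1`, `accessible_pre`, `accessible_proB`, and the
#'   four-way `label`.
#' @export
classify_dependence <- function(pax5_sites_proB, pax5_peaks_in_knockout,
                                ebf1_peaks_proB, atac_0h = NULL,
                                atac_proB = NULL,
                                cooccupancy_window_bp = 200) {
  sites <- pax5_sites_proB
  if (nrow(sites) == 0L) {
    warning("empty secondary-factor site universe")
    return(data.frame(site_id = character(), ebf1_cooccupied = logical(),
                      bound_without_ebf1 = logical(),
                      accessible_pre = logical(),
                      accessible_proB = logical(), label = character(),
                      stringsAsFactors = FALSE))
  }
  ctr <- interval_midpoint(sites)
  eb_ctr <- interval_midpoint(ebf1_peaks_proB)
  cooc <- vapply(seq_len(nrow(sites)), function(i) {
    any(ebf1_peaks_proB$chrom == sites$chrom[i] &
          abs(eb_ctr - ctr[i]) <= cooccupancy_window_bp)
  }, logical(1))
  bound_ko <- overlaps_any(sites, pax5_peaks_in_knockout)

  flag_from <- function(x) {
    if (is.null(x)) return(rep(NA, nrow(sites)))
    if (is.data.frame(x)) return(overlaps_any(sites, x))
    stopifnot(length(x) == nrow(sites))
    as.logical(x)
  }
  acc0 <- flag_from(atac_0h)
  accP <- flag_from(atac_proB)

  label <- paste0(ifelse(cooc, "cobound", "solo"), "_",
                  ifelse(bound_ko, "independent", "dependent"))
  data.frame(
    site_id = if ("name" %in% names(sites)) sites$name else
      sprintf("sf_%05d", seq_len(nrow(sites))),
    ebf1_cooccupied = cooc, bound_without_ebf1 = bound_ko,
    accessible_pre = acc0, accessible_proB = accP, label = label,
    stringsAsFactors = FALSE)
}

#' Accessibility contingency summary of the dependence classes
#'
#' Per-label counts of pre-induction and pro-B accessibility plus a Fisher
#' test of pre-accessibility in dependent versus independent sites.
#'
#' @param classification output of \code{\link{classify_dependence}}.
#' @return list with `table` (per-label counts and accessible fractions)
#'   and `fisher_pre` (dependent vs independent pre-accessibility test).
#' @export
dependence_accessibility_summary <- function(classification) {
  labels <- c("cobound_independent", "cobound_dependent",
              "solo_independent", "solo_dependent")
  tab <- do.call(rbind, lapply(labels, function(l) {
    sel <- classification$label == l
    data.frame(label = l, n = sum(sel),
               accessible_pre = sum(classification$accessible_pre[sel],
                                    na.rm = TRUE),
               accessible_proB = sum(classification$accessible_proB[sel],
                                     na.rm = TRUE),
               frac_accessible_pre = if (sum(sel)) {
                 mean(classification$accessible_pre[sel], na.rm = TRUE)
               } else NA_real_,
               frac_accessible_proB = if (sum(sel)) {
                 mean(classification$accessible_proB[sel], na.rm = TRUE)
               } else NA_real_,
               stringsAsFactors = FALSE)
  }))
  dep <- !classification$bound_without_ebf1
  ft <- if (any(dep) && any(!dep) && !all(is.na(classification$accessible_pre))) {
    m <- table(dependent = dep, accessible_pre = classification$accessible_pre)
    if (all(dim(m) == c(2, 2))) fisher.test(m) else NULL
  } else NULL
  list(table = tab,
       fisher_pre = if (is.null(ft)) NULL else
         list(odds_ratio = unname(ft$estimate), p_value = ft$p.value))
}

#' Early (6-h) occupancy overlap by temporal class
#'
#' Fraction of catalog sites per temporal class that overlap (>= 1 bp) a
#' peak from the early induction time point.
#'
#' @param catalog a classified `site_catalog` (pro-B site universe).
#' @param peaks_6h early-time-point peak set.
#' @param collapse_persistent also report persistent classes pooled.
#' @return data frame `class`, `n`, `n_overlap`, `fraction`.
#' @export
early_occupancy_overlap <- function(catalog, peaks_6h,
                                    collapse_persistent = TRUE) {
  hit <- overlaps_any(catalog$sites, peaks_6h)
  cls <- catalog$classes
  keep <- !is.na(cls) & cls != "unclassified"
  groups <- split(hit[keep], cls[keep])
  if (collapse_persistent) {
    pers <- cls[keep] %in% c("preexisting", "gain24", "gain72", "gainproB")
    if (any(pers)) groups$persistent <- hit[keep][pers]
  }
  do.call(rbind, lapply(names(groups), function(g) {
    data.frame(class = g, n = length(groups[[g]]),
               n_overlap = sum(groups[[g]]),
               fraction = mean(groups[[g]]), stringsAsFactors = FALSE)
  }))
}
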