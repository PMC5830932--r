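# CpG methylation tracks, low-methylated-region (LMR) detection, +/-100-bp
# site methylation, and class-resolved demethylation dynamics.

#' Construct a methylation track
#'
#' @param df data frame with `chrom`, `pos` (1-based CpG position), `frac`
#'   (methylated fraction in [0, 1]) and `cov` (read coverage).
#' @return object of class `methylation_track`.
#' @export
methylation_track <- function(df) {
  stopifnot(all(c("chrom", "pos", "frac", "cov") %in% names(df)))
  if (any(df$frac < 0 | df$frac > 1)) stopf("methylation fractions outside [0, 1]")
  for (chrom in unique(df$chrom)) {
    p <- df$pos[df$chrom == chrom]
    if (is.unsorted(p, strictly = TRUE)) {
      stopf("positions not strictly increasing on %s", chrom)
    }
  }
  structure(df, class = c("methylation_track", "data.frame"))
}

#' Read CpG methylation calls
#'
#' Expects a 4-column TSV (chrom, 1-based position, percent methylation,
#' coverage), bismark-coverage-like. Percentages are stored as proportions;
#' rows under `min_coverage` are dropped (count reported via message).
#'
#' @param path file path.
#' @param min_coverage minimum reads per CpG for inclusion.
#' @return a `methylation_track`.
#' @export
read_methylation <- function(path, min_coverage = 5) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "pos", "pct", "cov"),
                   colClasses = c("character", "integer", "numeric",
                                  "integer"))
  if (nrow(df) && (any(df$pct < 0) || any(df$pct > 100))) {
    stopf("validation error: percent methylation outside [0, 100] in %s", path)
  }
  dropped <- sum(df$cov < min_coverage)
  if (dropped > 0) {
    message(sprintf("read_methylation: dropped %d CpG(s) below %dx coverage",
                    dropped, min_coverage))
    df <- df[df$cov >= min_coverage, , drop = FALSE]
  }
  methylation_track(data.frame(chrom = df$chrom, pos = df$pos,
                               frac = df$pct / 100, cov = df$cov,
                               stringsAsFactors = FALSE))
}

#' Write a methylation track as a 4-column TSV
#'
#' @param track a `methylation_track`.
#' @param path output path.
#' @export
write_methylation <- function(track, path) {
  out <- data.frame(chrom = track$chrom, pos = track$pos,
                    pct = format(track$frac * 100, digits = 10,
                                 trim = TRUE, scientific = FALSE),
                    cov = track$cov)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Call low-methylated regions (LMRs)
#'
#' Maximal runs of consecutive CpGs, each below the upper band edge, with
#' inter-CpG gaps at most `max_gap_bp`, at least `min_cpgs` CpGs, and a run
#' mean inside `low_band`. Conventional LMR parameters (intermediate 10--50%
#' methylation, >= 4 CpGs) are the defaults.
#'
#' @param track a `methylation_track`.
#' @param low_band inclusive range the run mean must fall in.
#' @param min_cpgs minimum CpGs per region.
#' @param max_gap_bp maximum distance between consecutive CpGs in a run.
#' @return interval data frame (0-based half-open, spanning the outermost
#'   CpGs) with `mean_meth` and `n_cpgs`.
#' @export
call_lmrs <- function(track, low_band = c(0.10, 0.50), min_cpgs = 4,
                      max_gap_bp = 250) {
  if (nrow(track) == 0L) stopf("empty methylation track")
  out <- list()
  for (chrom in unique(track$chrom)) {
    sub <- track[track$chrom == chrom, , drop = FALSE]
    low <- sub$frac < low_band[2]
    # split low-CpG stretch wherever a high CpG or a long gap intervenes
    run_id <- integer(nrow(sub))
    cur <- 0L
    prev_pos <- -Inf
    prev_low <- FALSE
    for (i in seq_len(nrow(sub))) {
      if (low[i]) {
        if (!prev_low || sub$pos[i] - prev_pos > max_gap_bp) cur <- cur + 1L
        run_id[i] <- cur
      }
      prev_low <- low[i]
      prev_pos <- sub$pos[i]
    }
    for (r in unique(run_id[run_id > 0L])) {
      idx <- which(run_id == r)
      if (length(idx) < min_cpgs) next
      m <- mean(sub$frac[idx])
      if (m < low_band[1] || m > low_band[2]) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = sub$pos[idx[1]] - 1L,
        end = sub$pos[idx[length(idx)]],
        mean_meth = m, n_cpgs = length(idx), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), mean_meth = numeric(),
                      n_cpgs = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Mean methylation in a window around each site
#'
#' Coverage-weighted mean CpG fraction within `window_bp` of the site
#' centre; `NA` when no covered CpG falls in the window.
#'
#' @param track a `methylation_track`.
#' @param catalog a `site_catalog` (or data frame with `chrom`, `center`).
#' @param window_bp half-window (bp), default the +/-100-bp convention.
#' @param weighted coverage-weight the mean (default) or not.
#' @return named numeric per site.
#' @export
site_methylation <- function(track, catalog, window_bp = 100,
                             weighted = TRUE) {
  sites <- if (inherits(catalog, "site_catalog")) catalog$sites else catalog
  out <- setNames(rep(NA_real_, nrow(sites)), sites$site_id)
  for (chrom in unique(sites$chrom)) {
    sub <- track[track$chrom == chrom, , drop = FALSE]
    idx <- which(sites$chrom == chrom)
    if (nrow(sub) == 0L) next
    pos0 <- sub$pos - 1L
    for (i in idx) {
      sel <- abs(pos0 - sites$center[i]) <= window_bp
      if (!any(sel)) next
      out[i] <- if (weighted) {
        sum(sub$frac[sel] * sub$cov[sel]) / sum(sub$cov[sel])
      } else {
        mean(sub$frac[sel])
      }
    }
  }
  out
}

#' Class-resolved demethylation dynamics at LMR-associated sites
#'
#' Restricts the catalog to sites whose centre lies within `assoc_bp` of an
#' LMR and tabulates per-site window methylation across time points (the
#' cloud-map table) plus per-class medians of the 72h-0h and proB-72h
#' deltas.
#'
#' @param per_timepoint_site_methylation named list (time point -> named
#'   numeric from \code{\link{site_methylation}}).
#' @param catalog a classified `site_catalog`.
#' @param lmr_set LMR interval data frame.
#' @param assoc_bp association distance between site centre and LMR.
#' @return list with `table` (site_id, class, m_<tp> columns) and `summary`
#'   (per-class median deltas).
#' @export
methylation_dynamics <- function(per_timepoint_site_methylation, catalog,
                                 lmr_set, assoc_bp = 150) {
  tps <- order_timepoints(names(per_timepoint_site_methylation))
  meth <- per_timepoint_site_methylation[tps]
  sites <- catalog$sites
  ctr <- data.frame(chrom = sites$chrom, start = sites$center,
                    end = sites$center + 1L, stringsAsFactors = FALSE)
  near <- if (nrow(lmr_set) == 0L) rep(FALSE, nrow(sites)) else {
    grown <- data.frame(chrom = lmr_set$chrom,
                        start = pmax(0L, lmr_set$start - assoc_bp),
                        end = lmr_set$end + assoc_bp,
                        stringsAsFactors = FALSE)
    overlaps_any(ctr, grown)
  }
  keep <- near & !is.na(catalog$classes) & catalog$classes != "unclassified"
  tab <- data.frame(site_id = sites$site_id[keep],
                    class = catalog$classes[keep],
                    stringsAsFactors = FALSE)
  for (tp in tps) tab[[paste0("m_", tp)]] <- meth[[tp]][keep]

  deltas <- list()
  if (all(c("0h", "72h") %in% tps)) {
    deltas$delta_72h_0h <- tab$m_72h - tab$m_0h
  }
  if (all(c("72h", "proB") %in% tps)) {
    deltas$delta_proB_72h <- tab$m_proB - tab$m_72h
  }
  summary <- do.call(rbind, lapply(sort(unique(tab$class)), function(cl) {
    sel <- tab$class == cl
    row <- data.frame(class = cl, n = sum(sel), stringsAsFactors = FALSE)
    for (d in names(deltas)) {
      row[[paste0("median_", d)]] <- median(deltas[[d]][sel], na.rm = TRUE)
    }
    row
  }))
  list(table = tab, summary = summary)
}
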