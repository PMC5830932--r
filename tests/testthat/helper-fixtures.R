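# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from disk except files the tests themselves write to
# tempdir().

# A tiny hand-built catalog from explicit per-timepoint peak sets.
toy_catalog <- function(sets, accessible_0h = NULL, merge_gap_bp = 0) {
  cat_ <- build_site_catalog(sets, merge_gap_bp = merge_gap_bp)
  classify_temporal(cat_, accessible_0h = accessible_0h)
}

# Quadratic brute-force interval merge (union-find), the oracle for
# build_site_catalog.
bf_merge_intervals <- function(df, merge_gap_bp = 0) {
  n <- nrow(df)
  if (n == 0L) return(df[, c("chrom", "start", "end")])
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (df$chrom[i] == df$chrom[j] &&
          df$start[i] <= df$end[j] + merge_gap_bp &&
          df$start[j] <= df$end[i] + merge_gap_bp) {
        parent[find(j)] <- find(i)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- do.call(rbind, lapply(unique(root), function(r) {
    sub <- df[root == r, , drop = FALSE]
    data.frame(chrom = sub$chrom[1], start = min(sub$start),
               end = max(sub$end), stringsAsFactors = FALSE)
  }))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Brute-force overlap test (>= min_ov shared bases, half-open).
bf_overlaps <- function(a, b, min_ov = 1L) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] &
          pmin(a$end[i], b$end) - pmax(a$start[i], b$start) >= min_ov)
  }, logical(1))
}

# Random interval set on one toy chromosome.
random_intervals <- function(n, chrom_len = 1e5, width = c(50, 400),
                             chrom = "chrT1") {
  start <- sort(sample.int(chrom_len - width[2], n, replace = TRUE))
  w <- sample(width[1]:width[2], n, replace = TRUE)
  genomic_intervals(chrom, start, start + w)
}

# A signal_matrix object built directly from a values matrix.
toy_signal_matrix <- function(values, window_bp = 3000, bin_bp = 50) {
  structure(list(values = values,
                 bin_centers = seq(-window_bp + bin_bp / 2,
                                   window_bp - bin_bp / 2, by = bin_bp),
                 site_ids = rownames(values), window_bp = window_bp,
                 bin_bp = bin_bp,
                 edge_clipped = rep(FALSE, nrow(values))),
            class = "signal_matrix")
}

# A cut_track with an arbitrary nominal total (for normalization tests).
toy_cut_track <- function(cuts, chrom_sizes, total = nrow(cuts)) {
  structure(list(cuts = cuts, chrom_sizes = chrom_sizes, total = total),
            class = "cut_track")
}
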