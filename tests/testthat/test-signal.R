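test_that("RPKM values follow the normalization formula", {
  sites <- data.frame(site_id = "s1", chrom = "c", center = 5000L)
  cuts <- data.frame(chrom = "c", pos = 5010L, strand = "+")
  track <- toy_cut_track(cuts, c(c = 10000L), total = 1e6)
  mat <- compute_signal_matrix(track, sites, window_bp = 3000, bin_bp = 50)
  # one fragment in a 50-bp bin at 1e6 total fragments -> 20 RPKM
  expect_equal(sum(mat$values), 20)
  expect_equal(max(mat$values), 20)
  # doubling the total halves every value
  track2 <- toy_cut_track(cuts, c(c = 10000L), total = 2e6)
  mat2 <- compute_signal_matrix(track2, sites)
  expect_equal(mat2$values, mat$values / 2)
  # empty track warns and returns zeros
  empty <- toy_cut_track(cuts[0, ], c(c = 10000L))
  expect_warning(m0 <- compute_signal_matrix(empty, sites), "empty")
  expect_true(all(m0$values == 0))
})

test_that("signal matrix equals a naive per-bin recount oracle", {
  set.seed(5)
  n_sites <- 10
  sites <- data.frame(site_id = sprintf("s%02d", 1:n_sites), chrom = "c",
                      center = sort(sample(4000:96000, n_sites)))
  cuts <- data.frame(chrom = "c", pos = sample.int(1e5, 5000, replace = TRUE),
                     strand = "+")
  track <- toy_cut_track(cuts, c(c = 1e5L))
  mat <- compute_signal_matrix(track, sites, window_bp = 3000, bin_bp = 50)
  expect_equal(ncol(mat$values), 120L)
  oracle <- matrix(0, n_sites, 120)
  for (i in 1:n_sites) {
    for (b in 1:120) {
      lo <- sites$center[i] - 3000 + (b - 1) * 50
      cnt <- sum(cuts$pos >= lo & cuts$pos < lo + 50)
      oracle[i, b] <- cnt * 1e9 / (50 * nrow(cuts))
    }
  }
  expect_equal(mat$values, oracle, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("RPKM mass is conserved over non-overlapping windows", {
  set.seed(6)
  sites <- data.frame(site_id = c("a", "b"), chrom = "c",
                      center = c(10000L, 30000L))
  cuts <- data.frame(chrom = "c", pos = sample.int(40000, 2000, replace = TRUE),
                     strand = "+")
  track <- toy_cut_track(cuts, c(c = 40000L))
  mat <- compute_signal_matrix(track, sites)
  implied <- sum(mat$values) * 50 * track$total / 1e9
  direct <- sum(abs(cuts$pos - 10000) < 3000 | abs(cuts$pos - 30000) < 3000)
  expect_equal(implied, direct, tolerance = 1e-9)
})

test_that("accessibility thresholds implement the gain/pre-existing logic", {
  # hand-built central signals: one bin per side of centre carries the mean
  mk <- function(centrals) {
    lapply(centrals, function(v) {
      vals <- matrix(0, length(v), 120)
      vals[, 60:61] <- v  # centre bins only
      rownames(vals) <- sprintf("s%d", seq_along(v))
      toy_signal_matrix(vals)
    })
  }
  sets <- list("24h" = genomic_intervals("c", c(100, 1100), c(300, 1300)),
               "proB" = genomic_intervals("c", c(100, 1100), c(300, 1300)))
  cat_ <- build_site_catalog(sets)
  # site 1: accessible at 0 h and occupied at 24 h -> pre-existing
  # site 2: dark at 0 h, gains at 24 h -> gain24
  # the +/-500-bp central zone spans 20 bins, two of which carry the value,
  # so a stored value v yields central signal v/10
  mats <- mk(list("0h" = c(80, 5), "24h" = c(90, 360), "72h" = c(90, 420),
                  "proB" = c(90, 480)))
  lab <- classify_accessibility(mats, cat_, min_rpkm = 5)
  expect_equal(unname(lab), c("preexisting", "gain24"))
  # transient accessibility: gains by 72 h, closed again at pro-B
  mats2 <- mk(list("0h" = c(5), "24h" = c(360), "72h" = c(420),
                   "proB" = c(5)))
  cat2 <- build_site_catalog(lapply(sets, function(x) x[1, ]))
  expect_equal(unname(classify_accessibility(mats2, cat2, min_rpkm = 5)),
               "transient")
})

test_that("accessibility clusters recover planted classes on synthetic data", {
  g <- generate_genome(n_sites = 250, seed = 41)
  noise <- noise_model(peak_dropout_prob = 0.02)
  pk <- generate_timecourse_peaks(g, noise, n_replicates = 1, seed = 42)
  cat_ <- classify_temporal(build_site_catalog(lapply(pk, replicate_consensus)))
  cuts <- generate_cut_counts(g, noise, seed = 43)
  mats <- lapply(cuts, compute_signal_matrix, catalog = cat_)
  lab <- classify_accessibility(mats, cat_)
  truth <- g$sites$true_class[match_sites_to_truth(cat_, g)]
  ok <- !is.na(truth)
  expect_gt(mean(lab[ok] == truth[ok]), 0.9)
  # labels partition labeled sites
  expect_true(all(lab %in% c("preexisting", "gain24", "gain72", "gainproB",
                             "transient", "unclassified")))
})

test_that("central depletion profiles report the centre-to-shoulder ratio", {
  flat <- toy_signal_matrix(matrix(3, 10, 120,
                                   dimnames = list(sprintf("s%d", 1:10), NULL)))
  res <- central_depletion_profile(flat, rep("x", 10))
  expect_equal(unname(res$ratio["x"]), 1.0)
  # planted bimodal profile with a 0.5 centre/shoulder ratio
  prof <- rep(1, 120)
  bc <- seq(-2975, 2975, by = 50)
  prof[abs(bc) >= 500 & abs(bc) <= 1000] <- 4
  prof[abs(bc) <= 100] <- 2
  m <- toy_signal_matrix(matrix(rep(prof, each = 20), 20, 120,
                                dimnames = list(sprintf("s%d", 1:20), NULL)))
  res <- central_depletion_profile(m, rep("dip", 20))
  expect_equal(unname(res$ratio["dip"]), 0.5, tolerance = 0.05)
  # all-zero shoulders are degenerate
  z <- toy_signal_matrix(matrix(0, 5, 120,
                                dimnames = list(sprintf("s%d", 1:5), NULL)))
  expect_warning(rz <- central_depletion_profile(z, rep("z", 5)), "zero")
  expect_true(is.na(rz$ratio["z"]))
})

test_that("ATAC-peak clusters report planted site frequencies", {
  g <- generate_genome(n_sites = 400, seed = 44)
  noise <- noise_model(peak_dropout_prob = 0)
  at <- generate_timecourse_peaks(g, noise, assay = "atac", n_replicates = 1,
                                  atac_site_frequency = c(
                                    "0h" = 0.9, "24h" = 0.9, "72h" = 0.8,
                                    "proB" = 0.4, "transient" = 0.8),
                                  seed = 45)
  pk <- generate_timecourse_peaks(g, noise, n_replicates = 1, seed = 46)
  cat_ <- classify_temporal(build_site_catalog(lapply(pk, replicate_consensus)))
  freq <- atac_peak_site_frequency(lapply(at, `[[`, 1), cat_)
  f <- setNames(freq$fraction, freq$cluster)
  expect_lt(abs(f[["24h"]] - 0.9), 0.05)
  expect_lt(abs(f[["proB"]] - 0.4), 0.05)
  # trivial bounds: no overlap -> 0
  far <- cat_
  far$sites$start <- far$sites$start + 1000000L
  far$sites$end <- far$sites$end + 1000000L
  far$sites$center <- far$sites$center + 1000000L
  f0 <- atac_peak_site_frequency(lapply(at, `[[`, 1), far)
  expect_true(all(f0$fraction == 0))
})

test_that("the Poisson enrichment caller finds planted windows, not noise", {
  # uniform background yields no calls across 20 seeds
  fp_total <- 0L
  for (s in 1:20) {
    set.seed(s)
    cuts <- data.frame(chrom = "c", pos = sample.int(2e5, 2000, replace = TRUE),
                       strand = "+")
    pk <- call_enrichment_peaks(cut_track(cuts, c(c = 2e5L)),
                                p_threshold = 1e-5)
    fp_total <- fp_total + nrow(pk)
  }
  expect_lte(fp_total, 1L)
  # planted 10x window recovered within 100 bp
  set.seed(99)
  bg <- data.frame(chrom = "c", pos = sample.int(2e5, 2000, replace = TRUE),
                   strand = "+")
  hot <- data.frame(chrom = "c",
                    pos = sample(100000:100300, 300, replace = TRUE),
                    strand = "+")
  pk <- call_enrichment_peaks(cut_track(rbind(bg, hot), c(c = 2e5L)),
                              background_rate = 0.01)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$start - 100000), 100)
  expect_lt(abs(pk$end - 100300), 100)
  # empty track -> no peaks
  expect_equal(nrow(call_enrichment_peaks(cut_track(bg[0, ], c(c = 2e5L)))),
               0L)
})
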