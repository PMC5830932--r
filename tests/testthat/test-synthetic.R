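test_that("genome generation enforces exact class proportions and determinism", {
  g <- generate_genome(n_sites = 100, n_genes = 50, chrom_len = 1e6, seed = 1)
  tab <- table(g$sites$true_class)
  expect_equal(length(tab), 5L)
  expect_true(all(tab == 20L))
  g2 <- generate_genome(n_sites = 100, n_genes = 50, chrom_len = 1e6, seed = 1)
  expect_identical(g, g2)

  g3 <- generate_genome(n_sites = 50, seed = 2,
                        class_proportions = c(gain24 = 1))
  expect_true(all(g3$sites$true_class == "gain24"))
  expect_error(generate_genome(class_proportions = c(gain24 = 0.5)),
               "sum to 1")
  expect_error(generate_genome(n_sites = 3), ">= 5")
  # coordinates within bounds, unique ids
  expect_true(all(g$sites$center > 0 & g$sites$center < 1e6))
  expect_false(any(duplicated(g$sites$site_id)))
  expect_false(any(duplicated(g$genes$gene_id)))
})

test_that("peak emission is gated by temporal class", {
  g <- generate_genome(n_sites = 50, seed = 3)
  noise <- noise_model(peak_dropout_prob = 0)
  pk <- generate_timecourse_peaks(g, noise, n_replicates = 1, seed = 4)
  present <- function(tp, ids) ids %in% pk[[tp]][[1]]$name
  tr <- g$sites$site_id[g$sites$true_class == "transient"]
  expect_true(all(present("24h", tr)) && all(present("72h", tr)))
  expect_false(any(present("proB", tr)))
  gp <- g$sites$site_id[g$sites$true_class == "gainproB"]
  expect_false(any(present("24h", gp)) || any(present("72h", gp)))
  expect_true(all(present("proB", gp)))
  expect_false(any(present("0h", g$sites$site_id)))  # no ChIP before induction

  # total dropout empties every peak set
  pk0 <- generate_timecourse_peaks(g, noise_model(peak_dropout_prob = 1),
                                   n_replicates = 2, seed = 5)
  expect_true(all(vapply(unlist(pk0, recursive = FALSE), nrow, 1L) == 0L))

  # ATAC: pre-existing sites accessible before induction
  at <- generate_timecourse_peaks(g, noise, assay = "atac",
                                  n_replicates = 1, seed = 6)
  pre <- g$sites$site_id[g$sites$true_class == "preexisting"]
  expect_true(all(pre %in% at[["0h"]][[1]]$name))
  expect_false(any(gp %in% at[["0h"]][[1]]$name))
})

test_that("cut tracks deplete planted footprints and respect class gating", {
  g <- generate_genome(n_sites = 200, seed = 7,
                       class_proportions = c(gain24 = 1))
  noise <- noise_model(background_rate = 0, signal_depth = 400)
  cuts <- generate_cut_counts(g, noise, seed = 8)
  # unoccupied time point: no cuts anywhere (class-gated, zero background)
  expect_equal(nrow(cuts[["0h"]]$cuts), 0L)
  # interior/shoulder rate ratio over all sites approaches the planted 0.1
  tp <- cuts[["proB"]]$cuts
  rel <- unlist(lapply(seq_len(nrow(g$sites)), function(i) {
    tp$pos[tp$chrom == g$sites$chrom[i]] - g$sites$center[i]
  }))
  rel <- rel[abs(rel) < 150]
  fw <- g$sites$footprint_width[1]
  interior_rate <- sum(abs(rel) < fw / 2) / fw
  shoulder_rate <- sum(abs(rel) >= fw / 2) / (300 - fw)
  expect_lt(interior_rate / shoulder_rate, 0.2)
  expect_equal(interior_rate / shoulder_rate, 0.1, tolerance = 0.5)

  # zero depth and zero background: empty everywhere
  quiet <- generate_cut_counts(g, noise_model(background_rate = 0,
                                              signal_depth = 0), seed = 9)
  expect_equal(nrow(quiet[["proB"]]$cuts), 0L)
})

test_that("methylome recovers planted profiles in site windows", {
  g <- generate_genome(n_sites = 200, seed = 10)
  noise <- noise_model(meth_coverage = 30)
  meth <- generate_methylome(g, noise, seed = 11)
  sites_df <- data.frame(site_id = g$sites$site_id, chrom = g$sites$chrom,
                         center = g$sites$center)
  for (tp in c("0h", "72h", "proB")) {
    m <- site_methylation(meth[[tp]], sites_df)
    for (cl in c("gain24", "transient", "preexisting")) {
      idx <- g$sites$true_class == cl
      planted <- unname(g$meth_profiles[g$sites$site_id[idx], tp][1])
      expect_lt(abs(median(m[idx], na.rm = TRUE) - planted), 0.05)
    }
  }
  # transient sites are flat after 72 h
  m72 <- site_methylation(meth[["72h"]], sites_df)
  mPB <- site_methylation(meth[["proB"]], sites_df)
  tr <- g$sites$true_class == "transient"
  expect_lt(abs(median(mPB[tr] - m72[tr], na.rm = TRUE)), 0.05)
})

test_that("expression tables encode templates and template misuse errors", {
  g <- generate_genome(n_sites = 100, n_genes = 60, seed = 12)
  noise <- noise_model(expr_dispersion = 0)
  ex <- generate_expression(g, noise, seed = 13)
  ab <- ex$abundance
  # a U1-like linked gene is up > 10-fold at 24 h, with little further change
  u1 <- ex$truth$gene_id[ex$truth$template == "U1"][1]
  expect_false(is.na(u1))
  m0 <- mean(ab[u1, ex$samples$timepoint == "0h"])
  m24 <- mean(ab[u1, ex$samples$timepoint == "24h"])
  mPB <- mean(ab[u1, ex$samples$timepoint == "proB"])
  expect_gt(m24 / m0, 10)
  expect_equal(log2(mPB / m24), 0, tolerance = 0.25)
  # a D4-like gene rises before its sharp pro-B repression
  d4 <- ex$truth$gene_id[ex$truth$template == "D4"][1]
  expect_false(is.na(d4))
  expect_gt(mean(ab[d4, ex$samples$timepoint == "24h"]),
            mean(ab[d4, ex$samples$timepoint == "0h"]))
  expect_lt(mean(ab[d4, ex$samples$timepoint == "proB"]),
            mean(ab[d4, ex$samples$timepoint == "0h"]))

  expect_error(generate_expression(g, noise,
                                   cluster_templates = list(U1 = c(1, 2))),
               "length")

  # flat templates yield no differential genes at zero noise
  flat <- lapply(default_templates(), function(x) x * 0)
  ex0 <- generate_expression(g, noise_model(expr_dispersion = 0.05),
                             cluster_templates = flat, seed = 14)
  de <- differential_genes(ex0)
  expect_equal(sum(de$de), 0L)
})

test_that("generators are deterministic per seed", {
  g <- generate_genome(n_sites = 30, seed = 20)
  n <- noise_model(peak_dropout_prob = 0.1)
  expect_identical(generate_timecourse_peaks(g, n, seed = 21),
                   generate_timecourse_peaks(g, n, seed = 21))
  expect_identical(generate_cut_counts(g, n, seed = 22),
                   generate_cut_counts(g, n, seed = 22))
  expect_identical(generate_methylome(g, n, seed = 23),
                   generate_methylome(g, n, seed = 23))
  expect_identical(generate_expression(g, n, seed = 24),
                   generate_expression(g, n, seed = 24))
})
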