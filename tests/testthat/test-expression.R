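test_that("differential calling applies the fold, p and expression filters", {
  tab <- simulate_de_table(n_genes = 300, n_de = 60, n_low = 15, seed = 21)
  de <- differential_genes(tab)
  truth <- tab$truth
  sens <- sum(de$de & truth$de) / sum(truth$de)
  expect_gte(sens, 0.95)
  expect_lte(sum(de$de & !truth$de), 5)
  # the FPKM < 1-in-both filter removes planted low-expression genes exactly
  expect_equal(sum(de$de & truth$low_expressed), 0L)
  expect_true(all(de$low_expressed[truth$low_expressed]))

  # a flat gene (FC = 1) is never differential
  flat <- de[match(truth$gene_id[!truth$de & !truth$low_expressed],
                   de$gene_id), ]
  expect_true(all(!flat$de | abs(flat$log2fc) > 1))

  # low-expression example from the filter definition
  ab <- matrix(c(0.3, 0.3, 0.8, 0.8), 1,
               dimnames = list("g1", c("0h_rep1", "0h_rep2",
                                       "proB_rep1", "proB_rep2")))
  samples <- data.frame(timepoint = c("0h", "0h", "proB", "proB"),
                        replicate = c(1, 2, 1, 2),
                        sample_id = colnames(ab))
  genes <- data.frame(gene_id = "g1", chrom = "c", strand = "+", tss = 100L)
  et <- expression_table(ab, samples, genes)
  d1 <- differential_genes(et)
  expect_false(d1$de)
  expect_true(d1$low_expressed)

  # missing pro-B replicates are a configuration error
  et2 <- expression_table(ab[, 1:2, drop = FALSE], samples[1:2, ], genes)
  expect_error(differential_genes(et2), "proB")
})

test_that("nearest-TSS assignment respects the window and the nearest rule", {
  genes <- data.frame(gene_id = c("gB", "gA"), chrom = "c", strand = "+",
                      tss = c(50000L, 64000L))
  sites <- data.frame(site_id = c("s1", "s2", "s3"), chrom = "c",
                      center = c(60000L, 90000L, 40100L))
  map <- assign_genes_to_sites(sites, genes)
  # s1 is 10 kb from gB and 4 kb from gA: nearest only
  expect_equal(map$gene_id[map$site_id == "s1"], "gA")
  # s2 is 26 kb from the nearest TSS: unlinked
  expect_false("s2" %in% map$site_id)
  # s3 is 9.9 kb from gB: linked
  expect_equal(map$gene_id[map$site_id == "s3"], "gB")
  # exact tie goes to the lexicographically smaller gene id
  tie <- assign_genes_to_sites(
    data.frame(site_id = "t", chrom = "c", center = 57000L), genes)
  expect_equal(tie$gene_id, "gA")

  # brute-force nearest-TSS oracle on 200 random sites
  set.seed(22)
  g2 <- data.frame(gene_id = sprintf("g%03d", 1:40), chrom = "c",
                   strand = "+", tss = sample.int(5e5, 40))
  s2 <- data.frame(site_id = sprintf("s%03d", 1:200), chrom = "c",
                   center = sample.int(5e5, 200))
  map2 <- assign_genes_to_sites(s2, g2)
  for (i in seq_len(nrow(s2))) {
    d <- abs(s2$center[i] - g2$tss)
    linked <- map2[map2$site_id == s2$site_id[i], ]
    if (min(d) > 25000) {
      expect_equal(nrow(linked), 0L)
    } else {
      cand <- g2$gene_id[d == min(d)]
      expect_equal(linked$gene_id, sort(cand)[1])
    }
  }
  # each site maps to at most one gene
  expect_false(any(duplicated(map2$site_id)))
})

test_that("amplitude strata split at the 10-fold boundary", {
  de <- data.frame(gene_id = c("pdgfrb", "cebpb", "edge"),
                   log2fc = c(-log2(73), -log2(9.8), log2(10)),
                   de = TRUE)
  st <- stratify_by_amplitude(de)
  expect_equal(st$stratum, c("stringent", "lenient", "lenient"))
  expect_equal(sort(unique(st$stratum[st$fold_change > 10])), "stringent")
})

test_that("model-profile clustering is exact on noise-free trajectories", {
  tpl <- default_templates()
  profs <- do.call(rbind, lapply(tpl, function(x) matrix(rep(x, 20),
                                                         ncol = 3, byrow = TRUE)))
  rownames(profs) <- sprintf("%s_%02d", rep(names(tpl), each = 20), 1:20)
  colnames(profs) <- c("24h", "72h", "proB")
  res <- stem_cluster(profs, seed = 23)
  # all genes of one template land on one profile
  for (nm in names(tpl)) {
    ids <- res$assignment$profile_id[startsWith(res$assignment$gene_id, nm)]
    expect_equal(length(unique(ids)), 1L)
  }
  # deterministic and invariant to row order
  res2 <- stem_cluster(profs[rev(seq_len(nrow(profs))), ], seed = 23)
  a1 <- res$assignment[order(res$assignment$gene_id), ]
  a2 <- res2$assignment[order(res2$assignment$gene_id), ]
  expect_equal(a1$profile_id, a2$profile_id)
  expect_error(stem_cluster(profs[, 1, drop = FALSE]), "time points")
})

test_that("noisy planted trajectories are recovered and nulls stay silent", {
  set.seed(24)
  tpl <- default_templates()
  n_per <- 60
  profs <- do.call(rbind, lapply(names(tpl), function(nm) {
    m <- matrix(rep(tpl[[nm]], n_per), ncol = 3, byrow = TRUE) +
      rnorm(3 * n_per, 0, 0.3)
    rownames(m) <- sprintf("%s_%03d", nm, seq_len(n_per))
    m
  }))
  colnames(profs) <- c("24h", "72h", "proB")
  res <- stem_cluster(profs, seed = 25)
  refs <- vapply(names(tpl), function(nm) {
    stem_cluster(matrix(tpl[[nm]], 1, 3), n_permutations = 2,
                 seed = 1)$assignment$profile_id
  }, character(1))
  acc <- vapply(names(tpl), function(nm) {
    a <- res$assignment[startsWith(res$assignment$gene_id, nm), ]
    mean(a$profile_id == refs[[nm]])
  }, numeric(1))
  expect_gte(mean(acc), 0.9)
  # planted profiles reach permutation significance
  expect_gte(sum(res$profile_stats$significant), 2L)
  # time-permuted null data yields no significant profiles
  nullp <- t(apply(profs, 1, sample))
  colnames(nullp) <- colnames(profs)
  res0 <- stem_cluster(nullp, seed = 26)
  expect_equal(sum(res0$profile_stats$significant), 0L)
})

test_that("site-count and distance summaries detect planted enrichment", {
  set.seed(27)
  n_up <- 40; n_un <- 60
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(n_up + n_un)),
                      chrom = "c", strand = "+",
                      tss = seq_len(n_up + n_un) * 60000L)
  # up-regulated genes get 3 nearby sites, unchanged genes 1 distant site
  rows <- list()
  for (i in seq_len(n_up)) {
    for (k in 1:3) {
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = sprintf("s%03d_%d", i, k), gene_id = genes$gene_id[i],
        distance = sample(500:3000, 1))
    }
  }
  for (i in (n_up + 1):(n_up + n_un)) {
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = sprintf("s%03d_1", i), gene_id = genes$gene_id[i],
      distance = sample(15000:24000, 1))
  }
  map <- do.call(rbind, rows)
  de <- data.frame(gene_id = genes$gene_id,
                   fpkm_0h = 10, fpkm_proB = 10,
                   log2fc = c(rep(3, n_up), rep(0, n_un)),
                   p_value = c(rep(1e-6, n_up), rep(0.9, n_un)),
                   low_expressed = FALSE,
                   de = c(rep(TRUE, n_up), rep(FALSE, n_un)))
  s <- site_count_and_distance_summary(map, de)
  expect_equal(unique(s$per_gene$n_sites[s$per_gene$group == "up"]), 3L)
  t_up <- s$tests[s$tests$group == "up", ]
  expect_true(all(t_up$adjusted_p < 0.05))
  # an empty comparison group is reported as missing
  de2 <- de; de2$log2fc[de2$de] <- 3
  s2 <- site_count_and_distance_summary(map, de2)
  expect_true(is.na(s2$tests$p_value[s2$tests$group == "down"][1]))
})
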