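# Independent oracle for the protection score: explicit index arithmetic
# and a direct binomial CDF call, kept free of the package's cumsum path.
oracle_score <- function(fwd, rev, fp_start, fp_width, shoulder) {
  fp <- fp_start:(fp_start + fp_width - 1)
  up <- (fp_start - shoulder):(fp_start - 1)
  dn <- (fp_start + fp_width):(fp_start + fp_width + shoulder - 1)
  nf <- sum(fwd[fp]); sf <- sum(fwd[up])
  nr <- sum(rev[fp]); sr <- sum(rev[dn])
  if (sf == 0 || sr == 0) return(0)
  p0 <- fp_width / (fp_width + shoulder)
  -log10(pbinom(nf, nf + sf, p0)) - log10(pbinom(nr, nr + sr, p0))
}

test_that("protection score equals the binomial-CDF oracle on random profiles", {
  set.seed(10)
  for (i in 1:1000) {
    len <- sample(100:160, 1)
    fwd <- rpois(len, runif(1, 0, 3))
    rev <- rpois(len, runif(1, 0, 3))
    w <- sample(seq(11, 25, 2), 1)
    start <- sample(36:(len - w + 1 - 35), 1)
    got <- wellington_score(list(fwd = fwd, rev = rev), start, w, 35)
    want <- oracle_score(fwd, rev, start, w, 35)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("protection score behaves at the boundaries of information", {
  # full depletion example evaluated against the closed form
  prof <- list(fwd = c(rep(2, 35), rep(0, 11), rep(2, 35)),
               rev = c(rep(2, 35), rep(0, 11), rep(2, 35)))
  expect_equal(wellington_score(prof, 36, 11, 35),
               -2 * log10(pbinom(0, 70, 11 / 46)), tolerance = 1e-12)
  # all-zero profile carries no information
  zero <- list(fwd = rep(0L, 120), rev = rep(0L, 120))
  expect_equal(wellington_score(zero, 40, 15, 35), 0)
  # uniform cuts score less than a depleted interior
  unif <- list(fwd = rep(1L, 120), rev = rep(1L, 120))
  expect_lt(wellington_score(unif, 53, 15, 35),
            wellington_score(list(fwd = replace(rep(1L, 120), 53:67, 0L),
                                  rev = replace(rep(1L, 120), 53:67, 0L)),
                             53, 15, 35))
  expect_error(wellington_score(unif, 10, 15, 35), "outside")
})

test_that("deeper interior depletion never decreases the score", {
  set.seed(11)
  fwd <- rpois(120, 2) + 1L
  rev <- rpois(120, 2) + 1L
  start <- 50L; w <- 15L
  scores <- numeric(0)
  for (k in 0:5) {
    f <- fwd; r <- rev
    idx <- start:(start + w - 1)
    f[idx] <- pmax(0L, f[idx] - k)
    r[idx] <- pmax(0L, r[idx] - k)
    scores <- c(scores, wellington_score(list(fwd = f, rev = r), start, w, 35))
  }
  expect_true(all(diff(scores) >= 0))
})

test_that("footprint calls are calibrated and never overlap", {
  sim <- simulate_footprint_regions(n_true = 60, n_null = 60,
                                    shoulder_depth = 30, seed = 12)
  fp <- call_footprints(sim$track, sim$regions, seed = 13)
  # deterministic given the seed
  expect_identical(fp, call_footprints(sim$track, sim$regions, seed = 13))
  # no two calls overlap
  if (nrow(fp) > 1) {
    by_reg <- split(fp, fp$region)
    for (b in by_reg) {
      b <- b[order(b$start), ]
      if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
    }
  }
  # most true regions recovered at 30x depth
  hit <- length(unique(fp$region[startsWith(fp$region, "true")]))
  expect_gte(hit / 60, 0.85)
  # empty regions give an empty call set
  none <- call_footprints(sim$track, sim$regions[0, ], seed = 1)
  expect_equal(nrow(none), 0L)
})

test_that("null regions are called at no more than twice the nominal rate", {
  sim <- simulate_footprint_regions(n_true = 0, n_null = 300,
                                    shoulder_depth = 30, seed = 14)
  fp <- call_footprints(sim$track, sim$regions, fdr = 0.05, seed = 15)
  called <- length(unique(fp$region))
  expect_lte(called / 300, 2 * 0.05)
})

test_that("motif scanning is strand-symmetric and matches a per-position oracle", {
  set.seed(16)
  bases <- c("A", "C", "G", "T")
  seq1 <- paste(sample(bases, 2000, TRUE), collapse = "")
  cons <- "TCCCAGGG"
  rc <- "CCCTGGGA"
  substr(seq1, 301, 308) <- cons
  substr(seq1, 901, 908) <- rc
  pwm <- matrix(0.04, 4, 8, dimnames = list(bases, NULL))
  for (j in 1:8) pwm[substr(cons, j, j), j] <- 0.88
  seqs <- c(s1 = seq1)
  hits <- scan_motifs(seqs, pwm, log_odds_threshold = 8, motif_id = "m")
  fwd_hit <- hits[hits$start == 300, ]
  rev_hit <- hits[hits$start == 900, ]
  expect_equal(nrow(fwd_hit), 1L)
  expect_equal(fwd_hit$strand, "+")
  expect_equal(rev_hit$strand, "-")
  expect_equal(fwd_hit$score, rev_hit$score)
  # consensus achieves the maximal score
  expect_equal(fwd_hit$score, max(hits$score))

  # exhaustive oracle: per-position log-odds on both strands
  lo <- log2((pwm + 1e-3) / (0.25 + 1e-3))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ch <- strsplit(seq1, "")[[1]]
  want <- list()
  for (p in 1:(2000 - 8 + 1)) {
    word <- ch[p:(p + 7)]
    sf <- sum(vapply(1:8, function(j) lo[word[j], j], 1))
    rcword <- rev(unname(comp[word]))
    sr <- sum(vapply(1:8, function(j) lo[rcword[j], j], 1))
    if (sf >= 8) want[[length(want) + 1L]] <- c(p - 1, sf)
    if (sr >= 8) want[[length(want) + 1L]] <- c(p - 1, sr)
  }
  want <- do.call(rbind, want)
  expect_equal(sort(hits$start), sort(want[, 1]))
  expect_equal(sort(hits$score), sort(want[, 2]), tolerance = 1e-9)

  bad <- pwm; bad[, 3] <- 0
  expect_error(scan_motifs(seqs, bad, 5), "sum to 1")
})

test_that("JASPAR-style PWM files parse into probability matrices", {
  p <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">MA0038.1 EBF1",
               "A [ 10  0  0  0 40  0 ]",
               "C [ 10 40 40 40  0  0 ]",
               "G [ 10  0  0  0  0 40 ]",
               "T [ 10  0  0  0  0  0 ]"), p)
  pwms <- read_jaspar_pwms(p)
  expect_named(pwms, "MA0038.1")
  m <- pwms[[1]]
  expect_equal(dim(m), c(4L, 6L))
  expect_equal(unname(colSums(m)), rep(1, 6))
  expect_equal(unname(m["C", 2]), 1)
  # the parsed PWM drives the scanner directly
  hits <- scan_motifs(c(s = "AAACCCCAGAAA"), m, log_odds_threshold = 5,
                      motif_id = "EBF1")
  expect_equal(hits$start[hits$strand == "+"], 3L)
})

test_that("motif occupancy tracks footprints over time", {
  set.seed(17)
  # 60 EBF1 instances footprinted only after induction; 60 CTCF always
  mk_hits <- function(id, centers) {
    data.frame(motif_id = id, chrom = "c", start = centers - 5L,
               end = centers + 5L, stringsAsFactors = FALSE)
  }
  ebf <- mk_hits("EBF1", seq(1000, 60000, by = 1000))
  ctcf <- mk_hits("CTCF", seq(500, 59500, by = 1000))
  hits <- rbind(ebf, ctcf)
  fp_at <- function(centers) {
    data.frame(chrom = "c", start = centers - 10L, end = centers + 10L)
  }
  fps <- list(
    "0h" = fp_at(interval_midpoint(ctcf)),
    "24h" = fp_at(c(interval_midpoint(ctcf), interval_midpoint(ebf))),
    "proB" = fp_at(c(interval_midpoint(ctcf), interval_midpoint(ebf))))
  occ <- footprint_motif_occupancy(fps, hits)
  expect_equal(unname(occ$fractions["EBF1", "0h"]), 0)
  expect_equal(unname(occ$fractions["EBF1", "24h"]), 1)
  # EBF1 jump is significant, CTCF is stable
  t1 <- occ$tests[occ$tests$motif_id == "EBF1" & occ$tests$to == "24h", ]
  expect_lt(t1$adjusted_p, 0.05)
  t2 <- occ$tests[occ$tests$motif_id == "CTCF", ]
  expect_true(all(t2$adjusted_p > 0.05))
  # counts equal the brute-force midpoint-in-interval oracle
  mid <- interval_midpoint(hits)
  for (tp in names(fps)) {
    want <- vapply(seq_along(mid), function(i) {
      any(fps[[tp]]$start <= mid[i] & mid[i] < fps[[tp]]$end)
    }, logical(1))
    expect_equal(occ$occupancy[[tp]]$footprinted, want)
  }
})

test_that("co-occurrence enrichment flags planted pairs only", {
  set.seed(18)
  mk <- function(id, centers, foot) {
    data.frame(motif_id = id, chrom = "c", start = centers - 5L,
               end = centers + 5L, footprinted = foot,
               stringsAsFactors = FALSE)
  }
  base <- seq(2000, 120000, by = 2000)  # 60 loci, 2 kb apart
  # t1: EBF1 and FoxO footprinted but far apart; CTCF scattered
  occ1 <- rbind(mk("EBF1", base, TRUE),
                mk("FoxO", base + 1000L, TRUE),
                mk("CTCF", base + 500L, TRUE))
  # t2: FoxO moves next to EBF1 (within 100 bp) at every locus
  occ2 <- rbind(mk("EBF1", base, TRUE),
                mk("FoxO", base + 60L, TRUE),
                mk("CTCF", base + 500L, TRUE))
  res <- cooccurrence_enrichment(occ1, occ2, window_bp = 200)
  pr <- res$pairs
  hit <- pr[pr$motif_a == "EBF1" & pr$motif_b == "FoxO", ]
  expect_gt(hit$odds_ratio, 1)
  expect_lt(hit$adjusted_p, 0.05)
  null_pair <- pr[pr$motif_a == "CTCF" & pr$motif_b == "EBF1", ]
  expect_gt(null_pair$adjusted_p, 0.05)
  # identical occupancy at both time points gives odds ratios near 1
  same <- cooccurrence_enrichment(occ2, occ2)
  expect_true(all(abs(log2(same$pairs$odds_ratio)) < 0.2))
  # symmetric matrix and a display order covering all motifs
  expect_equal(res$log2_or, t(res$log2_or))
  expect_setequal(res$order, c("EBF1", "FoxO", "CTCF"))
  # counts equal a brute-force all-pairs distance oracle
  bf <- sum(vapply(which(occ2$motif_id == "EBF1"), function(i) {
    any(occ2$motif_id == "FoxO" & occ2$footprinted &
          abs(interval_midpoint(occ2) - interval_midpoint(occ2)[i]) <= 100)
  }, logical(1)))
  expect_equal(hit$co_t2, bf + bf)  # pooled A-anchored + B-anchored counts
})
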