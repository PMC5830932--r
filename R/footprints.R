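# Tn5-protection (digital footprinting) scoring and calling, motif
# scanning, footprint-anchored motif occupancy over time, and pairwise
# motif co-occurrence enrichment.
#
# The protection score is a simplified strand-aware binomial depletion
# statistic in the spirit of the Wellington algorithm: forward-strand cuts
# inside the candidate footprint are tested against the upstream shoulder,
# reverse-strand cuts against the downstream shoulder, each with a binomial
# lower tail at p0 = width / (width + shoulder).

#' Strand-aware Tn5 protection score
#'
#' For each strand, `p = pbinom(N_fp, N_fp + N_shoulder, w/(w + s))` with
#' forward cuts tested against the upstream shoulder and reverse cuts
#' against the downstream shoulder; the score is
#' `-log10(p_fwd) - log10(p_rev)`, and 0 when either shoulder carries no
#' cuts (no information).
#'
#' @param cut_profile list with integer vectors `fwd` and `rev` of per-base
#'   cut counts over a region (same length).
#' @param fp_start 1-based index of the first footprint base in the profile.
#' @param fp_width footprint width (bp).
#' @param shoulder_bp shoulder span (bp) on each side.
#' @return nonnegative numeric score.
#' @export
wellington_score <- function(cut_profile, fp_start, fp_width,
                             shoulder_bp = 35) {
  fwd <- cut_profile$fwd
  rev <- cut_profile$rev
  stopifnot(length(fwd) == length(rev))
  lo <- fp_start - shoulder_bp
  hi <- fp_start + fp_width - 1L + shoulder_bp
  if (lo < 1L || hi > length(fwd)) stopf("shoulders fall outside the profile")
  fp_idx <- fp_start:(fp_start + fp_width - 1L)
  up_idx <- lo:(fp_start - 1L)
  dn_idx <- (fp_start + fp_width):hi
  n_fp_f <- sum(fwd[fp_idx])
  n_sh_f <- sum(fwd[up_idx])
  n_fp_r <- sum(rev[fp_idx])
  n_sh_r <- sum(rev[dn_idx])
  if (n_sh_f == 0 || n_sh_r == 0) return(0)
  p0 <- fp_width / (fp_width + shoulder_bp)
  -log10(pbinom(n_fp_f, n_fp_f + n_sh_f, p0)) -
    log10(pbinom(n_fp_r, n_fp_r + n_sh_r, p0))
}

# Vectorized scores for all (start, width) candidates over one or many
# per-base cut-count columns at once (columns are e.g. the observed profile
# plus shuffles). `cf`/`cr` are (len + 1) x k cumulative-sum matrices with a
# leading zero row. Returns the per-start maximum over widths (len x k) and
# the argmax width.
score_candidates <- function(cf, cr, len, widths, shoulder_bp,
                             lookups = NULL) {
  k <- ncol(cf)
  best <- matrix(0, len, k)
  best_w <- matrix(NA_integer_, len, k)
  for (wi in seq_along(widths)) {
    w <- widths[wi]
    first <- shoulder_bp + 1L
    last <- len + 1L - w - shoulder_bp
    if (last < first) next
    st <- first:last
    n_fp_f <- cf[st + w, , drop = FALSE] - cf[st, , drop = FALSE]
    n_sh_f <- cf[st, , drop = FALSE] - cf[st - shoulder_bp, , drop = FALSE]
    n_fp_r <- cr[st + w, , drop = FALSE] - cr[st, , drop = FALSE]
    n_sh_r <- cr[st + w + shoulder_bp, , drop = FALSE] -
      cr[st + w, , drop = FALSE]
    p0 <- w / (w + shoulder_bp)
    if (is.null(lookups)) {
      s <- -log10(pbinom(n_fp_f, n_fp_f + n_sh_f, p0)) -
        log10(pbinom(n_fp_r, n_fp_r + n_sh_r, p0))
    } else {
      # log10 binomial CDF by table lookup (counts are small integers)
      lt <- lookups[[wi]]
      nr <- nrow(lt)
      s <- -(lt[n_fp_f + 1L + (n_fp_f + n_sh_f) * nr] +
               lt[n_fp_r + 1L + (n_fp_r + n_sh_r) * nr])
      dim(s) <- dim(n_fp_f)
    }
    s[n_sh_f == 0 | n_sh_r == 0] <- 0
    cur <- best[st, , drop = FALSE]
    upd <- s > cur
    cur[upd] <- s[upd]
    best[st, ] <- cur
    wcur <- best_w[st, , drop = FALSE]
    wcur[upd] <- w
    best_w[st, ] <- wcur
  }
  list(score = best, width = best_w)
}

# Single-profile convenience wrapper around score_candidates().
region_scores <- function(fwd, rev, widths, shoulder_bp) {
  cf <- matrix(c(0, cumsum(fwd)), ncol = 1)
  cr <- matrix(c(0, cumsum(rev)), ncol = 1)
  rs <- score_candidates(cf, cr, length(fwd), widths, shoulder_bp)
  list(score = rs$score[, 1], width = rs$width[, 1])
}

#' Call footprints with shuffle-calibrated thresholds
#'
#' Within each accessible region, every (position, width) candidate gets a
#' protection score; the per-position maximum over widths is compared with a
#' null built by shuffling the region's cut positions (preserving per-strand
#' totals): the threshold is the `1 - fdr` quantile of the per-shuffle
#' maximum scores. Calls exceeding the threshold are resolved greedily by
#' score so that accepted footprints never overlap.
#'
#' @param cut_track a `cut_track`.
#' @param regions interval data frame of accessible regions.
#' @param widths candidate footprint widths (bp).
#' @param shoulder_bp shoulder span (bp).
#' @param fdr target false-discovery level for the shuffle calibration.
#' @param n_shuffles shuffles per region; must be large enough to resolve
#'   the `1 - fdr` quantile (about `1/fdr` or more).
#' @param seed integer seed (shuffles are deterministic given it).
#' @return interval data frame of footprint calls with `score`, `width` and
#'   `region` columns.
#' @export
call_footprints <- function(cut_track, regions, widths = seq(11, 25, 2),
                            shoulder_bp = 35, fdr = 0.01, n_shuffles = 100,
                            seed = 1) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), score = numeric(), width = integer(),
                      region = character(), stringsAsFactors = FALSE)
  if (nrow(regions) == 0L) return(empty)
  cuts <- cut_track$cuts
  region_name <- if ("name" %in% names(regions)) regions$name else
    sprintf("region_%05d", seq_len(nrow(regions)))
  with_seed(seed, {
    calls <- list()
    lookups <- NULL
    look_n <- -1L
    build_lookups <- function(n_max) {
      lapply(widths, function(w) {
        p0 <- w / (w + shoulder_bp)
        n_tot <- rep(0:n_max, each = n_max + 1L)
        n_fp <- rep(0:n_max, n_max + 1L)
        matrix(log10(pbinom(n_fp, n_tot, p0)), nrow = n_max + 1L)
      })
    }
    for (i in seq_len(nrow(regions))) {
      chrom <- regions$chrom[i]
      lo <- regions$start[i]
      hi <- regions$end[i]
      len <- hi - lo
      sel <- cuts$chrom == chrom & cuts$pos >= lo & cuts$pos < hi
      if (!any(sel)) next
      pos <- cuts$pos[sel] - lo + 1L
      strand <- cuts$strand[sel]
      fwd <- tabulate(pos[strand == "+"], nbins = len)
      rev <- tabulate(pos[strand == "-"], nbins = len)
      rs <- region_scores(fwd, rev, widths, shoulder_bp)
      if (all(rs$score <= 0)) next
      n_f <- sum(fwd)
      n_r <- sum(rev)
      # shuffle null: redistribute the region's cuts uniformly, preserving
      # per-strand totals; all shuffles are scored in one matrix pass
      if (max(n_f, n_r) > look_n) {
        look_n <- max(n_f, n_r, 2L * look_n)
        lookups <- build_lookups(look_n)
      }
      sf <- stats::rmultinom(n_shuffles, n_f, rep(1, len))
      sr <- stats::rmultinom(n_shuffles, n_r, rep(1, len))
      cfm <- rbind(0, apply(sf, 2, cumsum))
      crm <- rbind(0, apply(sr, 2, cumsum))
      null_max <- apply(score_candidates(cfm, crm, len, widths, shoulder_bp,
                                         lookups)$score, 2, max)
      threshold <- quantile(null_max, 1 - fdr, names = FALSE, type = 7)
      cand <- which(rs$score > threshold)
      if (length(cand) == 0L) next
      cand <- cand[order(rs$score[cand], decreasing = TRUE)]
      taken <- rep(FALSE, len)
      for (s0 in cand) {
        w <- rs$width[s0]
        if (is.na(w)) next
        span <- s0:(s0 + w - 1L)
        if (any(taken[span])) next
        taken[span] <- TRUE
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = chrom, start = lo + s0 - 1L, end = lo + s0 - 1L + w,
          score = rs$score[s0], width = as.integer(w),
          region = region_name[i], stringsAsFactors = FALSE)
      }
    }
    if (length(calls) == 0L) return(empty)
    out <- do.call(rbind, calls)
    out[order(out$chrom, out$start), , drop = FALSE]
  })
}

#' Read a JASPAR-style PWM text file
#'
#' Accepts the common 4-row `A/C/G/T [ counts ]` layout with an optional
#' `>` header per motif.
#'
#' @param path file path.
#' @return named list of 4 x L probability matrices (rows ACGT).
#' @export
read_jaspar_pwms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  cur_name <- NULL
  rows <- list()
  flush <- function() {
    if (length(rows) == 4L) {
      m <- do.call(rbind, rows)
      rownames(m) <- c("A", "C", "G", "T")
      m <- sweep(m, 2, colSums(m), "/")
      out[[cur_name %||% sprintf("motif_%d", length(out) + 1L)]] <<- m
    }
    rows <<- list()
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      cur_name <- strsplit(trimws(sub("^>", "", ln)), "\\s+")[[1]][1]
    } else {
      nums <- as.numeric(regmatches(ln, gregexpr("[0-9.]+", ln))[[1]])
      rows[[length(rows) + 1L]] <- nums
    }
  }
  flush()
  out
}

#' Scan sequences for PWM matches
#'
#' Log-odds scan of both strands against a uniform background; columns of
#' the PWM must sum to 1. Overlapping same-motif hits on the same sequence
#' are deduplicated keeping the best score.
#'
#' @param sequences named character vector of DNA sequences.
#' @param pwm 4 x L probability matrix, rows A, C, G, T.
#' @param log_odds_threshold minimum log2-odds score for a hit.
#' @param motif_id label stored with the hits.
#' @param pseudo pseudo-probability added before the log-odds transform.
#' @return data frame of hits: `seqname`, `start` (0-based), `end`,
#'   `strand`, `score`, `motif_id`.
#' @export
scan_motifs <- function(sequences, pwm, log_odds_threshold, motif_id = "motif",
                        pseudo = 1e-3) {
  if (any(abs(colSums(pwm) - 1) > 1e-6)) {
    stopf("PWM columns must sum to 1")
  }
  lo <- log2((pwm + pseudo) / (0.25 + pseudo))
  L <- ncol(lo)
  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  comp <- c(4L, 3L, 2L, 1L)
  hits <- list()
  for (sn in names(sequences)) {
    s <- base_idx[strsplit(toupper(sequences[[sn]]), "")[[1]]]
    n <- length(s)
    if (n < L) next
    n_pos <- n - L + 1L
    fwd_sc <- rep(0, n_pos)
    rev_sc <- rep(0, n_pos)
    ok <- rep(TRUE, n_pos)
    for (j in seq_len(L)) {
      b <- s[j:(j + n_pos - 1L)]
      ok <- ok & !is.na(b)
      bb <- ifelse(is.na(b), 1L, b)
      fwd_sc <- fwd_sc + lo[cbind(bb, j)]
      rev_sc <- rev_sc + lo[cbind(comp[bb], L - j + 1L)]
    }
    for (str in c("+", "-")) {
      sc <- if (str == "+") fwd_sc else rev_sc
      w <- which(ok & sc >= log_odds_threshold)
      if (length(w)) {
        hits[[length(hits) + 1L]] <- data.frame(
          seqname = sn, start = w - 1L, end = w - 1L + L, strand = str,
          score = sc[w], motif_id = motif_id, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(seqname = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), motif_id = character(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, hits)
  # greedy dedup of overlapping same-motif hits, best score first
  df <- df[order(df$seqname, -df$score, df$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (sn in unique(df$seqname)) {
    idx <- which(df$seqname == sn)
    occupied <- integer(0)
    for (i in idx) {
      span <- df$start[i]:(df$end[i] - 1L)
      if (any(span %in% occupied)) {
        keep[i] <- FALSE
      } else {
        occupied <- c(occupied, span)
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$seqname, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Footprint-anchored motif occupancy over time
#'
#' A motif instance is footprinted at a time point when its midpoint lies
#' inside a footprint call there. Returns per-time-point occupancy flags,
#' per-motif footprinted fractions over time, and two-proportion tests
#' (Fisher) between consecutive time points with Benjamini-Hochberg
#' adjustment across motif x transition.
#'
#' @param footprints_by_timepoint named list of footprint interval frames.
#' @param motif_hits data frame with `motif_id`, `chrom`, `start`, `end`.
#' @return list with `occupancy` (per time point data frames), `fractions`
#'   (motif x time point), and `tests`.
#' @export
footprint_motif_occupancy <- function(footprints_by_timepoint, motif_hits) {
  tps <- order_timepoints(names(footprints_by_timepoint))
  mids <- interval_midpoint(motif_hits)
  occupancy <- lapply(tps, function(tp) {
    fp <- footprints_by_timepoint[[tp]]
    flag <- points_in_intervals(motif_hits$chrom, mids, fp)
    cbind(motif_hits, footprinted = flag)
  })
  names(occupancy) <- tps
  motifs <- sort(unique(motif_hits$motif_id))
  fractions <- vapply(tps, function(tp) {
    tapply(occupancy[[tp]]$footprinted, occupancy[[tp]]$motif_id,
           mean)[motifs]
  }, numeric(length(motifs)))
  fractions <- matrix(fractions, nrow = length(motifs),
                      dimnames = list(motifs, tps))
  tests <- list()
  if (length(tps) >= 2L) {
    for (k in seq_len(length(tps) - 1L)) {
      t1 <- tps[k]; t2 <- tps[k + 1L]
      for (m in motifs) {
        sel <- motif_hits$motif_id == m
        a1 <- sum(occupancy[[t1]]$footprinted[sel])
        a2 <- sum(occupancy[[t2]]$footprinted[sel])
        n <- sum(sel)
        p <- fisher.test(matrix(c(a2, n - a2, a1, n - a1), 2))$p.value
        tests[[length(tests) + 1L]] <- data.frame(
          motif_id = m, from = t1, to = t2, frac_from = a1 / n,
          frac_to = a2 / n, p_value = p, stringsAsFactors = FALSE)
      }
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(motif_id = character(), from = character(), to = character(),
               frac_from = numeric(), frac_to = numeric(),
               p_value = numeric())
  tests$adjusted_p <- p.adjust(tests$p_value, "BH")
  list(occupancy = occupancy, fractions = fractions, tests = tests)
}

#' Pairwise motif co-occurrence enrichment between two time points
#'
#' A footprinted instance of motif A co-occurs with motif B when a
#' footprinted B midpoint (of a different instance) lies within
#' `window_bp / 2` of A's midpoint. For each unordered pair the 2 x 2 table
#' (co-occurring vs not, t2 vs t1, pooling A-anchored and B-anchored
#' instances) gives a Fisher odds ratio and p-value, BH-adjusted across
#' pairs; zero marginals get the Haldane-Anscombe +0.5 correction (flagged).
#' Display order comes from average-linkage clustering of the log2
#' odds-ratio matrix.
#'
#' @param occupancy_t1,occupancy_t2 data frames (`motif_id`, `chrom`,
#'   `start`, `end`, `footprinted`) for the earlier and later time point.
#' @param window_bp co-occurrence window (centre-to-centre span).
#' @return list with `pairs` (per-pair statistics), `log2_or` matrix and
#'   `order` (motif display order).
#' @export
cooccurrence_enrichment <- function(occupancy_t1, occupancy_t2,
                                    window_bp = 200) {
  motifs <- sort(union(unique(occupancy_t1$motif_id),
                       unique(occupancy_t2$motif_id)))
  if (!setequal(unique(occupancy_t1$motif_id),
                unique(occupancy_t2$motif_id))) {
    stopf("both time points must use the same motif library")
  }
  half <- window_bp / 2

  cooccur_counts <- function(occ, a, b) {
    fa <- occ[occ$motif_id == a & occ$footprinted, , drop = FALSE]
    fb <- occ[occ$motif_id == b & occ$footprinted, , drop = FALSE]
    if (nrow(fa) == 0L) return(c(co = 0L, total = 0L))
    if (nrow(fb) == 0L) return(c(co = 0L, total = nrow(fa)))
    ma <- interval_midpoint(fa)
    mb <- interval_midpoint(fb)
    co <- vapply(seq_len(nrow(fa)), function(i) {
      same <- fb$chrom == fa$chrom[i] & abs(mb - ma[i]) <= half
      if (a == b) {
        # self-pairs: a different instance must co-occur
        same <- same & !(fb$start == fa$start[i] & mb == ma[i])
      }
      any(same)
    }, logical(1))
    c(co = sum(co), total = nrow(fa))
  }

  rows <- list()
  n_m <- length(motifs)
  lor <- matrix(0, n_m, n_m, dimnames = list(motifs, motifs))
  for (i in seq_len(n_m)) {
    for (j in i:n_m) {
      a <- motifs[i]; b <- motifs[j]
      c1 <- cooccur_counts(occupancy_t1, a, b) +
        (if (a != b) cooccur_counts(occupancy_t1, b, a) else 0)
      c2 <- cooccur_counts(occupancy_t2, a, b) +
        (if (a != b) cooccur_counts(occupancy_t2, b, a) else 0)
      tab <- matrix(c(c2["co"], c2["total"] - c2["co"],
                      c1["co"], c1["total"] - c1["co"]), 2)
      corrected <- FALSE
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        or <- ((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5)) /
          ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
        p <- 1
        corrected <- TRUE
      } else {
        ft <- fisher.test(tab)
        or <- unname(ft$estimate)
        p <- ft$p.value
        if (!is.finite(or) || or == 0) {
          or <- ((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5)) /
            ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
          corrected <- TRUE
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        motif_a = a, motif_b = b,
        co_t1 = unname(c1["co"]), total_t1 = unname(c1["total"]),
        co_t2 = unname(c2["co"]), total_t2 = unname(c2["total"]),
        odds_ratio = or, p_value = p, corrected = corrected,
        stringsAsFactors = FALSE)
      lor[i, j] <- lor[j, i] <- log2(or)
    }
  }
  pairs <- do.call(rbind, rows)
  pairs$adjusted_p <- p.adjust(pairs$p_value, "BH")
  ord <- if (n_m >= 3L) {
    motifs[hclust(dist(lor), method = "average")$order]
  } else motifs
  list(pairs = pairs, log2_or = lor, order = ord)
}
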