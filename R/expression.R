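# Differential expression with the fold-change / p-value / FPKM filters,
# +/-25-kb nearest-TSS gene assignment, amplitude stratification, and
# model-profile (STEM-style) trajectory clustering.

EXPR_PSEUDOCOUNT <- 0.1

#' Call differential genes between 0 h and pro-B
#'
#' Fold change is computed on replicate-mean FPKM with a 0.1 pseudocount;
#' evidence comes from a moderated t-test (limma) on log2(FPKM + 0.1),
#' borrowing variance information across genes, or from a per-gene Welch
#' test. A gene is differential when |log2 FC| > log2(`fc_threshold`), the
#' p-value is below `p_threshold`, and FPKM reaches `min_fpkm` at 0 h or
#' pro-B (genes lowly expressed at both ends are filtered out).
#'
#' @param table an `expression_table` with >= 2 replicates at 0 h and pro-B.
#' @param fc_threshold linear fold-change cutoff.
#' @param p_threshold p-value cutoff.
#' @param min_fpkm low-expression filter (applied to both end points).
#' @param method `"moderated"` (limma, default) or `"welch"`.
#' @return data frame per gene: mean FPKM at the end points, per-time-point
#'   `lfc_<tp>` columns (log2 vs 0 h), `log2fc` (pro-B vs 0 h), `p_value`,
#'   `low_expressed`, and the `de` flag.
#' @export
differential_genes <- function(table, fc_threshold = 2, p_threshold = 0.01,
                               min_fpkm = 1,
                               method = c("moderated", "welch")) {
  method <- match.arg(method)
  samples <- table$samples
  for (tp in c("0h", "proB")) {
    if (sum(samples$timepoint == tp) < 2L) {
      stopf("need >= 2 replicates at %s", tp)
    }
  }
  ab <- table$abundance
  tps <- order_timepoints(unique(samples$timepoint))
  tp_mean <- vapply(tps, function(tp) {
    rowMeans(ab[, samples$timepoint == tp, drop = FALSE])
  }, numeric(nrow(ab)))
  tp_mean <- matrix(tp_mean, nrow = nrow(ab),
                    dimnames = list(rownames(ab), tps))

  lfc <- log2(sweep(tp_mean + EXPR_PSEUDOCOUNT, 1,
                    tp_mean[, "0h"] + EXPR_PSEUDOCOUNT, "/"))
  log_ab <- log2(ab + EXPR_PSEUDOCOUNT)
  i0 <- which(samples$timepoint == "0h")
  iP <- which(samples$timepoint == "proB")
  if (method == "moderated") {
    sub <- log_ab[, c(i0, iP), drop = FALSE]
    design <- cbind(Intercept = 1,
                    proB = rep(c(0, 1), c(length(i0), length(iP))))
    fit <- limma::eBayes(limma::lmFit(sub, design))
    p <- fit$p.value[, "proB"]
  } else {
    p <- apply(log_ab, 1, function(x) {
      stats::t.test(x[iP], x[i0])$p.value
    })
  }
  low <- tp_mean[, "0h"] < min_fpkm & tp_mean[, "proB"] < min_fpkm
  de <- abs(lfc[, "proB"]) > log2(fc_threshold) & p < p_threshold & !low
  out <- data.frame(gene_id = rownames(ab),
                    fpkm_0h = tp_mean[, "0h"], fpkm_proB = tp_mean[, "proB"],
                    stringsAsFactors = FALSE)
  for (tp in setdiff(tps, "0h")) out[[paste0("lfc_", tp)]] <- lfc[, tp]
  out$log2fc <- lfc[, "proB"]
  out$p_value <- p
  out$low_expressed <- low
  out$de <- de
  rownames(out) <- NULL
  out
}

#' Assign binding sites to genes by the nearest TSS within a window
#'
#' A site is linked to the gene whose TSS is nearest to the site centre,
#' provided the distance is at most `window_kb` kb; sites within range of
#' several TSSs go to the nearest only (ties to the lexicographically
#' smaller `gene_id`).
#'
#' @param catalog a `site_catalog` (or data frame with `site_id`, `chrom`,
#'   `center`).
#' @param gene_models data frame with `gene_id`, `chrom`, `tss`.
#' @param window_kb association window in kb.
#' @return data frame `site_id`, `gene_id`, `distance` (signed
#'   centre - TSS), one row per linked site.
#' @export
assign_genes_to_sites <- function(catalog, gene_models, window_kb = 25) {
  sites <- if (inherits(catalog, "site_catalog")) catalog$sites else catalog
  win <- window_kb * 1000
  rows <- vector("list", nrow(sites))
  for (chrom in unique(sites$chrom)) {
    g <- gene_models[gene_models$chrom == chrom, , drop = FALSE]
    idx <- which(sites$chrom == chrom)
    if (nrow(g) == 0L) next
    g <- g[order(g$gene_id), , drop = FALSE]  # lexicographic tie-break
    for (i in idx) {
      d <- sites$center[i] - g$tss
      ad <- abs(d)
      if (min(ad) > win) next
      k <- which(ad == min(ad))[1]
      rows[[i]] <- data.frame(site_id = sites$site_id[i],
                              gene_id = g$gene_id[k], distance = d[k],
                              stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(site_id = character(), gene_id = character(),
                      distance = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Pioneer-factor-regulated differential genes
#'
#' @param site_gene_map output of \code{\link{assign_genes_to_sites}}.
#' @param de output of \code{\link{differential_genes}}.
#' @return character vector of differential genes with >= 1 assigned site.
#' @export
regulated_genes <- function(site_gene_map, de) {
  intersect(de$gene_id[de$de], unique(site_gene_map$gene_id))
}

#' Stratify differential genes by fold-change amplitude
#'
#' @param de output of \code{\link{differential_genes}} (only `de` rows are
#'   stratified).
#' @param cutoff_fold boundary; strictly greater lands in the stringent
#'   stratum, so exactly `cutoff_fold` is lenient.
#' @return data frame `gene_id`, `fold_change` (linear, >= 1), `stratum`.
#' @export
stratify_by_amplitude <- function(de, cutoff_fold = 10) {
  sub <- de[de$de, , drop = FALSE]
  fc <- 2^abs(sub$log2fc)
  data.frame(gene_id = sub$gene_id, fold_change = fc,
             stratum = ifelse(fc > cutoff_fold, "stringent", "lenient"),
             stringsAsFactors = FALSE)
}

# All integer-step model trajectories over the induced time points:
# cumulative sums of per-transition steps in -c..c, starting at 0,
# excluding the flat all-zero profile. Canonical (lexicographic) order.
model_profiles <- function(n_timepoints, c = 2) {
  steps <- as.matrix(expand.grid(rep(list(seq(-c, c)), n_timepoints),
                                 KEEP.OUT.ATTRS = FALSE))
  prof <- t(apply(steps, 1, cumsum))
  prof <- prof[rowSums(prof != 0) > 0, , drop = FALSE]
  ord <- do.call(order, as.data.frame(prof))
  prof[ord, , drop = FALSE]
}

# Correlation between trajectories anchored at 0 h (a leading 0 is
# prepended so amplitude relative to baseline matters, not only shape).
anchored_cor <- function(p, q) {
  a <- c(0, p)
  b <- c(0, q)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  cor(a, b)
}

# Greedy maximin selection of well-spread model profiles.
select_model_profiles <- function(candidates, n_select) {
  n <- nrow(candidates)
  if (n <= n_select) return(seq_len(n))
  cmat <- matrix(0, n, n)
  anch <- cbind(0, candidates)
  cs <- t(scale(t(anch)))
  cmat <- tcrossprod(cs) / (ncol(anch) - 1)
  d <- 1 - cmat
  selected <- 1L  # canonical first candidate
  while (length(selected) < n_select) {
    min_d <- apply(d[, selected, drop = FALSE], 1, min)
    min_d[selected] <- -Inf
    selected <- c(selected, which.max(min_d))
  }
  sort(selected)
}

#' STEM-style short time-series clustering
#'
#' Genes (log2 fold change vs 0 h over the ordered induced time points) are
#' assigned to the nearest of a fixed set of integer-step model profiles
#' (greedy maximin selection from all step trajectories over -c..c),
#' nearest by correlation with a 0-anchored profile. Profile significance is
#' assessed by permuting each gene's time order (`n_permutations` rounds,
#' Bonferroni across profiles); significant profiles correlating >= 0.7 are
#' merged into display clusters.
#'
#' @param de_gene_profiles matrix (genes x induced time points) of log2 fold
#'   changes vs 0 h; rownames are gene ids.
#' @param c maximum per-transition step.
#' @param n_model_profiles number of model profiles to keep.
#' @param n_permutations permutation rounds for significance; must exceed
#'   `n_model_profiles / alpha` for the Bonferroni bar to be attainable.
#' @param seed integer seed.
#' @param alpha significance level before Bonferroni.
#' @param merge_cor correlation threshold for merging significant profiles.
#' @return list with `assignment` (gene_id, profile_id, cor,
#'   cluster_label), `profiles` (the model-profile matrix), `profile_stats`
#'   (count, p_value, significant).
#' @export
stem_cluster <- function(de_gene_profiles, c = 2, n_model_profiles = 20,
                         n_permutations = 500, seed = 1, alpha = 0.05,
                         merge_cor = 0.7) {
  profs <- as.matrix(de_gene_profiles)
  if (is.null(rownames(profs))) {
    rownames(profs) <- sprintf("gene_%05d", seq_len(nrow(profs)))
  }
  n_tp <- ncol(profs)
  if (n_tp < 2L) stopf("need >= 2 induced time points (>= 3 total)")
  cand <- model_profiles(n_tp, c)
  sel <- select_model_profiles(cand, n_model_profiles)
  models <- cand[sel, , drop = FALSE]
  rownames(models) <- sprintf("P%02d", seq_len(nrow(models)))

  assign_to_model <- function(mat) {
    a_gene <- cbind(0, mat)
    a_model <- cbind(0, models)
    gs <- t(scale(t(a_gene)))
    ms <- t(scale(t(a_model)))
    gs[!is.finite(gs)] <- 0
    ms[!is.finite(ms)] <- 0
    cors <- tcrossprod(gs, ms) / (ncol(a_gene) - 1)
    idx <- apply(cors, 1, which.max)  # first max: lowest profile id on ties
    list(idx = idx, cor = cors[cbind(seq_len(nrow(mat)), idx)])
  }

  obs <- assign_to_model(profs)
  counts <- tabulate(obs$idx, nbins = nrow(models))

  with_seed(seed, {
    null_counts <- matrix(0L, n_permutations, nrow(models))
    for (b in seq_len(n_permutations)) {
      perm <- t(apply(profs, 1, function(x) x[sample.int(n_tp)]))
      null_counts[b, ] <- tabulate(assign_to_model(perm)$idx,
                                   nbins = nrow(models))
    }
    p_profile <- vapply(seq_len(nrow(models)), function(k) {
      (1 + sum(null_counts[, k] >= counts[k])) / (n_permutations + 1)
    }, numeric(1))
  })
  significant <- p_profile < alpha / nrow(models)

  # merge correlated significant profiles into display clusters
  cluster_of <- rep(NA_character_, nrow(models))
  sig_idx <- which(significant)
  if (length(sig_idx)) {
    a_model <- cbind(0, models[sig_idx, , drop = FALSE])
    ms <- t(scale(t(a_model)))
    cm <- tcrossprod(ms) / (ncol(a_model) - 1)
    adj <- cm >= merge_cor
    comp <- rep(0L, length(sig_idx))
    cur <- 0L
    for (i in seq_along(sig_idx)) {
      if (comp[i] == 0L) {
        cur <- cur + 1L
        queue <- i
        while (length(queue)) {
          v <- queue[1]; queue <- queue[-1]
          if (comp[v] == 0L) {
            comp[v] <- cur
            queue <- c(queue, which(adj[v, ] & comp == 0L))
          }
        }
      }
    }
    cluster_of[sig_idx] <- sprintf("C%d", comp)
  }

  assignment <- data.frame(
    gene_id = rownames(profs),
    profile_id = rownames(models)[obs$idx],
    cor = obs$cor,
    cluster_label = cluster_of[obs$idx],
    stringsAsFactors = FALSE)
  profile_stats <- data.frame(
    profile_id = rownames(models), count = counts, p_value = p_profile,
    significant = significant, cluster_label = cluster_of,
    stringsAsFactors = FALSE)
  list(assignment = assignment, profiles = models,
       profile_stats = profile_stats)
}

#' Cluster up- and down-regulated trajectories separately
#'
#' Convenience wrapper: splits differential genes by the sign of the pro-B
#' fold change and runs \code{\link{stem_cluster}} on each half.
#'
#' @param de output of \code{\link{differential_genes}}.
#' @param timepoints induced time points (columns `lfc_<tp>` must exist).
#' @param ... passed to \code{\link{stem_cluster}}.
#' @return list with `up` and `down` clustering results (NULL when empty).
#' @export
cluster_trajectories <- function(de, timepoints = INDUCED_TIMEPOINTS, ...) {
  sub <- de[de$de, , drop = FALSE]
  profs <- as.matrix(sub[, paste0("lfc_", timepoints), drop = FALSE])
  rownames(profs) <- sub$gene_id
  colnames(profs) <- timepoints
  run <- function(m) if (nrow(m) == 0L) NULL else stem_cluster(m, ...)
  list(up = run(profs[sub$log2fc > 0, , drop = FALSE]),
       down = run(profs[sub$log2fc <= 0, , drop = FALSE]))
}

#' Binding-site count and TSS-distance summaries per expression group
#'
#' For up-regulated, down-regulated and unchanged genes: the number of
#' assigned sites per gene and the distance from the TSS to the nearest
#' assigned site, with Mann-Whitney comparisons of each differential group
#' against the unchanged control (BH-adjusted).
#'
#' @param site_gene_map output of \code{\link{assign_genes_to_sites}}.
#' @param de output of \code{\link{differential_genes}}.
#' @param unchanged_max_fold |fold change| bound for the unchanged control
#'   set (which must also pass the expression floor).
#' @param min_fpkm expression floor for the control set.
#' @return list with `per_gene` (gene, group, n_sites, min_distance) and
#'   `tests`.
#' @export
site_count_and_distance_summary <- function(site_gene_map, de,
                                            unchanged_max_fold = 1.5,
                                            min_fpkm = 1) {
  group <- rep(NA_character_, nrow(de))
  group[de$de & de$log2fc > 0] <- "up"
  group[de$de & de$log2fc < 0] <- "down"
  unchanged <- !de$de & abs(de$log2fc) < log2(unchanged_max_fold) &
    de$fpkm_0h >= min_fpkm & de$fpkm_proB >= min_fpkm
  group[unchanged] <- "unchanged"

  n_sites <- table(factor(site_gene_map$gene_id, levels = de$gene_id))
  min_dist <- tapply(abs(site_gene_map$distance), site_gene_map$gene_id, min)
  per_gene <- data.frame(gene_id = de$gene_id, group = group,
                         n_sites = as.integer(n_sites[de$gene_id]),
                         min_distance = as.numeric(min_dist[de$gene_id]),
                         stringsAsFactors = FALSE)
  per_gene <- per_gene[!is.na(per_gene$group), , drop = FALSE]

  tests <- list()
  for (g in c("up", "down")) {
    for (what in c("n_sites", "min_distance")) {
      x <- per_gene[[what]][per_gene$group == g]
      y <- per_gene[[what]][per_gene$group == "unchanged"]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      p <- if (length(x) == 0L || length(y) == 0L) NA_real_ else
        suppressWarnings(wilcox.test(x, y)$p.value)
      tests[[length(tests) + 1L]] <- data.frame(
        group = g, measure = what, n_group = length(x),
        n_control = length(y), p_value = p, stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, tests)
  tests$adjusted_p <- p.adjust(tests$p_value, "BH")
  list(per_gene = per_gene, tests = tests)
}
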