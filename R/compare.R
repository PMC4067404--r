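#' Filter features ahead of clustering and differential testing
#'
#' Removes features (V(D)J combinations or families) with low counts or low
#' cross-sample variation: a feature is kept iff its total count across
#' samples is at least `min_total` and the variance of its per-sample
#' frequencies strictly exceeds `min_variance` (the default 0 removes
#' exactly the constant-frequency features, including all-zero ones).
#'
#' @param usage A `usage_table` from [usage_frequencies()].
#' @param min_total Minimum summed count across samples.
#' @param min_variance Frequency-variance threshold (strict).
#' @return Character vector of kept feature names.
#' @export
filter_features <- function(usage, min_total = 10, min_variance = 0) {
  counts <- usage$counts
  freq <- usage$freq
  keep <- rowSums(counts) >= min_total & apply(freq, 1, var) > min_variance
  rownames(counts)[keep]
}

#' Pearson correlation distance matrix
#'
#' Pairwise distances d = 1 - r (Pearson) between the rows (`axis =
#' "features"`) or columns (`axis = "samples"`) of a matrix. Distances lie
#' in [0, 2], are symmetric with zero diagonal; each vector must have
#' nonzero variance.
#'
#' @param m Numeric matrix (e.g. a frequency matrix).
#' @param axis Cluster features (rows) or samples (columns).
#' @return Symmetric distance matrix.
#' @export
correlation_distance <- function(m, axis = c("features", "samples")) {
  axis <- match.arg(axis)
  x <- if (axis == "features") t(m) else m
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("zero-variance vector(s): ", paste(colnames(x)[sds == 0], collapse = ", "))
  d <- 1 - cor(x)
  d[abs(d) < .Machine$double.eps^0.5] <- 0
  diag(d) <- 0
  d
}

#' Agglomerative hierarchical clustering
#'
#' Complete-linkage agglomerative clustering of a distance matrix
#' (delegated to [stats::hclust()]); with complete linkage the merge
#' heights are nondecreasing and the result has n-1 merges.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @param linkage Linkage rule (default and only tested value: complete).
#' @return An `hclust` tree.
#' @export
hierarchical_cluster <- function(d, linkage = "complete") {
  hclust(as.dist(d), method = linkage)
}

#' Export a dendrogram as a Newick string
#'
#' @param tree An `hclust` tree.
#' @return Newick string with merge heights as branch lengths.
#' @export
cluster_newick <- function(tree) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("cluster_newick() needs the 'ape' package")
  ape::write.tree(ape::as.phylo(tree))
}

#' Row-standardize a frequency matrix for heatmap display
#'
#' Each feature row is z-scored with the population standard deviation
#' (denominator n), then truncated to the display range [-3, +3]. A
#' constant row cannot be standardized and raises a `zero_variance_row`
#' error; [filter_features()] removes such rows upstream.
#'
#' @param m Feature-by-sample numeric matrix.
#' @return Matrix of standardized, truncated values.
#' @export
standardize_heatmap <- function(m) {
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  if (any(sd_pop == 0))
    stop("zero_variance_row: ",
         paste(rownames(m)[sd_pop == 0], collapse = ", "))
  z <- (m - mu) / sd_pop
  pmin(pmax(z, -3), 3)
}

# ---- negative-binomial GLM likelihood-ratio testing -------------------------

# Given dispersion phi, fit per-group means m_g for the model
# mu_ij = m_g(j) * s_j by Fisher scoring on the log link (fixed point:
# m <- sum(y w) / sum(s w), w = 1 / (1 + phi mu)). Returns fitted group
# means (per unit library size) and the log-likelihood.
nb_fit_groups <- function(y, s, group, phi, iter = 25) {
  m <- vapply(split(seq_along(y), group),
              function(ix) sum(y[ix]) / sum(s[ix]), 0)
  for (it in seq_len(iter)) {
    mu <- m[group] * s
    w <- 1 / (1 + phi * mu)
    m_new <- vapply(split(seq_along(y), group), function(ix) {
      denom <- sum(s[ix] * w[ix])
      if (denom <= 0) return(m[[as.character(group[ix[1]])]])
      sum(y[ix] * w[ix]) / denom
    }, 0)
    if (max(abs(m_new - m)) < 1e-12 * (1 + max(m))) { m <- m_new; break }
    m <- m_new
  }
  mu <- m[group] * s
  ll <- sum(dnbinom(y, size = 1 / max(phi, 1e-12), mu = pmax(mu, 1e-12), log = TRUE))
  list(means = m, mu = mu, loglik = ll)
}

nb_loglik_poisson_limit <- function(y, mu) {
  sum(dpois_safe(y, pmax(mu, 1e-12)))
}

dpois_safe <- function(y, mu) y * log(mu) - mu - lgamma(y + 1)

# Adjusted profile log-likelihood for the dispersion under the grouped
# model: NB log-likelihood at the fitted means minus the Cox-Reid term
# 0.5 * log det(X' W X) (X = group indicators, so the determinant is the
# product of per-group sums of working weights w = mu / (1 + phi mu)).
nb_apl <- function(y, s, group, phi) {
  fit <- if (phi < 1e-10) {
    m <- vapply(split(seq_along(y), group), function(ix) sum(y[ix]) / sum(s[ix]), 0)
    mu <- m[group] * s
    list(mu = mu, loglik = nb_loglik_poisson_limit(y, mu))
  } else nb_fit_groups(y, s, group, phi)
  w <- fit$mu / (1 + phi * fit$mu)
  cr <- 0.5 * sum(log(pmax(vapply(split(w, group), sum, 0), 1e-12)))
  fit$loglik - cr
}

#' Negative-binomial GLM likelihood-ratio test of differential usage
#'
#' Per feature, fits a negative-binomial log-linear model with library-size
#' offsets under the null (one common mean) and the alternative (a mean per
#' group), and reports the likelihood-ratio statistic against chi-square
#' with 1 df, the log2 fold change of fitted group means, and
#' Benjamini-Hochberg q-values.
#'
#' Dispersion is estimated by maximizing, on a log-spaced grid, the sum of
#' the feature's Cox-Reid adjusted profile likelihood and `prior_df /
#' residual df` times the average adjusted profile likelihood over all
#' features — a weighted-likelihood shrinkage of each feature's dispersion
#' toward the common value, with `prior_df` controlling its strength.
#' Without replication (one sample per group) dispersion is not estimable:
#' it is then fixed at `dispersion` with a loud warning. Supplying
#' `dispersion` always bypasses estimation.
#'
#' Fold changes are reported as group 2 over group 1 (factor level order)
#' from fitted mean counts at the geometric-mean library size, with a 0.5
#' pseudo-count added to both fitted means (reporting only) so zero counts
#' give finite values.
#'
#' @param counts Feature-by-sample count matrix (non-negative integers).
#' @param group_labels Factor (or coercible) of length ncol with exactly
#'   two levels.
#' @param dispersion Optional fixed dispersion (NB variance = mu + phi
#'   mu^2).
#' @param prior_df Prior degrees of freedom for shrinkage toward the common
#'   dispersion.
#' @param lib_sizes Library sizes (default: column sums); all must be > 0.
#' @return data.frame with one row per feature: `feature`, `log2fc`,
#'   `lrt_stat`, `p_value`, `q_value`, `dispersion`. Features with all-zero
#'   counts get NA statistics.
#' @export
nb_glm_lrt <- function(counts, group_labels, dispersion = NULL, prior_df = 10,
                       lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  group <- factor(group_labels)
  if (nlevels(group) != 2) stop("group_labels must have exactly two levels")
  if (length(group) != ncol(counts)) stop("one group label per sample required")
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  s <- lib_sizes / exp(mean(log(lib_sizes)))  # geometric-mean normalized
  nonzero <- rowSums(counts) > 0
  df_resid <- ncol(counts) - 2
  phi_grid <- exp(seq(log(1e-6), log(20), length.out = 41))

  if (is.null(dispersion)) {
    if (df_resid <= 0) {
      warning("no replication within groups: dispersion is NOT estimable; ",
              "fixing it at 0.1 - interpret p-values with caution",
              call. = FALSE)
      phi <- rep(0.1, nrow(counts))
    } else {
      apl <- matrix(NA_real_, nrow(counts), length(phi_grid))
      for (i in which(nonzero)) {
        y <- counts[i, ]
        apl[i, ] <- vapply(phi_grid, function(p) nb_apl(y, s, group, p), 0)
      }
      apl_bar <- colMeans(apl[nonzero, , drop = FALSE])
      prior_n <- prior_df / df_resid
      phi <- rep(NA_real_, nrow(counts))
      for (i in which(nonzero)) {
        crit <- apl[i, ] + prior_n * apl_bar
        phi[i] <- phi_grid[which.max(crit)]
      }
    }
  } else {
    phi <- rep(dispersion, nrow(counts))
  }

  res <- data.frame(feature = rownames(counts) %||% as.character(seq_len(nrow(counts))),
                    log2fc = NA_real_, lrt_stat = NA_real_, p_value = NA_real_,
                    q_value = NA_real_, dispersion = phi,
                    stringsAsFactors = FALSE)
  one_group <- factor(rep("all", ncol(counts)))
  for (i in which(nonzero)) {
    y <- counts[i, ]
    p <- max(phi[i], 1e-10)
    alt <- nb_fit_groups(y, s, group, p)
    null <- nb_fit_groups(y, s, one_group, p)
    stat <- max(0, 2 * (alt$loglik - null$loglik))
    res$lrt_stat[i] <- stat
    res$p_value[i] <- pchisq(stat, df = 1, lower.tail = FALSE)
    mu_g <- alt$means  # per unit normalized library size = mean count at the
                       # geometric-mean library size
    res$log2fc[i] <- log2((mu_g[[2]] + 0.5) / (mu_g[[1]] + 0.5))
  }
  res$q_value[nonzero] <- bh_fdr(res$p_value[nonzero])
  res
}

#' Benjamini-Hochberg step-up q-values
#'
#' q for the i-th smallest p is min over j >= i of (m/j) p_(j), clipped at
#' 1 and mapped back to input order (the classical step-up closed form;
#' computed via [stats::p.adjust()]).
#'
#' @param p_values Vector of p-values in [0, 1].
#' @return q-values in input order; `q >= p` everywhere and q is
#'   nondecreasing in the sorted-p order.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(is.na(p_values) | (p_values >= 0 & p_values <= 1)))
  p.adjust(p_values, method = "BH")
}

#' Largest fold changes
#'
#' The k features with largest absolute log fold change, reported in log10
#' scale and sorted descending by |fold change|; ties broken by smaller q,
#' then feature name. If k exceeds the number of testable features, all are
#' returned.
#'
#' @param diffexp Result of [nb_glm_lrt()].
#' @param k Number of features to report.
#' @return data.frame `feature`, `log2fc`, `log10fc`, `q_value`.
#' @export
top_fold_changes <- function(diffexp, k = 50) {
  d <- diffexp[!is.na(diffexp$log2fc), , drop = FALSE]
  ord <- order(-abs(d$log2fc), d$q_value, d$feature)
  d <- d[head(ord, k), c("feature", "log2fc", "q_value")]
  d$log10fc <- d$log2fc * log10(2)
  rownames(d) <- NULL
  d[, c("feature", "log2fc", "log10fc", "q_value")]
}

#' Compare repertoires across samples
#'
#' Convenience wrapper chaining [filter_features()], correlation distances
#' and complete-linkage trees on both axes, heatmap standardization and,
#' when group labels are given, [nb_glm_lrt()] with [top_fold_changes()].
#'
#' @param usage A `usage_table` (typically `vdj_combo` level).
#' @param group_labels Optional two-level grouping of the samples for
#'   differential testing.
#' @param min_total,min_variance Feature filter thresholds.
#' @param k Size of the top fold-change table.
#' @param ... Passed to [nb_glm_lrt()].
#' @return Object of class `comparison_result` with `kept_features`,
#'   `feature_dist`, `sample_dist`, `feature_tree`, `sample_tree`,
#'   `standardized_matrix`, and (with groups) `diffexp` and `top_k`.
#' @export
compare_repertoires <- function(usage, group_labels = NULL,
                                min_total = 10, min_variance = 0, k = 50, ...) {
  kept <- filter_features(usage, min_total, min_variance)
  if (length(kept) < 2) stop("fewer than 2 features survive filtering")
  freq <- usage$freq[kept, , drop = FALSE]
  counts <- usage$counts[kept, , drop = FALSE]
  fd <- correlation_distance(freq, "features")
  sdist <- correlation_distance(freq, "samples")
  out <- list(kept_features = kept,
              feature_dist = fd, sample_dist = sdist,
              feature_tree = hierarchical_cluster(fd),
              sample_tree = hierarchical_cluster(sdist),
              standardized_matrix = standardize_heatmap(freq))
  if (!is.null(group_labels)) {
    out$diffexp <- nb_glm_lrt(counts, group_labels,
                              lib_sizes = colSums(usage$counts), ...)
    out$top_k <- top_fold_changes(out$diffexp, k)
  }
  structure(out, class = "comparison_result")
}
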