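toy_usage <- function(counts) {
  freq <- sweep(counts, 2, pmax(colSums(counts), 1), "/")
  structure(list(level = "vdj_combo", counts = counts, freq = freq),
            class = "usage_table")
}

test_that("feature filter removes low-count and zero-variance features", {
  counts <- rbind(zero = c(0L, 0L, 0L, 0L),
                  constant = c(50L, 50L, 50L, 50L),
                  good = c(40L, 5L, 60L, 2L))
  colnames(counts) <- paste0("s", 1:4)
  # equal library sizes make the 'constant' feature constant in frequency too
  counts <- rbind(counts, filler = 200L - colSums(counts))
  kept <- filter_features(toy_usage(counts), min_total = 10, min_variance = 0)
  expect_true("good" %in% kept)
  expect_false("zero" %in% kept)
  expect_false("constant" %in% kept)
})

test_that("correlation distance matches its covariance definition and bounds", {
  m <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1))
  d <- correlation_distance(m, "features")
  expect_equal(d["a", "b"], 0)           # identical up to scale
  expect_equal(d["a", "c"], 2)           # exactly anti-correlated
  expect_equal(unname(diag(d)), rep(0, 3))
  set.seed(5)
  r <- matrix(rnorm(40), nrow = 5)
  dr <- correlation_distance(r, "features")
  for (i in 1:4) for (j in (i + 1):5) {
    x <- r[i, ]; y <- r[j, ]
    pearson <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(dr[i, j], 1 - pearson)
    expect_equal(dr[i, j], dr[j, i])
    expect_true(dr[i, j] >= 0 && dr[i, j] <= 2)
  }
  expect_error(correlation_distance(rbind(c(1, 1, 1), c(1, 2, 3)), "features"),
               "zero-variance")
})

test_that("complete-linkage merges match brute-force enumeration on small matrices", {
  d3 <- matrix(0, 3, 3)
  d3[1, 2] <- d3[2, 1] <- 1; d3[1, 3] <- d3[3, 1] <- 5; d3[2, 3] <- d3[3, 2] <- 4
  tree <- hierarchical_cluster(d3)
  expect_equal(tree$height, c(1, 5))
  expect_equal(sort(tree$merge[1, ]), c(-2, -1))  # first merge is {1,2}
  o <- oracle_complete_linkage(d3)
  expect_equal(tree$height, o$heights)
  expect_equal(as.matrix(stats::cophenetic(tree)), o$cophenetic,
               ignore_attr = TRUE)
  # random suite, sizes 3-5
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(3:5, 1)
    x <- matrix(runif(n * 6), n)
    d <- as.matrix(dist(x))
    tree <- hierarchical_cluster(d)
    o <- oracle_complete_linkage(d)
    expect_equal(sort(tree$height), sort(o$heights))
    expect_equal(as.matrix(stats::cophenetic(tree)), o$cophenetic,
                 ignore_attr = TRUE)
  }
  # n = 2: a single merge at d(1,2)
  d2 <- matrix(c(0, 0.7, 0.7, 0), 2)
  expect_equal(hierarchical_cluster(d2)$height, 0.7)
})

test_that("planted two-block sample structure splits at the top of the dendrogram", {
  set.seed(17)
  base1 <- runif(40); base2 <- runif(40)
  freq <- cbind(s1 = base1, s2 = base1 + rnorm(40, 0, 0.01),
                s3 = base1 + rnorm(40, 0, 0.01),
                s4 = base2, s5 = base2 + rnorm(40, 0, 0.01),
                s6 = base2 + rnorm(40, 0, 0.01))
  d <- correlation_distance(freq, "samples")
  tree <- hierarchical_cluster(d)
  grp <- stats::cutree(tree, 2)
  expect_equal(length(unique(grp[c("s1", "s2", "s3")])), 1L)
  expect_equal(length(unique(grp[c("s4", "s5", "s6")])), 1L)
  expect_false(grp[["s1"]] == grp[["s4"]])
  # clustering is invariant to feature row order
  perm <- sample(nrow(freq))
  tree2 <- hierarchical_cluster(correlation_distance(freq[perm, ], "samples"))
  expect_equal(stats::cophenetic(tree), stats::cophenetic(tree2))
})

test_that("heatmap standardization is a population z-score truncated to [-3, 3]", {
  z <- standardize_heatmap(rbind(a = c(1, 2, 3)))
  expect_equal(unname(z[1, ]), c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  set.seed(3)
  m <- matrix(rnorm(50, sd = 5), 5)
  zz <- standardize_heatmap(m)
  expect_true(all(zz >= -3 & zz <= 3))
  expect_equal(unname(rowMeans(standardize_heatmap(matrix(1:12, 3)))), rep(0, 3))
  expect_error(standardize_heatmap(rbind(ok = c(1, 2), flat = c(4, 4))),
               "zero_variance_row")
})

test_that("NB GLM LRT: null-identical groups give zero fold change and p near 1", {
  counts <- matrix(rep(c(30L, 60L, 90L), each = 4), nrow = 3, byrow = TRUE)
  res <- nb_glm_lrt(counts, c("A", "A", "B", "B"), dispersion = 0.1)
  expect_equal(res$log2fc, rep(0, 3), tolerance = 1e-8)
  expect_true(all(res$lrt_stat < 1e-6))
  expect_true(all(res$p_value > 0.999))
  # all-zero features are reported as NA
  res0 <- nb_glm_lrt(rbind(c(0L, 0L, 0L, 0L), c(5L, 6L, 7L, 8L)),
                     c("A", "A", "B", "B"), dispersion = 0.1)
  expect_true(is.na(res0$p_value[1]))
  expect_false(is.na(res0$p_value[2]))
})

test_that("NB GLM LRT agrees with edgeR at fixed dispersion", {
  skip_if_not_installed("edgeR")
  set.seed(42)
  nf <- 60
  grp <- factor(c("A", "A", "A", "B", "B", "B"))
  mu <- exp(rnorm(nf, log(40), 1))
  fc <- c(rep(2, 10), rep(1, nf - 10))
  y <- cbind(matrix(rnbinom(nf * 3, mu = rep(mu, 3), size = 10), nf, 3),
             matrix(rnbinom(nf * 3, mu = rep(mu * fc, 3), size = 10), nf, 3))
  mine <- nb_glm_lrt(y, grp, dispersion = 0.1)
  design <- stats::model.matrix(~grp)
  fit <- edgeR::glmFit(y, design, dispersion = 0.1, offset = log(colSums(y)),
                       prior.count = 0)
  lrt <- edgeR::glmLRT(fit)
  expect_equal(mine$lrt_stat, unname(lrt$table$LR), tolerance = 1e-4)
  expect_equal(mine$p_value, unname(lrt$table$PValue), tolerance = 1e-4)
})

test_that("LRT ranking matches the exact conditional binomial test in the Poisson limit", {
  set.seed(7)
  for (t in 1:20) {
    nf <- 8
    y <- cbind(rpois(nf, sample(80:600, nf)), rpois(nf, sample(80:600, nf)))
    s <- colSums(y)
    res <- suppressWarnings(nb_glm_lrt(y, c("A", "B"), dispersion = 1e-8,
                                       lib_sizes = s))
    pbin <- vapply(seq_len(nf), function(i)
      stats::binom.test(y[i, 1], sum(y[i, ]), p = s[1] / sum(s))$p.value, 0)
    expect_equal(order(res$p_value), order(pbin))
  }
})

test_that("planted fourfold changes are detected with high power at q < 0.05", {
  set.seed(202)
  nf <- 1000
  grp <- rep(c("A", "B"), each = 4)
  mu <- exp(rnorm(nf, log(50), 1))
  fc <- rep(1, nf); fc[1:50] <- 4
  y <- cbind(matrix(rnbinom(nf * 4, mu = rep(mu, 4), size = 10), nf, 4),
             matrix(rnbinom(nf * 4, mu = rep(mu * fc, 4), size = 10), nf, 4))
  res <- nb_glm_lrt(y, grp)
  expect_gte(mean(res$q_value[1:50] < 0.05), 0.9)
  expect_lte(mean(res$q_value[-(1:50)] < 0.05, na.rm = TRUE), 0.05)
})

test_that("dispersion is not estimable without replication and falls back loudly", {
  y <- rbind(c(10L, 20L), c(30L, 15L))
  expect_warning(res <- nb_glm_lrt(y, c("A", "B")), "NOT estimable")
  expect_equal(res$dispersion, c(0.1, 0.1))
})

test_that("BH step-up matches its closed form and is monotone above p", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(8)
  p <- runif(200)^2
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q <= 1))
})

test_that("top fold changes are ranked by |log FC| with a log10 column", {
  d <- data.frame(feature = c("a", "b", "c"),
                  log2fc = c(1, -3, 2), lrt_stat = 1, p_value = 0.5,
                  q_value = c(0.5, 0.2, 0.1))
  top <- top_fold_changes(d, k = 2)
  expect_equal(top$feature, c("b", "c"))
  expect_equal(top$log10fc, top$log2fc * log10(2))
  expect_equal(nrow(top_fold_changes(d, k = 10)), 3L)
})

test_that("compare_repertoires chains filtering, trees, heatmap and testing", {
  set.seed(12)
  counts <- matrix(rnbinom(50 * 6, mu = 40, size = 5), 50, 6,
                   dimnames = list(paste0("f", 1:50), paste0("s", 1:6)))
  u <- toy_usage(counts)
  cr <- compare_repertoires(u, group_labels = rep(c("A", "B"), each = 3),
                            dispersion = 0.1, k = 5)
  expect_true(length(cr$kept_features) >= 2)
  expect_true(all(abs(cr$standardized_matrix) <= 3))
  expect_s3_class(cr$sample_tree, "hclust")
  expect_equal(nrow(cr$top_k), 5L)
  expect_true(all(cr$diffexp$q_value >= cr$diffexp$p_value, na.rm = TRUE))
})
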