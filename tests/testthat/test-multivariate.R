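test_that("PCA recovers a single varying direction and duplicates score alike", {
  m <- matrix(5, nrow = 4, ncol = 6)        # features x samples
  m[2, ] <- c(1, 2, 3, 4, 5, 6)             # only feature 2 varies
  fm <- fm_from_matrix(m)
  p <- suppressWarnings(pca_model(fm, n_components = 1, scale = "none"))
  expect_equal(abs(p$loadings$PC1), c(0, 1, 0, 0), tolerance = 1e-10)

  m2 <- cbind(m, m[, 1])                    # duplicate sample
  colnames(m2) <- paste0("s", seq_len(ncol(m2)))
  p2 <- suppressWarnings(pca_model(fm_from_matrix(m2), n_components = 1,
                                   scale = "none"))
  expect_equal(p2$scores$PC1[1], p2$scores$PC1[7], tolerance = 1e-10)

  expect_warning(pca_model(fm, n_components = 10, scale = "none"), "rank")
})

test_that("PCA separates planted groups on the leading components", {
  x <- planted_two_group_fm(n_per_group = 10, n_features = 120,
                            n_planted = 25, effect_sd = 2, seed = 31)
  p <- pca_model(x$fm, n_components = 2)
  sc <- as.matrix(p$scores[, c("PC1", "PC2")])
  g <- x$labels[p$scores$sample_id]
  centro <- rbind(colMeans(sc[g == "a", ]), colMeans(sc[g == "b", ]))
  between <- sqrt(sum((centro[1, ] - centro[2, ])^2))
  within <- mean(c(sqrt(rowSums(sweep(sc[g == "a", ], 2, centro[1, ])^2)),
                   sqrt(rowSums(sweep(sc[g == "b", ], 2, centro[2, ])^2))))
  expect_gt(between / within, 2)
})

test_that("a single informative feature takes all the predictive weight", {
  set.seed(32)
  y <- rep(c("a", "b"), each = 6)
  m <- matrix(100, nrow = 4, ncol = 12)     # constant features carry nothing
  m[1, ] <- ifelse(y == "b", 10, 1) + rnorm(12, sd = 0.01)
  colnames(m) <- paste0("s", 1:12)
  fm <- fm_from_matrix(m)
  fit <- opls_da(fm, y, n_orth = 0, scale = "none")
  expect_gt(abs(fit$weights[1]), 0.99)
  v <- vip(fit)
  expect_equal(v$vip, c(2, 0, 0, 0), tolerance = 1e-6)   # one-hot, p = 4
})

test_that("OPLS-DA with zero orthogonal components reproduces PLS-DA", {
  x <- planted_two_group_fm(n_per_group = 8, n_features = 60, seed = 33)
  o <- opls_da(x$fm, x$labels, n_orth = 0)
  p <- pls_da(x$fm, x$labels, n_components = 1)
  expect_equal(o$scores, p$scores[, 1], tolerance = 1e-8)
  expect_equal(o$weights, p$weights[, 1], tolerance = 1e-8)
  expect_error(opls_da(x$fm, rep("a", 16)), "two classes")
})

test_that("orthogonal scores are uncorrelated with the class vector", {
  x <- planted_two_group_fm(n_per_group = 10, n_features = 80, seed = 34)
  o <- opls_da(x$fm, x$labels, n_orth = 2)
  for (k in seq_len(ncol(o$scores_orth))) {
    expect_lt(abs(cor(o$scores_orth[, k], o$y)), 1e-8)
  }
})

test_that("the VIP identity sum(VIP^2) = p holds on every fitted model", {
  for (seed in 35:37) {
    x <- planted_two_group_fm(n_per_group = 6, n_features = 50, seed = seed)
    o <- opls_da(x$fm, x$labels, n_orth = 1)
    p2 <- pls_da(x$fm, x$labels, n_components = 2)
    expect_equal(sum(vip(o)$vip^2), 50, tolerance = 1e-6)
    expect_equal(sum(vip(p2)$vip^2), 50, tolerance = 1e-6)
  }
})

test_that("joint covariance/correlation selection applies the strict 50% rule", {
  fake <- list(mz = 1:4,
               cov = c(10, 9, 2, 0),
               corr = c(0.9, 0.36, 0.88, 0))
  sel <- select_candidates(fake, pct_cutoff = 50)
  # feature 1 holds both maxima: (100%, 100%) -> selected
  expect_true(sel$selected[1])
  # feature 2 at (90%, 40%) fails the correlation axis
  expect_equal(sel$cov_pct[2], 90)
  expect_equal(round(sel$corr_pct[2]), 40)
  expect_false(sel$selected[2])

  none <- select_candidates(list(mz = 1:2, cov = c(0, 0), corr = c(0, 0)))
  expect_false(any(none$selected))
})

test_that("rank-sum selection reproduces exact small-sample p-values", {
  m <- rbind(c(1, 2, 3, 10, 11, 12),
             c(1, 2, 3, 3, 2, 1))
  colnames(m) <- paste0("s", 1:6)
  fm <- fm_from_matrix(m)
  w <- suppressWarnings(wilcoxon_select(fm, rep(c("g1", "g2"), each = 3)))
  expect_equal(w$p_value[1], 0.1, tolerance = 1e-12)
  expect_false(w$selected[1])

  m2 <- rbind(c(1, 2, 3, 4, 10, 11, 12, 13))
  colnames(m2) <- paste0("s", 1:8)
  w2 <- wilcoxon_select(fm_from_matrix(m2), rep(c("g1", "g2"), each = 4))
  expect_equal(w2$p_value, 2 / choose(8, 4), tolerance = 1e-12)  # 0.0286
  expect_true(w2$selected)

  m3 <- rbind(rep(c(5, 6, 7), 2))
  colnames(m3) <- paste0("s", 1:6)
  w3 <- suppressWarnings(wilcoxon_select(fm_from_matrix(m3),
                                         rep(c("g1", "g2"), each = 3)))
  expect_equal(w3$p_value, 1)
  expect_false(w3$selected)
})

test_that("hierarchical clustering honours linkage and monotone heights", {
  m <- rbind(c(0, 1, 10))
  colnames(m) <- c("a", "b", "c")
  hc <- hca(fm_from_matrix(m), linkage = "single", scale = "none")
  expect_equal(hc$height, c(1, 9))
  expect_false(is.unsorted(hc$height))

  dup <- rbind(c(3, 3, 8)); colnames(dup) <- c("a", "b", "c")
  hc2 <- hca(fm_from_matrix(dup), linkage = "average", scale = "none")
  expect_equal(hc2$height[1], 0)

  expect_error(hca(fm_from_matrix(m), linkage = "centroid"), "arg")
})

test_that("planted discriminative features are recovered by the triple rule", {
  x <- planted_two_group_fm(n_per_group = 12, n_features = 300,
                            n_planted = 30, effect_sd = 2, seed = 38)
  fit <- opls_da(x$fm, x$labels, n_orth = 1)
  v <- vip(fit)
  sel <- select_candidates(fit, 50)
  w <- wilcoxon_select(x$fm, x$labels)
  chosen <- which(v$vip >= 1 & sel$selected & w$selected)
  precision <- mean(chosen %in% x$planted)
  recall <- mean(x$planted %in% chosen)
  expect_gte(precision, 0.8)
  expect_gte(recall, 0.8)
})

test_that("VIP ranks planted features above noise features", {
  x <- planted_two_group_fm(n_per_group = 10, n_features = 250,
                            n_planted = 25, effect_sd = 2, seed = 39)
  v <- vip(opls_da(x$fm, x$labels, n_orth = 1))$vip
  is_planted <- seq_along(v) %in% x$planted
  # AUROC by rank-sum identity
  r <- rank(v)
  auroc <- (sum(r[is_planted]) - sum(is_planted) * (sum(is_planted) + 1) / 2) /
    (sum(is_planted) * sum(!is_planted))
  expect_gte(auroc, 0.95)
})

test_that("cross-validated Q2 supports real structure and rejects noise", {
  set.seed(40)
  x <- planted_two_group_fm(n_per_group = 10, n_features = 150,
                            n_planted = 25, effect_sd = 2.5, seed = 41)
  sup <- cluster_support(x$fm, x$labels, nperm = 50)
  expect_true(sup$supported)

  noise <- planted_two_group_fm(n_per_group = 10, n_features = 150,
                                n_planted = 1, effect_sd = 0, seed = 42)
  sup0 <- cluster_support(noise$fm, noise$labels, nperm = 50)
  expect_false(sup0$supported)
})
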