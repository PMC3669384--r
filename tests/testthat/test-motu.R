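fm_1d <- function(v, ids = NULL) {
  m <- matrix(v, nrow = 1)
  colnames(m) <- ids %||% paste0("st", seq_along(v))
  fm_from_matrix(m)
}

test_that("Ward merge heights are error-sum-of-squares increases", {
  # two 1-D points at distance 2: ESS of the union is 2
  hc <- ward_dendrogram(fm_1d(c(0, 2)), center = FALSE, scale = "none")
  expect_equal(hc$height, 2)
  expect_equal(attr(hc, "ward_max"), 2)

  # identical strains merge first, at zero cost
  hc2 <- ward_dendrogram(fm_1d(c(5, 5, 9)), center = FALSE, scale = "none")
  expect_equal(hc2$height[1], 0)
})

test_that("Ward agrees with the exhaustive greedy ESS oracle", {
  for (seed in 51:54) {
    set.seed(seed)
    x <- matrix(rnorm(8 * 5), nrow = 8)
    rownames(x) <- paste0("st", 1:8)
    hc <- ward_dendrogram(fm_from_matrix(t(x)), center = FALSE, scale = "none")
    orc <- oracle_ward(x)
    expect_equal(sort(hc$height), sort(orc$heights), tolerance = 1e-8)
    # partition agreement at every cluster count
    for (k in 2:7) {
      got <- stats::cutree(hc, k = k)
      # rebuild oracle partition at the same k from its merge list
      parent <- seq_len(8)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (mi in seq_len(8 - k)) {
        roots <- unique(vapply(orc$merges[[mi]], find, integer(1)))
        for (r in roots[-1]) parent[r] <- roots[1]
      }
      want <- vapply(seq_len(8), find, integer(1))
      tab <- table(got, want)
      expect_true(all(colSums(tab > 0) == 1) && all(rowSums(tab > 0) == 1))
    }
  }
})

test_that("percent cuts use the maximal Ward distance and nest", {
  # 1-D points {0, 2, 10}: merges at 2 (ESS of {0,2}) then 54
  fm <- fm_1d(c(0, 2, 10))
  hc <- ward_dendrogram(fm, center = FALSE, scale = "none")
  expect_equal(sort(hc$height), c(2, 54))
  expect_equal(attr(hc, "ward_max"), 54)

  expect_equal(length(unique(cut_percent(hc, 100)$cluster)), 1)
  p40 <- cut_percent(hc, 40)       # cut at 21.6: {0,2} together, {10} apart
  expect_equal(length(unique(p40$cluster)), 2)
  p3 <- cut_percent(hc, 3)         # cut at 1.62: all singletons
  expect_equal(length(unique(p3$cluster)), 3)
  expect_error(cut_percent(hc, 0), "pct")
  expect_error(cut_percent(hc, 101), "pct")

  # nestedness: every fine cluster sits inside one coarse cluster
  set.seed(55)
  hc2 <- ward_dendrogram(fm_from_matrix(matrix(rnorm(12 * 20), nrow = 20,
                                               dimnames = list(NULL, paste0("st", 1:12)))))
  fine <- cut_percent(hc2, 10)$cluster
  coarse <- cut_percent(hc2, 40)$cluster
  expect_true(all(tapply(coarse, fine, function(v) length(unique(v))) == 1))
})

test_that("the stated cut height is pct/100 x ward_max", {
  hc <- ward_dendrogram(fm_1d(c(0, 2, 10)), center = FALSE, scale = "none")
  attr(hc, "ward_max") <- 26000
  # with ward_max forced to 26000 the 40% cut sits at 10400, far above every
  # real merge: everything collapses to one cluster
  expect_equal(length(unique(cut_percent(hc, 40)$cluster)), 1)
  attr(hc, "ward_max") <- 54
  expect_equal(length(unique(cut_percent(hc, 40)$cluster)), 2)
})

test_that("Shannon, Good's coverage and rarefaction match closed forms", {
  expect_equal(shannon_index(c(7)), 0)
  expect_equal(shannon_index(c(5, 5)), log(2), tolerance = 1e-12)
  expect_equal(shannon_index(c(1, 2, 3)),
               -(1 / 6 * log(1 / 6) + 2 / 6 * log(2 / 6) + 3 / 6 * log(3 / 6)),
               tolerance = 1e-12)

  expect_equal(goods_coverage(c(2, 3, 4)), 1)
  expect_equal(goods_coverage(c(1, 1, 3)), 0.6, tolerance = 1e-12)
  expect_equal(goods_coverage(rep(1, 7)), 0)

  rc <- rarefaction_curve(c(2, 2), sizes = 2)
  expect_equal(rc$richness, 5 / 3, tolerance = 1e-12)
  full <- rarefaction_curve(c(3, 1, 2))
  expect_equal(full$richness[full$n == 1], 1)
  expect_equal(full$richness[full$n == 6], 3)
  expect_true(all(diff(full$richness) >= -1e-12))       # non-decreasing
  expect_true(all(diff(diff(full$richness)) <= 1e-12))  # concave
  expect_error(rarefaction_curve(c(2, 2), sizes = 5), "sizes")
})

test_that("rarefaction matches the vegan reference implementation", {
  counts <- c(9, 4, 4, 2, 1, 1)
  ours <- rarefaction_curve(counts, sizes = c(1, 5, 10, 21))
  theirs <- vegan::rarefy(counts, sample = c(1, 5, 10, 21))
  expect_equal(ours$richness, as.numeric(theirs), tolerance = 1e-10)
  expect_equal(shannon_index(counts),
               as.numeric(vegan::diversity(counts)), tolerance = 1e-12)
})

test_that("diversity profiles coarsen monotonically", {
  set.seed(56)
  m <- matrix(rnorm(15 * 30), nrow = 30,
              dimnames = list(NULL, paste0("st", 1:15)))
  hc <- ward_dendrogram(fm_from_matrix(m))
  prof <- diversity_profile(hc)
  expect_true(all(diff(prof$shannon) <= 1e-12))
  expect_true(all(diff(prof$goods) >= -1e-12))
  top <- prof[prof$pct == 100, ]
  expect_equal(top$n_motu, 1)
  expect_equal(top$shannon, 0)
  expect_equal(top$goods, 1)
})

test_that("planted metabotype clusters are recovered at the planted scale", {
  cfg <- truth_config(n_core = 150,
                      n_accessory = c(c1 = 25, c2 = 25, c3 = 25, c4 = 25),
                      effect_size = 2)
  tr <- generate_truth(cfg, seed = 57)
  sim <- simulate_peaklists(tr, noise_model(n_noise_peaks = 0,
                                            isotope_satellites = FALSE),
                            n_strains_per_group = c(c1 = 6, c2 = 6, c3 = 6,
                                                    c4 = 6), seed = 58)
  fm <- align_peaklists(sim$peaks)
  hc <- ward_dendrogram(fm)
  # the planted scale is where the m-OTU count plateaus at the planted
  # richness in the diversity profile
  prof <- diversity_profile(hc)
  plateau <- prof$pct[prof$n_motu == 4]
  expect_gt(length(plateau), 0)
  part <- cut_percent(hc, stats::median(plateau))
  truth_lab <- sub("^SP_(c[0-9])_.*$", "\\1", part$strain_id)
  expect_equal(length(unique(part$cluster)), 4)
  ari <- mclust::adjustedRandIndex(part$cluster, truth_lab)
  expect_gte(ari, 0.9)
})
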