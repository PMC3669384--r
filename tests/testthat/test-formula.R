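test_that("ion masses convert to neutral masses by one proton", {
  expect_equal(neutralize_mz(175.118952, "protonated"), 174.111676,
               tolerance = 1e-8)   # stated value printed to 6 decimals
  expect_equal(neutralize_mz(173.104400, "deprotonated"), 174.111676,
               tolerance = 1e-5)
  expect_error(neutralize_mz(0.5, "protonated"), "proton")
  expect_error(neutralize_mz(100, "sodiated"), "arg")
})

test_that("enumeration finds the expected formulas inside the window", {
  arg <- enumerate_formulas(174.111676, constraint_set(tol_ppm = 0.5))
  expect_true("C6H14N4O2" %in% arg$formula)
  expect_lt(abs(arg$error_ppm[arg$formula == "C6H14N4O2"]), 0.01)

  ch4 <- enumerate_formulas(16.031300, constraint_set(tol_ppm = 0.5))
  expect_equal(ch4$formula, "CH4")

  no_n <- enumerate_formulas(174.111676, constraint_set(max_N = 0))
  expect_false("C6H14N4O2" %in% no_n$formula)
})

test_that("enumeration matches the exhaustive nested-loop oracle", {
  set.seed(7)
  masses <- runif(40, 60, 500)
  cs <- constraint_set(tol_ppm = 0.5)
  for (m in masses) {
    got <- enumerate_formulas(m, cs)
    want <- oracle_enumerate(m, tol_ppm = 0.5)
    expect_identical(candidate_key(got), candidate_key(want))
  }
})

test_that("tightening any bound never adds candidates", {
  set.seed(8)
  masses <- runif(10, 100, 600)
  base <- constraint_set(tol_ppm = 0.5)
  tighter <- list(constraint_set(max_N = 2), constraint_set(max_S = 0),
                  constraint_set(max_oc_ratio = 0.5),
                  constraint_set(rdbe_range = c(0, 10)),
                  constraint_set(tol_ppm = 0.1))
  for (m in masses) {
    full <- candidate_key(enumerate_formulas(m, base))
    for (cs in tighter) {
      sub <- candidate_key(enumerate_formulas(m, cs))
      expect_true(all(sub %in% full))
    }
  }
})

test_that("rule checks name the violated rule", {
  expect_true(check_rules(c(C = 6, H = 14, N = 4, O = 2, S = 0))$pass)
  bad_oc <- check_rules(c(C = 6, H = 12, N = 0, O = 7, S = 0),
                        constraint_set(max_oc_ratio = 1))
  expect_false(bad_oc$pass)
  expect_equal(bad_oc$reason, "O/C")
  bad_rdbe <- check_rules(c(C = 1, H = 6, N = 0, O = 0, S = 0))
  expect_false(bad_rdbe$pass)
  expect_equal(bad_rdbe$reason, "RDBE")
  bad_n <- check_rules(c(C = 6, H = 13, N = 6, O = 2, S = 0))
  expect_false(bad_n$pass)
  expect_equal(bad_n$reason, "element bound")
})

test_that("theoretical masses are reproducible from the element masses", {
  counts <- parse_formula(c("C6H12O6", "C6H14N4O2", "CH4", "C10H20N2O4S"))
  manual <- counts$C * 12 + counts$H * 1.00782503 + counts$N * 14.00307401 +
    counts$O * 15.99491462 + counts$S * 31.97207069
  expect_equal(formula_mass(counts), manual, tolerance = 1e-6)
})

test_that("13C satellites are removed by spacing, ratio and pattern", {
  # glucose (C6, monoisotopic 180.06339) with its satellite at +1.00335,
  # satellite/parent ratio 0.07 (~ 6 x 0.0107), correlated pattern
  parent <- c(100, 200, 300, 400) * 1e3
  m <- rbind(parent, parent * 0.07)
  fm <- fm_from_matrix(m, mz = c(180.06339, 181.06674))
  out <- remove_isotopologues(fm, max_C = 100)
  expect_equal(out$mz, 180.06339)
  expect_equal(attr(out, "removed")$parent_mz, 180.06339)

  # heavy/light ratio 2.0 is impossible for a 13C satellite: both kept
  m2 <- rbind(parent, parent * 2)
  fm2 <- fm_from_matrix(m2, mz = c(180.06339, 181.06674))
  expect_equal(nrow(remove_isotopologues(fm2, max_C = 100)), 2)

  # isolated feature untouched
  fm3 <- fm_from_matrix(matrix(parent, nrow = 1), mz = 500.123)
  expect_equal(nrow(remove_isotopologues(fm3)), 1)

  # with assignments, the carbon count sharpens the ratio bound:
  # ratio 0.30 is far beyond 1.2 x 6 x 0.0107 but below the C=100 fallback
  m4 <- rbind(parent, parent * 0.30)
  fm4 <- fm_from_matrix(m4, mz = c(180.06339, 181.06674))
  asn <- tibble::tibble(mz = 180.06339, C = 6L)
  expect_equal(nrow(remove_isotopologues(fm4, assignments = asn)), 2)
  expect_equal(nrow(remove_isotopologues(fm4, max_C = 100)), 1)
})

test_that("assignment recovers planted formulas and flags the edge cases", {
  cfg <- truth_config(n_core = 100, n_accessory = c(old = 5, new = 5))
  tr <- generate_truth(cfg, seed = 3)
  sim <- simulate_peaklists(
    tr, noise_model(mass_noise_ppm = 0.2, dropout_prob = 0,
                    n_noise_peaks = 0, isotope_satellites = FALSE),
    n_strains_per_group = c(old = 3, new = 3), seed = 4)
  fm <- align_peaklists(sim$peaks, tol_ppm = 1)
  asn <- assign_formulas(fm)
  matched <- match_truth_features(tr, fm)
  hit <- dplyr::left_join(matched, asn, by = c(feature_mz = "mz"))
  recovery <- mean(hit$formula.x == hit$formula.y, na.rm = TRUE)
  expect_gte(recovery, 0.99)

  # a feature with no candidate stays unassigned
  lone <- assign_formulas(fm_from_matrix(matrix(1), mz = 150.000000))
  expect_true(is.na(lone$formula) || lone$n_candidates >= 1)

  # widening the tolerance creates ambiguity; best candidate ranks first
  wide <- enumerate_formulas(400.20, constraint_set(tol_ppm = 20))
  expect_gt(nrow(wide), 1)
  expect_true(all(diff(abs(wide$error_ppm)) >= 0))
})

test_that("formula recovery degrades as mass noise grows", {
  cfg <- truth_config(n_core = 80, n_accessory = c(old = 5, new = 5))
  tr <- generate_truth(cfg, seed = 5)
  recov <- vapply(c(0, 1), function(ppm) {
    sim <- simulate_peaklists(
      tr, noise_model(mass_noise_ppm = ppm, dropout_prob = 0,
                      n_noise_peaks = 0, isotope_satellites = FALSE),
      n_strains_per_group = c(old = 2, new = 2), seed = 6)
    fm <- align_peaklists(sim$peaks, tol_ppm = max(1, 3 * ppm))
    asn <- assign_formulas(fm)
    matched <- match_truth_features(tr, fm, tol_ppm = max(1, 3 * ppm))
    hit <- dplyr::left_join(matched, asn, by = c(feature_mz = "mz"))
    mean(hit$formula.x == hit$formula.y, na.rm = TRUE)
  }, numeric(1))
  expect_gte(recov[1], recov[2])
  expect_equal(recov[1], 1)     # noiseless closed loop is perfect
})
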