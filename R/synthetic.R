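# ---- ground-truth generation -------------------------------------------

#' Configuration for the synthetic ground truth
#'
#' Default sizes mirror the headline numbers of a single cellular fraction of
#' the study design this package targets (an intracellular fraction of ~5700
#' features of which ~400 discriminate reference from newly isolated strains):
#' a shared core metabolome plus group-specific accessory sets whose mean
#' intensities are elevated in their own group.
#'
#' @param n_core Number of core (shared, non-discriminative) formulas.
#' @param n_accessory Named integer vector: accessory formulas per group; the
#'   names define the groups (default `c(old = 274, new = 136)`).
#' @param effect_size Mean log-intensity elevation of an accessory formula in
#'   its own group, in units of the intensity noise SD (default 2).
#' @param window Ion m/z window after protonation (default `c(150, 2000)`).
#' @param base_meanlog,base_sdlog Log-normal spread of per-formula baseline
#'   intensities across the metabolome.
#' @param reference_fraction Fraction of formulas given entries in the
#'   synthetic annotation reference table (default 0.15, matching the low
#'   annotability typical of non-targeted FT-ICR data).
#' @param isomer_prob Probability that an annotated formula carries a second
#'   isomeric metabolite entry.
#' @return A list of class `"truth_config"`.
#' @export
truth_config <- function(n_core = 5332, n_accessory = c(old = 274, new = 136),
                         effect_size = 2, window = c(150, 2000),
                         base_meanlog = log(1e6), base_sdlog = 1,
                         reference_fraction = 0.15, isomer_prob = 0.1) {
  stopifnot(n_core > 0, length(n_accessory) >= 2, all(n_accessory > 0),
            !is.null(names(n_accessory)), effect_size >= 0)
  structure(list(n_core = n_core, n_accessory = n_accessory,
                 effect_size = effect_size, window = window,
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                 reference_fraction = reference_fraction,
                 isomer_prob = isomer_prob),
            class = "truth_config")
}

# draw n distinct CHNOS formulas, valid under `constraints`, with protonated
# mass inside `window`; construction guarantees the nitrogen rule and an
# integral RDBE (H = 2C + N + 2 - 2*RDBE)
sample_formulas <- function(n, window, constraints = constraint_set()) {
  got <- tibble::tibble(C = integer(), H = integer(), N = integer(),
                        O = integer(), S = integer())
  tries <- 0L
  while (nrow(got) < n) {
    tries <- tries + 1L
    if (tries > 200L) {
      stop("requested formula count exceeds lattice capacity under constraints",
           call. = FALSE)
    }
    m <- max(2L * (n - nrow(got)), 1000L)
    # metabolite-like size distribution: most species below ~1000 Da, where
    # sub-ppm CHNOS assignment is essentially unique
    C <- sample(5:40, m, replace = TRUE)
    N <- sample(0:5, m, replace = TRUE, prob = c(0.4, 0.25, 0.15, 0.1, 0.06, 0.04))
    S <- stats::rbinom(m, 1, 0.08)
    O <- floor(stats::runif(m) * (C + 1))          # 0..C keeps O/C <= 1
    r <- floor(stats::runif(m) * pmin(C, 20))      # RDBE
    H <- 2L * C + N + 2L - 2L * r
    cand <- tibble::tibble(C = C, H = H, N = N, O = O, S = S)
    ok <- H >= 0 & is.na(rule_violations(cand, constraints))
    cand <- cand[ok, ]
    mz <- ionize_mass(formula_mass(cand))
    cand <- cand[mz > window[1] & mz < window[2], ]
    got <- dplyr::distinct(dplyr::bind_rows(got, cand))
  }
  got[seq_len(n), ]
}

# class/pathway vocabulary for the synthetic reference table, with a planted
# skew so class rank order is a recoverable quantity
annotation_vocabulary <- function() {
  tibble::tibble(
    class = c("Lipid metabolism", "Metabolism of other amino acids",
              "Biosynthesis of other secondary metabolites",
              "Metabolism of terpenoids and polyketides",
              "Carbohydrate metabolism", "Nucleotide metabolism"),
    weight = c(0.30, 0.22, 0.18, 0.14, 0.10, 0.06),
    pathways = list(
      c("Fatty acid biosynthesis", "Ether lipid metabolism",
        "Sphingolipid metabolism"),
      c("Cyanoamino acid metabolism", "Glutathione metabolism"),
      c("Novobiocin biosynthesis", "Penicillin and cephalosporin biosynthesis"),
      c("Biosynthesis of type II polyketide products", "Terpenoid backbone"),
      c("Glycolysis", "Pentose phosphate pathway"),
      c("Purine metabolism", "Pyrimidine metabolism")
    )
  )
}

#' Generate a synthetic ground-truth metabolome
#'
#' Samples distinct, chemically valid CHNOS formulas (every one passes the
#' default [constraint_set()]), splits them into a shared core set and
#' disjoint per-group accessory sets, assigns each a baseline log-intensity,
#' and builds a synthetic annotation reference table over a subset of them.
#' Deterministic given `seed`.
#'
#' @param config A [truth_config()].
#' @param seed Integer seed.
#' @return An object of class `"truth_set"`: a list with `formulas` (tibble
#'   with counts, `formula`, `neutral_mass`, `role` = `"core"` or a group
#'   name, `base_log`), `groups`, `reference` (annotation table), `config`,
#'   `seed`.
#' @export
generate_truth <- function(config = truth_config(), seed = 1) {
  stopifnot(inherits(config, "truth_config"))
  set.seed(seed)
  groups <- names(config$n_accessory)
  n_total <- config$n_core + sum(config$n_accessory)
  counts <- sample_formulas(n_total, config$window)
  formulas <- counts |>
    dplyr::mutate(formula = formula_string(counts),
                  neutral_mass = formula_mass(counts),
                  role = rep(c("core", groups),
                             times = c(config$n_core, config$n_accessory)),
                  base_log = stats::rnorm(n_total, config$base_meanlog,
                                          config$base_sdlog))
  # synthetic annotation reference over a subset of the formulas
  vocab <- annotation_vocabulary()
  n_ref <- round(config$reference_fraction * n_total)
  ref_idx <- sample.int(n_total, n_ref)
  cls_i <- sample.int(nrow(vocab), n_ref, replace = TRUE, prob = vocab$weight)
  pathway <- vapply(cls_i, function(i) sample(vocab$pathways[[i]], 1),
                    character(1))
  reference <- tibble::tibble(
    formula = formulas$formula[ref_idx],
    metabolite = sprintf("metabolite_%04d", seq_len(n_ref)),
    pathway = pathway,
    class = vocab$class[cls_i]
  )
  extra <- which(stats::runif(n_ref) < config$isomer_prob)
  if (length(extra) > 0) {
    iso <- reference[extra, ]
    iso$metabolite <- sprintf("isomer_%04d", seq_along(extra))
    reference <- dplyr::bind_rows(reference, iso)
  }
  reference <- dplyr::bind_cols(reference, parse_formula(reference$formula))
  structure(list(formulas = formulas, groups = groups, reference = reference,
                 config = config, seed = seed),
            class = "truth_set")
}

# ---- peak-list simulation ----------------------------------------------

#' Noise model for simulated peak lists
#'
#' Defaults emulate externally calibrated broadband ICR-FT/MS acquisition:
#' sub-0.1-ppm mass error, intensity relative SD under 5%, occasional
#' absence of a core feature in a strain, spurious noise peaks, and 13C
#' isotopologue satellites.
#'
#' @param mass_noise_ppm SD of the relative mass error in ppm (default 0.1).
#' @param intensity_cv Technical coefficient of variation of intensities
#'   (default 0.05, replicate-injection reproducibility).
#' @param strain_cv Biological between-strain coefficient of variation of a
#'   feature's intensity (default 0.4): individual strains express the same
#'   metabolite at substantially different levels, far beyond instrument
#'   noise. Group effect sizes are expressed in units of the resulting total
#'   per-feature SD.
#' @param dropout_prob Per-strain absence probability of a core feature
#'   (default 0.05).
#' @param n_noise_peaks Spurious peaks per sample (default 100).
#' @param isotope_satellites Add 13C satellites (default TRUE).
#' @return A list of class `"noise_model"`.
#' @export
noise_model <- function(mass_noise_ppm = 0.1, intensity_cv = 0.05,
                        strain_cv = 0.4, dropout_prob = 0.05,
                        n_noise_peaks = 100, isotope_satellites = TRUE) {
  stopifnot(mass_noise_ppm >= 0, intensity_cv >= 0, strain_cv >= 0,
            dropout_prob >= 0, dropout_prob < 1, n_noise_peaks >= 0)
  structure(list(mass_noise_ppm = mass_noise_ppm, intensity_cv = intensity_cv,
                 strain_cv = strain_cv, dropout_prob = dropout_prob,
                 n_noise_peaks = n_noise_peaks,
                 isotope_satellites = isotope_satellites),
            class = "noise_model")
}

#' Simulate per-strain peak lists from a ground truth
#'
#' For every strain, each truth formula it expresses yields a protonated ion
#' peak at `(neutral + proton) x (1 + eps)`, `eps ~ N(0, mass_noise_ppm x
#' 1e-6)`, with log-normal intensity around its baseline; accessory formulas
#' of the strain's own group are elevated by `effect_size` noise-SD units.
#' Optional 13C satellites appear one 13C-12C spacing above the parent with
#' intensity ratio `0.0107 x C`. Noise peaks are drawn uniformly over the
#' window, rejected within 3 ppm of any truth ion mass. Deterministic given
#' `seed`.
#'
#' @param truth A [generate_truth()] truth set.
#' @param noise A [noise_model()].
#' @param n_strains_per_group Named integer vector keyed by the truth groups
#'   (default `c(old = 5, new = 35)` when the groups are old/new, else 10 per
#'   group).
#' @param seed Integer seed.
#' @param fraction,site Sample descriptors stamped on every simulated sample.
#' @return A list with `peaks` (long tibble ready for [align_peaklists()]),
#'   `manifest` (sample descriptors), `reference` (annotation table) and
#'   `truth`.
#' @export
simulate_peaklists <- function(truth, noise = noise_model(),
                               n_strains_per_group = NULL, seed = 1,
                               fraction = "intracellular_SN2", site = "SP") {
  stopifnot(inherits(truth, "truth_set"), inherits(noise, "noise_model"))
  groups <- truth$groups
  if (is.null(n_strains_per_group)) {
    n_strains_per_group <-
      if (setequal(groups, c("old", "new"))) {
        c(old = 5L, new = 35L)[groups]
      } else {
        stats::setNames(rep(10L, length(groups)), groups)
      }
  }
  stopifnot(setequal(names(n_strains_per_group), groups))
  set.seed(seed)
  # total per-feature log-intensity SD: technical + biological between-strain
  sdlog <- sqrt(log(1 + noise$intensity_cv^2) + log(1 + noise$strain_cv^2))
  shift <- truth$config$effect_size * sdlog
  fl <- truth$formulas
  ion_mass <- ionize_mass(fl$neutral_mass)
  window <- truth$config$window

  strain_tbl <- purrr::imap(n_strains_per_group, function(n, g) {
    tibble::tibble(group = g,
                   strain_id = sprintf("%s_%s_%02d", site, g, seq_len(n)))
  }) |> purrr::list_rbind()

  peaks <- purrr::pmap(strain_tbl, function(group, strain_id) {
    present <- rep(TRUE, nrow(fl))
    core <- fl$role == "core"
    present[core] <- stats::runif(sum(core)) >= noise$dropout_prob
    idx <- which(present)
    mu <- fl$base_log[idx] + ifelse(fl$role[idx] == group, shift, 0)
    intensity <- exp(stats::rnorm(length(idx), mu, sdlog))
    mz <- ion_mass[idx] *
      (1 + stats::rnorm(length(idx), 0, noise$mass_noise_ppm * 1e-6))
    out <- tibble::tibble(mz = mz, intensity = intensity,
                          sn = pmax(intensity / 1e4, 1))
    if (noise$isotope_satellites) {
      sat <- tibble::tibble(mz = mz + c13_delta,
                            intensity = intensity * 0.0107 * fl$C[idx],
                            sn = pmax(intensity * 0.0107 * fl$C[idx] / 1e4, 1))
      out <- dplyr::bind_rows(out, sat)
    }
    if (noise$n_noise_peaks > 0) {
      nz <- draw_noise_mz(noise$n_noise_peaks, window, ion_mass)
      out <- dplyr::bind_rows(out, tibble::tibble(
        mz = nz,
        intensity = exp(stats::rnorm(length(nz),
                                     truth$config$base_meanlog - 2, 1)),
        sn = exp(stats::rnorm(length(nz), log(5), 0.5))
      ))
    }
    out <- out[out$mz > window[1] & out$mz < window[2], ]
    out <- out[order(out$mz), ]
    age <- if (group %in% c("old", "new")) group else "new"
    tibble::tibble(sample_id = paste0(strain_id, "_", fraction),
                   strain_id = strain_id, fraction = fraction, site = site,
                   age_class = age, mode = "positive",
                   mz = out$mz, intensity = out$intensity, sn = out$sn)
  }) |> purrr::list_rbind()

  manifest <- peaks |>
    dplyr::distinct(.data$sample_id, .data$strain_id, .data$fraction,
                    .data$site, .data$age_class)
  list(peaks = peaks, manifest = manifest, reference = truth$reference,
       truth = truth)
}

# uniform noise masses rejected within 3 ppm of any truth ion mass
draw_noise_mz <- function(n, window, truth_mz) {
  sorted <- sort(truth_mz)
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::runif(2 * n, window[1], window[2])
    near <- findInterval(cand, sorted)
    lo <- pmax(near, 1L); hi <- pmin(near + 1L, length(sorted))
    d <- pmin(abs(cand - sorted[lo]), abs(cand - sorted[hi]))
    cand <- cand[d / cand * 1e6 > 3]
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

#' Map of planted truth formulas to aligned features
#'
#' Matches each truth formula's ion mass to the nearest consensus feature
#' within `tol_ppm`, giving the planted/recovered correspondence that
#' recovery statistics are computed from.
#'
#' @param truth A truth set.
#' @param fm A feature matrix aligned from peaks simulated off that truth.
#' @param tol_ppm Matching tolerance (default 1).
#' @return A tibble: truth columns plus `feature_mz` (`NA` when unmatched).
#' @export
match_truth_features <- function(truth, fm, tol_ppm = 1) {
  ion <- ionize_mass(truth$formulas$neutral_mass)
  idx <- findInterval(ion, fm$mz)
  lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, nrow(fm))
  pick <- ifelse(abs(ion - fm$mz[lo]) <= abs(ion - fm$mz[hi]), lo, hi)
  err <- abs(ion - fm$mz[pick]) / ion * 1e6
  feature_mz <- ifelse(err <= tol_ppm, fm$mz[pick], NA_real_)
  dplyr::bind_cols(truth$formulas,
                   tibble::tibble(ion_mass = ion, feature_mz = feature_mz))
}
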