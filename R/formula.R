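#' Chemical constraint set for CHNOS formula assignment
#'
#' Bounds and rules applied when enumerating candidate elemental formulas for
#' an exact neutral mass: element-count bounds (C <= 100, 0 <= O <= 80,
#' N <= 5, S <= 1), the nitrogen rule, an oxygen-to-carbon ratio cap, a rings
#' plus double-bond equivalents (RDBE) range, a valence cap on hydrogen
#' (H <= 2C + N + 2), and the assignment tolerance in ppm.
#'
#' @param max_C,max_N,max_S Upper element-count bounds.
#' @param O_range Length-2 integer range for oxygen.
#' @param max_oc_ratio Maximum O/C ratio (default 1, standard CHNOS filtering).
#' @param require_nitrogen_rule Enforce nominal-mass/nitrogen parity.
#' @param rdbe_range Allowed RDBE range (default 0 to 40).
#' @param tol_ppm Assignment tolerance in ppm (default 0.5).
#' @return A list of class `"constraint_set"`.
#' @export
constraint_set <- function(max_C = 100, O_range = c(0, 80), max_N = 5,
                           max_S = 1, max_oc_ratio = 1,
                           require_nitrogen_rule = TRUE,
                           rdbe_range = c(0, 40), tol_ppm = 0.5) {
  stopifnot(max_C >= 0, max_N >= 0, max_S >= 0, length(O_range) == 2,
            all(O_range >= 0), max_oc_ratio >= 0, length(rdbe_range) == 2,
            tol_ppm > 0)
  structure(list(max_C = max_C, O_range = O_range, max_N = max_N,
                 max_S = max_S, max_oc_ratio = max_oc_ratio,
                 require_nitrogen_rule = require_nitrogen_rule,
                 rdbe_range = rdbe_range, tol_ppm = tol_ppm),
            class = "constraint_set")
}

#' Convert an observed ion m/z to a neutral monoisotopic mass
#'
#' Only singly charged protonated/deprotonated species are supported:
#' `[M+H]+` peaks lose one proton mass, `[M-H]-` peaks gain one.
#'
#' @param mz Observed ion mass-to-charge (Da).
#' @param adduct `"protonated"` or `"deprotonated"`.
#' @return Neutral monoisotopic mass (Da).
#' @examples
#' neutralize_mz(175.118952, "protonated") # arginine [M+H]+
#' @export
neutralize_mz <- function(mz, adduct = c("protonated", "deprotonated")) {
  adduct <- match.arg(adduct)
  if (adduct == "protonated") {
    if (any(mz <= proton_mass)) {
      stop("protonated ion mass must exceed the proton mass", call. = FALSE)
    }
    mz - proton_mass
  } else {
    mz + proton_mass
  }
}

# inverse of neutralize_mz, used by the simulator
ionize_mass <- function(neutral, adduct = c("protonated", "deprotonated")) {
  adduct <- match.arg(adduct)
  if (adduct == "protonated") neutral + proton_mass else neutral - proton_mass
}

# Vectorised rule check: returns NA for rows passing all rules, else the name
# of the first violated rule. Checked in a fixed order: element bounds,
# nitrogen rule, O/C, RDBE, hydrogen valence cap.
rule_violations <- function(counts, constraints) {
  counts <- as.data.frame(counts)
  C <- counts$C; H <- counts$H; N <- counts$N; O <- counts$O; S <- counts$S
  out <- rep(NA_character_, nrow(counts))
  bad <- C > constraints$max_C | N > constraints$max_N |
    S > constraints$max_S | O < constraints$O_range[1] |
    O > constraints$O_range[2] | C < 0 | H < 0
  out[is.na(out) & bad] <- "element bound"
  if (constraints$require_nitrogen_rule) {
    # odd N implies odd nominal mass; for CHNOS nominal-mass parity is H parity
    bad <- (H %% 2) != (N %% 2)
    out[is.na(out) & bad] <- "nitrogen rule"
  }
  bad <- C > 0 & (O / C) > constraints$max_oc_ratio + 1e-12
  bad <- bad | (C == 0 & O > 0 & constraints$max_oc_ratio < Inf)
  out[is.na(out) & bad] <- "O/C"
  r <- C - H / 2 + N / 2 + 1
  bad <- r < constraints$rdbe_range[1] | r > constraints$rdbe_range[2]
  out[is.na(out) & bad] <- "RDBE"
  bad <- H > 2 * C + N + 2
  out[is.na(out) & bad] <- "H valence"
  out
}

#' Check a formula candidate against the chemical rules
#'
#' @param candidate Named vector or one-row data frame with counts `C`, `H`,
#'   `N`, `O`, `S`.
#' @param constraints A [constraint_set()].
#' @return A list with elements `pass` (logical) and `reason` (`NA` when
#'   passing, else the name of the first violated rule).
#' @export
check_rules <- function(candidate, constraints = constraint_set()) {
  if (is.numeric(candidate) && !is.null(names(candidate))) {
    candidate <- tibble::as_tibble(as.list(candidate))
  }
  stopifnot(all(c("C", "H", "N", "O", "S") %in% names(candidate)))
  v <- rule_violations(candidate, constraints)[1]
  list(pass = is.na(v), reason = v)
}

#' Enumerate CHNOS formula candidates for a neutral mass
#'
#' Exhaustively enumerates every CHNOS count vector within the constraint
#' bounds whose monoisotopic mass lies within `tol_ppm` of `neutral_mass` and
#' which passes all chemical rules. Hydrogen is solved directly: for each
#' (C, N, O, S) combination the only hydrogen count that can fall inside a
#' sub-ppm window is the nearest integer to the mass residual divided by the
#' hydrogen mass (neighbouring counts differ by ~1.008 Da).
#'
#' @param neutral_mass Neutral monoisotopic mass (Da).
#' @param constraints A [constraint_set()].
#' @return A tibble with columns `C`, `H`, `N`, `O`, `S`, `formula` (Hill
#'   order), `theoretical_mass`, `error_ppm` and `rdbe`, sorted by
#'   `abs(error_ppm)`. Zero rows when no candidate exists.
#' @export
enumerate_formulas <- function(neutral_mass, constraints = constraint_set()) {
  stopifnot(length(neutral_mass) == 1, neutral_mass > 0)
  tol_da <- constraints$tol_ppm * neutral_mass / 1e6
  c_max <- min(constraints$max_C, floor((neutral_mass + tol_da) / element_masses["C"]))
  if (c_max < 1) return(empty_candidates())
  o_max <- min(constraints$O_range[2],
               floor((neutral_mass + tol_da) / element_masses["O"]))
  grid <- expand.grid(C = seq_len(c_max),
                      O = seq.int(constraints$O_range[1], max(o_max, 0)),
                      N = 0:constraints$max_N,
                      S = 0:constraints$max_S)
  grid <- grid[grid$O <= grid$C * constraints$max_oc_ratio + 1e-12, , drop = FALSE]
  base <- grid$C * element_masses["C"] + grid$O * element_masses["O"] +
    grid$N * element_masses["N"] + grid$S * element_masses["S"]
  grid$H <- as.integer(round((neutral_mass - base) / element_masses["H"]))
  grid <- grid[grid$H >= 0, , drop = FALSE]
  if (nrow(grid) == 0) return(empty_candidates())
  theo <- formula_mass(grid[, c("C", "H", "N", "O", "S")])
  err <- (neutral_mass - theo) / theo * 1e6
  keep <- abs(err) <= constraints$tol_ppm
  grid <- grid[keep, , drop = FALSE]
  theo <- theo[keep]; err <- err[keep]
  if (nrow(grid) == 0) return(empty_candidates())
  keep <- is.na(rule_violations(grid, constraints))
  grid <- grid[keep, , drop = FALSE]
  theo <- theo[keep]; err <- err[keep]
  if (nrow(grid) == 0) return(empty_candidates())
  out <- tibble::tibble(
    C = as.integer(grid$C), H = as.integer(grid$H), N = as.integer(grid$N),
    O = as.integer(grid$O), S = as.integer(grid$S),
    formula = formula_string(grid[, c("C", "H", "N", "O", "S")]),
    theoretical_mass = theo, error_ppm = err,
    rdbe = grid$C - grid$H / 2 + grid$N / 2 + 1
  )
  out[order(abs(out$error_ppm)), ]
}

empty_candidates <- function() {
  tibble::tibble(C = integer(), H = integer(), N = integer(), O = integer(),
                 S = integer(), formula = character(),
                 theoretical_mass = double(), error_ppm = double(),
                 rdbe = double())
}

#' Remove carbon-13 isotopologue satellite features
#'
#' A feature is flagged as a 13C satellite and removed when (a) a lighter
#' feature exists at the 13C-12C spacing (1.0033548 Da) within `delta_tol`,
#' (b) the median heavy/light intensity ratio over samples where the light
#' feature is present does not exceed the natural-abundance bound
#' `ratio_factor x C x 0.0107` (C from the light feature's formula assignment
#' when supplied, else the constraint maximum), and (c) when three or more
#' samples carry both features, their intensity patterns correlate positively
#' (Pearson r >= `min_cor`; with fewer shared samples the correlation check is
#' vacuous).
#'
#' @param fm Feature matrix from [align_peaklists()].
#' @param delta 13C-12C mass spacing (Da).
#' @param delta_tol Absolute matching tolerance on the spacing (Da).
#' @param assignments Optional assignment table from [assign_formulas()] used
#'   to look up the carbon count of the light feature.
#' @param max_C Carbon bound used when no assignment is available.
#' @param ratio_factor Safety factor on the natural-abundance ratio
#'   (default 1.2).
#' @param min_cor Minimum Pearson correlation between heavy and light intensity
#'   patterns (default 0.5).
#' @return The filtered feature matrix; removed features are attached as the
#'   `"removed"` attribute (tibble with satellite and parent masses).
#' @export
remove_isotopologues <- function(fm, delta = c13_delta, delta_tol = 0.001,
                                 assignments = NULL, max_C = 100,
                                 ratio_factor = 1.2, min_cor = 0.5) {
  vals <- feature_values(fm)
  mz <- fm$mz
  stopifnot(!is.unsorted(mz))
  n <- length(mz)
  removed <- logical(n)
  parent <- rep(NA_real_, n)
  carbon <- rep(NA_integer_, n)
  if (!is.null(assignments)) {
    idx <- match(round(mz, 6), round(assignments$mz, 6))
    carbon <- assignments$C[idx]
  }
  for (j in seq_len(n)) {
    target <- mz[j] - delta
    cand <- which(abs(mz - target) <= delta_tol)
    cand <- cand[cand < j]
    for (i in cand) {
      cc <- if (!is.na(carbon[i])) carbon[i] else max_C
      max_ratio <- ratio_factor * cc * 0.0107
      light <- vals[i, ]; heavy <- vals[j, ]
      present <- light > 0
      if (!any(present)) next
      med_ratio <- stats::median(heavy[present] / light[present])
      if (med_ratio > max_ratio) next
      both <- light > 0 & heavy > 0
      if (sum(both) >= 3) {
        r <- suppressWarnings(stats::cor(light[both], heavy[both]))
        if (!is.na(r) && r < min_cor) next
      }
      removed[j] <- TRUE
      parent[j] <- mz[i]
      break
    }
  }
  out <- fm[!removed, , drop = FALSE]
  attr(out, "removed") <- tibble::tibble(mz = mz[removed],
                                         parent_mz = parent[removed])
  attr(out, "discards") <- attr(fm, "discards")
  out
}

#' Assign the best elemental formula to every feature
#'
#' Each consensus mass is converted to a neutral mass and enumerated under the
#' constraints; the candidate with the smallest absolute ppm error is kept.
#' Features with two or more candidates inside the tolerance are flagged
#' ambiguous; features with none are reported with `NA` formula.
#'
#' @param fm Feature matrix (isotopologues already removed).
#' @param constraints A [constraint_set()].
#' @param adduct Ion species assumed for all features (`"protonated"` by
#'   default, matching positive-mode acquisition).
#' @return A tibble with one row per feature: `mz`, `neutral_mass`, element
#'   counts, `formula`, `theoretical_mass`, `error_ppm`, `n_candidates`,
#'   `ambiguous`.
#' @export
assign_formulas <- function(fm, constraints = constraint_set(),
                            adduct = "protonated") {
  neutral <- neutralize_mz(fm$mz, adduct)
  rows <- purrr::map(neutral, function(m) {
    cand <- enumerate_formulas(m, constraints)
    if (nrow(cand) == 0) {
      tibble::tibble(C = NA_integer_, H = NA_integer_, N = NA_integer_,
                     O = NA_integer_, S = NA_integer_,
                     formula = NA_character_, theoretical_mass = NA_real_,
                     error_ppm = NA_real_, n_candidates = 0L,
                     ambiguous = FALSE)
    } else {
      best <- cand[1, c("C", "H", "N", "O", "S", "formula",
                        "theoretical_mass", "error_ppm")]
      best$n_candidates <- nrow(cand)
      best$ambiguous <- nrow(cand) > 1
      best
    }
  })
  dplyr::bind_cols(tibble::tibble(mz = fm$mz, neutral_mass = neutral),
                   purrr::list_rbind(rows))
}

#' Write a formula assignment table as CSV
#'
#' @param assignments Tibble from [assign_formulas()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  readr::write_csv(
    assignments[, c("mz", "formula", "theoretical_mass", "error_ppm",
                    "ambiguous")],
    path)
  invisible(path)
}
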