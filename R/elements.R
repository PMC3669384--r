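#' Monoisotopic element masses used throughout the package
#'
#' Exact monoisotopic masses (Da) of the five elements considered for formula
#' assignment (CHNOS), plus the proton mass used to convert between ion and
#' neutral masses and the 13C-12C spacing used for isotopologue detection.
#'
#' @format A named numeric vector with elements `C`, `H`, `N`, `O`, `S`.
#' @export
element_masses <- c(
  C = 12.000000,
  H = 1.00782503,
  N = 14.00307401,
  O = 15.99491462,
  S = 31.97207069
)

#' @rdname element_masses
#' @export
proton_mass <- 1.007276466

#' @rdname element_masses
#' @export
c13_delta <- 1.0033548

# nominal (integer) masses for the nitrogen-rule parity check
element_nominal <- c(C = 12, H = 1, N = 14, O = 16, S = 32)

#' Parse a molecular formula string into CHNOS element counts
#'
#' Accepts formulas written with element symbols followed by optional counts
#' (e.g. `"C6H12O6"`, `"CH4"`, `"C6H14N4O2"`). Only C, H, N, O and S are
#' allowed; any other symbol is an error.
#'
#' @param formula Character vector of formula strings.
#' @return A tibble with one row per input and integer columns `C`, `H`, `N`,
#'   `O`, `S`.
#' @examples
#' parse_formula(c("C6H12O6", "CH4"))
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula))
  out <- matrix(0L, nrow = length(formula), ncol = 5,
                dimnames = list(NULL, names(element_masses)))
  for (i in seq_along(formula)) {
    f <- formula[[i]]
    if (is.na(f) || !nzchar(f)) {
      stop("empty formula string at position ", i, call. = FALSE)
    }
    tokens <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]
    if (!nzchar(f) || paste(tokens, collapse = "") != f) {
      stop("cannot parse formula string: '", f, "'", call. = FALSE)
    }
    for (tok in tokens) {
      sym <- sub("[0-9]*$", "", tok)
      if (!sym %in% names(element_masses)) {
        stop("non-CHNOS element '", sym, "' in formula '", f, "'",
             call. = FALSE)
      }
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      out[i, sym] <- out[i, sym] + n
    }
  }
  tibble::as_tibble(out)
}

#' Write CHNOS counts as a formula string in Hill order
#'
#' Hill order for carbon-containing compounds is C, H, then remaining elements
#' alphabetically; a count of 1 is implicit and zero counts are omitted.
#'
#' @param counts A data frame with columns `C`, `H`, `N`, `O`, `S`.
#' @return Character vector of formula strings.
#' @export
formula_string <- function(counts) {
  counts <- as.data.frame(counts)[, c("C", "H", "N", "O", "S")]
  rownames(counts) <- NULL
  unname(apply(counts, 1, function(x) {
    parts <- vapply(c("C", "H", "N", "O", "S"), function(el) {
      n <- x[[el]]
      if (n == 0) "" else if (n == 1) el else paste0(el, n)
    }, character(1))
    paste(parts, collapse = "")
  }))
}

#' Monoisotopic neutral mass of CHNOS element counts
#'
#' @param counts Data frame with columns `C`, `H`, `N`, `O`, `S` (one row per
#'   formula), or a named vector.
#' @return Numeric vector of monoisotopic masses (Da).
#' @examples
#' formula_mass(parse_formula("C6H14N4O2"))
#' @export
formula_mass <- function(counts) {
  if (is.numeric(counts) && !is.null(names(counts))) {
    counts <- tibble::as_tibble(as.list(counts))
  }
  counts <- as.data.frame(counts)
  as.numeric(as.matrix(counts[, names(element_masses)]) %*% element_masses)
}

# nominal mass used by the nitrogen rule
formula_nominal_mass <- function(counts) {
  counts <- as.data.frame(counts)
  as.integer(as.matrix(counts[, names(element_nominal)]) %*% element_nominal)
}

#' Rings plus double-bond equivalents of a CHNOS formula
#'
#' RDBE = C - H/2 + N/2 + 1. A chemically valid neutral molecule has a
#' non-negative integer RDBE (sulfur and oxygen are divalent and do not enter).
#'
#' @inheritParams formula_mass
#' @return Numeric vector of RDBE values (may be half-integral for formulas
#'   violating the nitrogen rule).
#' @export
rdbe <- function(counts) {
  if (is.numeric(counts) && !is.null(names(counts))) {
    counts <- tibble::as_tibble(as.list(counts))
  }
  counts <- as.data.frame(counts)
  counts$C - counts$H / 2 + counts$N / 2 + 1
}
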