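#' @importFrom rlang .data
NULL

# controlled vocabularies for sample descriptors
fraction_levels <- c("extracellular_SN1", "intracellular_SN2", "pellet")
site_levels <- c("SP", "RM", "reference")
age_levels <- c("old", "new")
mode_levels <- c("positive", "negative")

default_window <- c(150, 2000)

check_enum <- function(x, levels, what) {
  bad <- setdiff(unique(as.character(x)), levels)
  if (length(bad) > 0) {
    stop("invalid ", what, " value(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(levels, collapse = ", "), ")", call. = FALSE)
  }
  invisible(x)
}

#' Read a single-sample peak list
#'
#' Reads a tab-separated peak list with columns `mz`, `intensity` and
#' (optionally) `sn`, applies the signal-to-noise threshold and the
#' acquisition-window filter, and attaches the sample descriptors as columns so
#' that peak lists from many samples can be row-bound directly.
#'
#' Peaks with `sn < min_sn` or `mz` outside `window` are dropped. When the file
#' has no `sn` column the list is assumed to be thresholded upstream and `sn`
#' is recorded as `Inf`. The result is sorted by ascending `mz`.
#'
#' @param path Path to a TSV file with a header row.
#' @param metadata Named list (or one-row data frame) of sample descriptors:
#'   `sample_id`, `strain_id`, `fraction` (one of `r paste(fraction_levels,
#'   collapse = ", ")`), `site` (`SP`, `RM`, `reference`), `age_class`
#'   (`old`, `new`) and optionally `mode` (default `"positive"`).
#' @param min_sn Minimum signal-to-noise ratio retained (default 1, the export
#'   threshold used for broadband ICR-FT/MS peak lists).
#' @param window Acquisition window as `c(low, high)` m/z; default
#'   `c(150, 2000)`.
#' @return A tibble with columns `sample_id`, `strain_id`, `fraction`, `site`,
#'   `age_class`, `mode`, `mz`, `intensity`, `sn`, sorted by `mz`.
#' @export
read_peaklist <- function(path, metadata, min_sn = 1,
                          window = default_window) {
  stopifnot(file.exists(path), length(window) == 2, window[1] < window[2])
  metadata <- as.list(metadata)
  needed <- c("sample_id", "strain_id", "fraction", "site", "age_class")
  missing <- setdiff(needed, names(metadata))
  if (length(missing) > 0) {
    stop("metadata missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(metadata$mode)) metadata$mode <- "positive"
  check_enum(metadata$fraction, fraction_levels, "fraction")
  check_enum(metadata$site, site_levels, "site")
  check_enum(metadata$age_class, age_levels, "age_class")
  check_enum(metadata$mode, mode_levels, "mode")

  raw <- suppressWarnings(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_double()),
                    progress = FALSE))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop("malformed peak list '", path, "': parse failure at line ",
         probs$row[1], " (expected ", probs$expected[1], ")", call. = FALSE)
  }
  if (!all(c("mz", "intensity") %in% names(raw))) {
    stop("peak list '", path, "' must have columns mz and intensity",
         call. = FALSE)
  }
  if (!"sn" %in% names(raw)) raw$sn <- Inf
  peaks <- raw |>
    dplyr::filter(.data$sn >= min_sn,
                  .data$mz >= window[1], .data$mz <= window[2]) |>
    dplyr::arrange(.data$mz)
  if (any(peaks$mz <= 0) || any(peaks$intensity < 0)) {
    stop("peak list '", path, "' contains non-positive mz or negative intensity",
         call. = FALSE)
  }
  if (nrow(peaks) == 0) {
    warning("peak list '", path, "' is empty after filtering", call. = FALSE)
  }
  tibble::tibble(
    sample_id = metadata$sample_id,
    strain_id = metadata$strain_id,
    fraction = metadata$fraction,
    site = metadata$site,
    age_class = metadata$age_class,
    mode = metadata$mode,
    mz = peaks$mz,
    intensity = peaks$intensity,
    sn = peaks$sn
  )
}

#' Write a peak list as TSV
#'
#' Writes only the `mz`, `intensity` and `sn` columns; doubles are written with
#' enough digits to round-trip exactly.
#'
#' @param peaklist A tibble as returned by [read_peaklist()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaklist, path) {
  readr::write_tsv(peaklist[, c("mz", "intensity", "sn")], path)
  invisible(path)
}

#' Read a sample manifest
#'
#' The manifest is a CSV with columns `sample_id`, `strain_id`, `fraction`,
#' `site`, `age_class` and `path` (the peak-list file for that sample).
#' Enumerated descriptors are validated, `(strain_id, fraction)` pairs must be
#' unique, and every row must carry a non-empty path.
#'
#' @param path Path to the manifest CSV.
#' @return A tibble of sample descriptors, one row per sample.
#' @export
read_manifest <- function(path) {
  stopifnot(file.exists(path))
  man <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("sample_id", "strain_id", "fraction", "site", "age_class", "path")
  missing <- setdiff(needed, names(man))
  if (length(missing) > 0) {
    stop("manifest missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  check_enum(man$fraction, fraction_levels, "fraction")
  check_enum(man$site, site_levels, "site")
  check_enum(man$age_class, age_levels, "age_class")
  dup <- man |>
    dplyr::count(.data$strain_id, .data$fraction) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate (strain_id, fraction) pair(s) in manifest: ",
         paste(paste(dup$strain_id, dup$fraction, sep = "/"), collapse = ", "),
         call. = FALSE)
  }
  no_path <- is.na(man$path) | !nzchar(man$path)
  if (any(no_path)) {
    stop("missing peak-list path for sample(s): ",
         paste(man$sample_id[no_path], collapse = ", "), call. = FALSE)
  }
  man
}

#' Read all peak lists named by a manifest
#'
#' @param manifest A tibble from [read_manifest()].
#' @param dir Directory that relative paths in the manifest are resolved
#'   against (default: current directory).
#' @inheritParams read_peaklist
#' @return A single tibble of peaks from all samples (row-bound peak lists).
#' @export
read_peaklists <- function(manifest, dir = ".", min_sn = 1,
                           window = default_window) {
  purrr::pmap(manifest, function(sample_id, strain_id, fraction, site,
                                 age_class, path, ...) {
    p <- if (file.exists(path)) path else file.path(dir, path)
    read_peaklist(p, metadata = list(sample_id = sample_id,
                                     strain_id = strain_id,
                                     fraction = fraction, site = site,
                                     age_class = age_class),
                  min_sn = min_sn, window = window)
  }) |>
    purrr::list_rbind()
}

#' Read a formula-to-metabolite reference table
#'
#' A local stand-in for web-service annotation: a CSV with columns `formula`,
#' `metabolite`, `pathway`, `class`. Formula strings are parsed to CHNOS
#' element counts (columns `C`, `H`, `N`, `O`, `S` in the result), and
#' `(formula, metabolite)` pairs must be unique.
#'
#' @param path Path to the reference CSV.
#' @return A tibble with the four input columns plus element-count columns.
#' @export
read_reference_table <- function(path) {
  stopifnot(file.exists(path))
  ref <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("formula", "metabolite", "pathway", "class")
  missing <- setdiff(needed, names(ref))
  if (length(missing) > 0) {
    stop("reference table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dup <- ref |>
    dplyr::count(.data$formula, .data$metabolite) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate (formula, metabolite) pair(s) in reference table: ",
         paste(paste(dup$formula, dup$metabolite, sep = "/"), collapse = ", "),
         call. = FALSE)
  }
  counts <- parse_formula(ref$formula)
  dplyr::bind_cols(ref, counts)
}
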