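#' Align peak lists into a feature matrix
#'
#' Pools the peaks of all samples, sorts them by mass, and cuts the sorted
#' sequence wherever the gap between consecutive masses exceeds
#' `tol_ppm x mean(mz)/1e6` (single-linkage binning). Each resulting bin is one
#' feature; its consensus m/z is the intensity-weighted mean of the member
#' masses. When one sample contributes two peaks to the same feature, the more
#' intense peak is kept (ties broken towards the lower mass) and the discard is
#' recorded.
#'
#' @param peaks A tibble of peaks from one or more samples, with at least
#'   `sample_id`, `mz`, `intensity` (as returned by [read_peaklists()] or
#'   [simulate_peaklists()]). All samples must share one ionization mode.
#' @param tol_ppm Alignment tolerance in parts per million (default 1).
#' @return A feature matrix: a tibble whose first column `mz` holds the
#'   consensus masses (strictly ascending) and whose remaining columns, one per
#'   sample, hold intensities (0 = absent). Discarded intra-sample duplicates
#'   are attached as the `"discards"` attribute.
#' @export
align_peaklists <- function(peaks, tol_ppm = 1) {
  if (is.null(peaks) || nrow(peaks) == 0) {
    stop("no peaks to align", call. = FALSE)
  }
  stopifnot(tol_ppm >= 0)
  if ("mode" %in% names(peaks) && length(unique(peaks$mode)) > 1) {
    stop("all peak lists must share one ionization mode", call. = FALSE)
  }
  pooled <- peaks |>
    dplyr::select(dplyr::any_of(c("sample_id", "mz", "intensity"))) |>
    dplyr::arrange(.data$mz)
  d <- diff(pooled$mz)
  thr <- tol_ppm * (pooled$mz[-1] + pooled$mz[-nrow(pooled)]) / 2 / 1e6
  pooled$feature <- cumsum(c(0L, as.integer(d > thr))) + 1L

  # intra-sample duplicates: keep highest intensity, tie -> lower mz
  resolved <- pooled |>
    dplyr::arrange(.data$feature, .data$sample_id,
                   dplyr::desc(.data$intensity), .data$mz) |>
    dplyr::group_by(.data$feature, .data$sample_id) |>
    dplyr::mutate(.keep_rank = dplyr::row_number()) |>
    dplyr::ungroup()
  discards <- resolved |>
    dplyr::filter(.keep_rank > 1) |>
    dplyr::select("sample_id", "mz", "intensity", "feature")
  kept <- resolved |>
    dplyr::filter(.keep_rank == 1) |>
    dplyr::select(-".keep_rank")

  consensus <- kept |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(mz = if (sum(.data$intensity) > 0) {
      stats::weighted.mean(.data$mz, .data$intensity)
    } else {
      mean(.data$mz)
    }, .groups = "drop")

  wide <- kept |>
    dplyr::select("feature", "sample_id", "intensity") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "intensity",
                       values_fill = 0) |>
    dplyr::left_join(consensus, by = "feature") |>
    dplyr::arrange(.data$mz) |>
    dplyr::select("mz", dplyr::everything(), -"feature")
  # keep sample columns in first-appearance order
  samp <- unique(peaks$sample_id)
  wide <- wide[, c("mz", intersect(samp, names(wide)))]
  attr(wide, "discards") <- discards
  attr(wide, "tol_ppm") <- tol_ppm
  wide
}

#' Extract the numeric intensity matrix from a feature matrix tibble
#'
#' @param fm A feature matrix as returned by [align_peaklists()].
#' @return A numeric matrix (features x samples) with consensus masses as row
#'   names.
#' @export
feature_values <- function(fm) {
  m <- as.matrix(fm[, setdiff(names(fm), "mz"), drop = FALSE])
  rownames(m) <- format(fm$mz, trim = TRUE)
  storage.mode(m) <- "double"
  m
}

#' Summary statistics of a feature matrix
#'
#' @param fm A feature matrix as returned by [align_peaklists()].
#' @return A tibble with one row per sample (`sample_id`, `n_present` = number
#'   of features with non-zero intensity). The total feature and sample counts
#'   are attached as attributes `n_features` and `n_samples`.
#' @export
matrix_stats <- function(fm) {
  vals <- feature_values(fm)
  out <- tibble::tibble(
    sample_id = colnames(vals),
    n_present = unname(colSums(vals > 0))
  )
  attr(out, "n_features") <- nrow(vals)
  attr(out, "n_samples") <- ncol(vals)
  out
}

#' Write a feature matrix as CSV
#'
#' First column is the consensus m/z, followed by one intensity column per
#' sample.
#'
#' @inheritParams feature_values
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  readr::write_csv(tibble::as_tibble(fm), path)
  invisible(path)
}
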