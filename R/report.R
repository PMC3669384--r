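# ---- annotation against the local reference table ----------------------

#' Annotate assigned features against a reference table
#'
#' Matches on exact CHNOS element counts. A formula matching several isomers
#' in the table yields one row per isomer, flagged via `n_isomers`. Features
#' whose formula is absent from the table are kept with `NA` annotation
#' columns.
#'
#' @param assignments Assignment table from [assign_formulas()].
#' @param reference Reference table from [read_reference_table()] (or a tibble
#'   with columns `metabolite`, `pathway`, `class` and element counts).
#' @return A tibble: one row per (feature, matching metabolite), with
#'   `n_isomers` per feature (0 when unannotated).
#' @export
annotate_features <- function(assignments, reference) {
  assigned <- assignments |>
    dplyr::filter(!is.na(.data$formula))
  ref <- reference |>
    dplyr::select("metabolite", "pathway", "class", "C", "H", "N", "O", "S")
  out <- assigned |>
    dplyr::left_join(ref, by = c("C", "H", "N", "O", "S")) |>
    dplyr::group_by(.data$mz) |>
    dplyr::mutate(n_isomers = sum(!is.na(.data$metabolite))) |>
    dplyr::ungroup()
  out
}

#' Class and pathway membership counts of selected features
#'
#' Counts annotated features per metabolic class and per pathway. A feature
#' annotated to k pathways contributes to each of the k tallies
#' (multi-counting, stated explicitly so the tallies are interpretable).
#'
#' @param annotations Tibble from [annotate_features()].
#' @param selected Optional vector of feature masses restricting the tally
#'   (e.g. the discriminative set); default all annotated features.
#' @return A tibble `level` (`"class"` or `"pathway"`), `value`, `n`, sorted
#'   by decreasing count within level.
#' @export
class_distribution <- function(annotations, selected = NULL) {
  ann <- annotations |>
    dplyr::filter(!is.na(.data$metabolite))
  if (!is.null(selected)) {
    ann <- ann |> dplyr::filter(.data$mz %in% selected)
  }
  by_class <- ann |>
    dplyr::distinct(.data$mz, .data$class) |>
    dplyr::count(.data$class, name = "n") |>
    dplyr::transmute(level = "class", value = .data$class, n = .data$n)
  by_pathway <- ann |>
    dplyr::distinct(.data$mz, .data$pathway) |>
    dplyr::count(.data$pathway, name = "n") |>
    dplyr::transmute(level = "pathway", value = .data$pathway, n = .data$n)
  dplyr::bind_rows(by_class, by_pathway) |>
    dplyr::arrange(.data$level, dplyr::desc(.data$n))
}

# ---- printed-style percentage arithmetic --------------------------------

round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a count as a printed-style percentage
#'
#' `integer_pct` rounds half away from zero to a whole percent (`"7%"`);
#' `one_decimal_pct` rounds to one decimal (`"34.7%"`).
#'
#' @param num,den Numerator and denominator counts.
#' @param style `"integer_pct"` or `"one_decimal_pct"`.
#' @return Character vector of formatted percentages.
#' @export
pct_format <- function(num, den, style = c("integer_pct", "one_decimal_pct")) {
  style <- match.arg(style)
  pct <- ifelse(den > 0, num / den * 100, 0)
  if (style == "integer_pct") {
    paste0(round_half_away(pct, 0), "%")
  } else {
    paste0(formatC(round_half_away(pct, 1), format = "f", digits = 1), "%")
  }
}

#' Build a discrimination report row
#'
#' Summarises a discriminative-metabolite analysis for one cellular fraction
#' in the layout of the headline summary tables: total metabolome size,
#' per-strain feature range, discriminative count with its percentage of the
#' total, annotable count with its percentage of the discriminative set, and
#' pathway-assigned count. Percentages are recomputed from the counts at
#' print style `style`, never stored independently.
#'
#' @param counts Named list or one-row data frame with fields `fraction`,
#'   `design`, `total`, `discriminative`, `annotable`, `with_pathway`, and
#'   optionally `range_min`, `range_max`, `discriminative_old`,
#'   `discriminative_new`, `annotable_old`, `annotable_new`.
#' @param style Percentage style: `"integer_pct"` (whole percent) or
#'   `"one_decimal_pct"`.
#' @return A one-row tibble with the counts and formatted percentage strings
#'   (`discriminative_pct`, `annotable_pct`, `with_pathway_pct`).
#' @export
build_report <- function(counts, style = c("integer_pct", "one_decimal_pct")) {
  style <- match.arg(style)
  counts <- as.list(counts)
  needed <- c("total", "discriminative", "annotable", "with_pathway")
  missing <- setdiff(needed, names(counts))
  if (length(missing) > 0) {
    stop("counts missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (counts$discriminative > counts$total) {
    stop("discriminative count exceeds total metabolome", call. = FALSE)
  }
  if (counts$annotable > counts$discriminative) {
    stop("annotable count exceeds discriminative count", call. = FALSE)
  }
  tibble::tibble(
    fraction = counts$fraction %||% NA_character_,
    design = counts$design %||% NA_character_,
    total = counts$total,
    range_min = counts$range_min %||% NA_integer_,
    range_max = counts$range_max %||% NA_integer_,
    discriminative = counts$discriminative,
    discriminative_pct = pct_format(counts$discriminative, counts$total, style),
    discriminative_old = counts$discriminative_old %||% NA_integer_,
    discriminative_new = counts$discriminative_new %||% NA_integer_,
    annotable = counts$annotable,
    annotable_pct = pct_format(counts$annotable, counts$discriminative, style),
    with_pathway = counts$with_pathway,
    with_pathway_pct = pct_format(counts$with_pathway, counts$discriminative,
                                  style)
  )
}
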