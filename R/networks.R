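#' Built-in list of biochemical mass differences
#'
#' Common biochemical transformations (hydrogenation, (de)methylation,
#' oxidation, condensation losses, amino-acid and sugar residues, sulfur
#' chemistry, ...) expressed as CHNOS compositions; the exact mass deltas are
#' computed from the monoisotopic element masses, never typed in by hand.
#'
#' @return A tibble with columns `name`, `composition` and `delta` (Da).
#' @export
mass_diff_list <- function() {
  defs <- c(
    "hydrogenation" = "H2",
    "oxidation" = "O",
    "condensation (water)" = "H2O",
    "methylenation" = "CH2",
    "formaldehyde addition" = "CH2O",
    "formic acid" = "CH2O2",
    "carbonylation" = "CO",
    "carboxylation" = "CO2",
    "amination" = "NH3",
    "imine" = "NH",
    "cyanide" = "CHN",
    "acetylene" = "C2H2",
    "ethylation" = "C2H4",
    "acetylation (ketene)" = "C2H2O",
    "acetaldehyde" = "C2H4O",
    "glycolic unit" = "C2H2O2",
    "ethanolamine" = "C2H5N",
    "propylation" = "C3H6",
    "acetone" = "C3H6O",
    "malonylation" = "C3H2O3",
    "glycerol unit" = "C3H6O2",
    "pyruvate unit" = "C3H2O2",
    "butylation" = "C4H8",
    "isoprene unit" = "C5H8",
    "benzene unit" = "C6H4",
    "sulfur" = "S",
    "hydrogen sulfide" = "H2S",
    "thiol to sulfonate" = "O3S",
    "sulfonation" = "SO3",
    "urea unit" = "CH2N2O",
    "glycine residue" = "C2H3NO",
    "alanine residue" = "C3H5NO",
    "serine residue" = "C3H5NO2",
    "proline residue" = "C5H7NO",
    "valine residue" = "C5H9NO",
    "threonine residue" = "C4H7NO2",
    "cysteine residue" = "C3H5NOS",
    "leucine residue" = "C6H11NO",
    "asparagine residue" = "C4H6N2O2",
    "aspartate residue" = "C4H5NO3",
    "glutamine residue" = "C5H8N2O2",
    "lysine residue" = "C6H12N2O",
    "glutamate residue" = "C5H7NO3",
    "methionine residue" = "C5H9NOS",
    "histidine residue" = "C6H7N3O",
    "phenylalanine residue" = "C9H9NO",
    "arginine residue" = "C6H12N4O",
    "tyrosine residue" = "C9H9NO2",
    "tryptophan residue" = "C11H10N2O",
    "pentose unit" = "C5H8O4",
    "deoxyhexose unit" = "C6H10O4",
    "hexose unit" = "C6H10O5",
    "glucuronic unit" = "C6H8O6",
    "N-acetylhexosamine unit" = "C8H13NO5"
  )
  # sulfonation and thiol-to-sulfonate share a composition; keep one
  defs <- defs[!duplicated(defs)]
  tibble::tibble(
    name = names(defs),
    composition = unname(defs),
    delta = formula_mass(parse_formula(unname(defs)))
  )
}

#' Build a mass-difference network over formula-assigned features
#'
#' Nodes are features carrying an accepted elemental formula (absolute
#' assignment error below `node_tol_ppm`); an edge labelled with a
#' transformation connects two nodes when the absolute difference of their
#' masses matches that transformation's exact delta within `edge_ppm`
#' (relative to the larger of the two masses). A pair matching several deltas
#' carries all labels, joined with `";"`.
#'
#' @param assignments Assignment table from [assign_formulas()].
#' @param mdiffs Mass-difference list, as from [mass_diff_list()].
#' @param edge_ppm Edge-formation tolerance in ppm (default 0.1).
#' @param node_tol_ppm Maximum absolute assignment error for a feature to
#'   become a node (default 0.5 ppm).
#' @param use_theoretical Use theoretical formula masses instead of measured
#'   neutral masses (useful for noise-free checks).
#' @return An undirected `igraph` graph. Node attributes: `name` (formula for
#'   readability is stored separately as `formula`), `mass`. Edge attributes:
#'   `label`, `weight` (= number of matching deltas).
#' @export
build_mass_difference_network <- function(assignments,
                                          mdiffs = mass_diff_list(),
                                          edge_ppm = 0.1,
                                          node_tol_ppm = 0.5,
                                          use_theoretical = FALSE) {
  if (is.null(mdiffs) || nrow(mdiffs) == 0) {
    stop("empty mass-difference list", call. = FALSE)
  }
  stopifnot(edge_ppm > 0)
  nodes <- assignments |>
    dplyr::filter(!is.na(.data$formula),
                  abs(.data$error_ppm) < node_tol_ppm) |>
    dplyr::arrange(.data$mz)
  mass <- if (use_theoretical) nodes$theoretical_mass else nodes$neutral_mass
  ord <- order(mass)
  nodes <- nodes[ord, ]
  mass <- mass[ord]
  ids <- format(nodes$mz, trim = TRUE, nsmall = 6)
  if (nrow(nodes) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }

  edge_rows <- purrr::pmap(mdiffs, function(name, composition, delta) {
    # generous candidate window; the exact ppm rule is applied below
    eps <- 2 * edge_ppm * max(mass) / 1e6 + 1e-6
    lo <- findInterval(mass + delta - eps, mass)
    hi <- findInterval(mass + delta + eps, mass)
    i <- rep.int(seq_along(mass), pmax(hi - lo, 0L))
    if (length(i) == 0) return(NULL)
    j <- unlist(lapply(seq_along(mass), function(k) {
      if (hi[k] > lo[k]) seq.int(lo[k] + 1L, hi[k]) else integer(0)
    }))
    err <- abs(abs(mass[j] - mass[i]) - delta) /
      pmax(mass[i], mass[j]) * 1e6
    keep <- err <= edge_ppm & i != j
    if (!any(keep)) return(NULL)
    tibble::tibble(from = i[keep], to = j[keep], label = name)
  }) |>
    purrr::compact() |>
    purrr::list_rbind()

  if (is.null(edge_rows) || nrow(edge_rows) == 0) {
    edges <- tibble::tibble(from = character(), to = character(),
                            label = character(), weight = integer())
  } else {
    edges <- edge_rows |>
      dplyr::mutate(a = pmin(.data$from, .data$to),
                    b = pmax(.data$from, .data$to)) |>
      dplyr::distinct(.data$a, .data$b, .data$label) |>
      dplyr::group_by(.data$a, .data$b) |>
      dplyr::summarise(label = paste(sort(.data$label), collapse = ";"),
                       weight = dplyr::n(), .groups = "drop") |>
      dplyr::transmute(from = ids[.data$a], to = ids[.data$b],
                       label = .data$label, weight = .data$weight)
  }
  g <- igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = data.frame(name = ids, formula = nodes$formula, mass = mass,
                          stringsAsFactors = FALSE)
  )
  g
}

#' Build a sample-correlation network
#'
#' Samples are nodes; two samples are connected when the Pearson correlation
#' between their feature-intensity vectors exceeds `r_threshold` (positive
#' correlations only). Zero-variance profiles are left isolated with a
#' warning.
#'
#' @param fm Feature matrix from [align_peaklists()] (>= 3 features).
#' @param r_threshold Correlation threshold (default 0.90, strict `>`).
#' @param sample_info Optional tibble with `sample_id` plus attribute columns
#'   (`fraction`, `site`, `age_class`, ...) copied onto the nodes.
#' @return An undirected `igraph` graph with edge attribute `weight` = r.
#' @export
build_correlation_network <- function(fm, r_threshold = 0.90,
                                      sample_info = NULL) {
  vals <- feature_values(fm)
  if (nrow(vals) < 3) stop("need at least 3 features per profile", call. = FALSE)
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance profile(s): ",
            paste(colnames(vals)[sds == 0], collapse = ", "),
            " left isolated", call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(vals))
  r[is.na(r)] <- 0
  r[lower.tri(r, diag = TRUE)] <- NA
  idx <- which(r > r_threshold & r > 0, arr.ind = TRUE)
  edges <- tibble::tibble(from = colnames(vals)[idx[, 1]],
                          to = colnames(vals)[idx[, 2]],
                          weight = r[idx])
  verts <- data.frame(name = colnames(vals), stringsAsFactors = FALSE)
  if (!is.null(sample_info)) {
    extra <- sample_info[match(verts$name, sample_info$sample_id), , drop = FALSE]
    extra$sample_id <- NULL
    verts <- cbind(verts, as.data.frame(extra))
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Per-component composition of a node attribute
#'
#' @param network An `igraph` graph.
#' @param attribute Name of a node attribute.
#' @return A tibble with columns `component`, `value`, `n`: for each connected
#'   component, the count of nodes carrying each attribute value.
#' @export
module_composition <- function(network, attribute) {
  if (!attribute %in% igraph::vertex_attr_names(network)) {
    stop("node attribute '", attribute, "' not present", call. = FALSE)
  }
  comp <- igraph::components(network)
  tibble::tibble(
    component = comp$membership,
    value = igraph::vertex_attr(network, attribute)
  ) |>
    dplyr::count(.data$component, .data$value, name = "n") |>
    dplyr::arrange(.data$component, dplyr::desc(.data$n))
}

#' Flag class-specific features by presence frequency
#'
#' A feature is specific to a class when its presence frequency (fraction of
#' samples in which it is detected) in that class is at least `factor` times
#' its mean presence frequency across the other classes. Features present in
#' one class and entirely absent elsewhere are specific to that class.
#'
#' @param fm Feature matrix.
#' @param classes Named character vector mapping sample id to class.
#' @param factor Fold-change threshold (default 10).
#' @return A tibble `mz`, `specific_to` (`NA` when not specific to any class).
#' @export
class_specificity <- function(fm, classes, factor = 10) {
  vals <- feature_values(fm) > 0
  cls <- classes[colnames(vals)]
  stopifnot(!any(is.na(cls)))
  freq <- sapply(unique(cls), function(cl) {
    rowMeans(vals[, cls == cl, drop = FALSE])
  })
  specific <- apply(freq, 1, function(f) {
    hits <- vapply(seq_along(f), function(k) {
      others <- mean(f[-k])
      f[k] > 0 && (others == 0 || f[k] >= factor * others)
    }, logical(1))
    if (sum(hits) == 1) colnames(freq)[hits] else NA_character_
  })
  tibble::tibble(mz = fm$mz, specific_to = unname(specific))
}

#' Export a network
#'
#' `write_network_graphml()` writes GraphML; `write_network_edgelist()` writes
#' a TSV of `source`, `target`, `label`, `weight`.
#'
#' @param network An `igraph` graph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_edgelist <- function(network, path) {
  el <- igraph::as_data_frame(network, what = "edges")
  if (!"label" %in% names(el)) el$label <- NA_character_
  if (!"weight" %in% names(el)) el$weight <- NA_real_
  readr::write_tsv(
    tibble::tibble(source = el$from, target = el$to, label = el$label,
                   weight = el$weight),
    path)
  invisible(path)
}
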