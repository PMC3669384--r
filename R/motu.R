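# ---- Ward dendrogram and percent-threshold m-OTU partitions ------------

#' Ward dendrogram of strain metabolite profiles
#'
#' Agglomerative clustering in which each merge minimises the increase in the
#' within-cluster error sum of squares (ESS). Merge heights equal the ESS
#' increase itself (so two singleton points at Euclidean distance d merge at
#' d^2/2), obtained by running the Ward update on squared Euclidean distances
#' halved. The maximal merge distance of the dataset is stored and defines
#' the 100% level for percent-threshold cuts.
#'
#' @param fm Feature matrix of one cellular fraction (samples = strains).
#' @param center,scale Preprocessing applied before the Euclidean distance
#'   (default mean centring + Pareto scaling, as for the latent-variable
#'   models).
#' @return An `hclust` object with an extra attribute `ward_max` (the last
#'   merge height).
#' @export
ward_dendrogram <- function(fm, center = TRUE,
                            scale = c("pareto", "uv", "none")) {
  scale <- match.arg(scale)
  x <- fm_samples_matrix(fm)
  if (nrow(x) < 2) stop("need at least 2 strains", call. = FALSE)
  x <- preprocess_matrix(x, center = center, scale = scale)
  d <- stats::dist(x)
  hc <- stats::hclust(d^2 / 2, method = "ward.D")
  attr(hc, "ward_max") <- max(hc$height)
  hc
}

#' Cut a Ward dendrogram at a percentage of its maximal distance
#'
#' The cut height is `pct/100 x ward_max`; clusters are the connected
#' subtrees below the cut. Strains merged at exactly the cut height belong to
#' the same cluster. The resulting partitions are nested: every cluster at a
#' lower percentage is contained in a cluster at any higher percentage.
#'
#' @param dendrogram An `hclust` from [ward_dendrogram()] (or any `hclust`;
#'   `ward_max` defaults to its maximal height).
#' @param pct Percentage threshold in (0, 100].
#' @return An object of class `"motu_partition"`: a tibble with columns
#'   `strain_id` and `cluster`, with attributes `threshold_pct` and
#'   `ward_max`.
#' @export
cut_percent <- function(dendrogram, pct) {
  if (length(pct) != 1 || is.na(pct) || pct <= 0 || pct > 100) {
    stop("pct must be a single value in (0, 100]", call. = FALSE)
  }
  ward_max <- attr(dendrogram, "ward_max")
  if (is.null(ward_max)) ward_max <- max(dendrogram$height)
  h <- pct / 100 * ward_max
  cl <- stats::cutree(dendrogram, h = h)
  out <- tibble::tibble(strain_id = names(cl) %||% as.character(seq_along(cl)),
                        cluster = unname(cl))
  attr(out, "threshold_pct") <- pct
  attr(out, "ward_max") <- ward_max
  class(out) <- c("motu_partition", class(out))
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

motu_sizes <- function(partition) {
  if (inherits(partition, "motu_partition") || is.data.frame(partition)) {
    as.integer(table(partition$cluster))
  } else {
    as.integer(partition)
  }
}

# ---- diversity statistics ----------------------------------------------

#' Shannon diversity of an m-OTU partition
#'
#' `H = -sum(p_i log p_i)` in natural log units, over cluster relative
#' abundances.
#'
#' @param partition A [cut_percent()] partition, or a vector of cluster sizes.
#' @return Shannon index (nats).
#' @export
shannon_index <- function(partition) {
  n <- motu_sizes(partition)
  n <- n[n > 0]
  p <- n / sum(n)
  -sum(p * log(p))
}

#' Good's coverage of an m-OTU partition
#'
#' `C = 1 - n1/nt`, where `n1` is the number of clusters observed exactly once
#' (singletons) and `nt` the total number of individuals.
#'
#' @inheritParams shannon_index
#' @return Coverage in \[0, 1\].
#' @export
goods_coverage <- function(partition) {
  n <- motu_sizes(partition)
  stopifnot(sum(n) >= 1)
  1 - sum(n == 1) / sum(n)
}

#' Analytical (hypergeometric) rarefaction
#'
#' Expected cluster richness in a random subsample of `n` individuals drawn
#' without replacement: `E[S_n] = sum_i (1 - choose(N - N_i, n)/choose(N, n))`.
#'
#' @inheritParams shannon_index
#' @param sizes Subsample sizes (each between 1 and the total count).
#' @return A tibble with columns `n` and `richness`.
#' @export
rarefaction_curve <- function(partition, sizes = NULL) {
  counts <- motu_sizes(partition)
  N <- sum(counts)
  if (is.null(sizes)) sizes <- seq_len(N)
  if (any(sizes > N) || any(sizes < 1)) {
    stop("subsample sizes must lie in [1, ", N, "]", call. = FALSE)
  }
  richness <- vapply(sizes, function(n) {
    # lchoose-based for numerical stability at large N
    sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
  }, numeric(1))
  tibble::tibble(n = sizes, richness = richness)
}

#' Diversity profile across a grid of clustering thresholds
#'
#' Cuts the dendrogram at each percentage in `pct_grid` and reports the
#' number of m-OTUs, Shannon diversity and Good's coverage. Because the
#' partitions are nested, the m-OTU count and Shannon index are non-increasing
#' and Good's coverage non-decreasing in the threshold; this is asserted on
#' every run.
#'
#' @param dendrogram An `hclust` from [ward_dendrogram()].
#' @param pct_grid Percent thresholds (default 5 to 100 in steps of 5).
#' @return A tibble `pct`, `n_motu`, `shannon`, `goods`.
#' @export
diversity_profile <- function(dendrogram, pct_grid = seq(5, 100, by = 5)) {
  stopifnot(all(pct_grid > 0), all(pct_grid <= 100))
  pct_grid <- sort(pct_grid)
  rows <- purrr::map(pct_grid, function(pct) {
    part <- cut_percent(dendrogram, pct)
    tibble::tibble(pct = pct,
                   n_motu = length(unique(part$cluster)),
                   shannon = shannon_index(part),
                   goods = goods_coverage(part))
  }) |>
    purrr::list_rbind()
  if (is.unsorted(-rows$shannon) || is.unsorted(rows$goods)) {
    stop("internal error: diversity profile not monotone under coarsening")
  }
  rows
}

#' Export a dendrogram as Newick
#'
#' Branch lengths reflect the merge heights.
#'
#' @param dendrogram An `hclust`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(dendrogram, path) {
  ape::write.tree(ape::as.phylo(dendrogram), file = path)
  invisible(path)
}

#' Write an m-OTU partition as CSV
#'
#' @param partition A [cut_percent()] partition.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  readr::write_csv(tibble::as_tibble(partition), path)
  invisible(path)
}
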