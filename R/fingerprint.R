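# ---- binary fingerprint similarity and dendrograms ---------------------

# count positions shared between two sorted position sets under a relative
# tolerance, by greedy nearest matching on the sorted sequences
match_positions <- function(a, b, tol) {
  a <- sort(a); b <- sort(b)
  i <- j <- 1L; n <- 0L
  while (i <= length(a) && j <= length(b)) {
    rel <- abs(a[i] - b[j]) / max(a[i], b[j])
    if (rel <= tol) {
      n <- n + 1L; i <- i + 1L; j <- j + 1L
    } else if (a[i] < b[j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  n
}

#' Percent similarity between two binary fingerprints
#'
#' Fingerprints are sets of positions: gel band sizes (kb) or spectral peak
#' masses (m/z). Positions match when their relative difference is within
#' `tol`. `dice` similarity is `2|A^B| / (|A| + |B|) x 100` (the usual choice
#' for band patterns); `matched_pct` is `|A^B| / max(|A|, |B|) x 100` (shared
#' identical peaks relative to the richer spectrum).
#'
#' @param a,b Numeric vectors of positions (non-empty, positive).
#' @param method `"dice"` or `"matched_pct"`.
#' @param tol Relative matching tolerance (default 0.01, i.e. 1%).
#' @return Percent similarity in \[0, 100\].
#' @export
pairwise_similarity <- function(a, b, method = c("dice", "matched_pct"),
                                tol = 0.01) {
  method <- match.arg(method)
  if (length(a) == 0 || length(b) == 0) {
    stop("empty fingerprint", call. = FALSE)
  }
  stopifnot(all(a > 0), all(b > 0), all(is.finite(a)), all(is.finite(b)))
  m <- match_positions(a, b, tol)
  if (method == "dice") {
    2 * m / (length(a) + length(b)) * 100
  } else {
    m / max(length(a), length(b)) * 100
  }
}

#' All-pairs similarity matrix of fingerprints
#'
#' @param fingerprints Named list of position vectors, or a tibble with
#'   columns `sample_id` and `position` (one row per position).
#' @inheritParams pairwise_similarity
#' @return A symmetric percent-similarity matrix with 100 on the diagonal.
#' @export
similarity_matrix <- function(fingerprints, method = c("dice", "matched_pct"),
                              tol = 0.01) {
  method <- match.arg(method)
  if (is.data.frame(fingerprints)) {
    fingerprints <- split(fingerprints$position, fingerprints$sample_id)
  }
  n <- length(fingerprints)
  ids <- names(fingerprints) %||% as.character(seq_len(n))
  s <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      s[i, j] <- s[j, i] <- pairwise_similarity(fingerprints[[i]],
                                                fingerprints[[j]],
                                                method = method, tol = tol)
    }
  }
  s
}

#' Similarity dendrogram of binary fingerprints
#'
#' Agglomerates on similarity (most similar pairs merge first); merge heights
#' are `100 - similarity`, so duplicates merge at height 0 and totally
#' dissimilar profiles at 100. UPGMA (average linkage) is the convention for
#' gel band patterns; single linkage on identical peaks is the convention for
#' whole-cell MALDI spectra.
#'
#' @inheritParams similarity_matrix
#' @param linkage `"upgma"` or `"single"`.
#' @param method Similarity coefficient; defaults to `"dice"` for UPGMA (band
#'   patterns) and `"matched_pct"` for single linkage (spectral peaks) when
#'   not given.
#' @return An `hclust` object (heights on the 0-100 dissimilarity scale).
#' @export
similarity_dendrogram <- function(fingerprints, linkage = c("upgma", "single"),
                                  method = NULL, tol = 0.01) {
  linkage <- match.arg(linkage)
  if (is.null(method)) {
    method <- if (linkage == "upgma") "dice" else "matched_pct"
  }
  s <- similarity_matrix(fingerprints, method = method, tol = tol)
  if (nrow(s) < 2) stop("need at least 2 fingerprints", call. = FALSE)
  d <- stats::as.dist(100 - s)
  stats::hclust(d, method = if (linkage == "upgma") "average" else "single")
}
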