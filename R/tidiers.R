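#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a PCA model
#'
#' @param x An [pca_model()] fit.
#' @param matrix Which component to return: `"scores"`, `"loadings"` or
#'   `"variance"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mdiv_pca <- function(x, matrix = c("scores", "loadings", "variance"),
                          ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
         scores = x$scores,
         loadings = x$loadings,
         variance = tibble::tibble(component = seq_along(x$explained_variance),
                                   explained_variance = x$explained_variance))
}

#' @export
glance.mdiv_pca <- function(x, ...) {
  tibble::tibble(n_components = length(x$explained_variance),
                 cumulative_variance = sum(x$explained_variance),
                 center = x$preprocessing$center,
                 scale = x$preprocessing$scale)
}

#' Tidy an OPLS-DA model
#'
#' One row per feature: predictive weight, VIP, covariance and correlation of
#' the feature with the predictive score.
#'
#' @param x An [opls_da()] fit.
#' @param ... Unused.
#' @return A tibble `mz`, `weight`, `vip`, `cov`, `corr`.
#' @export
tidy.opls_da <- function(x, ...) {
  tibble::tibble(mz = x$mz, weight = x$weights, vip = vip(x)$vip,
                 cov = x$cov, corr = x$corr)
}

#' @export
glance.opls_da <- function(x, ...) {
  tibble::tibble(n_samples = length(x$sample_id),
                 n_features = length(x$mz),
                 n_orth = x$n_orth,
                 r2y = x$R2Y,
                 class_low = x$classes[1], class_high = x$classes[2])
}

#' Tidy a PLS-DA model
#'
#' @param x A [pls_da()] fit.
#' @param ... Unused.
#' @return A tibble `mz`, `weight` (first component), `vip`, `cov`, `corr`.
#' @export
tidy.pls_da <- function(x, ...) {
  tibble::tibble(mz = x$mz, weight = x$weights[, 1], vip = vip(x)$vip,
                 cov = x$cov, corr = x$corr)
}

#' @export
glance.pls_da <- function(x, ...) {
  tibble::tibble(n_samples = length(x$sample_id),
                 n_features = length(x$mz),
                 n_components = ncol(x$scores),
                 r2y = x$R2Y,
                 class_low = x$classes[1], class_high = x$classes[2])
}

#' @export
glance.motu_partition <- function(x, ...) {
  tibble::tibble(threshold_pct = attr(x, "threshold_pct"),
                 n_motu = length(unique(x$cluster)),
                 shannon = shannon_index(x),
                 goods = goods_coverage(x))
}
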