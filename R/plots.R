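#' Score plot of a PCA model
#'
#' @param object A [pca_model()] fit.
#' @param colour_by Optional named vector (sample id to group) used to colour
#'   the points.
#' @param components Which two components to plot (default 1 and 2).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mdiv_pca <- function(object, colour_by = NULL,
                              components = c(1, 2), ...) {
  sc <- object$scores
  xn <- paste0("PC", components[1]); yn <- paste0("PC", components[2])
  df <- tibble::tibble(sample_id = sc$sample_id,
                       x = sc[[xn]], y = sc[[yn]])
  lab <- sprintf("%s (%.1f%%)", c(xn, yn),
                 100 * object$explained_variance[components])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(colour_by)) {
    df$group <- colour_by[df$sample_id]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          colour = .data$group))
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_minimal()
}

#' S-plot of an OPLS-DA model
#'
#' Covariance of each feature with the predictive score against its
#' correlation; candidate features selected by the joint
#' covariance/correlation rule ([select_candidates()]) are highlighted, the
#' remainder form the non-discriminative core.
#'
#' @param object An [opls_da()] fit.
#' @param pct_cutoff Cutoff passed to [select_candidates()] (default 50).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.opls_da <- function(object, pct_cutoff = 50, ...) {
  sel <- select_candidates(object, pct_cutoff)
  df <- tibble::tibble(cov = sel$cov, corr = sel$corr,
                       status = ifelse(sel$selected, "candidate", "core"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cov, y = .data$corr,
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(candidate = "#D55E00",
                                            core = "grey60")) +
    ggplot2::labs(x = "cov(t1, x)", y = "corr(t1, x)") +
    ggplot2::theme_minimal()
}

#' Rarefaction curve plot
#'
#' @param curves A tibble from [rarefaction_curve()], or several such tibbles
#'   row-bound with an extra `label` column.
#' @return A ggplot object.
#' @export
plot_rarefaction <- function(curves) {
  aes <- if ("label" %in% names(curves)) {
    ggplot2::aes(x = .data$n, y = .data$richness, colour = .data$label)
  } else {
    ggplot2::aes(x = .data$n, y = .data$richness)
  }
  ggplot2::ggplot(curves, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "strains sampled", y = "expected m-OTU richness") +
    ggplot2::theme_minimal()
}

#' Diversity-profile plot across clustering thresholds
#'
#' Shannon diversity and Good's coverage against the percent clustering
#' threshold, with the conventional 10% and 40% working range marked.
#'
#' @param profile A tibble from [diversity_profile()].
#' @param highlight Thresholds to mark with vertical lines (default 10, 40).
#' @return A ggplot object.
#' @export
plot_diversity_profile <- function(profile, highlight = c(10, 40)) {
  long <- tidyr::pivot_longer(profile[, c("pct", "shannon", "goods")],
                              -"pct", names_to = "index")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pct, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = highlight, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "clustering threshold (% of maximal Ward distance)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
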