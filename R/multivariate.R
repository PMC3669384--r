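# ---- preprocessing -----------------------------------------------------

#' Centre and scale a samples-by-features matrix
#'
#' Mean centring plus Pareto scaling (division by the square root of the
#' column standard deviation) is the default, the common choice for FT-MS
#' intensity data because it shrinks the dominance of the most intense ions
#' without inflating noise the way unit-variance scaling does.
#'
#' @param x Numeric matrix, samples in rows.
#' @param center Mean-centre columns (default TRUE).
#' @param scale One of `"pareto"`, `"uv"` (unit variance), `"none"`.
#' @return The transformed matrix; constant columns are left unscaled.
#' @export
preprocess_matrix <- function(x, center = TRUE,
                              scale = c("pareto", "uv", "none")) {
  scale <- match.arg(scale)
  if (center) x <- sweep(x, 2, colMeans(x), "-")
  if (scale != "none") {
    s <- apply(x, 2, stats::sd)
    s[s == 0] <- 1
    div <- if (scale == "pareto") sqrt(s) else s
    x <- sweep(x, 2, div, "/")
  }
  x
}

# samples-by-features matrix from a feature matrix tibble
fm_samples_matrix <- function(fm) t(feature_values(fm))

# align a label vector (possibly named) with the sample order
align_labels <- function(labels, sample_ids) {
  if (!is.null(names(labels))) {
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing) > 0) {
      stop("labels missing for sample(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    stop("labels must be named or match the number of samples", call. = FALSE)
  }
  as.character(labels)
}

# ---- PCA ---------------------------------------------------------------

#' Principal component analysis of a feature matrix
#'
#' @param fm Feature matrix from [align_peaklists()] (features x samples);
#'   samples become observations.
#' @param n_components Number of components to retain.
#' @inheritParams preprocess_matrix
#' @return An object of class `"mdiv_pca"` with elements `scores` (tibble:
#'   `sample_id`, `PC1`, ...), `loadings` (tibble: `mz`, `PC1`, ...),
#'   `explained_variance` (fraction per component) and `preprocessing`.
#' @export
pca_model <- function(fm, n_components = 2, center = TRUE,
                      scale = c("pareto", "uv", "none")) {
  scale <- match.arg(scale)
  x <- fm_samples_matrix(fm)
  if (nrow(x) < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  xp <- preprocess_matrix(x, center = center, scale = scale)
  fit <- stats::prcomp(xp, center = FALSE, scale. = FALSE)
  rank <- sum(fit$sdev > max(fit$sdev) * 1e-10)
  if (n_components > rank) {
    warning("n_components (", n_components, ") exceeds rank (", rank,
            "); truncated", call. = FALSE)
    n_components <- rank
  }
  k <- seq_len(n_components)
  scores <- tibble::as_tibble(fit$x[, k, drop = FALSE])
  loadings <- tibble::as_tibble(fit$rotation[, k, drop = FALSE])
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(sample_id = rownames(x)), scores),
    loadings = dplyr::bind_cols(tibble::tibble(mz = fm$mz), loadings),
    explained_variance = (fit$sdev^2 / sum(fit$sdev^2))[k],
    preprocessing = list(center = center, scale = scale)
  ), class = "mdiv_pca")
}

# ---- PLS-DA / OPLS-DA --------------------------------------------------

# encode a two-class factor as -1/+1 on sorted class names
encode_classes <- function(labels) {
  classes <- sort(unique(labels))
  if (length(classes) != 2) {
    stop("exactly two classes required, got: ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  y <- ifelse(labels == classes[2], 1, -1)
  list(y = y, classes = classes)
}

# NIPALS PLS1 on preprocessed X and centred y
pls1_fit <- function(x, y, ncomp) {
  p <- ncol(x)
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, nrow(x), ncomp)
  q <- ssy <- numeric(ncomp)
  xr <- x; yr <- y
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(xr, yr))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      Tm <- Tm[, seq_len(a - 1), drop = FALSE]
      q <- q[seq_len(a - 1)]; ssy <- ssy[seq_len(a - 1)]
      break
    }
    w <- w / nw
    t <- drop(xr %*% w)
    tt <- sum(t^2)
    pv <- drop(crossprod(xr, t)) / tt
    qa <- sum(yr * t) / tt
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t; q[a] <- qa
    ssy[a] <- qa^2 * tt          # Y variance explained by component a
    xr <- xr - tcrossprod(t, pv)
    yr <- yr - t * qa
  }
  list(W = W, P = P, T = Tm, q = q, ssy = ssy, y_residual = yr)
}

#' Fit a PLS-DA model (two classes)
#'
#' NIPALS partial least squares regression of a -1/+1 class encoding on the
#' preprocessed intensity matrix.
#'
#' @param fm Feature matrix.
#' @param labels Class labels: a vector in sample-column order, or a named
#'   vector keyed by sample id. Exactly two classes; the alphabetically later
#'   class is encoded +1.
#' @param n_components Number of latent components (default 1).
#' @inheritParams preprocess_matrix
#' @return An object of class `"pls_da"` with scores, weights, loadings,
#'   per-component explained Y variance, per-feature VIP and the covariance/
#'   correlation profile of the first score.
#' @export
pls_da <- function(fm, labels, n_components = 1, center = TRUE,
                   scale = c("pareto", "uv", "none")) {
  scale <- match.arg(scale)
  x <- fm_samples_matrix(fm)
  labels <- align_labels(labels, rownames(x))
  enc <- encode_classes(labels)
  xp <- preprocess_matrix(x, center = center, scale = scale)
  y <- enc$y - mean(enc$y)
  fit <- pls1_fit(xp, y, n_components)
  t1 <- fit$T[, 1]
  structure(list(
    sample_id = rownames(x), mz = fm$mz,
    labels = labels, classes = enc$classes, y = enc$y,
    scores = fit$T, weights = fit$W, loadings = fit$P, q = fit$q,
    ssy = fit$ssy,
    cov = drop(crossprod(xp, t1)) / (nrow(xp) - 1),
    corr = suppressWarnings(drop(stats::cor(xp, t1))),
    R2Y = sum(fit$ssy) / sum(y^2),
    preprocessing = list(center = center, scale = scale)
  ), class = "pls_da")
}

#' Fit an OPLS-DA model (two classes)
#'
#' Orthogonal projections to latent structures: `n_orth` Y-orthogonal
#' components are identified and removed from the preprocessed matrix
#' (orthogonal-signal-correction deflation), then a single predictive PLS
#' component is fitted to the corrected matrix. With `n_orth = 0` the model
#' coincides with one-component PLS-DA.
#'
#' The covariance and correlation profiles of the predictive score against the
#' preprocessed (pre-deflation) intensities are stored for S-plot style
#' feature selection ([select_candidates()]).
#'
#' @inheritParams pls_da
#' @param n_orth Number of orthogonal components removed (default 1).
#' @return An object of class `"opls_da"`.
#' @export
opls_da <- function(fm, labels, n_orth = 1, center = TRUE,
                    scale = c("pareto", "uv", "none")) {
  scale <- match.arg(scale)
  stopifnot(n_orth >= 0)
  x <- fm_samples_matrix(fm)
  labels <- align_labels(labels, rownames(x))
  enc <- encode_classes(labels)
  xp <- preprocess_matrix(x, center = center, scale = scale)
  y <- enc$y - mean(enc$y)

  xr <- xp
  n <- nrow(xp); p <- ncol(xp)
  t_orth <- matrix(0, n, 0); p_orth <- w_orth <- matrix(0, p, 0)
  for (a in seq_len(n_orth)) {
    w <- drop(crossprod(xr, y)); w <- w / sqrt(sum(w^2))
    t <- drop(xr %*% w)
    pv <- drop(crossprod(xr, t)) / sum(t^2)
    wo <- pv - drop(crossprod(w, pv)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10) break           # no orthogonal variation left
    wo <- wo / nwo
    to <- drop(xr %*% wo)
    po <- drop(crossprod(xr, to)) / sum(to^2)
    xr <- xr - tcrossprod(to, po)
    t_orth <- cbind(t_orth, to)
    w_orth <- cbind(w_orth, wo)
    p_orth <- cbind(p_orth, po)
  }
  fit <- pls1_fit(xr, y, 1L)
  t1 <- fit$T[, 1]
  structure(list(
    sample_id = rownames(x), mz = fm$mz,
    labels = labels, classes = enc$classes, y = enc$y,
    scores = t1, weights = drop(fit$W), loadings = drop(fit$P),
    q = fit$q[1], ssy = fit$ssy,
    n_orth = ncol(t_orth),
    scores_orth = t_orth, weights_orth = w_orth, loadings_orth = p_orth,
    cov = drop(crossprod(xp, t1)) / (nrow(xp) - 1),
    corr = suppressWarnings(drop(stats::cor(xp, t1))),
    R2Y = sum(fit$ssy) / sum(y^2),
    preprocessing = list(center = center, scale = scale)
  ), class = "opls_da")
}

# ---- VIP ---------------------------------------------------------------

#' Variable importance in the projection
#'
#' `VIP_j = sqrt(p * sum_a w_ja^2 SSY_a / sum_a SSY_a)` over the predictive
#' components, where `p` is the number of features and `SSY_a` the Y variance
#' explained by component `a`. The mean of `VIP^2` is 1, so features with
#' VIP >= 1 contribute more than an average feature.
#'
#' @param model A fitted [pls_da()] or [opls_da()] model.
#' @return A tibble with columns `mz` and `vip`.
#' @export
vip <- function(model) {
  UseMethod("vip")
}

#' @export
vip.pls_da <- function(model) {
  W <- model$weights
  ssy <- model$ssy
  p <- nrow(W)
  v <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  tibble::tibble(mz = model$mz, vip = v)
}

#' @export
vip.opls_da <- function(model) {
  w <- model$weights
  p <- length(w)
  tibble::tibble(mz = model$mz, vip = sqrt(p * w^2 / sum(w^2)))
}

# ---- feature selection -------------------------------------------------

#' S-plot candidate selection on joint covariance/correlation magnitude
#'
#' The absolute covariance and absolute correlation of each feature with the
#' predictive score are each rescaled so that their maxima equal 100%; a
#' feature is a candidate when both rescaled values exceed `pct_cutoff`
#' (strict `>`).
#'
#' @param model A fitted [opls_da()] (or [pls_da()]) model.
#' @param pct_cutoff Percentage cutoff applied to both axes (default 50).
#' @return A tibble `mz`, `cov`, `corr`, `cov_pct`, `corr_pct`, `selected`.
#' @export
select_candidates <- function(model, pct_cutoff = 50) {
  cv <- abs(model$cov); cr <- abs(model$corr)
  cr[is.na(cr)] <- 0
  cov_pct <- if (max(cv) > 0) cv / max(cv) * 100 else rep(0, length(cv))
  corr_pct <- if (max(cr) > 0) cr / max(cr) * 100 else rep(0, length(cr))
  tibble::tibble(
    mz = model$mz,
    cov = model$cov, corr = model$corr,
    cov_pct = cov_pct, corr_pct = corr_pct,
    selected = cov_pct > pct_cutoff & corr_pct > pct_cutoff
  )
}

#' Per-feature Wilcoxon rank-sum selection
#'
#' Two-sided Wilcoxon rank-sum test of each feature between two strain groups.
#' Selection is on the raw p-value (`p < alpha`), matching common chemometric
#' practice for these data; Benjamini-Hochberg q-values are reported alongside
#' for reference but do not drive the selection.
#'
#' @param fm Feature matrix.
#' @param labels Two-class labels (vector in column order or named by sample).
#' @param alpha Significance level (default 0.05).
#' @return A tibble `mz`, `p_value`, `q_value`, `selected`.
#' @export
wilcoxon_select <- function(fm, labels, alpha = 0.05) {
  x <- fm_samples_matrix(fm)
  labels <- align_labels(labels, rownames(x))
  enc <- encode_classes(labels)
  g1 <- enc$y < 0
  if (sum(g1) < 3 || sum(!g1) < 3) {
    warning("group size below 3; the rank-sum test has essentially no power",
            call. = FALSE)
  }
  p <- unname(apply(x, 2, function(v) {
    suppressWarnings(stats::wilcox.test(v[g1], v[!g1])$p.value)
  }))
  tibble::tibble(
    mz = fm$mz,
    p_value = p,
    q_value = stats::p.adjust(p, method = "BH"),
    selected = p < alpha
  )
}

# ---- HCA ---------------------------------------------------------------

#' Hierarchical cluster analysis of samples
#'
#' @param fm Feature matrix.
#' @param linkage One of `"average"`, `"single"`, `"complete"`, `"ward"`
#'   (Ward on squared Euclidean/2, i.e. merge heights are within-cluster
#'   sum-of-squares increases).
#' @param metric Distance metric passed to [stats::dist()].
#' @inheritParams preprocess_matrix
#' @return An `hclust` object over samples.
#' @export
hca <- function(fm, linkage = c("average", "single", "complete", "ward"),
                metric = "euclidean", center = FALSE,
                scale = c("none", "pareto", "uv")) {
  linkage <- match.arg(linkage)
  scale <- match.arg(scale)
  x <- fm_samples_matrix(fm)
  if (nrow(x) < 2) stop("need at least 2 samples", call. = FALSE)
  x <- preprocess_matrix(x, center = center, scale = scale)
  d <- stats::dist(x, method = metric)
  if (linkage == "ward") {
    stats::hclust(d^2 / 2, method = "ward.D")
  } else {
    stats::hclust(d, method = linkage)
  }
}

# ---- cluster statistical support --------------------------------------

#' Cross-validated support for a cluster partition
#'
#' Fits a one-component PLS-DA of a two-group labelling (one cluster against
#' the rest, or any two-class vector), estimates predictive ability Q2 by
#' k-fold cross-validation, and computes a permutation p-value by refitting
#' under label permutation. A partition is called supported when
#' `Q2 >= q2_min` and the permutation p-value is below `alpha`.
#'
#' @param fm Feature matrix.
#' @param labels Two-class labels.
#' @param nfold Number of cross-validation folds (default 7).
#' @param nperm Number of label permutations (default 200).
#' @param q2_min Minimum Q2 (default 0.4).
#' @param alpha Permutation significance level (default 0.05).
#' @return A list: `q2`, `perm_p`, `supported`.
#' @export
cluster_support <- function(fm, labels, nfold = 7, nperm = 200,
                            q2_min = 0.4, alpha = 0.05) {
  x <- fm_samples_matrix(fm)
  labels <- align_labels(labels, rownames(x))
  enc <- encode_classes(labels)
  q2_obs <- cv_q2(x, enc$y, nfold)
  perm <- replicate(nperm, cv_q2(x, sample(enc$y), nfold))
  p <- (sum(perm >= q2_obs) + 1) / (nperm + 1)
  list(q2 = q2_obs, perm_p = p, supported = q2_obs >= q2_min && p < alpha)
}

# k-fold cross-validated Q2 of a 1-component PLS on pareto-scaled data
cv_q2 <- function(x, y, nfold) {
  n <- length(y)
  folds <- rep_len(seq_len(nfold), n)[sample.int(n)]
  press <- 0
  yc <- y - mean(y)
  for (k in unique(folds)) {
    tr <- folds != k
    if (sum(tr) < 2 || length(unique(y[tr])) < 2) return(NA_real_)
    xtr <- preprocess_matrix(x[tr, , drop = FALSE])
    mu <- colMeans(x[tr, , drop = FALSE])
    s <- apply(x[tr, , drop = FALSE], 2, stats::sd); s[s == 0] <- 1
    ytr <- y[tr] - mean(y[tr])
    f <- pls1_fit(xtr, ytr, 1L)
    xte <- sweep(sweep(x[!tr, , drop = FALSE], 2, mu, "-"), 2, sqrt(s), "/")
    pred <- drop(xte %*% f$W[, 1]) * f$q[1] + mean(y[tr])
    press <- press + sum((y[!tr] - pred)^2)
  }
  1 - press / sum(yc^2)
}
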