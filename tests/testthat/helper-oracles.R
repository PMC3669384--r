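# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive everything from first principles (explicit
# loops, full enumeration) and share no code path with the package internals.

# exact monoisotopic masses, restated locally so the oracle does not depend on
# the package's constants
.om <- c(C = 12.000000, H = 1.00782503, N = 14.00307401, O = 15.99491462,
         S = 31.97207069)

# Exhaustive CHNOS enumeration under the default constraint set, for masses
# below 510 Da. The complete (C, N, S, O, H) lattice is materialised once per
# session with hydrogen enumerated explicitly (never solved for), the
# mass-independent rules are applied to every tuple (nitrogen rule via
# nominal-mass parity, O/C <= 1, RDBE in [0, 40], valence cap), and each
# query is a linear ppm-window scan over the whole lattice.
.oracle_cache <- new.env(parent = emptyenv())

oracle_lattice <- function() {
  if (!is.null(.oracle_cache$lat)) return(.oracle_cache$lat)
  c_hi <- floor(510 / .om["C"])                 # 42
  o_hi <- floor(510 / .om["O"])                 # 31
  h_hi <- 2 * c_hi + 5 + 2
  full <- expand.grid(C = 1:c_hi, N = 0:5, S = 0:1, O = 0:o_hi, H = 0:h_hi)
  m <- full$C * .om["C"] + full$H * .om["H"] + full$N * .om["N"] +
    full$O * .om["O"] + full$S * .om["S"]
  nominal <- 12 * full$C + 1 * full$H + 14 * full$N + 16 * full$O +
    32 * full$S
  r <- full$C - full$H / 2 + full$N / 2 + 1
  ok <- (nominal %% 2) == (full$N %% 2) &       # nitrogen rule
    full$O <= full$C &                          # O/C <= 1
    r >= 0 & r <= 40 &                          # RDBE window
    full$H <= 2 * full$C + full$N + 2           # valence cap
  lat <- list(counts = full[ok, c("C", "H", "N", "O", "S")],
              mass = m[ok])
  .oracle_cache$lat <- lat
  lat
}

oracle_enumerate <- function(mass, tol_ppm = 0.5) {
  stopifnot(mass < 510)
  lat <- oracle_lattice()
  keep <- abs((mass - lat$mass) / lat$mass * 1e6) <= tol_ppm
  out <- lat$counts[keep, , drop = FALSE]
  out[order(out$C, out$H, out$N, out$O, out$S), , drop = FALSE]
}

# canonical string form of a candidate set for set comparison
candidate_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  unname(sort(apply(df[, c("C", "H", "N", "O", "S")], 1, paste,
                    collapse = "/")))
}

# Single-linkage peak grouping by transitive closure of the pairwise rule
# |mz_i - mz_j| <= tol_ppm * mean(mz_i, mz_j) / 1e6 (union-find).
oracle_align_groups <- function(mz, tol_ppm) {
  n <- length(mz)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (abs(mz[i] - mz[j]) <= tol_ppm * mean(c(mz[i], mz[j])) / 1e6) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Greedy Ward clustering by explicit error-sum-of-squares recomputation:
# at each step merge the pair of clusters whose union increases total ESS
# least; heights are the ESS increases.
oracle_ward <- function(x) {
  x <- as.matrix(x)
  ess <- function(rows) {
    xs <- x[rows, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs), "-")^2)
  }
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in seq.int(i + 1, length(clusters))) {
        d <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, best[1])
    merges <- c(merges, list(sort(c(clusters[[i]], clusters[[j]]))))
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# All-pairs mass-difference edge oracle: double loop over node pairs and
# transformations.
oracle_mdn_edges <- function(mass, deltas, edge_ppm) {
  edges <- character(0)
  n <- length(mass)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      for (k in seq_along(deltas)) {
        err <- abs(abs(mass[i] - mass[j]) - deltas[k]) /
          max(mass[i], mass[j]) * 1e6
        if (err <= edge_ppm) {
          edges <- c(edges, paste(i, j, names(deltas)[k], sep = "|"))
        }
      }
    }
  }
  sort(edges)
}

# Brute-force average-linkage (UPGMA) agglomeration: cluster dissimilarity is
# recomputed as the mean of all member pairwise dissimilarities at each step.
oracle_upgma <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in seq.int(i + 1, length(clusters))) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best[1]) best <- c(dd, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# ---- small fixture builders ---------------------------------------------

# feature-matrix tibble from a plain matrix (features x samples)
fm_from_matrix <- function(m, mz = NULL) {
  if (is.null(mz)) mz <- 100 + seq_len(nrow(m))
  out <- tibble::tibble(mz = mz)
  cn <- colnames(m)
  if (is.null(cn)) cn <- paste0("s", seq_len(ncol(m)))
  for (k in seq_along(cn)) out[[cn[k]]] <- m[, k]
  out
}

# long peak tibble for align_peaklists from per-sample mz/intensity lists
peaks_from_list <- function(lst) {
  purrr::imap(lst, function(p, id) {
    tibble::tibble(sample_id = id, mz = p$mz,
                   intensity = p$intensity %||% rep(1, length(p$mz)),
                   sn = 10)
  }) |> purrr::list_rbind()
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# deterministic two-group feature matrix with planted mean shifts
planted_two_group_fm <- function(n_per_group = 20, n_features = 200,
                                 n_planted = 20, effect_sd = 2, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  labels <- rep(c("a", "b"), each = n_per_group)
  m <- matrix(rnorm(n_features * n), nrow = n_features, ncol = n)
  m[seq_len(n_planted), labels == "b"] <-
    m[seq_len(n_planted), labels == "b"] + effect_sd
  m <- exp(m / 4) * 1e5          # positive, log-scale-ish intensities
  colnames(m) <- paste0("s", seq_len(n))
  list(fm = fm_from_matrix(m), labels = stats::setNames(labels, colnames(m)),
       planted = seq_len(n_planted))
}
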