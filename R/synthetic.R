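#' The worked 2 x 3 example matrix
#'
#' A two-cell, three-feature count matrix whose first column is exactly
#' twice its second: rows `(40, 20, 10)` and `(20, 10, 15)`. It
#' illustrates why leverage-based selection differs from per-column
#' thresholds — count, variance, and dispersion all pick the two
#' collinear columns (a rank-1 submatrix), while DCSS at `k = 2` with a
#' tolerance above 0.2 picks columns 1 and 3 (rank 2). Its rank-2
#' leverage profile is `(0.8, 0.2, 1.0)`.
#'
#' @return `toy_matrix()` returns the matrix wrapped as an
#'   `expr_matrix`; `toy_matrix_values()` the bare 2 x 3 numeric matrix.
#' @export
toy_matrix <- function() {
  expr_matrix(toy_matrix_values(),
              cell_ids = c("cell_1", "cell_2"),
              feature_ids = c("feature_1", "feature_2", "feature_3"))
}

#' @rdname toy_matrix
#' @export
toy_matrix_values <- function() {
  rbind(c(40, 20, 10),
        c(20, 10, 15))
}

#' Simulate a planted-cluster count matrix
#'
#' Generates a cells-by-features Poisson count matrix emulating the
#' structural traits of single-cell expression data that matter for
#' leverage-based selection: a small set of informative features with
#' high counts in exactly one cluster, a large background of
#' low-abundance noise features, non-negative sparse counts, and a
#' rapidly decaying sorted leverage profile. Cells are assigned to
#' clusters round-robin (so cluster sizes are exactly reproducible), and
#' informative features are assigned round-robin to clusters. An
#' informative feature draws `Poisson(cluster_mean_scale)` counts in
#' cells of its own cluster and `Poisson(noise_rate)` elsewhere; noise
#' features draw `Poisson(noise_rate)` everywhere.
#'
#' Defaults give 200 cells x 530 features in 3 clusters with a strong
#' (100x) abundance separation between informative and noise features.
#'
#' @param n_cells number of cells (rows).
#' @param n_informative number of cluster-marking features.
#' @param n_noise number of background features.
#' @param n_clusters number of planted clusters (`<= n_cells`).
#' @param cluster_mean_scale expected count of an informative feature in
#'   its "on" cluster.
#' @param noise_rate expected count everywhere else (lambda of the
#'   background Poisson). `0` gives identically zero noise columns.
#' @param seed integer seed (mandatory; the simulation is only defined
#'   jointly with it).
#' @return list with `matrix` (an `expr_matrix`), `labels` (planted
#'   cluster labels, integers `1..n_clusters`), `informative` (indices of
#'   the informative columns, `1..n_informative`), and the parameters
#'   under `params`.
#' @export
simulate_counts <- function(n_cells = 200L, n_informative = 30L,
                            n_noise = 500L, n_clusters = 3L,
                            cluster_mean_scale = 50, noise_rate = 0.5,
                            seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  n_cells <- as.integer(n_cells)
  n_informative <- as.integer(n_informative)
  n_noise <- as.integer(n_noise)
  n_clusters <- as.integer(n_clusters)
  if (n_cells < 1L || n_informative < 0L || n_noise < 0L ||
      n_informative + n_noise < 1L) {
    stop("invalid dimensions")
  }
  if (n_clusters < 1L || n_clusters > n_cells) {
    stop("n_clusters must lie in [1, n_cells]")
  }
  if (cluster_mean_scale < 0 || noise_rate < 0) {
    stop("rates must be non-negative")
  }
  labels <- rep(seq_len(n_clusters), length.out = n_cells)
  feat_cluster <- rep(seq_len(n_clusters), length.out = n_informative)
  d <- n_informative + n_noise
  lam <- matrix(noise_rate, n_cells, d)
  for (j in seq_len(n_informative)) {
    lam[labels == feat_cluster[j], j] <- cluster_mean_scale
  }
  set.seed(as.integer(seed))
  counts <- matrix(stats::rpois(n_cells * d, lambda = lam), n_cells, d)
  feature_ids <- c(if (n_informative > 0L)
                     sprintf("marker_c%d_%03d", feat_cluster,
                             seq_len(n_informative)),
                   if (n_noise > 0L) sprintf("noise_%04d", seq_len(n_noise)))
  list(matrix = expr_matrix(counts,
                            cell_ids = sprintf("cell_%04d", seq_len(n_cells)),
                            feature_ids = feature_ids),
       labels = labels,
       informative = seq_len(n_informative),
       params = list(n_cells = n_cells, n_informative = n_informative,
                     n_noise = n_noise, n_clusters = n_clusters,
                     cluster_mean_scale = cluster_mean_scale,
                     noise_rate = noise_rate, seed = as.integer(seed)))
}

#' Exact power-law leverage profile
#'
#' Builds a sorted leverage profile decaying as `tau_(i) ~ i^(-a)`
#' (1-based sorted index), rescaled so the scores sum to `k`. When the
#' rescaling would push leading scores above 1 (impossible for genuine
#' leverage scores) those scores are clipped to 1 and the remainder
#' renormalized to keep the sum at `k`; the `clipped` attribute flags
#' when this happened, since the clipped profile is no longer an exact
#' power law.
#'
#' @param d number of columns (`>= k`).
#' @param a decay exponent, `> 1`.
#' @param k rank the scores sum to.
#' @return a `leverage_profile` (scores already sorted, identity
#'   permutation) with attribute `clipped` (logical).
#' @export
power_law_profile <- function(d, a, k) {
  d <- as.integer(d)
  k <- as.integer(k)
  if (!is.numeric(a) || length(a) != 1L || a <= 1) stop("need a > 1")
  if (k < 1L) stop("k must be >= 1")
  if (d < k) stop("infeasible: need d >= k")
  raw <- seq_len(d)^(-a)
  tau <- k * raw / sum(raw)
  clipped <- FALSE
  while (any(tau > 1 + 1e-12)) {
    clipped <- TRUE
    over <- tau >= 1
    rem <- k - sum(over)
    tau[over] <- 1
    if (rem <= 0 || !any(!over)) {
      tau[!over] <- 0
      break
    }
    tau[!over] <- rem * raw[!over] / sum(raw[!over])
  }
  prof <- new_leverage_profile(tau, k)
  attr(prof, "clipped") <- clipped
  prof
}
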