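#' Normalize cells to probability mass functions
#'
#' Each cell's count vector is divided by its total, giving a probability
#' mass function over features — the representation used for
#' Jensen-Shannon distances. Cells with zero total count have no PMF and
#' are rejected with an error naming them.
#'
#' @param a an `expr_matrix` or non-negative matrix.
#' @return an `expr_matrix` (dense) whose rows each sum to 1.
#' @export
rows_to_pmf <- function(a) {
  a <- as_expr_matrix(a)
  m <- as.matrix(a)
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    bad <- a$cell_ids[rs <= 0]
    stop("cells with zero total count have no probability mass function: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L)
         else "")
  }
  expr_matrix(m / rs, a$cell_ids, a$feature_ids)
}

entropy_base2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Pairwise Jensen-Shannon distance matrix
#'
#' The JS distance between PMFs p and q is the square root of the JS
#' divergence `(KL(p||m) + KL(q||m)) / 2` with mixture `m = (p + q)/2`,
#' using base-2 logarithms so the distance lies in `[0, 1]` (0 for
#' identical PMFs, 1 for disjoint supports) and is a metric. Computed via
#' the entropy form `JSD(p, q) = H(m) - (H(p) + H(q)) / 2` with the
#' convention `0 log 0 = 0`.
#'
#' @param p an `expr_matrix` of PMFs (rows summing to 1, e.g. from
#'   [rows_to_pmf()]) or such a matrix.
#' @return symmetric n x n numeric matrix with zero diagonal, dimnames
#'   set to the cell identifiers.
#' @export
js_distance_matrix <- function(p) {
  p <- as_expr_matrix(p)
  m <- as.matrix(p)
  if (any(abs(rowSums(m) - 1) > 1e-8)) {
    stop("rows must sum to 1; run rows_to_pmf() first")
  }
  n <- nrow(m)
  h <- apply(m, 1L, entropy_base2)
  dist <- matrix(0, n, n, dimnames = list(p$cell_ids, p$cell_ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      pi_row <- m[i, ]
      for (j in seq.int(i + 1L, n)) {
        mix <- (pi_row + m[j, ]) / 2
        d2 <- entropy_base2(mix) - (h[i] + h[j]) / 2
        d2 <- min(max(d2, 0), 1)  # guard tiny negative round-off
        dist[i, j] <- dist[j, i] <- sqrt(d2)
      }
    }
  }
  dist
}

#' Spectral clustering of a distance matrix
#'
#' The clustering used for workflow comparison: similarity
#' `S = 1 - D` entrywise; symmetric normalized Laplacian
#' `L = I - Deg^(-1/2) S Deg^(-1/2)` with `Deg` the diagonal of row sums
#' of `S`; the `k_embed` eigenvectors of `L` with smallest eigenvalues as
#' the embedding; and seeded k-means (k-means++-style multiple starts via
#' `nstart = 10`) on the embedded rows.
#'
#' @param d symmetric distance matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @param n_clusters number of clusters, `>= 1`.
#' @param k_embed embedding dimension (default `n_clusters`).
#' @param seed integer seed for the k-means initialization.
#' @param normalize_rows logical; renormalize embedded rows to unit length
#'   before k-means (off by default).
#' @return object of class `"cluster_assignment"`: list with `labels`
#'   (integers in `1..n_clusters`), `n_clusters`, `k_embed`, `seed`.
#' @export
spectral_cluster <- function(d, n_clusters, k_embed = n_clusters, seed = 1L,
                             normalize_rows = FALSE) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (ncol(d) != n) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-8)) stop("distance matrix must have zero diagonal")
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 1L || n_clusters > n) {
    stop("n_clusters must lie in [1, n]")
  }
  if (n_clusters == 1L) {
    return(structure(list(labels = rep(1L, n), n_clusters = 1L,
                          k_embed = as.integer(k_embed),
                          seed = as.integer(seed)),
                     class = "cluster_assignment"))
  }
  s <- 1 - d
  # self-similarity is always 1, so isolation must be judged off-diagonal
  if (any(rowSums(s) - diag(s) <= 0)) {
    stop("similarity graph has a zero-degree node; spectral embedding undefined")
  }
  deg <- rowSums(s)
  inv_sqrt <- 1 / sqrt(deg)
  lap <- diag(n) - s * tcrossprod(inv_sqrt)
  k_embed <- as.integer(k_embed)
  if (k_embed < 1L || k_embed > n) stop("k_embed must lie in [1, n]")
  es <- eigen(lap, symmetric = TRUE)
  # eigen() orders eigenvalues decreasing; take the k_embed smallest
  emb <- es$vectors[, seq.int(n, n - k_embed + 1L), drop = FALSE]
  if (normalize_rows) {
    rn <- sqrt(rowSums(emb^2))
    rn[rn == 0] <- 1
    emb <- emb / rn
  }
  set.seed(as.integer(seed))
  km <- stats::kmeans(emb, centers = n_clusters, nstart = 10L,
                      iter.max = 100L)
  structure(list(labels = as.integer(km$cluster), n_clusters = n_clusters,
                 k_embed = k_embed, seed = as.integer(seed)),
            class = "cluster_assignment")
}

#' Adjusted Rand index
#'
#' Pair-counting similarity between two partitions, adjusted for chance
#' via the hypergeometric expectation on the contingency table:
#' `ARI = (sum_ij C(n_ij,2) - E) / (max_index - E)` with
#' `E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2)` and
#' `max_index = (sum_i C(a_i,2) + sum_j C(b_j,2)) / 2`. Symmetric,
#' invariant to label names; 1 for identical partitions, expectation 0
#' for independent random partitions, and can be negative for
#' worse-than-chance agreement.
#'
#' @param labels1,labels2 equal-length label vectors (any atomic type, or
#'   `cluster_assignment` objects).
#' @return a number in `[-1, 1]`.
#' @examples
#' adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1))  # -0.5
#' @export
adjusted_rand_index <- function(labels1, labels2) {
  if (inherits(labels1, "cluster_assignment")) labels1 <- labels1$labels
  if (inherits(labels2, "cluster_assignment")) labels2 <- labels2$labels
  if (length(labels1) != length(labels2)) {
    stop("label vectors must have equal length")
  }
  n <- length(labels1)
  if (n < 2L) return(1)
  tab <- table(labels1, labels2)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Full-matrix vs submatrix clustering concordance
#'
#' The evaluation protocol for a feature selection: run the full pipeline
#' (PMF normalization, JS distances, spectral clustering) on the complete
#' matrix and on each column-selected submatrix, repeating the seeded
#' k-means `t_restarts` times (seeds `seed .. seed + t_restarts - 1`),
#' and report the mean and standard deviation of the adjusted Rand index
#' of each submatrix workflow against the complete-data workflow run with
#' the same seed — treating the complete-data clustering as the
#' reference. Cells whose counts become all zero under a selection have
#' no PMF; they are dropped from both labelings for that comparison and
#' counted in the report.
#'
#' @param a the complete `expr_matrix` (or matrix).
#' @param selections named list of `column_selection` objects and/or
#'   1-based index vectors.
#' @param n_clusters number of spectral clusters.
#' @param t_restarts number of seeded k-means restarts (default 10).
#' @param seed base seed; restart `t` uses `seed + t - 1`.
#' @param k_embed spectral embedding dimension (default `n_clusters`).
#' @return object of class `"comparison_report"`: list with `summary`
#'   (data.frame: method, mean_ari, sd_ari, n_columns, n_cells_dropped),
#'   `ari` (matrix of per-restart ARIs), `t_restarts`, `n_clusters`,
#'   `seed`, `reference = "complete"`.
#' @export
concordance_experiment <- function(a, selections, n_clusters,
                                   t_restarts = 10L, seed = 1L,
                                   k_embed = n_clusters) {
  a <- as_expr_matrix(a)
  if (!is.list(selections)) selections <- list(selection = selections)
  nm <- names(selections)
  if (is.null(nm)) nm <- paste0("selection_", seq_along(selections))
  t_restarts <- as.integer(t_restarts)
  if (t_restarts < 1L) stop("t_restarts must be >= 1")
  seeds <- as.integer(seed) + seq_len(t_restarts) - 1L
  d_full <- js_distance_matrix(rows_to_pmf(a))
  ref <- lapply(seeds, function(s)
    spectral_cluster(d_full, n_clusters, k_embed, seed = s)$labels)
  ari <- matrix(NA_real_, nrow = t_restarts, ncol = length(selections),
                dimnames = list(NULL, nm))
  n_cols <- integer(length(selections))
  n_drop <- integer(length(selections))
  for (si in seq_along(selections)) {
    idx <- selection_indices(selections[[si]])
    n_cols[si] <- length(idx)
    sub <- extract_submatrix(a, idx)
    keep <- rowSums(as.matrix(sub)) > 0
    n_drop[si] <- sum(!keep)
    sub_kept <- expr_matrix(as.matrix(sub)[keep, , drop = FALSE],
                            sub$cell_ids[keep], sub$feature_ids)
    d_sub <- js_distance_matrix(rows_to_pmf(sub_kept))
    for (t in seq_len(t_restarts)) {
      lab_sub <- spectral_cluster(d_sub, n_clusters, k_embed,
                                  seed = seeds[t])$labels
      ari[t, si] <- adjusted_rand_index(ref[[t]][keep], lab_sub)
    }
  }
  structure(list(
    summary = data.frame(method = nm,
                         mean_ari = colMeans(ari),
                         sd_ari = apply(ari, 2L, stats::sd),
                         n_columns = n_cols,
                         n_cells_dropped = n_drop,
                         stringsAsFactors = FALSE),
    ari = ari,
    t_restarts = t_restarts,
    n_clusters = as.integer(n_clusters),
    seed = as.integer(seed),
    reference = "complete"),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(
    "<comparison_report> %d clusters, %d restarts, reference = %s\n",
    x$n_clusters, x$t_restarts, x$reference))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
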