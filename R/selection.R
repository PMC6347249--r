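#' Deterministic column subset selection
#'
#' The DCSS rule: walk the columns in descending leverage order,
#' accumulating scores, and stop at the first prefix whose leverage mass
#' strictly exceeds `k - epsilon`. If fewer than `k` columns were taken,
#' keep adding in order until `|Theta| = k` (and flag the fill). The
#' leverage of the last included column is the realized threshold `theta`;
#' the leftover mass `epsilon_realized = k - sum(tau[Theta])` satisfies
#' `epsilon_realized < epsilon` whenever no fill occurred.
#'
#' A tolerance `epsilon >= k` makes the stopping rule trivially satisfied
#' at the first column; this is permitted, and the fill to `k` columns
#' then applies. Exact ties at the boundary are resolved by the profile's
#' stable sort (ties by ascending column index).
#'
#' @param profile a `leverage_profile`.
#' @param epsilon error tolerance, `> 0`. Smaller values keep more columns.
#' @return object of class `"dcss_selection"`: list with `indices`
#'   (1-based column indices in inclusion order, i.e. descending
#'   leverage), `size`, `theta` (leverage of the last included column),
#'   `epsilon`, `epsilon_realized`, `k`, `d`, `forced_fill`,
#'   `feature_ids` (of the selected columns, when the profile carries
#'   identifiers).
#' @examples
#' p <- leverage_scores(rank_k_factorize(expr_matrix(toy_matrix_values()), 2))
#' dcss_select(p, 0.3)$indices  # 3 1
#' @export
dcss_select <- function(profile, epsilon) {
  stopifnot(inherits(profile, "leverage_profile"))
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0) {
    stop("'epsilon' must be a single positive number")
  }
  tau <- profile$scores
  k <- profile$k
  ord <- profile$order
  d <- length(tau)
  cs <- cumsum(tau[ord])
  stop_at <- which(cs > k - epsilon)[1L]  # strict inequality
  if (is.na(stop_at)) stop_at <- d  # unreachable for epsilon > 0, defensive
  forced_fill <- FALSE
  if (stop_at < k) {
    stop_at <- min(k, d)
    forced_fill <- TRUE
  }
  idx <- ord[seq_len(stop_at)]
  theta <- tau[idx[length(idx)]]
  structure(list(method = "dcss",
                 indices = idx,
                 size = length(idx),
                 theta = theta,
                 epsilon = epsilon,
                 epsilon_realized = k - sum(tau[idx]),
                 k = k,
                 d = d,
                 forced_fill = forced_fill,
                 feature_ids = if (!is.null(profile$feature_ids))
                   profile$feature_ids[idx] else NULL),
            class = c("dcss_selection", "column_selection"))
}

#' @export
print.dcss_selection <- function(x, ...) {
  cat(sprintf(
    "<dcss_selection> |Theta| = %d of %d (k = %d, epsilon = %g)\n",
    x$size, x$d, x$k, x$epsilon))
  cat(sprintf("  theta = %.6g, realized error = %.6g%s\n", x$theta,
              x$epsilon_realized,
              if (x$forced_fill) " (forced fill to k)" else ""))
  invisible(x)
}

#' Extract a column submatrix
#'
#' Forms `C = A S` for a selection of columns: the submatrix keeps all
#' cells, the chosen features in the given (inclusion) order, and the
#' original values — so non-negativity and sparsity patterns are
#' preserved, unlike a PCA truncation.
#'
#' @param a an `expr_matrix` or matrix.
#' @param indices a `column_selection` object or vector of distinct
#'   1-based column indices.
#' @return an `expr_matrix` with `length(indices)` columns.
#' @export
extract_submatrix <- function(a, indices) {
  a <- as_expr_matrix(a, check_nonneg = FALSE)
  if (inherits(indices, "column_selection")) indices <- indices$indices
  indices <- as.integer(indices)
  d <- ncol(a$values)
  if (length(indices) < 1L) stop("empty column selection")
  if (any(is.na(indices)) || any(indices < 1L) || any(indices > d)) {
    stop(sprintf("column indices must lie in [1, %d]", d))
  }
  if (anyDuplicated(indices)) stop("duplicate column indices")
  expr_matrix(a$values[, indices, drop = FALSE],
              cell_ids = a$cell_ids,
              feature_ids = a$feature_ids[indices],
              check_nonneg = FALSE)
}

#' Simple column-thresholding baselines
#'
#' The per-column scores commonly used to filter genes: total count
#' (column sum — equivalent in ordering to the column mean for a fixed
#' number of cells, so a separate mean method is not exposed), empirical
#' variance (population convention, divide by n), and index of dispersion
#' (variance / mean, with 0/0 defined as 0 so all-zero columns rank
#' last). Each score looks at one column in isolation, ignoring
#' collinearity — the contrast motivating DCSS.
#'
#' @param a an `expr_matrix` or matrix.
#' @param method one of `"count"`, `"variance"`, `"dispersion"`.
#' @param n_select number of columns to keep, `1 <= n_select <= d`.
#' @return object of class `"baseline_selection"`: list with `method`,
#'   `indices` (1-based, descending score, ties by ascending index),
#'   `size`, `scores` (all d per-column scores), `threshold` (score of
#'   the last kept column), `d`, `feature_ids`.
#' @export
threshold_by_score <- function(a, method = c("count", "variance", "dispersion"),
                               n_select) {
  method <- match.arg(method)
  a <- as_expr_matrix(a, check_nonneg = FALSE)
  m <- as.matrix(a)
  d <- ncol(m)
  n_select <- as.integer(n_select)
  if (length(n_select) != 1L || is.na(n_select) || n_select < 1L ||
      n_select > d) {
    stop(sprintf("n_select must be an integer in [1, %d]", d))
  }
  mu <- colMeans(m)
  varp <- colMeans(m^2) - mu^2  # population variance
  score <- unname(switch(method,
    count = colSums(m),
    variance = varp,
    dispersion = ifelse(mu > 0, varp / mu, 0)))
  ord <- order(-score)  # stable: ties by ascending index
  idx <- ord[seq_len(n_select)]
  structure(list(method = method,
                 indices = idx,
                 size = n_select,
                 scores = score,
                 threshold = score[idx[n_select]],
                 d = d,
                 feature_ids = a$feature_ids[idx]),
            class = c("baseline_selection", "column_selection"))
}

#' Randomized leverage-score column sampling
#'
#' The randomized counterpart to DCSS: draws `t` column indices i.i.d.
#' with replacement, with probability proportional to the leverage
#' scores. Duplicates are collapsed for submatrix extraction; the draw
#' multiplicities are retained in the returned object (no reweighting of
#' retained columns is applied).
#'
#' @param profile a `leverage_profile`; must contain a positive score.
#' @param t number of draws, `>= 1`.
#' @param seed integer seed for reproducibility.
#' @return object of class `"baseline_selection"`: `method =
#'   "random_leverage"`, `indices` (unique draws in first-draw order),
#'   `draws` (all t draws), `multiplicity` (named table of draw counts),
#'   `size`, `d`, `seed`.
#' @export
random_leverage_sample <- function(profile, t, seed) {
  stopifnot(inherits(profile, "leverage_profile"))
  t <- as.integer(t)
  if (length(t) != 1L || is.na(t) || t < 1L) stop("t must be a positive integer")
  tau <- profile$scores
  if (all(tau <= 0)) stop("all leverage scores are zero; cannot sample")
  set.seed(as.integer(seed))
  draws <- sample.int(length(tau), size = t, replace = TRUE, prob = tau)
  idx <- unique(draws)
  structure(list(method = "random_leverage",
                 indices = idx,
                 draws = draws,
                 multiplicity = table(draws),
                 size = length(idx),
                 d = length(tau),
                 seed = as.integer(seed),
                 feature_ids = if (!is.null(profile$feature_ids))
                   profile$feature_ids[idx] else NULL),
            class = c("baseline_selection", "column_selection"))
}

selection_indices <- function(x) {
  if (inherits(x, "column_selection")) x$indices else as.integer(x)
}

#' Overlap between column selections
#'
#' Pairwise and overall agreement between two or more selections over the
#' same feature axis: intersection and union sizes and Jaccard indices
#' (the numbers behind a Venn diagram of selected features).
#'
#' @param selections named list of `column_selection` objects and/or
#'   1-based index vectors, all over the same number of columns `d`.
#' @param d total number of columns; inferred from selection objects when
#'   omitted.
#' @return object of class `"selection_overlap"`: list with `pairwise`
#'   (data.frame: method_a, method_b, intersection, union, jaccard),
#'   `common` (indices in every selection), `sizes`.
#' @export
selection_overlap <- function(selections, d = NULL) {
  if (!is.list(selections) || length(selections) < 2L) {
    stop("need at least two selections")
  }
  ds <- vapply(selections, function(s)
    if (inherits(s, "column_selection")) s$d else NA_integer_, integer(1L))
  if (is.null(d)) {
    d <- ds[!is.na(ds)][1L]
    if (is.na(d) || is.null(d)) stop("'d' could not be inferred; supply it")
  }
  if (any(!is.na(ds) & ds != d)) stop("selections are over different d")
  idx <- lapply(selections, selection_indices)
  for (v in idx) {
    if (any(v < 1L) || any(v > d)) stop("selection index outside [1, d]")
  }
  nm <- names(selections)
  if (is.null(nm)) nm <- paste0("selection_", seq_along(selections))
  pairs <- utils::combn(length(idx), 2L)
  pw <- data.frame(
    method_a = nm[pairs[1L, ]],
    method_b = nm[pairs[2L, ]],
    intersection = apply(pairs, 2L, function(p)
      length(intersect(idx[[p[1L]]], idx[[p[2L]]]))),
    union = apply(pairs, 2L, function(p)
      length(union(idx[[p[1L]]], idx[[p[2L]]]))),
    stringsAsFactors = FALSE)
  pw$jaccard <- ifelse(pw$union > 0, pw$intersection / pw$union, NA_real_)
  structure(list(pairwise = pw,
                 common = sort(Reduce(intersect, idx)),
                 sizes = stats::setNames(lengths(idx), nm),
                 d = d),
            class = "selection_overlap")
}

#' @export
print.selection_overlap <- function(x, ...) {
  cat(sprintf("<selection_overlap> over d = %d columns\n", x$d))
  print(x$pairwise, row.names = FALSE)
  cat("  common to all:", length(x$common), "columns\n")
  invisible(x)
}
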