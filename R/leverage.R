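#' Rank-k factorization of an expression matrix
#'
#' Computes the top-k singular triplets of `A` (the factors of `A_k`, the
#' best rank-k approximation in Frobenius norm). The output is made
#' deterministic by a sign convention: the largest-magnitude entry of each
#' right singular vector is made positive, so repeated runs and serialized
#' outputs are comparable bit-for-bit.
#'
#' @param a an `expr_matrix` or numeric matrix.
#' @param k target rank, `1 <= k <= min(n, d)`; the numerical rank of `a`
#'   must be at least `k`.
#' @param rank_tol relative tolerance for declaring rank deficiency: a
#'   singular value `sigma_j <= rank_tol * sigma_1` does not count toward
#'   the numerical rank.
#' @return object of class `"rank_k_factorization"`: list with `k`, `u`
#'   (n x k, orthonormal columns), `d` (singular values, non-increasing,
#'   strictly positive), `v` (d x k, orthonormal columns), and
#'   `feature_ids`.
#' @seealso [leverage_scores()]
#' @export
rank_k_factorize <- function(a, k, rank_tol = 1e-10) {
  a <- as_expr_matrix(a, check_nonneg = FALSE)
  m <- as.matrix(a)
  n <- nrow(m); d <- ncol(m)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > min(n, d)) {
    stop(sprintf("k must be an integer in [1, %d]", min(n, d)))
  }
  sv <- svd(m)
  r <- sum(sv$d > rank_tol * sv$d[1L])
  if (k > r) {
    stop(sprintf("matrix is rank deficient: requested k = %d but numerical rank is %d",
                 k, r))
  }
  u <- sv$u[, seq_len(k), drop = FALSE]
  s <- sv$d[seq_len(k)]
  v <- sv$v[, seq_len(k), drop = FALSE]
  # deterministic sign: flip each component so the dominant entry of the
  # right singular vector is positive (ties: first index wins)
  for (j in seq_len(k)) {
    i0 <- which.max(abs(v[, j]))
    if (v[i0, j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  structure(list(k = k, u = u, d = s, v = v, feature_ids = a$feature_ids),
            class = "rank_k_factorization")
}

new_leverage_profile <- function(scores, k, feature_ids = NULL) {
  scores <- as.numeric(scores)
  # stable descending sort: ties broken by ascending column index
  ord <- order(-scores)
  structure(list(scores = scores, k = k, order = ord,
                 feature_ids = feature_ids),
            class = "leverage_profile")
}

#' @export
print.leverage_profile <- function(x, ...) {
  cat(sprintf("<leverage_profile> d = %d features, k = %d, sum(tau) = %.6f\n",
              length(x$scores), x$k, sum(x$scores)))
  top <- x$order[seq_len(min(5L, length(x$order)))]
  cat("  top scores:", paste(sprintf("%.4f", x$scores[top]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Rank-k subspace leverage scores
#'
#' The rank-k subspace leverage score of column `a_i` is the quadratic form
#' `tau_i = a_i' (A_k A_k')^+ a_i`, where `^+` is the Moore-Penrose
#' pseudoinverse. Writing `A_k = U_k S V_k'` and substituting gives
#' `tau_i = a_i' U_k S^-2 U_k' a_i`; and since the i-th column of `A_k` is
#' `U_k S (V_k' e_i)` while columns of `A` and `A_k` have identical
#' projections onto the column space of `U_k`, this collapses to
#' `tau_i = || V_k[i, ] ||^2`, the squared Euclidean norm of the i-th row
#' of the right singular vectors. That identity (tested here against a
#' direct pseudoinverse oracle) is what this function computes: O(dk)
#' from a factorization instead of an n x n pseudoinverse.
#'
#' Scores satisfy `0 <= tau_i <= 1` and `sum(tau) = k`, and are invariant
#' to positive rescaling of `A`. Columns collinear with others split
#' leverage among themselves, which is what distinguishes this score from
#' per-column statistics such as count or variance.
#'
#' @param f a `rank_k_factorization` from [rank_k_factorize()].
#' @return object of class `"leverage_profile"`: list with `scores`
#'   (length d), `k`, `order` (permutation sorting scores descending,
#'   ties by ascending index), `feature_ids`.
#' @examples
#' a <- expr_matrix(toy_matrix_values())
#' leverage_scores(rank_k_factorize(a, 2))$scores  # 0.8 0.2 1.0
#' @export
leverage_scores <- function(f) {
  stopifnot(inherits(f, "rank_k_factorization"))
  tau <- rowSums(f$v^2)
  new_leverage_profile(tau, f$k, f$feature_ids)
}

#' Leverage scores by explicit pseudoinverse (test oracle)
#'
#' Direct evaluation of the defining quadratic form
#' `tau_i = a_i' (A_k A_k')^+ a_i`: builds `A_k` explicitly, forms the
#' Moore-Penrose pseudoinverse of the n x n Gram matrix `A_k A_k'`
#' (via `MASS::ginv`), and evaluates the form per column. Intended as an
#' independent correctness oracle on small dense matrices (d up to a few
#' hundred); use [leverage_scores()] for real work.
#'
#' @inheritParams rank_k_factorize
#' @return a `leverage_profile`.
#' @export
leverage_scores_pinv_oracle <- function(a, k, rank_tol = 1e-10) {
  a <- as_expr_matrix(a, check_nonneg = FALSE)
  m <- as.matrix(a)
  f <- rank_k_factorize(a, k, rank_tol)
  ak <- f$u %*% (f$d * t(f$v))
  gram_pinv <- MASS::ginv(tcrossprod(ak))
  tau <- vapply(seq_len(ncol(m)),
                function(i) drop(crossprod(m[, i], gram_pinv %*% m[, i])),
                numeric(1L))
  new_leverage_profile(tau, f$k, a$feature_ids)
}

#' Leverage scores by minimum-norm least squares (test oracle)
#'
#' The leverage score can equivalently be characterized as
#' `tau_i = ||x_hat||^2` where `x_hat` is the minimum-norm solution of the
#' least-squares problem `A_k x ~ a_i` over `x` in R^d — it measures how
#' easily column `a_i` is expressed as a combination of the columns of
#' `A_k`. Computed here as `x_hat = A_k^+ a_i` with an explicit
#' pseudoinverse of `A_k`. Test-only oracle for small dense matrices;
#' agrees with [leverage_scores()] and [leverage_scores_pinv_oracle()] to
#' high precision.
#'
#' @inheritParams rank_k_factorize
#' @return a `leverage_profile`.
#' @export
leverage_scores_lsq_oracle <- function(a, k, rank_tol = 1e-10) {
  a <- as_expr_matrix(a, check_nonneg = FALSE)
  m <- as.matrix(a)
  f <- rank_k_factorize(a, k, rank_tol)
  ak <- f$u %*% (f$d * t(f$v))
  ak_pinv <- MASS::ginv(ak)
  tau <- vapply(seq_len(ncol(m)),
                function(i) sum((ak_pinv %*% m[, i])^2),
                numeric(1L))
  new_leverage_profile(tau, f$k, a$feature_ids)
}

#' Leverage scores for an arbitrary set of singular components
#'
#' Generalizes the leading-k subspace: scores are computed for the subspace
#' spanned by the named singular components of `A` (e.g. drop component 1
#' but keep component 2, useful when a leading component tracks batch or
#' other confounding). Scores are the squared row norms of `V` restricted
#' to those components; they sum to the number of components.
#'
#' @param a an `expr_matrix` or matrix.
#' @param components integer vector of singular-component indices (1-based,
#'   each at most the numerical rank of `a`).
#' @param rank_tol relative rank tolerance, as in [rank_k_factorize()].
#' @return a `leverage_profile` with `k = length(components)`.
#' @export
leverage_scores_custom_subspace <- function(a, components, rank_tol = 1e-10) {
  a <- as_expr_matrix(a, check_nonneg = FALSE)
  m <- as.matrix(a)
  components <- as.integer(components)
  if (length(components) < 1L || anyDuplicated(components) ||
      any(is.na(components)) || any(components < 1L)) {
    stop("'components' must be distinct positive integers")
  }
  sv <- svd(m)
  r <- sum(sv$d > rank_tol * sv$d[1L])
  if (max(components) > r) {
    stop(sprintf("component %d exceeds the numerical rank %d",
                 max(components), r))
  }
  tau <- rowSums(sv$v[, components, drop = FALSE]^2)
  new_leverage_profile(tau, length(components), a$feature_ids)
}
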