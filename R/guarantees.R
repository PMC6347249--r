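#' Verify the spectral (Loewner) guarantees of a DCSS selection
#'
#' A DCSS submatrix `C` satisfies, in the Loewner partial order,
#' `(1 - eps) A_k A_k' <= U_k U_k' C C' U_k U_k' <= A_k A_k'`, and as a
#' consequence the two-sided form with upper factor `(1 + eps)`. Because
#' every matrix involved acts inside the k-dimensional column space of
#' `U_k`, the n x n statements reduce exactly to k x k ones: with
#' `G = U_k' C C' U_k` and `D = diag(sigma^2)`, each ordering holds iff
#' the corresponding difference (`G - (1 - eps) D`, `D - G`,
#' `(1 + eps) D - G`) has smallest eigenvalue `>= 0`. This function forms
#' those k x k matrices and reports the most negative eigenvalue of each
#' (the "slack"), passing a check when the slack is above `-tol`.
#'
#' @param a the full `expr_matrix` (or matrix).
#' @param f the `rank_k_factorization` of `a` used for the selection.
#' @param selection a `column_selection` (DCSS output; arbitrary
#'   selections are accepted so violations can be demonstrated).
#' @param epsilon the error tolerance the selection was run with.
#' @param tol absolute eigenvalue tolerance; defaults to
#'   `1e-8 * sigma_1^2` so pass/fail is invariant to the scale of `a`.
#' @return object of class `"bound_report"`: list with booleans
#'   `loewner_lower_ok`, `loewner_upper_ok`, `two_sided_ok`, the
#'   `min_eigenvalue_slacks` (named: lower, upper, two_sided), `tol`,
#'   `epsilon`, and (after [verify_frobenius_bound()]) a `frobenius`
#'   element.
#' @export
verify_spectral_bounds <- function(a, f, selection, epsilon, tol = NULL) {
  stopifnot(inherits(f, "rank_k_factorization"))
  a <- as_expr_matrix(a, check_nonneg = FALSE)
  m <- as.matrix(a)
  if (nrow(m) != nrow(f$u)) stop("matrix and factorization shapes disagree")
  idx <- selection_indices(selection)
  if (any(idx < 1L) || any(idx > ncol(m))) stop("selection index out of range")
  if (is.null(tol)) tol <- 1e-8 * f$d[1L]^2
  cm <- m[, idx, drop = FALSE]
  uc <- crossprod(f$u, cm)          # k x |Theta|
  g <- tcrossprod(uc)               # U_k' C C' U_k
  dm <- diag(f$d^2, nrow = f$k)
  slack <- function(mat) min(eigen(mat, symmetric = TRUE,
                                   only.values = TRUE)$values)
  s_lower <- slack(g - (1 - epsilon) * dm)
  s_upper <- slack(dm - g)
  s_two <- slack((1 + epsilon) * dm - g)
  structure(list(
    loewner_lower_ok = s_lower >= -tol,
    loewner_upper_ok = s_upper >= -tol,
    two_sided_ok = s_two >= -tol,
    min_eigenvalue_slacks = c(lower = s_lower, upper = s_upper,
                              two_sided = s_two),
    tol = tol,
    epsilon = epsilon,
    frobenius = NULL),
    class = "bound_report")
}

#' Verify the Frobenius-norm guarantee of a DCSS selection
#'
#' Checks `(1 - eps) ||A_k||_F^2 <= ||C||_F^2 <= ||A||_F^2` with relative
#' tolerance `1e-10`. When `A` is column-mean centered, squared Frobenius
#' norms are total empirical variances, so the bound says the submatrix
#' retains at least a `(1 - eps)` share of the rank-k variance.
#'
#' @inheritParams verify_spectral_bounds
#' @param report optional `bound_report` to attach the result to.
#' @return a `bound_report` whose `frobenius` element is a list
#'   `(frob_a2, frob_ak2, frob_c2, lower_ok, upper_ok)` of the three
#'   squared norms and the two verdicts.
#' @export
verify_frobenius_bound <- function(a, f, selection, epsilon, report = NULL) {
  stopifnot(inherits(f, "rank_k_factorization"))
  a <- as_expr_matrix(a, check_nonneg = FALSE)
  m <- as.matrix(a)
  idx <- selection_indices(selection)
  frob_a2 <- sum(m^2)
  frob_ak2 <- sum(f$d^2)
  frob_c2 <- sum(m[, idx, drop = FALSE]^2)
  rel <- 1e-10 * max(frob_a2, 1)
  frob <- list(frob_a2 = frob_a2, frob_ak2 = frob_ak2, frob_c2 = frob_c2,
               lower_ok = frob_c2 >= (1 - epsilon) * frob_ak2 - rel,
               upper_ok = frob_c2 <= frob_a2 + rel)
  if (is.null(report)) {
    report <- structure(list(loewner_lower_ok = NA, loewner_upper_ok = NA,
                             two_sided_ok = NA, min_eigenvalue_slacks = NULL,
                             tol = NA_real_, epsilon = epsilon,
                             frobenius = frob),
                        class = "bound_report")
  } else {
    report$frobenius <- frob
  }
  report
}

#' Full bound report for a selection
#'
#' Convenience wrapper running [verify_spectral_bounds()] and
#' [verify_frobenius_bound()] together.
#'
#' @inheritParams verify_spectral_bounds
#' @return a `bound_report` with both spectral and Frobenius verdicts.
#' @export
verify_dcss <- function(a, f, selection, epsilon, tol = NULL) {
  rep <- verify_spectral_bounds(a, f, selection, epsilon, tol)
  verify_frobenius_bound(a, f, selection, epsilon, report = rep)
}

#' @export
print.bound_report <- function(x, ...) {
  ok <- function(b) if (isTRUE(b)) "ok" else if (isFALSE(b)) "VIOLATED" else "n/a"
  cat("<bound_report>\n")
  cat(sprintf("  Loewner lower (1-eps):  %s (slack %.3g)\n",
              ok(x$loewner_lower_ok), x$min_eigenvalue_slacks["lower"]))
  cat(sprintf("  Loewner upper:          %s (slack %.3g)\n",
              ok(x$loewner_upper_ok), x$min_eigenvalue_slacks["upper"]))
  cat(sprintf("  Two-sided (1+eps):      %s (slack %.3g)\n",
              ok(x$two_sided_ok), x$min_eigenvalue_slacks["two_sided"]))
  if (!is.null(x$frobenius)) {
    cat(sprintf("  Frobenius: ||C||^2 = %.6g in [(1-eps)||A_k||^2 = %.6g, ||A||^2 = %.6g]: %s/%s\n",
                x$frobenius$frob_c2, (1 - x$epsilon) * x$frobenius$frob_ak2,
                x$frobenius$frob_a2, ok(x$frobenius$lower_ok),
                ok(x$frobenius$upper_ok)))
  }
  invisible(x)
}

#' @describeIn verify_dcss TRUE iff every verdict in a report passed.
#' @param x a `bound_report`.
#' @export
all_bounds_ok <- function(x) {
  stopifnot(inherits(x, "bound_report"))
  core <- isTRUE(x$loewner_lower_ok) && isTRUE(x$loewner_upper_ok) &&
    isTRUE(x$two_sided_ok)
  if (!is.null(x$frobenius)) {
    core <- core && isTRUE(x$frobenius$lower_ok) && isTRUE(x$frobenius$upper_ok)
  }
  core
}

#' Power-law fit to a sorted leverage profile
#'
#' Sorted leverage profiles of expression matrices typically decay like
#' `tau_(i) ~ b * i^(-a)` in the 1-based sorted index `i`. The decay rate
#' `a` feeds the predicted-selection-size formula
#' ([predicted_dcss_size()]), which is only valid for `a > 1`. The fit is
#' ordinary least squares of `log tau` on `log i` over the top `n_top`
#' sorted scores; `a` is reported positive for decay (the negated slope),
#' and R-squared on the log-log scale lets the user judge how reasonable
#' the power-law assumption is.
#'
#' @param profile a `leverage_profile`.
#' @param n_top number of top-ranked scores to fit (`>= 3`, all strictly
#'   positive).
#' @return object of class `"power_law_fit"`: list with `a` (decay
#'   exponent, positive for decay), `b` (prefactor), `r_squared`,
#'   `n_top`.
#' @export
fit_power_law <- function(profile, n_top) {
  stopifnot(inherits(profile, "leverage_profile"))
  n_top <- as.integer(n_top)
  if (length(n_top) != 1L || is.na(n_top) || n_top < 3L) {
    stop("n_top must be an integer >= 3")
  }
  if (n_top > length(profile$scores)) stop("n_top exceeds number of columns")
  s <- profile$scores[profile$order][seq_len(n_top)]
  if (any(s <= 0)) {
    stop(sprintf("fit requires strictly positive scores; only %d of the top %d are positive",
                 sum(s > 0), n_top))
  }
  x <- log(seq_len(n_top))
  y <- log(s)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  r2 <- if (ss_tot <= 1e-28) 1 else 1 - ss_res / ss_tot
  structure(list(a = unname(-co[2L]), b = unname(exp(co[1L])),
                 r_squared = r2, n_top = n_top),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> tau_(i) ~ %.4g * i^(-%.4g), R^2 = %.4f (top %d)\n",
              x$b, x$a, x$r_squared, x$n_top))
  invisible(x)
}

#' Predicted DCSS selection size under power-law decay
#'
#' For an exactly power-law profile with decay exponent `a > 1`, the
#' number of columns DCSS selects is
#' `max((2k/eps)^(1/(a-1)), (2k(a-1)/eps)^(1/(a-1)) - 1, k)`.
#'
#' @param k rank.
#' @param epsilon error tolerance, `> 0`.
#' @param a power-law decay exponent, must exceed 1.
#' @return list with `size` (ceiling, integer) and `raw` (the real value
#'   of the max).
#' @examples
#' predicted_dcss_size(2, 0.2, 2)$size  # 20
#' @export
predicted_dcss_size <- function(k, epsilon, a) {
  if (!is.numeric(a) || length(a) != 1L || a <= 1) {
    stop("the size formula requires decay exponent a > 1")
  }
  if (epsilon <= 0) stop("epsilon must be positive")
  if (k < 1) stop("k must be >= 1")
  p <- 1 / (a - 1)
  raw <- max((2 * k / epsilon)^p, (2 * k * (a - 1) / epsilon)^p - 1, k)
  list(size = as.integer(ceiling(raw)), raw = raw)
}

#' Random-sampling column count for the same spectral accuracy
#'
#' The number of with-replacement leverage-score draws sufficient for the
#' two-sided spectral bound to hold with failure probability `delta`:
#' `t >= (2/eps^2) (k + m*gamma) (1 + eps/3) ln(16k/delta)`, where `m` is
#' the number of zero-leverage columns and `gamma` the smallest non-zero
#' leverage score.
#'
#' @param k rank.
#' @param epsilon accuracy, `> 0`.
#' @param delta failure probability, in (0, 1).
#' @param m number of zero-leverage columns (default 0).
#' @param gamma minimum non-zero leverage score (default 0).
#' @return the bound (a real number of draws).
#' @export
random_sampling_size <- function(k, epsilon, delta, m = 0, gamma = 0) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta >= 1) {
    stop("delta must lie in (0, 1)")
  }
  if (epsilon <= 0) stop("epsilon must be positive")
  if (k < 1) stop("k must be >= 1")
  (2 / epsilon^2) * (k + m * gamma) * (1 + epsilon / 3) * log(16 * k / delta)
}

#' @describeIn random_sampling_size TRUE when the deterministic selection
#'   is predicted to need fewer columns than random sampling at the same
#'   accuracy.
#' @param a power-law decay exponent (`> 1`).
#' @export
dcss_beats_sampling <- function(k, epsilon, a, delta, m = 0, gamma = 0) {
  predicted_dcss_size(k, epsilon, a)$raw <
    random_sampling_size(k, epsilon, delta, m, gamma)
}

#' Log-likelihood of columns under the degenerate-Gaussian model
#'
#' Interpreting the columns `a_i` as i.i.d. draws from the degenerate
#' multivariate normal `N(0, A_k A_k')`, the log-likelihood of a set of
#' `c` columns is
#' `-(k c / 2) log(2 pi) - c * sum_j log(sigma_j) - (1/2) sum tau_i`
#' over the columns in the set — the leverage scores are exactly the
#' per-column Mahalanobis terms. This is the statistical reading of DCSS:
#' keeping the highest-leverage columns discards the least likelihood.
#'
#' @param f a `rank_k_factorization`.
#' @param columns 1-based column indices, or `NULL` for all columns.
#' @return the log-likelihood (a finite number).
#' @export
log_likelihood <- function(f, columns = NULL) {
  stopifnot(inherits(f, "rank_k_factorization"))
  tau <- rowSums(f$v^2)
  d <- length(tau)
  if (is.null(columns)) columns <- seq_len(d)
  columns <- as.integer(columns)
  if (any(columns < 1L) || any(columns > d)) stop("column index out of range")
  cc <- length(columns)
  -(f$k * cc / 2) * log(2 * pi) - cc * sum(log(f$d)) -
    0.5 * sum(tau[columns])
}

#' Likelihood identity between the full matrix and a DCSS submatrix
#'
#' Under the degenerate-Gaussian model the submatrix and full-matrix
#' likelihoods are linked exactly:
#' `log L(C) = log L(A) + eps_realized/2 + (k (d - s) / 2) log(2 pi)
#'  + (d - s) sum_j log(sigma_j)` with `s = |Theta|`. Both sides are
#' computed independently and the residual reported; it should vanish to
#' numerical precision for any DCSS selection, and the realized error
#' satisfies `eps_realized < epsilon` whenever no forced fill occurred
#' (the submatrix preserves total likelihood up to a factor below
#' `exp(epsilon/2)` and a normalization constant).
#'
#' @param f the `rank_k_factorization` the selection was computed from.
#' @param selection a `dcss_selection`.
#' @param tol residual tolerance for the `identity_ok` verdict.
#' @return object of class `"likelihood_report"`: list with `log_l_a`,
#'   `log_l_c`, `epsilon_realized`, `identity_residual`, `identity_ok`,
#'   `epsilon_ok` (`NA` when forced fill makes the epsilon comparison
#'   inapplicable).
#' @export
likelihood_identity_check <- function(f, selection, tol = 1e-6) {
  stopifnot(inherits(f, "rank_k_factorization"),
            inherits(selection, "dcss_selection"))
  d <- nrow(f$v)
  s <- selection$size
  ll_a <- log_likelihood(f)
  ll_c <- log_likelihood(f, selection$indices)
  rhs <- ll_a + selection$epsilon_realized / 2 +
    (f$k * (d - s) / 2) * log(2 * pi) + (d - s) * sum(log(f$d))
  res <- ll_c - rhs
  structure(list(log_l_a = ll_a, log_l_c = ll_c,
                 epsilon_realized = selection$epsilon_realized,
                 identity_residual = res,
                 identity_ok = abs(res) < tol,
                 epsilon_ok = if (selection$forced_fill) NA else
                   selection$epsilon_realized < selection$epsilon),
            class = "likelihood_report")
}

#' @export
print.likelihood_report <- function(x, ...) {
  cat(sprintf("<likelihood_report> logL(A) = %.6g, logL(C) = %.6g\n",
              x$log_l_a, x$log_l_c))
  cat(sprintf("  identity residual = %.3g (%s), realized error = %.6g\n",
              x$identity_residual, if (x$identity_ok) "ok" else "VIOLATED",
              x$epsilon_realized))
  invisible(x)
}

#' Eigenvalue spectrum of the cell-cell Gram matrix
#'
#' Returns the leading eigenvalues of `A A'` (squared singular values of
#' `A`), the quantity examined when choosing the rank `k` by the "elbow"
#' heuristic. No automatic elbow detection is attempted — the choice is
#' the analyst's — but the index with the largest consecutive eigenvalue
#' ratio is reported as a hint (ratios are only considered down to the
#' numerical rank; near-zero trailing eigenvalues are clamped so noise
#' beyond the rank cannot win).
#'
#' @param a an `expr_matrix` or matrix.
#' @param k_max number of leading eigenvalues to return (default
#'   `min(n, d)`).
#' @return list with `eigenvalues` (descending, length `<= k_max`),
#'   `hint_k` (index of largest consecutive ratio), `numerical_rank`.
#' @export
eigenvalue_scan <- function(a, k_max = NULL) {
  a <- as_expr_matrix(a, check_nonneg = FALSE)
  m <- as.matrix(a)
  sv <- svd(m, nu = 0, nv = 0)$d
  ev <- sv^2
  if (is.null(k_max)) k_max <- length(ev)
  k_max <- min(as.integer(k_max), length(ev))
  if (k_max < 1L) stop("k_max must be >= 1")
  r <- sum(sv > 1e-10 * sv[1L])
  hint <- NA_integer_
  n_ratio <- min(k_max, length(ev) - 1L, r)
  if (n_ratio >= 1L) {
    floor_ev <- 1e-12 * ev[1L]
    ratios <- ev[seq_len(n_ratio)] / pmax(ev[seq_len(n_ratio) + 1L], floor_ev)
    hint <- which.max(ratios)
  }
  list(eigenvalues = ev[seq_len(k_max)], hint_k = hint, numerical_rank = r)
}
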