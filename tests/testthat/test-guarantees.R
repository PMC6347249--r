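test_that("spectral bounds hold for DCSS and detect corrupted selections", {
  toy <- toy_matrix()
  f <- rank_k_factorize(toy, 2)
  sel <- dcss_select(leverage_scores(f), 0.3)
  rep <- verify_spectral_bounds(toy, f, sel, 0.3)
  expect_true(rep$loewner_lower_ok)
  expect_true(rep$loewner_upper_ok)
  expect_true(rep$two_sided_ok)

  # full selection: G = D exactly, slacks tight at zero or positive
  full <- verify_spectral_bounds(toy, f, 1:3, 0.3)
  expect_true(all_bounds_ok(verify_frobenius_bound(toy, f, 1:3, 0.3,
                                                   report = full)))
  expect_gte(full$min_eigenvalue_slacks["upper"], -full$tol)

  # dropping the tau = 1 column keeps only 1.0 of the needed 1.4 mass:
  # the lower Loewner bound must fail
  bad <- verify_spectral_bounds(toy, f, c(1L, 2L), 0.3)
  expect_false(bad$loewner_lower_ok)
  expect_lt(bad$min_eigenvalue_slacks["lower"], -bad$tol)
})

test_that("the k-dimensional check equals the dense projected statement", {
  a <- expr_matrix(rand_count_matrix(8, 20, seed = 31))
  f <- rank_k_factorize(a, 3)
  sel <- dcss_select(leverage_scores(f), 0.2)
  m <- as.matrix(a)
  cm <- m[, sel$indices]
  proj <- f$u %*% t(f$u)
  lhs_dense <- proj %*% cm %*% t(cm) %*% proj        # n x n statement
  akakt <- f$u %*% diag(f$d^2) %*% t(f$u)
  dense_slack <- min(eigen(lhs_dense - (1 - 0.2) * akakt,
                           symmetric = TRUE, only.values = TRUE)$values)
  rep <- verify_spectral_bounds(a, f, sel, 0.2)
  # both formulations agree on the minimum slack (up to the n - k zero
  # eigenvalues the dense form carries, which cap the slack at 0)
  expect_equal(min(rep$min_eigenvalue_slacks["lower"], 0),
               min(dense_slack, 0), tolerance = 1e-6 * f$d[1]^2)
})

test_that("Frobenius bound brackets the submatrix mass on the worked example", {
  toy <- toy_matrix()
  f <- rank_k_factorize(toy, 2)
  sel <- dcss_select(leverage_scores(f), 0.3)
  rep <- verify_frobenius_bound(toy, f, sel, 0.3)
  expect_equal(rep$frobenius$frob_a2, 2825)
  expect_equal(rep$frobenius$frob_ak2, 2825, tolerance = 1e-8)  # full rank
  expect_equal(rep$frobenius$frob_c2, 2325)  # columns 3 and 1: 325 + 2000
  expect_true(rep$frobenius$lower_ok)
  expect_true(rep$frobenius$upper_ok)
  # epsilon -> 0 at full rank forces the full selection, norms equal
  tiny <- dcss_select(leverage_scores(f), 1e-9)
  rep2 <- verify_frobenius_bound(toy, f, tiny, 1e-9)
  expect_equal(rep2$frobenius$frob_c2, rep2$frobenius$frob_a2)
})

test_that("randomized grid: every DCSS run passes all bound checks", {
  for (rep_i in 1:15) {
    set.seed(400 + rep_i)
    n <- sample(8:30, 1)
    d <- sample(20:100, 1)
    a <- expr_matrix(rand_count_matrix(n, d, lambda = 5, seed = 500 + rep_i))
    for (k in c(2, 4, 6)) {
      f <- rank_k_factorize(a, k)
      p <- leverage_scores(f)
      for (eps in c(0.05, 0.1, 0.3)) {
        sel <- dcss_select(p, eps)
        expect_true(all_bounds_ok(verify_dcss(a, f, sel, eps)),
                    label = sprintf("bounds n=%d d=%d k=%d eps=%g",
                                    n, d, k, eps))
      }
    }
  }
})

test_that("power-law fit recovers exact and noisy decay exponents", {
  # exact i^-2 decay (k = 1 avoids the clipping regime)
  p <- power_law_profile(100, a = 2, k = 1)
  expect_false(attr(p, "clipped"))
  fit <- fit_power_law(p, 100)
  expect_equal(fit$a, 2, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # constant profile: zero slope
  flat <- dcss:::new_leverage_profile(rep(0.1, 30), 3)
  expect_equal(fit_power_law(flat, 30)$a, 0, tolerance = 1e-12)

  # multiplicative lognormal noise: exponent recovered within 0.1
  for (s in c(11, 22, 33)) {
    set.seed(s)
    raw <- (1:300)^(-1.5) * exp(rnorm(300, 0, 0.1))
    noisy <- dcss:::new_leverage_profile(3 * raw / sum(raw), 3)
    expect_lt(abs(fit_power_law(noisy, 100)$a - 1.5), 0.1)
  }

  expect_error(fit_power_law(p, 2), "n_top")
  zeros <- dcss:::new_leverage_profile(c(1, 1, 0, 0), 2)
  expect_error(fit_power_law(zeros, 4), "positive")
})

test_that("predicted selection size evaluates the closed form", {
  expect_equal(predicted_dcss_size(2, 0.2, 2)$size, 20L)
  expect_equal(predicted_dcss_size(2, 0.2, 2)$raw, 20)
  expect_equal(predicted_dcss_size(5, 0.1, 2)$size, 100L)
  # a -> infinity: both exponent terms tend to 1, leaving the k floor
  expect_equal(predicted_dcss_size(3, 0.1, 60)$size, 3L)
  expect_error(predicted_dcss_size(2, 0.2, 1), "a > 1")
  expect_error(predicted_dcss_size(2, -0.1, 2), "epsilon")

  # consistency: on power-law profiles the realized selection is no
  # larger than the prediction (+1 for ceiling effects)
  p2 <- power_law_profile(500, a = 1.5, k = 2)
  expect_false(attr(p2, "clipped"))
  sel <- dcss_select(p2, 0.2)
  expect_lte(sel$size, predicted_dcss_size(2, 0.2, 1.5)$size + 1)
})

test_that("random-sampling size bound and comparison predicate", {
  expect_equal(random_sampling_size(2, 0.2, 0.1),
               50 * 2 * (1 + 0.2 / 3) * log(320), tolerance = 1e-12)
  expect_equal(random_sampling_size(2, 0.2, 0.1), 615.2876, tolerance = 1e-4)
  expect_true(dcss_beats_sampling(2, 0.2, 2, 0.1))
  # monotone decreasing in delta
  ts <- vapply(c(0.01, 0.1, 0.5, 0.9),
               function(dd) random_sampling_size(2, 0.2, dd), numeric(1))
  expect_true(all(diff(ts) < 0))
  # m zero-leverage columns inflate the bound
  expect_gt(random_sampling_size(2, 0.2, 0.1, m = 10, gamma = 0.05),
            random_sampling_size(2, 0.2, 0.1))
  expect_error(random_sampling_size(2, 0.2, 1.5), "delta")
  expect_error(random_sampling_size(2, 0, 0.1), "epsilon")
})

test_that("degenerate-Gaussian likelihood identity holds exactly", {
  toy <- toy_matrix()
  f <- rank_k_factorize(toy, 2)
  p <- leverage_scores(f)
  # exponent terms: -tau/2 summed over the columns considered
  norm_const <- function(cols) -(f$k * cols / 2) * log(2 * pi) -
    cols * sum(log(f$d))
  expect_equal(log_likelihood(f) - norm_const(3), -1)          # sum tau = k
  expect_equal(log_likelihood(f, c(3, 1)) - norm_const(2), -0.9)

  sel <- dcss_select(p, 0.3)
  lik <- likelihood_identity_check(f, sel)
  expect_lt(abs(lik$identity_residual), 1e-6)
  expect_true(lik$identity_ok)
  expect_true(lik$epsilon_ok)
  expect_equal(lik$epsilon_realized, 0.2, tolerance = 1e-10)

  # full selection: epsilon_realized = 0, L(C) = L(A)
  full <- dcss_select(p, 1e-9)
  lik_full <- likelihood_identity_check(f, full)
  expect_equal(lik_full$epsilon_realized, 0, tolerance = 1e-10)
  expect_equal(lik_full$log_l_a, lik_full$log_l_c)

  # optimality: among the 2-column subsets, DCSS carries the most mass
  combos <- combn(3, 2)
  masses <- apply(combos, 2, function(cc) sum(p$scores[cc]))
  expect_equal(max(masses), sum(p$scores[sel$indices]), tolerance = 1e-12)
})

test_that("eigenvalue scan reports the spectrum and a gap hint", {
  toy <- toy_matrix()
  es <- eigenvalue_scan(toy)
  expect_equal(sum(es$eigenvalues), 2825, tolerance = 1e-8)  # trace identity
  expect_equal(es$numerical_rank, 2L)

  r1 <- outer(c(1, 2, 3), c(4, 5, 6, 7))
  es1 <- eigenvalue_scan(r1)
  expect_equal(es1$hint_k, 1L)
  expect_equal(es1$numerical_rank, 1L)

  # planted rank-3 structure with a strong eigengap
  set.seed(77)
  u <- qr.Q(qr(matrix(rnorm(60), 20, 3)))
  v <- qr.Q(qr(matrix(rnorm(150), 50, 3)))
  planted <- u %*% diag(c(100, 70, 50)) %*% t(v) +
    matrix(rnorm(1000, sd = 0.5), 20, 50)
  es3 <- eigenvalue_scan(expr_matrix(planted, check_nonneg = FALSE), 10)
  expect_equal(es3$hint_k, 3L)
})
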