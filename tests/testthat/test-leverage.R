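test_that("rank-k factorization returns valid, deterministic factors", {
  a <- expr_matrix(rand_count_matrix(8, 15, seed = 3))
  f <- rank_k_factorize(a, 4)
  expect_s3_class(f, "rank_k_factorization")
  expect_equal(crossprod(f$u), diag(4), tolerance = 1e-8)
  expect_equal(crossprod(f$v), diag(4), tolerance = 1e-8)
  expect_true(all(diff(f$d) <= 1e-12))
  expect_true(all(f$d > 0))
  # reconstruction is the best rank-k approximation (svd truncation)
  sv <- svd(as.matrix(a))
  ak <- f$u %*% (f$d * t(f$v))
  best <- sv$u[, 1:4] %*% diag(sv$d[1:4]) %*% t(sv$v[, 1:4])
  expect_equal(ak, best, tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: dominant entry of each right vector positive, and
  # two runs agree exactly
  for (j in 1:4) expect_gt(f$v[which.max(abs(f$v[, j])), j], 0)
  f2 <- rank_k_factorize(a, 4)
  expect_identical(f$v, f2$v)

  expect_equal(rank_k_factorize(diag(3), 3)$d, rep(1, 3))
  toy <- toy_matrix()
  expect_equal(sum(rank_k_factorize(toy, 2)$d^2), 2825)  # Frobenius mass
  expect_error(rank_k_factorize(toy, 3), "k must be")  # k > min(n, d)
  expect_error(rank_k_factorize(toy, 0), "k must be")
  # square but rank-deficient: the achievable rank is named
  deficient <- cbind(c(1, 2, 3), c(2, 4, 6), c(1, 0, 1))
  expect_error(rank_k_factorize(deficient, 3), "rank deficient.*rank is 2")
})

test_that("toy-matrix leverage scores match the pseudoinverse definition", {
  toy <- toy_matrix()
  expected <- c(0.8, 0.2, 1.0)  # frozen from a_i' (A A')^+ a_i by hand
  for (fn in list(function() leverage_scores(rank_k_factorize(toy, 2)),
                  function() leverage_scores_pinv_oracle(toy, 2),
                  function() leverage_scores_lsq_oracle(toy, 2))) {
    p <- fn()
    expect_equal(p$scores, expected, tolerance = 1e-10)
    expect_equal(sum(p$scores), 2, tolerance = 1e-10)
  }
  expect_equal(sum(leverage_scores_pinv_oracle(toy, 1)$scores), 1,
               tolerance = 1e-8)
  # collinear pair splits one unit of leverage; independent column gets 1
  expect_equal(expected[1] + expected[2], 1)
  # identity: every column is its own direction
  p_id <- leverage_scores(rank_k_factorize(diag(5), 5))
  expect_equal(p_id$scores, rep(1, 5))
})

test_that("three leverage implementations agree on random matrices", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(4:20, 1)
    d <- sample(6:60, 1)
    k <- sample(seq_len(min(n, d, 8)), 1)
    a <- expr_matrix(rand_real_matrix(n, d, seed = 100 + rep),
                     check_nonneg = FALSE)
    p_fast <- leverage_scores(rank_k_factorize(a, k))
    p_pinv <- leverage_scores_pinv_oracle(a, k)
    p_lsq <- leverage_scores_lsq_oracle(a, k)
    expect_equal(p_fast$scores, p_pinv$scores, tolerance = 1e-8)
    expect_equal(p_pinv$scores, p_lsq$scores, tolerance = 1e-8)
    expect_equal(sum(p_fast$scores), k, tolerance = 1e-8)
    expect_true(all(p_fast$scores >= -1e-12 & p_fast$scores <= 1 + 1e-12))
  }
})

test_that("leverage scores are scale invariant and sorted stably", {
  a <- rand_count_matrix(10, 25, seed = 7)
  p1 <- leverage_scores(rank_k_factorize(a, 3))
  p2 <- leverage_scores(rank_k_factorize(a * 17.5, 3))
  expect_equal(p1$scores, p2$scores, tolerance = 1e-9)
  # permutation sorts descending with ties by ascending index
  expect_setequal(p1$order, seq_along(p1$scores))
  s <- p1$scores[p1$order]
  expect_true(all(diff(s) <= 1e-12))
  tied <- new_tied_profile <- dcss:::new_leverage_profile(c(0.5, 0.5, 1), 2)
  expect_equal(tied$order, c(3L, 1L, 2L))
  # zero column carries zero leverage (least-squares formulation)
  az <- cbind(rand_count_matrix(6, 4, seed = 9), 0)
  pz <- leverage_scores_lsq_oracle(expr_matrix(az), 2)
  expect_equal(pz$scores[5], 0, tolerance = 1e-12)
})

test_that("custom-subspace scores generalize the leading-k subspace", {
  toy <- toy_matrix()
  expect_equal(leverage_scores_custom_subspace(toy, c(1, 2))$scores,
               leverage_scores(rank_k_factorize(toy, 2))$scores,
               tolerance = 1e-10)
  p2 <- leverage_scores_custom_subspace(toy, 2)
  expect_equal(sum(p2$scores), 1, tolerance = 1e-10)
  expect_error(leverage_scores_custom_subspace(toy, 3), "numerical rank")

  # differs from component 1, and matches a pinv oracle built from the
  # selected singular direction alone
  a <- rand_real_matrix(10, 20, seed = 11)
  p_c1 <- leverage_scores_custom_subspace(a, 1)
  p_c2 <- leverage_scores_custom_subspace(a, 2)
  expect_gt(max(abs(p_c1$scores - p_c2$scores)), 1e-3)
  sv <- svd(a)
  a_sub <- sv$u[, 2, drop = FALSE] %*% (sv$d[2] * t(sv$v[, 2, drop = FALSE]))
  gram_pinv <- MASS::ginv(tcrossprod(a_sub))
  tau_oracle <- apply(a, 2, function(ai) drop(crossprod(ai, gram_pinv %*% ai)))
  expect_equal(p_c2$scores, tau_oracle, tolerance = 1e-8)
})

test_that("column centering zeroes the means and is idempotent", {
  toy <- toy_matrix()
  cen <- center_columns(toy)
  expect_equal(unname(cen$mu), c(30, 15, 12.5))
  expect_equal(as.matrix(cen$centered)[, 1], c(cell_1 = 10, cell_2 = -10))
  expect_true(all(abs(colSums(as.matrix(cen$centered))) < 1e-10))
  again <- center_columns(cen$centered)
  expect_equal(as.matrix(again$centered), as.matrix(cen$centered),
               tolerance = 1e-12)
  expect_true(all(abs(again$mu) < 1e-12))
})

test_that("expression matrix container validates its invariants", {
  expect_error(expr_matrix(matrix(c(1, NA, 2, 3), 2)), "finite")
  expect_error(expr_matrix(matrix(c(1, -1, 2, 3), 2)), "negative")
  m <- matrix(c(1, -1, 2, 3), 2)
  expect_silent(expr_matrix(m, check_nonneg = FALSE))
  expect_error(expr_matrix(diag(2), cell_ids = c("a", "a")), "unique")
  expect_error(expr_matrix(diag(2), feature_ids = "x"), "length")
  sp <- Matrix::sparseMatrix(i = 1, j = 2, x = 3, dims = c(2, 3))
  a <- expr_matrix(sp)
  expect_true(inherits(a$values, "sparseMatrix"))
  expect_equal(dim(a), c(2L, 3L))
})
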