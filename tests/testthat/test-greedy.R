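test_that("select_columns maximizes correlation with deterministic ties", {
  A <- cbind(c(1, 0), c(0, 1), c(1, 1) / sqrt(2))
  expect_identical(select_columns(A, c(2, 0), 1), 1L)

  # zero residual: all tie, lowest indices win
  expect_identical(select_columns(A, c(0, 0), 2), c(1L, 2L))

  expect_error(select_columns(A, c(1, 0), 4), "exceed")
})

test_that("least_squares_on_support solves the normal equations", {
  # orthonormal columns: projection coefficients
  psi <- as.matrix(dct_basis(8))[, 1:3]
  set.seed(41)
  y <- rnorm(8)
  expect_equal(least_squares_on_support(psi, y, 1:3),
               drop(crossprod(psi, y)), tolerance = 1e-12)

  # y in the span: zero residual
  A <- gaussian_matrix(6, 8, seed = 42)
  h0 <- c(1.5, -2)
  y <- drop(A[, c(2, 5)] %*% h0)
  h <- least_squares_on_support(A, y, c(2, 5))
  expect_equal(h, h0, tolerance = 1e-10)

  # local optimality against random perturbations
  y <- rnorm(6)
  cols <- c(1, 3, 4)
  h <- least_squares_on_support(A, y, cols)
  base <- sum((y - A[, cols] %*% h)^2)
  for (i in 1:100) {
    expect_lte(base, sum((y - A[, cols] %*% (h + rnorm(3, sd = 0.1)))^2))
  }

  expect_error(least_squares_on_support(A, y, 1:7), "underdetermined")

  # rank-deficient support: minimum-norm solution, flagged
  A_dup <- cbind(A[, 1], A[, 1], A[, 2])
  h <- least_squares_on_support(A_dup, y, 1:3)
  expect_true(isTRUE(attr(h, "rank_deficient")))
  expect_equal(h[1], h[2], tolerance = 1e-8)
})

test_that("OMP recovers exactly on orthonormal and aligned cases", {
  res <- omp_reconstruct(diag(4), c(0, 3, 0, -1), k = 2)
  expect_equal(res$x, c(0, 3, 0, -1))
  expect_identical(res$support, c(2L, 4L))
  expect_lt(tail(res$residual_trace, 1), 1e-12)

  # one column parallel to y
  A <- cbind(c(1, 1) / sqrt(2), c(1, 0))
  y <- c(2, 2)
  res <- omp_reconstruct(A, y, k = 1)
  expect_identical(res$support, 1L)
  expect_lt(tail(res$residual_trace, 1), 1e-12)

  expect_error(omp_reconstruct(A, y, k = 3), "exceed")
})

test_that("OMP support matches the exhaustive l0 oracle on well-conditioned instances", {
  tested <- 0L
  for (seed in 1:30) {
    if (tested >= 5L) break
    A <- gaussian_matrix(8, 12, seed = 400 + seed)
    set.seed(500 + seed)
    sup_true <- sort(sample(12, 2))
    if (!erc_holds(A, sup_true)) next  # keep only well-conditioned cases
    tested <- tested + 1L
    x_star <- numeric(12)
    x_star[sup_true] <- c(1.3, -0.8) * sample(c(-1, 1), 2, replace = TRUE)
    y <- drop(A %*% x_star)
    # exhaustive l0 search over all size-2 supports
    refit_err <- combn(12, 2, function(sup) {
      h <- least_squares_on_support(A, y, sup)
      sqrt(sum((y - A[, sup] %*% h)^2))
    })
    all_sup <- combn(12, 2)
    oracle <- sort(all_sup[, which.min(refit_err)])
    res <- omp_reconstruct(A, y, k = 2)
    expect_identical(res$support, as.integer(oracle))
    expect_lt(rel_err(res$x, x_star), 1e-8)
  }
  expect_gte(tested, 3L)  # the seed pool must yield enough valid cases
})

test_that("OMP residuals are orthogonal to the active set and non-increasing", {
  prob <- make_problem(N = 64, M = 32, k = 10, seed = 43)
  res <- omp_reconstruct(prob$A, prob$y, k = 10)
  expect_identical(length(res$support), 10L)
  r <- prob$y - drop(prob$A %*% res$x)
  for (j in res$support) {
    expect_lt(abs(sum(prob$A[, j] * r)),
              1e-8 * max(sqrt(sum(r^2)), 1e-12) * sqrt(sum(prob$A[, j]^2)))
  }
  expect_true(all(diff(res$residual_trace) <= 1e-12))
})

test_that("CoSaMP recovers k-sparse signals and honors its clamps", {
  # orthonormal case: one iteration
  psi <- as.matrix(dct_basis(16))
  x_star <- numeric(16); x_star[c(3, 9)] <- c(2, -1)
  y <- drop(psi %*% x_star)
  res <- cosamp_reconstruct(psi, y, k = 2)
  expect_lt(tail(res$residual_trace, 1), 1e-10)
  expect_equal(res$x, x_star, tolerance = 1e-10)

  # gamma = 0 clamps the selection width to one column and still runs
  prob <- make_problem(N = 32, M = 16, k = 3, seed = 44, basis = haar_basis)
  res0 <- cosamp_reconstruct(prob$A, prob$y, k = 3, gamma = 0)
  expect_lt(rel_err(res0$x, prob$x_star), 1e-6)

  # k + kS > M: clamped with a warning flag instead of aborting
  res_cl <- cosamp_reconstruct(prob$A, prob$y, k = 12, gamma = 1)
  expect_match(paste(res_cl$warnings, collapse = " "), "clamped")
  expect_lte(sum(res_cl$x != 0), 12)

  expect_error(cosamp_reconstruct(prob$A, prob$y, k = 20), "exceed")
  expect_error(cosamp_reconstruct(prob$A, prob$y, k = 2, gamma = 1.5), "gamma")
})

test_that("CoSaMP Monte-Carlo recovery on Bernoulli x Haar instances", {
  ok <- 0L
  for (seed in 1:100) {
    prob <- make_problem(N = 64, M = 32, k = 4, seed = 4000 + seed,
                         basis = haar_basis)
    res <- cosamp_reconstruct(prob$A, prob$y, k = 4, gamma = 0.5)
    if (rel_err(res$x, prob$x_star) < 1e-6) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("NIHT step vector and scalar step match their closed forms", {
  A_unit <- as.matrix(dct_basis(8))
  expect_equal(niht_step_vector(A_unit), rep(1, 8), tolerance = 1e-12)

  A2 <- cbind(c(1, 0), c(0, 2))
  expect_equal(niht_step_vector(A2), c(1, 0.5))
  expect_equal(max(niht_step_vector(gaussian_matrix(6, 10, seed = 45))), 1)
  expect_error(niht_step_vector(cbind(c(1, 0), c(0, 0))), "zero column")

  # orthonormal square, full support: one exact step
  Q <- qr.Q(qr(gaussian_matrix(6, 6, seed = 46)))
  y <- rnorm(6)
  x <- rnorm(6)
  q <- drop(crossprod(Q, drop(Q %*% x) - y))  # unnormalized gradient, rho = 1
  mu <- niht_mu(Q, q, x, y, 1:6)
  expect_equal(as.numeric(mu), 1, tolerance = 1e-10)
  expect_lt(sqrt(sum((Q %*% (x - as.numeric(mu) * q) - y)^2)), 1e-10)

  # zero direction: stagnation flag
  mu0 <- niht_mu(Q, rep(0, 6), x, y, 1:6)
  expect_identical(as.numeric(mu0), 0)
  expect_true(isTRUE(attr(mu0, "stagnation")))
})

test_that("NIHT scalar step matches a golden-section line search", {
  golden_mu <- function(A, q, x, y, lam, lo = -10, hi = 10, tol = 1e-10) {
    qs <- restrict_support(q, lam)
    xs <- restrict_support(x, lam)
    obj <- function(mu) sum((drop(A %*% (xs - mu * qs)) - y)^2)
    gr <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
    while (b - a > tol) {
      if (obj(c1) < obj(c2)) b <- c2 else a <- c1
      c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
    }
    (a + b) / 2
  }
  for (seed in 1:5) {
    A <- gaussian_matrix(12, 24, seed = 600 + seed)
    set.seed(700 + seed)
    x <- rnorm(24); y <- rnorm(12); q <- rnorm(24)
    lam <- sort(sample(24, 6))
    mu <- as.numeric(niht_mu(A, q, x, y, lam))
    expect_equal(mu, golden_mu(A, q, x, y, lam), tolerance = 1e-6)
  }
})

test_that("NIHT recovers k-sparse signals and exact orthonormal systems", {
  # orthonormal square, k = N: solved in one iteration
  Q <- qr.Q(qr(gaussian_matrix(8, 8, seed = 47)))
  y <- rnorm(8)
  res <- niht_reconstruct(Q, y, k = 8)
  expect_lt(rel_err(res$x, drop(crossprod(Q, y))), 1e-8)
  expect_lte(res$iterations, 2L)

  ok <- 0L
  n_steps <- 0L; n_increase <- 0L
  for (seed in 1:100) {
    prob <- make_problem(N = 64, M = 32, k = 4, seed = 5000 + seed,
                         basis = haar_basis)
    res <- niht_reconstruct(prob$A, prob$y, k = 4)
    if (rel_err(res$x, prob$x_star) < 1e-4) ok <- ok + 1L
    if (seed <= 20) {
      d <- diff(res$residual_trace)
      n_steps <- n_steps + length(d)
      n_increase <- n_increase + sum(d > 1e-10)
    }
  }
  expect_gte(ok, 90L)
  # accepted outer steps almost never raise the residual
  expect_lte(n_increase / n_steps, 0.01)
})
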