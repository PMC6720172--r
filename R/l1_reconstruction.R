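# Normalized projected-gradient l1-minimization (basis pursuit by projected
# subgradient descent). The iterate stays on the affine feasible set
# {x : A x = y} because the subgradient of the l1 norm is projected onto the
# null space of A before each step; the step size is tied to the desired
# steady-state ripple rather than to the signal power.

#' Initialize the l1 solver: minimum-norm start and null-space projector
#'
#' Computes the pseudo-inverse `A^+ = t(A) (A t(A))^-1`, the feasible
#' starting point `x0 = A^+ y` (the minimum-l2-norm solution of `A x = y`)
#' and the null-space projector `P = I - A^+ A`.
#'
#' @param A M x N sensing operator with full row rank.
#' @param y Measurement vector of length M.
#' @param cond_threshold Conditioning limit on `A t(A)`; a reciprocal
#'   condition estimate below `1/cond_threshold` raises an error.
#' @return A list of class `cs_projector` with fields `x0`, `pinv`
#'   (N x M), `P` (N x N), `rcond`.
#' @export
l1_init <- function(A, y, cond_threshold = 1e12) {
  A <- as.matrix(A)
  if (nrow(A) != length(y)) {
    stop("`y` length does not match the rows of `A`", call. = FALSE)
  }
  AAt <- tcrossprod(A)
  rc <- rcond(AAt)
  if (!is.finite(rc) || rc < 1 / cond_threshold) {
    stop(sprintf(
      "A %%*%% t(A) is numerically singular (reciprocal condition %.3g): cannot form the null-space projector",
      rc
    ), call. = FALSE)
  }
  pinv <- t(solve(AAt, A))              # N x M
  P <- diag(ncol(A)) - pinv %*% A       # N x N
  x0 <- drop(pinv %*% y)
  structure(list(x0 = x0, pinv = pinv, P = P, rcond = rc),
            class = "cs_projector")
}

#' Ripple-bounded step size
#'
#' The convergence parameter `mu` is chosen so the steady-state relative
#' ripple of the iterate stays below `eps_max`:
#' `mu = eps_max * N / ||P sgn(x0)||_2`. Returns 0 when `P sgn(x0) = 0`
#' (the start is already a fixed point and the solver exits immediately).
#'
#' @param eps_max Desired steady-state ripple (relative change per step).
#' @param N Problem dimension.
#' @param P Null-space projector from [l1_init()].
#' @param x0 Starting iterate.
#' @return Scalar step parameter `mu`.
#' @export
l1_step_size <- function(eps_max, N, P, x0) {
  s0 <- sign(x0)
  q0n <- l2(drop(P %*% s0))
  # rounding-level projections (e.g. P = 0 up to float for a square
  # invertible A) are treated as an exact fixed point
  if (q0n <= 1e-12 * max(l2(s0), 1)) return(0)
  eps_max * N / q0n
}

#' Incremental projected-sign update
#'
#' Maintains `q_t = P %*% sgn(x_t)` across iterations by touching only the
#' columns of `P` whose sign entry changed:
#' `q_t = q_{t-1} + sum_{j in Omega_t} P_j (s_t(j) - s_{t-1}(j))`.
#' For entries flipping between -1 and +1 the increment is the classic
#' `2 P_j s_t(j)`; the difference form also stays exact when an entry passes
#' through `sgn(0) = 0`. The result is identical (to rounding) to the direct
#' product `P %*% s_t` at every iteration, at a fraction of the products
#' once the sign pattern stabilizes.
#'
#' @param q_prev Previous projected-sign vector `q_{t-1}`.
#' @param P Null-space projector (its columns are the `P_j`).
#' @param s_t Current sign vector, entries in `{-1, 0, 1}`.
#' @param s_prev Previous sign vector.
#' @return Updated vector `q_t`.
#' @export
l1_update_q <- function(q_prev, P, s_t, s_prev) {
  if (length(s_t) != length(s_prev) || length(s_t) != length(q_prev)) {
    stop("`q_prev`, `s_t` and `s_prev` must have equal length", call. = FALSE)
  }
  changed <- which(s_t != s_prev)
  if (!length(changed)) return(q_prev)
  q_prev + drop(P[, changed, drop = FALSE] %*%
                  (s_t[changed] - s_prev[changed]))
}

#' Projected-gradient l1-minimization reconstruction
#'
#' Iterates the normalized update
#' `x_{t+1} = x_t - mu * (||x_t||_1 / N) * q_t`, with
#' `q_t = P sgn(x_t)` maintained incrementally via [l1_update_q()], starting
#' from the minimum-norm feasible point `x0 = A^+ y`. Every iterate satisfies
#' `A x_t = y` (up to rounding) because `q_t` lies in the null space of `A`.
#' The solver stops when the relative ripple `||x_{t+1}-x_t|| / ||x_t||`
#' stays below `eps_max` for 5 consecutive iterations (a single-iteration
#' ripple is noisy), or after `n_iter` iterations.
#'
#' @param A M x N sensing operator.
#' @param y Measurement vector.
#' @param eps_max Ripple tolerance controlling both the step size and the
#'   stopping rule. Default `1e-3`.
#' @param n_iter Iteration cap. Default 2000.
#' @param k Optional sparsity: when given, the returned coefficients are the
#'   k-term truncation [reduce_k()] of the final iterate (applied on output
#'   only; no least-squares refit unless `refit = TRUE`).
#' @param psi Optional `cs_basis` for basis-weighted truncation and frame
#'   synthesis.
#' @param init Optional precomputed [l1_init()] result for `A` (reused
#'   across calls sharing the sensing operator).
#' @param refit Logical; refit the truncated support by least squares.
#'   Default `FALSE`.
#' @param update_mode `"auto"` (incremental update, falling back to the
#'   direct product on iterations where more than N/8 signs changed),
#'   `"incremental"`, or `"direct"`.
#' @param diagnostics Logical; when `TRUE`, records per-iteration feasibility
#'   `||A x_t - y||_2 / ||y||_2` (attribute `feasibility_trace`), the
#'   per-iteration l1 norm of the iterate (attribute `l1_trace`) and the
#'   deviation `max|q_t - P sgn(x_t)|` of the maintained update from the
#'   direct product (attribute `q_deviation`).
#' @return A `cs_reconstruction`; `residual_trace` holds the per-iteration
#'   relative ripple.
#' @export
l1_reconstruct <- function(A, y, eps_max = 1e-3, n_iter = 2000, k = NULL,
                           psi = NULL, init = NULL, refit = FALSE,
                           update_mode = c("auto", "incremental", "direct"),
                           diagnostics = FALSE) {
  update_mode <- match.arg(update_mode)
  stopifnot(eps_max > 0, n_iter >= 1)
  A <- as.matrix(A)
  N <- ncol(A)
  if (is.null(init)) init <- l1_init(A, y)
  P <- init$P
  # x0 depends on y; a cached init may have been built for a different
  # measurement vector, so the feasible start is always recomputed here
  x <- drop(init$pinv %*% y)

  mu <- l1_step_size(eps_max, N, P, x)
  warnings <- character(0)
  ripple_trace <- numeric(0)
  feas_trace <- numeric(0)
  l1_trace <- numeric(0)
  q_dev <- 0
  yn <- l2(y)
  converged <- FALSE
  iterations <- 0L

  if (mu > 0) {
    s_prev <- NULL
    q <- NULL
    consec <- 0L
    for (t in 0:(n_iter - 1L)) {
      s <- sign(x)
      if (t == 0L) {
        q <- drop(P %*% s)
      } else if (update_mode == "direct") {
        q <- drop(P %*% s)
      } else {
        n_changed <- sum(s != s_prev)
        if (update_mode == "auto" && n_changed > N / 8) {
          q <- drop(P %*% s)
        } else {
          q <- l1_update_q(q, P, s, s_prev)
        }
      }
      if (diagnostics) {
        q_dev <- max(q_dev, max(abs(q - drop(P %*% s))))
        feas_trace <- c(feas_trace, l2(drop(A %*% x) - y) / yn)
        l1_trace <- c(l1_trace, sum(abs(x)))
      }
      x_new <- x - mu * sum(abs(x)) / N * q
      ripple <- l2(x_new - x) / l2(x)
      ripple_trace <- c(ripple_trace, ripple)
      x <- x_new
      s_prev <- s
      iterations <- t + 1L
      consec <- if (ripple < eps_max) consec + 1L else 0L
      if (consec >= 5L) {
        converged <- TRUE
        break
      }
    }
  } else {
    # P sgn(x0) = 0: x0 is a fixed point (e.g. M = N, A invertible)
    converged <- TRUE
  }

  support <- NULL
  if (!is.null(k)) {
    xk <- reduce_k(x, k, psi)
    support <- attr(xk, "support")
    if (refit) {
      h <- least_squares_on_support(A, y, support)
      if (isTRUE(attr(h, "rank_deficient"))) {
        warnings <- c(warnings, "rank-deficient refit: minimum-norm solution")
      }
      xk <- restrict_support(replace(numeric(N), support, h), support)
    }
    x <- as.numeric(xk)
  } else {
    support <- which(x != 0)
  }

  out <- new_cs_reconstruction(
    x = x, support = support, algorithm = "l1", iterations = iterations,
    converged = converged, residual_trace = ripple_trace,
    warnings = warnings, psi = psi
  )
  if (diagnostics) {
    attr(out, "feasibility_trace") <- feas_trace
    attr(out, "l1_trace") <- l1_trace
    attr(out, "q_deviation") <- q_dev
  }
  out
}
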