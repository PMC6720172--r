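# Greedy reconstruction algorithms: OMP, CoSaMP and NIHT. All share the
# correlation-based column-selection primitive and a least-squares refit on
# the active support.

#' Select the columns most correlated with a residual
#'
#' Returns the `m` column indices of `A` with largest `|a_j' r|`. Because the
#' objective `||A_W' r||_1` is separable over columns, this is the exact
#' maximizer over all size-`m` subsets. Ties are broken by lower index (an
#' all-zero residual therefore yields `1:m`).
#'
#' @param A M x N sensing operator.
#' @param r Residual vector of length M.
#' @param m Number of columns to select, `1 <= m <= N`.
#' @return Sorted integer vector of `m` indices.
#' @export
select_columns <- function(A, r, m) {
  A <- as.matrix(A)
  m <- check_scalar_count(m, "m")
  if (m > ncol(A)) stop("`m` must not exceed the number of columns",
                        call. = FALSE)
  corr <- abs(drop(crossprod(A, r)))
  sort(order(corr, decreasing = TRUE)[seq_len(m)])
}

#' Least-squares refit on a column subset
#'
#' Minimizes `||y - A[, cols] h||_2` via QR. When `A[, cols]` is
#' rank-deficient the minimum-norm solution is returned (computed by SVD
#' pseudo-inverse) and the result carries attribute `rank_deficient = TRUE`
#' so callers can flag rather than abort.
#'
#' @param A M x N sensing operator.
#' @param y Measurement vector.
#' @param cols Column indices, `length(cols) <= M`.
#' @return Numeric coefficient vector of length `length(cols)` (aligned with
#'   `cols`).
#' @export
least_squares_on_support <- function(A, y, cols) {
  A <- as.matrix(A)
  cols <- as.integer(cols)
  if (length(cols) > nrow(A)) {
    stop("underdetermined refit: more support columns than measurements",
         call. = FALSE)
  }
  Ac <- A[, cols, drop = FALSE]
  qrA <- qr(Ac)
  if (qrA$rank < length(cols)) {
    sv <- svd(Ac)
    pos <- sv$d > max(sv$d[1], 0) * 1e-10
    h <- drop(sv$v[, pos, drop = FALSE] %*%
                ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos]))
    return(structure(h, rank_deficient = TRUE))
  }
  drop(qr.coef(qrA, y))
}

#' Orthogonal matching pursuit
#'
#' Runs exactly `k` iterations: pick the column most correlated with the
#' current residual, merge it into the active set, refit all active
#' coefficients by least squares and update the residual. The refit makes
#' the residual orthogonal to the active columns, so no column is ever
#' selected twice. The normal equations are maintained through a rank-one
#' Cholesky update, so each iteration costs O(MN + t^2) rather than a fresh
#' O(M t^2) factorization.
#'
#' @param A M x N sensing operator.
#' @param y Measurement vector.
#' @param k Sparsity level, `k <= M`.
#' @param psi Optional `cs_basis` for frame synthesis of the result.
#' @return A `cs_reconstruction`; `residual_trace` holds the residual norms
#'   per iteration.
#' @export
omp_reconstruct <- function(A, y, k, psi = NULL) {
  A <- as.matrix(A)
  M <- nrow(A)
  N <- ncol(A)
  k <- check_scalar_count(k, "k")
  if (k > M) stop("`k` must not exceed the number of measurements M",
                  call. = FALSE)
  r <- y
  yn <- l2(y)
  idx <- integer(0)
  Rch <- NULL        # Cholesky factor of crossprod(A[, idx])
  At <- NULL
  xs <- numeric(0)
  trace <- numeric(0)
  warnings <- character(0)
  for (t in seq_len(k)) {
    corr <- abs(drop(crossprod(A, r)))
    if (length(idx)) corr[idx] <- -Inf  # guard against rounding-level ties
    j <- which.max(corr)
    a <- A[, j]
    if (is.null(Rch)) {
      d2 <- sum(a^2)
      if (d2 <= 0) {
        warnings <- c(warnings, "zero column selected; stopped early")
        break
      }
      Rch <- matrix(sqrt(d2), 1L, 1L)
      At <- matrix(a, ncol = 1L)
    } else {
      u <- backsolve(Rch, drop(crossprod(At, a)), transpose = TRUE)
      d2 <- sum(a^2) - sum(u^2)
      if (d2 < 1e-12 * sum(a^2)) {
        warnings <- c(warnings,
                      "selected column numerically dependent on active set; stopped early")
        break
      }
      Rch <- cbind(rbind(Rch, 0), c(u, sqrt(d2)))
      At <- cbind(At, a)
    }
    idx <- c(idx, j)
    xs <- backsolve(Rch, backsolve(Rch, drop(crossprod(At, y)),
                                   transpose = TRUE))
    r <- y - drop(At %*% xs)
    trace <- c(trace, l2(r))
    if (l2(r) <= 1e-13 * yn) break  # exact fit reached
  }
  x <- numeric(N)
  x[idx] <- xs
  new_cs_reconstruction(
    x = x, support = sort(idx), algorithm = "omp",
    iterations = length(trace), converged = TRUE,
    residual_trace = trace, warnings = warnings, psi = psi
  )
}

#' Compressive sampling matching pursuit
#'
#' Each iteration selects the `kS = max(1, round(gamma * k))` columns most
#' correlated with the residual, merges them with the current support,
#' refits by least squares on the merged set, prunes back to the `k` largest
#' (basis-weighted) coefficients and updates the residual. The support is
#' initialized from the raw measurements. When `k + kS` would exceed `M`,
#' `kS` is clamped to `M - k` (and the result flagged) so that the refit
#' stays overdetermined; sweeps over high sparsity ratios then still
#' complete.
#'
#' @param A M x N sensing operator.
#' @param y Measurement vector.
#' @param k Sparsity level, `k <= M`.
#' @param gamma Fraction of `k` selected per iteration, in `[0, 1]`;
#'   `gamma = 0` is clamped to one column. Default 0.5.
#' @param n_iter Iteration cap. Default 50.
#' @param psi Optional `cs_basis` (basis-weighted pruning, frame synthesis).
#' @param tol Relative residual-change stopping tolerance. Default `1e-8`.
#' @return A `cs_reconstruction`.
#' @export
cosamp_reconstruct <- function(A, y, k, gamma = 0.5, n_iter = 50,
                               psi = NULL, tol = 1e-8) {
  A <- as.matrix(A)
  M <- nrow(A)
  N <- ncol(A)
  k <- check_scalar_count(k, "k")
  if (k > M) stop("`k` must not exceed the number of measurements M",
                  call. = FALSE)
  if (gamma < 0 || gamma > 1) stop("`gamma` must lie in [0, 1]",
                                   call. = FALSE)
  warnings <- character(0)
  kS <- max(1L, as.integer(floor(gamma * k + 0.5)))
  if (k + kS > M) {
    kS <- M - k
    warnings <- c(warnings, sprintf(
      "k + kS exceeds M: selection width clamped to kS = %d", kS))
  }
  lam <- select_columns(A, y, k)
  r <- y
  yn <- l2(y)
  x <- numeric(N)
  rn_prev <- Inf
  trace <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  for (t in seq_len(n_iter)) {
    Tset <- if (kS > 0L) sort(union(lam, select_columns(A, r, kS))) else lam
    h <- least_squares_on_support(A, y, Tset)
    if (isTRUE(attr(h, "rank_deficient"))) {
      warnings <- unique(c(warnings,
                           "rank-deficient refit: minimum-norm solution"))
    }
    full <- numeric(N)
    full[Tset] <- h
    lam <- supp_k(full, k, psi)
    x <- restrict_support(full, lam)
    r <- y - drop(A[, lam, drop = FALSE] %*% x[lam])
    rn <- l2(r)
    trace <- c(trace, rn)
    iterations <- t
    if (rn <= 1e-12 * yn ||
        (is.finite(rn_prev) && abs(rn - rn_prev) <= tol * max(rn_prev, 1e-300))) {
      converged <- TRUE
      break
    }
    rn_prev <- rn
  }
  new_cs_reconstruction(
    x = x, support = lam, algorithm = "cosamp", iterations = iterations,
    converged = converged, residual_trace = trace, warnings = warnings,
    psi = psi
  )
}

#' Per-coordinate step-size vector for NIHT
#'
#' `rho_j = min_i ||a_i||_2 / ||a_j||_2`, which normalizes the gradient
#' coordinates by the column norms; all entries lie in `(0, 1]` and the
#' columns of minimal norm get step 1.
#'
#' @param A M x N sensing operator with no zero column.
#' @return Numeric vector of length N.
#' @export
niht_step_vector <- function(A) {
  A <- as.matrix(A)
  cn <- sqrt(colSums(A^2))
  if (any(cn == 0)) stop("`A` has a zero column", call. = FALSE)
  min(cn) / cn
}

#' Optimal scalar step on a proposed support
#'
#' Exact minimizer of `||A (x_Lam - mu * q_Lam) - y||_2^2` over `mu`:
#' `mu = (w' e) / (w' w)` with `w = A q_Lam` and `e = A x_Lam - y`, both
#' restricted to the proposed support `lam_star`. Returns 0 with attribute
#' `stagnation = TRUE` when `w = 0` (no descent direction on the support).
#'
#' @param A M x N sensing operator.
#' @param q Normalized gradient vector (length N).
#' @param x Current iterate (length N).
#' @param y Measurement vector.
#' @param lam_star Proposed support indices.
#' @return Scalar step `mu_t`.
#' @export
niht_mu <- function(A, q, x, y, lam_star) {
  A <- as.matrix(A)
  w <- drop(A %*% restrict_support(q, lam_star))
  e <- drop(A %*% restrict_support(x, lam_star)) - y
  wtw <- sum(w^2)
  if (wtw == 0) return(structure(0, stagnation = TRUE))
  sum(w * e) / wtw
}

#' Normalized iterative hard thresholding
#'
#' Gradient descent on the residual with per-coordinate normalization
#' ([niht_step_vector()]) and hard thresholding to `k` terms. The support is
#' initialized from the `k` columns most correlated with the measurements
#' and the coefficients by a least-squares fit there. Each outer iteration
#' computes the normalized gradient `q_t = rho * (A' (A x_t - y))` and the
#' optimal scalar step [niht_mu()] on a proposed support; because that step
#' depends on the support selected after the update, the pair (step,
#' support) is stabilized by an inner loop that re-proposes the support
#' until it stops changing (at most `max_inner` passes). The first outer
#' iteration uses the full index set as proposed support.
#'
#' @param A M x N sensing operator.
#' @param y Measurement vector.
#' @param k Sparsity level, `k <= M`.
#' @param psi Optional `cs_basis` (basis-weighted thresholding, synthesis).
#' @param n_iter Outer iteration cap. Default 100.
#' @param tol Relative residual-change stopping tolerance. Default `1e-8`.
#' @param max_inner Inner support-stabilization passes. Default 10.
#' @return A `cs_reconstruction`.
#' @export
niht_reconstruct <- function(A, y, k, psi = NULL, n_iter = 100, tol = 1e-8,
                             max_inner = 10) {
  A <- as.matrix(A)
  M <- nrow(A)
  N <- ncol(A)
  k <- check_scalar_count(k, "k")
  if (k > M) stop("`k` must not exceed the number of measurements M",
                  call. = FALSE)
  rho <- niht_step_vector(A)
  lam <- select_columns(A, y, k)
  h <- least_squares_on_support(A, y, lam)
  warnings <- character(0)
  if (isTRUE(attr(h, "rank_deficient"))) {
    warnings <- c(warnings, "rank-deficient initial fit: minimum-norm solution")
  }
  x <- numeric(N)
  x[lam] <- h
  yn <- l2(y)
  rn_prev <- Inf
  trace <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  for (t in seq_len(n_iter)) {
    r <- drop(A %*% x) - y
    q <- rho * drop(crossprod(A, r))
    if (t == 1L) {
      mu <- niht_mu(A, q, x, y, seq_len(N))
      x_tilde <- x - mu * q
      lam <- supp_k(x_tilde, k, psi)
    } else {
      lam_star <- lam
      x_tilde <- x
      for (pass in seq_len(max_inner)) {
        mu <- niht_mu(A, q, x, y, lam_star)
        if (isTRUE(attr(mu, "stagnation"))) {
          warnings <- unique(c(warnings, "stagnation: zero step direction"))
          break
        }
        x_tilde <- x - as.numeric(mu) * q
        lam_new <- supp_k(x_tilde, k, psi)
        if (identical(lam_new, lam_star)) break
        lam_star <- lam_new
      }
      lam <- lam_star
    }
    x <- restrict_support(x_tilde, lam)
    rn <- l2(drop(A %*% x) - y)
    trace <- c(trace, rn)
    iterations <- t
    if (rn <= 1e-12 * yn ||
        (is.finite(rn_prev) && abs(rn - rn_prev) <= tol * max(rn_prev, 1e-300))) {
      converged <- TRUE
      break
    }
    rn_prev <- rn
  }
  new_cs_reconstruction(
    x = x, support = lam, algorithm = "niht", iterations = iterations,
    converged = converged, residual_trace = trace, warnings = warnings,
    psi = psi
  )
}
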