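# Orthonormal sparsifying bases. All three constructions return an explicit
# dense N x N synthesis matrix Psi (columns = basis vectors, f = Psi %*% x),
# matching the matrix formulation A = Phi %*% Psi used by the solvers.

# Daubechies 4-vanishing-moment scaling filter ("db4", 8 taps), unit energy.
DB4_SCALING <- c(
   0.23037781330889650,  0.71484657055291570,  0.63088076792985890,
  -0.02798376941685985, -0.18703481171909309,  0.03084138183556076,
   0.03288301166688520, -0.01059740178506903
)

new_cs_basis <- function(columns, kind, levels = NA_integer_) {
  structure(
    list(
      columns = columns,
      kind = kind,
      levels = as.integer(levels),
      column_norms = sqrt(colSums(columns^2))
    ),
    class = "cs_basis"
  )
}

#' @export
print.cs_basis <- function(x, ...) {
  lev <- if (is.na(x$levels)) "" else sprintf(", %d levels", x$levels)
  cat(sprintf("<cs_basis %s %d x %d%s>\n",
              x$kind, nrow(x$columns), ncol(x$columns), lev))
  invisible(x)
}

#' @export
as.matrix.cs_basis <- function(x, ...) x$columns

basis_columns <- function(psi) {
  if (inherits(psi, "cs_basis")) psi$columns else as.matrix(psi)
}

# One decomposition level of a periodized orthogonal filter bank on length m:
# rows 1..m/2 are even shifts of the scaling filter h, rows m/2+1..m the
# quadrature-mirror wavelet filter g[l] = (-1)^l h[L-1-l] (0-based l).
# Periodization (circular indexing) is what keeps the operator orthonormal.
wavelet_level_matrix <- function(m, h) {
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  T <- matrix(0, m, m)
  half <- m %/% 2L
  for (i in seq_len(half)) {
    idx <- ((2L * (i - 1L) + seq_len(L) - 1L) %% m) + 1L
    for (l in seq_len(L)) {
      T[i, idx[l]] <- T[i, idx[l]] + h[l]
      T[half + i, idx[l]] <- T[half + i, idx[l]] + g[l]
    }
  }
  T
}

# Full analysis matrix W of a `levels`-deep dyadic decomposition; the
# synthesis basis is its transpose. Coefficient ordering: coarse approximation
# first, then detail bands from coarsest to finest.
wavelet_basis_matrix <- function(N, h, levels) {
  W <- diag(N)
  m <- N
  for (j in seq_len(levels)) {
    W[1:m, ] <- wavelet_level_matrix(m, h) %*% W[1:m, , drop = FALSE]
    m <- m %/% 2L
  }
  t(W)
}

#' Orthonormal DCT-II basis
#'
#' Columns are the synthesis vectors of the orthonormal type-II discrete
#' cosine transform: column 1 is the constant (DC) vector, higher columns the
#' cosine harmonics. Useful when the signal was low-pass filtered during
#' acquisition, which concentrates energy at low frequencies.
#'
#' @param N Frame length, `N >= 2`.
#' @return A `cs_basis` of kind `"DCT"`.
#' @export
dct_basis <- function(N) {
  N <- check_scalar_count(N, "N")
  if (N < 2L) stop("`N` must be at least 2", call. = FALSE)
  n <- 0:(N - 1L)
  C <- sqrt(2 / N) * cos(pi * outer(n, 2 * n + 1) / (2 * N))
  C[1L, ] <- sqrt(1 / N)
  new_cs_basis(t(C), "DCT")
}

#' Orthonormal Haar wavelet basis
#'
#' Periodized Haar filter-bank synthesis matrix of a `levels`-deep dyadic
#' decomposition. Exactly orthonormal up to floating point.
#'
#' @param N Frame length, a power of 2.
#' @param levels Decomposition depth, `1 <= levels <= log2(N)`. Defaults to
#'   full depth.
#' @return A `cs_basis` of kind `"HAAR"`.
#' @export
haar_basis <- function(N, levels = log2(N)) {
  N <- check_scalar_count(N, "N")
  if (!is_pow2(N)) stop("`N` must be a power of 2", call. = FALSE)
  levels <- check_scalar_count(levels, "levels")
  if (levels > log2(N)) {
    stop("`levels` must not exceed log2(N)", call. = FALSE)
  }
  new_cs_basis(wavelet_basis_matrix(N, c(1, 1) / sqrt(2), levels),
               "HAAR", levels)
}

#' Orthonormal Daubechies db4 wavelet basis
#'
#' Periodized filter-bank synthesis matrix for the Daubechies wavelet with 4
#' vanishing moments (the 8-tap filter called "db4" in common software
#' naming; note some texts use "DB4" for the 4-tap filter, available here as
#' `daubechies_taps = 4`). Periodic boundary handling makes the square matrix
#' exactly orthonormal.
#'
#' @param N Frame length, a power of 2.
#' @param levels Decomposition depth, `1 <= levels <= log2(N) - 2`. Defaults
#'   to `log2(N) - 3` (at least 1), which keeps the coarse band longer than
#'   the filter for typical frame lengths.
#' @param daubechies_taps Either 8 (default, the 4-vanishing-moment "db4"
#'   filter) or 4 (the 4-tap filter, i.e. "db2" in the vanishing-moment
#'   naming), for users who read "DB4" as the tap count.
#' @return A `cs_basis` of kind `"DB4"`.
#' @export
db4_basis <- function(N, levels = max(1, log2(N) - 3), daubechies_taps = 8) {
  N <- check_scalar_count(N, "N")
  if (!is_pow2(N)) stop("`N` must be a power of 2", call. = FALSE)
  levels <- check_scalar_count(levels, "levels")
  if (levels > log2(N) - 2) {
    stop("`levels` must not exceed log2(N) - 2", call. = FALSE)
  }
  h <- switch(as.character(daubechies_taps),
    "8" = DB4_SCALING,
    "4" = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    stop("`daubechies_taps` must be 8 or 4", call. = FALSE)
  )
  new_cs_basis(wavelet_basis_matrix(N, h, levels), "DB4", levels)
}

#' Build a basis by kind
#'
#' Convenience dispatcher used by the evaluation harness and the CLI.
#'
#' @param kind One of `"DCT"`, `"HAAR"`, `"DB4"` (case-insensitive).
#' @param N Frame length.
#' @param levels Wavelet decomposition depth; `NULL` for the kind's default.
#' @return A `cs_basis`.
#' @export
build_basis <- function(kind, N, levels = NULL) {
  switch(toupper(kind),
    DCT = dct_basis(N),
    HAAR = if (is.null(levels)) haar_basis(N) else haar_basis(N, levels),
    DB4 = if (is.null(levels)) db4_basis(N) else db4_basis(N, levels),
    stop(sprintf("unknown basis kind '%s' (use DCT, HAAR or DB4)", kind),
         call. = FALSE)
  )
}

#' Synthesize a frame from coefficients
#'
#' Computes `f = Psi %*% x`.
#'
#' @param psi A `cs_basis` (or N x N matrix).
#' @param x Coefficient vector of length N.
#' @return Numeric frame vector of length N.
#' @export
synthesize <- function(psi, x) {
  Psi <- basis_columns(psi)
  if (ncol(Psi) != length(x)) {
    stop("coefficient vector length does not match the basis", call. = FALSE)
  }
  drop(Psi %*% x)
}

#' Analyze a frame into basis coefficients
#'
#' Inverse of [synthesize()] for orthonormal bases: `x = t(Psi) %*% f`.
#'
#' @param psi A `cs_basis` (or N x N matrix with orthonormal columns).
#' @param f Frame vector of length N.
#' @return Coefficient vector of length N.
#' @export
analyze <- function(psi, f) {
  Psi <- basis_columns(psi)
  f <- frame_samples(f)
  if (nrow(Psi) != length(f)) {
    stop("frame length does not match the basis", call. = FALSE)
  }
  drop(crossprod(Psi, f))
}
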