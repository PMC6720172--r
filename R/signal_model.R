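#' Segment a signal into fixed-length frames
#'
#' Splits a sampled signal into consecutive non-overlapping frames of `N`
#' samples, the unit on which encoding and reconstruction operate. A trailing
#' remainder shorter than `N` is dropped; the number of dropped samples is
#' attached to the result as attribute `"dropped"` and reported via a message.
#'
#' @param signal Numeric vector of samples (finite values).
#' @param N Frame length in samples.
#' @param fs Sampling rate in Hz.
#' @return A list of `cs_frame` objects (fields `samples`, `fs`, `index`,
#'   frame index starting at 1), with attribute `dropped`.
#' @examples
#' frames <- frame_signal(sin(seq_len(2500) / 10), N = 1024, fs = 2000)
#' length(frames)           # 2
#' attr(frames, "dropped")  # 452
#' @export
frame_signal <- function(signal, N, fs) {
  N <- check_scalar_count(N, "N")
  if (!is.numeric(signal) || !all(is.finite(signal))) {
    stop("`signal` must be a numeric vector of finite values", call. = FALSE)
  }
  if (length(signal) < N) {
    stop(sprintf(
      "signal has %d samples but at least N = %d are required for one frame",
      length(signal), N
    ), call. = FALSE)
  }
  n_frames <- length(signal) %/% N
  dropped <- length(signal) - n_frames * N
  frames <- lapply(seq_len(n_frames), function(k) {
    cs_frame(signal[((k - 1L) * N + 1L):(k * N)], fs = fs, index = k)
  })
  if (dropped > 0L) {
    message(sprintf("frame_signal: dropped %d trailing samples (< N)", dropped))
  }
  structure(frames, dropped = dropped)
}

#' Construct a single signal frame
#'
#' @param samples Numeric vector of finite sample values.
#' @param fs Sampling rate in Hz.
#' @param index Frame ordinal (1-based).
#' @return An object of class `cs_frame`.
#' @export
cs_frame <- function(samples, fs, index = 1L) {
  if (!is.numeric(samples) || !all(is.finite(samples))) {
    stop("frame samples must be finite numbers", call. = FALSE)
  }
  structure(
    list(samples = as.numeric(samples), fs = fs, index = as.integer(index)),
    class = "cs_frame"
  )
}

#' @export
print.cs_frame <- function(x, ...) {
  cat(sprintf(
    "<cs_frame #%d: %d samples @ %g Hz, RMS %.4g>\n",
    x$index, length(x$samples), x$fs, sqrt(mean(x$samples^2))
  ))
  invisible(x)
}

frame_samples <- function(frame) {
  if (inherits(frame, "cs_frame")) frame$samples else as.numeric(frame)
}

#' Seeded Bernoulli measurement matrix
#'
#' Builds the M x N sensing operator with i.i.d. entries drawn uniformly from
#' \{-1, +1\}, the standard hardware-friendly choice for CS encoders (the
#' product `y = Phi f` needs only signed additions). Entries are drawn from a
#' single seeded stream in row-major order, so a matrix is fully reproducible
#' from `(M, N, seed)`.
#'
#' @param M Number of measurements (rows), `1 <= M <= N`.
#' @param N Frame length (columns).
#' @param seed Integer seed for the generator.
#' @return An object of class `cs_measurement_matrix` with fields `entries`
#'   (M x N matrix of +/-1), `M`, `N`, `seed`.
#' @export
bernoulli_matrix <- function(M, N, seed) {
  M <- check_scalar_count(M, "M")
  N <- check_scalar_count(N, "N")
  if (M > N) {
    stop("M > N: over-determined sensing is outside the compressed-sensing regime",
         call. = FALSE)
  }
  entries <- local_seed(seed, matrix(
    sample(c(-1, 1), M * N, replace = TRUE), M, N, byrow = TRUE
  ))
  structure(
    list(entries = entries, M = M, N = N, seed = as.integer(seed)),
    class = "cs_measurement_matrix"
  )
}

#' @export
print.cs_measurement_matrix <- function(x, ...) {
  cat(sprintf("<cs_measurement_matrix %d x %d, seed %d>\n", x$M, x$N, x$seed))
  invisible(x)
}

#' @export
as.matrix.cs_measurement_matrix <- function(x, ...) x$entries

measurement_entries <- function(phi) {
  if (inherits(phi, "cs_measurement_matrix")) phi$entries else as.matrix(phi)
}

#' Encode a frame into compressed measurements
#'
#' Computes `y = Phi f`, the M-dimensional measurement vector. With +/-1
#' entries this is a multiplication-free signed accumulation in hardware; here
#' it is evaluated as the exact matrix-vector product.
#'
#' @param frame A `cs_frame` or numeric vector of length N.
#' @param phi A `cs_measurement_matrix` (or plain M x N matrix).
#' @return Numeric measurement vector of length M.
#' @export
encode <- function(frame, phi) {
  f <- frame_samples(frame)
  Phi <- measurement_entries(phi)
  if (ncol(Phi) != length(f)) {
    stop(sprintf(
      "dimension mismatch: measurement matrix has N = %d columns but frame has %d samples",
      ncol(Phi), length(f)
    ), call. = FALSE)
  }
  drop(Phi %*% f)
}

#' Compression and sparsity metrics
#'
#' For a frame of length `N`, `M` measurements and sparsity `k`:
#' compression ratio `CR = N/M`, compression factor `CF = M/N = 1/CR`,
#' sparsity relative to the frame `SN = k/N`, and sparsity relative to the
#' measurements `SM = k/M`. The identities `CR * CF = 1` and `SM = CR * SN`
#' hold exactly.
#'
#' @param N Frame length.
#' @param M Number of measurements, `M <= N`.
#' @param k Sparsity level, `k <= N`.
#' @return A list of class `cs_metrics` with fields `CR`, `CF`, `SN`, `SM`.
#' @examples
#' compression_metrics(N = 1024, M = 512, k = 256)  # CR 2, CF 0.5, SM 0.5
#' @export
compression_metrics <- function(N, M, k) {
  N <- check_scalar_count(N, "N")
  M <- check_scalar_count(M, "M")
  k <- check_scalar_count(k, "k")
  if (M > N) stop("M must not exceed N", call. = FALSE)
  if (k > N) stop("k must not exceed N", call. = FALSE)
  structure(
    list(CR = N / M, CF = M / N, SN = k / N, SM = k / M),
    class = "cs_metrics"
  )
}

#' @export
print.cs_metrics <- function(x, ...) {
  cat(sprintf("<cs_metrics CR %.4g  CF %.4g  SN %.4g  SM %.4g>\n",
              x$CR, x$CF, x$SN, x$SM))
  invisible(x)
}

#' Coherence between a sensing matrix and a sparsifying basis
#'
#' Largest absolute correlation between any (unit-normalized) row of `phi`
#' and (unit-normalized) column of `psi`, scaled by `sqrt(N)` so the value
#' lies in `[1, sqrt(N)]`: 1 for maximally incoherent pairs (the regime where
#' random matrices operate), `sqrt(N)` when a sensing row is aligned with a
#' basis column. Diagnostic only; no algorithm consumes it.
#'
#' @param phi Sensing matrix (`cs_measurement_matrix` or plain matrix, rows =
#'   measurement vectors).
#' @param psi Sparsifying basis (`cs_basis` or plain N x N matrix, columns =
#'   basis vectors).
#' @return Scalar coherence `nu`.
#' @export
cs_coherence <- function(phi, psi) {
  Phi <- measurement_entries(phi)
  Psi <- basis_columns(psi)
  if (ncol(Phi) != nrow(Psi)) {
    stop("incompatible dimensions between `phi` and `psi`", call. = FALSE)
  }
  rn <- sqrt(rowSums(Phi^2))
  cn <- sqrt(colSums(Psi^2))
  if (any(rn == 0)) stop("`phi` has a zero row", call. = FALSE)
  if (any(cn == 0)) stop("`psi` has a zero column", call. = FALSE)
  G <- (Phi / rn) %*% (Psi %*% diag(1 / cn, length(cn)))
  sqrt(nrow(Psi)) * max(abs(G))
}

#' Combined sensing operator
#'
#' Forms the dense `A = Phi %*% Psi` matrix the reconstruction algorithms
#' operate on (measurements as linear functionals of the coefficient vector).
#'
#' @inheritParams cs_coherence
#' @return M x N numeric matrix.
#' @export
sensing_operator <- function(phi, psi) {
  Phi <- measurement_entries(phi)
  Psi <- basis_columns(psi)
  if (ncol(Phi) != nrow(Psi)) {
    stop("incompatible dimensions between `phi` and `psi`", call. = FALSE)
  }
  Phi %*% Psi
}
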