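# Synthetic test-signal generators. Everything here is a pure function of
# its seed and parameters, so fixtures are reproducible without any
# recorded data.

#' Parameters for the EMG-like signal generator
#'
#' Defaults emulate a surface-EMG acquisition chain: 5--500 Hz passband
#' sampled at 2 kHz, with muscle-activation bursts of 0.3 s once per second
#' at 8x the resting amplitude (plausible for dynamic contractions; purely a
#' fixture choice).
#'
#' @param fs Sampling rate in Hz.
#' @param N Frame length in samples.
#' @param band Passband `c(low, high)` in Hz, `0 < low < high < fs/2`.
#' @param burst_rate Bursts per second.
#' @param burst_duration Burst length in seconds;
#'   `burst_rate * burst_duration < 1`.
#' @param burst_gain Active/rest amplitude ratio (rest level is 1).
#' @param edge_time Raised-cosine burst edge duration in seconds.
#' @param seed Integer seed.
#' @return A list of class `emg_synthesis_params`.
#' @export
emg_synthesis_params <- function(fs = 2000, N = 1024, band = c(5, 500),
                                 burst_rate = 1, burst_duration = 0.3,
                                 burst_gain = 8, edge_time = 0.05, seed = 1) {
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= fs / 2) {
    stop("`band` must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
  if (burst_rate * burst_duration >= 1) {
    stop("`burst_rate * burst_duration` must be below 1 (bursts must not overlap)",
         call. = FALSE)
  }
  structure(
    list(fs = fs, N = N, band = band, burst_rate = burst_rate,
         burst_duration = burst_duration, burst_gain = burst_gain,
         edge_time = edge_time, seed = seed),
    class = "emg_synthesis_params"
  )
}

# Raised-cosine-edged burst envelope: rest level 1, burst level `gain`,
# half-cosine ramps of `edge_time` seconds inside the burst window.
burst_envelope <- function(n, fs, rate, duration, gain, edge_time, phase) {
  t <- (seq_len(n) - 1) / fs
  period <- 1 / rate
  pos <- (t + phase) %% period
  env <- rep(1, n)
  inb <- pos < duration
  edge <- pmin(pos[inb], duration - pos[inb])
  shape <- ifelse(edge >= edge_time, 1, 0.5 * (1 - cos(pi * edge / edge_time)))
  env[inb] <- 1 + (gain - 1) * shape
  env
}

#' Generate band-limited, burst-modulated EMG-like frames
#'
#' Seeded white Gaussian noise is band-pass filtered to the configured
#' passband (4th-order Butterworth applied forward and backward, so the
#' filtering is zero-phase and the burst envelope is not skewed), multiplied
#' by a raised-cosine-edged burst envelope emulating muscle-activation
#' epochs, segmented into frames of `N` samples, and standardized to unit
#' RMS per frame. The burst train phase is drawn from the seed, so
#' independently seeded calls sample burst/frame alignment.
#'
#' @param params An [emg_synthesis_params()] object.
#' @param n_frames Number of consecutive frames to generate.
#' @return A list of `cs_frame` objects of length `n_frames`.
#' @export
generate_emg_like <- function(params = emg_synthesis_params(), n_frames = 1) {
  stopifnot(inherits(params, "emg_synthesis_params"))
  n_frames <- check_scalar_count(n_frames, "n_frames")
  n <- n_frames * params$N
  wn <- local_seed(params$seed, rnorm(n))
  bf <- signal::butter(4, params$band / (params$fs / 2), type = "pass")
  x <- signal::filtfilt(bf, wn)
  phase <- local_seed(params$seed + 7L, runif(1)) / params$burst_rate
  env <- burst_envelope(n, params$fs, params$burst_rate,
                        params$burst_duration, params$burst_gain,
                        params$edge_time, phase)
  x <- x * env
  lapply(seq_len(n_frames), function(k) {
    f <- x[((k - 1L) * params$N + 1L):(k * params$N)]
    cs_frame(f / sqrt(mean(f^2)), fs = params$fs, index = k)
  })
}

#' Generate an exactly k-sparse ground-truth fixture
#'
#' Draws `k` support indices uniformly without replacement, coefficient
#' magnitudes log-uniform in `[0.1, 1]` with random signs, and returns both
#' the coefficient vector and the synthesized frame `f = Psi x`. Used as
#' ground truth for exact-recovery tests.
#'
#' @param N Frame length.
#' @param k Sparsity, `1 <= k <= N`.
#' @param psi A `cs_basis` (or N x N matrix).
#' @param seed Integer seed.
#' @return A list with elements `frame` (numeric length N), `x` (coefficient
#'   vector with attributes `support`, `k`).
#' @export
generate_sparse_fixture <- function(N, k, psi, seed) {
  N <- check_scalar_count(N, "N")
  k <- check_scalar_count(k, "k")
  if (k > N) stop("`k` must not exceed `N`", call. = FALSE)
  draws <- local_seed(seed, {
    list(
      support = sort(sample.int(N, k)),
      mags = 10^runif(k, min = -1, max = 0),
      signs = sample(c(-1, 1), k, replace = TRUE)
    )
  })
  x <- numeric(N)
  x[draws$support] <- draws$mags * draws$signs
  list(
    frame = synthesize(psi, x),
    x = structure(x, support = draws$support, k = as.integer(k))
  )
}

#' k-term approximation quality per basis
#'
#' For each frame and each `k` in `k_grid`, the SNR between the frame and
#' its best k-term approximation `Psi [x]_k` with `x = analyze(psi, f)` —
#' the compressibility of the signal in the basis, which upper-bounds what
#' any reconstruction at sparsity k can achieve against the original frame.
#'
#' @param frames List of frames (numeric vectors or `cs_frame`).
#' @param psi A `cs_basis`.
#' @param k_grid Integer vector of sparsity levels.
#' @param cap SNR cap in dB passed to [snr_db()].
#' @return data.frame with columns `frame`, `k`, `snr_db`.
#' @export
compressibility_report <- function(frames, psi, k_grid, cap = 300) {
  rows <- lapply(seq_along(frames), function(i) {
    f <- frame_samples(frames[[i]])
    x <- analyze(psi, f)
    data.frame(
      frame = i, k = as.integer(k_grid),
      snr_db = vapply(k_grid, function(k) {
        snr_db(f, synthesize(psi, as.numeric(reduce_k(x, k, psi))), cap = cap)
      }, numeric(1))
    )
  })
  do.call(rbind, rows)
}
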