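# Evaluation harness: reconstruction SNR, measurement-noise injection, the
# noise-bound relationship, and the sparsity/compression/noise sweep
# experiments.

#' Reconstruction signal-to-noise ratio in dB
#'
#' `SNR = 20 log10(||ref||_2 / ||ref - rec||_2)`. Scale-invariant. An exact
#' reconstruction returns the cap (finite sentinel standing in for +Inf so
#' results remain tabulable).
#'
#' @param reference Reference vector (must not be all zero).
#' @param reconstructed Reconstructed vector of the same length.
#' @param cap Upper sentinel in dB. Default 300.
#' @return SNR in dB, capped at `cap`.
#' @export
snr_db <- function(reference, reconstructed, cap = 300) {
  reference <- frame_samples(reference)
  reconstructed <- frame_samples(reconstructed)
  if (length(reference) != length(reconstructed)) {
    stop("`reference` and `reconstructed` must have equal length",
         call. = FALSE)
  }
  rn <- l2(reference)
  if (rn == 0) stop("`reference` must not be the zero vector", call. = FALSE)
  e <- l2(reference - reconstructed)
  if (e == 0) return(cap)
  min(20 * log10(rn / e), cap)
}

#' Add white Gaussian noise at an exact measurement SNR
#'
#' Draws seeded Gaussian noise and rescales it so that
#' `20 log10(||y||_2 / ||n||_2)` equals `target_snr_db` exactly (norm-exact
#' scaling rather than expectation-level), then returns `y + n`. A target of
#' `Inf` returns `y` unchanged.
#'
#' @param y Measurement vector (not all zero).
#' @param target_snr_db Measurement SNR in dB.
#' @param seed Integer seed for the noise draw.
#' @return Noisy measurement vector with attribute `noise_snr_db`.
#' @export
add_noise <- function(y, target_snr_db, seed) {
  if (l2(y) == 0) stop("`y` must not be the zero vector", call. = FALSE)
  if (is.infinite(target_snr_db)) return(y)
  n <- local_seed(seed, rnorm(length(y)))
  n <- n * (l2(y) / l2(n)) / 10^(target_snr_db / 20)
  structure(y + n, noise_snr_db = target_snr_db)
}

#' Upper bound on noisy reconstruction SNR
#'
#' For a reconstruction whose error splits into a noise-free part (linear
#' amplitude SNR `snr_nf`) and a noise-induced part (`snr_noise`), the
#' achievable linear SNR is bounded by
#' `snr_nf * snr_noise / (snr_nf - snr_noise)`. When `snr_nf <= snr_noise`
#' the bound is vacuous (`Inf`); as `snr_nf -> Inf` it degenerates to
#' `snr_noise` (heavy noise dominates the reconstruction).
#'
#' @param snr_nf Noise-free linear amplitude ratio (> 0; may be `Inf`).
#' @param snr_noise Noise-induced linear amplitude ratio (> 0).
#' @return A list of class `cs_noise_bound` with fields `snr_nf`,
#'   `snr_noise`, `bound` (linear ratio, possibly `Inf`).
#' @export
noise_snr_bound <- function(snr_nf, snr_noise) {
  if (!is.numeric(snr_nf) || snr_nf <= 0 ||
      !is.numeric(snr_noise) || snr_noise <= 0) {
    stop("`snr_nf` and `snr_noise` must be positive", call. = FALSE)
  }
  bound <- if (is.infinite(snr_nf)) {
    snr_noise
  } else if (snr_nf <= snr_noise) {
    Inf
  } else {
    snr_nf * snr_noise / (snr_nf - snr_noise)
  }
  structure(list(snr_nf = snr_nf, snr_noise = snr_noise, bound = bound),
            class = "cs_noise_bound")
}

#' @export
print.cs_noise_bound <- function(x, ...) {
  cat(sprintf("<cs_noise_bound snr_nf %.4g  snr_noise %.4g  bound %.4g>\n",
              x$snr_nf, x$snr_noise, x$bound))
  invisible(x)
}

default_cell_params <- function() {
  list(
    eps_max = 1e-3,       # l1 ripple tolerance
    n_iter_l1 = 2000,
    n_iter_cosamp = 50,
    n_iter_niht = 100,
    gamma = 0.5,          # CoSaMP selection fraction
    sparsify = TRUE,      # enforce k-sparsity on the frame before encoding
    snr_cap = 300,
    snr_domain = "frame", # or "measurement"
    cache = NULL          # environment for l1 projector reuse
  )
}

run_one_frame <- function(f, psi, algo, M, k, noise_snr_db, seed, params) {
  N <- length(f)
  phi <- bernoulli_matrix(M, N, seed)
  A <- sensing_operator(phi, psi)
  if (isTRUE(params$sparsify)) {
    xk <- reduce_k(analyze(psi, f), k, psi)
    y <- drop(A %*% as.numeric(xk))
  } else {
    y <- encode(f, phi)
  }
  if (!is.null(noise_snr_db) && is.finite(noise_snr_db)) {
    y <- add_noise(y, noise_snr_db, seed = seed + 500000L)
  }
  rec <- switch(algo,
    l1 = {
      init <- NULL
      if (is.environment(params$cache)) {
        key <- sprintf("proj_%d_%d_%d", M, N, seed)
        if (is.null(params$cache[[key]])) {
          params$cache[[key]] <- l1_init(A, as.numeric(y))
        }
        init <- params$cache[[key]]
      }
      l1_reconstruct(A, as.numeric(y), eps_max = params$eps_max,
                     n_iter = params$n_iter_l1, k = k, psi = psi,
                     init = init)
    },
    omp = omp_reconstruct(A, as.numeric(y), k, psi = psi),
    cosamp = cosamp_reconstruct(A, as.numeric(y), k, gamma = params$gamma,
                                n_iter = params$n_iter_cosamp, psi = psi),
    niht = niht_reconstruct(A, as.numeric(y), k, psi = psi,
                            n_iter = params$n_iter_niht),
    stop(sprintf("unknown algorithm '%s' (use l1, omp, cosamp or niht)", algo),
         call. = FALSE)
  )
  snr <- if (identical(params$snr_domain, "measurement")) {
    snr_db(encode(f, phi), drop(A %*% rec$x), cap = params$snr_cap)
  } else {
    snr_db(f, rec$f_rec, cap = params$snr_cap)
  }
  list(snr = snr, iterations = rec$iterations,
       warnings = rec$warnings)
}

#' Evaluate one experiment cell
#'
#' Runs one (algorithm, basis, CF, SM, noise) condition over a set of
#' frames. Per frame: a fresh seeded Bernoulli matrix is built, the frame is
#' k-sparsified in the basis (default; the step the SNR-vs-sparsity
#' experiments are defined on — disable with `params$sparsify = FALSE`),
#' encoded, optionally corrupted with measurement noise, reconstructed, and
#' scored with [snr_db()] against the original (un-sparsified) frame. The
#' derived sizes are `M = round(CF * N)` and `k = round(SM * M)`, half away
#' from zero, floored at 1.
#'
#' @param frames List of `cs_frame` objects (or numeric vectors), all of
#'   length N.
#' @param algo One of `"l1"`, `"omp"`, `"cosamp"`, `"niht"`.
#' @param basis A `cs_basis` of matching N.
#' @param CF Compression factor M/N in (0, 1].
#' @param SM Sparsity ratio k/M.
#' @param noise_snr_db Measurement SNR of injected noise in dB, or `NULL`
#'   for noiseless.
#' @param seeds Integer vector of per-frame measurement-matrix seeds
#'   (recycled noise seeds are derived from them).
#' @param params Named list of overrides: `eps_max`, `n_iter_l1`,
#'   `n_iter_cosamp`, `n_iter_niht`, `gamma`, `sparsify`, `snr_cap`,
#'   `snr_domain`, `cache`.
#' @return One-row data.frame with columns `algorithm`, `basis`, `CF`, `SM`,
#'   `M`, `k`, `noise_snr_db`, `n_frames`, `n_failed`, `mean_snr_db`,
#'   `std_snr_db`, `mean_iterations`, `note`; per-frame SNRs are attached as
#'   attribute `per_frame`.
#' @export
run_cell <- function(frames, algo, basis, CF, SM, noise_snr_db = NULL,
                     seeds = seq_along(frames), params = list()) {
  params <- modifyList(default_cell_params(), params)
  if (!length(frames)) stop("`frames` must not be empty", call. = FALSE)
  if (length(seeds) != length(frames)) {
    stop("`seeds` must supply one seed per frame", call. = FALSE)
  }
  N <- length(frame_samples(frames[[1]]))
  M <- round_count(CF * N)
  k <- round_count(SM * M)
  base_row <- data.frame(
    algorithm = algo, basis = if (inherits(basis, "cs_basis")) basis$kind else "custom",
    CF = CF, SM = SM, M = M, k = k,
    noise_snr_db = if (is.null(noise_snr_db)) NA_real_ else noise_snr_db,
    n_frames = length(frames), n_failed = 0L,
    mean_snr_db = NA_real_, std_snr_db = NA_real_,
    mean_iterations = NA_real_, note = "", stringsAsFactors = FALSE
  )
  if (M > N) {
    base_row$note <- "invalid cell: M > N"
    return(base_row)
  }
  if (algo != "l1" && k > M) {
    base_row$note <- "invalid cell: k > M for greedy reconstruction"
    return(base_row)
  }
  snrs <- rep(NA_real_, length(frames))
  iters <- rep(NA_real_, length(frames))
  notes <- character(0)
  for (i in seq_along(frames)) {
    f <- frame_samples(frames[[i]])
    res <- tryCatch(
      run_one_frame(f, basis, algo, M, k, noise_snr_db, seeds[i], params),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      notes <- c(notes, sprintf("frame %d: %s", i, conditionMessage(res)))
    } else {
      snrs[i] <- res$snr
      iters[i] <- res$iterations
      if (length(res$warnings)) notes <- unique(c(notes, res$warnings))
    }
  }
  ok <- !is.na(snrs)
  base_row$n_failed <- sum(!ok)
  if (any(ok)) {
    base_row$mean_snr_db <- mean(snrs[ok])
    base_row$std_snr_db <- if (sum(ok) > 1) sd(snrs[ok]) else 0
    base_row$mean_iterations <- mean(iters[ok])
  }
  base_row$note <- paste(notes, collapse = "; ")
  attr(base_row, "per_frame") <- snrs
  base_row
}

#' Experiment configuration for [cs_sweep()]
#'
#' @param frames List of frames (all length N).
#' @param algorithms Character vector from `c("l1","omp","cosamp","niht")`.
#' @param basis_kinds Character vector from `c("DCT","HAAR","DB4")`, or a
#'   list of prebuilt `cs_basis` objects.
#' @param CF_grid Compression factors in (0, 1].
#' @param SM_grid Sparsity ratios k/M.
#' @param noise_snr_db Noise levels in dB; use `NA` for the noiseless
#'   condition. Default `NA`.
#' @param base_seed Base integer seed; frame `i` uses seed `base_seed + i`.
#' @param params Cell parameter overrides (see [run_cell()]).
#' @return A list of class `cs_experiment_config`.
#' @export
cs_experiment_config <- function(frames, algorithms, basis_kinds, CF_grid,
                                 SM_grid, noise_snr_db = NA, base_seed = 1,
                                 params = list()) {
  axes <- list(algorithms = algorithms, basis_kinds = basis_kinds,
               CF_grid = CF_grid, SM_grid = SM_grid,
               noise_snr_db = noise_snr_db)
  empty <- names(axes)[vapply(axes, length, 1L) == 0L]
  if (length(empty)) {
    stop(sprintf("empty experiment axis: %s", paste(empty, collapse = ", ")),
         call. = FALSE)
  }
  if (!length(frames)) stop("`frames` must not be empty", call. = FALSE)
  structure(
    list(frames = frames, algorithms = algorithms, basis_kinds = basis_kinds,
         CF_grid = CF_grid, SM_grid = SM_grid, noise_snr_db = noise_snr_db,
         base_seed = base_seed, params = params),
    class = "cs_experiment_config"
  )
}

#' Sweep reconstruction SNR over algorithms, bases, CF, SM and noise
#'
#' Cartesian product of the configured axes, delegated cell by cell to
#' [run_cell()]. Within a compression factor the l1 null-space projector of
#' each frame's sensing operator is cached and shared across SM values and
#' noise levels; the cache is dropped when CF changes.
#'
#' @param config A `cs_experiment_config`.
#' @return A tidy data.frame, one row per cell (see [run_cell()]).
#' @export
cs_sweep <- function(config) {
  stopifnot(inherits(config, "cs_experiment_config"))
  N <- length(frame_samples(config$frames[[1]]))
  bases <- lapply(config$basis_kinds, function(b) {
    if (inherits(b, "cs_basis")) b else build_basis(b, N)
  })
  seeds <- config$base_seed + seq_along(config$frames)
  rows <- list()
  for (bi in seq_along(bases)) {
    for (CF in config$CF_grid) {
      cache <- new.env(parent = emptyenv())
      params <- modifyList(config$params, list(cache = cache))
      for (noise in config$noise_snr_db) {
        for (SM in config$SM_grid) {
          for (algo in config$algorithms) {
            rows[[length(rows) + 1L]] <- run_cell(
              config$frames, algo, bases[[bi]], CF, SM,
              noise_snr_db = if (is.na(noise)) NULL else noise,
              seeds = seeds, params = params
            )
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}
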