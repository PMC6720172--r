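---
title: "Compressed sensing of EMG-like signals: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressed sensing of EMG-like signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The sensing model

A frame `f` of `N` samples is encoded into `M < N` measurements
`y = Φ f` by a Bernoulli matrix with i.i.d. ±1 entries — the standard
choice for low-power encoders, since the product reduces to signed
accumulation. Reconstruction assumes `f = Ψ x` with `x` sparse in an
orthonormal basis `Ψ`, and solves the underdetermined system
`y = ΦΨ x = A x` under that prior. The package works throughout with the
explicit dense operator `A` (N ≤ a few thousand), which keeps every
algorithm a few lines of linear algebra rather than an operator framework.

Bookkeeping quantities: compression ratio `CR = N/M`, compression factor
`CF = M/N`, and the two sparsity ratios `SN = k/N` and `SM = k/M = CR·SN`.
Curves are reported against `SM` because behavior changes qualitatively as
`k` approaches `M`, regardless of `N`.

Coherence between sensing rows and basis columns is provided as a
diagnostic, normalized as `ν = √N · max |⟨φ_i/‖φ_i‖, ψ_j/‖ψ_j‖⟩|`, so that
`ν ∈ [1, √N]`: 1 is the incoherent optimum that random matrices approach,
`√N` the worst case of an aligned pair. This scaled convention is the one
under which "random matrices are incoherent (ν ≈ 1)" reads correctly; the
unscaled inner-product maximum alone would shrink with `N`.

### Support operators

`supp_k()` selects the `k` indices with largest `|x_i|·‖Ψ_i‖₂`. The
basis-weighted form matters only for non-normalized bases — all three bases
built here are orthonormal, making the weights 1 — but it is implemented as
defined so externally supplied bases behave correctly. Ties are broken
toward the lower index; the selection is deterministic, which exact
reproducibility of sweeps requires. When `x` carries fewer than `k`
nonzeros the returned support still has cardinality `k` (zero-valued
indices are admitted), preserving the operator's fixed-cardinality
contract. `reduce_k()` (select, then zero the complement) is idempotent
and, for orthonormal `Ψ`, yields the best k-term approximation of the
synthesized frame; the test suite checks this against exhaustive search
over all supports at small `N`.

## Sparsifying bases

Three bases are built as explicit `N × N` orthonormal synthesis matrices:

* **DCT-II** — useful when acquisition already low-pass filtered the
  signal, concentrating energy at low frequencies.
* **Haar** and **Daubechies db4** — dyadic filter-bank wavelets, built by
  applying one decomposition level at a time to the coarse band and
  transposing the resulting analysis matrix.

Periodic (circular) boundary handling is used for the wavelets: it is the
only boundary rule that makes the square filter-bank matrix exactly
orthonormal, which in turn is what the solvers' analysis/synthesis
round-trips rely on. "db4" follows the vanishing-moment naming of common
wavelet software (the 8-tap filter with 4 vanishing moments). Some texts
use "DB4" for the 4-tap filter; `db4_basis(..., daubechies_taps = 4)`
selects that reading.

Default decomposition depths: full depth (`log2 N`) for Haar, whose filter
never outgrows the coarse band, and `log2(N) − 3` for db4, which keeps the
coarse band longer than the 8-tap filter at the frame lengths used here.
Both are configurable; orthonormality holds at any admissible depth.

## Reconstruction algorithms

### Projected-gradient l1 minimization

Basis pursuit — minimize `‖x‖₁` subject to `Ax = y` — is solved by
subgradient descent projected onto the feasible manifold:

```
x_{t+1} = x_t − μ (‖x_t‖₁ / N) · P sgn(x_t),     P = I − A⁺A,
```

starting from the minimum-norm feasible point `x₀ = A⁺y`. Because `P`
projects onto the null space of `A`, every iterate satisfies `A x_t = y`
to rounding — a property the suite asserts at every iteration of seeded
runs. The `‖x_t‖₁/N` factor makes the step scale-free in the signal power.

Design choices worth knowing:

* **Step size.** `μ = ε_max · N / ‖P sgn(x₀)‖₂` ties the asymptotic
  per-iteration ripple `‖x_{t+1} − x_t‖/‖x_t‖` to the accuracy target
  `ε_max`. Defaults: `ε_max = 1e-3`, at most 2000 iterations.
* **Stopping.** The ripple of a single iteration is noisy near the
  solution, so convergence is declared after 5 consecutive iterations below
  `ε_max`.
* **`sgn(0) = 0`.** Zero entries contribute nothing to the step; 0→±1
  transitions are treated as sign changes by the incremental update.
* **Incremental update.** `q_t = P sgn(x_t)` is maintained as
  `q_t = q_{t−1} + Σ_{j∈Ω} P_j (s_t(j) − s_{t−1}(j))` over the sign-changed
  set Ω — equal to the classic `2 P_j s_t(j)` increment for ±1 flips, and
  still exact through zeros. Once the sign pattern stabilizes this costs a
  handful of column operations instead of a full `N × N` product; the
  `auto` mode falls back to the direct product on iterations where more
  than `N/8` signs changed, which is cheaper in dense linear algebra. The
  suite verifies incremental and direct paths agree to `1e-10` across
  seeded runs.
* **Conditioning.** `A Aᵀ` is factored once per operator; a reciprocal
  condition estimate below `1e-12` raises an error rather than returning a
  garbage projector. The projector and pseudo-inverse are reusable across
  calls (`init` argument); the feasible start is always recomputed from the
  supplied `y`, since a cached `x₀` belongs to the measurement vector that
  built it.
* **Sparsity input.** The solver itself never uses `k`; when given, it is
  applied as a final `reduce_k()` truncation on output (optionally followed
  by a least-squares refit, off by default).

### Orthogonal matching pursuit

Exactly `k` greedy iterations: select the column most correlated with the
residual, refit all active coefficients by least squares, update the
residual. The refit keeps the residual orthogonal to the active set, so no
column is ever selected twice (a rounding-level guard masks already-active
columns). The active-set normal equations are maintained by rank-one
Cholesky updates — `O(MN + t²)` per iteration — which is what makes
frame-length sweeps up to `k ≈ 0.9·M` affordable. Iterations end early
only on an exact fit (residual below `1e-13·‖y‖`) or a numerically
dependent selection.

### CoSaMP

Per iteration: select `kS = max(1, round(γk))` new candidate columns
against the residual, merge with the current support, refit on the merged
set, prune to the `k` largest weighted coefficients, update the residual.
`γ = 0.5` by default — the correction width is conventionally constrained
to `γ ∈ [0, 1]` with the value left open, and 0.5 balances correction
capacity against refit cost; `γ = 0` is clamped to one column so the
algorithm still moves. When `k + kS` would exceed `M`, `kS` is clamped to
`M − k` (with a warning flag on the result) so the merged refit stays
overdetermined; without this, every sweep cell beyond `SM ≈ 1/(1+γ)` would
abort. Stopping: `n_iter` (default 50), a relative residual-change
tolerance of `1e-8`, or an exact fit.

### NIHT

Gradient descent on the residual with a per-coordinate step vector
`ρ_j = min_i‖a_i‖/‖a_j‖` normalizing the gradient, followed by hard
thresholding to `k` terms. The scalar step `μ_t = (wᵀε)/(wᵀw)` is the
exact minimizer of the residual along the thresholded direction, but it
depends on the support selected *after* the step; the implementation
stabilizes the pair with an inner loop — propose the previous support,
compute `μ_t`, update, re-threshold, repeat until the support stops
changing (at most 10 passes). The first outer iteration uses the full
index set as the proposed support. A zero step direction sets a stagnation
flag instead of dividing by zero. Stopping mirrors CoSaMP (default 100
outer iterations).

On exactly sparse noiseless instances at `M = 2k·log-ish` scales all four
algorithms recover the ground truth in ≥ 90% of seeded trials (the suite
runs 100 per algorithm); the greedy algorithms to `1e-6` relative error,
the subgradient l1 solver to `1e-2` within its iteration budget.

## Evaluation pipeline

`run_cell()` evaluates one (algorithm, basis, CF, SM, noise) condition
over a frame set, and `cs_sweep()` expands the full grid. Choices that
define the numbers:

* **Sparsity enforcement before encoding.** By default each frame is first
  truncated to its best k-term approximation in the basis, encoded as
  `y = A [x]_k`, and the SNR is measured against the *original* frame.
  This is the convention under which SNR-vs-sparsity curves have their
  characteristic shape: the rising branch tracks the k-term approximation
  ceiling, and the collapse past the peak marks the recovery phase
  transition as `k → M`. Encoding the raw (non-sparsified) frame is
  available via `params$sparsify = FALSE`; with the mildly compressible
  synthetic frames it compresses the whole curve toward low SNR without
  changing its qualitative shape.
* **SNR reference.** `20·log₁₀(‖f‖/‖f − Ψx̂‖)` against the original frame;
  a flag switches to measurement-domain SNR. Exact reconstructions are
  capped at a configurable 300 dB sentinel so tables stay finite.
* **Rounding.** `M = round(CF·N)`, `k = round(SM·M)`, half away from zero,
  floored at 1 — SM grids rarely hit integers.
* **Fresh Φ per frame.** Frame `i` uses seed `base_seed + i`, so frame
  averages are not conditioned on a single matrix draw.
* **Noise.** Measurement noise is Gaussian, rescaled so the realized
  `20·log₁₀(‖y‖/‖n‖)` equals the target exactly (norm-exact, not in
  expectation); the noise seed derives from the frame seed.
* **Failure handling.** Cells whose preconditions fail (e.g. `k > M` for a
  greedy algorithm) or whose frames error are flagged rows, not aborts, so
  grids always complete.
* **Caching.** Within one compression factor the l1 projector of each
  frame's operator is cached and shared across SM values and noise levels
  (the projector depends only on `A`); the cache is dropped when CF
  changes to bound memory at `N = 1024`.

The noise-split bound `SNR ≤ SNR_NF·SNR_noise/(SNR_NF − SNR_noise)` (all
linear amplitude ratios; `SNR_noise = ‖f‖/‖Ψ x_e‖` with `x_e = A⁺n` for
the l1 solver) is exposed by `noise_snr_bound()`. It is informative only
when the noise-induced error dominates the noise-free error
(`SNR_NF > SNR_noise`), which for the synthetic frames means exactly-sparse
signals; the suite checks it there on 50 seeded instances and finds it
binding (measured SNR up to ~0.6 of the bound) and never violated beyond
the 5% slack.

## The synthetic generator

`generate_emg_like()` produces seeded white Gaussian noise, zero-phase
band-pass filtered to 5–500 Hz (4th-order Butterworth run forward and
backward — zero phase so the burst envelope is not skewed), multiplied by
a raised-cosine-edged burst envelope (rest level 1; defaults: 1 burst/s,
0.3 s duration, 8× amplitude gain, 50 ms edges), segmented into frames of
`N = 1024` at 2 kHz and standardized to unit RMS per frame. The burst
phase is drawn from the seed, so independently seeded calls sample
burst/frame alignment — the validation experiments use one seed per frame
for exactly that reason (contiguous frames of a single record alias the
burst phase against the 0.512 s frame length).

What it emulates: the passband of a typical sEMG acquisition chain, the
on/off amplitude structure of dynamic contractions, and reproducibility.
What it does **not** emulate: motor-unit action-potential waveforms, the
shaped (non-flat) sEMG power spectrum, amplitude nonstationarity within a
contraction, or multi-channel structure. The in-band spectrum being flat
makes these frames markedly *less* compressible in any of the three bases
than real sEMG. Consequences to keep in mind when reading the validation
results: absolute SNR levels are several dB lower than on real
recordings, the SNR-vs-SM peak sits at the low edge of the expected
0.4–0.5 ridge (typically 0.3 here), and peak-to-floor drops are
correspondingly smaller. Passing tests therefore demonstrate algorithmic
correctness and the qualitative phenomenology — peak-then-collapse for
greedy algorithms, k-independent flatness for l1 under noise — not
real-data SNR magnitudes.

## Validation problem sizes

The suite's end-to-end experiments run at desk scale, chosen to finish in
minutes on one core while keeping Monte-Carlo fractions meaningful:
100 seeded trials at `N = 256, M = 128, k = 8` for exact recovery; 20
independently seeded frames at `N = 1024, CF = 0.5` for the noiseless
SNR-peak experiment (the same experiment `scripts/acceptance.R` re-runs
from a caller-supplied seed); 10 frames for the four-algorithm noisy
sweep; 50 exactly-sparse instances for the noise bound; 50 frames for the
db4-vs-Haar compressibility comparison.

## Known limitations

* Dense `N × N` bases and `N × N` projectors bound practical frame lengths
  to a few thousand samples; an operator-based formulation would lift this
  but is out of scope.
* The subgradient l1 solver inherits the slow tail convergence of its
  class: `1e-2`-level coefficient accuracy within 2000 iterations, not the
  `1e-6` of the greedy methods on easy instances. Its iteration count —
  not its failure rate — is the cost of its robustness to noise and to
  `k` misspecification.
* Exact reproduction of any specific published wavelet matrix is not
  attempted; orthonormality and perfect reconstruction are the contract.
* The noise-split bound uses the minimum-norm error model `x_e = A⁺n`,
  which describes the feasible-start perturbation exactly but only
  approximates the converged solver's error; it is validated empirically
  at 5% slack rather than proved for the iterate path.
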