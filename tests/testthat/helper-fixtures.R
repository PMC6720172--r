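# Shared test helpers. All fixtures are built in code from fixed seeds.

rel_err <- function(est, truth) {
  sqrt(sum((est - truth)^2)) / sqrt(sum(truth^2))
}

# Seeded dense Gaussian matrix (test-only; the package itself only uses
# Bernoulli sensing matrices).
gaussian_matrix <- function(M, N, seed) {
  set.seed(seed)
  matrix(rnorm(M * N), M, N)
}

# Exact recovery condition for a support set: max_{j outside} of
# ||A_sup^+ a_j||_1 < 1. When it holds, greedy column selection provably
# identifies `sup` from noiseless measurements, so such instances count as
# well-conditioned for oracle comparisons.
erc_holds <- function(A, sup) {
  pinvs <- solve(crossprod(A[, sup]), t(A[, sup]))
  G <- pinvs %*% A[, -sup, drop = FALSE]
  max(colSums(abs(G))) < 1
}

# A small seeded sensing problem: Bernoulli phi times an orthonormal basis,
# with an exactly k-sparse ground truth.
make_problem <- function(N, M, k, seed, basis = db4_basis) {
  psi <- basis(N)
  fix <- generate_sparse_fixture(N, k, psi, seed = seed)
  phi <- bernoulli_matrix(M, N, seed = seed)
  list(
    psi = psi, phi = phi,
    A = sensing_operator(phi, psi),
    x_star = as.numeric(fix$x),
    support = attr(fix$x, "support"),
    y = encode(fix$frame, phi),
    frame = fix$frame
  )
}
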