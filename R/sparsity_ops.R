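# Support-selection and truncation operators shared by CoSaMP, NIHT and the
# evaluation harness.

#' Select the k largest basis-weighted coefficients
#'
#' Returns the index set Lambda of the `k` entries of `x` with largest
#' weighted magnitude `|x_i| * ||Psi_i||_2`. For the orthonormal bases built
#' by this package the column norms are all 1, so the weighting coincides
#' with plain magnitude; it is applied as defined so non-normalized bases are
#' handled correctly. Ties are broken by lower index, making the selection
#' deterministic.
#'
#' @param x Numeric coefficient vector.
#' @param k Number of indices to keep, `1 <= k <= length(x)`.
#' @param psi Optional `cs_basis` (or matrix) supplying column norms;
#'   `NULL` (the default) means unit weights.
#' @return Sorted integer vector of `k` indices.
#' @export
supp_k <- function(x, k, psi = NULL) {
  k <- check_scalar_count(k, "k")
  if (k > length(x)) {
    stop("`k` must not exceed the length of `x`", call. = FALSE)
  }
  gamma <- abs(x)
  if (!is.null(psi)) {
    norms <- if (inherits(psi, "cs_basis")) psi$column_norms
             else sqrt(colSums(as.matrix(psi)^2))
    if (length(norms) != length(x)) {
      stop("`psi` does not match the length of `x`", call. = FALSE)
    }
    gamma <- gamma * norms
  }
  # order() with decreasing magnitude is stable, so ties fall to lower index
  sort(order(gamma, decreasing = TRUE)[seq_len(k)])
}

#' Restrict a vector to a support set
#'
#' Keeps the entries of `x` indexed by `support` and sets every other entry
#' to exactly zero.
#'
#' @param x Numeric vector.
#' @param support Integer indices in `1:length(x)` (duplicates ignored);
#'   may be empty, giving the zero vector.
#' @return Numeric vector of the same length as `x`.
#' @export
restrict_support <- function(x, support) {
  support <- as.integer(support)
  if (length(support) && (min(support) < 1L || max(support) > length(x))) {
    stop("`support` contains indices outside 1:length(x)", call. = FALSE)
  }
  out <- numeric(length(x))
  out[support] <- x[support]
  out
}

#' Best k-term truncation (reduced operator)
#'
#' The composition of [supp_k()] and [restrict_support()]: keeps the `k`
#' coefficients with largest basis-weighted magnitude and zeroes the rest.
#' For an orthonormal basis this is the best k-term approximation of the
#' synthesized frame in the l2 sense. Idempotent; the support always has
#' cardinality `k` even if `x` has fewer nonzeros (zero-valued indices are
#' then admitted).
#'
#' @inheritParams supp_k
#' @return Numeric vector with at most `k` nonzero entries; attributes
#'   `support` (the sorted index set) and `k`.
#' @export
reduce_k <- function(x, k, psi = NULL) {
  lam <- supp_k(x, k, psi)
  structure(restrict_support(x, lam), support = lam, k = as.integer(k))
}
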