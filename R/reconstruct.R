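# Common reconstruction-result container and algorithm dispatcher.

new_cs_reconstruction <- function(x, support, algorithm, iterations,
                                  converged, residual_trace = numeric(0),
                                  warnings = character(0), psi = NULL) {
  f_rec <- if (!is.null(psi)) synthesize(psi, x) else NULL
  structure(
    list(
      x = x,
      support = support,
      f_rec = f_rec,
      algorithm = algorithm,
      iterations = as.integer(iterations),
      converged = isTRUE(converged),
      residual_trace = residual_trace,
      warnings = warnings
    ),
    class = "cs_reconstruction"
  )
}

#' @export
print.cs_reconstruction <- function(x, ...) {
  cat(sprintf(
    "<cs_reconstruction %s: %d/%d nonzero, %d iterations, %s%s>\n",
    x$algorithm, sum(x$x != 0), length(x$x), x$iterations,
    if (x$converged) "converged" else "iteration limit",
    if (length(x$warnings)) sprintf(", %d warning(s)", length(x$warnings)) else ""
  ))
  invisible(x)
}

#' Reconstruct sparse coefficients from compressed measurements
#'
#' Dispatches to one of the four reconstruction algorithms. All operate on
#' the combined sensing operator `A = Phi %*% Psi` (see
#' [sensing_operator()]) and the measurement vector `y`.
#'
#' @param A M x N sensing operator.
#' @param y Measurement vector of length M.
#' @param algo One of `"l1"`, `"omp"`, `"cosamp"`, `"niht"`.
#' @param k Sparsity level (required for the greedy algorithms; for `"l1"`
#'   an optional final truncation).
#' @param psi Optional `cs_basis`; when given, the result carries the
#'   synthesized frame `f_rec` and k-term selection is basis-weighted.
#' @param ... Further arguments passed to the algorithm (e.g. `eps_max`,
#'   `n_iter`, `gamma`).
#' @return A `cs_reconstruction` object.
#' @export
reconstruct <- function(A, y, algo = c("l1", "omp", "cosamp", "niht"),
                        k = NULL, psi = NULL, ...) {
  algo <- match.arg(algo)
  switch(algo,
    l1 = l1_reconstruct(A, y, k = k, psi = psi, ...),
    omp = omp_reconstruct(A, y, k = k, psi = psi, ...),
    cosamp = cosamp_reconstruct(A, y, k = k, psi = psi, ...),
    niht = niht_reconstruct(A, y, k = k, psi = psi, ...)
  )
}
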