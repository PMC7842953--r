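#' Block-coordinate footprint update (HALS)
#'
#' One or more passes of the per-neuron nonnegative update
#' \deqn{A_{p(n),n} \leftarrow \lfloor A_{p(n),n} +
#'   (L_{p(n),n} - (AM)_{p(n),n}) / M_{nn} \rfloor_+}
#' restricted to each component's allowed support `p(n)`, with cached
#' sufficient statistics `L = (Y - B) C'` and `M = C C'` (any common
#' scaling of `L` and `M` cancels). The residual objective is
#' non-increasing.
#'
#' @param L `d x N` matrix.
#' @param M `N x N` matrix.
#' @param A `d x N` matrix (dense or sparse).
#' @param supports list of pixel-index vectors `p(n)`.
#' @param n_pass passes over all neurons.
#' @return updated dense `d x N` matrix.
#' @export
hals_update_A <- function(L, M, A, supports, n_pass = 1L) {
  A <- as.matrix(A)
  N <- ncol(A)
  for (pass in seq_len(n_pass)) {
    for (n in seq_len(N)) {
      if (M[n, n] <= 0) {
        warning("component ", n, " has zero temporal energy; skipped")
        next
      }
      p <- supports[[n]]
      am <- A[p, , drop = FALSE] %*% M[, n]
      A[p, n] <- pmax(0, A[p, n] + (L[p, n] - am) / M[n, n])
    }
  }
  A
}

#' Block-coordinate trace update
#'
#' Per-component nonnegative least-squares refinement of the traces given
#' footprints and the background-subtracted data, using cached
#' `A'(Y - B)` and `A'A`; the fit objective is non-increasing.
#'
#' @param A `d x N` footprints.
#' @param YmB `d x T` background-subtracted data `Y - B`.
#' @param C `N x T` current traces (warm start).
#' @param n_pass passes over components.
#' @return updated `N x T` matrix.
#' @export
update_C_batch <- function(A, YmB, C, n_pass = 1L) {
  AtY <- as.matrix(Matrix::crossprod(A, YmB))
  AtA <- as.matrix(Matrix::crossprod(A))
  N <- nrow(C)
  for (pass in seq_len(n_pass)) {
    for (n in seq_len(N)) {
      if (AtA[n, n] <= 0) {
        warning("component ", n, " has zero spatial energy; skipped")
        next
      }
      resid_n <- AtY[n, ] - AtA[n, ] %*% C
      C[n, ] <- pmax(0, C[n, ] + as.numeric(resid_n) / AtA[n, n])
    }
  }
  C
}
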