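#' Ring neighborhoods on the pixel lattice
#'
#' `ring_neighbors` returns the pixel indices at Euclidean distance
#' `[l, l + 1)` from pixel `i` (clipped to the field of view);
#' `ring_graph` precomputes them for every pixel.
#'
#' @param i pixel index (1-based, column-major).
#' @param l ring radius in pixels, `l > 0`.
#' @param dims FOV dimensions `c(rows, cols)`.
#' @return `ring_neighbors`: integer vector of pixel indices.
#'   `ring_graph`: object of class `ring_graph` with the per-pixel index
#'   lists, the radius and the dims.
#' @export
ring_neighbors <- function(i, l, dims) {
  if (l <= 0) stop("ring radius l must be > 0", call. = FALSE)
  offs <- ring_offsets(l)
  rc <- pix_rowcol(i, dims)
  r <- rc[1] + offs[, 1]; c_ <- rc[2] + offs[, 2]
  ok <- r >= 1 & r <= dims[1] & c_ >= 1 & c_ <= dims[2]
  sort(pix_index(r[ok], c_[ok], dims))
}

# lattice offsets with Euclidean norm in [l, l+1)
ring_offsets <- function(l, width = 1) {
  h <- ceiling(l + width)
  g <- as.matrix(expand.grid(dr = -h:h, dc = -h:h))
  d <- sqrt(rowSums(g^2))
  g[d >= l & d < l + width, , drop = FALSE]
}

#' @rdname ring_neighbors
#' @export
ring_graph <- function(l, dims) {
  offs <- ring_offsets(l)
  d <- prod(dims)
  rows <- rep(seq_len(dims[1]), dims[2])
  cols <- rep(seq_len(dims[2]), each = dims[1])
  nb <- vector("list", d)
  # vectorized over pixels, looping offsets
  idx_mat <- matrix(NA_integer_, d, nrow(offs))
  for (k in seq_len(nrow(offs))) {
    r <- rows + offs[k, 1]; c_ <- cols + offs[k, 2]
    ok <- r >= 1 & r <= dims[1] & c_ >= 1 & c_ <= dims[2]
    idx_mat[ok, k] <- pix_index(r[ok], c_[ok], dims)
  }
  for (i in seq_len(d)) {
    v <- idx_mat[i, ]
    nb[[i]] <- sort(v[!is.na(v)])
  }
  structure(list(neighbors = nb, l = l, dims = as.integer(dims)),
            class = "ring_graph")
}

#' Estimate ring weights from second-moment statistics
#'
#' Solves, for every pixel `i`, the per-pixel normal equations
#' \deqn{W_{i, r_l(i)} = \chi_{i, r_l(i)} \chi_{r_l(i), r_l(i)}^{-1}}
#' where `chi` accumulates `X X'` of the neuron- and baseline-subtracted
#' movie `X`. Rank-deficient blocks are regularized by a tiny ridge
#' (`1e-9 * trace / |ring|`), falling back to the least-norm solution.
#'
#' @param chi `d x d` second-moment matrix (dense or sparse), or `NULL`
#'   if `X` is given.
#' @param graph a [ring_graph()].
#' @param X optional `d x T` residual movie from which `chi = X %*% t(X)`
#'   is formed.
#' @return sparse `dgCMatrix` `W` with row supports on the rings.
#' @export
solve_ring_weights <- function(chi = NULL, graph, X = NULL) {
  if (is.null(chi)) {
    stopifnot(!is.null(X))
    chi <- tcrossprod(X)
  }
  d <- prod(graph$dims)
  stopifnot(nrow(chi) == d)
  nb <- graph$neighbors
  nnz <- sum(lengths(nb))
  ii <- integer(nnz); jj <- integer(nnz); xx <- numeric(nnz)
  pos <- 0L
  for (i in seq_len(d)) {
    r <- nb[[i]]
    k <- length(r)
    if (k == 0L) next
    Crr <- chi[r, r, drop = FALSE]
    cir <- chi[i, r]
    tr <- sum(diag(Crr))
    w <- if (tr <= 0) {
      numeric(k)
    } else {
      eps <- 1e-9 * tr / k
      sol <- tryCatch(solve(Crr + diag(eps, k), cir),
                      error = function(e) qr.solve(Crr, cir, tol = 1e-12))
      as.numeric(sol)
    }
    idx <- pos + seq_len(k)
    ii[idx] <- i; jj[idx] <- r; xx[idx] <- w
    pos <- pos + k
  }
  Matrix::sparseMatrix(i = ii[seq_len(pos)], j = jj[seq_len(pos)],
                       x = xx[seq_len(pos)], dims = c(d, d))
}

#' Evaluate the ring background model
#'
#' Returns \eqn{B = \bar b 1' + W (Y - A C - \bar b 1')} for the given
#' frames. With spatial decimation active the fluctuating part is
#' computed in the decimated space and upsampled (nearest neighbor); the
#' baseline stays at full resolution.
#'
#' @param W sparse ring weight matrix (in decimated space if
#'   `decimate > 1`).
#' @param b_bar constant baseline (full resolution, length `d`).
#' @param Y `d x T` frames.
#' @param A,C footprints and traces (may be 0-column/0-row for none).
#' @param dims FOV dims.
#' @param decimate integer decimation factor of `W`'s space.
#' @return `d x T` matrix of background frames.
#' @export
evaluate_background <- function(W, b_bar, Y, A = NULL, C = NULL, dims,
                                decimate = 1L) {
  X <- Y - b_bar
  if (!is.null(A) && ncol(A) > 0) X <- X - as.matrix(A %*% C)
  if (decimate > 1L) {
    Xd <- decimate_frames(X, dims, decimate)
    Bf <- as.matrix(W %*% Xd)
    Bf <- undecimate_frames(Bf, dims, decimate)
  } else {
    Bf <- as.matrix(W %*% X)
  }
  Bf + b_bar
}

#' Block-mean spatial decimation and nearest-neighbor upsampling
#'
#' `decimate_image` averages `factor x factor` blocks (trailing rows or
#' columns that do not fill a block are averaged over the partial block);
#' `undecimate_image` repeats each decimated pixel back to full size.
#' `factor = 1` is the identity.
#'
#' @param img matrix.
#' @param factor positive integer.
#' @return matrix of reduced (resp. restored) size.
#' @export
decimate_image <- function(img, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("decimation factor must be >= 1", call. = FALSE)
  if (factor == 1L) return(img)
  rgrp <- (seq_len(nrow(img)) - 1L) %/% factor + 1L
  cgrp <- (seq_len(ncol(img)) - 1L) %/% factor + 1L
  sums <- rowsum(img, rgrp)
  sums <- t(rowsum(t(sums), cgrp))
  cnt <- outer(tabulate(rgrp), tabulate(cgrp))
  sums / cnt
}

#' @rdname decimate_image
#' @param dims_full original dimensions for `undecimate_image`.
#' @export
undecimate_image <- function(img, factor, dims_full) {
  factor <- as.integer(factor)
  if (factor == 1L) return(img)
  ridx <- (seq_len(dims_full[1]) - 1L) %/% factor + 1L
  cidx <- (seq_len(dims_full[2]) - 1L) %/% factor + 1L
  img[ridx, cidx, drop = FALSE]
}

decimated_dims <- function(dims, factor) {
  as.integer(ceiling(dims / factor))
}

# d x T <-> d_dec x T convenience wrappers
decimate_frames <- function(Y, dims, factor) {
  if (factor == 1L) return(Y)
  dd <- decimated_dims(dims, factor)
  out <- matrix(0, prod(dd), ncol(Y))
  for (t in seq_len(ncol(Y)))
    out[, t] <- as.numeric(decimate_image(matrix(Y[, t], dims[1]), factor))
  out
}

undecimate_frames <- function(Yd, dims, factor) {
  if (factor == 1L) return(Yd)
  dd <- decimated_dims(dims, factor)
  out <- matrix(0, prod(dims), ncol(Yd))
  for (t in seq_len(ncol(Yd)))
    out[, t] <- as.numeric(undecimate_image(matrix(Yd[, t], dd[1]), factor,
                                            dims))
  out
}
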