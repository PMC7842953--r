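# Internal helpers: indexing, separable filtering, local maxima.

# pixel index <-> (row, col), 1-based, column-major
pix_index <- function(row, col, dims) (col - 1L) * dims[1] + row
pix_rowcol <- function(i, dims) {
  i <- as.integer(i - 1L)
  cbind(row = i %% dims[1] + 1L, col = i %/% dims[1] + 1L)
}

# movie array (rows x cols x T) -> d x T matrix and back
vec_frames <- function(movie) {
  d <- dim(movie)
  matrix(movie, nrow = d[1] * d[2], ncol = if (length(d) == 3) d[3] else 1L)
}
unvec_frames <- function(Y, dims) {
  array(Y, dim = c(dims[1], dims[2], ncol(Y)))
}

gaussian_kernel1d <- function(sigma, truncate = 2.5) {
  h <- max(1L, as.integer(ceiling(truncate * sigma)))
  x <- (-h):h
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 1-D convolution along rows (margin = 1) or cols (margin = 2) of a matrix,
# replicate-padded at the borders
conv1d_mat <- function(img, kernel, margin) {
  h <- (length(kernel) - 1L) %/% 2L
  n <- dim(img)[margin]
  out <- matrix(0, nrow(img), ncol(img))
  for (j in seq_along(kernel)) {
    off <- j - h - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- out + kernel[j] * (if (margin == 1L) img[idx, , drop = FALSE]
                              else img[, idx, drop = FALSE])
  }
  out
}

# separable Gaussian blur with replicate borders
gblur <- function(img, sigma, truncate = 2.5) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel1d(sigma, truncate)
  conv1d_mat(conv1d_mat(img, k, 1L), k, 2L)
}

# zero-sum Gaussian band-pass (Gaussian minus box mean over the same
# support), the spatial filter applied before computing seed images;
# suppresses both pixel noise and the spatially coarse background
spatial_bandpass <- function(img, sigma, truncate = 2.5) {
  k <- gaussian_kernel1d(sigma, truncate)
  box <- rep(1 / length(k), length(k))
  g <- conv1d_mat(conv1d_mat(img, k, 1L), k, 2L)
  b <- conv1d_mat(conv1d_mat(img, box, 1L), box, 2L)
  g - b
}

# high-pass used for motion templates: image minus a wide Gaussian blur
spatial_highpass <- function(img, sigma) img - gblur(img, sigma)

# grey-scale dilation with a square window of half-width h (replicate border)
dilate_square <- function(img, h) {
  out <- img
  for (off in seq_len(h)) {
    n <- nrow(img)
    idx_up <- pmin(pmax(seq_len(n) + off, 1L), n)
    idx_dn <- pmin(pmax(seq_len(n) - off, 1L), n)
    out <- pmax(out, img[idx_up, , drop = FALSE], img[idx_dn, , drop = FALSE])
  }
  tmp <- out
  for (off in seq_len(h)) {
    m <- ncol(img)
    idx_up <- pmin(pmax(seq_len(m) + off, 1L), m)
    idx_dn <- pmin(pmax(seq_len(m) - off, 1L), m)
    out <- pmax(out, tmp[, idx_up, drop = FALSE], tmp[, idx_dn, drop = FALSE])
  }
  out
}

# local maxima of an image with an exclusion half-width; returns pixel
# indices ordered by decreasing value
local_maxima <- function(img, halfwidth, min_value = -Inf) {
  dil <- dilate_square(img, max(1L, as.integer(halfwidth)))
  idx <- which(img >= dil & img > min_value)
  idx[order(img[idx], decreasing = TRUE)]
}

# deterministic small sub-seed derived from a master seed and a label
derive_seed <- function(seed, salt) {
  (as.integer(seed) * 7919L + sum(utf8ToInt(salt)) * 104729L) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
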