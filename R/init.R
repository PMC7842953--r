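# Batch initialization: seed images, greedy seeding with local rank-1 NMF,
# alternating HALS / ring-background refinement on the initial frames.

# TRUE for pixels within `margin` of the FOV border (seed images are
# unreliable there: border handling of the spatial filter leaks the
# coarse background)
border_mask <- function(dims, margin) {
  rows <- rep(seq_len(dims[1]), dims[2])
  cols <- rep(seq_len(dims[2]), each = dims[1])
  rows <= margin | rows > dims[1] - margin |
    cols <= margin | cols > dims[2] - margin
}

# 8-connected neighbor index map: d x 8 matrix of pixel indices (NA at the
# FOV border)
neighbor_map <- function(dims) {
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  d <- prod(dims)
  rows <- rep(seq_len(dims[1]), dims[2])
  cols <- rep(seq_len(dims[2]), each = dims[1])
  out <- matrix(NA_integer_, d, 8)
  for (k in 1:8) {
    r <- rows + offs[k, 1]; c_ <- cols + offs[k, 2]
    ok <- r >= 1 & r <= dims[1] & c_ >= 1 & c_ <= dims[2]
    out[ok, k] <- pix_index(r[ok], c_[ok], dims)
  }
  out
}

# mean Pearson correlation with the 8-connected neighbors, per pixel
local_corr_image <- function(Y, dims, nbr = neighbor_map(dims)) {
  T_ <- ncol(Y)
  mu <- rowMeans(Y)
  v <- rowMeans(Y^2) - mu^2
  sdv <- sqrt(pmax(v, 0))
  corr_sum <- numeric(nrow(Y))
  cnt <- numeric(nrow(Y))
  for (k in seq_len(ncol(nbr))) {
    j <- nbr[, k]
    ok <- which(!is.na(j))
    nu <- rowSums(Y[ok, , drop = FALSE] * Y[j[ok], , drop = FALSE]) / T_
    den <- sdv[ok] * sdv[j[ok]]
    r <- ifelse(den > 1e-12, (nu - mu[ok] * mu[j[ok]]) / den, 0)
    corr_sum[ok] <- corr_sum[ok] + r
    cnt[ok] <- cnt[ok] + 1
  }
  corr_sum / pmax(cnt, 1)
}

pnr_image <- function(Y, sigma) {
  mx <- apply(Y, 1, max)
  ifelse(sigma > 1e-12, mx / sigma, 0)
}

# band-pass filter every frame of a d x T matrix
filter_frames <- function(Y, dims, sigma_filter) {
  out <- Y
  for (t in seq_len(ncol(Y)))
    out[, t] <- as.numeric(spatial_bandpass(matrix(Y[, t], dims[1]),
                                            sigma_filter))
  out
}

window_indices <- function(center_pix, halfwidth, dims) {
  rc <- pix_rowcol(center_pix, dims)
  r <- max(1, rc[1] - halfwidth):min(dims[1], rc[1] + halfwidth)
  c_ <- max(1, rc[2] - halfwidth):min(dims[2], rc[2] + halfwidth)
  as.integer(outer(r, (c_ - 1L) * dims[1], "+"))
}

# local rank-1 NMF of a (window x T) data block. The temporal factor is
# anchored at `c0` (the band-pass-filtered trace at the seed pixel, which
# is free of the coarse background): if the alternation drifts away from
# the anchor it is restarted from the plain regression against c0.
# Returns unit-peak-normalized footprint and scaled trace.
local_rank1_nmf <- function(R_w, seed_row, c0 = NULL, n_iter = 30L) {
  Rp <- pmax(R_w, 0)
  c_ <- if (!is.null(c0)) pmax(c0, 0) else pmax(Rp[seed_row, ], 0)
  if (sum(c_^2) < 1e-12) c_ <- colMeans(Rp)
  anchor <- c_
  regression_pair <- function(cv) {
    a <- pmax(0, as.numeric(Rp %*% cv) / sum(cv^2))
    cv2 <- if (sum(a^2) > 1e-12)
      pmax(0, as.numeric(crossprod(Rp, a)) / sum(a^2)) else cv
    list(a = a, c = cv2)
  }
  a <- numeric(nrow(Rp))
  for (it in seq_len(n_iter)) {
    cc <- sum(c_^2)
    if (cc < 1e-12) break
    a <- pmax(0, as.numeric(Rp %*% c_) / cc)
    aa <- sum(a^2)
    if (aa < 1e-12) break
    c_ <- pmax(0, as.numeric(crossprod(Rp, a)) / aa)
  }
  drift <- sum(anchor^2) > 1e-12 && sum(c_^2) > 1e-12 &&
    suppressWarnings(cor(c_, anchor)) < 0.5
  if (drift || sum(c_^2) < 1e-12) {
    fit <- regression_pair(anchor)
    a <- fit$a; c_ <- fit$c
  }
  pk <- max(a)
  if (pk > 0) { c_ <- c_ * pk; a <- a / pk }
  list(a = a, c = c_)
}

# subtract, per frame, the median over the window border (local coarse
# background) before the rank-1 fit
local_residual_block <- function(R, w_idx, dims, halfwidth, center_pix) {
  blk <- R[w_idx, , drop = FALSE]
  rc_c <- pix_rowcol(center_pix, dims)
  rc <- pix_rowcol(w_idx, dims)
  border <- pmax(abs(rc[, 1] - rc_c[1]), abs(rc[, 2] - rc_c[2])) >=
    halfwidth - 1
  if (sum(border) >= 4) {
    bg <- apply(blk[border, , drop = FALSE], 2, median)
    blk <- sweep(blk, 2, bg)
  }
  blk
}

#' Initialize components and background from an initial batch
#'
#' Greedy seeding on the spatially band-pass-filtered data: while the
#' pixel maximizing the product of local-correlation and peak-to-noise
#' images passes both thresholds (`min_corr`, `min_pnr`), a component is
#' initialized there by local rank-1 NMF of the residual in a window of
#' four neuron radii, and subtracted. The component set is then refined by
#' alternating trace updates (block-coordinate + OASIS), footprint HALS,
#' and ring-background weight estimation.
#'
#' @param movie `rows x cols x T_b` array (or `d x T` matrix plus `dims`).
#' @param config a [cnmfe_config()].
#' @param dims FOV dims if `movie` is a matrix.
#' @param background `"ring"` (the 1-photon ring model) or `"flat"`
#'   (constant baseline only, for data whose coarse background has
#'   already been removed).
#' @return list with `A` (sparse `d x N`), `C`, `C_raw`, `S`, `supports`,
#'   `W` (sparse, decimated space), `b_bar`, `sigma` (per-pixel noise of
#'   the raw data), `gamma`, `lambda` (per component), `graph`, `seeds`
#'   (data frame of accepted seeds), `dims`.
#' @export
initialize_batch <- function(movie, config, dims = NULL,
                             background = c("ring", "flat")) {
  background <- match.arg(background)
  if (length(dim(movie)) == 3L) {
    dims <- dim(movie)[1:2]
    Y <- vec_frames(movie)
  } else {
    stopifnot(!is.null(dims))
    Y <- movie
  }
  d <- nrow(Y); T_ <- ncol(Y)
  if (T_ < 32L) stop("initial batch too short (need >= 32 frames)",
                     call. = FALSE)
  cfg <- config
  sig_filt <- cfg$neuron_radius / 2
  nbr <- neighbor_map(dims)

  sigma_raw <- estimate_noise(Y)
  Yf <- filter_frames(Y, dims, sig_filt)
  sigma_f <- estimate_noise(Yf)

  halfwin <- max(2L, as.integer(round(2 * cfg$neuron_radius)))
  b_bar <- rowMeans(Y)
  R_raw <- Y - b_bar                  # running residual, raw scale
  Rf <- Yf                            # running residual, filtered scale

  A_cols <- list(); C_rows <- list(); supports <- list()
  seeds <- data.frame(pixel = integer(0), row = integer(0),
                      col = integer(0), corr = numeric(0),
                      pnr = numeric(0))
  corr_img <- local_corr_image(Rf, dims, nbr)
  pnr_img <- pnr_image(Rf, sigma_f)
  max_seeds <- 4L * max(10L, as.integer(d / (cfg$neuron_radius^2 * 16)))
  suppressed <- border_mask(dims, max(1L, round(cfg$neuron_radius)))
  excl <- max(1L, as.integer(round(cfg$neuron_radius)))

  repeat {
    eligible <- corr_img >= cfg$min_corr & pnr_img >= cfg$min_pnr &
      !suppressed
    if (!any(eligible)) break
    score <- ifelse(eligible, corr_img * pnr_img, -Inf)
    seed <- which.max(score)
    w_idx <- window_indices(seed, halfwin, dims)
    blk <- local_residual_block(R_raw, w_idx, dims, halfwin, seed)
    anchor <- pmax(Rf[seed, ], 0)
    fit <- local_rank1_nmf(blk, match(seed, w_idx), c0 = anchor)
    qc_ok <- max(fit$a) > 0 && sum(fit$c^2) > 1e-12 &&
      sum(anchor^2) > 1e-12 &&
      suppressWarnings(cor(fit$c, anchor)) >= 0.6 &&
      max(fit$c) >= cfg$min_pnr * 0.5 * sigma_raw[seed]
    if (!qc_ok) {
      # unconvincing fit: exclude this pixel from further seeding
      suppressed[seed] <- TRUE
      next
    }
    n_new <- length(A_cols) + 1L
    A_cols[[n_new]] <- list(idx = w_idx, val = fit$a)
    C_rows[[n_new]] <- fit$c
    supports[[n_new]] <- w_idx
    rc <- pix_rowcol(seed, dims)
    seeds <- rbind(seeds, data.frame(pixel = seed, row = rc[1], col = rc[2],
                                     corr = corr_img[seed],
                                     pnr = pnr_img[seed]))
    # subtract from both residuals and refresh images locally
    R_raw[w_idx, ] <- R_raw[w_idx, ] - outer(fit$a, fit$c)
    refresh <- window_indices(seed, halfwin + as.integer(ceiling(3 * sig_filt)),
                              dims)
    ac_img <- matrix(0, dims[1], dims[2])
    ac_img[w_idx] <- fit$a
    af <- as.numeric(spatial_bandpass(ac_img, sig_filt))
    Rf[refresh, ] <- Rf[refresh, ] - outer(af[refresh], fit$c)
    corr_img[refresh] <- local_corr_image(Rf, dims, nbr)[refresh]
    pnr_img[refresh] <- pnr_image(Rf[refresh, , drop = FALSE],
                                  sigma_f[refresh])
    suppressed[window_indices(seed, excl, dims)] <- TRUE
    if (length(A_cols) >= max_seeds) break
  }

  N <- length(A_cols)
  A <- if (N == 0) {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(d, 0))
  } else {
    Matrix::sparseMatrix(
      i = unlist(lapply(A_cols, `[[`, "idx")),
      j = rep(seq_len(N), vapply(A_cols, function(z) length(z$idx), 1L)),
      x = unlist(lapply(A_cols, `[[`, "val")), dims = c(d, N))
  }
  C <- if (N) do.call(rbind, C_rows) else matrix(0, 0, T_)

  graph <- if (background == "ring")
    ring_graph(max(1, cfg$ring_radius / cfg$decimate),
               decimated_dims(dims, cfg$decimate)) else NULL
  W <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = rep(prod(decimated_dims(dims,
                                                           cfg$decimate)), 2))
  gamma_n <- rep(list(if (is.null(cfg$gamma)) NULL else cfg$gamma), N)
  lambda_n <- rep(NA_real_, N)
  S <- matrix(0, N, T_)
  C_raw <- C

  for (outer in seq_len(cfg$outer_iter)) {
    b_bar <- rowMeans(Y - as.matrix(A %*% C))
    if (background == "ring") {
      X <- Y - as.matrix(A %*% C) - b_bar
      Xd <- decimate_frames(X, dims, cfg$decimate)
      W <- solve_ring_weights(graph = graph, X = Xd)
      B <- evaluate_background(W, b_bar, Y, A, C, dims, cfg$decimate)
    } else {
      B <- matrix(b_bar, d, T_)
    }
    YmB <- Y - B
    if (N) {
      C_raw <- update_C_batch(A, YmB, C_raw, n_pass = 3L)
      for (n in seq_len(N)) {
        if (is.null(gamma_n[[n]]))
          gamma_n[[n]] <- estimate_ar_coefs(C_raw[n, ], p = cfg$ar_order)
        if (is.na(lambda_n[n]))
          lambda_n[n] <- if (is.null(cfg$lambda))
            default_lambda(C_raw[n, ]) else cfg$lambda
        dec <- oasis(C_raw[n, ], gamma_n[[n]], lambda_n[n], cfg$s_min)
        C[n, ] <- dec$c
        S[n, ] <- dec$s
      }
      A <- hals_update_A(compute_L(YmB, C), compute_M(C), A, supports,
                         n_pass = 3L)
      A <- Matrix::drop0(methods::as(A, "CsparseMatrix"))
    }
  }
  b_bar <- rowMeans(Y - as.matrix(A %*% C))

  list(A = A, C = C, C_raw = C_raw, S = S, supports = supports, W = W,
       b_bar = b_bar, sigma = sigma_raw, gamma = gamma_n,
       lambda = lambda_n, graph = graph, seeds = seeds, dims = dims)
}

compute_L <- function(YmB, C) as.matrix(YmB %*% t(C))
compute_M <- function(C) C %*% t(C)

# l1 penalty scaled to the estimated noise level of the trace
default_lambda <- function(y, scale = 1) {
  if (length(y) >= 32) scale * estimate_noise(y) else 0
}

#' Residual objective of the factorization
#'
#' `||Y - AC - B||_F^2` for the current estimates; used to monitor the
#' alternating refinement.
#' @param Y `d x T` data.
#' @param A,C,B current factors (B as `d x T` background).
#' @return scalar.
#' @export
cnmfe_objective <- function(Y, A, C, B) {
  R <- Y - B
  if (ncol(A) > 0) R <- R - as.matrix(A %*% C)
  sum(R^2)
}
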