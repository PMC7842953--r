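#' Convolutional ring background model
#'
#' A background model with `K` shared annular convolution kernels `h_k`
#' (support: lattice offsets at distance `[l, l + w)` from the center),
#' per-pixel mixing weights `w_k` and a constant baseline:
#' `f(y) = sum_k w_k * (h_k conv y) + b_bar` (zero padding at the FOV
#' border). It parametrizes the ring weight matrix as
#' `W = sum_k diag(w_k) H_k`, with `K (d + |annulus|) + d` parameters in
#' total, and is trained to under-approximate the raw movie with a
#' quantile (pinball) loss.
#'
#' @param H `|annulus| x K` kernel matrix.
#' @param Wmap `d x K` mixing weights.
#' @param b_bar length-`d` baseline.
#' @param dims FOV dims.
#' @param inner_radius inner annulus radius `l`.
#' @param width annulus width `w` in pixels.
#' @param quantile quantile `q` of the training loss.
#' @return object of class `ring_cnn`.
#' @export
ring_cnn_model <- function(H, Wmap, b_bar, dims, inner_radius, width,
                           quantile = 0.02) {
  offs <- ring_offsets(inner_radius, width)
  stopifnot(nrow(H) == nrow(offs), nrow(Wmap) == prod(dims),
            length(b_bar) == prod(dims), ncol(H) == ncol(Wmap))
  structure(list(H = as.matrix(H), Wmap = as.matrix(Wmap),
                 b_bar = as.numeric(b_bar), dims = as.integer(dims),
                 inner_radius = inner_radius, width = width,
                 quantile = quantile, offsets = offs,
                 shift_idx = shift_index_map(offs, dims)),
            class = "ring_cnn")
}

# d x n_offsets matrix of source pixel indices (NA outside the FOV)
shift_index_map <- function(offs, dims) {
  d <- prod(dims)
  rows <- rep(seq_len(dims[1]), dims[2])
  cols <- rep(seq_len(dims[2]), each = dims[1])
  out <- matrix(NA_integer_, d, nrow(offs))
  for (k in seq_len(nrow(offs))) {
    r <- rows + offs[k, 1]; c_ <- cols + offs[k, 2]
    ok <- r >= 1 & r <= dims[1] & c_ >= 1 & c_ <= dims[2]
    out[ok, k] <- pix_index(r[ok], c_[ok], dims)
  }
  out
}

#' Number of free parameters of a ring-CNN model
#'
#' `K (d + |annulus|) + d`, counted by enumeration of the model arrays.
#' @param model a `ring_cnn`.
#' @return integer.
#' @export
ring_cnn_n_parameters <- function(model) {
  length(model$H) + length(model$Wmap) + length(model$b_bar)
}

# shifted copies of a frame vector for all annulus offsets (zero padded)
shifted_frame <- function(y, shift_idx) {
  out <- matrix(y[shift_idx], nrow(shift_idx), ncol(shift_idx))
  out[is.na(shift_idx)] <- 0
  out
}

#' Apply the ring-CNN background model to a frame
#'
#' @param model a [ring_cnn_model()].
#' @param y frame as length-`d` vector (or matrix of `dims`).
#' @return length-`d` background estimate.
#' @export
apply_model <- function(model, y) {
  y <- as.numeric(y)
  stopifnot(length(y) == prod(model$dims))
  Ysh <- shifted_frame(y, model$shift_idx)
  conv <- Ysh %*% model$H                 # d x K
  rowSums(model$Wmap * conv) + model$b_bar
}

#' Compile the ring-CNN into an explicit sparse matrix
#'
#' Returns the sparse `d x d` matrix `W = sum_k diag(w_k) H_k` such that
#' `W %*% y + b_bar` equals [apply_model()] for every frame.
#'
#' @param model a `ring_cnn`.
#' @return a `dgCMatrix`.
#' @export
to_sparse_matrix <- function(model) {
  d <- prod(model$dims)
  P <- model$shift_idx
  n_off <- ncol(P)
  K <- ncol(model$H)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (o in seq_len(n_off)) {
    ok <- which(!is.na(P[, o]))
    val <- numeric(length(ok))
    for (k in seq_len(K))
      val <- val + model$Wmap[ok, k] * model$H[o, k]
    ii <- c(ii, ok); jj <- c(jj, P[ok, o]); xx <- c(xx, val)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(d, d))
}

#' Quantile (pinball) loss
#'
#' `l_q(x, y) = q (x - y)` if `x >= y`, else `(1 - q)(y - x)`; the total
#' loss is `2 * sum(l_q)`. With `q = 0.5` the total equals the L1 norm of
#' `x - y`; small `q` penalizes over-approximation (`y > x`) more and
#' drives `y` to under-approximate `x`.
#'
#' @param x observed values.
#' @param y predicted values (same shape).
#' @param q quantile in `(0, 1]`.
#' @return total loss (nonnegative scalar).
#' @export
quantile_loss <- function(x, y, q) {
  if (q <= 0 || q > 1) stop("q must lie in (0, 1]", call. = FALSE)
  l <- ifelse(x >= y, q * (x - y), (1 - q) * (y - x))
  2 * sum(l)
}

# subgradient of quantile_loss wrt y; ties take the x >= y branch
quantile_loss_grad <- function(x, y, q) {
  2 * ifelse(x >= y, -q, 1 - q)
}

#' Train the ring-CNN background model
#'
#' Minimizes the quantile loss between the raw frames and the model
#' output by minibatch stochastic gradient descent with adaptive moment
#' estimation (the model is linear in its parameters, so gradients are
#' analytic). Frames are split into training and validation sets; the
#' parameters with the best validation loss are returned.
#'
#' @param Y `d x T` matrix of (motion-corrected) frames, or a movie
#'   array.
#' @param dims FOV dims (inferred from an array input).
#' @param config a [cnmfe_config()]; uses the `ringcnn` settings.
#' @param seed integer seed for the split and minibatch order.
#' @param verbose print per-epoch losses.
#' @return a trained `ring_cnn`; attribute `history` holds the loss
#'   trace, attribute `val_loss` the best validation loss (per frame).
#' @export
train_ring_cnn <- function(Y, config, dims = NULL, seed = 1,
                           verbose = FALSE) {
  if (length(dim(Y)) == 3L) { dims <- dim(Y)[1:2]; Y <- vec_frames(Y) }
  stopifnot(!is.null(dims))
  rc <- config$ringcnn
  d <- nrow(Y); T_ <- ncol(Y)
  if (T_ < 25L) stop("need at least 25 frames to train", call. = FALSE)
  set.seed(derive_seed(seed, "train_ring_cnn"))
  q <- rc$quantile
  K <- rc$n_kernels
  offs <- ring_offsets(config$ring_radius, rc$width)
  n_off <- nrow(offs)

  n_val <- max(1L, round(rc$val_frac * T_))
  idx <- sample.int(T_)
  val <- idx[seq_len(n_val)]
  trn <- idx[-seq_len(n_val)]

  # init: first kernel a normalized annulus mean at half weight, the
  # baseline at half the per-pixel median, so the initial prediction is
  # already close to the data everywhere (including the border, where
  # the zero-padded convolution is attenuated); further kernels start as
  # small perturbations
  H <- matrix(rnorm(n_off * K, 0, 0.01 / n_off), n_off, K)
  H[, 1] <- 1 / n_off
  Wmap <- matrix(0, d, K); Wmap[, 1] <- 0.5
  med <- apply(Y[, trn[seq_len(min(50, length(trn)))], drop = FALSE],
               1, median)
  b_bar <- pmax(0, 0.5 * med)
  model <- ring_cnn_model(H, Wmap, b_bar, dims, config$ring_radius,
                          rc$width, q)
  P <- model$shift_idx

  # Adam state
  mo <- list(H = 0 * H, W = 0 * Wmap, b = 0 * b_bar)
  ve <- mo
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- rc$lr
  step <- 0L
  batch_loss <- function(cols, H, Wmap, b_bar, with_grad = TRUE) {
    gH <- 0 * H; gW <- 0 * Wmap; gb <- 0 * b_bar; loss <- 0
    for (tt in cols) {
      y <- Y[, tt]
      Ysh <- shifted_frame(y, P)
      conv <- Ysh %*% H
      pred <- rowSums(Wmap * conv) + b_bar
      loss <- loss + quantile_loss(y, pred, q)
      if (with_grad) {
        g <- quantile_loss_grad(y, pred, q)
        gW <- gW + g * conv
        gH <- gH + crossprod(Ysh, g * Wmap)
        gb <- gb + g
      }
    }
    list(loss = loss / length(cols), gH = gH / length(cols),
         gW = gW / length(cols), gb = gb / length(cols))
  }

  best <- list(loss = Inf, H = H, W = Wmap, b = b_bar)
  hist <- data.frame(epoch = integer(0), train = numeric(0),
                     val = numeric(0))
  init_val <- NULL
  for (ep in seq_len(rc$epochs)) {
    lr_ep <- lr / sqrt(ep)      # decay tempers the quantile-loss
    ord <- sample(trn)          # oscillation around the optimum
    tr_loss <- 0; nb <- 0L
    for (start in seq(1, length(ord), by = rc$batch_size)) {
      cols <- ord[start:min(start + rc$batch_size - 1L, length(ord))]
      bl <- batch_loss(cols, H, Wmap, b_bar)
      tr_loss <- tr_loss + bl$loss; nb <- nb + 1L
      step <- step + 1L
      upd <- function(m, v, g) {
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g^2
        mh <- m / (1 - beta1^step); vh <- v / (1 - beta2^step)
        list(m = m, v = v, delta = lr_ep * mh / (sqrt(vh) + eps))
      }
      uH <- upd(mo$H, ve$H, bl$gH); mo$H <- uH$m; ve$H <- uH$v
      H <- H - uH$delta
      uW <- upd(mo$W, ve$W, bl$gW); mo$W <- uW$m; ve$W <- uW$v
      Wmap <- Wmap - uW$delta
      ub <- upd(mo$b, ve$b, bl$gb); mo$b <- ub$m; ve$b <- ub$v
      b_bar <- b_bar - ub$delta
    }
    vl <- batch_loss(val, H, Wmap, b_bar, with_grad = FALSE)$loss
    if (is.null(init_val)) init_val <- vl
    hist <- rbind(hist, data.frame(epoch = ep, train = tr_loss / nb,
                                   val = vl))
    if (verbose) message(sprintf("epoch %d train %.3f val %.3f", ep,
                                 tr_loss / nb, vl))
    if (vl < best$loss) best <- list(loss = vl, H = H, W = Wmap, b = b_bar)
    if (vl > 10 * init_val)
      stop("ring-CNN training diverged (validation loss ",
           signif(vl, 4), " vs initial ", signif(init_val, 4), ")",
           call. = FALSE)
  }
  # exact coordinate minimization of the baseline: for fixed kernels and
  # weights the pinball-optimal b_bar is the per-pixel q-quantile of the
  # residual (data minus convolutional part) over the training frames
  H <- best$H; Wmap <- best$W
  P_model <- shift_index_map(ring_offsets(config$ring_radius, rc$width),
                             dims)
  convpart <- sapply(trn, function(tt)
    rowSums(Wmap * (shifted_frame(Y[, tt], P_model) %*% H)))
  b_exact <- pmax(0, apply(Y[, trn, drop = FALSE] - convpart, 1,
                           quantile, probs = q, names = FALSE))
  vl_exact <- batch_loss(val, H, Wmap, b_exact, with_grad = FALSE)$loss
  if (vl_exact < best$loss) best <- list(loss = vl_exact, H = H, W = Wmap,
                                         b = b_exact)
  out <- ring_cnn_model(best$H, best$W, best$b, dims,
                        config$ring_radius, rc$width, q)
  attr(out, "history") <- hist
  attr(out, "val_loss") <- best$loss
  attr(out, "val_frames") <- val
  out
}

#' Order the kernels of a ring-CNN by importance (SVD normalization)
#'
#' The model output is invariant to a joint rotation of the kernel and
#' weight matrices. This rotates them so that `Wmap %*% t(H)` is
#' unchanged while the implied singular values are non-increasing, and
#' optionally truncates kernels whose singular value falls below a
#' threshold.
#'
#' @param model a `ring_cnn`.
#' @param truncate optional singular-value threshold.
#' @return normalized (possibly truncated) `ring_cnn`; attribute
#'   `singular_values` holds the spectrum.
#' @export
svd_normalize <- function(model, truncate = NULL) {
  qw <- qr(model$Wmap)
  qh <- qr(model$H)
  core <- qr.R(qw) %*% t(qr.R(qh))
  sv <- svd(core)
  s_half <- sqrt(sv$d)
  W_new <- qr.Q(qw) %*% sv$u %*% diag(s_half, length(s_half))
  H_new <- qr.Q(qh) %*% sv$v %*% diag(s_half, length(s_half))
  keep <- seq_along(sv$d)
  if (!is.null(truncate)) keep <- which(sv$d >= truncate)
  if (!length(keep)) keep <- 1L
  out <- ring_cnn_model(H_new[, keep, drop = FALSE],
                        W_new[, keep, drop = FALSE],
                        model$b_bar, model$dims, model$inner_radius,
                        model$width, model$quantile)
  attr(out, "singular_values") <- sv$d
  out
}

#' Online processing with a ring-CNN background model
#'
#' Trains the convolutional background model on the first
#' `ringcnn$init_frames` frames, removes the background from every frame
#' (`x_t = y_t - f(y_t - A c_{t-1})`), and runs the streaming
#' factorization on the background-free frames with a low-rank residual
#' background (rank `ringcnn$bg_rank` components with full-FOV support,
#' not deconvolved), detection of new components from the residual
#' buffer, and periodic shape updates. The background model is frozen
#' after initialization. With multiple epochs the final epoch only
#' tracks activity.
#'
#' @param movie `rows x cols x T` array.
#' @param config a [cnmfe_config()].
#' @param epochs passes over the movie; `NULL` uses 3 (convention for
#'   this pipeline), detection disabled on the last.
#' @param post_process merge and screen at the end.
#' @param verbose print progress.
#' @return a [results_bundle()] with a low-rank background and the
#'   trained model.
#' @export
run_ringcnn <- function(movie, config, epochs = NULL, post_process = TRUE,
                        verbose = FALSE) {
  cfg <- config
  epochs <- epochs %||% 3L
  Y <- if (length(dim(movie)) == 3L) vec_frames(movie) else movie
  dims <- dim(movie)[1:2]
  d <- nrow(Y); T_ <- ncol(Y)
  Tini <- min(cfg$ringcnn$init_frames, T_)
  if (cfg$offset != 0) Y <- Y - cfg$offset
  set.seed(derive_seed(cfg$seed, "run_ringcnn"))

  model <- train_ring_cnn(Y[, seq_len(Tini), drop = FALSE], cfg,
                          dims = dims, seed = cfg$seed,
                          verbose = verbose)
  Wsp <- to_sparse_matrix(model)
  subtract_bg <- function(Ycols, Cprev = NULL, A = NULL) {
    # x = y - f(y - A c_prev)
    inp <- Ycols
    if (!is.null(A) && ncol(A) > 0)
      inp <- inp - as.matrix(A %*% Cprev)
    pmax(Ycols - as.matrix(Wsp %*% inp) - model$b_bar, 0)
  }

  Xini <- subtract_bg(Y[, seq_len(min(cfg$init_frames, Tini)),
                        drop = FALSE])
  ini <- initialize_batch_2p(Xini, cfg, dims,
                             bg_rank = cfg$ringcnn$bg_rank)
  st <- online_state_2p(ini, cfg, T_, bg_rank = cfg$ringcnn$bg_rank,
                        X0 = Xini)
  T0 <- ncol(Xini)

  for (epoch in seq_len(epochs)) {
    detect_this <- (epochs == 1L || epoch < epochs)
    if (epoch > 1L) {
      st$oasis <- lapply(seq_len(ncol(st$A)), function(n)
        if (st$is_bg[n]) NULL else
          oasis_state(st$gamma[[n]][1], st$lambda[n], cfg$s_min))
    }
    t_range <- if (epoch == 1L) seq_len(T_)[-seq_len(T0)] else seq_len(T_)
    for (tt in t_range) {
      y_t <- Y[, tt]
      N <- ncol(st$A)
      neuron <- which(!st$is_bg)
      c_prev <- if (N > 0) {
        if (tt > 1L) st$C_raw[, tt - 1L] else st$C_raw[, 1L]
      } else numeric(0)
      x_t <- as.numeric(subtract_bg(matrix(y_t, ncol = 1),
                                    Cprev = c_prev[neuron],
                                    A = st$A[, neuron, drop = FALSE]))
      st$t <- st$t + 1L
      c_t <- update_traces(st, x_t, c_prev)
      cden <- c_t
      if (N > 0) {
        st$C_raw[, tt] <- c_t
        for (n in neuron) {
          st$oasis[[n]] <- oasis_step(st$oasis[[n]], c_t[n])
          cden[n] <- oasis_head(st$oasis[[n]])
        }
        st$C_den[, tt] <- cden
      }
      r_t <- x_t - (if (N > 0) as.numeric(st$A %*% cden) else 0)
      st <- buffer_push(st, r_t, cden)
      st <- accumulate_stats(st, x_t, cden, numeric(d))
      if (detect_this && tt %% cfg$detect_every == 0L)
        st <- detect_new_components(st, tt)
      if ((st$t - st$t_init) %% cfg$update_every == 0L)
        st <- periodic_update(st)
      if (verbose && tt %% 500L == 0L)
        message("frame ", tt, " (epoch ", epoch, "): ",
                sum(!st$is_bg), " components")
    }
    st <- periodic_update(st)
  }

  neuron <- which(!st$is_bg)
  bgc <- which(st$is_bg)
  C <- matrix(0, length(neuron), T_); S <- matrix(0, length(neuron), T_)
  for (k in seq_along(neuron)) {
    n <- neuron[k]
    dec <- oasis(st$C_raw[n, ], st$gamma[[n]][1], st$lambda[n], cfg$s_min)
    C[k, ] <- dec$c; S[k, ] <- dec$s
  }
  log <- if (length(st$log)) do.call(rbind, st$log) else NULL
  bundle <- results_bundle(
    A = st$A[, neuron, drop = FALSE], C = C, S = S,
    C_raw = st$C_raw[neuron, , drop = FALSE], dims = dims,
    background = list(type = "lowrank",
                      b = as.matrix(st$A[, bgc, drop = FALSE]),
                      f = st$C_raw[bgc, , drop = FALSE],
                      model = model),
    birth_frame = st$birth[neuron], config = cfg, log = log,
    frame_rate = attr(movie, "frame_rate"))
  if (post_process) {
    Xfull <- subtract_bg(Y, Cprev = bundle$C_raw, A = bundle$A)
    bundle <- merge_and_screen(bundle, cfg, movie = Xfull)
  }
  bundle
}

# 2-photon-style initialization on background-subtracted frames: greedy
# seeding and HALS with a flat baseline, then refinement against a
# low-rank residual background so footprints do not absorb the smooth
# remainder that the convolutional model left behind
initialize_batch_2p <- function(X, cfg, dims, bg_rank = 2L) {
  cfg2 <- cfg
  cfg2$decimate <- 1L
  R <- min(bg_rank, ncol(X) - 1L)
  lowrank_bg <- function(resid) {
    sv <- svd(resid, nu = R, nv = 0)
    U <- sv$u[, seq_len(R), drop = FALSE]
    sgn <- ifelse(colSums(U) >= 0, 1, -1)
    b <- pmax(sweep(U, 2, sgn, "*"), 0)
    list(b = b, f = pmax(crossprod(b, resid), 0))
  }
  # the smooth remainder dominates the leading singular vectors of the
  # background-filtered data (transients are sparse in time), so seed on
  # the low-rank-subtracted movie to keep footprints compact
  bg <- lowrank_bg(X)
  ini <- initialize_batch(pmax(X - bg$b %*% bg$f, 0), cfg2, dims = dims,
                          background = "flat")
  N <- ncol(ini$A)
  for (iter in 1:2) {
    bg <- lowrank_bg(X - (if (N) as.matrix(ini$A %*% ini$C_raw) else 0))
    if (N == 0) break
    YmB <- X - bg$b %*% bg$f
    ini$C_raw <- update_C_batch(ini$A, YmB, ini$C_raw, n_pass = 3L)
    for (n in seq_len(N)) {
      dec <- oasis(ini$C_raw[n, ], ini$gamma[[n]][1],
                   ini$lambda[n], cfg$s_min)
      ini$C[n, ] <- dec$c
      ini$S[n, ] <- dec$s
    }
    A_new <- hals_update_A(compute_L(YmB, ini$C), compute_M(ini$C),
                           ini$A, ini$supports, n_pass = 3L)
    ini$A <- Matrix::drop0(methods::as(A_new, "CsparseMatrix"))
  }
  ini$bg_b <- bg$b
  ini$bg_f <- bg$f
  ini
}

# engine state for the 2P-style mode: ring weights zero, low-rank
# background columns appended as always-on components
online_state_2p <- function(ini, cfg, total_frames, bg_rank, X0) {
  d <- nrow(X0)
  N <- ncol(ini$A)
  if (!is.null(ini$bg_b)) {
    b <- ini$bg_b; f <- ini$bg_f
  } else {
    resid <- X0 - as.matrix(ini$A %*% ini$C_raw)
    R <- min(bg_rank, ncol(X0) - 1L)
    sv <- svd(resid, nu = R, nv = 0)
    U <- sv$u[, seq_len(R), drop = FALSE]
    sgn <- ifelse(colSums(U) >= 0, 1, -1)
    b <- pmax(sweep(U, 2, sgn, "*"), 0)
    f <- pmax(crossprod(b, resid), 0)    # R x T
  }
  R <- ncol(b)
  ini$A <- methods::cbind2(ini$A, Matrix::Matrix(b, sparse = TRUE))
  ini$C_raw <- rbind(ini$C_raw, f)
  ini$C <- rbind(ini$C, f)
  ini$S <- rbind(ini$S, 0 * f)
  ini$supports <- c(ini$supports,
                    replicate(R, seq_len(d), simplify = FALSE))
  ini$gamma <- c(ini$gamma, replicate(R, 0.9, simplify = FALSE))
  ini$lambda <- c(ini$lambda, rep(0, R))
  ini$W <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(d, d))
  ini$b_bar <- numeric(d)
  ini$graph <- NULL
  cfg$decimate <- 1L
  st <- online_state(ini, cfg, total_frames)
  st$is_bg <- c(rep(FALSE, N), rep(TRUE, R))
  st$update_W <- FALSE
  st <- seed_stats_from_init_2p(st, X0)
  st
}

seed_stats_from_init_2p <- function(st, X0) {
  T0 <- ncol(X0)
  C0 <- st$C_den[, seq_len(T0), drop = FALSE]
  st$Lsum <- X0 %*% t(C0)
  st$Msum <- tcrossprod(C0)
  st$t <- T0
  lb <- st$cfg$buffer_frames
  take <- max(1L, T0 - lb + 1L):T0
  Rres <- X0[, take, drop = FALSE] -
    as.matrix(st$A %*% C0[, take, drop = FALSE])
  for (k in seq_along(take)) st <- buffer_push(st, Rres[, k], C0[, take[k]])
  st
}
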