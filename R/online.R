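# Online engine: streaming trace tracking, sufficient statistics,
# periodic footprint / background updates.

#' Partition components into spatially non-overlapping groups
#'
#' Greedy first-fit over components in index order: each component joins
#' the first group none of whose members share a support pixel with it,
#' otherwise it opens a new group. Traces of components within one group
#' can be updated jointly in vector form.
#'
#' @param A `d x N` footprint matrix (dense or sparse).
#' @return list of integer vectors covering `1:N` exactly once.
#' @export
determine_groups <- function(A) {
  N <- ncol(A)
  if (N == 0) return(list())
  Ab <- A > 0
  OV <- as.matrix(Matrix::crossprod(Ab)) > 0
  groups <- list()
  for (n in seq_len(N)) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (!any(OV[n, groups[[g]]])) {
        groups[[g]] <- c(groups[[g]], n)
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- n
  }
  groups
}

# add one component to an existing partition
groups_add <- function(groups, OV_new_row) {
  n <- length(OV_new_row) + 1L
  for (g in seq_along(groups)) {
    if (!any(OV_new_row[groups[[g]]])) {
      groups[[g]] <- c(groups[[g]], n)
      return(groups)
    }
  }
  c(groups, list(n))
}

# --- cached projections -----------------------------------------------------
# With spatial decimation D (block mean) and nearest-neighbor upsampling U,
# the background column is b_t = b_bar + U W (D y_t - DA c_t - D b_bar) and
# A' U = (sum-pooled A)'. Caches: P1 = (sum-pooled A)' W, P2 = P1 DA,
# AtA; the baseline part P1 D b_bar - A' b_bar is recomputed per frame.
refresh_projections <- function(st) {
  A <- st$A
  if (st$decimate > 1L) {
    Asum <- decimate_frames(as.matrix(A), st$dims, st$decimate) *
      st$decimate^2
    Amean <- decimate_frames(as.matrix(A), st$dims, st$decimate)
  } else {
    Asum <- as.matrix(A)
    Amean <- Asum
  }
  st$P1 <- as.matrix(Matrix::crossprod(Asum, st$W))       # N x d_dec
  st$P2 <- st$P1 %*% Amean                                 # N x N
  st$AtA <- as.matrix(Matrix::crossprod(A))
  st$Asum_dec <- Asum
  st$Amean_dec <- Amean
  st
}

dec_vec <- function(v, dims, factor) {
  if (factor == 1L) return(v)
  as.numeric(decimate_image(matrix(v, dims[1]), factor))
}

undec_vec <- function(v, dims, factor, dims_dec) {
  if (factor == 1L) return(v)
  as.numeric(undecimate_image(matrix(v, dims_dec[1]), factor, dims))
}

#' Track component activity on a single frame
#'
#' Block-coordinate nonnegative update of the trace vector `c_t` given
#' the frame, footprints, and the ring background (expanded through the
#' cached projections so that the background term is refreshed as `c_t`
#' changes). Groups of non-overlapping components are updated jointly;
#' iterations stop after `inner_iter` rounds or when the relative change
#' falls below `tol`.
#'
#' @param st engine state (see [online_state()]).
#' @param y_t frame as a length-`d` vector.
#' @param c_prev warm-start trace vector.
#' @return updated length-`N` trace vector.
#' @export
update_traces <- function(st, y_t, c_prev,
                          inner_iter = st$cfg$inner_iter, tol = 1e-4) {
  N <- ncol(st$A)
  if (N == 0) return(numeric(0))
  yd <- dec_vec(y_t, st$dims, st$decimate)
  bd <- dec_vec(st$b_bar, st$dims, st$decimate)
  Aty <- as.numeric(Matrix::crossprod(st$A, y_t))
  # q collects all terms that do not depend on c
  q <- Aty - as.numeric(st$P1 %*% yd) +
    (as.numeric(st$P1 %*% bd) - as.numeric(Matrix::crossprod(st$A, st$b_bar)))
  G <- st$AtA - st$P2
  c_ <- c_prev
  num <- q - as.numeric(G %*% c_)
  dg <- pmax(diag(st$AtA), 1e-12)
  for (it in seq_len(inner_iter)) {
    delta_tot <- 0
    for (g in st$groups) {
      delta <- pmax(0, c_[g] + num[g] / dg[g]) - c_[g]
      if (any(delta != 0)) {
        c_[g] <- c_[g] + delta
        num <- num - as.numeric(G[, g, drop = FALSE] %*% delta)
        delta_tot <- delta_tot + sum(abs(delta))
      }
    }
    if (delta_tot <= tol * max(sum(abs(c_)), 1e-9)) break
  }
  c_
}

# background column for the current frame given trace vector c
background_column <- function(st, y_t, c_) {
  x <- y_t - st$b_bar
  if (ncol(st$A) > 0) x <- x - as.numeric(st$A %*% c_)
  xd <- dec_vec(x, st$dims, st$decimate)
  bf <- as.numeric(st$W %*% xd)
  st$b_bar + undec_vec(bf, st$dims, st$decimate, st$dims_dec)
}

#' Online engine state
#'
#' Assembles the streaming state from a batch initialization. The state
#' holds the component set, ring background, cached projections, the
#' unnormalized sufficient statistics (`L`, `M`, `chi` as plain sums;
#' any common scaling cancels in the footprint and background updates),
#' the residual buffer with its incremental summary statistics, and the
#' event log. Its size is independent of the stream length (apart from
#' the output traces).
#'
#' @param init result of [initialize_batch()].
#' @param config a [cnmfe_config()].
#' @param total_frames frames to pre-allocate for the output traces.
#' @return an `online_state` environment-free list.
#' @export
online_state <- function(init, config, total_frames) {
  dims <- init$dims
  d <- prod(dims)
  cfg <- config
  N <- ncol(init$A)
  T0 <- ncol(init$C)
  st <- list(cfg = cfg, dims = dims, d = d,
             decimate = cfg$decimate,
             dims_dec = decimated_dims(dims, cfg$decimate),
             A = init$A, supports = init$supports,
             W = init$W, graph = init$graph,
             b_bar = init$b_bar,
             sigma = init$sigma,
             gamma = init$gamma, lambda = init$lambda,
             t = 0L, t_init = T0,
             birth = rep(1L, N),
             log = list())
  st$groups <- determine_groups(st$A)
  st$is_bg <- rep(FALSE, N)
  st$update_W <- TRUE
  st <- refresh_projections(st)

  # trace storage (output; grows with T by design). C_den holds the
  # streaming-OASIS denoised values as they were available at each frame;
  # they feed the baseline, sufficient-statistic and residual updates.
  st$C_raw <- matrix(0, N, total_frames)
  st$C_den <- matrix(0, N, total_frames)
  st$S <- matrix(0, N, total_frames)
  if (N > 0 && T0 > 0) {
    st$C_raw[, seq_len(T0)] <- init$C_raw
    st$C_den[, seq_len(T0)] <- init$C
  }
  st$oasis <- lapply(seq_len(N), function(n)
    oasis_state(init$gamma[[n]][1], init$lambda[n], cfg$s_min))
  # warm the streaming deconvolution with the initialization batch
  for (n in seq_len(N)) for (tt in seq_len(T0))
    st$oasis[[n]] <- oasis_step(st$oasis[[n]], init$C_raw[n, tt])

  # sufficient statistics as unnormalized sums over all seen frames
  st$Lsum <- matrix(0, d, N)
  st$Msum <- matrix(0, N, N)
  st$track_chi <- !is.null(init$graph)
  st$chi <- if (st$track_chi)
    matrix(0, prod(st$dims_dec), prod(st$dims_dec)) else NULL
  st$x_block <- if (st$track_chi)
    matrix(0, prod(st$dims_dec), cfg$update_every) else NULL
  st$x_pos <- 0L
  st$yb_block <- NULL   # unused; L is accumulated per frame

  # residual buffer and summary statistics
  st$nbr <- neighbor_map(dims)
  st$Rbuf <- matrix(0, d, cfg$buffer_frames)
  st$Cbuf <- matrix(0, max(N, 0), cfg$buffer_frames)
  st$buf_pos <- 0L
  st$buf_n <- 0L
  st$mu_sum <- numeric(d)
  st$nu_sum <- matrix(0, d, 9L)   # col 1 self, cols 2..9 neighbors
  st$i_max <- rep(-Inf, d)
  st$var_e_sum <- numeric(d)
  st$border <- border_mask(dims, max(1L, round(cfg$neuron_radius)))

  if (cfg$motion$enabled) {
    st$motion <- motion_state(dims, cfg$motion$template_frames,
                              cfg$motion$max_shift, cfg$motion$hp_sigma)
  }
  st
}

# seed the engine's statistics from the initialization batch, so that
# after t frames the sums equal their definitions over frames 1..t
seed_stats_from_init <- function(st, Y_init) {
  T0 <- ncol(Y_init)
  N <- ncol(st$A)
  C0 <- if (N) st$C_den[, seq_len(T0), drop = FALSE] else
    matrix(0, 0, T0)
  AC <- if (N) as.matrix(st$A %*% C0) else matrix(0, st$d, T0)
  X_full <- Y_init - AC - st$b_bar
  Xd <- decimate_frames(X_full, st$dims, st$decimate)
  B <- evaluate_background(st$W, st$b_bar, Y_init, st$A, C0, st$dims,
                           st$decimate)
  if (N) {
    st$Lsum <- (Y_init - B) %*% t(C0)
    st$Msum <- tcrossprod(C0)
  }
  st$chi <- tcrossprod(Xd)
  st$t <- T0
  # fill the residual buffer with the most recent init residuals
  lb <- st$cfg$buffer_frames
  take <- max(1L, T0 - lb + 1L):T0
  R <- Y_init[, take, drop = FALSE] - B[, take, drop = FALSE] -
    (if (N) as.matrix(st$A %*% C0[, take, drop = FALSE]) else 0)
  for (k in seq_along(take)) st <- buffer_push(st, R[, k],
                                               C0[, take[k]])
  st
}

# --- streaming sufficient statistics ---------------------------------------

# per-frame accumulation; chi is folded in blocks of T_p for speed
accumulate_stats <- function(st, y_t, c_t, b_t) {
  if (ncol(st$A) > 0) {
    st$Lsum <- st$Lsum + outer(y_t - b_t, c_t)
    st$Msum <- st$Msum + outer(c_t, c_t)
  }
  if (st$track_chi) {
    x <- y_t - st$b_bar
    if (ncol(st$A) > 0) x <- x - as.numeric(st$A %*% c_t)
    st$x_pos <- st$x_pos + 1L
    st$x_block[, st$x_pos] <- dec_vec(x, st$dims, st$decimate)
  }
  st
}

fold_chi <- function(st) {
  if (st$track_chi && st$x_pos > 0L) {
    xb <- st$x_block[, seq_len(st$x_pos), drop = FALSE]
    st$chi <- st$chi + tcrossprod(xb)
    st$x_pos <- 0L
  }
  st
}

#' Running sufficient statistics in their running-mean form
#'
#' Returns `L`, `M` and `chi` divided by the frame counter, matching the
#' streaming running-mean recursions; used by tests and diagnostics.
#' @param st engine state.
#' @return list with `L`, `M`, `chi`, `b_bar`, `t`.
#' @export
suff_stats <- function(st) {
  st <- fold_chi(st)
  list(L = st$Lsum / max(st$t, 1L), M = st$Msum / max(st$t, 1L),
       chi = if (st$track_chi) st$chi / max(st$t, 1L),
       b_bar = st$b_bar, t = st$t)
}

# periodic updates: fold chi, refit W, HALS on shapes, refresh caches
periodic_update <- function(st) {
  st <- fold_chi(st)
  if (st$update_W && st$track_chi)
    st$W <- solve_ring_weights(chi = st$chi, graph = st$graph)
  if (ncol(st$A) > 0) {
    A_new <- hals_update_A(st$Lsum, st$Msum, st$A, st$supports, n_pass = 2L)
    st$A <- Matrix::drop0(methods::as(A_new, "CsparseMatrix"))
  }
  st <- refresh_projections(st)
  st
}
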