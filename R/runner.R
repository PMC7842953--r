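#' Run the full online source-extraction pipeline
#'
#' Processes a movie in streaming fashion: a short initial batch is
#' factorized offline ([initialize_batch()]) to seed the state, then each
#' subsequent frame is (optionally) motion-aligned, its traces tracked,
#' the constant baseline updated, new components detected from the
#' residual buffer, and every `update_every` frames the sufficient
#' statistics, ring weights and footprints are refreshed. With
#' `epochs > 1` the movie is re-streamed, with detection disabled on the
#' final epoch (tracking only). Afterwards traces are denoised and
#' deconvolved (OASIS), and components are merged and screened.
#'
#' @param movie `rows x cols x T` array (or `cnmfe_movie`).
#' @param config a [cnmfe_config()].
#' @param init optional result of [initialize_batch()] to warm-start.
#' @param detect enable detection of new components.
#' @param post_process merge and screen components at the end.
#' @param verbose print progress.
#' @return a [results_bundle()].
#' @export
run_onacid_e <- function(movie, config, init = NULL, detect = TRUE,
                         post_process = TRUE, verbose = FALSE) {
  cfg <- config
  Y <- if (length(dim(movie)) == 3L) vec_frames(movie) else movie
  dims <- dim(movie)[1:2]
  T_ <- ncol(Y)
  if (cfg$offset != 0) Y <- Y - cfg$offset
  if (T_ < cfg$init_frames)
    stop("stream shorter than the initial batch (", cfg$init_frames,
         " frames)", call. = FALSE)
  set.seed(derive_seed(cfg$seed, "run_onacid_e"))
  if (is.null(init))
    init <- initialize_batch(Y[, seq_len(cfg$init_frames), drop = FALSE],
                             cfg, dims = dims)
  T0 <- ncol(init$C)
  st <- online_state(init, cfg, total_frames = T_)
  st <- seed_stats_from_init(st, Y[, seq_len(T0), drop = FALSE])
  shifts <- matrix(0, T_, 2)

  for (epoch in seq_len(cfg$epochs)) {
    detect_this <- detect && (cfg$epochs == 1L || epoch < cfg$epochs)
    if (epoch > 1L) {
      # traces are recomputed from the first frame on re-streaming
      st$oasis <- lapply(seq_len(ncol(st$A)), function(n)
        oasis_state(st$gamma[[n]][1], st$lambda[n], cfg$s_min))
    }
    t_range <- if (epoch == 1L) seq_len(T_)[-seq_len(T0)] else seq_len(T_)
    for (tt in t_range) {
      st <- online_step(st, Y[, tt], tt, detect = detect_this)
      if (epoch == 1L && !is.null(st$last_shift))
        shifts[tt, ] <- st$last_shift
      if (verbose && tt %% 500L == 0L)
        message("frame ", tt, " (epoch ", epoch, "): ", ncol(st$A),
                " components")
    }
    # consolidate shapes and background at the end of each epoch
    st <- periodic_update(st)
  }

  bundle <- finalize_bundle(st, Y, dims, shifts,
                            frame_rate = attr(movie, "frame_rate"))
  if (post_process) {
    B <- evaluate_background(st$W, st$b_bar, Y, bundle$A, bundle$C_raw,
                             dims, st$decimate)
    bundle <- merge_and_screen(bundle, cfg, movie = Y - B)
  }
  bundle
}

# process one frame: align, track, deconvolve, update baseline, push the
# residual, detect, and fire the periodic updates
online_step <- function(st, y_t, tt, detect = TRUE) {
  cfg <- st$cfg
  st$last_shift <- NULL
  if (!is.null(st$motion)) {
    al <- align_frame(st$motion, matrix(y_t, st$dims[1]))
    y_t <- as.numeric(al$frame)
    st$last_shift <- al$shift
  }
  st$t <- st$t + 1L
  N <- ncol(st$A)
  c_prev <- if (N > 0) {
    if (tt > 1L) st$C_raw[, tt - 1L] else st$C_raw[, 1L]
  } else numeric(0)
  c_t <- update_traces(st, y_t, c_prev)
  cden <- c_t
  if (N > 0) {
    st$C_raw[, tt] <- c_t
    for (n in seq_len(N)) {
      st$oasis[[n]] <- oasis_step(st$oasis[[n]], c_t[n])
      cden[n] <- oasis_head(st$oasis[[n]])
    }
    st$C_den[, tt] <- cden
  }
  st$b_bar <- (st$t - 1) / st$t * st$b_bar +
    (1 / st$t) * (y_t - if (N > 0) as.numeric(st$A %*% cden) else 0)
  b_t <- background_column(st, y_t, cden)
  r_t <- y_t - b_t - (if (N > 0) as.numeric(st$A %*% cden) else 0)
  st <- buffer_push(st, r_t, cden)
  st <- accumulate_stats(st, y_t, cden, b_t)
  if (!is.null(st$motion))
    st$motion <- motion_update(st$motion, y_t - r_t)
  if (detect && tt %% cfg$detect_every == 0L)
    st <- detect_new_components(st, tt)
  if ((st$t - st$t_init) %% cfg$update_every == 0L) {
    st <- periodic_update(st)
    st$log[[length(st$log) + 1L]] <- data.frame(
      frame = tt, event = "periodic_update", row = NA_integer_,
      col = NA_integer_, value = ncol(st$A))
  }
  st
}

# deconvolve accumulated raw traces and assemble the results bundle
finalize_bundle <- function(st, Y, dims, shifts = NULL, frame_rate = NULL) {
  N <- ncol(st$A)
  T_ <- ncol(st$C_raw)
  C <- matrix(0, N, T_); S <- matrix(0, N, T_)
  for (n in seq_len(N)) {
    dec <- oasis(st$C_raw[n, ], st$gamma[[n]][1], st$lambda[n],
                 st$cfg$s_min)
    C[n, ] <- dec$c
    S[n, ] <- dec$s
  }
  log <- if (length(st$log)) do.call(rbind, st$log) else NULL
  results_bundle(A = st$A, C = C, S = S, C_raw = st$C_raw, dims = dims,
                 background = list(type = "ring", W = st$W,
                                   b_bar = st$b_bar,
                                   decimate = st$decimate),
                 shifts = shifts, birth_frame = st$birth, config = st$cfg,
                 log = log, frame_rate = frame_rate)
}

#' Track a fixed component set over a movie
#'
#' Streams over the movie with the component set, ring weights and
#' baseline held fixed (no detection, no periodic updates), recomputing
#' all traces from the first frame.
#'
#' @param movie movie array or `d x T` matrix.
#' @param bundle a `cnmfe_bundle` (provides `A`, background, config).
#' @param config optional config override.
#' @return a new `cnmfe_bundle` with recomputed `C_raw`, `C`, `S`.
#' @export
track_components <- function(movie, bundle, config = NULL) {
  cfg <- config %||% bundle$config
  if (is.null(cfg)) stop("no configuration available", call. = FALSE)
  Y <- if (length(dim(movie)) == 3L) vec_frames(movie) else movie
  dims <- bundle$dims
  if (nrow(Y) != prod(dims))
    stop("movie does not match the bundle's FOV", call. = FALSE)
  T_ <- ncol(Y)
  N <- ncol(bundle$A)
  bg <- bundle$background
  if (is.null(bg) || bg$type != "ring")
    stop("track_components requires a ring-background bundle",
         call. = FALSE)
  supports <- lapply(seq_len(N), function(n) which(bundle$A[, n] > 0))
  init <- list(A = bundle$A, C_raw = matrix(0, N, 0),
               C = matrix(0, N, 0), S = matrix(0, N, 0),
               supports = supports, W = bg$W, b_bar = bg$b_bar,
               sigma = rep(1, prod(dims)),
               gamma = lapply(seq_len(N), function(n)
                 if (is.null(cfg$gamma)) 0.9 else cfg$gamma),
               lambda = rep(if (is.null(cfg$lambda)) 0 else cfg$lambda, N),
               graph = ring_graph(max(1, cfg$ring_radius / cfg$decimate),
                                  decimated_dims(dims, cfg$decimate)),
               dims = dims)
  st <- online_state(init, cfg, total_frames = T_)
  st$birth <- bundle$birth_frame
  for (tt in seq_len(T_)) {
    y_t <- Y[, tt]
    st$t <- st$t + 1L
    c_prev <- if (N > 0 && tt > 1L) st$C_raw[, tt - 1L] else numeric(N)
    c_t <- update_traces(st, y_t, c_prev)
    if (N > 0) st$C_raw[, tt] <- c_t
  }
  # per-component dynamics from the recomputed traces
  for (n in seq_len(N)) {
    st$gamma[[n]] <- if (is.null(cfg$gamma))
      estimate_ar_coefs(st$C_raw[n, ], p = cfg$ar_order) else cfg$gamma
    st$lambda[n] <- if (is.null(cfg$lambda))
      default_lambda(st$C_raw[n, ]) else cfg$lambda
  }
  out <- finalize_bundle(st, Y, dims, shifts = bundle$shifts,
                         frame_rate = bundle$frame_rate)
  out$birth_frame <- bundle$birth_frame
  out
}

#' Second online pass over a movie
#'
#' Re-streams the movie with the final component set of a first pass held
#' fixed, recomputing every trace from frame one, so that components
#' detected late in the first pass obtain full-length traces.
#'
#' @param movie the movie of the first pass.
#' @param bundle first-pass results.
#' @param config optional config override.
#' @return bundle with full-length traces.
#' @export
second_pass <- function(movie, bundle, config = NULL) {
  if (ncol(bundle$A) == 0) {
    out <- bundle
    return(out)
  }
  track_components(movie, bundle, config)
}
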