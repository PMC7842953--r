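#' Simulate a 1-photon microendoscopic movie with ground truth
#'
#' Generates a synthetic miniscope movie `Y = A* C* + B* + E` (optionally
#' followed by rigid drift): sparse truncated-Gaussian somata with
#' minimum-separation centers, Bernoulli spike trains filtered by stable
#' AR dynamics, a spatially coarse fluctuating background (constant
#' baseline plus a few smooth spatial modes with slow AR(1) time courses,
#' so the ring background model applies), and pixel-wise Gaussian noise.
#'
#' @param dims FOV `c(rows, cols)`.
#' @param n_neurons number of neurons (`>= 0`).
#' @param n_frames number of frames.
#' @param neuron_radius soma radius in pixels; footprints are isotropic
#'   Gaussians with `sd = neuron_radius / 2`, truncated at
#'   `2.5 * neuron_radius`, unit peak before scaling.
#' @param frame_rate Hz.
#' @param firing_rate mean spike rate (Hz); per-frame spike probability is
#'   `firing_rate / frame_rate`.
#' @param gamma AR coefficients of the calcium dynamics.
#' @param amplitude peak fluorescence scale; each spike's amplitude is
#'   drawn uniform `[0.5, 1.5] * amplitude`. The default `16 * sigma`
#'   keeps the peak SNR of the dimmest transient at or above 8.
#' @param background_spec list: `baseline`, `n_modes`, `spatial_sigma`
#'   (Gaussian filter width of the smooth modes; default
#'   `6 * neuron_radius`, so the background autocorrelation length is well
#'   above 3 neuron radii), `temporal_ar`, `sd` (per-pixel sd of the
#'   fluctuating part).
#' @param sigma noise standard deviation (scalar or per-pixel vector).
#' @param min_separation minimal distance between neuron centers; default
#'   `2.5 * neuron_radius`.
#' @param shift_spec optional `list(max_shift =, ar =)` generating a
#'   smooth rigid random-walk drift applied to the frames (last).
#' @param seed integer seed.
#' @return list with `movie` (`rows x cols x T` array, attribute
#'   `frame_rate`) and `truth` (class `simulation_truth`): `A` (`d x N`),
#'   `C`, `S` (`N x T`), `centers`, background parts (`baseline`,
#'   `modes`, `mode_traces`), `sigma`, `shifts`, `gamma`.
#' @export
simulate_movie <- function(dims = c(64, 64), n_neurons = 20,
                           n_frames = 1500, neuron_radius = 4,
                           frame_rate = 10, firing_rate = 0.2,
                           gamma = 0.9, amplitude = NULL,
                           background_spec = list(), sigma = 1,
                           min_separation = NULL, shift_spec = NULL,
                           seed = 1) {
  stopifnot(n_neurons >= 0, n_frames >= 1)
  assert_stable_ar(gamma)
  set.seed(derive_seed(seed, "simulate_movie"))
  d <- prod(dims)
  if (is.null(min_separation)) min_separation <- 2.5 * neuron_radius
  if (is.null(amplitude)) amplitude <- 16 * mean(sigma)
  bg <- modifyList(list(baseline = 20, n_modes = 3,
                        spatial_sigma = 6 * neuron_radius,
                        temporal_ar = 0.98, sd = 2, static_sd = 1),
                   background_spec)

  centers <- sample_centers(n_neurons, dims, neuron_radius, min_separation)
  A <- footprint_matrix(centers, dims, neuron_radius)

  p_spike <- firing_rate / frame_rate
  S <- matrix(0, n_neurons, n_frames)
  C <- matrix(0, n_neurons, n_frames)
  if (n_neurons > 0) {
    spikes <- matrix(rbinom(n_neurons * n_frames, 1, p_spike),
                     n_neurons, n_frames)
    amps <- matrix(runif(n_neurons * n_frames, 0.5, 1.5) * amplitude,
                   n_neurons, n_frames)
    S <- spikes * amps
    for (n in seq_len(n_neurons))
      C[n, ] <- as.numeric(stats::filter(S[n, ], gamma, "recursive"))
  }

  # time-constant textured baseline field (blood vessels, speckle); part
  # of the model's per-pixel constant baseline
  baseline <- rep(bg$baseline, d)
  if (bg$static_sd > 0) {
    tex <- gblur(matrix(rnorm(d), dims[1], dims[2]), neuron_radius)
    tex <- (tex - mean(tex)) / sd(tex)
    baseline <- pmax(baseline + bg$static_sd * as.numeric(tex), 0)
  }

  modes <- matrix(0, d, bg$n_modes)
  mode_traces <- matrix(0, bg$n_modes, n_frames)
  if (bg$n_modes > 0 && bg$sd > 0) {
    for (k in seq_len(bg$n_modes)) {
      m <- gblur(matrix(rnorm(d), dims[1], dims[2]), bg$spatial_sigma)
      m <- m - mean(m)
      modes[, k] <- as.numeric(m) / sd(m)
      innov <- rnorm(n_frames, 0, sqrt(1 - bg$temporal_ar^2))
      f <- as.numeric(stats::filter(innov, bg$temporal_ar, "recursive",
                                    init = rnorm(1)))
      mode_traces[k, ] <- f * bg$sd / sqrt(bg$n_modes)
    }
  }

  Y <- matrix(baseline, d, n_frames)
  if (n_neurons > 0) Y <- Y + A %*% C
  if (bg$n_modes > 0) Y <- Y + modes %*% mode_traces
  if (any(sigma > 0))
    Y <- Y + matrix(rnorm(d * n_frames, 0, sigma), d, n_frames)

  shifts <- NULL
  mov <- unvec_frames(Y, dims)
  if (!is.null(shift_spec)) {
    shift_spec <- modifyList(list(max_shift = 3, ar = 0.95), shift_spec)
    shifts <- simulate_shifts(n_frames, shift_spec)
    for (t in seq_len(n_frames))
      mov[, , t] <- apply_shift(mov[, , t], shifts[t, ])
  }

  truth <- structure(list(
    A = A, C = C, S = S, centers = centers,
    baseline = baseline, modes = modes, mode_traces = mode_traces,
    sigma = sigma, shifts = shifts, gamma = gamma,
    neuron_radius = neuron_radius, dims = as.integer(dims)),
    class = "simulation_truth")
  list(movie = as_movie(mov, frame_rate), truth = truth)
}

sample_centers <- function(n, dims, radius, min_sep) {
  if (n == 0) return(matrix(0, 0, 2))
  margin <- ceiling(radius)
  lo <- 1 + margin
  hi <- dims - margin
  if (any(hi <= lo))
    stop("FOV too small for the requested neuron radius", call. = FALSE)
  centers <- matrix(0, 0, 2)
  tries <- 0L
  while (nrow(centers) < n) {
    cand <- c(runif(1, lo, hi[1]), runif(1, lo, hi[2]))
    ok <- !nrow(centers) ||
      min(sqrt(colSums((t(centers) - cand)^2))) >= min_sep
    if (ok) centers <- rbind(centers, cand)
    tries <- tries + 1L
    if (tries > 2000L * n)
      stop("FOV too small to place ", n, " neurons at minimum separation ",
           min_sep, call. = FALSE)
  }
  dimnames(centers) <- NULL
  centers
}

footprint_matrix <- function(centers, dims, radius) {
  d <- prod(dims)
  n <- nrow(centers)
  rows <- rep(seq_len(dims[1]), dims[2])
  cols <- rep(seq_len(dims[2]), each = dims[1])
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  s2 <- (radius / 2)^2
  for (k in seq_len(n)) {
    d2 <- (rows - centers[k, 1])^2 + (cols - centers[k, 2])^2
    keep <- which(d2 <= (2.5 * radius)^2)
    ii <- c(ii, keep); jj <- c(jj, rep(k, length(keep)))
    xx <- c(xx, exp(-d2[keep] / (2 * s2)))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(d, n))
}

simulate_shifts <- function(n_frames, spec) {
  sh <- matrix(0, n_frames, 2)
  for (j in 1:2) {
    innov <- rnorm(n_frames, 0, 1 - spec$ar)
    s <- as.numeric(stats::filter(innov, spec$ar, "recursive"))
    s <- s / max(abs(s), 1e-9) * spec$max_shift * runif(1, 0.5, 1)
    sh[, j] <- s
  }
  sh
}

#' Reconstruct the ground-truth background movie
#'
#' @param truth a `simulation_truth`.
#' @return `d x T` matrix `B* = baseline + modes %*% mode_traces`.
#' @export
truth_background <- function(truth) {
  truth$baseline + truth$modes %*% truth$mode_traces
}

#' Simulate a movie that exactly obeys the ring background model
#'
#' Produces frames `B = W B + b_bar` for a planted ring weight matrix.
#' When `W_true` is supplied, the fluctuating part is one ring projection
#' of a smooth latent field (`B_f = W_true %*% latent`). When it is not,
#' a self-consistent pair is constructed: a smooth low-rank spatial basis
#' `U` (`latent_rank` columns) and, per pixel, the least-norm ring weights
#' satisfying `W U = U` exactly, so the returned frames `U F + b_bar`
#' satisfy the ring fixed-point identity and `W` is recoverable from the
#' movie as the minimum-norm least-squares solution.
#'
#' @param dims FOV `c(rows, cols)`.
#' @param l ring radius.
#' @param n_frames number of frames.
#' @param b_bar constant baseline (scalar or length-`d`).
#' @param W_true optional planted sparse ring matrix.
#' @param latent_rank rank of the self-consistent construction; must stay
#'   below the interior ring size.
#' @param spatial_sigma smoothness of the latent spatial modes.
#' @param seed integer seed.
#' @return list with `movie` (`d x T` matrix), `W`, `b_bar`, `graph`, and
#'   the latent factors.
#' @export
simulate_ring_background <- function(dims, l, n_frames = 100, b_bar = 10,
                                     W_true = NULL, latent_rank = 8,
                                     spatial_sigma = NULL, seed = 1) {
  set.seed(derive_seed(seed, "ring_background"))
  d <- prod(dims)
  graph <- ring_graph(l, dims)
  if (is.null(spatial_sigma)) spatial_sigma <- max(2, l / 2)
  b_bar <- rep_len(b_bar, d)
  if (!is.null(W_true)) {
    check_ring_support(W_true, graph)
    latent <- smooth_field(dims, latent_rank, spatial_sigma)
    F_ <- matrix(rnorm(latent_rank * n_frames), latent_rank, n_frames)
    Bf <- as.matrix(W_true %*% (latent %*% F_))
    return(list(movie = Bf + b_bar, W = W_true, b_bar = b_bar,
                graph = graph, U = latent, F = F_))
  }
  min_ring <- min(lengths(graph$neighbors))
  if (latent_rank >= min_ring)
    stop("latent_rank must be below the smallest ring size (",
         min_ring, ")", call. = FALSE)
  U <- smooth_field(dims, latent_rank, spatial_sigma)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (i in seq_len(d)) {
    r <- graph$neighbors[[i]]
    Ur <- U[r, , drop = FALSE]             # |r| x R
    # least-norm w with t(Ur) %*% w = U[i, ]
    G <- crossprod(Ur)                     # R x R
    w <- Ur %*% solve(G + diag(1e-12 * sum(diag(G)) / ncol(G), ncol(G)),
                      U[i, ])
    ii <- c(ii, rep(i, length(r))); jj <- c(jj, r); xx <- c(xx, w)
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(d, d))
  F_ <- matrix(rnorm(latent_rank * n_frames), latent_rank, n_frames)
  list(movie = as.matrix(U %*% F_) + b_bar, W = W, b_bar = b_bar,
       graph = graph, U = U, F = F_)
}

smooth_field <- function(dims, rank, sigma) {
  sapply(seq_len(rank), function(k) {
    m <- gblur(matrix(rnorm(prod(dims)), dims[1], dims[2]), sigma)
    v <- as.numeric(m)
    (v - mean(v)) / sd(v)
  })
}

check_ring_support <- function(W, graph) {
  Wt <- as(as(W, "CsparseMatrix"), "generalMatrix")
  trip <- Matrix::summary(Wt)
  bad <- !mapply(function(i, j) j %in% graph$neighbors[[i]],
                 trip$i, trip$j)
  if (any(bad))
    stop("W support violates the ring constraint at ",
         sum(bad), " entries", call. = FALSE)
  invisible(TRUE)
}
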