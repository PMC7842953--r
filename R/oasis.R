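#' Denoise and deconvolve a calcium trace (OASIS)
#'
#' Solves the sparsity-penalized projection of a noisy fluorescence trace
#' onto stable AR(P) calcium dynamics,
#' \deqn{\min_{c,s} \tfrac12\|c - y\|^2 + \lambda \|s\|_1
#'   \quad s.t.\quad s_t = c_t - \sum_p \gamma_p c_{t-p},\;
#'   (s_t \ge s_{min} \;or\; s_t = 0),\; c \ge 0.}
#' For AR(1) the exact pool-adjacent-violators style active-set algorithm
#' is used (both the \eqn{\ell_1} penalty and the minimal-spike-size
#' variants; `s_min > 0` takes precedence over `lambda`). For AR(2) the
#' problem is solved as a box-constrained convex program on the spike
#' vector (`lambda` mode only).
#'
#' @param y numeric trace.
#' @param gamma AR coefficients (length 1 or 2); must be stable.
#' @param lambda nonnegative sparsity penalty.
#' @param s_min minimal spike size (AR(1) only); when positive, spikes are
#'   greedily forced to zero unless they exceed `s_min`.
#' @return list with `c` (denoised trace), `s` (deconvolved activity,
#'   `s[t] = c[t] - sum(gamma * c[t - (1:P)])`, zero-padded at the start).
#' @export
oasis <- function(y, gamma, lambda = 0, s_min = 0) {
  stopifnot(is.numeric(y), all(is.finite(y)))
  assert_stable_ar(gamma)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  P <- length(gamma)
  if (!P %in% c(1L, 2L)) stop("AR order must be 1 or 2", call. = FALSE)
  if (length(y) == 0) return(list(c = numeric(0), s = numeric(0)))
  if (P == 1L) {
    st <- oasis_state(gamma, lambda, s_min)
    for (v in y) st <- oasis_step(st, v)
    oasis_finalize(st)
  } else {
    if (s_min > 0)
      stop("s_min mode is only supported for AR(1) dynamics", call. = FALSE)
    oasis_ar2(y, gamma, lambda)
  }
}

#' Streaming OASIS for AR(1) dynamics
#'
#' `oasis_state` creates the per-trace state, `oasis_step` appends one
#' sample, `oasis_finalize` returns the full `(c, s)` solution, which
#' equals the batch [oasis()] output. Mid-stream, `oasis_head(state)`
#' returns the current estimate of the most recent sample (which may still
#' be revised while its active pool grows).
#'
#' @inheritParams oasis
#' @export
oasis_state <- function(gamma, lambda = 0, s_min = 0) {
  assert_stable_ar(gamma)
  stopifnot(length(gamma) == 1L, lambda >= 0, s_min >= 0)
  list(g = gamma, lambda = lambda, s_min = s_min,
       # pools: columns v (pool value), w (weight), t (start), l (length)
       v = numeric(0), w = numeric(0), t = integer(0), l = integer(0),
       n = 0L)
}

pool_thresh <- function(st) if (st$s_min > 0) st$s_min else 0

merge_tail_pools <- function(st) {
  thr <- pool_thresh(st)
  k <- length(st$v)
  while (k > 1L &&
         st$v[k] < st$g^st$l[k - 1L] * st$v[k - 1L] + thr) {
    gl <- st$g^st$l[k - 1L]
    w_new <- st$w[k - 1L] + gl^2 * st$w[k]
    v_new <- (st$w[k - 1L] * st$v[k - 1L] + gl * st$v[k] * st$w[k]) / w_new
    st$v[k - 1L] <- v_new
    st$w[k - 1L] <- w_new
    st$l[k - 1L] <- st$l[k - 1L] + st$l[k]
    st$v <- st$v[-k]; st$w <- st$w[-k]; st$t <- st$t[-k]; st$l <- st$l[-k]
    k <- k - 1L
  }
  st
}

#' @rdname oasis_state
#' @param state an `oasis_state`.
#' @param y_t new sample.
#' @export
oasis_step <- function(state, y_t) {
  if (is.null(state$g)) stop("state not initialized", call. = FALSE)
  state$n <- state$n + 1L
  # running samples get the interior l1 adjustment; the terminal
  # correction is applied in oasis_finalize
  ytil <- y_t - state$lambda * (1 - state$g)
  state$v <- c(state$v, ytil)
  state$w <- c(state$w, 1)
  state$t <- c(state$t, state$n)
  state$l <- c(state$l, 1L)
  merge_tail_pools(state)
}

#' @rdname oasis_state
#' @export
oasis_head <- function(state) {
  k <- length(state$v)
  if (k == 0L) return(NA_real_)
  max(state$v[k], 0) * state$g^(state$l[k] - 1L)
}

#' @rdname oasis_state
#' @export
oasis_finalize <- function(state) {
  st <- state
  if (st$n == 0L) return(list(c = numeric(0), s = numeric(0)))
  # switch the last sample from the interior to the terminal adjustment:
  # subtract the missing lambda * g from the pool average
  if (st$lambda > 0) {
    k <- length(st$v)
    st$v[k] <- st$v[k] - st$lambda * st$g * st$g^(st$l[k] - 1L) / st$w[k]
    st <- merge_tail_pools(st)
  }
  # clamp pools at zero (c >= 0), then re-merge any boundary the clamping
  # invalidated
  repeat {
    st$v <- pmax(st$v, 0)
    thr <- pool_thresh(st)
    k <- length(st$v)
    bad <- which(st$v[-1] < st$g^st$l[-k] * st$v[-k] + thr &
                 st$v[-1] > 0)
    if (!length(bad)) break
    st <- merge_tail_pools_at(st, bad[1] + 1L)
  }
  cvec <- numeric(st$n)
  for (k in seq_along(st$v)) {
    idx <- st$t[k]:(st$t[k] + st$l[k] - 1L)
    cvec[idx] <- max(st$v[k], 0) * st$g^(seq_along(idx) - 1L)
  }
  svec <- c(cvec[1], cvec[-1] - st$g * cvec[-st$n])
  svec[abs(svec) < 1e-12] <- 0
  list(c = cvec, s = pmax(svec, 0))
}

# merge pool k into k-1, then continue standard tail merging downstream
merge_tail_pools_at <- function(st, k) {
  gl <- st$g^st$l[k - 1L]
  w_new <- st$w[k - 1L] + gl^2 * st$w[k]
  v_new <- (st$w[k - 1L] * st$v[k - 1L] + gl * st$v[k] * st$w[k]) / w_new
  st$v[k - 1L] <- v_new; st$w[k - 1L] <- w_new
  st$l[k - 1L] <- st$l[k - 1L] + st$l[k]
  st$v <- st$v[-k]; st$w <- st$w[-k]; st$t <- st$t[-k]; st$l <- st$l[-k]
  st
}

# AR(2): solve on the spike parameterization with box constraints.
# c = G^{-1} s via the forward recursion; gradient uses the adjoint.
oasis_ar2 <- function(y, gamma, lambda) {
  T_ <- length(y)
  ar_filter <- function(s) {
    c_ <- numeric(T_)
    c_[1] <- s[1]
    if (T_ >= 2) c_[2] <- s[2] + gamma[1] * c_[1]
    for (t in seq_len(T_ - 2) + 2L)
      c_[t] <- s[t] + gamma[1] * c_[t - 1] + gamma[2] * c_[t - 2]
    c_
  }
  ar_filter_adj <- function(v) {
    u <- numeric(T_)
    u[T_] <- v[T_]
    if (T_ >= 2) u[T_ - 1] <- v[T_ - 1] + gamma[1] * u[T_]
    for (t in rev(seq_len(T_ - 2)))
      u[t] <- v[t] + gamma[1] * u[t + 1] + gamma[2] * u[t + 2]
    u
  }
  fn <- function(s) {
    r <- ar_filter(s) - y
    0.5 * sum(r^2) + lambda * sum(s)
  }
  gr <- function(s) ar_filter_adj(ar_filter(s) - y) + lambda
  s0 <- pmax(c(y[1], y[-1] - gamma[1] * y[-T_] -
                 gamma[2] * c(0, y[-c(T_ - 1, T_)])), 0)
  opt <- optim(s0, fn, gr, method = "L-BFGS-B", lower = 0,
               control = list(maxit = 500, factr = 1e4))
  s <- opt$par
  c_ <- ar_filter(s)
  s[abs(s) < 1e-10] <- 0
  list(c = c_, s = s)
}

#' Estimate AR coefficients from a noisy trace
#'
#' Uses the autocovariance method: for lags beyond zero the noise does not
#' contribute, so the AR coefficients solve the Yule-Walker-type relations
#' on the empirical autocovariance at lags `1..n_lags`.
#'
#' @param y numeric trace.
#' @param p AR order (1 or 2).
#' @param n_lags number of autocovariance lags used.
#' @param bounds AR(1) clip range to keep the estimate stable.
#' @return numeric vector of length `p`.
#' @export
estimate_ar_coefs <- function(y, p = 1L, n_lags = 5L,
                              bounds = c(0.2, 0.99)) {
  T_ <- length(y)
  n_lags <- min(n_lags, T_ - p - 1L)
  ac <- acf(y, lag.max = n_lags + p, type = "covariance",
            plot = FALSE, demean = TRUE)$acf[, 1, 1]
  if (p == 1L) {
    num <- sum(ac[(2:(n_lags + 1)) + 1] * ac[(1:n_lags) + 1])
    den <- sum(ac[(1:n_lags) + 1]^2)
    g <- if (den > 0) num / den else bounds[2]
    return(min(max(g, bounds[1]), bounds[2]))
  }
  # AR(2): ac[k] = g1 ac[k-1] + g2 ac[k-2] for k >= 2
  k <- 2:(n_lags + 1)
  Xm <- cbind(ac[k], ac[k - 1])
  b <- ac[k + 1]
  g <- tryCatch(solve(crossprod(Xm), crossprod(Xm, b))[, 1],
                error = function(e) c(bounds[2], 0))
  if (any(Mod(polyroot(c(1, -g))) <= 1.001)) g <- c(min(g[1], 0.95), 0)
  g
}

#' Per-trace noise level from the power spectral density
#'
#' Estimates the noise standard deviation as the square root of the mean
#' periodogram power over the upper half of the frequency band
#' (`f in (0.25, 0.5]` cycles/frame), where slow calcium and background
#' signals contribute negligibly.
#'
#' @param Y numeric vector, or matrix with one time series per row.
#' @return numeric vector of noise standard deviations.
#' @export
estimate_noise <- function(Y) {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
  T_ <- ncol(Y)
  if (T_ < 32L) stop("need at least 32 frames to estimate noise",
                     call. = FALSE)
  ft <- mvfft(t(Y))                      # T x d
  pow <- Mod(ft)^2 / T_
  lo <- floor(T_ * 0.25) + 1L
  hi <- floor(T_ * 0.5)
  sqrt(colMeans(pow[lo:hi, , drop = FALSE]))
}
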