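#' Rigid shift estimation against a template
#'
#' Both images are high-pass filtered (subtraction of a wide Gaussian
#' blur) to suppress the coarse 1-photon background, then the rigid shift
#' is the peak of the FFT cross-correlation, refined to subpixel accuracy
#' by quadratic interpolation of the correlation surface around the peak
#' and clipped to `max_shift`. The returned `c(dy, dx)` is the amount by
#' which the frame content is displaced relative to the template, so
#' `apply_shift(frame, -shift)` aligns the frame.
#'
#' @param frame,template matrices of equal size.
#' @param max_shift maximal allowed displacement (pixels).
#' @param hp_sigma width of the high-pass Gaussian (pixels); 0 disables
#'   filtering.
#' @return numeric `c(dy, dx)`.
#' @export
estimate_shift <- function(frame, template, max_shift = 10, hp_sigma = 12) {
  stopifnot(all(dim(frame) == dim(template)))
  f <- if (hp_sigma > 0) spatial_highpass(frame, hp_sigma) else frame
  tmpl <- if (hp_sigma > 0) spatial_highpass(template, hp_sigma)
          else template
  if (var(as.numeric(f)) < 1e-12 || var(as.numeric(tmpl)) < 1e-12) {
    warning("flat frame or template; returning zero shift")
    return(c(0, 0))
  }
  nr <- nrow(f); nc <- ncol(f)
  m <- as.integer(ceiling(max_shift))
  if (nr <= 2 * m + 2 || nc <= 2 * m + 2)
    stop("max_shift too large for the FOV", call. = FALSE)
  # normalized cross-correlation of the frame's interior against the
  # template, over all integer lags within max_shift; the valid-overlap
  # formulation has no border or wrap-around artifacts, so an exactly
  # shifted frame scores 1 at the true lag
  crop_r <- (m + 1):(nr - m); crop_c <- (m + 1):(nc - m)
  fc <- f[crop_r, crop_c]
  fc <- fc - mean(fc)
  fn <- sqrt(sum(fc^2))
  lags <- -m:m
  ncc <- matrix(-Inf, 2 * m + 1, 2 * m + 1)
  for (iy in seq_along(lags)) for (ix in seq_along(lags)) {
    tw <- tmpl[crop_r - lags[iy], crop_c - lags[ix]]
    tw <- tw - mean(tw)
    den <- fn * sqrt(sum(tw^2))
    if (den > 1e-12) ncc[iy, ix] <- sum(fc * tw) / den
  }
  pk <- arrayInd(which.max(ncc), dim(ncc))
  dy <- lags[pk[1]]; dx <- lags[pk[2]]
  # a perfect raw-pixel match at the peak lag is an exact integer shift
  # (the high-pass filter does not commute with translation near the
  # borders, so the perfect-match test uses the unfiltered overlap)
  fr <- frame[crop_r, crop_c]; fr <- fr - mean(fr)
  tr <- template[crop_r - dy, crop_c - dx]; tr <- tr - mean(tr)
  raw_den <- sqrt(sum(fr^2)) * sqrt(sum(tr^2))
  raw_ncc <- if (raw_den > 1e-12) sum(fr * tr) / raw_den else 0
  if (raw_ncc < 1 - 1e-9) {
    para <- function(cm, c0, cp) {
      den <- cm - 2 * c0 + cp
      if (!is.finite(den) || abs(den) < 1e-12) 0
      else max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
    }
    at <- function(i, j) if (i >= 1 && i <= nrow(ncc) &&
                             j >= 1 && j <= ncol(ncc)) ncc[i, j] else NA
    cm_y <- at(pk[1] - 1, pk[2]); cp_y <- at(pk[1] + 1, pk[2])
    cm_x <- at(pk[1], pk[2] - 1); cp_x <- at(pk[1], pk[2] + 1)
    if (all(is.finite(c(cm_y, cp_y))))
      dy <- dy + para(cm_y, ncc[pk[1], pk[2]], cp_y)
    if (all(is.finite(c(cm_x, cp_x))))
      dx <- dx + para(cm_x, ncc[pk[1], pk[2]], cp_x)
  }
  c(max(-max_shift, min(max_shift, dy)),
    max(-max_shift, min(max_shift, dx)))
}

#' Translate a frame by a (possibly subpixel) rigid shift
#'
#' Bilinear interpolation; pixels sampled outside the FOV are filled by
#' edge replication. `apply_shift(x, c(0, 0))` is the identity and
#' integer shifts relocate pixels exactly on the interior.
#'
#' @param frame matrix.
#' @param shift numeric `c(dy, dx)`: content displacement.
#' @return shifted matrix.
#' @export
apply_shift <- function(frame, shift) {
  stopifnot(all(is.finite(shift)))
  if (all(shift == 0)) return(frame)
  nr <- nrow(frame); nc <- ncol(frame)
  src_r <- seq_len(nr) - shift[1]
  src_c <- seq_len(nc) - shift[2]
  r0 <- pmin(pmax(floor(src_r), 1), nr); r1 <- pmin(r0 + 1, nr)
  c0 <- pmin(pmax(floor(src_c), 1), nc); c1 <- pmin(c0 + 1, nc)
  fr <- pmin(pmax(src_r - floor(src_r), 0), 1)
  fc <- pmin(pmax(src_c - floor(src_c), 0), 1)
  fr[src_r < 1 | src_r > nr] <- 0
  fc[src_c < 1 | src_c > nc] <- 0
  w00 <- outer(1 - fr, 1 - fc); w01 <- outer(1 - fr, fc)
  w10 <- outer(fr, 1 - fc);     w11 <- outer(fr, fc)
  frame[r0, c0] * w00 + frame[r0, c1] * w01 +
    frame[r1, c0] * w10 + frame[r1, c1] * w11
}

# periodic Gaussian blur subtraction
highpass_fft <- function(img, sigma) {
  n <- nrow(img); m <- ncol(img)
  gy <- exp(-0.5 * (pmin(0:(n - 1), n - (0:(n - 1)))^2) / sigma^2)
  gx <- exp(-0.5 * (pmin(0:(m - 1), m - (0:(m - 1)))^2) / sigma^2)
  K <- outer(gy, gx)
  K <- K / sum(K)
  img - Re(fft(fft(img) * fft(K), inverse = TRUE)) / (n * m)
}

#' Running motion-correction state
#'
#' Keeps a circular store of the last `template_frames` denoised frames
#' whose mean serves as the registration template, so a single corrupt
#' frame perturbs the template by at most `1/M` of its norm.
#'
#' @param dims FOV dims.
#' @param template_frames number of frames averaged (`M`, typically 50).
#' @param max_shift,hp_sigma see [estimate_shift()].
#' @return a `motion_state` list.
#' @export
motion_state <- function(dims, template_frames = 50L, max_shift = 10,
                         hp_sigma = 12) {
  structure(list(store = matrix(0, prod(dims), template_frames),
                 n = 0L, pos = 0L, dims = as.integer(dims),
                 M = as.integer(template_frames),
                 max_shift = max_shift, hp_sigma = hp_sigma),
            class = "motion_state")
}

#' @rdname motion_state
#' @param state a `motion_state`.
#' @param denoised_frame the background-corrected denoised frame
#'   (`Ac + b`) appended to the template store.
#' @export
motion_update <- function(state, denoised_frame) {
  state$pos <- state$pos %% state$M + 1L
  state$store[, state$pos] <- as.numeric(denoised_frame)
  state$n <- min(state$n + 1L, state$M)
  state
}

#' @rdname motion_state
#' @export
motion_template <- function(state) {
  if (state$n == 0L) return(NULL)
  matrix(rowMeans(state$store[, seq_len(state$n), drop = FALSE]),
         state$dims[1], state$dims[2])
}

#' @rdname motion_state
#' @param frame raw incoming frame.
#' @return `align_frame`: list with `frame` (aligned) and `shift`.
#' @export
align_frame <- function(state, frame) {
  tmpl <- motion_template(state)
  if (is.null(tmpl)) return(list(frame = frame, shift = c(0, 0)))
  sh <- estimate_shift(frame, tmpl, state$max_shift, state$hp_sigma)
  list(frame = apply_shift(frame, -sh), shift = sh)
}
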