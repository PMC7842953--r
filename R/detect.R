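# Residual buffer, incremental summary images, new-component detection
# and incorporation.

# push a residual frame (and the trace vector used for it) into the ring
# buffer, updating the incremental first/second-moment statistics
buffer_push <- function(st, r_t, c_t) {
  lb <- st$cfg$buffer_frames
  pos <- st$buf_pos %% lb + 1L
  full <- st$buf_n == lb
  r_in <- as.numeric(r_t)
  nbr_prod <- function(r) {
    rn <- matrix(r[st$nbr], st$d, 8L)
    rn[is.na(st$nbr)] <- 0
    cbind(r * r, r * rn)
  }
  if (full) {
    r_out <- st$Rbuf[, pos]
    st$mu_sum <- st$mu_sum + r_in - r_out
    st$nu_sum <- st$nu_sum + nbr_prod(r_in) - nbr_prod(r_out)
    if (st$cfg$summary_mode == "variance") {
      f_in <- as.numeric(gblur(matrix(r_in, st$dims[1]),
                               st$cfg$neuron_radius / 2))
      f_out <- as.numeric(gblur(matrix(r_out, st$dims[1]),
                                st$cfg$neuron_radius / 2))
      st$var_e_sum <- st$var_e_sum + f_in^2 - f_out^2
    }
  } else {
    st$mu_sum <- st$mu_sum + r_in
    st$nu_sum <- st$nu_sum + nbr_prod(r_in)
    if (st$cfg$summary_mode == "variance") {
      f_in <- as.numeric(gblur(matrix(r_in, st$dims[1]),
                               st$cfg$neuron_radius / 2))
      st$var_e_sum <- st$var_e_sum + f_in^2
    }
    st$buf_n <- st$buf_n + 1L
  }
  st$Rbuf[, pos] <- r_in
  if (nrow(st$Cbuf) > 0) st$Cbuf[, pos] <- c_t
  st$buf_pos <- pos
  st$i_max <- pmax(st$i_max, r_in)
  st
}

# chronological order of the buffer columns (oldest first)
buffer_order <- function(st) {
  lb <- st$cfg$buffer_frames
  if (st$buf_n < lb) seq_len(st$buf_n)
  else ((st$buf_pos + seq_len(lb) - 1L) %% lb) + 1L
}

#' Summary image of the residual buffer
#'
#' In `"corr_pnr"` mode returns the pixel-wise product of the local
#' cross-correlation image (mean Pearson correlation with the
#' 8-connected neighbors, computed from the incrementally maintained
#' first and second moments) and the peak-to-noise image
#' (running residual maximum over the init-batch noise level). In
#' `"variance"` mode returns the mean energy of the spatially smoothed
#' buffer.
#'
#' @param st engine state.
#' @param mode override of `st$cfg$summary_mode`.
#' @return list with `e`, and for `corr_pnr` also `i_corr`, `i_pnr`.
#' @export
summary_image <- function(st, mode = st$cfg$summary_mode) {
  n <- max(st$buf_n, 1L)
  if (mode == "variance") {
    return(list(e = st$var_e_sum / n))
  }
  mu <- st$mu_sum / n
  nu <- st$nu_sum / n
  v <- pmax(nu[, 1] - mu^2, 0)
  sdv <- sqrt(v)
  corr_sum <- numeric(st$d)
  cnt <- numeric(st$d)
  for (k in 1:8) {
    j <- st$nbr[, k]
    ok <- which(!is.na(j))
    den <- sdv[ok] * sdv[j[ok]]
    r <- ifelse(den > 1e-12,
                (nu[ok, k + 1L] - mu[ok] * mu[j[ok]]) / den, 0)
    corr_sum[ok] <- corr_sum[ok] + r
    cnt[ok] <- cnt[ok] + 1
  }
  i_corr <- corr_sum / pmax(cnt, 1)
  i_pnr <- ifelse(st$sigma > 1e-12, pmax(st$i_max, 0) / st$sigma, 0)
  list(e = i_corr * i_pnr, i_corr = i_corr, i_pnr = i_pnr)
}

#' Propose, screen and incorporate new components from the buffer
#'
#' Takes the top local maxima of the summary image that pass the seed
#' thresholds, fits a local rank-1 NMF of the buffered residual around
#' each, and screens the candidate: (i) the footprint must correlate at
#' least `theta_sp` with the time-averaged buffer on its support;
#' (ii) if it spatially overlaps an existing component, its trace must
#' not be highly correlated (>= 0.85) with that component's buffered
#' trace (duplicate); (iii) the trace SNR (peak over a
#' median-absolute-deviation noise estimate) must reach `theta_snr`.
#' Accepted components are incorporated immediately: footprints, traces,
#' sufficient statistics (over the buffered window), cached projections,
#' groups and the buffer summary statistics are all augmented.
#'
#' @param st engine state.
#' @param frame current frame index (for the log).
#' @return updated state; `st$n_accepted` holds the number accepted.
#' @export
detect_new_components <- function(st, frame) {
  cfg <- st$cfg
  st$n_accepted <- 0L
  if (st$buf_n < max(10L, cfg$buffer_frames %/% 4L)) return(st)
  si <- summary_image(st)
  if (cfg$summary_mode == "corr_pnr") {
    eligible <- si$i_corr >= cfg$min_corr & si$i_pnr >= cfg$min_pnr &
      !st$border
  } else {
    thr <- quantile(si$e, 0.999)
    eligible <- si$e >= thr & !st$border
  }
  if (!any(eligible)) return(st)
  e <- ifelse(eligible, si$e, -Inf)
  peaks <- local_maxima(matrix(e, st$dims[1]), round(cfg$neuron_radius),
                        min_value = 0)
  peaks <- head(peaks, cfg$max_candidates)
  halfwin <- max(2L, as.integer(round(2 * cfg$neuron_radius)))
  ord <- buffer_order(st)
  for (pk in peaks) {
    if (!eligible[pk]) next
    w_idx <- window_indices(pk, halfwin, st$dims)
    blk <- st$Rbuf[w_idx, ord, drop = FALSE]
    anchor <- pmax(st$Rbuf[pk, ord], 0)
    fit <- local_rank1_nmf(blk, match(pk, w_idx), c0 = anchor)
    outcome <- screen_candidate(st, fit, w_idx, ord)
    rc <- pix_rowcol(pk, st$dims)
    st$log[[length(st$log) + 1L]] <- data.frame(
      frame = frame, event = if (outcome == "accept") "detect" else
        paste0("reject_", outcome),
      row = rc[1], col = rc[2], value = max(fit$c))
    if (outcome == "accept") {
      st <- incorporate_component(st, fit$a, fit$c, w_idx, frame)
      st$n_accepted <- st$n_accepted + 1L
      si <- summary_image(st)
      if (cfg$summary_mode == "corr_pnr") {
        eligible <- si$i_corr >= cfg$min_corr & si$i_pnr >= cfg$min_pnr &
          !st$border
      } else eligible <- si$e >= quantile(si$e, 0.999) & !st$border
    }
  }
  st
}

screen_candidate <- function(st, fit, w_idx, ord) {
  cfg <- st$cfg
  if (max(fit$a) <= 0 || sum(fit$c^2) < 1e-12) return("degenerate")
  sup <- which(fit$a > 0.1 * max(fit$a))
  # a soma is compact; diffuse background blobs fill the whole window
  if (length(sup) > cfg$max_fill * length(w_idx)) return("shape")
  mean_buf <- rowMeans(st$Rbuf[w_idx[sup], ord, drop = FALSE])
  sp_corr <- suppressWarnings(cor(fit$a[sup], mean_buf))
  if (!is.finite(sp_corr) || sp_corr < cfg$theta_sp) return("space")
  # duplicate test against overlapping existing components
  if (ncol(st$A) > 0) {
    sup_pix <- w_idx[sup]
    overl <- which(Matrix::colSums(st$A[sup_pix, , drop = FALSE] > 0) > 0)
    overl <- setdiff(overl, which(st$is_bg))
    for (m in overl) {
      r <- suppressWarnings(cor(fit$c, st$Cbuf[m, ord]))
      if (is.finite(r) && r >= 0.85) return("duplicate")
    }
  }
  noise <- mad(fit$c)
  if (noise < 1e-12) noise <- sd(fit$c)
  snr <- max(fit$c) / max(noise, 1e-12)
  if (snr < cfg$theta_snr) return("snr")
  "accept"
}

#' @rdname detect_new_components
#' @param a_w footprint on the window (unit peak).
#' @param c_new trace over the buffered frames (chronological).
#' @param w_idx window pixel indices.
#' @export
incorporate_component <- function(st, a_w, c_new, w_idx, frame) {
  ord <- buffer_order(st)
  nb <- st$buf_n
  N_old <- ncol(st$A)
  # sufficient statistics over the buffered window (component inactive
  # before): Y_buf - B_buf = R_buf + A C_buf with the pre-update buffer
  YmB <- st$Rbuf[, ord, drop = FALSE]
  if (N_old > 0)
    YmB <- YmB + as.matrix(st$A %*% st$Cbuf[, ord, drop = FALSE])
  L_new <- as.numeric(YmB %*% c_new)
  M_cross <- if (N_old > 0)
    as.numeric(st$Cbuf[, ord, drop = FALSE] %*% c_new) else numeric(0)

  a_full_idx <- w_idx[a_w > 0]
  a_full_val <- a_w[a_w > 0]
  st$A <- methods::cbind2(st$A, Matrix::sparseMatrix(
    i = a_full_idx, j = rep(1L, length(a_full_idx)), x = a_full_val,
    dims = c(st$d, 1L)))
  st$supports <- c(st$supports, list(w_idx))
  st$birth <- c(st$birth, frame)
  st$is_bg <- c(st$is_bg, FALSE)

  st$Lsum <- cbind(st$Lsum, L_new)
  M_new <- rbind(cbind(st$Msum, M_cross),
                 c(M_cross, sum(c_new^2)))
  dimnames(M_new) <- NULL
  st$Msum <- M_new
  dimnames(st$Lsum) <- NULL

  # traces: backfill the buffered window
  Tall <- ncol(st$C_raw)
  new_row <- numeric(Tall)
  frames_buf <- (frame - nb + 1L):frame
  keep <- frames_buf >= 1L
  new_row[frames_buf[keep]] <- c_new[keep]
  st$C_raw <- rbind(st$C_raw, new_row)
  st$S <- rbind(st$S, numeric(Tall))
  gam <- if (is.null(st$cfg$gamma))
    estimate_ar_coefs(c_new, p = st$cfg$ar_order) else st$cfg$gamma
  lam <- if (is.null(st$cfg$lambda)) default_lambda(c_new) else
    st$cfg$lambda
  st$gamma <- c(st$gamma, list(gam))
  st$lambda <- c(st$lambda, lam)
  # streaming deconvolution state, warmed with the buffered history
  os <- oasis_state(gam[1], lam, st$cfg$s_min)
  cden_hist <- numeric(nb)
  for (k in seq_len(nb)) {
    os <- oasis_step(os, c_new[k])
    cden_hist[k] <- oasis_head(os)
  }
  st$oasis <- c(st$oasis, list(os))
  new_den <- numeric(Tall)
  new_den[frames_buf[keep]] <- cden_hist[keep]
  st$C_den <- rbind(st$C_den, new_den)

  # augment buffer traces and correct the residual buffer
  Cb <- matrix(0, N_old + 1L, ncol(st$Cbuf))
  if (N_old > 0) Cb[seq_len(N_old), ] <- st$Cbuf
  Cb[N_old + 1L, ord] <- c_new
  st$Cbuf <- Cb
  st$Rbuf[a_full_idx, ord] <- st$Rbuf[a_full_idx, ord] -
    outer(a_full_val, c_new)

  # refresh summary statistics locally (exact, from the corrected buffer)
  aff <- unique(c(a_full_idx, na.omit(as.integer(st$nbr[a_full_idx, ]))))
  st <- refresh_buffer_stats(st, aff)
  st$i_max[a_full_idx] <- 0

  # groups and cached projections
  ov <- as.numeric(Matrix::crossprod(st$A[, seq_len(N_old), drop = FALSE] > 0,
                                     st$A[, N_old + 1L, drop = FALSE] > 0)) > 0
  st$groups <- groups_add(st$groups, ov)
  st <- refresh_projections(st)
  st
}

# recompute mu / nu sums (and variance-mode energy) from the buffer
# contents for the given pixels
refresh_buffer_stats <- function(st, pixels) {
  cols <- seq_len(st$buf_n)
  R <- st$Rbuf[, cols, drop = FALSE]
  st$mu_sum[pixels] <- rowSums(R[pixels, , drop = FALSE])
  st$nu_sum[pixels, 1] <- rowSums(R[pixels, , drop = FALSE]^2)
  for (k in 1:8) {
    j <- st$nbr[pixels, k]
    ok <- which(!is.na(j))
    st$nu_sum[pixels[ok], k + 1L] <-
      rowSums(R[pixels[ok], , drop = FALSE] * R[j[ok], , drop = FALSE])
  }
  if (st$cfg$summary_mode == "variance") {
    acc <- numeric(length(pixels))
    for (cc in cols) {
      f <- as.numeric(gblur(matrix(st$Rbuf[, cc], st$dims[1]),
                            st$cfg$neuron_radius / 2))
      acc <- acc + f[pixels]^2
    }
    st$var_e_sum[pixels] <- acc
  }
  st
}
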