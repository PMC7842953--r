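# Residual buffer, incremental summary images, candidate screening and
# incorporation.

noise_state <- function(dims = c(16, 16), n_comp = 0, lb = 20,
                        cfg_args = list()) {
  d <- prod(dims)
  cfg <- do.call(cnmfe_config,
                 modifyList(list(neuron_radius = 3, buffer_frames = lb,
                                 init_frames = 32), cfg_args))
  A <- matrix(0, d, n_comp)
  if (n_comp > 0) A[1:4, seq_len(n_comp)] <- 1
  init <- list(A = methods::as(A, "CsparseMatrix"),
               C = matrix(0, n_comp, 0), C_raw = matrix(0, n_comp, 0),
               S = matrix(0, n_comp, 0),
               supports = lapply(seq_len(n_comp), function(n) 1:4),
               W = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                        x = numeric(0), dims = c(d, d)),
               b_bar = numeric(d), sigma = rep(1, d),
               gamma = replicate(n_comp, 0.9, simplify = FALSE),
               lambda = rep(0, n_comp), graph = ring_graph(2, dims),
               dims = dims)
  online_state(init, cfg, total_frames = 200L)
}

from_scratch_stats <- function(st) {
  cols <- seq_len(st$buf_n)
  R <- st$Rbuf[, cols, drop = FALSE]
  d <- nrow(R)
  mu <- rowSums(R)
  nu <- matrix(0, d, 9)
  nu[, 1] <- rowSums(R^2)
  for (k in 1:8) {
    j <- st$nbr[, k]
    ok <- which(!is.na(j))
    nu[ok, k + 1] <- rowSums(R[ok, , drop = FALSE] *
                               R[j[ok], , drop = FALSE])
  }
  list(mu = mu, nu = nu)
}

test_that("incremental buffer moments equal from-scratch recomputation", {
  set.seed(41)
  st <- noise_state(lb = 12)
  d <- 256
  # over-fill the buffer (3x its length) with seeded residuals
  for (tt in 1:36)
    st <- oncnmfe:::buffer_push(st, rnorm(d), numeric(0))
  ref <- from_scratch_stats(st)
  expect_lt(max(abs(st$mu_sum - ref$mu)), 1e-6)
  expect_lt(max(abs(st$nu_sum - ref$nu)), 1e-6)
  expect_equal(st$buf_n, 12)
  # pushing a frame identical to the outgoing one leaves sums unchanged
  ord <- oncnmfe:::buffer_order(st)
  oldest <- st$Rbuf[, ord[1]]
  mu0 <- st$mu_sum; nu0 <- st$nu_sum
  st <- oncnmfe:::buffer_push(st, oldest, numeric(0))
  expect_equal(st$mu_sum, mu0, tolerance = 1e-10)
  expect_equal(st$nu_sum, nu0, tolerance = 1e-10)
  # all-nonpositive residuals keep the running max nonpositive
  st2 <- noise_state(lb = 5)
  for (tt in 1:8) st2 <- oncnmfe:::buffer_push(st2, -abs(rnorm(d)),
                                               numeric(0))
  expect_lte(max(st2$i_max), 0)
})

test_that("summary image reproduces exact correlation and PNR values", {
  st <- noise_state(lb = 16)
  d <- 256
  set.seed(42)
  base <- rnorm(16)
  for (tt in 1:16) {
    r <- rnorm(d, 0, 0.01)
    # two neighboring pixels carry identical traces plus distinct
    # constants: their pairwise correlation must be exactly 1
    r[100] <- base[tt] + 5
    r[101] <- base[tt] - 2
    st <- oncnmfe:::buffer_push(st, r, numeric(0))
  }
  n <- st$buf_n
  mu <- st$mu_sum / n; nu <- st$nu_sum / n
  # pixel 101 is the downward neighbor of 100 (offset +1 row, column 8 of
  # the neighbor map is (dr = 1, dc = 0))
  k <- which(!is.na(st$nbr[100, ]) & st$nbr[100, ] == 101)
  v100 <- nu[100, 1] - mu[100]^2
  v101 <- nu[101, 1] - mu[101]^2
  r_pair <- (nu[100, k + 1] - mu[100] * mu[101]) / sqrt(v100 * v101)
  expect_equal(r_pair, 1, tolerance = 1e-10)
  # PNR: i_max = 5 sigma gives value 5
  st$i_max[7] <- 5 * st$sigma[7]
  si <- summary_image(st)
  expect_equal(si$i_pnr[7], 5)
})

test_that("a planted transient is accepted exactly once, noise never", {
  set.seed(43)
  dims <- c(16, 16); d <- 256
  st <- noise_state(dims, lb = 30)
  # planted Gaussian blob with a clean calcium transient, SNR ~ 10
  rows <- rep(1:16, 16); cols <- rep(1:16, each = 16)
  blob <- exp(-((rows - 8)^2 + (cols - 9)^2) / (2 * 1.5^2))
  trace <- 10 * 0.85^(0:29)
  trace <- c(rep(0, 10), trace[1:20])
  for (tt in 1:30)
    st <- oncnmfe:::buffer_push(st, blob * trace[tt] + rnorm(d, 0, 0.5),
                                numeric(0))
  st$sigma <- rep(0.5, d)
  st <- detect_new_components(st, frame = 30L)
  expect_equal(st$n_accepted, 1L)
  cent <- oncnmfe:::footprint_centroids(st$A, dims)
  expect_lt(sqrt((cent[1, 1] - 8)^2 + (cent[1, 2] - 9)^2), 1.5)
  # a second sweep must not re-accept the same transient
  st <- detect_new_components(st, frame = 31L)
  expect_equal(st$n_accepted, 0L)

  # pure-noise buffer at striatum thresholds: no acceptances
  st0 <- noise_state(dims, lb = 30,
                     cfg_args = list(min_corr = 0.7, min_pnr = 7,
                                     theta_sp = 0.55, theta_snr = 3.5))
  for (tt in 1:30) st0 <- oncnmfe:::buffer_push(st0, rnorm(d), numeric(0))
  st0 <- detect_new_components(st0, frame = 30L)
  expect_equal(st0$n_accepted, 0L)
})

test_that("duplicates of existing components are rejected", {
  set.seed(44)
  dims <- c(16, 16); d <- 256
  st <- noise_state(dims, lb = 30)
  rows <- rep(1:16, 16); cols <- rep(1:16, each = 16)
  blob <- exp(-((rows - 8)^2 + (cols - 9)^2) / (2 * 1.5^2))
  trace <- c(rep(0, 10), 10 * 0.85^(0:19))
  for (tt in 1:30)
    st <- oncnmfe:::buffer_push(st, blob * trace[tt] + rnorm(d, 0, 0.4),
                                numeric(0))
  st$sigma <- rep(0.4, d)
  st <- detect_new_components(st, 30L)
  expect_equal(ncol(st$A), 1L)
  # feed the same leak again: existing component's buffered trace now
  # matches the residual, so the candidate is screened out as duplicate
  for (tt in 1:30) {
    r <- 0.6 * blob * trace[tt] + rnorm(d, 0, 0.4)
    st <- oncnmfe:::buffer_push(st, r, c(trace[tt]))
  }
  before <- ncol(st$A)
  st <- detect_new_components(st, 60L)
  expect_equal(ncol(st$A), before)
  expect_true(any(grepl("duplicate",
                        sapply(st$log, function(z) z$event))))
})

test_that("raising screening thresholds never increases acceptances", {
  set.seed(45)
  dims <- c(16, 16); d <- 256
  mk <- function(theta_sp, theta_snr) {
    st <- noise_state(dims, lb = 30,
                      cfg_args = list(theta_sp = theta_sp,
                                      theta_snr = theta_snr))
    rows <- rep(1:16, 16); cols <- rep(1:16, each = 16)
    set.seed(45)
    blob1 <- exp(-((rows - 5)^2 + (cols - 5)^2) / 4)
    blob2 <- exp(-((rows - 12)^2 + (cols - 11)^2) / 4)
    tr1 <- c(rep(0, 5), 8 * 0.85^(0:24))
    tr2 <- c(rep(0, 15), 4 * 0.85^(0:14))
    for (tt in 1:30)
      st <- oncnmfe:::buffer_push(st, blob1 * tr1[tt] + blob2 * tr2[tt] +
                                    rnorm(d, 0, 0.5), numeric(0))
    st$sigma <- rep(0.5, d)
    st <- detect_new_components(st, 30L)
    st$n_accepted
  }
  n_low <- mk(0.3, 2)
  expect_lte(mk(0.7, 2), n_low)
  expect_lte(mk(0.3, 8), n_low)
})

test_that("incorporation augments statistics exactly over the buffer", {
  set.seed(46)
  dims <- c(16, 16); d <- 256
  st <- noise_state(dims, n_comp = 1, lb = 20)
  # stream frames through the full step so L, M, buffer stay consistent
  rows <- rep(1:16, 16); cols <- rep(1:16, each = 16)
  blob <- exp(-((rows - 10)^2 + (cols - 6)^2) / (2 * 1.5^2))
  tr <- c(rep(0, 25), 12 * 0.85^(0:14))
  Ys <- matrix(abs(rnorm(d * 40, 3)), d, 40)
  for (tt in 1:40) Ys[, tt] <- Ys[, tt] + blob * tr[tt]
  for (tt in 1:40)
    st <- oncnmfe:::online_step(st, Ys[, tt], tt, detect = FALSE)
  st$sigma <- estimate_noise(Ys)
  L_before <- st$Lsum; M_before <- st$Msum
  st2 <- detect_new_components(st, 40L)
  expect_equal(st2$n_accepted, 1L)
  N <- ncol(st2$A)
  # Eq-15-style augmentation: new L column equals (Y_buf - B_buf) c_new'
  # computed from the pre-incorporation buffer; check via the
  # from-scratch identity YmB = R_buf + A C_buf of the old state
  ord <- oncnmfe:::buffer_order(st)
  YmB <- st$Rbuf[, ord] + as.matrix(st$A %*% st$Cbuf[, ord])
  c_new <- st2$Cbuf[N, oncnmfe:::buffer_order(st2)]
  expect_equal(as.numeric(st2$Lsum[, N]), as.numeric(YmB %*% c_new),
               tolerance = 1e-6)
  expect_equal(st2$Msum[N, N], sum(c_new^2), tolerance = 1e-8)
  expect_equal(st2$Msum[1, N],
               sum(st$Cbuf[1, ord] * c_new), tolerance = 1e-8)
  expect_equal(st2$Lsum[, 1], L_before[, 1])  # existing columns untouched
  # buffer moments remain consistent after the residual correction
  ref <- from_scratch_stats(st2)
  expect_lt(max(abs(st2$mu_sum - ref$mu)), 1e-6)
  expect_lt(max(abs(st2$nu_sum - ref$nu)), 1e-6)
  # i_max zeroed on the new support
  sup <- which(st2$A[, N] > 0)
  expect_true(all(st2$i_max[sup] == 0))
})
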