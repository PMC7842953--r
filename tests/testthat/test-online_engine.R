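# Online engine: grouping, single-frame trace updates, incremental
# sufficient statistics, memory contract, second pass.

test_that("greedy grouping covers all components without in-group overlap", {
  d <- 50
  A_disjoint <- matrix(0, d, 3)
  A_disjoint[1:10, 1] <- 1; A_disjoint[11:20, 2] <- 1
  A_disjoint[21:30, 3] <- 1
  expect_equal(determine_groups(A_disjoint), list(1:3))
  A_overlap <- matrix(1, d, 3)
  expect_equal(determine_groups(A_overlap), list(1L, 2L, 3L))
  set.seed(31)
  for (rep in 1:5) {
    A <- matrix(rbinom(d * 6, 1, 0.15), d, 6)
    gr <- determine_groups(A)
    expect_setequal(unlist(gr), 1:6)
    expect_equal(length(unlist(gr)), 6)
    OV <- crossprod(A > 0) > 0
    for (g in gr)
      if (length(g) > 1)
        for (i in seq_along(g)[-1])
          expect_false(any(OV[g[i], g[seq_len(i - 1)]]))
  }
})

make_toy_state <- function(A, dims, W = NULL, b_bar = NULL,
                           cfg = cnmfe_config(inner_iter = 60,
                                              init_frames = 32,
                                              buffer_frames = 10)) {
  d <- prod(dims); N <- ncol(A)
  if (is.null(W))
    W <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                              x = numeric(0), dims = c(d, d))
  if (is.null(b_bar)) b_bar <- numeric(d)
  init <- list(A = methods::as(A, "CsparseMatrix"),
               C = matrix(0, N, 0), C_raw = matrix(0, N, 0),
               S = matrix(0, N, 0),
               supports = lapply(seq_len(N), function(n) which(A[, n] > 0)),
               W = W, b_bar = b_bar, sigma = rep(1, d),
               gamma = replicate(N, 0.9, simplify = FALSE),
               lambda = rep(0, N), graph = ring_graph(2, dims),
               dims = dims)
  online_state(init, cfg, total_frames = 64L)
}

test_that("single-frame trace updates solve the frame NNLS problem", {
  dims <- c(6, 6)
  a <- numeric(36); a[c(14, 15, 20, 21)] <- 0.5   # unit norm
  st <- make_toy_state(matrix(a), dims)
  c_t <- update_traces(st, a * 3, 0)
  expect_equal(c_t, 3, tolerance = 1e-8)
  # multiple non-overlapping neurons with a baseline, W = 0
  A <- matrix(0, 36, 2); A[1:6, 1] <- runif(6); A[30:36, 2] <- runif(7)
  bb <- runif(36)
  st2 <- make_toy_state(A, dims, b_bar = bb)
  c_star <- c(2.2, 0.7)
  y <- as.numeric(A %*% c_star) + bb
  expect_equal(update_traces(st2, y, c(0, 0)), c_star, tolerance = 1e-6)
  # overlapping footprints: KKT conditions against a generic NNLS oracle
  set.seed(32)
  A3 <- matrix(abs(rnorm(36 * 3)), 36, 3)
  st3 <- make_toy_state(A3, dims)
  y3 <- abs(rnorm(36))
  c3 <- update_traces(st3, y3, c(0, 0, 0), inner_iter = 500, tol = 0)
  grad <- as.numeric(crossprod(A3, A3 %*% c3 - y3))
  expect_true(all(grad > -1e-6 | c3 > 1e-10))   # active-set stationarity
  expect_true(all(abs(grad[c3 > 1e-10]) < 1e-5))
  nn <- nnls_oracle(A3, y3)
  expect_equal(sum((y3 - A3 %*% c3)^2), sum((y3 - A3 %*% nn)^2),
               tolerance = 1e-8)
})

test_that("incremental sufficient statistics equal batch recomputation", {
  set.seed(33)
  dims <- c(8, 8); d <- 64
  A <- matrix(0, d, 2)
  A[c(10, 11, 18, 19), 1] <- runif(4); A[c(40, 41, 48), 2] <- runif(3)
  st <- make_toy_state(A, dims)
  T_ <- 30
  Ys <- matrix(abs(rnorm(d * T_, 5)), d, T_)
  cs <- matrix(0, 2, T_); bs <- matrix(0, d, T_)
  for (tt in seq_len(T_)) {
    st <- oncnmfe:::online_step(st, Ys[, tt], tt, detect = FALSE)
    cs[, tt] <- st$C_den[, tt]
    bs[, tt] <- oncnmfe:::background_column(st, Ys[, tt], cs[, tt])
  }
  ss <- suff_stats(st)
  expect_equal(ss$t, T_)
  L_batch <- (Ys - bs) %*% t(cs) / T_
  M_batch <- cs %*% t(cs) / T_
  expect_lt(max(abs(ss$L - L_batch)) / max(abs(L_batch)), 1e-8)
  expect_lt(max(abs(ss$M - M_batch)) / max(abs(M_batch)), 1e-8)
  expect_true(isSymmetric(ss$M, tol = 1e-12))
  expect_gte(min(eigen(ss$M, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)
  # chi equals the accumulation of x x' with the running baseline
  # (recompute with the logged traces and per-step baselines)
  st2 <- make_toy_state(A, dims)
  chi_ref <- matrix(0, d, d)
  bb <- st2$b_bar
  for (tt in seq_len(T_)) {
    st2 <- oncnmfe:::online_step(st2, Ys[, tt], tt, detect = FALSE)
    x <- Ys[, tt] - as.numeric(A %*% st2$C_den[, tt]) - st2$b_bar
    chi_ref <- chi_ref + outer(x, x)
  }
  ss2 <- suff_stats(st2)
  expect_lt(max(abs(ss2$chi - chi_ref / T_)) / max(abs(chi_ref / T_)),
            1e-8)
  # base case t = 1
  st1 <- make_toy_state(A, dims)
  st1 <- oncnmfe:::online_step(st1, Ys[, 1], 1, detect = FALSE)
  s1 <- suff_stats(st1)
  b1 <- oncnmfe:::background_column(st1, Ys[, 1], st1$C_den[, 1])
  expect_equal(s1$L, outer(Ys[, 1] - b1, st1$C_den[, 1]),
               tolerance = 1e-10)
  expect_equal(s1$M, outer(st1$C_den[, 1], st1$C_den[, 1]),
               tolerance = 1e-10)
})

test_that("periodic updates fire on schedule and keep A valid", {
  sim <- small_sim()
  bundle <- small_run()
  lg <- bundle$log[bundle$log$event == "periodic_update", ]
  cfg <- small_config()
  expected <- seq(cfg$init_frames + cfg$update_every, 500,
                  by = cfg$update_every)
  expect_true(all(expected %in% lg$frame))
  expect_true(all(bundle$A@x >= 0))
})

test_that("the engine state does not accumulate frames with stream length", {
  dims <- c(8, 8); d <- 64
  A <- matrix(0, d, 1); A[c(28, 29), 1] <- 1
  sizes <- sapply(c(20L, 60L), function(T_) {
    st <- make_toy_state(A, dims)
    Ys <- matrix(abs(rnorm(d * T_, 5)), d, T_)
    for (tt in seq_len(T_))
      st <- oncnmfe:::online_step(st, Ys[, tt], tt, detect = FALSE)
    # state size excluding the output trace matrices
    st$C_raw <- NULL; st$C_den <- NULL; st$S <- NULL; st$oasis <- NULL
    as.numeric(object.size(st))
  })
  expect_equal(sizes[1], sizes[2], tolerance = 0.01)
  st <- make_toy_state(A, dims)
  expect_equal(ncol(st$Rbuf), st$cfg$buffer_frames)
  expect_equal(ncol(st$x_block), st$cfg$update_every)
})

test_that("a second pass recovers early activity of late-born components", {
  sim <- fixture("late_sim", function() {
    # one neuron silent during the initial batch, active from mid-stream
    base <- simulate_movie(dims = c(32, 32), n_neurons = 3, n_frames = 400,
                           neuron_radius = 3, seed = 9, firing_rate = 0.3)
    tr <- base$truth
    n <- 3
    S <- tr$S
    # silence neuron 3 before frame 220, add clear activity after
    S[n, 1:219] <- 0
    if (sum(S[n, 220:400] > 0) < 3) S[n, c(250, 300, 350)] <- 16
    C <- tr$C
    C[n, ] <- as.numeric(stats::filter(S[n, ], tr$gamma, "recursive"))
    Y <- as.matrix(tr$A %*% C) + truth_background(tr) +
      matrix(rnorm(1024 * 400), 1024, 400)
    tr$C <- C; tr$S <- S
    list(movie = as_movie_test(Y, c(32, 32)), truth = tr)
  })
  cfg <- small_config(init_frames = 100, update_every = 100)
  bundle <- run_onacid_e(sim$movie, cfg)
  reg <- register_components(sim$truth$A, bundle$A, c(32, 32),
                             neuron_radius = 3)
  expect_equal(reg$f1, 1)
  m <- reg$matches
  j_late <- m$j[m$i == 3]
  expect_gte(bundle$birth_frame[j_late], 200)
  b2 <- second_pass(sim$movie, bundle)
  # first-pass trace is zero before birth; second-pass recovers activity
  expect_gt(max(b2$C_raw[j_late, 1:219]), 0)
  expect_gt(cor(b2$C[j_late, ], sim$truth$C[3, ]), 0.9)
  # stable components barely change on the second pass
  j0 <- m$j[m$i == 1]
  expect_gt(cor(b2$C_raw[j0, ], bundle$C_raw[j0, ]), 0.99)
  # empty bundle passes through
  e <- results_bundle(A = Matrix::sparseMatrix(i = integer(0),
                                               j = integer(0),
                                               x = numeric(0),
                                               dims = c(1024, 0)),
                      C = matrix(0, 0, 400), S = matrix(0, 0, 400),
                      dims = c(32, 32))
  expect_equal(ncol(second_pass(sim$movie, e)$A), 0)
})
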