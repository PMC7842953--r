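# Convolutional ring background model.

toy_model <- function(dims = c(12, 12), l = 3, w = 2, K = 2, seed = 61) {
  set.seed(seed)
  offs <- oncnmfe:::ring_offsets(l, w)
  H <- matrix(rnorm(nrow(offs) * K, 0, 0.1), nrow(offs), K)
  Wm <- matrix(runif(prod(dims) * K), prod(dims), K)
  ring_cnn_model(H, Wm, runif(prod(dims), 0, 2), dims, l, w)
}

test_that("quantile loss matches its definition and the L1 limit", {
  expect_equal(quantile_loss(3, 3, 0.3), 0)
  # q = 0.02 asymmetry: under-approximation cheap, over-approximation dear
  expect_equal(quantile_loss(0, 1, 0.02) / 2, 0.98)
  expect_equal(quantile_loss(1, 0, 0.02) / 2, 0.02)
  g <- expand.grid(x = seq(-2, 2, by = 0.4), y = seq(-2, 2, by = 0.4))
  expect_equal(quantile_loss(g$x, g$y, 0.5), sum(abs(g$x - g$y)))
  expect_error(quantile_loss(1, 1, 0), "q must lie")
})

test_that("applying the model equals the compiled sparse matrix", {
  m <- toy_model()
  Wsp <- to_sparse_matrix(m)
  for (k in 1:3) {
    y <- runif(144, 0, 10)
    expect_lt(max(abs(apply_model(m, y) -
                        (as.numeric(Wsp %*% y) + m$b_bar))), 1e-6)
  }
  # row supports equal brute-force annulus enumeration per pixel
  g_off <- oncnmfe:::ring_offsets(3, 2)
  Wb <- Matrix::drop0(Wsp)
  rows <- rep(1:12, 12); cols <- rep(1:12, each = 12)
  for (i in c(1, 40, 78, 144)) {
    r <- rows[i] + g_off[, 1]; c_ <- cols[i] + g_off[, 2]
    ok <- r >= 1 & r <= 12 & c_ >= 1 & c_ <= 12
    expect_setequal(which(Wb[i, ] != 0),
                    pix_index_test(r[ok], c_[ok], c(12, 12)))
  }
})

test_that("uniform averaging kernel gives the ring mean; zero weights b_bar", {
  dims <- c(12, 12)
  offs <- oncnmfe:::ring_offsets(3, 1)
  H <- matrix(1 / nrow(offs), nrow(offs), 1)
  bb <- runif(144)
  m <- ring_cnn_model(H, matrix(1, 144, 1), bb, dims, 3, 1)
  y <- runif(144, 0, 5)
  i <- pix_index_test(6, 6, dims)
  nb <- ring_neighbors(i, 3, dims)
  expect_equal(apply_model(m, y)[i], mean(y[nb]) + bb[i],
               tolerance = 1e-10)
  m0 <- ring_cnn_model(0 * H, matrix(0, 144, 1), bb, dims, 3, 1)
  expect_equal(apply_model(m0, y), bb)
})

test_that("output is invariant to rotations of the parameters", {
  m <- toy_model(K = 2)
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  m2 <- ring_cnn_model(m$H %*% R, m$Wmap %*% R, m$b_bar, m$dims,
                       m$inner_radius, m$width)
  y <- runif(144, 0, 8)
  expect_lt(max(abs(apply_model(m, y) - apply_model(m2, y))), 1e-6)
})

test_that("parameter count follows K(d + |annulus|) + d by enumeration", {
  for (spec in list(c(3, 1, 1), c(3, 2, 2), c(5, 5, 2))) {
    l <- spec[1]; w <- spec[2]; K <- spec[3]
    dims <- c(14, 14); d <- 196
    n_ann <- nrow(oncnmfe:::ring_offsets(l, w))
    m <- ring_cnn_model(matrix(0, n_ann, K), matrix(0, d, K),
                        numeric(d), dims, l, w)
    expect_equal(ring_cnn_n_parameters(m), K * (d + n_ann) + d)
    # annulus size close to the analytic count pi * w * (2l + w - 1)
    expect_lt(abs(n_ann - pi * w * (2 * l + w - 1)),
              0.25 * pi * w * (2 * l + w - 1) + 4)
  }
})

test_that("SVD normalization preserves the product and orders kernels", {
  m <- toy_model(K = 3, seed = 63)
  y <- runif(144, 0, 4)
  mn <- svd_normalize(m)
  expect_lt(max(abs(apply_model(mn, y) - apply_model(m, y))), 1e-8)
  sv <- attr(mn, "singular_values")
  expect_true(all(diff(sv) <= 1e-12))
  # truncation below the top singular value keeps one kernel and bounds
  # the output change by the discarded energy
  mt <- svd_normalize(m, truncate = sv[2] + 1e-9)
  expect_equal(ncol(mt$H), 1L)
  drop_norm <- sqrt(sum(sv[-1]^2))
  expect_lte(max(abs(apply_model(mt, y) - apply_model(m, y))),
             drop_norm * max(abs(y)) + 1e-8)
})

test_that("training approaches the generating parameters' loss", {
  mv <- ringcnn_train_movie()
  cfg <- cnmfe_config(neuron_radius = 2, ring_radius = 3,
                      ringcnn = list(n_kernels = 1, width = 2,
                                     quantile = 0.02, epochs = 30,
                                     batch_size = 12, lr = 0.05))
  fit <- train_ring_cnn(mv$Y, cfg, dims = mv$dims, seed = 2)
  val <- attr(fit, "val_frames")
  # both models predict the frame from the frame itself (the setting the
  # loss is defined in); the generating parameters are the yardstick
  gen_loss <- mean(sapply(val, function(t)
    quantile_loss(mv$Y[, t], apply_model(mv$gen, mv$Y[, t]), 0.02)))
  fit_loss <- mean(sapply(val, function(t)
    quantile_loss(mv$Y[, t], apply_model(fit, mv$Y[, t]), 0.02)))
  expect_lte(fit_loss, 1.1 * gen_loss)
  # under-approximation: rarely above the data
  preds <- sapply(val, function(t) apply_model(fit, mv$Y[, t]))
  expect_lte(mean(preds > mv$Y[, val]), 0.1)
  # determinism: same seed gives identical losses
  fit2 <- train_ring_cnn(mv$Y, cfg, dims = mv$dims, seed = 2)
  expect_identical(attr(fit, "history"), attr(fit2, "history"))
})

test_that("a constant movie is absorbed by the baseline", {
  cfg <- cnmfe_config(neuron_radius = 2, ring_radius = 3,
                      ringcnn = list(n_kernels = 1, width = 2,
                                     epochs = 40, batch_size = 10,
                                     lr = 0.1))
  Y <- matrix(7, 144, 60)
  fit <- train_ring_cnn(Y, cfg, dims = c(12, 12), seed = 3)
  expect_lt(max(abs(apply_model(fit, Y[, 1]) - 7)), 0.07)
})
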