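# Ring graph construction, weight estimation, background evaluation,
# decimation.

test_that("ring neighborhoods match brute-force offset enumeration", {
  dims <- c(11, 11)
  center <- pix_index_test(6, 6, dims)
  nb <- ring_neighbors(center, 2, dims)
  offs <- brute_ring_offsets(2)
  expect_equal(nrow(offs), 16)
  expected <- sort(pix_index_test(6 + offs[, 1], 6 + offs[, 2], dims))
  expect_equal(nb, expected)
  # corner pixel keeps only the in-FOV members of the same offset set
  nb_corner <- ring_neighbors(pix_index_test(1, 1, dims), 2, dims)
  keep <- offs[, 1] + 1 >= 1 & offs[, 2] + 1 >= 1
  expect_equal(nb_corner,
               sort(pix_index_test(1 + offs[keep, 1], 1 + offs[keep, 2],
                                   dims)))
  expect_error(ring_neighbors(center, 0, dims), "l must be > 0")
})

test_that("ring membership is symmetric and interior counts match 2*pi*l", {
  dims <- c(21, 21)
  for (l in c(2, 4, 6)) {
    g <- ring_graph(l, dims)
    i <- pix_index_test(11, 11, dims)
    for (j in g$neighbors[[i]])
      expect_true(i %in% g$neighbors[[j]])
    expect_equal(length(g$neighbors[[i]]), nrow(brute_ring_offsets(l)))
    expect_lt(abs(length(g$neighbors[[i]]) - 2 * pi * l),
              0.5 * 2 * pi * l)
  }
})

test_that("zero data yield zero weights (least-norm branch)", {
  g <- ring_graph(2, c(8, 8))
  W <- solve_ring_weights(graph = g, X = matrix(0, 64, 1))
  expect_equal(Matrix::nnzero(Matrix::drop0(W)), 0)
})

test_that("a planted ring weight matrix is recovered from noiseless data", {
  out <- simulate_ring_background(c(16, 16), 3, n_frames = 120,
                                  b_bar = 0, latent_rank = 5, seed = 2)
  W_hat <- solve_ring_weights(graph = out$graph, X = out$movie)
  rel <- Matrix::norm(W_hat - out$W, "F") / Matrix::norm(out$W, "F")
  expect_lt(rel, 1e-3)
})

test_that("per-pixel rows solve the normal equations optimally", {
  set.seed(4)
  dims <- c(10, 10)
  g <- ring_graph(2, dims)
  X <- matrix(rnorm(100 * 50), 100, 50) +
    outer(as.numeric(gblur(matrix(rnorm(100), 10), 3)), rnorm(50))
  W <- solve_ring_weights(graph = g, X = X)
  for (i in c(1, 35, 55, 100)) {
    r <- g$neighbors[[i]]
    w <- as.numeric(W[i, r])
    base <- sum((X[i, ] - w %*% X[r, , drop = FALSE])^2)
    # exact normal-equation oracle (lm without intercept)
    fit <- lm.fit(t(X[r, , drop = FALSE]), X[i, ])
    expect_lt(base, sum(fit$residuals^2) + 1e-8)
    for (k in 1:5) {
      wp <- w + rnorm(length(w), 0, 0.01)
      expect_gte(sum((X[i, ] - wp %*% X[r, , drop = FALSE])^2),
                 base - 1e-9)
    }
  }
})

test_that("background evaluation matches a dense oracle and edge cases", {
  set.seed(5)
  dims <- c(16, 16); d <- 256
  g <- ring_graph(3, dims)
  X <- matrix(rnorm(d * 30), d, 30)
  W <- solve_ring_weights(graph = g, X = X)
  b <- runif(d, 1, 2)
  A <- Matrix::rsparsematrix(d, 2, 0.1); A@x <- abs(A@x)
  C <- matrix(abs(rnorm(60)), 2, 30)
  Y <- as.matrix(A %*% C) + X + b
  B <- evaluate_background(W, b, Y, A, C, dims, 1)
  B_dense <- as.matrix(W) %*% (Y - as.matrix(A %*% C) - b) + b
  expect_equal(B, B_dense, tolerance = 1e-10)
  # W = 0 reduces to the constant baseline
  W0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                             x = numeric(0), dims = c(d, d))
  expect_true(all(evaluate_background(W0, b, Y, A, C, dims, 1) == b))
  # perfect demixing leaves no fluctuating part
  Yp <- as.matrix(A %*% C) + b
  expect_lt(max(abs(evaluate_background(W, b, Yp, A, C, dims, 1) - b)),
            1e-10)
})

test_that("block-mean decimation and nearest-neighbor upsampling", {
  img <- matrix(runif(36), 6, 6)
  expect_identical(decimate_image(img, 1), img)
  cst <- matrix(3, 4, 4)
  expect_true(all(decimate_image(cst, 2) == 3))
  dec <- decimate_image(img, 2)
  for (i in 1:3) for (j in 1:3)
    expect_equal(dec[i, j],
                 mean(img[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]))
  up <- undecimate_image(dec, 2, c(6, 6))
  expect_equal(dim(up), c(6, 6))
  expect_equal(up[1, 1], dec[1, 1])
  expect_equal(up[6, 6], dec[3, 3])
  # non-dividing dims: trailing partial blocks are averaged
  img5 <- matrix(runif(25), 5, 5)
  d5 <- decimate_image(img5, 2)
  expect_equal(dim(d5), c(3, 3))
  expect_equal(d5[3, 3], img5[5, 5])
  expect_error(decimate_image(img, 0), "factor")
})
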