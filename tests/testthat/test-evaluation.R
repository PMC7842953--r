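# Component registration, F1 scoring, similarity measures, merging and
# screening.

test_that("published count triples reproduce their printed F1 scores", {
  expect_equal(round(f1_score(506, 48, 76), 3), 0.891)
  expect_equal(round(f1_score(21, 0, 2), 3), 0.955)
  expect_equal(round(f1_score(126, 16, 13), 3), 0.897)
  expect_error(f1_score(0, 0, 0), "zero")
})

random_footprints <- function(n, dims = c(20, 20), seed = 71) {
  set.seed(seed)
  d <- prod(dims)
  rows <- rep(seq_len(dims[1]), dims[2])
  cols <- rep(seq_len(dims[2]), each = dims[1])
  A <- matrix(0, d, n)
  ctr <- cbind(runif(n, 4, dims[1] - 3), runif(n, 4, dims[2] - 3))
  for (k in seq_len(n))
    A[, k] <- exp(-((rows - ctr[k, 1])^2 + (cols - ctr[k, 2])^2) / 4)
  A[A < 0.05] <- 0
  A
}

test_that("registration is exact for identical and disjoint sets", {
  A <- random_footprints(5)
  reg <- register_components(A, A, c(20, 20))
  expect_equal(reg$TP, 5); expect_equal(reg$f1, 1)
  B <- matrix(0, 400, 2); B[1:4, 1] <- 1; B[397:400, 2] <- 1
  reg2 <- register_components(A, B, c(20, 20))
  expect_equal(reg2$TP, 0)
  expect_equal(reg2$FP, 2); expect_equal(reg2$FN, 5)
})

test_that("assignment equals the brute-force permutation optimum", {
  # crafted 3x3 distance matrix
  D <- matrix(c(0.2, 0.9, 0.8,
                0.7, 0.1, 0.9,
                0.9, 0.8, 0.3), 3, 3, byrow = TRUE)
  asg <- oncnmfe:::hungarian_assignment(D)
  bf <- brute_force_assignment(D)
  expect_equal(asg$j[order(asg$i)], bf$assignment)
  set.seed(72)
  for (rep in 1:8) {
    n1 <- sample(2:6, 1); n2 <- n1 + sample(0:(6 - n1), 1)
    D <- matrix(runif(n1 * n2), n1, n2)
    asg <- oncnmfe:::hungarian_assignment(D)
    cost <- sum(D[cbind(asg$i, asg$j)])
    expect_equal(cost, brute_force_assignment(D)$cost, tolerance = 1e-12)
  }
})

test_that("swapping the inputs swaps FP and FN and preserves F1", {
  A1 <- random_footprints(6, seed = 73)
  A2 <- random_footprints(4, seed = 74)
  r12 <- register_components(A1, A2, c(20, 20))
  r21 <- register_components(A2, A1, c(20, 20))
  expect_equal(r12$TP, r21$TP)
  expect_equal(r12$FP, r21$FN)
  expect_equal(r12$FN, r21$FP)
  expect_equal(r12$f1, r21$f1)
})

test_that("shape and trace similarities have their invariances", {
  a <- runif(30)
  expect_equal(shape_similarity(a, a), 1)
  b <- numeric(30); b[which(a == 0)] <- 1
  a2 <- c(a, 0); b2 <- c(b, 1) * c(rep(0, 30), 1)
  expect_equal(shape_similarity(c(a, 0), c(numeric(30), 1)), 0)
  expect_error(shape_similarity(a, numeric(30)), "zero-norm")
  cc <- cumsum(rnorm(40))
  expect_equal(trace_similarity(cc, 2 * cc + 5), 1)
})

test_that("merging collapses duplicates and keeps distinct overlaps", {
  set.seed(75)
  d <- 400; T_ <- 120
  a <- random_footprints(1, seed = 76)[, 1]
  tr <- as.numeric(stats::filter(rbinom(T_, 1, 0.08) * 10, 0.9,
                                 "recursive"))
  # the same neuron split into two half-footprints with the same trace
  a1 <- a * (seq_len(d) %% 2 == 0); a2 <- a * (seq_len(d) %% 2 == 1)
  a1[which.max(a)] <- max(a); a2[which.max(a)] <- max(a)  # shared pixel
  other <- random_footprints(1, seed = 77)[, 1]
  tr2 <- as.numeric(stats::filter(rbinom(T_, 1, 0.08) * 10, 0.9,
                                  "recursive"))
  A <- Matrix::Matrix(cbind(a1, a2, a * 0.5 + other), sparse = TRUE)
  Cr <- rbind(tr + rnorm(T_, 0, 0.05), tr + rnorm(T_, 0, 0.05), tr2)
  bundle <- results_bundle(A = A, C = pmax(Cr, 0), S = 0 * Cr,
                           C_raw = Cr, dims = c(20, 20),
                           birth_frame = c(1L, 1L, 1L))
  out <- merge_and_screen(bundle, cnmfe_config(theta_snr = 0))
  expect_equal(ncol(out$A), 2L)   # duplicates merged, distinct one kept
  # merged trace still matches the underlying activity
  cors <- apply(out$C_raw, 1, function(z) cor(z, tr))
  expect_gt(max(cors), 0.95)
})
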