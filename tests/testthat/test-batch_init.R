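# Batch initialization: HALS updates, greedy seeding, threshold
# monotonicity.

test_that("HALS footprint update has the documented fixed points", {
  set.seed(21)
  d <- 25; N <- 3; T_ <- 40
  A_true <- matrix(0, d, N)
  supports <- list(1:9, 10:17, 18:25)
  for (n in 1:N) A_true[supports[[n]], n] <- runif(length(supports[[n]]))
  C <- matrix(abs(rnorm(N * T_)) + 0.2, N, T_)
  Y <- A_true %*% C
  L <- Y %*% t(C); M <- C %*% t(C)
  # exact data with correct supports: one pass from the truth is a fixed
  # point
  A1 <- hals_update_A(L, M, A_true, supports)
  expect_equal(A1, A_true, tolerance = 1e-10)
  # scalar case: closed form max(0, L/M)
  y1 <- matrix(2.5, 1, 1) # single pixel, single neuron, c = 1
  expect_equal(hals_update_A(matrix(5), matrix(2), matrix(0), list(1)),
               matrix(2.5))
  expect_equal(hals_update_A(matrix(-3), matrix(2), matrix(0), list(1)),
               matrix(0))
})

test_that("repeated HALS passes reach the projected-gradient optimum", {
  set.seed(22)
  d <- 25; N <- 3; T_ <- 60
  A0 <- matrix(abs(rnorm(d * N)), d, N)
  C <- matrix(abs(rnorm(N * T_)), N, T_)
  Y <- matrix(abs(rnorm(d * T_)), d, T_)
  L <- Y %*% t(C); M <- C %*% t(C)
  supports <- replicate(N, 1:d, simplify = FALSE)
  A <- hals_update_A(L, M, A0, supports, n_pass = 50L)
  obj <- function(A) sum((Y - A %*% C)^2)
  # projected-gradient oracle
  Ap <- A0
  step <- 1 / (2 * norm(M, "2"))
  for (k in 1:4000) Ap <- pmax(Ap - step * 2 * (Ap %*% M - L), 0)
  expect_lt(obj(A) - obj(Ap), 1e-6 * max(1, obj(Ap)))
  # objective never increases across passes
  prev <- obj(A0)
  Ax <- A0
  for (k in 1:5) {
    Ax <- hals_update_A(L, M, Ax, supports)
    expect_lte(obj(Ax), prev + 1e-10)
    prev <- obj(Ax)
  }
})

test_that("trace updates are exact for orthogonal footprints and recover C", {
  set.seed(23)
  d <- 30; T_ <- 50
  A <- matrix(0, d, 2)
  A[1:15, 1] <- runif(15); A[16:30, 2] <- runif(15)
  C_true <- matrix(abs(rnorm(2 * T_)), 2, T_)
  Y <- A %*% C_true
  C1 <- update_C_batch(A, Y, matrix(0, 2, T_))
  expect_equal(C1, C_true, tolerance = 1e-10)  # one pass, non-overlapping
  # overlapping: convergence to the truth over passes
  A2 <- matrix(abs(rnorm(d * 3)), d, 3)
  C2_true <- matrix(abs(rnorm(3 * T_)), 3, T_)
  C2 <- update_C_batch(A2, A2 %*% C2_true, matrix(0, 3, T_), n_pass = 100L)
  expect_gt(min(diag(cor(t(C2), t(C2_true)))), 0.999)
  # all-zero data drive C to zero
  expect_equal(update_C_batch(A, 0 * Y, C_true, n_pass = 50L),
               matrix(0, 2, T_), tolerance = 1e-6)
})

test_that("initialization finds all well-separated bright neurons", {
  sim <- small_sim()
  ini <- initialize_batch(sim$movie[, , 1:100], small_config())
  expect_equal(ncol(ini$A), nrow(sim$truth$centers))
  reg <- register_components(sim$truth$A, ini$A, c(40, 40),
                             neuron_radius = 3)
  expect_equal(reg$f1, 1)
  # zero-variance movie yields no components
  flat <- array(5, c(24, 24, 40))
  ini0 <- initialize_batch(flat, cnmfe_config(init_frames = 40))
  expect_equal(ncol(ini0$A), 0)
})

test_that("raising seed thresholds never increases the seed count", {
  sim <- small_sim()
  base <- small_config()
  n_seeds <- function(cfg)
    nrow(initialize_batch(sim$movie[, , 1:100], cfg)$seeds)
  n0 <- n_seeds(base)
  expect_lte(n_seeds(small_config(min_pnr = base$min_pnr * 2)), n0)
  expect_lte(n_seeds(small_config(min_corr = 0.95)), n0)
})

test_that("alternating refinement does not increase the fit objective", {
  sim <- small_sim()
  Y <- vec_frames(sim$movie)[, 1:100]
  cfg1 <- small_config(outer_iter = 1)
  cfg3 <- small_config(outer_iter = 3)
  obj_of <- function(ini) {
    B <- evaluate_background(ini$W, ini$b_bar, Y, ini$A, ini$C,
                             c(40, 40), 1)
    cnmfe_objective(Y, ini$A, ini$C, B)
  }
  expect_lte(obj_of(initialize_batch(Y, cfg3, dims = c(40, 40))),
             obj_of(initialize_batch(Y, cfg1, dims = c(40, 40))) * 1.001)
})
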