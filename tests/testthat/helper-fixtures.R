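# Shared fixtures, computed lazily once per test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

# small simulated movie + full pipeline run used by several test files
small_sim <- function() fixture("small_sim", function() {
  simulate_movie(dims = c(40, 40), n_neurons = 6, n_frames = 500,
                 neuron_radius = 3, seed = 5)
})

small_config <- function(...) {
  config_preset("simulation", neuron_radius = 3, ring_radius = 5,
                init_frames = 100, buffer_frames = 80, ...)
}

small_run <- function() fixture("small_run", function() {
  run_onacid_e(small_sim()$movie, small_config())
})

# brute-force minimal-cost assignment over all permutations (n <= 7)
brute_force_assignment <- function(D) {
  n1 <- nrow(D); n2 <- ncol(D)
  stopifnot(n1 <= n2, n2 <= 7)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n2))) {
    cost <- sum(D[cbind(seq_len(n1), p[seq_len(n1)])])
    if (cost < best_cost) { best_cost <- cost; best <- p[seq_len(n1)] }
  }
  list(assignment = best, cost = best_cost)
}

# independent constrained-QP solve of the AR(1) deconvolution problem on
# the spike parameterization (L-BFGS-B with box constraints)
qp_oasis_oracle <- function(y, g, lambda) {
  T_ <- length(y)
  fwd <- function(s) as.numeric(stats::filter(s, g, "recursive"))
  fn <- function(s) 0.5 * sum((fwd(s) - y)^2) + lambda * sum(s)
  gr <- function(s) {
    r <- fwd(s) - y
    rev(as.numeric(stats::filter(rev(r), g, "recursive"))) + lambda
  }
  s0 <- pmax(c(y[1], y[-1] - g * y[-T_]), 0)
  o <- optim(s0, fn, gr, method = "L-BFGS-B", lower = 0,
             control = list(maxit = 5000, factr = 10))
  cvec <- fwd(o$par)
  list(c = cvec, s = o$par, objective = o$value)
}

oasis_objective <- function(y, cvec, g, lambda) {
  svec <- c(cvec[1], cvec[-1] - g * cvec[-length(cvec)])
  0.5 * sum((cvec - y)^2) + lambda * sum(svec)
}

# movie generated exactly by a ring-CNN background plus sparse
# nonnegative foreground; used for training-recovery bounds
ringcnn_train_movie <- function(seed = 64) fixture("rcnn_movie", function() {
  set.seed(seed)
  dims <- c(16, 16); d <- 256; T_ <- 120
  offs <- oncnmfe:::ring_offsets(3, 2)
  H <- matrix(0, nrow(offs), 1); H[, 1] <- 1 / nrow(offs)
  Wm <- matrix(runif(d, 0.8, 1.2), d, 1)
  bb <- runif(d, 4, 6)
  gen <- ring_cnn_model(H, Wm, bb, dims, 3, 2)
  latent <- matrix(rnorm(d * T_, 10, 2), d, T_)
  bg <- sapply(seq_len(T_), function(t) apply_model(gen, latent[, t]))
  fg <- matrix(0, d, T_)
  fg[sample(d, 20), ] <- matrix(pmax(rnorm(20 * T_, 0, 2), 0), 20)
  list(Y = bg + fg, gen = gen, latent = latent, dims = dims)
})

# nonnegative least squares via box-constrained quasi-Newton
nnls_oracle <- function(A, y) {
  fn <- function(x) 0.5 * sum((A %*% x - y)^2)
  gr <- function(x) as.numeric(crossprod(A, A %*% x - y))
  o <- optim(rep(0, ncol(A)), fn, gr, method = "L-BFGS-B", lower = 0,
             control = list(maxit = 2000, factr = 10))
  o$par
}

# wrap a d x T matrix as a movie array
as_movie_test <- function(Y, dims, frame_rate = 10) {
  arr <- array(Y, c(dims[1], dims[2], ncol(Y)))
  attr(arr, "frame_rate") <- frame_rate
  arr
}

# 1-based column-major pixel index (the package-wide convention)
pix_index_test <- function(row, col, dims) (col - 1) * dims[1] + row

# brute-force enumeration of lattice offsets at distance [l, l+1)
brute_ring_offsets <- function(l) {
  h <- ceiling(l) + 1
  out <- NULL
  for (dr in -h:h) for (dc in -h:h) {
    d <- sqrt(dr^2 + dc^2)
    if (d >= l && d < l + 1) out <- rbind(out, c(dr, dc))
  }
  out
}
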