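#' F1 score from match counts
#'
#' Harmonic mean of precision and recall,
#' `F1 = 2 TP / (2 TP + FP + FN)`.
#'
#' @param TP,FP,FN nonnegative counts (not all zero).
#' @return value in `[0, 1]` (full precision; round to 3 decimals for
#'   reporting).
#' @export
f1_score <- function(TP, FP, FN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  if (TP + FP + FN == 0) stop("all counts are zero", call. = FALSE)
  2 * TP / (2 * TP + FP + FN)
}

#' Register two sets of spatial footprints
#'
#' Builds a pairwise distance matrix (Jaccard distance between footprints
#' binarized at 20% of their peak, set to the maximal distance when the
#' centroids are further apart than one neuron diameter), solves the
#' optimal assignment with the Hungarian algorithm, and counts matches
#' with distance at most `threshold` as true positives. Unmatched
#' components of `A1` are false negatives, of `A2` false positives
#' (i.e. `A1` is treated as the reference).
#'
#' @param A1,A2 `d x N` footprint matrices on the same FOV.
#' @param dims FOV dims.
#' @param threshold maximal Jaccard distance of a valid match.
#' @param neuron_radius used for the centroid-distance gate.
#' @param binarize_quantile footprint binarization level (fraction of
#'   the per-component peak).
#' @return list of class `registration_result`: `matches` (data frame
#'   with indices and distances), `TP`, `FP`, `FN`, `f1`, `precision`,
#'   `recall`.
#' @export
register_components <- function(A1, A2, dims, threshold = 0.7,
                                neuron_radius = 4,
                                binarize_quantile = 0.2) {
  if (nrow(A1) != nrow(A2))
    stop("footprint matrices live on different FOVs", call. = FALSE)
  n1 <- ncol(A1); n2 <- ncol(A2)
  if (n1 == 0 || n2 == 0) {
    return(registration_result(
      data.frame(i = integer(0), j = integer(0), distance = numeric(0)),
      TP = 0L, FP = n2, FN = n1))
  }
  B1 <- binarize_footprints(A1, binarize_quantile)
  B2 <- binarize_footprints(A2, binarize_quantile)
  cent1 <- footprint_centroids(A1, dims)
  cent2 <- footprint_centroids(A2, dims)
  inter <- as.matrix(Matrix::crossprod(B1, B2))
  s1 <- Matrix::colSums(B1); s2 <- Matrix::colSums(B2)
  uni <- outer(s1, s2, "+") - inter
  D <- 1 - inter / pmax(uni, 1)
  cd <- sqrt(outer(cent1[, 1], cent2[, 1], "-")^2 +
             outer(cent1[, 2], cent2[, 2], "-")^2)
  D[cd > 2 * neuron_radius] <- 1
  asg <- hungarian_assignment(D)
  ok <- which(D[cbind(asg$i, asg$j)] <= threshold)
  matches <- data.frame(i = asg$i[ok], j = asg$j[ok],
                        distance = D[cbind(asg$i[ok], asg$j[ok])])
  registration_result(matches, TP = nrow(matches),
                      FP = n2 - nrow(matches), FN = n1 - nrow(matches))
}

registration_result <- function(matches, TP, FP, FN) {
  structure(list(matches = matches, TP = TP, FP = FP, FN = FN,
                 f1 = if (TP + FP + FN > 0) f1_score(TP, FP, FN) else NA,
                 precision = if (TP + FP > 0) TP / (TP + FP) else NA,
                 recall = if (TP + FN > 0) TP / (TP + FN) else NA),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration> TP %d FP %d FN %d | F1 %.3f precision %.3f recall %.3f\n",
              x$TP, x$FP, x$FN, x$f1, x$precision, x$recall))
  invisible(x)
}

binarize_footprints <- function(A, q) {
  A <- methods::as(A, "CsparseMatrix")
  pk <- apply(A, 2, max)
  Matrix::t(Matrix::t(A) > q * pmax(pk, 1e-12)) * 1
}

footprint_centroids <- function(A, dims) {
  A <- as.matrix(A)
  rows <- rep(seq_len(dims[1]), dims[2])
  cols <- rep(seq_len(dims[2]), each = dims[1])
  w <- colSums(A)
  cbind(colSums(A * rows) / pmax(w, 1e-12),
        colSums(A * cols) / pmax(w, 1e-12))
}

# optimal assignment minimizing total distance; rows i matched to cols j.
# Rectangular matrices are padded to square.
hungarian_assignment <- function(D) {
  n1 <- nrow(D); n2 <- ncol(D)
  n <- max(n1, n2)
  Dp <- matrix(max(D) + 1, n, n)
  Dp[seq_len(n1), seq_len(n2)] <- D
  sol <- as.integer(clue::solve_LSAP(Dp))
  i <- seq_len(n1)
  j <- sol[i]
  keep <- j <= n2
  list(i = i[keep], j = j[keep])
}

#' Shape and trace similarity
#'
#' `shape_similarity` is the cosine similarity
#' `a'a* / (||a|| ||a*||)`; `trace_similarity` the Pearson correlation.
#'
#' @param a,a_star footprint vectors.
#' @return scalar similarity.
#' @export
shape_similarity <- function(a, a_star) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(a_star^2))
  if (na < 1e-12 || nb < 1e-12) stop("zero-norm footprint", call. = FALSE)
  sum(a * a_star) / (na * nb)
}

#' @rdname shape_similarity
#' @param c_,c_star trace vectors.
#' @export
trace_similarity <- function(c_, c_star) {
  if (sd(c_) < 1e-12 || sd(c_star) < 1e-12)
    stop("constant trace", call. = FALSE)
  cor(c_, c_star)
}

#' Compare an extraction result to ground truth or to another result
#'
#' Registers the footprints and summarizes match quality: F1, precision,
#' recall, per-match cosine shape similarity and trace correlation
#' (median with a bootstrap standard error of the median).
#'
#' @param bundle a `cnmfe_bundle`.
#' @param reference another `cnmfe_bundle` or a `simulation_truth`.
#' @param threshold,binarize_quantile see [register_components()].
#' @param n_boot bootstrap replicates for the standard error.
#' @return list with the `registration_result`, `shape_similarity`,
#'   `trace_correlation` vectors and their medians (`media`ns +/- SEM).
#' @export
evaluate_against <- function(bundle, reference, threshold = 0.7,
                             binarize_quantile = 0.2, n_boot = 200L) {
  if (inherits(reference, "simulation_truth")) {
    A_ref <- reference$A; C_ref <- reference$C
    radius <- reference$neuron_radius
  } else {
    A_ref <- reference$A; C_ref <- reference$C
    radius <- bundle$config$neuron_radius %||% 4
  }
  reg <- register_components(A_ref, bundle$A, bundle$dims,
                             threshold = threshold,
                             neuron_radius = radius,
                             binarize_quantile = binarize_quantile)
  m <- reg$matches
  Tc <- min(ncol(C_ref), ncol(bundle$C))
  shp <- numeric(nrow(m)); trc <- numeric(nrow(m))
  for (k in seq_len(nrow(m))) {
    shp[k] <- shape_similarity(as.numeric(A_ref[, m$i[k]]),
                               as.numeric(bundle$A[, m$j[k]]))
    trc[k] <- suppressWarnings(
      cor(C_ref[m$i[k], seq_len(Tc)], bundle$C[m$j[k], seq_len(Tc)]))
  }
  med_se <- function(v) {
    if (!length(v)) return(c(NA, NA))
    bs <- replicate(n_boot, median(sample(v, replace = TRUE)))
    c(median(v), sd(bs))
  }
  list(registration = reg, shape_similarity = shp,
       trace_correlation = trc,
       median_shape = med_se(shp), median_trace = med_se(trc))
}

#' Merge duplicate components and screen for quality
#'
#' Components whose footprints overlap and whose raw traces correlate at
#' least `merge_threshold` are merged (footprints summed, the merged
#' trace re-fit by a rank-1 factorization of their joint activity).
#' Surviving components are screened by the SNR of their full trace
#' (peak over the spectral noise estimate) against `theta_snr`; when the
#' movie is available the spatial screen (`theta_sp` correlation between
#' footprint and time-averaged component-plus-residual data on the
#' support) is applied as well.
#'
#' @param bundle a `cnmfe_bundle`.
#' @param config a `cnmfe_config`.
#' @param merge_threshold trace-correlation threshold for merging.
#' @param movie optional `d x T` matrix for the spatial screen.
#' @return filtered bundle.
#' @export
merge_and_screen <- function(bundle, config, merge_threshold = 0.8,
                             movie = NULL) {
  N <- ncol(bundle$A)
  if (N == 0) return(bundle)
  Cr <- bundle$C_raw %||% bundle$C
  OV <- as.matrix(Matrix::crossprod(bundle$A > 0)) > 0
  parent <- seq_len(N)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(N - 1)) for (j in seq(i + 1, N)) {
    if (OV[i, j]) {
      r <- suppressWarnings(cor(Cr[i, ], Cr[j, ]))
      if (is.finite(r) && r >= merge_threshold) {
        parent[find(j)] <- find(i)
      }
    }
  }
  groups <- split(seq_len(N), vapply(seq_len(N), find, 1L))
  A_new <- NULL; Cr_new <- NULL; C_new <- NULL; S_new <- NULL
  birth <- integer(0)
  merged_any <- any(lengths(groups) > 1)
  cols <- list(); crs <- list(); cs <- list(); ss <- list()
  for (g in groups) {
    if (length(g) == 1L) {
      cols[[length(cols) + 1L]] <- bundle$A[, g, drop = FALSE]
      crs[[length(crs) + 1L]] <- Cr[g, ]
      cs[[length(cs) + 1L]] <- bundle$C[g, ]
      ss[[length(ss) + 1L]] <- bundle$S[g, ]
    } else {
      joint <- as.matrix(bundle$A[, g, drop = FALSE]) %*%
        Cr[g, , drop = FALSE]
      f <- local_rank1_nmf(joint, which.max(rowSums(joint)))
      cols[[length(cols) + 1L]] <- Matrix::Matrix(f$a, ncol = 1,
                                                  sparse = TRUE)
      crs[[length(crs) + 1L]] <- f$c
      gam <- estimate_ar_coefs(f$c, p = 1L)
      dec <- oasis(f$c, gam, default_lambda(f$c), config$s_min)
      cs[[length(cs) + 1L]] <- dec$c
      ss[[length(ss) + 1L]] <- dec$s
    }
    birth <- c(birth, min(bundle$birth_frame[g]))
  }
  A_new <- Reduce(methods::cbind2, cols)
  Cr_new <- do.call(rbind, crs); C_new <- do.call(rbind, cs)
  S_new <- do.call(rbind, ss)

  max_size <- config$max_fill * (4 * config$neuron_radius + 1)^2
  keep <- vapply(seq_len(ncol(A_new)), function(n) {
    tr <- Cr_new[n, ]
    noise <- max(estimate_noise(tr), 1e-9)
    snr_ok <- max(C_new[n, ]) / noise >= config$theta_snr
    # somata are compact above 20% of peak; diffuse background
    # components stay broad at that level
    if (sum(A_new[, n] > 0.2 * max(A_new[, n])) > max_size)
      return(FALSE)
    sp_ok <- TRUE
    if (!is.null(movie)) {
      # project the data onto the (centered) trace: background that does
      # not co-fluctuate with the component averages out
      sup <- which(A_new[, n] > 0.1 * max(A_new[, n]))
      others <- setdiff(seq_len(ncol(A_new)), n)
      rec_others <- if (length(others))
        as.matrix(A_new[sup, others, drop = FALSE]) %*%
          Cr_new[others, , drop = FALSE] else 0
      w <- tr - mean(tr)
      dat <- as.numeric((movie[sup, , drop = FALSE] - rec_others) %*% w)
      sp <- suppressWarnings(cor(as.numeric(A_new[sup, n]), dat))
      sp_ok <- is.finite(sp) && sp >= config$theta_sp
    }
    snr_ok && sp_ok
  }, logical(1))

  log <- bundle$log
  if (any(!keep) || merged_any) {
    extra <- data.frame(frame = NA_integer_,
                        event = sprintf("post_process_kept_%d_of_%d",
                                        sum(keep), N),
                        row = NA_integer_, col = NA_integer_,
                        value = sum(!keep))
    log <- if (is.null(log)) extra else rbind(log, extra)
  }
  results_bundle(A = A_new[, keep, drop = FALSE],
                 C = C_new[keep, , drop = FALSE],
                 S = S_new[keep, , drop = FALSE],
                 C_raw = Cr_new[keep, , drop = FALSE],
                 dims = bundle$dims, background = bundle$background,
                 shifts = bundle$shifts, birth_frame = birth[keep],
                 config = bundle$config, log = log,
                 frame_rate = bundle$frame_rate)
}
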