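#' Configuration for online source extraction
#'
#' Builds a validated configuration object controlling initialization,
#' component detection, background modelling, deconvolution, motion
#' correction and the ring-CNN variant. Defaults follow common practice for
#' microendoscopic data; detection thresholds in particular should be
#' adjusted per dataset (see [config_preset()]).
#'
#' @param neuron_radius expected neuron soma radius in pixels; sets the
#'   spatial band-pass width for seed images, the local NMF window and the
#'   ring radius default.
#' @param ring_radius inner radius `l` of the background ring (pixels);
#'   default `round(1.5 * neuron_radius)`, chosen to exclude contributions
#'   from a neuron underlying the pixel itself.
#' @param init_frames length `T_b` of the initial batch processed offline
#'   to seed the online state.
#' @param update_every period `T_p` (frames) of the sufficient-statistic,
#'   footprint and background-weight updates.
#' @param buffer_frames length `l_b` of the residual ring buffer used to
#'   detect newly active components.
#' @param min_corr,min_pnr seed thresholds `L_min` (local correlation) and
#'   `P_min` (peak-to-noise ratio) on the summary images.
#' @param theta_sp spatial-correlation acceptance threshold for candidate
#'   footprints.
#' @param theta_snr minimal SNR of a candidate trace.
#' @param max_candidates candidate components examined per frame.
#' @param detect_every look for new components every k-th frame.
#' @param max_fill maximal fraction of the candidate window a footprint
#'   may fill (above its 10%-of-peak level); rejects diffuse background
#'   blobs that are not soma-shaped.
#' @param summary_mode `"corr_pnr"` (product of local-correlation and
#'   peak-to-noise images) or `"variance"` (energy of the smoothed buffer).
#' @param ar_order order `P` of the calcium AR dynamics (1 or 2).
#' @param gamma AR coefficients; `NULL` to estimate per component from the
#'   autocovariance of the initial batch.
#' @param lambda sparsity penalty for deconvolution; `NULL` scales a default
#'   from the estimated trace noise.
#' @param s_min minimal spike size (AR(1) only); takes precedence over
#'   `lambda` when positive.
#' @param decimate integer spatial decimation factor applied to background
#'   estimation only (footprints and traces stay at full resolution).
#' @param inner_iter coordinate-descent iterations per frame when tracking
#'   traces.
#' @param outer_iter alternations of the initialization refinement.
#' @param epochs passes over the movie; for multi-epoch runs detection is
#'   disabled on the final epoch, which only tracks activity.
#' @param offset constant camera offset subtracted from every frame.
#' @param motion list: `enabled`, `max_shift` (pixels), `template_frames`
#'   (number of denoised frames averaged into the template), `hp_sigma`
#'   (high-pass Gaussian width, default 3 neuron radii).
#' @param ringcnn list: `n_kernels` (K), `width` (annulus width, pixels),
#'   `quantile` (q of the pinball loss), `init_frames` (T_init),
#'   `bg_rank`, `lr`, `batch_size`, `epochs`, `val_frac`.
#' @param seed integer seed for all stochastic operations.
#'
#' @return an object of class `cnmfe_config` (a validated named list).
#' @export
cnmfe_config <- function(neuron_radius = 4,
                         ring_radius = NULL,
                         init_frames = 200L,
                         update_every = 200L,
                         buffer_frames = 100L,
                         min_corr = 0.8,
                         min_pnr = 6,
                         theta_sp = 0.5,
                         theta_snr = 3,
                         max_candidates = 3L,
                         detect_every = 1L,
                         max_fill = 0.6,
                         summary_mode = c("corr_pnr", "variance"),
                         ar_order = 1L,
                         gamma = NULL,
                         lambda = NULL,
                         s_min = 0,
                         decimate = 1L,
                         inner_iter = 5L,
                         outer_iter = 2L,
                         epochs = 1L,
                         offset = 0,
                         motion = list(),
                         ringcnn = list(),
                         seed = 1L) {
  summary_mode <- match.arg(summary_mode)
  if (is.null(ring_radius)) ring_radius <- round(1.5 * neuron_radius)
  motion <- modifyList(list(enabled = FALSE, max_shift = 10,
                            template_frames = 50L,
                            hp_sigma = 3 * neuron_radius), motion)
  ringcnn <- modifyList(list(n_kernels = 2L, width = 5L, quantile = 0.02,
                             init_frames = 500L, bg_rank = 2L, lr = 0.05,
                             batch_size = 10L, epochs = 15L,
                             val_frac = 0.2), ringcnn)
  cfg <- structure(list(
    neuron_radius = neuron_radius, ring_radius = ring_radius,
    init_frames = as.integer(init_frames),
    update_every = as.integer(update_every),
    buffer_frames = as.integer(buffer_frames),
    min_corr = min_corr, min_pnr = min_pnr,
    theta_sp = theta_sp, theta_snr = theta_snr,
    max_candidates = as.integer(max_candidates),
    detect_every = as.integer(detect_every),
    max_fill = max_fill,
    summary_mode = summary_mode,
    ar_order = as.integer(ar_order), gamma = gamma, lambda = lambda,
    s_min = s_min, decimate = as.integer(decimate),
    inner_iter = as.integer(inner_iter),
    outer_iter = as.integer(outer_iter),
    epochs = as.integer(epochs), offset = offset,
    motion = motion, ringcnn = ringcnn, seed = as.integer(seed)),
    class = "cnmfe_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid config field '%s': %s", field, why), call. = FALSE)
  }
  if (!is.numeric(cfg$neuron_radius) || cfg$neuron_radius <= 0)
    fail("neuron_radius", "must be a positive number")
  if (cfg$ring_radius <= 0) fail("ring_radius", "must be > 0")
  if (cfg$init_frames < 32L) fail("init_frames", "need at least 32 frames")
  if (cfg$update_every < 1L) fail("update_every", "must be >= 1")
  if (cfg$buffer_frames < 2L) fail("buffer_frames", "must be >= 2")
  if (cfg$min_corr < 0 || cfg$min_corr > 1)
    fail("min_corr", "must lie in [0, 1]")
  if (cfg$min_pnr < 0) fail("min_pnr", "must be >= 0")
  if (cfg$theta_sp < 0 || cfg$theta_sp > 1)
    fail("theta_sp", "must lie in [0, 1]")
  if (cfg$theta_snr < 0) fail("theta_snr", "must be >= 0")
  if (cfg$max_candidates < 1L) fail("max_candidates", "must be >= 1")
  if (cfg$detect_every < 1L) fail("detect_every", "must be >= 1")
  if (cfg$max_fill <= 0 || cfg$max_fill > 1)
    fail("max_fill", "must lie in (0, 1]")
  if (!cfg$ar_order %in% c(1L, 2L)) fail("ar_order", "must be 1 or 2")
  if (!is.null(cfg$gamma)) assert_stable_ar(cfg$gamma)
  if (!is.null(cfg$lambda) && cfg$lambda < 0) fail("lambda", "must be >= 0")
  if (cfg$s_min < 0) fail("s_min", "must be >= 0")
  if (cfg$decimate < 1L) fail("decimate", "must be a positive integer")
  if (cfg$epochs < 1L) fail("epochs", "must be >= 1")
  q <- cfg$ringcnn$quantile
  if (q <= 0 || q > 1) fail("ringcnn$quantile", "must lie in (0, 1]")
  if (cfg$ringcnn$n_kernels < 1L) fail("ringcnn$n_kernels", "must be >= 1")
  if (cfg$ringcnn$width < 1L) fail("ringcnn$width", "must be >= 1")
  invisible(cfg)
}

assert_stable_ar <- function(gamma) {
  if (any(!is.finite(gamma)))
    stop("invalid config field 'gamma': must be finite", call. = FALSE)
  roots <- polyroot(c(1, -gamma))
  if (any(Mod(roots) <= 1 + 1e-12))
    stop("invalid config field 'gamma': AR process is unstable ",
         "(roots of 1 - sum(gamma_p z^p) must lie outside the unit circle)",
         call. = FALSE)
  invisible(gamma)
}

#' Named detection-threshold presets
#'
#' Threshold sets that have proven adequate for four typical recording
#' targets (dorsal striatum, prefrontal cortex, ventral hippocampus, bed
#' nucleus of the stria terminalis), plus a `"simulation"` preset suited to
#' the synthetic movies produced by [simulate_movie()]. Thresholds should
#' always be inspected against the summary images of the initial batch.
#'
#' @param name one of `"striatum"`, `"pfc"`, `"hippocampus"`, `"bnst"`,
#'   `"simulation"`.
#' @param ... further arguments passed to [cnmfe_config()], overriding the
#'   preset.
#' @return a `cnmfe_config`.
#' @export
config_preset <- function(name = c("striatum", "pfc", "hippocampus", "bnst",
                                   "simulation"), ...) {
  name <- match.arg(name)
  pre <- switch(name,
    striatum    = list(min_corr = 0.7,  min_pnr = 7,  theta_sp = 0.55,
                       theta_snr = 3.5),
    pfc         = list(min_corr = 0.9,  min_pnr = 15, theta_sp = 0.9,
                       theta_snr = 2.8),
    hippocampus = list(min_corr = 0.9,  min_pnr = 15, theta_sp = 0.85,
                       theta_snr = 2.8),
    bnst        = list(min_corr = 0.92, min_pnr = 15, theta_sp = 0.6,
                       theta_snr = 3.5),
    simulation  = list(min_corr = 0.8,  min_pnr = 6,  theta_sp = 0.5,
                       theta_snr = 3))
  do.call(cnmfe_config, modifyList(pre, list(...)))
}

#' Read / write a configuration as YAML
#'
#' @param path file path.
#' @return `load_config` returns a validated `cnmfe_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  preset <- raw$preset
  raw$preset <- NULL
  known <- names(formals(cnmfe_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(preset)) do.call(config_preset, c(list(name = preset), raw))
  else do.call(cnmfe_config, raw)
}

#' @rdname load_config
#' @param cfg a `cnmfe_config`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.cnmfe_config <- function(x, ...) {
  cat("<cnmfe_config>\n")
  cat(sprintf("  neuron radius %g px, ring radius %g px, decimate %d\n",
              x$neuron_radius, x$ring_radius, x$decimate))
  cat(sprintf("  init %d frames, update every %d, buffer %d\n",
              x$init_frames, x$update_every, x$buffer_frames))
  cat(sprintf("  thresholds: L_min %.2f P_min %.1f theta_sp %.2f theta_SNR %.1f\n",
              x$min_corr, x$min_pnr, x$theta_sp, x$theta_snr))
  invisible(x)
}
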