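#' Results container for an extraction run
#'
#' Bundles spatial footprints, raw and denoised traces, deconvolved
#' activity, background parameters, per-frame motion shifts, component
#' birth frames, the configuration snapshot and the event log.
#'
#' @param A sparse nonnegative `d x N` footprint matrix (`dgCMatrix`).
#' @param C `N x T` denoised calcium traces.
#' @param S `N x T` deconvolved activity, `S >= 0`.
#' @param C_raw `N x T` traces before deconvolution (optional).
#' @param dims FOV dimensions `c(rows, cols)`.
#' @param background list describing the background model: either
#'   `list(type = "ring", W = <sparse d_b x d_b>, b_bar = <d>, decimate, ...)`
#'   or `list(type = "lowrank", b = <d x R>, f = <R x T>, model = <ring_cnn>)`.
#' @param shifts `T x 2` matrix of rigid shifts (dy, dx), or `NULL`.
#' @param birth_frame integer vector, frame at which each component was
#'   first incorporated.
#' @param config the `cnmfe_config` used.
#' @param log data frame of events (detections, rejections, updates).
#' @param frame_rate Hz.
#' @return object of class `cnmfe_bundle`.
#' @export
results_bundle <- function(A, C, S, dims, background = NULL, C_raw = NULL,
                           shifts = NULL, birth_frame = NULL, config = NULL,
                           log = NULL, frame_rate = NULL) {
  A <- as(as(A, "CsparseMatrix"), "generalMatrix")
  C <- as.matrix(C); S <- as.matrix(S)
  n <- ncol(A)
  if (nrow(C) != n || nrow(S) != n || ncol(C) != ncol(S))
    stop("A, C, S dimensions are inconsistent", call. = FALSE)
  if (nrow(A) != prod(dims))
    stop("A row count does not match prod(dims)", call. = FALSE)
  if (length(S) && min(S) < -1e-12)
    stop("S must be nonnegative", call. = FALSE)
  if (is.null(birth_frame)) birth_frame <- rep(1L, n)
  structure(list(A = A, C = C, S = S, C_raw = C_raw, dims = as.integer(dims),
                 background = background, shifts = shifts,
                 birth_frame = as.integer(birth_frame), config = config,
                 log = log, frame_rate = frame_rate),
            class = "cnmfe_bundle")
}

#' @export
print.cnmfe_bundle <- function(x, ...) {
  cat(sprintf("<cnmfe_bundle> %d components, %d x %d FOV, %d frames, %s background\n",
              ncol(x$A), x$dims[1], x$dims[2], ncol(x$C),
              x$background$type %||% "none"))
  invisible(x)
}

# full object paths (without the leading slash) of an HDF5 file
h5_object_names <- function(path) {
  info <- rhdf5::h5ls(path)
  full <- ifelse(info$group == "/", paste0("/", info$name),
                 paste(info$group, info$name, sep = "/"))
  sub("^/", "", full)
}

write_sparse_h5 <- function(M, path, group) {
  M <- as(as(M, "CsparseMatrix"), "generalMatrix")
  rhdf5::h5createGroup(path, group)
  rhdf5::h5write(dim(M), path, paste0(group, "/shape"))
  rhdf5::h5write(M@i, path, paste0(group, "/indices"))
  rhdf5::h5write(M@p, path, paste0(group, "/indptr"))
  rhdf5::h5write(M@x, path, paste0(group, "/data"))
}

read_sparse_h5 <- function(path, group) {
  shp <- as.integer(rhdf5::h5read(path, paste0(group, "/shape")))
  new("dgCMatrix",
      i = as.integer(rhdf5::h5read(path, paste0(group, "/indices"))),
      p = as.integer(rhdf5::h5read(path, paste0(group, "/indptr"))),
      x = as.numeric(rhdf5::h5read(path, paste0(group, "/data"))),
      Dim = shp)
}

#' Write / read an extraction results file
#'
#' Serializes a [results_bundle()] to an HDF5 container; sparse matrices
#' are stored in compressed-sparse-column triplet layout, the config as an
#' embedded YAML string. `read_results(write_results(x))` restores `x`
#' within floating-point representation.
#'
#' @param bundle a `cnmfe_bundle`.
#' @param path output `.h5` path.
#' @return `write_results` returns `path` invisibly; `read_results`
#'   returns the restored `cnmfe_bundle`.
#' @export
write_results <- function(bundle, path) {
  required <- c("A", "C", "S", "dims")
  for (f in required)
    if (is.null(bundle[[f]]))
      stop("bundle is missing required field '", f, "'", call. = FALSE)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  write_sparse_h5(bundle$A, path, "A")
  rhdf5::h5write(bundle$C, path, "C")
  rhdf5::h5write(bundle$S, path, "S")
  if (!is.null(bundle$C_raw)) rhdf5::h5write(bundle$C_raw, path, "C_raw")
  rhdf5::h5write(bundle$dims, path, "dims")
  rhdf5::h5write(bundle$birth_frame, path, "birth_frame")
  if (!is.null(bundle$shifts)) rhdf5::h5write(bundle$shifts, path, "shifts")
  if (!is.null(bundle$frame_rate))
    rhdf5::h5write(bundle$frame_rate, path, "frame_rate")
  bg <- bundle$background
  if (!is.null(bg)) {
    rhdf5::h5createGroup(path, "background")
    rhdf5::h5write(bg$type, path, "background/type")
    if (bg$type == "ring") {
      write_sparse_h5(bg$W, path, "background/W")
      rhdf5::h5write(bg$b_bar, path, "background/b_bar")
      rhdf5::h5write(bg$decimate %||% 1L, path, "background/decimate")
    } else if (bg$type == "lowrank") {
      rhdf5::h5write(bg$b, path, "background/b")
      rhdf5::h5write(bg$f, path, "background/f")
      if (!is.null(bg$model)) {
        rhdf5::h5createGroup(path, "background/model")
        rhdf5::h5write(bg$model$H, path, "background/model/H")
        rhdf5::h5write(bg$model$Wmap, path, "background/model/Wmap")
        rhdf5::h5write(bg$model$b_bar, path, "background/model/b_bar")
        rhdf5::h5write(c(bg$model$inner_radius, bg$model$width,
                         bg$model$quantile), path, "background/model/geom")
        rhdf5::h5write(bg$model$dims, path, "background/model/dims")
      }
    }
  }
  if (!is.null(bundle$config))
    rhdf5::h5write(yaml::as.yaml(unclass(bundle$config)), path, "config_yaml")
  if (!is.null(bundle$log) && nrow(bundle$log))
    rhdf5::h5write(as.character(jsonlite::toJSON(bundle$log,
                                                 digits = NA)),
                   path, "log_json")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path,
                               call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  nms <- h5_object_names(path)
  has <- function(nm) nm %in% nms
  A <- read_sparse_h5(path, "A")
  C <- as.matrix(rhdf5::h5read(path, "C"))
  S <- as.matrix(rhdf5::h5read(path, "S"))
  dims <- as.integer(rhdf5::h5read(path, "dims"))
  if (ncol(A) == 0) { C <- matrix(0, 0, ncol(C)); S <- matrix(0, 0, ncol(S)) }
  bg <- NULL
  if (has("background/type")) {
    type <- as.character(rhdf5::h5read(path, "background/type"))
    if (type == "ring") {
      bg <- list(type = "ring",
                 W = read_sparse_h5(path, "background/W"),
                 b_bar = as.numeric(rhdf5::h5read(path, "background/b_bar")),
                 decimate = as.integer(rhdf5::h5read(path,
                                                     "background/decimate")))
    } else {
      bg <- list(type = "lowrank",
                 b = as.matrix(rhdf5::h5read(path, "background/b")),
                 f = as.matrix(rhdf5::h5read(path, "background/f")))
      if (has("background/model/H")) {
        geom <- as.numeric(rhdf5::h5read(path, "background/model/geom"))
        bg$model <- ring_cnn_model(
          H = as.matrix(rhdf5::h5read(path, "background/model/H")),
          Wmap = as.matrix(rhdf5::h5read(path, "background/model/Wmap")),
          b_bar = as.numeric(rhdf5::h5read(path, "background/model/b_bar")),
          dims = as.integer(rhdf5::h5read(path, "background/model/dims")),
          inner_radius = geom[1], width = geom[2], quantile = geom[3])
      }
    }
  }
  cfg <- NULL
  if (has("config_yaml")) {
    lst <- yaml::yaml.load(as.character(rhdf5::h5read(path, "config_yaml")))
    cfg <- structure(lst, class = "cnmfe_config")
  }
  log <- NULL
  if (has("log_json"))
    log <- as.data.frame(jsonlite::fromJSON(
      as.character(rhdf5::h5read(path, "log_json"))))
  results_bundle(
    A = A, C = C, S = S,
    C_raw = if (has("C_raw")) as.matrix(rhdf5::h5read(path, "C_raw")),
    dims = dims, background = bg,
    shifts = if (has("shifts")) as.matrix(rhdf5::h5read(path, "shifts")),
    birth_frame = as.integer(rhdf5::h5read(path, "birth_frame")),
    config = cfg, log = log,
    frame_rate = if (has("frame_rate"))
      as.numeric(rhdf5::h5read(path, "frame_rate")))
}

#' Export traces as CSV / footprints as a labeled mask
#'
#' @param bundle a `cnmfe_bundle`.
#' @param path output file.
#' @param which `"C"`, `"S"` or `"C_raw"`.
#' @export
export_traces_csv <- function(bundle, path, which = c("C", "S", "C_raw")) {
  which <- match.arg(which)
  M <- bundle[[which]]
  df <- as.data.frame(t(M))
  names(df) <- paste0("comp", seq_len(nrow(M)))
  df <- cbind(frame = seq_len(ncol(M)), df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_traces_csv
#' @param threshold footprint pixels above `threshold * max` belong to the
#'   component; later components overwrite earlier ones where they overlap.
#' @export
export_label_mask <- function(bundle, path, threshold = 0.2) {
  dims <- bundle$dims
  lab <- matrix(0L, dims[1], dims[2])
  A <- as.matrix(bundle$A)
  for (n in seq_len(ncol(A))) {
    a <- A[, n]
    lab[a > threshold * max(a)] <- n
  }
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}
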