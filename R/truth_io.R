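# Ground-truth serialization alongside simulated movies (HDF5 "truth/*").

write_truth_h5 <- function(truth, path) {
  rhdf5::h5createGroup(path, "truth")
  write_sparse_h5(methods::as(truth$A, "CsparseMatrix"), path, "truth/A")
  rhdf5::h5write(truth$C, path, "truth/C")
  rhdf5::h5write(truth$S, path, "truth/S")
  rhdf5::h5write(truth$centers, path, "truth/centers")
  rhdf5::h5write(truth$baseline, path, "truth/baseline")
  rhdf5::h5write(truth$modes, path, "truth/modes")
  rhdf5::h5write(truth$mode_traces, path, "truth/mode_traces")
  rhdf5::h5write(truth$sigma, path, "truth/sigma")
  if (!is.null(truth$shifts)) rhdf5::h5write(truth$shifts, path,
                                             "truth/shifts")
  rhdf5::h5write(truth$gamma, path, "truth/gamma")
  rhdf5::h5write(truth$neuron_radius, path, "truth/neuron_radius")
  rhdf5::h5write(truth$dims, path, "truth/dims")
  invisible(path)
}

#' Read simulation ground truth stored in a movie file
#'
#' @param path an HDF5 movie written by [write_movie()] with a `truth`
#'   argument.
#' @return a `simulation_truth`.
#' @export
read_truth_h5 <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  nms <- h5_object_names(path)
  has <- function(nm) nm %in% nms
  if (!has("truth/C")) stop("no truth group in ", path, call. = FALSE)
  structure(list(
    A = read_sparse_h5(path, "truth/A"),
    C = as.matrix(rhdf5::h5read(path, "truth/C")),
    S = as.matrix(rhdf5::h5read(path, "truth/S")),
    centers = as.matrix(rhdf5::h5read(path, "truth/centers")),
    baseline = as.numeric(rhdf5::h5read(path, "truth/baseline")),
    modes = as.matrix(rhdf5::h5read(path, "truth/modes")),
    mode_traces = as.matrix(rhdf5::h5read(path, "truth/mode_traces")),
    sigma = as.numeric(rhdf5::h5read(path, "truth/sigma")),
    shifts = if (has("truth/shifts"))
      as.matrix(rhdf5::h5read(path, "truth/shifts")),
    gamma = as.numeric(rhdf5::h5read(path, "truth/gamma")),
    neuron_radius = as.numeric(rhdf5::h5read(path, "truth/neuron_radius")),
    dims = as.integer(rhdf5::h5read(path, "truth/dims"))),
    class = "simulation_truth")
}
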