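#' Read a movie of fluorescence frames
#'
#' Reads a multi-page TIFF or an HDF5 dataset into a `rows x cols x T`
#' array with attribute `frame_rate`. HDF5 files follow the C-order
#' `(frames, rows, cols)` layout commonly written by acquisition software;
#' TIFF pages are frames in acquisition order. Integer TIFF data are
#' returned as raw digital numbers.
#'
#' @param path path to a `.tif`/`.tiff` or `.h5`/`.hdf5` file.
#' @param format `"auto"` (by extension), `"tiff"` or `"hdf5"`.
#' @param frames optional integer vector of 1-based frame indices to load
#'   (e.g. `1:100`); `integer(0)` yields an empty movie whose spatial
#'   dimensions are preserved.
#' @param dataset HDF5 dataset name (default `"movie"`).
#' @param frame_rate acquisition rate in Hz attached as an attribute.
#' @param offset constant camera offset subtracted after reading.
#' @return numeric array `rows x cols x T`, class `cnmfe_movie`.
#' @export
read_movie <- function(path, format = c("auto", "tiff", "hdf5"),
                       frames = NULL, dataset = "movie", frame_rate = NULL,
                       offset = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("movie file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5"
              else "tiff"
  if (!is.null(frames)) {
    frames <- as.integer(frames)
    if (any(frames < 1L)) stop("frame indices must be >= 1", call. = FALSE)
    if (is.unsorted(frames, strictly = FALSE) && any(diff(frames) < 0))
      stop("frame indices must be non-decreasing", call. = FALSE)
  }
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.null(frames)) pages <- pages[frames]
    shp <- if (length(pages)) dim(pages[[1]])
           else dim(tiff::readTIFF(path, as.is = TRUE))
    if (length(pages)) {
      shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
      if (length(unique(shapes)) > 1L)
        stop("inconsistent frame shapes in TIFF: ",
             paste(unique(shapes), collapse = ", "), call. = FALSE)
    }
    mov <- array(unlist(pages, use.names = FALSE),
                 dim = c(shp[1], shp[2], length(pages)))
  } else {
    fid_dims <- h5_movie_dims(path, dataset)
    n_frames <- fid_dims[1]
    rows <- fid_dims[2]; cols <- fid_dims[3]
    sel <- frames %||% seq_len(n_frames)
    if (length(sel)) {
      # file layout (frames, rows, cols) C-order appears reversed in R
      raw <- rhdf5::h5read(path, dataset,
                           index = list(NULL, NULL, sel))
      mov <- aperm(raw, c(2, 1, 3))
    } else {
      mov <- array(0, dim = c(rows, cols, 0))
    }
  }
  mov <- mov - offset
  if (any(!is.finite(mov))) stop("movie contains non-finite values",
                                 call. = FALSE)
  as_movie(mov, frame_rate)
}

h5_movie_dims <- function(path, dataset) {
  info <- rhdf5::h5ls(path)
  row <- info[info$name == dataset & info$otype == "H5I_DATASET", ]
  if (nrow(row) == 0)
    stop("HDF5 dataset '", dataset, "' not found in ", path, call. = FALSE)
  d <- rev(as.integer(strsplit(row$dim[1], " x ")[[1]]))
  if (length(d) != 3L)
    stop("HDF5 dataset must be 3-dimensional (frames x rows x cols)",
         call. = FALSE)
  d  # (frames, rows, cols) in C order
}

#' Write a movie to TIFF or HDF5
#'
#' The HDF5 writer stores lossless double precision in C-order
#' `(frames, rows, cols)`, interoperable with h5py/tifffile conventions.
#' The TIFF writer stores nonnegative integer-valued data exactly as
#' 16-bit pages; non-integer data are linearly scaled into the 16-bit
#' range (lossy), so HDF5 is preferred for float movies.
#'
#' @param movie array `rows x cols x T`.
#' @param path output path ending in `.tif(f)` or `.h5`/`.hdf5`.
#' @param dataset HDF5 dataset name.
#' @param truth optional `simulation_truth` object saved alongside under
#'   `truth/*` (HDF5 only).
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, dataset = "movie", truth = NULL) {
  stopifnot(length(dim(movie)) == 3L)
  if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(aperm(movie, c(2, 1, 3)), path, dataset)
    fr <- attr(movie, "frame_rate")
    if (!is.null(fr)) rhdf5::h5write(fr, path, "frame_rate")
    if (!is.null(truth)) write_truth_h5(truth, path)
    rhdf5::h5closeAll()
  } else {
    vals <- as.numeric(movie)
    if (any(vals < 0)) stop("TIFF writer requires nonnegative values",
                            call. = FALSE)
    integral <- all(vals == round(vals)) && max(vals) <= 65535
    sc <- if (integral) 65535 else max(vals, 1e-12)
    pages <- lapply(seq_len(dim(movie)[3]),
                    function(t) movie[, , t] / sc)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  }
  invisible(path)
}

as_movie <- function(mov, frame_rate = NULL) {
  if (!is.null(frame_rate)) attr(mov, "frame_rate") <- frame_rate
  class(mov) <- c("cnmfe_movie", class(array(0, c(1, 1, 1))))
  mov
}
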