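#' CBCT voxel volume
#'
#' The common container for an axial CBCT image stack: an 8-bit intensity
#' grid indexed `[slice z, row y, col x]` plus its physical sampling.  The
#' segmentation chain assumes isotropic in-plane sampling (one
#' `pixel_size_mm` for rows and columns) and a constant axial spacing
#' `slice_spacing_mm`; the clinical acquisition this models uses 0.3 mm
#' isotropic voxels, which is also the default for both fields.
#'
#' @param intensities 3D integer array, dims `(n_slices, n_rows, n_cols)`,
#'   values in 0--255.  A matrix is promoted to a single-slice volume.
#' @param pixel_size_mm positive in-plane pixel edge length (mm).
#' @param slice_spacing_mm positive axial distance between slices (mm).
#' @return An object of class `voxel_volume`: a list with fields
#'   `intensities`, `pixel_size_mm`, `slice_spacing_mm`.
#' @examples
#' v <- voxel_volume(array(0L, c(2, 4, 4)))
#' dim(v$intensities)
#' @export
voxel_volume <- function(intensities, pixel_size_mm = 0.3,
                         slice_spacing_mm = 0.3) {
  if (is.matrix(intensities)) {
    intensities <- array(intensities, c(1L, dim(intensities)))
  }
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    dr_stop("`intensities` must be a 3D array (z, y, x)",
            "dynroot_input_error")
  d <- dim(intensities)
  if (d[1] < 1L || d[2] < 3L || d[3] < 3L)
    dr_stop("volume needs >= 1 slice of at least 3x3 pixels",
            "dynroot_input_error")
  if (anyNA(intensities))
    dr_stop("volume intensities contain NA", "dynroot_input_error")
  if (min(intensities) < 0 || max(intensities) > 255)
    dr_stop("intensities must lie in [0, 255] (8-bit contract)",
            "dynroot_input_error")
  if (any(intensities != as.integer(intensities)))
    dr_stop("intensities must be integral", "dynroot_input_error")
  if (!is.numeric(pixel_size_mm) || length(pixel_size_mm) != 1L ||
      !is.finite(pixel_size_mm) || pixel_size_mm <= 0)
    dr_stop("`pixel_size_mm` must be a positive number",
            "dynroot_input_error")
  if (!is.numeric(slice_spacing_mm) || length(slice_spacing_mm) != 1L ||
      !is.finite(slice_spacing_mm) || slice_spacing_mm <= 0)
    dr_stop("`slice_spacing_mm` must be a positive number",
            "dynroot_input_error")
  storage.mode(intensities) <- "integer"
  structure(list(intensities = intensities,
                 pixel_size_mm = as.numeric(pixel_size_mm),
                 slice_spacing_mm = as.numeric(slice_spacing_mm)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("voxel_volume: %d slice(s) of %d x %d px, %.4g mm/px, %.4g mm between slices\n",
              d[1], d[2], d[3], x$pixel_size_mm, x$slice_spacing_mm))
  cat(sprintf("  intensity range %d..%d\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$intensities)

# ---- portable raw-volume fixture format ------------------------------------
#
# Byte layout (documented contract, used by tests and the CLI):
#   * one ASCII header line terminated by LF (0x0A):
#       "DYNROOTVOL 1 <n_slices> <n_rows> <n_cols> <pixel_size_mm> <slice_spacing_mm>"
#     fields separated by single spaces, spacings printed with up to 17
#     significant digits so the round trip is exact;
#   * exactly n_slices * n_rows * n_cols payload bytes, one unsigned byte
#     per voxel, slice-major then row-major (column index fastest).

#' Write a volume in the portable raw fixture format
#'
#' A deliberately trivial single-file format (one ASCII header line plus a
#' raw 8-bit payload) used for test fixtures, label volumes and phantom
#' exchange.  `read_volume(write_volume(v, path))` is the identity on all
#' fields.  See the package vignette for the exact byte layout.
#'
#' @param volume a [voxel_volume()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  d <- dim(volume$intensities)
  header <- sprintf("DYNROOTVOL 1 %d %d %d %s %s\n", d[1], d[2], d[3],
                    format(volume$pixel_size_mm, digits = 17),
                    format(volume$slice_spacing_mm, digits = 17))
  # payload: slice-major, row-major within a slice (x fastest)
  payload <- as.raw(as.vector(aperm(volume$intensities, c(3L, 2L, 1L))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(payload, con)
  invisible(path)
}

#' Read a volume from the portable raw fixture format
#'
#' @param path file written by [write_volume()].
#' @return a [voxel_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    dr_stop(sprintf("no such file: %s", path), "dynroot_input_error")
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  nl <- which(bytes == as.raw(0x0A))[1]
  if (is.na(nl))
    dr_stop("corrupt fixture: no header line", "dynroot_corrupt_file_error")
  header <- strsplit(rawToChar(bytes[seq_len(nl - 1L)]), " ", fixed = TRUE)[[1]]
  if (length(header) != 7L || header[1] != "DYNROOTVOL" || header[2] != "1")
    dr_stop("corrupt fixture: bad header", "dynroot_corrupt_file_error")
  d <- as.integer(header[3:5])
  sp <- as.numeric(header[6:7])
  if (anyNA(d) || anyNA(sp))
    dr_stop("corrupt fixture: unparseable header fields",
            "dynroot_corrupt_file_error")
  payload <- bytes[-seq_len(nl)]
  if (length(payload) != prod(d))
    dr_stop(sprintf(
      "corrupt fixture: payload has %d bytes, header promises %d",
      length(payload), prod(d)), "dynroot_corrupt_file_error")
  arr <- aperm(array(as.integer(payload), dim = rev(d)), c(3L, 2L, 1L))
  voxel_volume(arr, pixel_size_mm = sp[1], slice_spacing_mm = sp[2])
}
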