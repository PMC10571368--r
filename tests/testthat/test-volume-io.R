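# voxel_volume container and the raw fixture format

test_that("voxel_volume enforces the 8-bit and geometry contract", {
  expect_s3_class(voxel_volume(array(0L, c(1, 3, 3))), "voxel_volume")
  expect_error(voxel_volume(array(-1L, c(1, 3, 3))), class = "dynroot_input_error")
  expect_error(voxel_volume(array(256L, c(1, 3, 3))), class = "dynroot_input_error")
  expect_error(voxel_volume(array(0L, c(1, 2, 3))), class = "dynroot_input_error")
  expect_error(voxel_volume(array(0L, c(1, 3, 3)), pixel_size_mm = 0),
               class = "dynroot_input_error")
  expect_error(voxel_volume(array(0.5, c(1, 3, 3))), class = "dynroot_input_error")
  # matrix promotes to a single-slice volume
  expect_equal(dim(voxel_volume(matrix(7L, 4, 5))), c(1L, 4L, 5L))
})

test_that("fixture write/read round-trips bit-exactly on random phantoms", {
  set.seed(11)
  for (i in 1:100) {
    v <- random_volume()
    path <- tempfile(fileext = ".rvol")
    write_volume(v, path)
    expect_identical(read_volume(path), v)
    unlink(path)
  }
})

test_that("fixture payload layout is header + one byte per voxel", {
  v <- voxel_volume(array(0L, c(1, 3, 3)))
  path <- tempfile(fileext = ".rvol")
  write_volume(v, path)
  bytes <- readBin(path, "raw", file.info(path)$size)
  nl <- which(bytes == as.raw(0x0A))[1]
  expect_equal(length(bytes) - nl, 9)          # 1*3*3 payload bytes
  # payload is x-fastest: flip one voxel and check its byte offset
  v2 <- voxel_volume(array(c(rep(0L, 8), 5L), c(1, 3, 3))[, , , drop = FALSE])
  v2$intensities[1, 1, 2] <- 9L                # row 1, col 2 -> 2nd payload byte
  write_volume(v2, path)
  bytes <- readBin(path, "raw", file.info(path)$size)
  expect_equal(as.integer(bytes[nl + 2]), 9L)
})

test_that("truncated or corrupted fixtures are rejected", {
  v <- random_volume()
  path <- tempfile(fileext = ".rvol")
  write_volume(v, path)
  bytes <- readBin(path, "raw", file.info(path)$size)
  writeBin(bytes[-length(bytes)], path)        # drop last payload byte
  expect_error(read_volume(path), class = "dynroot_corrupt_file_error")
  writeBin(charToRaw("not a volume\nxxxx"), path)
  expect_error(read_volume(path), class = "dynroot_corrupt_file_error")
})

# DICOM series reader/writer

test_that("an 8-bit DICOM series round-trips through write + read", {
  ph <- generate_phantom(phantom_spec(root_height_slices = 3L,
                                      crown_height_slices = 2L,
                                      cross_section_px = 4L))
  dir <- tempfile()
  write_dicom_series(ph$volume, dir)
  v <- read_dicom_series(dir)
  expect_identical(v$intensities, ph$volume$intensities)
  expect_equal(v$pixel_size_mm, 0.3)
  expect_equal(v$slice_spacing_mm, 0.3)
  unlink(dir, recursive = TRUE)
})

test_that("slice order comes from spatial position, not filename", {
  set.seed(21)
  v <- random_volume()
  while (dim(v)[1] < 3) v <- random_volume()
  dir <- tempfile()
  write_dicom_series(v, dir)
  # shuffle the filenames; positions inside the files are untouched
  files <- list.files(dir, full.names = TRUE)
  shuffled <- file.path(dir, sprintf("scrambled_%s.dcm",
                                     sample(letters, length(files))))
  file.rename(files, shuffled)
  expect_identical(read_dicom_series(dir)$intensities, v$intensities)
  unlink(dir, recursive = TRUE)
})

test_that("16-bit volumes are min-max rescaled to 0-255, max mapping to 255", {
  v <- voxel_volume(array(c(0L, 64L, 128L, 255L, rep(10L, 14)), c(2, 3, 3)))
  dir <- tempfile()
  write_dicom_series(v, dir, bits = 16L)       # stored upscaled by 16
  got <- read_dicom_series(dir)$intensities
  # oracle: voxelwise scalar min-max map of the stored 16-bit values
  stored <- v$intensities * 16L
  lo <- min(stored); hi <- max(stored)
  want <- array(as.integer(floor((stored - lo) / (hi - lo) * 255 + 0.5)),
                dim(stored))
  expect_identical(got, want)
  expect_equal(max(got), 255L)
  unlink(dir, recursive = TRUE)
})

test_that("empty directories and mixed series are input errors", {
  dir <- tempfile(); dir.create(dir)
  expect_error(read_dicom_series(dir), class = "dynroot_input_error")
  v <- voxel_volume(array(5L, c(1, 3, 3)))
  write_dicom_series(v, dir, series_uid = "1.2.3.1")
  file.rename(file.path(dir, "slice_001.dcm"), file.path(dir, "a.dcm"))
  write_dicom_series(v, dir, series_uid = "1.2.3.2")
  expect_error(read_dicom_series(dir), class = "dynroot_input_error")
  unlink(dir, recursive = TRUE)
})

test_that("missing spacing metadata falls back to 0.3 mm with a warning", {
  v <- voxel_volume(array(5L, c(2, 3, 3)), pixel_size_mm = 0.5,
                    slice_spacing_mm = 0.5)
  dir <- tempfile()
  write_dicom_series(v, dir, omit_spacing = TRUE)
  expect_warning(got <- read_dicom_series(dir),
                 class = "dynroot_spacing_warning")
  expect_equal(got$pixel_size_mm, 0.3)
  unlink(dir, recursive = TRUE)
})

test_that("the reader parses DICOM files written by an independent library", {
  # pydicom writes the series; only the reader under test touches it
  dir <- tempfile(); dir.create(dir)
  script <- sprintf('
import numpy as np
import pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, SecondaryCaptureImageStorage, generate_uid
series = generate_uid()
rng = np.random.default_rng(7)
vol = rng.integers(0, 256, size=(4, 5, 6), dtype=np.uint8)
np.save(%s, vol)
for z in range(4):
    meta = FileMetaDataset()
    meta.MediaStorageSOPClassUID = SecondaryCaptureImageStorage
    meta.MediaStorageSOPInstanceUID = generate_uid()
    meta.TransferSyntaxUID = ExplicitVRLittleEndian
    ds = Dataset()
    ds.file_meta = meta
    ds.SOPClassUID = SecondaryCaptureImageStorage
    ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID
    ds.SeriesInstanceUID = series
    ds.InstanceNumber = z + 1
    ds.ImagePositionPatient = [0, 0, z * 0.3]
    ds.PixelSpacing = [0.3, 0.3]
    ds.SliceThickness = 0.3
    ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    ds.Rows, ds.Columns = 5, 6
    ds.BitsAllocated, ds.BitsStored, ds.HighBit = 8, 8, 7
    ds.PixelRepresentation = 0
    ds.PixelData = vol[z].tobytes()
    pydicom.dcmwrite(f"%s/s{z}.dcm", ds, enforce_file_format=True)
', shQuote(file.path(dir, "vol.npy")), dir)
  status <- system2("python", "-", input = script, stdout = FALSE,
                    stderr = FALSE)
  expect_equal(status, 0L)
  got <- read_dicom_series(dir)
  # recover the generated array for comparison via numpy's plain text dump
  script2 <- sprintf(
    'import numpy as np; v = np.load(%s); print("\\n".join(" ".join(map(str, s.ravel())) for s in v))',
    shQuote(file.path(dir, "vol.npy")))
  txt <- system2("python", "-", input = script2, stdout = TRUE)
  want <- array(0L, c(4, 5, 6))
  for (z in 1:4)
    want[z, , ] <- matrix(as.integer(strsplit(txt[z], " ")[[1]]),
                          nrow = 5, byrow = TRUE)
  expect_identical(got$intensities, want)
  expect_equal(got$pixel_size_mm, 0.3)
  unlink(dir, recursive = TRUE)
})
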