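# Minimal DICOM support: single-frame grayscale images, one series per
# directory, uncompressed explicit- or implicit-VR little endian.  This is
# all the CBCT export path needs; multi-frame/enhanced objects and
# compressed transfer syntaxes are out of scope.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
SOP_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"

LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# ---- low-level element encoding (explicit VR little endian) ----------------

dcm_uint <- function(x, size) {
  writeBin(as.integer(x), raw(), size = size, endian = "little")
}

dcm_pad <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

dcm_element <- function(group, element, vr, value) {
  bytes <- switch(vr,
    US = dcm_uint(value, 2L),
    UL = dcm_uint(value, 4L),
    OB = ,
    OW = value,                    # already raw
    # string VRs; UI pads with NUL, the rest with space
    {
      b <- charToRaw(paste(value, collapse = "\\"))
      dcm_pad(b, if (vr == "UI") as.raw(0x00) else as.raw(0x20))
    })
  if (vr %in% c("OB", "OW")) bytes <- dcm_pad(bytes, as.raw(0x00))
  head_ <- c(dcm_uint(group, 2L), dcm_uint(element, 2L), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(head_, as.raw(c(0, 0)), dcm_uint(length(bytes), 4L), bytes)
  } else {
    c(head_, dcm_uint(length(bytes), 2L), bytes)
  }
}

dcm_uid <- function(...) {
  # deterministic study-local UIDs under a test root
  paste("1.2.826.0.1.3680043.9999", ..., sep = ".")
}

#' Write a volume as a single-frame DICOM series
#'
#' Emits one explicit-VR little-endian grayscale file per axial slice
#' (`slice_###.dcm`), with `PixelSpacing`, `SpacingBetweenSlices`,
#' `SliceThickness`, `ImagePositionPatient` and a common
#' `SeriesInstanceUID`.  Intended for phantoms and fixtures, to exercise
#' [read_dicom_series()]; not a clinical exporter.
#'
#' @param volume a [voxel_volume()].
#' @param dir output directory (created if needed).
#' @param bits 8 or 16; at 16 the 8-bit intensities are stored upscaled by
#'   16 (so the reader's min--max rescale is exercised).
#' @param series_uid optional series UID override.
#' @param omit_spacing if `TRUE`, spacing tags are left out (tests the
#'   reader's 0.3 mm fallback).
#' @return the directory path, invisibly.
#' @export
write_dicom_series <- function(volume, dir, bits = 8L, series_uid = NULL,
                               omit_spacing = FALSE) {
  stopifnot(inherits(volume, "voxel_volume"), bits %in% c(8L, 16L))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(volume$intensities)
  if (is.null(series_uid)) series_uid <- dcm_uid("1", "1")
  for (z in seq_len(d[1])) {
    slice <- volume$intensities[z, , , drop = TRUE]
    if (bits == 8L) {
      pix <- as.raw(as.vector(t(slice)))        # row-major
      vr <- "OB"
    } else {
      pix <- writeBin(as.integer(t(slice)) * 16L, raw(), size = 2L,
                      endian = "little")
      vr <- "OW"
    }
    sop_uid <- dcm_uid("1", "2", z)
    meta <- c(
      dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      dcm_element(0x0002, 0x0002, "UI", SOP_SECONDARY_CAPTURE),
      dcm_element(0x0002, 0x0003, "UI", sop_uid),
      dcm_element(0x0002, 0x0010, "UI", TS_EXPLICIT_LE),
      dcm_element(0x0002, 0x0012, "UI", dcm_uid("0", "1"))
    )
    ds <- c(
      dcm_element(0x0008, 0x0016, "UI", SOP_SECONDARY_CAPTURE),
      dcm_element(0x0008, 0x0018, "UI", sop_uid),
      dcm_element(0x0008, 0x0060, "CS", "CT"),
      if (!omit_spacing)
        dcm_element(0x0018, 0x0050, "DS",
                    format(volume$slice_spacing_mm, digits = 10)),
      if (!omit_spacing)
        dcm_element(0x0018, 0x0088, "DS",
                    format(volume$slice_spacing_mm, digits = 10)),
      dcm_element(0x0020, 0x000E, "UI", series_uid),
      dcm_element(0x0020, 0x0013, "IS", as.character(z)),
      if (!omit_spacing)
        dcm_element(0x0020, 0x0032, "DS",
                    c("0", "0", format((z - 1) * volume$slice_spacing_mm,
                                       digits = 10))),
      dcm_element(0x0028, 0x0002, "US", 1L),
      dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_element(0x0028, 0x0010, "US", d[2]),
      dcm_element(0x0028, 0x0011, "US", d[3]),
      if (!omit_spacing)
        dcm_element(0x0028, 0x0030, "DS",
                    rep(format(volume$pixel_size_mm, digits = 10), 2L)),
      dcm_element(0x0028, 0x0100, "US", bits),
      dcm_element(0x0028, 0x0101, "US", if (bits == 8L) 8L else 12L),
      dcm_element(0x0028, 0x0102, "US", if (bits == 8L) 7L else 11L),
      dcm_element(0x0028, 0x0103, "US", 0L),
      dcm_element(0x7FE0, 0x0010, vr, pix)
    )
    meta <- c(dcm_element(0x0002, 0x0000, "UL", length(meta)), meta)
    con <- file(file.path(dir, sprintf("slice_%03d.dcm", z)), "wb")
    writeBin(c(raw(128L), charToRaw("DICM"), meta, ds), con)
    close(con)
  }
  invisible(dir)
}

# ---- parsing ---------------------------------------------------------------

dcm_read_uint <- function(bytes, pos, size) {
  v <- 0
  for (i in seq_len(size) - 1L) v <- v + as.integer(bytes[pos + i]) * 256^i
  v
}

# parse one data element; returns list(tag, vr, value_raw, next_pos)
dcm_read_element <- function(bytes, pos, explicit) {
  group <- dcm_read_uint(bytes, pos, 2L)
  element <- dcm_read_uint(bytes, pos + 2L, 2L)
  if (explicit) {
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% LONG_VRS) {
      len <- dcm_read_uint(bytes, pos + 8L, 4L)
      data_pos <- pos + 12L
    } else {
      len <- dcm_read_uint(bytes, pos + 6L, 2L)
      data_pos <- pos + 8L
    }
  } else {
    vr <- NA_character_
    len <- dcm_read_uint(bytes, pos + 4L, 4L)
    data_pos <- pos + 8L
  }
  if (len == 4294967295) # undefined length (sequences): unsupported here
    dr_stop("undefined-length DICOM elements are not supported",
            "dynroot_unsupported_format_error")
  value <- if (len > 0L) bytes[data_pos:(data_pos + len - 1L)] else raw(0)
  list(group = group, element = element, vr = vr, value = value,
       next_pos = data_pos + len)
}

dcm_tag_key <- function(group, element) sprintf("%04X,%04X", group, element)

dcm_str <- function(raw_value) {
  # drop trailing space/NUL padding before decoding
  while (length(raw_value) > 0L &&
         raw_value[length(raw_value)] %in% as.raw(c(0x00, 0x20)))
    raw_value <- raw_value[-length(raw_value)]
  if (length(raw_value) == 0L) return("")
  rawToChar(raw_value)
}

dcm_numbers <- function(raw_value) {
  as.numeric(strsplit(dcm_str(raw_value), "\\", fixed = TRUE)[[1]])
}

# parse one file into a tag -> raw value map
dcm_parse_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140L ||
      rawToChar(bytes[129:132]) != "DICM")
    dr_stop(sprintf("not a DICOM part-10 file: %s", path),
            "dynroot_unsupported_format_error")
  # file meta group is always explicit VR
  el <- dcm_read_element(bytes, 133L, explicit = TRUE)
  if (el$group != 2L || el$element != 0L)
    dr_stop(sprintf("missing file meta group length: %s", path),
            "dynroot_unsupported_format_error")
  meta_len <- dcm_read_uint(el$value, 1L, 4L)
  pos <- el$next_pos
  meta_end <- pos + meta_len
  tags <- list()
  while (pos < meta_end) {
    el <- dcm_read_element(bytes, pos, explicit = TRUE)
    tags[[dcm_tag_key(el$group, el$element)]] <- el$value
    pos <- el$next_pos
  }
  ts <- dcm_str(tags[["0002,0010"]])
  explicit <- if (identical(ts, TS_IMPLICIT_LE)) FALSE
              else if (identical(ts, TS_EXPLICIT_LE) || ts == "") TRUE
              else dr_stop(sprintf("unsupported transfer syntax %s", ts),
                           "dynroot_unsupported_format_error")
  n <- length(bytes)
  while (pos < n) {
    el <- dcm_read_element(bytes, pos, explicit = explicit)
    tags[[dcm_tag_key(el$group, el$element)]] <- el$value
    pos <- el$next_pos
  }
  tags
}

dcm_slice_matrix <- function(tags, path) {
  rows <- dcm_read_uint(tags[["0028,0010"]], 1L, 2L)
  cols <- dcm_read_uint(tags[["0028,0011"]], 1L, 2L)
  bits <- dcm_read_uint(tags[["0028,0100"]], 1L, 2L)
  spp <- if (!is.null(tags[["0028,0002"]]))
    dcm_read_uint(tags[["0028,0002"]], 1L, 2L) else 1L
  photo <- if (!is.null(tags[["0028,0004"]]))
    dcm_str(tags[["0028,0004"]]) else "MONOCHROME2"
  signed <- !is.null(tags[["0028,0103"]]) &&
    dcm_read_uint(tags[["0028,0103"]], 1L, 2L) == 1L
  if (spp != 1L || !photo %in% c("MONOCHROME1", "MONOCHROME2"))
    dr_stop(sprintf("non-grayscale DICOM image: %s", path),
            "dynroot_unsupported_format_error")
  pix <- tags[["7FE0,0010"]]
  if (is.null(pix))
    dr_stop(sprintf("no pixel data: %s", path),
            "dynroot_unsupported_format_error")
  vals <- if (bits <= 8L) {
    as.integer(pix[seq_len(rows * cols)])
  } else {
    readBin(pix, "integer", n = rows * cols, size = 2L,
            endian = "little", signed = signed)
  }
  list(mat = matrix(vals, nrow = rows, byrow = TRUE), bits = bits)
}

dcm_slice_position <- function(tags) {
  if (!is.null(tags[["0020,0032"]])) {
    p <- dcm_numbers(tags[["0020,0032"]])
    if (length(p) >= 3L && !anyNA(p)) return(p[3])
  }
  if (!is.null(tags[["0020,1041"]])) {
    p <- dcm_numbers(tags[["0020,1041"]])
    if (length(p) >= 1L && !is.na(p[1])) return(p[1])
  }
  if (!is.null(tags[["0020,0013"]])) {
    p <- dcm_numbers(tags[["0020,0013"]])
    if (length(p) >= 1L && !is.na(p[1])) return(p[1])
  }
  NA_real_
}

#' Read a single-frame grayscale DICOM series into a voxel volume
#'
#' Reads every `*.dcm` file (falling back to all files) in `directory`,
#' checks that they belong to one series, sorts slices by spatial position
#' along the scan axis (`ImagePositionPatient` z, then `SliceLocation`,
#' then `InstanceNumber`) -- never by filename -- and stacks them into a
#' [voxel_volume()].  Volumes stored at more than 8 bits are min--max
#' rescaled to 0--255 with round-half-up.  Missing spacing metadata falls
#' back to 0.3 mm with a warning, the acquisition geometry this method was
#' developed for.
#'
#' @param directory path containing one DICOM series.
#' @return a [voxel_volume()].
#' @export
read_dicom_series <- function(directory) {
  if (!dir.exists(directory))
    dr_stop(sprintf("no such directory: %s", directory),
            "dynroot_input_error")
  files <- list.files(directory, pattern = "\\.dcm$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L)
    files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    dr_stop(sprintf("no DICOM files in %s", directory),
            "dynroot_input_error")
  parsed <- lapply(files, dcm_parse_file)

  series <- vapply(parsed, function(t) dcm_str(t[["0020,000E"]]), "")
  if (length(unique(series[series != ""])) > 1L)
    dr_stop("directory mixes more than one SeriesInstanceUID",
            "dynroot_input_error")

  pos <- vapply(parsed, dcm_slice_position, 0)
  ord <- order(pos, seq_along(parsed))   # stable for missing/tied positions
  parsed <- parsed[ord]
  files <- files[ord]
  pos <- pos[ord]

  slices <- mapply(dcm_slice_matrix, parsed, files, SIMPLIFY = FALSE)
  dims <- vapply(slices, function(s) dim(s$mat), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    dr_stop("slices disagree on Rows/Columns", "dynroot_input_error")
  bits <- max(vapply(slices, function(s) s$bits, 0))

  arr <- array(0L, c(length(slices), dims[1, 1], dims[2, 1]))
  for (z in seq_along(slices)) arr[z, , ] <- slices[[z]]$mat
  if (bits > 8L || max(arr) > 255L) {
    lo <- min(arr); hi <- max(arr)
    arr <- if (hi == lo) array(0L, dim(arr))
           else array(as.integer(round_half_up((arr - lo) / (hi - lo) * 255)),
                      dim(arr))
  }

  px <- NULL
  for (t in parsed) {
    if (!is.null(t[["0028,0030"]])) { px <- dcm_numbers(t[["0028,0030"]])[1]; break }
  }
  if (is.null(px) || is.na(px)) {
    dr_warn("PixelSpacing absent; assuming 0.3 mm", "dynroot_spacing_warning")
    px <- 0.3
  }
  sp <- NULL
  for (key in c("0018,0088", "0018,0050")) {
    for (t in parsed) {
      if (!is.null(t[[key]])) { sp <- dcm_numbers(t[[key]])[1]; break }
    }
    if (!is.null(sp) && !is.na(sp)) break
  }
  if ((is.null(sp) || is.na(sp)) && length(slices) > 1L && !anyNA(pos)) {
    dpos <- diff(pos)
    if (all(dpos > 0)) sp <- stats::median(dpos)
  }
  if (is.null(sp) || is.na(sp)) {
    dr_warn("slice spacing absent; assuming 0.3 mm", "dynroot_spacing_warning")
    sp <- 0.3
  }
  voxel_volume(arr, pixel_size_mm = px, slice_spacing_mm = sp)
}
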