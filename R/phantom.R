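# Synthetic CBCT-like tooth phantoms with analytic ground truth.  The
# phantoms emulate the one feature the dynamic threshold relies on: a
# bimodal surface-intensity structure, cementum-like (root, darker) vs.
# enamel-like (crown, brighter), with the root/crown boundary being a
# pure intensity change with no geometric marking (like the CEJ).

#' Specification of a synthetic tooth phantom
#'
#' Defaults describe a plausible isolated tooth at 0.3 mm isotropic
#' sampling: a root prism 12 px across and 20 slices long (~3.6 mm x
#' 6 mm) under a wider crown prism (root + 4 px) of 8 slices, root mode
#' at intensity 90, crown mode at 190, air at 10, noise-free.  The two
#' intensity means must be separated by at least 4 noise SDs so the
#' phantom is solvable by construction.
#'
#' @param shape `"two_part_tooth"` (root prism below a wider crown
#'   prism), `"square_prism"` (root only), or `"cylinder"` (digitized
#'   disc cross-section, root only; `cross_section_px` is the diameter).
#' @param root_height_slices,crown_height_slices axial extents; the crown
#'   height is ignored (0) for the root-only shapes.
#' @param cross_section_px root cross-section side (or cylinder diameter).
#' @param crown_cross_section_px crown prism side, default root + 4.
#' @param root_mean_intensity,crown_mean_intensity,air_mean_intensity
#'   region intensity means (0--255), root < crown.
#' @param noise_sd Gaussian intensity noise SD; draws are rounded and
#'   clipped to 0--255 (the 8-bit contract).
#' @param seed integer seed; generation is deterministic given the spec.
#' @param pixel_size_mm,slice_spacing_mm physical sampling.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c("two_part_tooth", "square_prism", "cylinder"),
                         root_height_slices = 20L,
                         crown_height_slices = 8L,
                         cross_section_px = 12L,
                         crown_cross_section_px = cross_section_px + 4L,
                         root_mean_intensity = 90L,
                         crown_mean_intensity = 190L,
                         air_mean_intensity = 10L,
                         noise_sd = 0,
                         seed = 1L,
                         pixel_size_mm = 0.3,
                         slice_spacing_mm = 0.3) {
  shape <- match.arg(shape)
  if (shape != "two_part_tooth") crown_height_slices <- 0L
  spec <- list(shape = shape,
               root_height_slices = as.integer(root_height_slices),
               crown_height_slices = as.integer(crown_height_slices),
               cross_section_px = as.integer(cross_section_px),
               crown_cross_section_px = as.integer(crown_cross_section_px),
               root_mean_intensity = as.integer(root_mean_intensity),
               crown_mean_intensity = as.integer(crown_mean_intensity),
               air_mean_intensity = as.integer(air_mean_intensity),
               noise_sd = as.numeric(noise_sd),
               seed = as.integer(seed),
               pixel_size_mm = as.numeric(pixel_size_mm),
               slice_spacing_mm = as.numeric(slice_spacing_mm))
  if (spec$root_height_slices < 1L || spec$cross_section_px < 2L)
    dr_stop("root must be at least 2 px across and 1 slice tall",
            "dynroot_spec_error")
  if (shape == "two_part_tooth" &&
      (spec$crown_height_slices < 1L ||
       spec$crown_cross_section_px < spec$cross_section_px))
    dr_stop("crown must be at least 1 slice tall and no narrower than the root",
            "dynroot_spec_error")
  if (spec$root_mean_intensity >= spec$crown_mean_intensity)
    dr_stop("root mode must be darker than crown mode (cementum < enamel)",
            "dynroot_spec_error")
  if (spec$air_mean_intensity >= spec$root_mean_intensity)
    dr_stop("air must be darker than the root mode", "dynroot_spec_error")
  if (spec$noise_sd < 0 ||
      (spec$noise_sd > 0 &&
       (spec$crown_mean_intensity - spec$root_mean_intensity) < 4 * spec$noise_sd))
    dr_stop("intensity modes must be separated by >= 4 noise SDs",
            "dynroot_spec_error")
  structure(spec, class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %s, root %d px x %d slices", x$shape,
              x$cross_section_px, x$root_height_slices))
  if (x$shape == "two_part_tooth")
    cat(sprintf(", crown %d px x %d slices", x$crown_cross_section_px,
                x$crown_height_slices))
  cat(sprintf("\n  intensities air/root/crown = %d/%d/%d, noise sd %.3g, seed %d\n",
              x$air_mean_intensity, x$root_mean_intensity,
              x$crown_mean_intensity, x$noise_sd, x$seed))
  invisible(x)
}

# in-plane footprint mask (logical ny x nx) of a region
phantom_footprint <- function(shape, side, ny, nx) {
  m <- matrix(FALSE, ny, nx)
  if (shape == "cylinder") {
    r <- side / 2
    cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
    for (y in seq_len(ny)) for (x in seq_len(nx))
      if ((y - cy)^2 + (x - cx)^2 <= r^2) m[y, x] <- TRUE
  } else {
    y0 <- floor((ny - side) / 2) + 1L
    x0 <- floor((nx - side) / 2) + 1L
    m[y0:(y0 + side - 1L), x0:(x0 + side - 1L)] <- TRUE
  }
  m
}

# edge pixels of a 2D footprint under the 8-neighborhood rule
footprint_edge_count <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(FALSE, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- m
  n <- 0L
  for (y in 2:(ny + 1L)) for (x in 2:(nx + 1L)) {
    if (!pad[y, x]) next
    nb <- pad[(y - 1L):(y + 1L), (x - 1L):(x + 1L)]
    if (sum(nb) < 9L) n <- n + 1L
  }
  n
}

#' Generate a synthetic tooth phantom with analytic ground truth
#'
#' Builds the clean geometry from the spec, computes the truth fields
#' combinatorially from it (before any noise), then draws voxel
#' intensities region-wise from `Normal(mean, noise_sd)`, rounded
#' half-up and clipped to 0--255.  Given the same spec the volume is
#' bit-identical across calls; the caller's RNG state is untouched.
#'
#' Truth fields: `true_root_edge_pixels` is the clean per-slice
#' 8-neighborhood edge count summed over root slices; `true_rsa_mm2 =
#' true_root_edge_pixels * pixel_size_mm * slice_spacing_mm`;
#' `true_threshold_bin` is the integer bin minimizing the analytic
#' two-mode mixture density (weights = clean root/crown edge counts)
#' between the two means -- for a noise-free or root-only phantom, the
#' midpoint of the two means.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [voxel_volume()]) and `truth`
#'   (`phantom_truth`: `true_threshold_bin`, `true_root_edge_pixels`,
#'   `true_crown_edge_pixels`, `true_rsa_mm2`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  margin <- 6L
  side_r <- spec$cross_section_px
  side_c <- if (spec$shape == "two_part_tooth") spec$crown_cross_section_px
            else side_r
  ny <- nx <- side_c + 2L * margin
  nz <- spec$root_height_slices + spec$crown_height_slices + 2L * margin
  if (ny < 3L || nz < 1L)
    dr_stop("phantom volume degenerate", "dynroot_spec_error")

  root_fp <- phantom_footprint(spec$shape, side_r, ny, nx)
  crown_fp <- if (spec$crown_height_slices > 0L)
    phantom_footprint("square_prism", side_c, ny, nx) else NULL

  region <- array(0L, c(nz, ny, nx))   # 0 air, 1 root, 2 crown
  z_root <- margin + seq_len(spec$root_height_slices)
  for (z in z_root) region[z, , ][root_fp] <- 1L
  if (!is.null(crown_fp)) {
    z_crown <- margin + spec$root_height_slices +
      seq_len(spec$crown_height_slices)
    for (z in z_crown) region[z, , ][crown_fp] <- 2L
  }

  # analytic truth from the clean geometry
  root_edges_per_slice <- footprint_edge_count(root_fp)
  n_root_edges <- root_edges_per_slice * spec$root_height_slices
  n_crown_edges <- if (is.null(crown_fp)) 0L
    else footprint_edge_count(crown_fp) * spec$crown_height_slices
  m1 <- spec$root_mean_intensity; m2 <- spec$crown_mean_intensity
  true_bin <- if (spec$noise_sd > 0 && n_crown_edges > 0L) {
    grid <- (m1 + 1L):(m2 - 1L)
    dens <- n_root_edges * stats::dnorm(grid, m1, spec$noise_sd) +
            n_crown_edges * stats::dnorm(grid, m2, spec$noise_sd)
    grid[which.min(dens)]
  } else {
    (m1 + m2) %/% 2L
  }
  truth <- structure(list(
    true_threshold_bin = as.integer(true_bin),
    true_root_edge_pixels = as.integer(n_root_edges),
    true_crown_edge_pixels = as.integer(n_crown_edges),
    true_rsa_mm2 = n_root_edges * spec$pixel_size_mm * spec$slice_spacing_mm),
    class = "phantom_truth")

  means <- c(spec$air_mean_intensity, spec$root_mean_intensity,
             spec$crown_mean_intensity)[region + 1L]
  intensities <- if (spec$noise_sd == 0) {
    array(as.integer(means), dim(region))
  } else {
    with_seed(spec$seed, array(clip8(stats::rnorm(length(means), means,
                                                  spec$noise_sd)),
                               dim(region)))
  }
  list(volume = voxel_volume(intensities, spec$pixel_size_mm,
                             spec$slice_spacing_mm),
       truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "phantom_truth: %d root / %d crown edge px, threshold bin %d, RSA %.4f mm^2\n",
    x$true_root_edge_pixels, x$true_crown_edge_pixels,
    x$true_threshold_bin, x$true_rsa_mm2))
  invisible(x)
}

#' Read/write a phantom spec as a flat key=value file
#'
#' @param spec a [phantom_spec()].
#' @param path file path.
#' @return `write_phantom_spec`: the path; `read_phantom_spec`: a
#'   [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  writeLines(sprintf("%s=%s", names(spec),
                     vapply(spec, function(v) format(v, digits = 17), "")),
             path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L))
    dr_stop("phantom spec file must be key=value lines",
            "dynroot_input_error")
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  names(vals) <- trimws(vapply(kv, `[[`, "", 1L))
  known <- names(formals(phantom_spec))
  if (!all(names(vals) %in% known))
    dr_stop(sprintf("unknown phantom spec keys: %s",
                    paste(setdiff(names(vals), known), collapse = ", ")),
            "dynroot_input_error")
  args <- as.list(vals)
  num <- setdiff(names(args), "shape")
  args[num] <- lapply(args[num], as.numeric)
  if (anyNA(args[num]))
    dr_stop("non-numeric value for a numeric phantom spec key",
            "dynroot_input_error")
  do.call(phantom_spec, args)
}
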