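#' Segment tooth roots and measure root surface area
#'
#' Runs the whole chain on a CBCT volume of one or more isolated teeth:
#' air/tooth binarization, 3D connected-component labelling, per-slice
#' surface-pixel extraction, surface-intensity histogram, personalized
#' dynamic threshold (P, X), root/crown edge classification and RSA
#' accumulation.  The threshold is found independently for every tooth
#' component -- thresholds vary between teeth, which is the point of the
#' personalized rule.
#'
#' @param volume a [voxel_volume()] (or a path accepted by
#'   [read_volume()] / [read_dicom_series()]).
#' @param air_threshold optional manual air/tooth cut for [binarize()].
#' @param smoothing_window,min_prominence_fraction passed to
#'   [find_threshold()].
#' @param min_component_voxels passed to [connected_components()].
#' @param x_threshold optional manual segmentation threshold X applied to
#'   every component, bypassing [find_threshold()] (useful for unimodal
#'   surfaces, e.g. a crownless root fragment).
#' @return `tooth_segmentation` object: list with
#'   \describe{
#'     \item{components}{per-tooth results: histogram, `threshold_result`
#'       (or the error message if the threshold failed), `edge_labeling`,
#'       `rsa_result`.}
#'     \item{table}{one row per tooth: `component_id`, `voxel_count`,
#'       `edge_pixels`, `P`, `X`, `root_edge_pixels`, `crown_edge_pixels`,
#'       `rsa_mm2`.}
#'     \item{label_volume}{integer array: 0 background, 1 root edge,
#'       2 crown edge, 3 interior tooth.}
#'   }
#' @section Errors: a volume with no components at all raises
#'   `dynroot_no_components_error`.
#' @examples
#' ph <- generate_phantom(phantom_spec())
#' seg <- segment_tooth_roots(ph$volume)
#' seg$table$rsa_mm2 - ph$truth$true_rsa_mm2
#' @export
segment_tooth_roots <- function(volume,
                                air_threshold = NULL,
                                smoothing_window = 5L,
                                min_prominence_fraction = 0.05,
                                min_component_voxels = 27L,
                                x_threshold = NULL) {
  if (is.character(volume)) {
    volume <- if (dir.exists(volume)) read_dicom_series(volume)
              else read_volume(volume)
  }
  stopifnot(inherits(volume, "voxel_volume"))
  mask <- binarize(volume, air_threshold)
  comps <- connected_components(mask, min_voxels = min_component_voxels)
  if (length(comps) == 0L)
    dr_stop("no components: nothing above the air threshold survived the size filter",
            "dynroot_no_components_error")

  label_volume <- array(0L, dim(volume$intensities))
  results <- vector("list", length(comps))
  rows <- vector("list", length(comps))
  for (k in seq_along(comps)) {
    comp <- comps[[k]]
    edges <- extract_edges(comp)
    hist <- surface_histogram(volume, edges)
    thr <- NULL; thr_error <- NA_character_
    if (is.null(x_threshold)) {
      thr <- tryCatch(
        find_threshold(hist, smoothing_window, min_prominence_fraction),
        dynroot_error = function(e) {
          thr_error <<- sprintf("component %d, stage find_threshold: %s",
                                comp$component_id, conditionMessage(e))
          NULL
        })
    }
    X <- if (!is.null(thr)) thr$X else x_threshold
    if (is.null(X)) {
      labeling <- NULL; rsa <- NULL
    } else {
      labeling <- classify_edges(volume, edges, if (!is.null(thr)) thr else X)
      rsa <- compute_rsa(labeling, volume)
      label_volume[comp$mask] <- 3L
      label_volume[labeling$crown_edges] <- 2L
      label_volume[labeling$root_edges] <- 1L
    }
    results[[k]] <- list(component_id = comp$component_id,
                         voxel_count = comp$voxel_count,
                         edges = edges, histogram = hist,
                         threshold = thr, threshold_error = thr_error,
                         labeling = labeling, rsa = rsa)
    rows[[k]] <- data.frame(
      component_id = comp$component_id,
      voxel_count = comp$voxel_count,
      edge_pixels = sum(edges),
      P = if (!is.null(thr)) thr$P else NA_integer_,
      X = if (!is.null(X)) as.numeric(X) else NA_real_,
      root_edge_pixels = if (!is.null(rsa)) rsa$root_edge_pixels else NA_integer_,
      crown_edge_pixels = if (!is.null(labeling)) sum(labeling$crown_edges) else NA_integer_,
      rsa_mm2 = if (!is.null(rsa)) rsa$rsa_mm2 else NA_real_)
  }
  structure(list(components = results,
                 table = do.call(rbind, rows),
                 label_volume = label_volume,
                 volume = volume,
                 air_threshold = attr(mask, "air_threshold"),
                 params = list(smoothing_window = smoothing_window,
                               min_prominence_fraction = min_prominence_fraction,
                               min_component_voxels = min_component_voxels,
                               x_threshold = x_threshold),
                 call = match.call()),
            class = "tooth_segmentation")
}

#' @export
print.tooth_segmentation <- function(x, ...) {
  cat(sprintf("tooth_segmentation: %d component(s), air threshold %d\n",
              nrow(x$table), x$air_threshold))
  print(x$table, row.names = FALSE)
  bad <- !vapply(x$components, function(c) is.na(c$threshold_error), TRUE)
  for (msg in vapply(x$components[bad], `[[`, "", "threshold_error"))
    cat("  !", msg, "\n")
  invisible(x)
}

#' @export
summary.tooth_segmentation <- function(object, ...) object$table

#' @export
as.data.frame.tooth_segmentation <- function(x, ...) x$table

#' Plot the surface histogram and dynamic threshold of one tooth
#'
#' Raw counts (grey), the smoothed curve actually searched (black), and
#' vertical marks at the root peak P, the threshold X and the crown peak.
#'
#' @param x a `tooth_segmentation`.
#' @param component which component (row of `x$table`) to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tooth_segmentation <- function(x, component = 1L, ...) {
  comp <- x$components[[component]]
  counts <- as.numeric(unclass(comp$histogram))
  graphics::plot(0:255, counts, type = "h", col = "grey70",
                 xlab = "surface pixel intensity (bin)",
                 ylab = "pixel count",
                 main = sprintf("component %d", comp$component_id), ...)
  if (!is.null(comp$threshold)) {
    thr <- comp$threshold
    graphics::lines(0:255, thr$smoothed_counts, lwd = 1.5)
    graphics::abline(v = thr$P, col = "firebrick", lty = 2)
    graphics::abline(v = thr$X, col = "blue", lwd = 2)
    graphics::abline(v = thr$crown_peak, col = "grey40", lty = 2)
    graphics::mtext(sprintf("P = %d   X = %d", thr$P, thr$X), side = 3,
                    line = 0.2, cex = 0.9)
  }
  invisible(x)
}

#' Axial overlay image of the segmentation
#'
#' Renders one axial slice as grayscale with root edge pixels in red and
#' crown edge pixels in white, the standard visual check of where the
#' personalized threshold put the root/crown boundary.
#'
#' @param seg a `tooth_segmentation`.
#' @param z slice index.
#' @return an H x W x 3 numeric RGB array in `[0, 1]`.
#' @export
overlay_slice <- function(seg, z) {
  stopifnot(inherits(seg, "tooth_segmentation"))
  g <- seg$volume$intensities[z, , ] / 255
  lab <- seg$label_volume[z, , ]
  rgb <- array(rep(g, 3L), c(dim(g), 3L))
  root <- lab == 1L; crown <- lab == 2L
  for (ch in 1:3) {
    plane <- rgb[, , ch]
    plane[root] <- if (ch == 1L) 1 else 0
    plane[crown] <- 1
    rgb[, , ch] <- plane
  }
  rgb
}

#' Write PNG overlays for a set of slices
#'
#' @param seg a `tooth_segmentation`.
#' @param dir output directory.
#' @param slices slice indices (default: all).
#' @return paths written, invisibly.
#' @export
write_overlays <- function(seg, dir, slices = NULL) {
  if (is.null(slices)) slices <- seq_len(dim(seg$volume$intensities)[1])
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (z in slices) {
    p <- file.path(dir, sprintf("overlay_z%03d.png", z))
    png::writePNG(overlay_slice(seg, z), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Export a surface histogram as a two-column table
#'
#' Plain-text export (bin, count), tab-separated with a header line.
#'
#' @param hist a [surface_histogram()].
#' @param path output path.
#' @export
write_histogram <- function(hist, path) {
  utils::write.table(
    data.frame(bin = 0:255, count = as.integer(unclass(hist))),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
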