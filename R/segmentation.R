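# Core segmentation chain: air/tooth binarization, 3D connected
# components, per-slice edge extraction, surface histogram, and the
# personalized dynamic threshold (P, X).

#' Binarize a CBCT volume into tooth and air
#'
#' The non-air part is the tooth; a voxel is tooth when its intensity
#' exceeds `air_threshold`.  When no threshold is given it is chosen
#' automatically by maximizing the between-class variance of the
#' whole-volume intensity histogram (Otsu's criterion) -- isolated teeth
#' scanned in air give a strongly bimodal histogram, so the automatic
#' split is reliable, and the manual override keeps runs reproducible when
#' it is not.
#'
#' @param volume a [voxel_volume()].
#' @param air_threshold optional integer in 0--255; voxels strictly above
#'   it are tooth.
#' @return logical 3D array (`TRUE` = tooth) with attribute
#'   `air_threshold` (the threshold actually used).  An all-`TRUE` or
#'   all-`FALSE` mask raises a degenerate-input warning.
#' @export
binarize <- function(volume, air_threshold = NULL) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (is.null(air_threshold)) {
    air_threshold <- otsu_threshold(tabulate(volume$intensities + 1L, 256L))
  } else {
    if (!is.numeric(air_threshold) || length(air_threshold) != 1L ||
        air_threshold < 0 || air_threshold > 255)
      dr_stop("`air_threshold` must be a single value in [0, 255]",
              "dynroot_input_error")
    air_threshold <- as.integer(air_threshold)
  }
  mask <- volume$intensities > air_threshold
  if (all(mask) || !any(mask))
    dr_warn(sprintf(
      "degenerate binarization: mask is all-%s at threshold %d",
      if (all(mask)) "tooth" else "air", air_threshold),
      "dynroot_degenerate_warning")
  attr(mask, "air_threshold") <- air_threshold
  mask
}

# Otsu's criterion on a 256-bin histogram: threshold t (0..254) assigns
# bins <= t to background; returns the t maximizing between-class
# variance, taking the midpoint of a tied plateau.
otsu_threshold <- function(counts) {
  p <- counts / sum(counts)
  bins <- 0:255
  omega <- cumsum(p)                # P(class0) for t = 0..255
  mu <- cumsum(p * bins)
  mu_total <- mu[256]
  t_cand <- 1:255                   # indices; threshold t = index - 1
  w0 <- omega[t_cand]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_total * w0[valid] - mu[t_cand][valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  best <- which(sigma_b == max(sigma_b))
  as.integer(floor(mean(range(best))) - 1L)
}

#' Label 3D connected components of a tooth mask
#'
#' Each tooth in the scan volume is one connected component in 3D space.
#' Components are labelled under 26-connectivity (the most inclusive
#' standard choice), sorted by voxel count descending, and specks below
#' `min_voxels` (default 27, one 3x3x3 cube) are dropped as noise.
#'
#' @param mask logical 3D array from [binarize()].
#' @param min_voxels minimum voxel count for a component to be kept.
#' @param connectivity 26 (default) or 6.
#' @return list of `tooth_component` objects, each with fields
#'   `component_id`, `mask` (logical array, full volume shape) and
#'   `voxel_count`.  Empty mask gives an empty list.
#' @export
connected_components <- function(mask, min_voxels = 27L, connectivity = 26L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L,
            connectivity %in% c(6L, 26L))
  vox <- which(mask)
  if (length(vox) == 0L) return(list())

  d <- dim(mask)
  offsets <- half_neighborhood_3d(connectivity)
  idx <- array(seq_along(mask), d)
  from <- integer(0); to <- integer(0)
  for (off in offsets) {
    a <- shift_window(d, off)
    A <- idx[a$src$z, a$src$y, a$src$x, drop = FALSE]
    B <- idx[a$dst$z, a$dst$y, a$dst$x, drop = FALSE]
    keep <- mask[A] & mask[B]
    from <- c(from, A[keep]); to <- c(to, B[keep])
  }
  vid <- match(c(from, to), vox)     # compress to vertex ids 1..n
  g <- igraph::make_graph(rbind(vid[seq_along(from)],
                                vid[length(from) + seq_along(to)]),
                          n = length(vox), directed = FALSE)
  memb <- igraph::components(g)$membership

  sizes <- tabulate(memb)
  keep_comp <- order(sizes, decreasing = TRUE)
  keep_comp <- keep_comp[sizes[keep_comp] >= min_voxels]
  out <- vector("list", length(keep_comp))
  for (i in seq_along(keep_comp)) {
    cm <- array(FALSE, d)
    cm[vox[memb == keep_comp[i]]] <- TRUE
    out[[i]] <- structure(list(component_id = i, mask = cm,
                               voxel_count = sizes[keep_comp[i]]),
                          class = "tooth_component")
  }
  out
}

#' @export
print.tooth_component <- function(x, ...) {
  cat(sprintf("tooth_component %d: %d voxels\n", x$component_id,
              x$voxel_count))
  invisible(x)
}

# positive half of the 3D neighborhood offsets (undirected edges)
half_neighborhood_3d <- function(connectivity) {
  offs <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    if (connectivity == 6L && abs(dz) + abs(dy) + abs(dx) != 1L) next
    # keep one direction per undirected pair
    if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0))
      offs[[length(offs) + 1L]] <- c(dz, dy, dx)
  }
  offs
}

# index windows so that src[i] and dst[i] are `off` apart
shift_window <- function(d, off) {
  rng <- function(n, o) {
    if (o >= 0) list(src = seq_len(n - o), dst = seq_len(n - o) + o)
    else list(src = seq_len(n + o) - o, dst = seq_len(n + o))
  }
  z <- rng(d[1], off[1]); y <- rng(d[2], off[2]); x <- rng(d[3], off[3])
  list(src = list(z = z$src, y = y$src, x = x$src),
       dst = list(z = z$dst, y = y$dst, x = x$dst))
}

#' Extract surface (edge) pixels of a tooth component
#'
#' A pixel is an edge pixel when at least one of its 8 in-plane neighbors
#' (same axial slice) is background; pixels outside the slice count as
#' background, so components touching the volume border have a well
#' defined edge.  Neighborhoods never cross slices: the surface is
#' accumulated slice by slice, which is also what the perimeter-based
#' area rule expects.
#'
#' @param component a `tooth_component` from [connected_components()], or
#'   a logical 3D array.
#' @return logical 3D array, `TRUE` at edge pixels.
#' @export
extract_edges <- function(component) {
  m <- if (inherits(component, "tooth_component")) component$mask
       else component
  stopifnot(is.logical(m), length(dim(m)) == 3L)
  d <- dim(m)
  bg <- !m
  has_bg_neighbor <- array(FALSE, d)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    shifted <- array(TRUE, d)       # out-of-bounds = background
    a <- shift_window(d, c(0L, dy, dx))
    shifted[a$src$z, a$src$y, a$src$x] <- bg[a$dst$z, a$dst$y, a$dst$x]
    has_bg_neighbor <- has_bg_neighbor | shifted
  }
  m & has_bg_neighbor
}

#' Histogram of surface-pixel intensities
#'
#' Counts edge-pixel intensities into 256 bins (0--255).  This is the
#' curve whose two modes -- cementum (root) low, enamel (crown) high --
#' drive the personalized threshold.
#'
#' @param volume a [voxel_volume()].
#' @param edges logical edge array from [extract_edges()], same shape.
#' @return integer vector of length 256, class `surface_histogram`;
#'   `sum(counts)` equals the edge-pixel count.  An empty edge map gives
#'   all zeros with a warning.
#' @export
surface_histogram <- function(volume, edges) {
  stopifnot(inherits(volume, "voxel_volume"), is.logical(edges))
  if (!identical(dim(volume$intensities), dim(edges)))
    dr_stop("edge map shape differs from volume shape",
            "dynroot_input_error")
  if (!any(edges))
    dr_warn("empty edge map: all-zero histogram", "dynroot_degenerate_warning")
  counts <- tabulate(volume$intensities[edges] + 1L, 256L)
  structure(counts, class = "surface_histogram")
}

#' @export
print.surface_histogram <- function(x, ...) {
  nz <- which(x > 0) - 1L
  cat(sprintf("surface_histogram: %d edge pixels in %d nonzero bins (%s)\n",
              sum(x), length(nz),
              if (length(nz)) sprintf("intensity %d..%d", min(nz), max(nz))
              else "empty"))
  invisible(x)
}

# ---- dynamic threshold -----------------------------------------------------

# centered moving average with reflection at the boundaries
smooth_counts <- function(counts, window) {
  window <- as.integer(window)
  if (window %% 2L != 1L || window < 1L)
    dr_stop("`smoothing_window` must be odd and >= 1", "dynroot_input_error")
  if (window == 1L) return(as.numeric(counts))
  h <- window %/% 2L
  n <- length(counts)
  padded <- c(counts[(h + 1L):2L], counts, counts[(n - 1L):(n - h)])
  as.numeric(stats::filter(padded, rep(1 / window, window),
                           sides = 2))[(h + 1L):(h + n)]
}

# plateau-aware local maxima with topographic prominence.
# Returns data.frame(index, height, prominence); index is 1-based into y,
# plateau position is the plateau midpoint.
local_peaks <- function(y) {
  n <- length(y)
  out <- data.frame(index = integer(0), height = numeric(0),
                    prominence = numeric(0))
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && y[j + 1L] == y[i]) j <- j + 1L
    is_peak <- ((i == 1L) || y[i - 1L] < y[i]) &&
               ((j == n) || y[j + 1L] < y[i]) &&
               !(i == 1L && j == n)
    if (is_peak) {
      h <- y[i]
      # walk outwards until terrain rises above h; base = lowest point
      # passed (or the signal end).  A peak on the very first/last bin has
      # no terrain on that side, so its prominence is one-sided.
      lb <- if (i == 1L) NA_real_ else {
        k <- i - 1L; b <- Inf
        while (k >= 1L && y[k] <= h) { b <- min(b, y[k]); k <- k - 1L }
        b
      }
      rb <- if (j == n) NA_real_ else {
        k <- j + 1L; b <- Inf
        while (k <= n && y[k] <= h) { b <- min(b, y[k]); k <- k + 1L }
        b
      }
      out <- rbind(out, data.frame(index = (i + j) %/% 2L, height = h,
                                   prominence = h - max(lb, rb, na.rm = TRUE)))
    }
    i <- j + 1L
  }
  out
}

#' Personalized dynamic segmentation threshold from a surface histogram
#'
#' Implements the per-tooth threshold rule: the surface-pixel histogram of
#' a tooth has two modes, cementum (root, left) and enamel (crown,
#' right); the first peak is `P` and the valley following it, at bin `X`,
#' is the tooth's segmentation threshold.  Surface pixels below `X` are
#' root, at or above `X` crown.
#'
#' Real 256-bin histograms are noisy, so the raw rule is wrapped in a
#' robustness layer: counts are smoothed by a centered moving average
#' (width `smoothing_window`, reflected at the boundaries); candidate
#' peaks must have topographic prominence of at least
#' `min_prominence_fraction` times the smoothed curve's range; the root
#' and crown peaks are the qualifying pair separated by the deepest
#' valley; and `X` is the minimum of the smoothed curve between them,
#' ties going to the minimal bin closest to the midpoint of the two peaks
#' (the maximum-margin cut, which matters when the modes are so well
#' separated that the valley is a flat run of zeros).  With
#' `smoothing_window = 1` and `min_prominence_fraction = 0` this reduces
#' to the literal raw-histogram rule on clean bimodal data.
#'
#' @param hist a [surface_histogram()] (or integer vector of length 256).
#' @param smoothing_window odd moving-average width, default 5.
#' @param min_prominence_fraction minimum peak prominence as a fraction of
#'   the smoothed curve's range (max - min), default 0.05.
#' @return `threshold_result`: list with integer bins `P` and `X`
#'   (`0 <= P < X <= 255`), `smoothed_counts` (length 256), `crown_peak`
#'   (bin of the second mode) and `peaks` (all qualifying peaks).
#' @section Errors: a histogram with fewer than two qualifying peaks
#'   signals a unimodal surface (no detectable enamel/cementum contrast)
#'   and raises a `dynroot_no_peak_error`; a degenerate peak pair with no
#'   interior bins raises `dynroot_threshold_failure_error`.
#' @export
find_threshold <- function(hist, smoothing_window = 5L,
                           min_prominence_fraction = 0.05) {
  counts <- as.numeric(unclass(hist))
  if (length(counts) != 256L)
    dr_stop("surface histogram must have 256 bins", "dynroot_input_error")
  if (sum(counts > 0) < 2L)
    dr_stop("histogram needs at least two nonzero bins spanning two intensities",
            "dynroot_no_peak_error")
  s <- smooth_counts(counts, smoothing_window)
  prom_min <- min_prominence_fraction * (max(s) - min(s))
  pk <- local_peaks(s)
  pk <- pk[pk$prominence >= prom_min, , drop = FALSE]
  if (nrow(pk) < 2L)
    dr_stop(sprintf(
      "no second qualifying peak (found %d): surface histogram looks unimodal",
      nrow(pk)), "dynroot_no_peak_error")

  # root/crown peak pair: the qualifying pair with the deepest valley
  # between them (robust when noise splits a mode into several peaks)
  best <- NULL; best_key <- c(-Inf, -Inf)
  for (a in seq_len(nrow(pk) - 1L)) {
    for (b in (a + 1L):nrow(pk)) {
      i <- pk$index[a]; j <- pk$index[b]
      if (j - i < 2L) next
      depth <- min(pk$height[a], pk$height[b]) - min(s[(i + 1L):(j - 1L)])
      # rank by valley depth, then by the weaker peak's prominence (so a
      # mode-flank wiggle never displaces the true mode peak), then left
      key <- c(depth, min(pk$prominence[a], pk$prominence[b]))
      if (key[1] > best_key[1] + 1e-9 ||
          (abs(key[1] - best_key[1]) <= 1e-9 && key[2] > best_key[2] + 1e-9)) {
        best <- c(i, j); best_key <- key
      }
    }
  }
  if (is.null(best))
    dr_stop("no interior bins between candidate peaks",
            "dynroot_threshold_failure_error")
  P_i <- best[1]; Q_i <- best[2]
  seg <- s[(P_i + 1L):(Q_i - 1L)]
  argmin <- which(seg == min(seg)) + P_i
  mid <- (P_i + Q_i) / 2
  X_i <- argmin[which.min(abs(argmin - mid))]

  structure(list(P = P_i - 1L, X = X_i - 1L, crown_peak = Q_i - 1L,
                 smoothed_counts = s,
                 peaks = transform(pk, bin = index - 1L),
                 smoothing_window = as.integer(smoothing_window),
                 min_prominence_fraction = min_prominence_fraction),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "dynamic threshold: P = %d (root peak), X = %d, crown peak = %d\n",
    x$P, x$X, x$crown_peak))
  invisible(x)
}

#' Split edge pixels into root and crown by the dynamic threshold
#'
#' Root edges are the edge pixels with intensity strictly below `X`,
#' crown edges those at or above; the two sets partition the edge map.
#' Each pixel is classified by its own intensity only.
#'
#' @param volume a [voxel_volume()].
#' @param edges logical edge array from [extract_edges()].
#' @param threshold a `threshold_result` from [find_threshold()], or a
#'   bare numeric threshold `X`.
#' @return `edge_labeling`: list with logical arrays `root_edges` and
#'   `crown_edges` and the numeric `X` used.
#' @export
classify_edges <- function(volume, edges, threshold) {
  stopifnot(inherits(volume, "voxel_volume"), is.logical(edges))
  X <- if (inherits(threshold, "threshold_result")) threshold$X
       else as.numeric(threshold)
  root <- edges & (volume$intensities < X)
  crown <- edges & (volume$intensities >= X)
  structure(list(root_edges = root, crown_edges = crown, X = X),
            class = "edge_labeling")
}

#' @export
print.edge_labeling <- function(x, ...) {
  cat(sprintf("edge_labeling at X = %s: %d root / %d crown edge pixels\n",
              format(x$X), sum(x$root_edges), sum(x$crown_edges)))
  invisible(x)
}
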