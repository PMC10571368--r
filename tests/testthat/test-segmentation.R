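# binarization, connected components, edge extraction, surface histogram

test_that("manual binarization thresholds exactly at 'greater than'", {
  arr <- array(0L, c(2, 4, 4)); arr[1, 2, 2] <- 200L
  v <- voxel_volume(arr)
  m <- binarize(v, air_threshold = 50)
  expect_equal(sum(m), 1)
  expect_true(m[1, 2, 2])
  # threshold 255 leaves nothing and warns
  expect_warning(m2 <- binarize(v, air_threshold = 255),
                 class = "dynroot_degenerate_warning")
  expect_false(any(m2))
})

test_that("automatic binarization maximizes between-class variance", {
  # clean bimodal volume: half voxels at 10, half at 200
  arr <- array(c(rep(10L, 32), rep(200L, 32)), c(4, 4, 4))
  v <- voxel_volume(arr)
  m <- binarize(v)
  expect_true(all(m[arr == 200L]))
  expect_false(any(m[arr == 10L]))
  # threshold agrees with the brute-force variance scan up to the
  # optimum plateau (any threshold in it yields the same classes)
  t_auto <- attr(m, "air_threshold")
  t_oracle <- oracle_otsu(arr)
  expect_identical(arr > t_auto, arr > t_oracle)

  # noisy bimodal: the chosen threshold must still match the scan's classes
  set.seed(5)
  arr2 <- array(as.integer(pmin(255, pmax(0, round(c(
    rnorm(200, 40, 12), rnorm(200, 180, 12)))))), c(4, 10, 10))
  v2 <- voxel_volume(arr2)
  t2 <- attr(binarize(v2), "air_threshold")
  expect_identical(arr2 > t2, arr2 > oracle_otsu(arr2))
})

test_that("3D components are 26-connected, size-filtered and sorted", {
  arr <- array(FALSE, c(8, 8, 8))
  arr[1:2, 1:2, 1:2] <- TRUE            # cube A: 8 voxels
  arr[6:7, 6:7, 6:7] <- TRUE            # cube B: 8 voxels
  comps <- connected_components(arr, min_voxels = 1L)
  expect_length(comps, 2)
  expect_equal(vapply(comps, `[[`, 0L, "voxel_count"), c(8L, 8L))

  # diagonal touch merges under 26-connectivity
  arr2 <- array(FALSE, c(8, 8, 8))
  arr2[2:4, 2:4, 2:4] <- TRUE
  arr2[5, 5, 5] <- TRUE                 # corner-adjacent stray voxel
  comps2 <- connected_components(arr2, min_voxels = 1L)
  expect_length(comps2, 1)
  expect_equal(comps2[[1]]$voxel_count, 28L)
  # ... but not under 6-connectivity
  expect_length(connected_components(arr2, min_voxels = 1L,
                                     connectivity = 6L), 2)

  # default min size drops a 2-voxel speck
  arr3 <- array(FALSE, c(5, 5, 5)); arr3[1, 1, 1:2] <- TRUE
  expect_length(connected_components(arr3), 0)
  expect_length(connected_components(array(FALSE, c(3, 3, 3))), 0)
})

test_that("component labelling agrees with a flood-fill oracle", {
  set.seed(31)
  for (i in 1:5) {
    mask <- array(runif(6 * 7 * 7) < 0.35, c(6, 7, 7))
    comps <- connected_components(mask, min_voxels = 1L)
    lab <- oracle_flood_fill(mask)
    expect_equal(length(comps), max(lab))
    sizes <- sort(tabulate(lab[lab > 0]), decreasing = TRUE)
    expect_equal(vapply(comps, `[[`, 0L, "voxel_count"), sizes)
    # each reported component is exactly one oracle label
    for (comp in comps) {
      ids <- unique(lab[comp$mask])
      expect_length(ids, 1)
      expect_equal(sum(lab == ids), comp$voxel_count)
    }
  }
})

test_that("edge extraction follows the in-plane 8-neighborhood rule", {
  # solid 3x3 square: all but the center are edges
  m <- array(FALSE, c(1, 5, 5)); m[1, 2:4, 2:4] <- TRUE
  e <- extract_edges(m)
  expect_equal(sum(e), 8)
  expect_false(e[1, 3, 3])
  # isolated pixel is its own edge
  m2 <- array(FALSE, c(1, 3, 3)); m2[1, 2, 2] <- TRUE
  expect_equal(sum(extract_edges(m2)), 1)
  # solid s x s square has 4s - 4 edge pixels, s = 2..10
  for (s in 2:10) {
    m3 <- array(FALSE, c(1, s + 2, s + 2))
    m3[1, 2:(s + 1), 2:(s + 1)] <- TRUE
    expect_equal(sum(extract_edges(m3)), 4 * s - 4)
  }
  # a square touching the volume border: outside counts as background,
  # so the full perimeter is still edge
  m4 <- array(TRUE, c(1, 4, 4))
  expect_equal(sum(extract_edges(m4)), 12)
})

test_that("edge extraction matches the exhaustive oracle on random slices", {
  set.seed(41)
  for (i in 1:50) {
    mask <- array(runif(1 * 9 * 9) < 0.5, c(1, 9, 9))
    expect_identical(extract_edges(mask), oracle_edges_3d(mask))
  }
})

test_that("surface histogram counts every edge pixel exactly once", {
  arr <- array(0L, c(1, 5, 5)); arr[1, 2:4, 2:4] <- 100L
  v <- voxel_volume(arr)
  e <- extract_edges(arr > 0)
  h <- surface_histogram(v, e)
  expect_equal(h[100 + 1], 8)
  expect_equal(sum(h), 8)

  arr2 <- array(0L, c(1, 5, 5))
  arr2[1, 2, 2] <- 10L; arr2[1, 2, 4] <- 10L; arr2[1, 4, 2] <- 200L
  v2 <- voxel_volume(arr2)
  h2 <- surface_histogram(v2, arr2 > 0)
  expect_equal(h2[10 + 1], 2)
  expect_equal(h2[200 + 1], 1)
  expect_equal(sum(h2), 3)

  # conservation on a random phantom, against an independent tally
  ph <- generate_phantom(phantom_spec(noise_sd = 6, seed = 3))
  mask <- binarize(ph$volume, air_threshold = 50)
  comp <- connected_components(mask)[[1]]
  e3 <- extract_edges(comp)
  h3 <- surface_histogram(ph$volume, e3)
  expect_equal(sum(h3), sum(oracle_edges_3d(comp$mask)))

  expect_warning(h0 <- surface_histogram(v, array(FALSE, c(1, 5, 5))),
                 class = "dynroot_degenerate_warning")
  expect_equal(sum(h0), 0)
})

test_that("root and crown edges always partition the edge set", {
  arr <- array(0L, c(1, 5, 5))
  arr[1, 2, 2:4] <- c(100L, 100L, 200L)
  v <- voxel_volume(arr)
  e <- arr > 0
  lab <- classify_edges(v, e, 150)
  expect_equal(sum(lab$root_edges), 2)
  expect_equal(sum(lab$crown_edges), 1)
  # X = 0: everything is crown
  lab0 <- classify_edges(v, e, 0)
  expect_false(any(lab0$root_edges))
  expect_identical(lab0$crown_edges, e)
  # partition property on random phantoms and random thresholds
  set.seed(51)
  for (i in 1:10) {
    ph <- generate_phantom(phantom_spec(noise_sd = 5, seed = i))
    edges <- extract_edges(binarize(ph$volume, 50))
    X <- sample(0:255, 1)
    lb <- classify_edges(ph$volume, edges, X)
    expect_identical(lb$root_edges | lb$crown_edges, edges)
    expect_false(any(lb$root_edges & lb$crown_edges))
  }
})
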