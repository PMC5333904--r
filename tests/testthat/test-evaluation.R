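test_that("CDF error is zero iff the distributions agree on the shared range", {
  ph <- fx_phantom()
  cdf <- cumulative_distribution(compute_histogram(ph$volume, labels = ph$labels))
  e <- cdf_abs_error(cdf, cdf)
  expect_equal(e$average_abs_error, 0)
  expect_equal(e$maximum_abs_error, 0)

  # closed-form oracle: uniform on [0, 2047] vs uniform on [0, 4095]
  a <- cumulative_distribution(compute_histogram(
    tiny_volume(rep(1:2047, each = 2), intensity_min = 0, intensity_max = 4095)))
  b <- cumulative_distribution(compute_histogram(
    tiny_volume(rep(1:4095, each = 1), intensity_min = 0, intensity_max = 4095)))
  e2 <- cdf_abs_error(a, b)
  expect_equal(e2$maximum_abs_error, a$P[a$levels == 2047] - b$P[b$levels == 2047],
               tolerance = 1e-12)
  expect_equal(e2$maximum_abs_error, 0.5, tolerance = 1e-3)
  expect_true(e2$average_abs_error <= e2$maximum_abs_error)

  # symmetry
  e3 <- cdf_abs_error(b, a)
  expect_equal(e3$average_abs_error, e2$average_abs_error)
  expect_equal(e3$maximum_abs_error, e2$maximum_abs_error)

  # disjoint supports
  lo <- cumulative_distribution(compute_histogram(tiny_volume(rep(1000, 10))))
  hi <- cumulative_distribution(compute_histogram(tiny_volume(rep(3000, 10))))
  expect_error(cdf_abs_error(lo, hi), "shared")
})

test_that("voxelwise differences average over consensus tissue voxels", {
  ph0 <- fx_phantom_noiseless()
  lab <- ph0$labels
  expect_equal(voxelwise_intensity_difference(ph0$volume, ph0$volume, lab, lab, "wm"), 0)
  shifted <- intensity_volume(ph0$volume$data + 100,
                              voxel_size = ph0$volume$voxel_size)
  expect_equal(voxelwise_intensity_difference(ph0$volume, shifted, lab, lab, "wm"), 100)

  # brute-force voxel loop oracle under a known linear distortion
  d <- distortion_spec("linear", offset = 80, slope = 0.95)
  tgt <- apply_distortion(ph0$volume, d)
  got <- voxelwise_intensity_difference(ph0$volume, tgt, lab, lab, "wm")
  wm_idx <- which(lab$labels == 3L)
  acc <- 0
  for (i in wm_idx) acc <- acc + abs(ph0$volume$data[i] - tgt$data[i])
  expect_equal(got, acc / length(wm_idx))
  expect_equal(got, mean(abs((0.95 - 1) * 3246 + 80)), tolerance = 1e-9)

  # empty consensus errors
  other <- tissue_label_map(array(1L, dim(lab$labels)), lab$voxel_size)
  expect_error(voxelwise_intensity_difference(ph0$volume, tgt, lab, other, "wm"),
               "no voxels")
})

test_that("the three-colour transfer function hits its anchors", {
  cm <- colour_map_t1w()
  v <- tiny_volume(c(0, 0.60 * 4000, 4000, 4095))
  rgb <- colorize(v, cm)
  expect_equal(as.vector(rgb[1, 1, 1, ]), c(255, 0, 0))       # red at the low end
  expect_equal(as.vector(rgb[2, 1, 1, ]), c(255, 255, 255))   # white point exact
  expect_equal(as.vector(rgb[3, 1, 1, ]), c(0, 0, 255))       # blue at the top
  expect_equal(as.vector(rgb[4, 1, 1, ]), c(0, 0, 255))       # clamped above hi
  expect_true(all(rgb >= 0 & rgb <= 255))

  cmq <- colour_map_t1map()
  vq <- tiny_volume(c(950, 950 + 0.4 * (3700 - 950), 3700))
  rgbq <- colorize(vq, cmq)
  expect_equal(as.vector(rgbq[1, 1, 1, ]), c(0, 0, 255))
  expect_equal(as.vector(rgbq[2, 1, 1, ]), c(255, 255, 255))
  expect_equal(as.vector(rgbq[3, 1, 1, ]), c(255, 0, 0))
  expect_error(colour_map(100, 50), "lo")
})

test_that("white-point fraction and boundary intensity convert both ways", {
  cm <- colour_map(0, 4000, mid_fraction = 0.60)
  expect_equal(white_fraction_to_intensity(cm, 0.60), 2400)
  cm2 <- colour_map(0, 100)
  expect_equal(white_fraction_to_intensity(cm2, 0.5), 50)
  for (f in c(0.25, 0.5, 0.75))
    expect_equal(intensity_to_white_fraction(cm, white_fraction_to_intensity(cm, f)), f)
  expect_error(white_fraction_to_intensity(cm, 1.2), "fraction")
})

test_that("interface boundary intensity sits between the tissue levels", {
  two <- tiny_volume(c(1907, 3246), dims = c(2, 1, 1))
  lab2 <- tiny_labels(c(2, 3), dims = c(2, 1, 1))
  expect_equal(interface_boundary_intensity(two, lab2), (1907 + 3246) / 2)

  # noiseless phantom: only the two tissue levels occur at the interface, so
  # the median lands inside the closed [GM, WM] interval
  ph0 <- fx_phantom_noiseless()
  b <- interface_boundary_intensity(ph0$volume, ph0$labels)
  expect_gte(b, 1907); expect_lte(b, 3246)

  nogm <- tiny_labels(c(1, 1), dims = c(2, 1, 1))
  expect_error(interface_boundary_intensity(two, nogm), "interface")
})

test_that("standardisation tightens the boundary intensity across a phantom set", {
  # ten small phantoms with random linear distortions: after RLS the spread
  # of the GM/WM interface intensity collapses
  set.seed(81)
  ref <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 32),
                                       hypothalamus_radius_vox = 4,
                                       wm_shell_radius_vox = 7, seed = 1000))
  ref_rois <- phantom_rois(ref$labels)
  before <- after <- numeric(10)
  for (i in 1:10) {
    ph <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 32),
                                        hypothalamus_radius_vox = 4,
                                        wm_shell_radius_vox = 7, seed = 2000 + i))
    d <- distortion_spec("linear", offset = runif(1, -150, 150),
                         slope = runif(1, 0.9, 1.1))
    tgt <- apply_distortion(ph$volume, d)
    before[i] <- interface_boundary_intensity(tgt, ph$labels)
    rois <- phantom_rois(ph$labels)
    med <- function(v, m) median(v$data[m$mask])
    tf <- build_rls(list(gm_target = med(tgt, rois$gm), wm_target = med(tgt, rois$wm),
                         gm_reference = med(ref$volume, ref_rois$gm),
                         wm_reference = med(ref$volume, ref_rois$wm)))
    after[i] <- interface_boundary_intensity(apply_transform(tgt, tf), ph$labels)
  }
  expect_lt(sd(after), sd(before))
})
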