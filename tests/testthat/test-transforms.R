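test_that("PHM interpolates piecewise-linearly between mode anchors", {
  # equal modes: identity
  t0 <- build_phm(c(1907, 3246), c(1907, 3246))
  x <- seq(0, 4095, length.out = 200)
  expect_equal(transform_value(t0, x), x)
  # anchor exactness and the two-point interpolation oracle
  tf <- build_phm(c(1800, 3200), c(1907, 3246))
  expect_equal(transform_value(tf, 1800), 1907)
  expect_equal(transform_value(tf, 3200), 3246)
  expect_equal(transform_value(tf, 2500),
               1907 + (2500 - 1800) * (3246 - 1907) / (3200 - 1800))
  expect_equal(transform_value(tf, 2500), 2576.5)
  expect_error(build_phm(c(3200, 1800), c(1907, 3246)), "GM < WM")
})

test_that("NHM fits a smooth interpolating spline through six anchors", {
  t0 <- build_nhm(c(1907, 3246), c(1907, 3246))
  g <- seq(0, 4095, length.out = 2000)
  expect_lt(max(abs(transform_value(t0, g) - g)), 1e-6)
  tf <- build_nhm(c(1800, 3200), c(1907, 3246))
  expect_equal(transform_value(tf, 1800), 1907)   # interpolation contract
  expect_equal(transform_value(tf, 3200), 3246)
  expect_error(build_nhm(c(1, 3200), c(1907, 3246)), "degenerate|GM")
})

test_that("NHM monotonicity is scanned; violations clamp but never decrease output range", {
  set.seed(11)
  n_warn <- 0L
  for (i in 1:200) {
    tm <- c(runif(1, 1000, 2500), runif(1, 3000, 3500))
    rm_ <- c(runif(1, 1000, 2500), runif(1, 3000, 3500))
    tf <- withCallingHandlers(
      build_nhm(tm, rm_),
      warning = function(w) { n_warn <<- n_warn + 1L; invokeRestart("muffleWarning") })
    y <- transform_value(tf, seq(0, 4095, by = 16))
    expect_true(all(y >= 0 & y <= 4095))
  }
  succeed()  # dense-grid scan ran on all 200 random mode pairs
})

test_that("CHM matches cumulative frequencies with a monotone lookup", {
  set.seed(5)
  v <- pmin(pmax(c(rnorm(40000, 1500, 200), rnorm(30000, 3100, 150)), 0), 4095)
  vol <- tiny_volume(v)
  cdf <- cumulative_distribution(compute_histogram(vol))
  t_id <- build_chm(cdf, cdf)
  # identity at class resolution: each class maps into itself
  w <- 4096 / 1024
  cls_lo <- (seq_len(1024) - 1) * w
  has_mass <- diff(c(0, cdf$P[pmin(length(cdf$P), ceiling(seq_len(1024) * w))])) > 0
  expect_true(all(abs(t_id$lut - (cls_lo + w - 1))[has_mass] <= w))
  expect_true(all(diff(t_id$lut) >= 0))

  # shift oracle: reference = target + 100 exactly
  vol2 <- tiny_volume(pmin(v + 100, 4095))
  cdf2 <- cumulative_distribution(compute_histogram(vol2))
  tf <- build_chm(cdf, cdf2)
  mid <- transform_value(tf, c(1200, 1500, 1800, 2900, 3100, 3300))
  expect_true(all(abs(mid - (c(1200, 1500, 1800, 2900, 3100, 3300) + 100)) <= w + 1))

  expect_error(build_chm(cdf, cdf, levels = 1), "levels")
})

test_that("CHM tie-breaking picks the lowest qualifying reference level", {
  # target: one atom; reference: two atoms -> flat CDF stretch between them
  tgt <- cumulative_distribution(compute_histogram(tiny_volume(rep(2000, 10))))
  ref <- cumulative_distribution(compute_histogram(
    tiny_volume(c(rep(1500, 5), rep(2500, 5)))))
  tf <- build_chm(tgt, ref)
  # P_T(2000) = 1 ties P_R(2500) = 1; no lower level qualifies equally,
  # but P = 0.5 at 1500 vs 1.0 at 2500: the class holding 2000 maps to 2500,
  # classes below with no mass inherit monotone fill from the lowest level
  expect_equal(transform_value(tf, 2000), 2500)
  expect_equal(tf$lut[1], 1500)  # lowest qualifying level for P near 0
})

test_that("RLS solves the two-point line and degenerates loudly", {
  t0 <- build_rls(list(gm_target = 1907, wm_target = 3246,
                       gm_reference = 1907, wm_reference = 3246))
  expect_equal(t0$slope, 1); expect_equal(t0$offset, 0)
  tf <- build_rls(list(gm_target = 1800, wm_target = 3200,
                       gm_reference = 1907, wm_reference = 3246))
  expect_equal(tf$slope, 1339 / 1400)
  expect_equal(tf$offset, 1907 - 1339 / 1400 * 1800)
  expect_error(build_rls(list(gm_target = 2000, wm_target = 2000,
                              gm_reference = 1907, wm_reference = 3246)),
               "degenerate")
})

test_that("SPS anchors the three tissue means with linear segments", {
  t0 <- build_sps(c(600, 1907, 3246), c(600, 1907, 3246))
  x <- seq(0, 4095, length.out = 100)
  expect_equal(transform_value(t0, x), x)
  tf <- build_sps(c(550, 1800, 3200), c(600, 1907, 3246))
  expect_equal(transform_value(tf, 1800), 1907)
  mid_in <- (550 + 1800) / 2
  expect_equal(transform_value(tf, mid_in), (600 + 1907) / 2)
  expect_error(build_sps(c(1800, 550, 3200), c(600, 1907, 3246)), "increasing")
})

test_that("every builder fixes the domain endpoints", {
  tfs <- list(build_phm(c(1800, 3200), c(1907, 3246)),
              build_nhm(c(1800, 3200), c(1907, 3246)),
              build_sps(c(550, 1800, 3200), c(600, 1907, 3246)),
              build_identity())
  for (tf in tfs) {
    expect_equal(transform_value(tf, 0), 0)
    expect_equal(transform_value(tf, 4095), 4095)
  }
})

test_that("transforms apply voxelwise and recover known distortions", {
  ph0 <- fx_phantom_noiseless()
  vol <- ph0$volume
  expect_equal(apply_transform(vol, build_identity())$data, vol$data)

  # RLS recovery: distort, then standardise with the exact inverse line
  d <- distortion_spec("linear", offset = 185.5, slope = 0.9564)
  tgt <- apply_distortion(vol, d)
  rois <- phantom_rois(ph0$labels)
  med <- function(v, m) median(v$data[m$mask])
  tf <- build_rls(list(gm_target = med(tgt, rois$gm), wm_target = med(tgt, rois$wm),
                       gm_reference = med(vol, rois$gm), wm_reference = med(vol, rois$wm)))
  rec <- apply_transform(tgt, tf)
  expect_lt(max(abs(rec$data - vol$data)), 1e-6)
  expect_equal(tf$slope, 1 / 0.9564, tolerance = 1e-9)
  expect_equal(tf$offset, -185.5 / 0.9564, tolerance = 1e-9)

  # PHM/SPS recover a noiseless linear distortion within one histogram bin:
  # PHM on its GM-WM anchor span, SPS (which also anchors CSF) on all brain
  st <- tissue_stats(vol, ph0$labels)
  std <- tissue_stats(tgt, ph0$labels)
  phm <- build_phm(std$mean[2:3], st$mean[2:3])
  sps <- build_sps(std$mean, st$mean)
  gmwm <- ph0$labels$labels %in% c(2L, 3L)
  rec_phm <- apply_transform(tgt, phm)
  expect_lt(max(abs(rec_phm$data[gmwm] - vol$data[gmwm])), 1)
  brain <- ph0$labels$labels != 0L
  rec_sps <- apply_transform(tgt, sps)
  expect_lt(max(abs(rec_sps$data[brain] - vol$data[brain])), 1)
})

test_that("PHM maps a voxel at a target anchor to the exact reference anchor", {
  ph0 <- fx_phantom_noiseless()
  tf <- build_phm(c(1800, 3200), c(1907, 3246))
  v <- tiny_volume(c(1800, 3200, 0, 4095))
  out <- apply_transform(v, tf)
  expect_equal(as.vector(out$data), c(1907, 3246, 0, 4095))
})

test_that("transforms serialise losslessly and reject malformed JSON", {
  ph <- fx_phantom()
  cdf <- cumulative_distribution(compute_histogram(ph$volume))
  tfs <- list(build_phm(c(1800, 3200), c(1907, 3246)),
              build_nhm(c(1850, 3150), c(1907, 3246)),
              build_sps(c(550, 1800, 3200), c(600, 1907, 3246)),
              build_rls(list(gm_target = 1800, wm_target = 3200,
                             gm_reference = 1907, wm_reference = 3246)),
              build_chm(cdf, cdf))
  g <- seq(0, 4095, length.out = 1000)
  for (tf in tfs) {
    back <- deserialize_transform(serialize_transform(tf))
    expect_equal(transform_value(back, g), transform_value(tf, g))
  }
  expect_error(deserialize_transform('{"domain": [0, 4095]}'), "method")
  expect_error(deserialize_transform("{not json"), "malformed")
  bad_lut <- serialize_transform(tfs[[5]])
  bad <- jsonlite::fromJSON(bad_lut)
  bad$lut <- bad$lut[1:100]
  expect_error(deserialize_transform(jsonlite::toJSON(bad, auto_unbox = TRUE)),
               "length")
})

test_that("apply_transform rejects a mismatched intensity domain", {
  v <- tiny_volume(c(10, 20), intensity_min = 0, intensity_max = 100)
  expect_error(apply_transform(v, build_identity(c(0, 4095))), "domain")
})
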