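#' Specify a synthetic brain phantom
#'
#' The phantom is a nest of concentric ellipsoids — a CSF shell around a GM
#' ribbon around a WM core — plus one small central GM sphere (a stand-in for
#' the hypothalamus) surrounded by a WM shell, so that ROI-based
#' standardisation always has a pure deep-GM/WM anchor pair. Each tissue
#' voxel draws its intensity from a Gaussian with the tissue's mean and SD,
#' clamped to the declared range.
#'
#' Default GM and WM means are the sample means of GM and WM median
#' intensities in high-resolution T1-weighted MP2RAGE cohorts (1907 and 3246
#' on the 12-bit scale); tissue SDs default to the between-subject SDs of the
#' tissue means (CSF 130.9, GM 75.9, WM 58.5). A CSF mean is not part of that
#' convention; 600 keeps CSF well below the GM mode-search window.
#'
#' `gm_scale` and `wm_scale` are the linear scale factors of the GM and WM
#' ellipsoid surfaces relative to the outer brain surface; the defaults give
#' brain-volume fractions of roughly CSF 0.40, GM 0.34, WM 0.26 once the
#' central GM sphere is carved from the WM core. Setting
#' `gm_scale = 1` removes the CSF shell (a two-tissue calibration phantom).
#'
#' @param grid_shape Integer triple, default `c(64, 64, 64)`.
#' @param tissue_means Named intensities `c(csf=, gm=, wm=)`, strictly
#'   increasing.
#' @param tissue_sds Named non-negative SDs `c(csf=, gm=, wm=)`.
#' @param hypothalamus_radius_vox Radius (voxels) of the central GM sphere.
#' @param wm_shell_radius_vox Outer radius (voxels) of the surrounding WM
#'   shell; must exceed `hypothalamus_radius_vox` and fit inside the WM core.
#' @param gm_scale,wm_scale Surface scale factors, `0 < wm_scale < gm_scale <= 1`.
#' @param semiaxes_frac Outer-ellipsoid semi-axes as fractions of the
#'   half-grid.
#' @param voxel_size Voxel edge lengths in mm.
#' @param intensity_min,intensity_max Declared intensity range.
#' @param seed Integer seed driving the voxel noise.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         tissue_means = c(csf = 600, gm = 1907, wm = 3246),
                         tissue_sds = c(csf = 130.9, gm = 75.9, wm = 58.5),
                         hypothalamus_radius_vox = 8,
                         wm_shell_radius_vox = 12,
                         gm_scale = 0.843, wm_scale = 0.661,
                         semiaxes_frac = c(0.875, 0.8125, 0.75),
                         voxel_size = c(0.7, 0.7, 0.7),
                         intensity_min = 0, intensity_max = 4095,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L))
  tissue_means <- unlist(tissue_means)[c("csf", "gm", "wm")]
  tissue_sds <- unlist(tissue_sds)[c("csf", "gm", "wm")]
  if (anyNA(tissue_means) || anyNA(tissue_sds))
    stop("tissue_means and tissue_sds need entries csf, gm, wm")
  if (!(tissue_means["csf"] < tissue_means["gm"] &&
        tissue_means["gm"] < tissue_means["wm"]))
    stop("tissue means must be ordered CSF < GM < WM")
  if (any(tissue_sds < 0)) stop("tissue SDs must be non-negative")
  if (!(wm_scale > 0 && wm_scale < gm_scale && gm_scale <= 1))
    stop("need 0 < wm_scale < gm_scale <= 1")
  if (wm_shell_radius_vox <= hypothalamus_radius_vox)
    stop("wm_shell_radius_vox must exceed hypothalamus_radius_vox")
  semiaxes <- semiaxes_frac * grid_shape / 2
  if (wm_shell_radius_vox > wm_scale * min(semiaxes))
    stop("WM shell (radius ", wm_shell_radius_vox,
         " vox) does not fit inside the WM core (min semi-axis ",
         round(wm_scale * min(semiaxes), 1), " vox)")
  structure(list(grid_shape = grid_shape, tissue_means = tissue_means,
                 tissue_sds = tissue_sds,
                 hypothalamus_radius_vox = hypothalamus_radius_vox,
                 wm_shell_radius_vox = wm_shell_radius_vox,
                 gm_scale = gm_scale, wm_scale = wm_scale,
                 semiaxes = semiaxes, voxel_size = as.numeric(voxel_size),
                 intensity_min = intensity_min, intensity_max = intensity_max,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# squared normalised ellipsoid radius for every voxel
.ellipsoid_r2 <- function(grid_shape, centre, semiaxes) {
  u <- lapply(1:3, function(k) ((seq_len(grid_shape[k]) - centre[k]) / semiaxes[k])^2)
  r2 <- array(0, grid_shape)
  r2 <- r2 + u[[1]]
  r2 <- r2 + rep(u[[2]], each = grid_shape[1])
  r2 + rep(u[[3]], each = grid_shape[1] * grid_shape[2])
}

# squared Euclidean voxel distance from the grid centre
.centre_d2 <- function(grid_shape, centre) {
  u <- lapply(1:3, function(k) (seq_len(grid_shape[k]) - centre[k])^2)
  d2 <- array(0, grid_shape)
  d2 <- d2 + u[[1]]
  d2 <- d2 + rep(u[[2]], each = grid_shape[1])
  d2 + rep(u[[3]], each = grid_shape[1] * grid_shape[2])
}

#' Generate a synthetic brain phantom
#'
#' Builds the tissue geometry described in [phantom_spec()] and draws voxel
#' intensities from the per-tissue Gaussians. Bit-reproducible for a given
#' spec: the label map depends only on the geometry, the noise only on
#' `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `volume` ([intensity_volume()]) and `labels`
#'   ([tissue_label_map()], carrying the central-structure geometry needed by
#'   [phantom_rois()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  centre <- (gs + 1) / 2
  r2 <- .ellipsoid_r2(gs, centre, spec$semiaxes)
  lab <- array(TISSUE_CODES[["background"]], gs)
  lab[r2 <= 1] <- TISSUE_CODES[["csf"]]
  lab[r2 <= spec$gm_scale^2] <- TISSUE_CODES[["gm"]]
  lab[r2 <= spec$wm_scale^2] <- TISSUE_CODES[["wm"]]
  d2 <- .centre_d2(gs, centre)
  # central deep-GM sphere carved into the WM core
  lab[d2 <= spec$hypothalamus_radius_vox^2] <- TISSUE_CODES[["gm"]]

  labels <- tissue_label_map(lab, voxel_size = spec$voxel_size)
  labels$geometry <- list(centre = centre,
                          hypothalamus_radius_vox = spec$hypothalamus_radius_vox,
                          wm_shell_radius_vox = spec$wm_shell_radius_vox)

  data <- array(0, gs)
  brain <- lab != 0L
  tis <- lab[brain]
  set.seed(spec$seed)
  z <- stats::rnorm(sum(brain))
  data[brain] <- spec$tissue_means[tis] + spec$tissue_sds[tis] * z
  data <- pmin(pmax(data, spec$intensity_min), spec$intensity_max)
  dim(data) <- gs
  list(volume = intensity_volume(data, spec$intensity_min, spec$intensity_max,
                                 voxel_size = spec$voxel_size),
       labels = labels)
}

#' Extract the deep-GM and surrounding-WM ROI masks of a phantom
#'
#' The GM ROI is the central GM sphere; the WM ROI is the spherical WM shell
#' around it. Both are pure-tissue by construction, mirroring the cleaned
#' hypothalamic GM ROI / surrounding WM ROI used by ROI-based linear
#' standardisation.
#'
#' @param labels A [tissue_label_map()] produced by [generate_phantom()].
#' @return List with elements `gm` and `wm`, both [roi_mask()].
#' @export
phantom_rois <- function(labels) {
  stopifnot(inherits(labels, "tissue_label_map"))
  g <- labels$geometry
  if (is.null(g))
    stop("label map lacks the central phantom structures (not produced by generate_phantom)")
  if (g$wm_shell_radius_vox <= g$hypothalamus_radius_vox)
    stop("WM shell radius must exceed the GM sphere radius")
  d2 <- .centre_d2(dim(labels$labels), g$centre)
  gm_mask <- d2 <= g$hypothalamus_radius_vox^2
  wm_mask <- d2 > g$hypothalamus_radius_vox^2 & d2 <= g$wm_shell_radius_vox^2
  gm_mask <- gm_mask & labels$labels == TISSUE_CODES[["gm"]]
  wm_mask <- wm_mask & labels$labels == TISSUE_CODES[["wm"]]
  list(gm = roi_mask(gm_mask, "gm", labels$voxel_size),
       wm = roi_mask(wm_mask, "wm", labels$voxel_size))
}

#' Specify a known intensity distortion
#'
#' The distortion families model the interscan intensity variation that
#' standardisation is meant to undo: a global offset (over/underexposure), a
#' linear map `m*I + n` (exposure scaling with intensity), a tissue-wise
#' piecewise-linear map (tissue-specific over/underexposure), and a smooth
#' monotone nonlinearity (cubic through monotone control points). The
#' resulting map must be monotone non-decreasing on the intensity domain.
#'
#' @param kind One of `"identity"`, `"offset"`, `"linear"`,
#'   `"tissue_piecewise"`, `"smooth_nonlinear"`.
#' @param offset Offset `n` (kinds `offset`, `linear`).
#' @param slope Slope `m > 0` (kind `linear`).
#' @param anchors Two-column matrix of (input, output) pairs, inputs strictly
#'   increasing and outputs non-decreasing (kind `tissue_piecewise`; endpoints
#'   are added at the domain boundaries along the identity diagonal if absent).
#' @param control_points Two-column matrix of monotone control points (kind
#'   `smooth_nonlinear`); interpolated with a monotone (Hyman-filtered) cubic.
#' @param domain Intensity domain, default `c(0, 4095)`.
#' @return Object of class `distortion_spec`.
#' @export
distortion_spec <- function(kind = c("identity", "offset", "linear",
                                     "tissue_piecewise", "smooth_nonlinear"),
                            offset = 0, slope = 1, anchors = NULL,
                            control_points = NULL, domain = c(0, 4095)) {
  kind <- match.arg(kind)
  d <- structure(list(kind = kind, offset = offset, slope = slope,
                      anchors = anchors, control_points = control_points,
                      domain = domain),
                 class = "distortion_spec")
  if (kind == "linear" && slope <= 0)
    stop("linear distortion needs slope > 0 (monotone)")
  if (kind == "tissue_piecewise") {
    if (is.null(anchors) || ncol(anchors) != 2L)
      stop("tissue_piecewise needs a 2-column anchors matrix")
    a <- anchors[order(anchors[, 1]), , drop = FALSE]
    if (a[1, 1] > domain[1]) a <- rbind(c(domain[1], domain[1]), a)
    if (a[nrow(a), 1] < domain[2]) a <- rbind(a, c(domain[2], domain[2]))
    if (any(diff(a[, 1]) <= 0)) stop("anchor inputs must be strictly increasing")
    if (any(diff(a[, 2]) < 0)) stop("non-monotone anchor outputs")
    d$anchors <- a
  }
  if (kind == "smooth_nonlinear") {
    if (is.null(control_points) || ncol(control_points) != 2L)
      stop("smooth_nonlinear needs a 2-column control_points matrix")
    cp <- control_points[order(control_points[, 1]), , drop = FALSE]
    if (any(diff(cp[, 1]) <= 0) || any(diff(cp[, 2]) < 0))
      stop("control points must be monotone")
    # monotone interpolant: verify on a dense grid
    f <- stats::splinefun(cp[, 1], cp[, 2], method = "hyman")
    g <- seq(domain[1], domain[2], length.out = 2048L)
    if (any(diff(f(g)) < -1e-9)) stop("non-monotone distortion")
    d$control_points <- cp
  }
  d
}

.distortion_eval <- function(d, x) {
  y <- switch(d$kind,
    identity = x,
    offset = x + d$offset,
    linear = d$slope * x + d$offset,
    tissue_piecewise = stats::approx(d$anchors[, 1], d$anchors[, 2],
                                     xout = x, rule = 2)$y,
    smooth_nonlinear = stats::splinefun(d$control_points[, 1],
                                        d$control_points[, 2],
                                        method = "hyman")(x))
  pmin(pmax(y, d$domain[1]), d$domain[2])
}

#' Apply a known distortion to a volume
#'
#' Voxelwise remapping, clamped to the volume's declared intensity range;
#' the input volume is left untouched. Background voxels (exactly at the
#' declared minimum) are preserved: skull-stripping zeroes the background
#' after acquisition, so interscan distortions never show up there.
#'
#' @param vol An [intensity_volume()].
#' @param d A [distortion_spec()].
#' @return A new [intensity_volume()].
#' @export
apply_distortion <- function(vol, d) {
  stopifnot(inherits(vol, "intensity_volume"), inherits(d, "distortion_spec"))
  bg <- vol$data == vol$intensity_min
  out <- .distortion_eval(d, as.vector(vol$data))
  out <- pmin(pmax(out, vol$intensity_min), vol$intensity_max)
  out[bg] <- vol$intensity_min
  dim(out) <- dim(vol$data)
  intensity_volume(out, vol$intensity_min, vol$intensity_max, vol$voxel_size)
}

#' Generate a synthetic subject cohort with an imposed age effect
#'
#' Emulates the study design the evaluation protocol assumes: one
#' representative reference brain plus `n_subjects` target brains whose GM/WM
#' proportion varies with subject age (GM fraction declines linearly with
#' age, WM takes up the difference), and whose intensity scales are corrupted
#' by per-subject random linear distortions. The age-driven GM volume signal
#' is made strong (correlation around -0.9 before noise) so that its loss
#' under a standardisation method is unambiguous.
#'
#' @param n_subjects Number of target subjects (default 20).
#' @param grid_shape Phantom grid (default `c(48, 48, 48)`).
#' @param seed Integer seed; drives ages, geometry jitter, noise and
#'   distortions.
#' @param age_range Uniform age range in years (default 25--65).
#' @param gm_frac_base GM brain-volume fraction at the youngest age.
#' @param gm_frac_slope Change of GM fraction per year (default -0.003).
#' @param gm_frac_jitter SD of the per-subject GM-fraction jitter.
#' @param slope_range,offset_range Ranges of the per-subject linear
#'   distortion parameters.
#' @param tissue_sds Per-tissue noise SDs (set to 0 for noiseless cohorts).
#' @param extreme_targets If `TRUE`, subject ages are drawn from the outer
#'   30% tails of `age_range` only, mirroring the selection of targets with
#'   extreme tissue intensities/proportions.
#' @return List with `reference` (list: `volume`, `labels`) and `subjects`,
#'   a list of per-subject lists (`age`, `native`, `distorted`, `labels`,
#'   `distortion`, `gm_fraction`).
#' @export
generate_cohort <- function(n_subjects = 20L, grid_shape = c(48L, 48L, 48L),
                            seed = 1L, age_range = c(25, 65),
                            gm_frac_base = 0.40, gm_frac_slope = -0.003,
                            gm_frac_jitter = 0.012,
                            slope_range = c(0.9, 1.1),
                            offset_range = c(-150, 150),
                            tissue_sds = c(csf = 130.9, gm = 75.9, wm = 58.5),
                            extreme_targets = FALSE) {
  stopifnot(n_subjects >= 3L)
  gmin <- min(grid_shape)
  h_r <- max(2L, round(gmin / 8))
  s_r <- max(h_r + 2L, round(gmin * 3 / 16))
  gm_scale <- 0.843
  set.seed(seed)
  ages <- stats::runif(n_subjects, age_range[1], age_range[2])
  if (extreme_targets) {
    span <- diff(age_range)
    u <- stats::runif(n_subjects)
    ages <- ifelse(u < 0.5,
                   age_range[1] + u * 2 * 0.3 * span,
                   age_range[2] - (1 - u) * 2 * 0.3 * span)
  }
  f_gm <- gm_frac_base + gm_frac_slope * (ages - age_range[1]) +
    stats::rnorm(n_subjects, 0, gm_frac_jitter)
  f_gm <- pmin(pmax(f_gm, 0.15), gm_scale^3 - 0.12)
  ms <- stats::runif(n_subjects, slope_range[1], slope_range[2])
  ns <- stats::runif(n_subjects, offset_range[1], offset_range[2])
  sub_seeds <- sample.int(.Machine$integer.max %/% 2L, n_subjects + 1L)

  # the central GM sphere counts towards the GM fraction: subtract its share
  # of the brain volume before solving for the WM surface scale
  semiaxes <- c(0.875, 0.8125, 0.75) * grid_shape / 2
  hypo_frac <- (4 / 3) * pi * h_r^3 / ((4 / 3) * pi * prod(semiaxes))
  mk <- function(f_gm_i, seed_i) {
    wm_scale <- (gm_scale^3 - max(f_gm_i - hypo_frac, 0.05))^(1/3)
    sp <- phantom_spec(grid_shape = grid_shape, tissue_sds = tissue_sds,
                       hypothalamus_radius_vox = h_r, wm_shell_radius_vox = s_r,
                       gm_scale = gm_scale, wm_scale = wm_scale, seed = seed_i)
    generate_phantom(sp)
  }

  ref_fgm <- gm_frac_base + gm_frac_slope * diff(age_range) / 2
  reference <- mk(ref_fgm, sub_seeds[n_subjects + 1L])

  subjects <- lapply(seq_len(n_subjects), function(i) {
    ph <- mk(f_gm[i], sub_seeds[i])
    dst <- distortion_spec("linear", offset = ns[i], slope = ms[i])
    list(age = ages[i], native = ph$volume,
         distorted = apply_distortion(ph$volume, dst),
         labels = ph$labels, distortion = dst, gm_fraction = f_gm[i])
  })
  list(reference = reference, subjects = subjects)
}
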