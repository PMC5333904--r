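#' Absolute error between two cumulative distributions
#'
#' Compares tissue-specific cumulative probability distributions of a target
#' and a reference image over their shared intensity range (the intersection
#' of the two occupied supports). The average absolute error is a global
#' similarity measure; the maximum absolute error is a stricter, local one.
#' Cumulative distributions are used because plain histogram errors are
#' biased against techniques that produce empty levels or local voxel
#' pile-ups.
#'
#' @param target,reference [cumulative_distribution()] objects on the same
#'   level grid.
#' @return List: `average_abs_error`, `maximum_abs_error`, `shared_range`
#'   (`c(low, high)`).
#' @export
cdf_abs_error <- function(target, reference) {
  stopifnot(inherits(target, "cumulative_distribution"),
            inherits(reference, "cumulative_distribution"))
  if (!identical(target$levels, reference$levels))
    stop("CDFs are not on the same level grid")
  lo <- max(target$support[1], reference$support[1])
  hi <- min(target$support[2], reference$support[2])
  if (lo > hi) stop("empty shared intensity range")
  sel <- target$levels >= lo & target$levels <= hi
  err <- abs(target$P[sel] - reference$P[sel])
  list(average_abs_error = mean(err), maximum_abs_error = max(err),
       shared_range = c(lo, hi))
}

#' Average voxelwise intensity difference within a tissue
#'
#' Mean absolute intensity difference between a reference and a (grid
#' aligned) target volume over the voxels labelled as the given tissue in
#' BOTH label maps, optionally intersected with an ROI. Consensus labelling
#' avoids charging a method for disagreements in segmentation.
#'
#' @param reference,target [intensity_volume()]s on one grid.
#' @param ref_labels,tgt_labels [tissue_label_map()]s on the same grid.
#' @param tissue `"gm"` or `"wm"`.
#' @param roi Optional [roi_mask()].
#' @return Scalar mean absolute difference.
#' @export
voxelwise_intensity_difference <- function(reference, target, ref_labels,
                                           tgt_labels, tissue = c("gm", "wm"),
                                           roi = NULL) {
  tissue <- match.arg(tissue)
  assert_same_grid(reference, target, "reference and target")
  assert_same_grid(reference, ref_labels, "volume and reference labels")
  assert_same_grid(reference, tgt_labels, "volume and target labels")
  code <- TISSUE_CODES[[tissue]]
  sel <- ref_labels$labels == code & tgt_labels$labels == code
  if (!is.null(roi)) {
    assert_same_grid(reference, roi, "volume and ROI")
    sel <- sel & roi$mask
  }
  if (!any(sel)) stop("no voxels labelled ", toupper(tissue), " in both maps",
                      if (!is.null(roi)) " within the ROI" else "")
  mean(abs(reference$data[sel] - target$data[sel]))
}

#' Three-colour transfer function
#'
#' Piecewise-linear mapping from an intensity range to 8-bit RGB using three
#' colours: `colour_lo` at the low end, `colour_hi` at the high end, and an
#' adjustable intermediary colour (typically white) at
#' `lo + mid_fraction * (hi - lo)`. Moving the white point until it
#' highlights an anatomical boundary is how a rater reads off the boundary's
#' intensity.
#'
#' @param lo,hi Intensity range (`lo < hi`).
#' @param colour_lo,colour_mid,colour_hi RGB triples in 0--255.
#' @param mid_fraction Position of the intermediary colour in (0, 1).
#' @return Object of class `colour_map`.
#' @export
colour_map <- function(lo, hi, colour_lo = c(255, 0, 0),
                       colour_mid = c(255, 255, 255),
                       colour_hi = c(0, 0, 255), mid_fraction = 0.5) {
  if (lo >= hi) stop("lo must be < hi")
  if (!(mid_fraction > 0 && mid_fraction < 1))
    stop("mid_fraction must be in (0, 1)")
  for (cc in list(colour_lo, colour_mid, colour_hi))
    if (length(cc) != 3L || any(cc < 0) || any(cc > 255))
      stop("colours must be RGB triples in 0-255")
  structure(list(lo = lo, hi = hi, colour_lo = colour_lo,
                 colour_mid = colour_mid, colour_hi = colour_hi,
                 mid_fraction = mid_fraction),
            class = "colour_map")
}

#' T1-weighted preset: range (0, 4000), red -> white -> blue, white at 60%
#' (the boundary between hypothalamic GM and surrounding WM of a
#' representative reference image).
#' @rdname colour_map
#' @export
colour_map_t1w <- function() {
  colour_map(0, 4000, c(255, 0, 0), c(255, 255, 255), c(0, 0, 255), 0.60)
}

#' T1-map preset: range (950, 3700), blue -> white -> red, white at 40%
#' (comparable contrast for quantitative T1 maps).
#' @rdname colour_map
#' @export
colour_map_t1map <- function() {
  colour_map(950, 3700, c(0, 0, 255), c(255, 255, 255), c(255, 0, 0), 0.40)
}

#' Colour-code a volume
#'
#' Applies a [colour_map()] voxelwise: intensities are clamped to
#' `[lo, hi]`, mapped linearly `colour_lo -> colour_mid` below the white
#' point and `colour_mid -> colour_hi` above it.
#'
#' @param vol An [intensity_volume()].
#' @param cm A [colour_map()].
#' @return Integer array `dim(vol) x 3` with values in 0--255.
#' @export
colorize <- function(vol, cm) {
  stopifnot(inherits(vol, "intensity_volume"), inherits(cm, "colour_map"))
  x <- pmin(pmax(as.vector(vol$data), cm$lo), cm$hi)
  f <- (x - cm$lo) / (cm$hi - cm$lo)
  below <- f <= cm$mid_fraction
  t1 <- f / cm$mid_fraction
  t2 <- (f - cm$mid_fraction) / (1 - cm$mid_fraction)
  out <- array(0L, c(dim(vol$data), 3L))
  for (ch in 1:3) {
    v <- numeric(length(f))
    v[below] <- cm$colour_lo[ch] + t1[below] * (cm$colour_mid[ch] - cm$colour_lo[ch])
    v[!below] <- cm$colour_mid[ch] + t2[!below] * (cm$colour_hi[ch] - cm$colour_mid[ch])
    out[, , , ch] <- as.integer(round(pmin(pmax(v, 0), 255)))
  }
  out
}

#' Convert between white-point fraction and boundary intensity
#'
#' The rater's adjustable white point, expressed as a fraction of the colour
#' map's intensity range, corresponds to the boundary intensity
#' `lo + fraction * (hi - lo)`; these two helpers convert in both
#' directions.
#'
#' @param cm A [colour_map()].
#' @param fraction White-point position in (0, 1); defaults to the map's
#'   `mid_fraction`.
#' @return Intensity (`white_fraction_to_intensity`) or fraction
#'   (`intensity_to_white_fraction`).
#' @export
white_fraction_to_intensity <- function(cm, fraction = cm$mid_fraction) {
  stopifnot(inherits(cm, "colour_map"))
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  cm$lo + fraction * (cm$hi - cm$lo)
}

#' @rdname white_fraction_to_intensity
#' @param intensity Intensity inside the map's range.
#' @export
intensity_to_white_fraction <- function(cm, intensity) {
  stopifnot(inherits(cm, "colour_map"))
  f <- (intensity - cm$lo) / (cm$hi - cm$lo)
  if (any(f <= 0 | f >= 1)) stop("intensity outside the colour map's open range")
  f
}

#' Class-resolution matching error of a CHM transform
#'
#' For every intensity class of a cumulative-histogram-matching transform
#' that carries target mass, the absolute difference between the target's
#' cumulative frequency at the class's upper edge and the reference's
#' cumulative frequency at the assigned output level. The maximum over
#' classes quantifies how closely the matching equalised the two cumulative
#' distributions at class resolution.
#'
#' @param t A CHM [transform_function] from [build_chm()].
#' @param target_cdf,reference_cdf The [cumulative_distribution()]s the
#'   transform was built from.
#' @return List: `max_abs_error`, `average_abs_error`, `n_classes` (classes
#'   with target mass).
#' @export
chm_matching_error <- function(t, target_cdf, reference_cdf) {
  stopifnot(inherits(t, "transform_function"))
  if (t$method != "chm") stop("transform is not a CHM lookup table")
  n_lev <- length(target_cdf$levels)
  width <- n_lev / t$levels
  edge_idx <- pmin(n_lev, ceiling(seq_len(t$levels) * width))
  p_t <- target_cdf$P[edge_idx]
  class_mass <- diff(c(0, p_t))
  has_mass <- class_mass > 0
  p_r <- reference_cdf$P[match(t$lut, reference_cdf$levels)]
  err <- abs(p_t - p_r)[has_mass]
  list(max_abs_error = max(err), average_abs_error = mean(err),
       n_classes = sum(has_mass))
}

#' GM/WM interface boundary intensity
#'
#' An automated surrogate for the rater procedure, usable on phantoms with
#' known labels: the median intensity over interface voxels — GM voxels with
#' a face-adjacent WM neighbour and WM voxels with a face-adjacent GM
#' neighbour. After perfect standardisation this boundary intensity is the
#' same across subjects, so its spread over a cohort measures residual
#' interscan variation.
#'
#' @param vol An [intensity_volume()].
#' @param labels A [tissue_label_map()] on the same grid containing adjacent
#'   GM and WM voxels.
#' @return Scalar median interface intensity.
#' @export
interface_boundary_intensity <- function(vol, labels) {
  stopifnot(inherits(vol, "intensity_volume"), inherits(labels, "tissue_label_map"))
  assert_same_grid(vol, labels, "volume and label map")
  lab <- labels$labels
  gm <- lab == TISSUE_CODES[["gm"]]
  wm <- lab == TISSUE_CODES[["wm"]]
  d <- dim(lab)
  touches <- function(a, b) {
    out <- array(FALSE, d)
    out[-d[1], , ] <- out[-d[1], , ] | (a[-d[1], , ] & b[-1, , ])
    out[-1, , ]    <- out[-1, , ]    | (a[-1, , ]    & b[-d[1], , ])
    out[, -d[2], ] <- out[, -d[2], ] | (a[, -d[2], ] & b[, -1, ])
    out[, -1, ]    <- out[, -1, ]    | (a[, -1, ]    & b[, -d[2], ])
    out[, , -d[3]] <- out[, , -d[3]] | (a[, , -d[3]] & b[, , -1])
    out[, , -1]    <- out[, , -1]    | (a[, , -1]    & b[, , -d[3]])
    out
  }
  iface <- touches(gm, wm) | touches(wm, gm)
  if (!any(iface)) stop("label map has no GM/WM interface")
  stats::median(vol$data[iface])
}
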