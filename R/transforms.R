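#' Intensity transform objects
#'
#' All five standardisation techniques produce a `transform_function`: a
#' serialisable monotone mapping from target-image intensities to
#' reference-image intensities. The anchor-based methods (PHM, NHM, RLS, SPS)
#' store ordered (input, output) anchor pairs; cumulative histogram matching
#' stores a per-class lookup table. Evaluation clamps inputs and outputs to
#' the intensity domain.
#'
#' @name transform_function
NULL

new_transform <- function(method, anchors = NULL, lut = NULL, levels = NULL,
                          domain = c(0, 4095), monotone = TRUE) {
  structure(list(method = method, anchors = anchors, lut = lut,
                 levels = levels, domain = as.numeric(domain),
                 monotone = isTRUE(monotone)),
            class = "transform_function")
}

#' @export
print.transform_function <- function(x, ...) {
  cat("<transform_function> method:", toupper(x$method),
      " domain: [", x$domain[1], ",", x$domain[2], "]\n")
  if (!is.null(x$anchors)) {
    cat("  anchors:\n")
    print(round(x$anchors, 2))
  }
  if (!is.null(x$lut))
    cat("  lookup table:", x$levels, "classes\n")
  if (!x$monotone) cat("  note: monotonicity violated; outputs are clamped\n")
  invisible(x)
}

.check_modes <- function(modes, what, domain) {
  modes <- as.numeric(modes)
  if (length(modes) != 2L || anyNA(modes))
    stop(what, " must be two finite intensities (GM, WM)")
  if (!(domain[1] < modes[1] && modes[1] < modes[2] && modes[2] < domain[2]))
    stop(what, " must satisfy ", domain[1], " < GM < WM < ", domain[2],
         " (got ", modes[1], ", ", modes[2], ")")
  modes
}

#' Piecewise linear histogram matching (PHM)
#'
#' Linear interpolation between the minimum intensity, the GM and WM
#' histogram modes of target and reference, and the maximum intensity:
#' anchors (min,min), (GM_t,GM_r), (WM_t,WM_r), (max,max). The transform
#' bends at the two mode anchors and matches intensities linearly in
#' between.
#'
#' @param target_modes,reference_modes Numeric `(GM, WM)` mode intensities
#'   (or lists of `mode_estimate`s from [detect_modes()]).
#' @param domain Intensity domain, default `c(0, 4095)`.
#' @return A [transform_function].
#' @export
build_phm <- function(target_modes, reference_modes, domain = c(0, 4095)) {
  t <- .check_modes(.as_mode_pair(target_modes), "target modes", domain)
  r <- .check_modes(.as_mode_pair(reference_modes), "reference modes", domain)
  anchors <- cbind(input = c(domain[1], t[1], t[2], domain[2]),
                   output = c(domain[1], r[1], r[2], domain[2]))
  new_transform("phm", anchors = anchors, domain = domain)
}

.as_mode_pair <- function(m) {
  if (is.list(m) && !is.null(m$gm)) c(m$gm$intensity, m$wm$intensity) else m
}

#' Non-linear (spline) histogram matching (NHM)
#'
#' A smoothed variant of PHM: the two mode anchors are complemented by two
#' points on the identity diagonal one intensity unit inside each end of the
#' domain (to prevent overshoot), and an interpolating cubic spline is fitted
#' through the six points (min,min), (min+1,min+1), (GM_t,GM_r), (WM_t,WM_r),
#' (max-1,max-1), (max,max). Unlike PHM the mapping has a continuous first
#' derivative, avoiding artificial contrast at the anchor intensities.
#' Monotonicity is checked on a dense grid; violations produce a warning and
#' outputs are clamped to the domain on evaluation.
#'
#' @inheritParams build_phm
#' @return A [transform_function].
#' @export
build_nhm <- function(target_modes, reference_modes, domain = c(0, 4095)) {
  t <- .check_modes(.as_mode_pair(target_modes), "target modes", domain)
  r <- .check_modes(.as_mode_pair(reference_modes), "reference modes", domain)
  xi <- c(domain[1], domain[1] + 1, t[1], t[2], domain[2] - 1, domain[2])
  yi <- c(domain[1], domain[1] + 1, r[1], r[2], domain[2] - 1, domain[2])
  if (any(diff(xi) <= 0))
    stop("degenerate spline: anchor inputs coincide")
  anchors <- cbind(input = xi, output = yi)
  f <- stats::splinefun(xi, yi, method = "fmm")
  g <- seq(domain[1], domain[2], length.out = 4096L)
  monotone <- !any(diff(f(g)) < -1e-9)
  if (!monotone)
    warning("NHM spline is not monotone on the full domain; outputs will be clamped")
  new_transform("nhm", anchors = anchors, domain = domain, monotone = monotone)
}

#' Cumulative histogram matching (CHM)
#'
#' Matches all histogram percentiles at once: the intensity range is
#' partitioned into `levels` equal-width classes and each class is assigned
#' the reference intensity level whose relative cumulative frequency is
#' closest to the class's cumulative frequency in the target (ties to the
#' lowest qualifying level). The lookup table is forced non-decreasing,
#' conserving the order from black to white.
#'
#' @param target_cdf,reference_cdf [cumulative_distribution()] objects.
#' @param levels Number of intensity classes (default 1024).
#' @return A [transform_function] with a lookup table.
#' @export
build_chm <- function(target_cdf, reference_cdf, levels = 1024L) {
  stopifnot(inherits(target_cdf, "cumulative_distribution"),
            inherits(reference_cdf, "cumulative_distribution"))
  if (levels < 2L) stop("levels must be at least 2")
  domain <- range(target_cdf$levels)
  n_lev <- length(target_cdf$levels)
  width <- n_lev / levels
  # cumulative frequency of the target at each class's upper edge
  edge_idx <- pmin(n_lev, ceiling(seq_len(levels) * width))
  p_t <- target_cdf$P[edge_idx]
  # candidate outputs: occupied reference levels (strictly increasing P there)
  occ <- which(reference_cdf$counts > 0L)
  rl <- reference_cdf$levels[occ]
  rp <- reference_cdf$P[occ]
  i <- findInterval(p_t, rp)
  lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(rp))
  pick_hi <- abs(rp[hi] - p_t) < abs(rp[lo] - p_t)  # ties: keep the lower level
  lut <- ifelse(pick_hi, rl[hi], rl[lo])
  lut <- cummax(lut)
  new_transform("chm", lut = lut, levels = as.integer(levels), domain = domain)
}

#' ROI-based linear standardisation (RLS)
#'
#' The unique line mapping the target's GM-ROI and WM-ROI median intensities
#' onto the reference's: slope `m = (wm_ref - gm_ref) / (wm_t - gm_t)`,
#' offset `n = gm_ref - m * gm_t`, applied to the whole image and clamped to
#' the domain.
#'
#' @param med List or named vector with `gm_target`, `wm_target`,
#'   `gm_reference`, `wm_reference` median intensities.
#' @param domain Intensity domain.
#' @return A [transform_function].
#' @export
build_rls <- function(med, domain = c(0, 4095)) {
  med <- as.list(med)
  need <- c("gm_target", "wm_target", "gm_reference", "wm_reference")
  if (!all(need %in% names(med)))
    stop("med needs fields ", paste(need, collapse = ", "))
  if (med$wm_target == med$gm_target)
    stop("degenerate ROIs: target GM and WM medians are equal")
  if (med$wm_target < med$gm_target || med$wm_reference < med$gm_reference)
    stop("WM median must exceed GM median in both images")
  m <- (med$wm_reference - med$gm_reference) / (med$wm_target - med$gm_target)
  n <- med$gm_reference - m * med$gm_target
  anchors <- cbind(input = c(med$gm_target, med$wm_target),
                   output = c(med$gm_reference, med$wm_reference))
  tf <- new_transform("rls", anchors = anchors, domain = domain)
  tf$slope <- m; tf$offset <- n
  tf
}

#' Segmentation-based piecewise linear standardisation (SPS)
#'
#' Continuous piecewise-linear map anchored at the three tissue-mean
#' intensities: (min,min), (CSF_t,CSF_r), (GM_t,GM_r), (WM_t,WM_r),
#' (max,max). Tissue means come from a three-class segmentation of each
#' image, so the transform uses spatial as well as intensity information.
#'
#' @param target_means,reference_means Numeric `(CSF, GM, WM)` mean
#'   intensities, strictly increasing, inside the domain.
#' @param domain Intensity domain.
#' @return A [transform_function].
#' @export
build_sps <- function(target_means, reference_means, domain = c(0, 4095)) {
  t <- as.numeric(target_means); r <- as.numeric(reference_means)
  for (v in list(t, r))
    if (length(v) != 3L || any(diff(v) <= 0) || v[1] <= domain[1] || v[3] >= domain[2])
      stop("tissue means must be strictly increasing CSF < GM < WM inside the domain")
  anchors <- cbind(input = c(domain[1], t, domain[2]),
                   output = c(domain[1], r, domain[2]))
  new_transform("sps", anchors = anchors, domain = domain)
}

#' Identity transform
#' @param domain Intensity domain.
#' @return A [transform_function] mapping every intensity to itself.
#' @export
build_identity <- function(domain = c(0, 4095)) {
  new_transform("identity",
                anchors = cbind(input = domain, output = domain),
                domain = domain)
}

#' Evaluate a transform at intensity values
#'
#' @param t A [transform_function].
#' @param x Numeric intensities (clamped to the domain before evaluation;
#'   outputs are clamped after).
#' @return Numeric vector of mapped intensities.
#' @export
transform_value <- function(t, x) {
  stopifnot(inherits(t, "transform_function"))
  x <- pmin(pmax(x, t$domain[1]), t$domain[2])
  y <- switch(t$method,
    identity = x,
    phm = ,
    sps = stats::approx(t$anchors[, 1], t$anchors[, 2], xout = x, rule = 2)$y,
    nhm = stats::splinefun(t$anchors[, 1], t$anchors[, 2], method = "fmm")(x),
    rls = t$slope * x + t$offset,
    chm = {
      w <- (t$domain[2] - t$domain[1] + 1) / t$levels
      idx <- pmin(t$levels, floor((x - t$domain[1]) / w) + 1L)
      t$lut[idx]
    },
    stop("unknown transform method: ", t$method))
  pmin(pmax(y, t$domain[1]), t$domain[2])
}

#' Apply a transform to a volume
#'
#' Voxelwise evaluation of a standardisation transform. Background voxels
#' (exact minimum intensity) stay at the minimum: for anchor-based methods
#' this already follows from the (min, min) anchor, and the CHM lookup —
#' built from brain-only histograms — is likewise never allowed to move the
#' background.
#'
#' @param vol An [intensity_volume()].
#' @param t A [transform_function] whose domain equals the volume's declared
#'   range.
#' @return A new [intensity_volume()].
#' @export
apply_transform <- function(vol, t) {
  stopifnot(inherits(vol, "intensity_volume"))
  if (!isTRUE(all.equal(c(vol$intensity_min, vol$intensity_max), t$domain)))
    stop("transform domain [", t$domain[1], ", ", t$domain[2],
         "] does not match the volume's declared range")
  bg <- vol$data == vol$intensity_min
  out <- transform_value(t, as.vector(vol$data))
  out[bg] <- vol$intensity_min
  dim(out) <- dim(vol$data)
  intensity_volume(out, vol$intensity_min, vol$intensity_max, vol$voxel_size)
}

#' Serialise / deserialise a transform
#'
#' Lossless JSON round-trip of method, anchors or lookup table, and domain,
#' for audit trails alongside standardised outputs.
#'
#' @param t A [transform_function].
#' @return `serialize_transform`: a JSON string. `deserialize_transform`: a
#'   [transform_function].
#' @export
serialize_transform <- function(t) {
  stopifnot(inherits(t, "transform_function"))
  obj <- list(method = t$method, domain = t$domain, monotone = t$monotone)
  if (!is.null(t$anchors))
    obj$anchors <- list(input = t$anchors[, 1], output = t$anchors[, 2])
  if (!is.null(t$lut)) { obj$lut <- t$lut; obj$levels <- t$levels }
  if (!is.null(t$slope)) { obj$slope <- t$slope; obj$offset <- t$offset }
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}

#' @rdname serialize_transform
#' @param json JSON string produced by `serialize_transform`.
#' @export
deserialize_transform <- function(json) {
  obj <- tryCatch(jsonlite::fromJSON(json),
                  error = function(e) stop("malformed transform JSON: ",
                                           conditionMessage(e)))
  if (is.null(obj$method)) stop("transform JSON is missing the \"method\" field")
  if (is.null(obj$domain) || length(obj$domain) != 2L)
    stop("transform JSON is missing a valid \"domain\" field")
  t <- new_transform(obj$method, domain = obj$domain,
                     monotone = isTRUE(obj$monotone))
  if (!is.null(obj$anchors))
    t$anchors <- cbind(input = obj$anchors$input, output = obj$anchors$output)
  if (!is.null(obj$lut)) {
    if (is.null(obj$levels) || length(obj$lut) != obj$levels)
      stop("CHM lookup table length (", length(obj$lut),
           ") does not match declared levels (", obj$levels %||% "missing", ")")
    t$lut <- obj$lut; t$levels <- as.integer(obj$levels)
  }
  if (obj$method == "rls") {
    if (is.null(obj$slope)) stop("RLS transform JSON is missing slope/offset")
    t$slope <- obj$slope; t$offset <- obj$offset
  }
  if (obj$method %in% c("phm", "nhm", "sps", "rls", "identity") && is.null(t$anchors))
    stop("anchor-based transform JSON is missing anchors")
  if (obj$method == "chm" && is.null(t$lut))
    stop("CHM transform JSON is missing its lookup table")
  t
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a transform JSON file
#' @param t A [transform_function].
#' @param path File path.
#' @return `write_transform`: `path` invisibly; `read_transform`: a
#'   [transform_function].
#' @export
write_transform <- function(t, path) {
  writeLines(serialize_transform(t), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  deserialize_transform(paste(readLines(path, warn = FALSE), collapse = "\n"))
}
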