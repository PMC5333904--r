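#' Compute a unit-bin intensity histogram
#'
#' Counts voxels at each integer intensity level of the declared range (bin
#' width exactly one intensity unit; a value `v` falls in bin `floor(v)`).
#' The selection is either an ROI mask, or a tissue of a label map, or — with
#' no selection — all non-background voxels, background being exact-zero
#' voxels (the skull-stripped convention).
#'
#' @param vol An [intensity_volume()].
#' @param mask Optional [roi_mask()] on the same grid.
#' @param labels Optional [tissue_label_map()] on the same grid.
#' @param tissue With `labels`: `"csf"`, `"gm"` or `"wm"` selects that tissue;
#'   `NULL` selects all non-background voxels.
#' @return Object of class `intensity_histogram`: `levels` (integer grid from
#'   `intensity_min` to `intensity_max`), `counts`, `total`, and the occupied
#'   `support` range.
#' @export
compute_histogram <- function(vol, mask = NULL, labels = NULL, tissue = NULL) {
  stopifnot(inherits(vol, "intensity_volume"))
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "roi_mask"))
    assert_same_grid(vol, mask, "volume and mask")
    sel <- mask$mask
  } else if (!is.null(labels)) {
    stopifnot(inherits(labels, "tissue_label_map"))
    assert_same_grid(vol, labels, "volume and label map")
    sel <- if (is.null(tissue)) labels$labels != 0L
           else labels$labels == TISSUE_CODES[[match.arg(tissue, c("csf", "gm", "wm"))]]
  } else {
    sel <- vol$data != 0
  }
  v <- vol$data[sel]
  if (length(v) == 0L) stop("selection contains no voxels")
  lo <- vol$intensity_min; hi <- vol$intensity_max
  idx <- floor(pmin(pmax(v, lo), hi)) - lo + 1L
  nlev <- hi - lo + 1L
  counts <- tabulate(idx, nbins = nlev)
  occ <- which(counts > 0L)
  structure(list(levels = seq.int(lo, hi), counts = counts,
                 total = length(v),
                 support = c(lo + occ[1L] - 1L, lo + occ[length(occ)] - 1L)),
            class = "intensity_histogram")
}

# Robust local quadratic regression on an evenly spaced grid: tricube kernel
# over a fixed window, bisquare reweighting on Poisson-standardised residuals.
# The local fits reduce to rolling weighted sums, done via embed().
.rloess_grid <- function(y, span = 0.01, iterations = 5L) {
  n <- length(y)
  k <- max(7L, ceiling(span * n))
  if (k %% 2L == 0L) k <- k + 1L
  m <- (k - 1L) %/% 2L
  d <- seq(-m, m)
  K <- (1 - (abs(d) / (m + 1))^3)^3
  rw <- rep(1, n)
  ypad <- c(rep(NA_real_, m), y, rep(NA_real_, m))
  Yw <- t(embed(ypad, k))[k:1, , drop = FALSE]
  naY <- is.na(Yw)
  Y0 <- Yw; Y0[naY] <- 0
  fitted <- y
  for (it in seq_len(iterations + 1L)) {
    rpad <- c(rep(0, m), rw, rep(0, m))
    W <- t(embed(rpad, k))[k:1, , drop = FALSE] * K
    W[naY] <- 0
    s0 <- colSums(W);       s1 <- colSums(W * d);      s2 <- colSums(W * d^2)
    s3 <- colSums(W * d^3); s4 <- colSums(W * d^4)
    t0 <- colSums(W * Y0);  t1 <- colSums(W * d * Y0); t2 <- colSums(W * d^2 * Y0)
    det <- s0 * (s2 * s4 - s3 * s3) - s1 * (s1 * s4 - s3 * s2) +
           s2 * (s1 * s3 - s2 * s2)
    b0 <- (t0 * (s2 * s4 - s3 * s3) - s1 * (t1 * s4 - s3 * t2) +
           s2 * (t1 * s3 - s2 * t2)) / det
    bad <- !is.finite(b0)
    b0[bad] <- (t0 / s0)[bad]
    b0[!is.finite(b0)] <- y[!is.finite(b0)]
    fitted <- b0
    if (it > iterations) break
    res <- (y - fitted) / sqrt(pmax(fitted, 1))
    s <- 6 * stats::median(abs(res)[y > 0])
    if (!is.finite(s) || s <= .Machine$double.eps) break
    rw <- pmax(0, 1 - (res / s)^2)^2
  }
  fitted
}

#' Smooth a histogram with robust local regression
#'
#' Robust locally weighted quadratic regression (tricube kernel, bisquare
#' reweighting with a fixed iteration count) over the histogram counts, with
#' a span of `span_fraction` of the intensity levels of the declared range,
#' followed by cubic-spline parameterisation of the smoothed curve. The
#' bisquare residuals are standardised by the local Poisson scale so that
#' count noise at tall tissue peaks is not mistaken for outliers.
#'
#' @param h An [intensity_histogram()][compute_histogram].
#' @param span_fraction Local-regression span as a fraction of the number of
#'   intensity levels (default 0.01, i.e. a 41-level window on a 12-bit
#'   range).
#' @param iterations Robustness (bisquare) iterations, default 5.
#' @return Object of class `smoothed_density`: `grid` (intensity levels),
#'   `values` (smoothed counts), `support`, and `spline` (the interpolating
#'   cubic-spline function).
#' @export
smooth_histogram <- function(h, span_fraction = 0.01, iterations = 5L) {
  stopifnot(inherits(h, "intensity_histogram"))
  if (h$total <= 0L) stop("histogram is empty")
  if (!(span_fraction > 0 && span_fraction < 1))
    stop("span_fraction must be in (0, 1)")
  n <- length(h$levels)
  if (ceiling(span_fraction * n) < 6)
    stop("span too small: local quadratic fit underdetermined (< 6 points per window)")
  values <- .rloess_grid(as.numeric(h$counts), span = span_fraction,
                         iterations = iterations)
  spline <- stats::splinefun(h$levels, values, method = "fmm")
  structure(list(grid = h$levels, values = values, support = h$support,
                 spline = spline, total = h$total, counts = h$counts),
            class = "smoothed_density")
}

# local maxima of f on [lo, hi] at resolution `by`; returns (location, value)
.local_maxima <- function(f, lo, hi, by = 0.25) {
  g <- seq(lo, hi, by = by)
  if (length(g) < 3L) return(list(x = numeric(0), y = numeric(0)))
  v <- f(g)
  dm <- diff(v)
  idx <- which(dm[-length(dm)] > 0 & dm[-1] <= 0) + 1L
  list(x = g[idx], y = v[idx])
}

#' Detect the GM and WM histogram modes
#'
#' Skull-stripped MP2RAGE-like histograms are multimodal with distinct tissue
#' peaks; searching fixed intensity windows guarantees correct tissue
#' correspondence. Within each window, the mode is the intensity of the
#' highest local maximum of the spline-parameterised smoothed density (a
#' first-derivative zero-crossing with negative curvature). With
#' `from = "cdf"`, the spline is instead fitted to the cumulative histogram
#' and its derivative is searched — the second derivative's zero-crossings of
#' the cumulative curve are the density's extrema; both routes agree on
#' unimodal windows.
#'
#' @param d A [smooth_histogram()] result.
#' @param gm_window,wm_window Intensity windows `(low, high)` for the GM and
#'   WM peaks (defaults `c(1000, 2500)` and `c(3000, 3500)`).
#' @param from `"density"` (default) or `"cdf"`.
#' @return List with elements `gm` and `wm`, each a `mode_estimate` (fields
#'   `tissue`, `intensity`, `window`).
#' @export
detect_modes <- function(d, gm_window = c(1000, 2500), wm_window = c(3000, 3500),
                         from = c("density", "cdf")) {
  stopifnot(inherits(d, "smoothed_density"))
  from <- match.arg(from)
  f <- if (from == "density") d$spline else {
    cdf <- cumsum(d$counts) / d$total
    cs <- stats::splinefun(d$grid, cdf, method = "fmm")
    function(x) cs(x, deriv = 1L)
  }
  one <- function(win, tissue) {
    lo <- max(win[1], d$support[1]); hi <- min(win[2], d$support[2])
    if (lo > hi) stop("window (", win[1], ", ", win[2],
                      ") lies outside the histogram support")
    occ_in <- d$grid[d$counts > 0 & d$grid >= lo & d$grid <= hi]
    if (length(occ_in) == 1L) {
      # all window mass at a single level: that level is the mode
      return(structure(list(tissue = tissue, intensity = occ_in, window = win),
                       class = "mode_estimate"))
    }
    mx <- .local_maxima(f, lo, hi)
    keep <- mx$y > 0
    if (!any(keep)) stop("no mode in window (", win[1], ", ", win[2], ")")
    x <- mx$x[keep]; y <- mx$y[keep]
    best <- which(y >= max(y) - 1e-12)[1L]  # ties: lower intensity
    structure(list(tissue = tissue, intensity = x[best], window = win),
              class = "mode_estimate")
  }
  list(gm = one(gm_window, "gm"), wm = one(wm_window, "wm"))
}

#' Cumulative distribution of a histogram
#'
#' Relative cumulative frequencies `P(level) = #(voxels <= level) / total` on
#' the integer level grid.
#'
#' @param h An [intensity_histogram()][compute_histogram].
#' @return Object of class `cumulative_distribution`: `levels`, `P`
#'   (non-decreasing, final value 1), `counts`, `total`, `support`.
#' @export
cumulative_distribution <- function(h) {
  stopifnot(inherits(h, "intensity_histogram"))
  if (h$total <= 0L) stop("histogram is empty")
  structure(list(levels = h$levels, P = cumsum(h$counts) / h$total,
                 counts = h$counts, total = h$total, support = h$support),
            class = "cumulative_distribution")
}
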