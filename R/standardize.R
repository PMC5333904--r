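#' Standardise a target volume to a reference
#'
#' One-call driver around the five transform builders: derives whatever each
#' method needs (histogram modes for PHM/NHM, cumulative distributions for
#' CHM, cleaned ROI medians for RLS, tissue means for SPS) and returns the
#' standardised volume together with the fitted transform. Label maps are
#' obtained by fuzzy c-means segmentation when not supplied; RLS additionally
#' needs GM/WM ROI masks for both images.
#'
#' @param target,reference [intensity_volume()]s with the same declared
#'   intensity range (grids may differ except where ROIs/labels tie them).
#' @param method One of `"phm"`, `"nhm"`, `"chm"`, `"rls"`, `"sps"`,
#'   `"identity"`.
#' @param target_labels,reference_labels Optional [tissue_label_map()]s; if
#'   missing, computed by [fuzzy_segment()] + [hard_labels()].
#' @param target_rois,reference_rois For RLS: lists with elements `gm` and
#'   `wm` ([roi_mask()]s), e.g. from [phantom_rois()]. Cleaned against the
#'   label maps before taking medians.
#' @param span_fraction,gm_window,wm_window Histogram smoothing and
#'   mode-search settings for PHM/NHM.
#' @param levels CHM class count (default 1024).
#' @param clean_floor Minimum surviving ROI voxel count for RLS.
#' @return List: `volume` (standardised [intensity_volume()]), `transform`
#'   (a [transform_function]).
#' @export
standardize_volume <- function(target, reference,
                               method = c("phm", "nhm", "chm", "rls", "sps",
                                          "identity"),
                               target_labels = NULL, reference_labels = NULL,
                               target_rois = NULL, reference_rois = NULL,
                               span_fraction = 0.01,
                               gm_window = c(1000, 2500),
                               wm_window = c(3000, 3500),
                               levels = 1024L, clean_floor = 100L) {
  method <- match.arg(method)
  stopifnot(inherits(target, "intensity_volume"),
            inherits(reference, "intensity_volume"))
  domain <- c(target$intensity_min, target$intensity_max)
  seg <- function(vol, labels) {
    if (!is.null(labels)) labels else hard_labels(fuzzy_segment(vol))
  }
  tf <- switch(method,
    identity = build_identity(domain),
    phm = ,
    nhm = {
      modes_of <- function(vol, labels) {
        h <- if (is.null(labels)) compute_histogram(vol)
             else compute_histogram(vol, labels = labels)
        detect_modes(smooth_histogram(h, span_fraction),
                     gm_window = gm_window, wm_window = wm_window)
      }
      mt <- modes_of(target, target_labels)
      mr <- modes_of(reference, reference_labels)
      if (method == "phm") build_phm(mt, mr, domain) else build_nhm(mt, mr, domain)
    },
    chm = {
      cdf_of <- function(vol, labels) {
        h <- if (is.null(labels)) compute_histogram(vol)
             else compute_histogram(vol, labels = labels)
        cumulative_distribution(h)
      }
      build_chm(cdf_of(target, target_labels), cdf_of(reference, reference_labels),
                levels = levels)
    },
    rls = {
      if (is.null(target_rois) || is.null(reference_rois))
        stop("RLS needs GM/WM ROI masks for both target and reference")
      tl <- seg(target, target_labels); rl <- seg(reference, reference_labels)
      med <- function(vol, roi, labels) {
        stats::median(vol$data[clean_roi(roi, labels, clean_floor)$mask])
      }
      build_rls(list(
        gm_target = med(target, target_rois$gm, tl),
        wm_target = med(target, target_rois$wm, tl),
        gm_reference = med(reference, reference_rois$gm, rl),
        wm_reference = med(reference, reference_rois$wm, rl)), domain)
    },
    sps = {
      tl <- seg(target, target_labels); rl <- seg(reference, reference_labels)
      mt <- tissue_stats(target, tl)$mean
      mr <- tissue_stats(reference, rl)$mean
      build_sps(mt, mr, domain)
    })
  list(volume = apply_transform(target, tf), transform = tf)
}
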