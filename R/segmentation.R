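#' Three-class fuzzy c-means tissue segmentation
#'
#' Segments a skull-stripped brain volume into CSF, GM and WM by fuzzy
#' c-means clustering of voxel intensities. Initialisation is deterministic
#' (class centroids at the 10th/50th/90th intensity percentiles of the brain
#' voxels), convergence is declared when the maximum centroid movement falls
#' below `tol` or after `max_iter` iterations. The per-voxel memberships are
#' the standard FCM closed form and sum to one at every brain voxel. An
#' optional spatial regularisation averages each membership map with its
#' 6-neighbourhood mean and renormalises, which suppresses isolated
#' misclassified voxels.
#'
#' Because clustering uses intensities only and all quantities are affine
#' equivariant, applying `m*I + n` (m > 0) to the volume maps the centroids
#' by the same line and leaves the hard labels unchanged.
#'
#' @param vol An [intensity_volume()].
#' @param brain_mask Optional [roi_mask()]-like logical selection of brain
#'   voxels; by default, brain = exact non-zero voxels (skull-stripped
#'   convention).
#' @param fuzziness FCM fuzziness exponent (default 2).
#' @param smoothing_weight Weight in \[0, 1) of the spatial membership
#'   smoothing (default 0 = off).
#' @param tol Centroid-movement convergence threshold (default 1e-3).
#' @param max_iter Iteration cap (default 200); hitting it issues a warning
#'   and returns the partial result flagged `converged = FALSE`.
#' @return Object of class `fuzzy_membership`: `memberships` (list of three
#'   3D arrays `csf`, `gm`, `wm`, zero outside the brain), `centroids`
#'   (named, strictly increasing), `mask`, `converged`, `iterations`.
#' @export
fuzzy_segment <- function(vol, brain_mask = NULL, fuzziness = 2,
                          smoothing_weight = 0, tol = 1e-3, max_iter = 200L) {
  stopifnot(inherits(vol, "intensity_volume"))
  mask <- if (is.null(brain_mask)) vol$data != 0 else {
    m <- if (inherits(brain_mask, "roi_mask")) brain_mask$mask else brain_mask
    assert_same_grid(vol, m, "volume and brain mask")
    m
  }
  x <- vol$data[mask]
  if (length(unique(x)) < 3L)
    stop("brain contains fewer than 3 distinct intensity values; cannot fit 3 classes")
  if (!(smoothing_weight >= 0 && smoothing_weight < 1))
    stop("smoothing_weight must be in [0, 1)")
  cen <- as.numeric(stats::quantile(x, c(0.1, 0.5, 0.9)))
  p <- 2 / (fuzziness - 1)
  U <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    D <- abs(outer(x, cen, "-"))
    D[D < 1e-12] <- 1e-12
    iD <- D^(-p)
    U <- iD / rowSums(iD)
    Um <- U^fuzziness
    new_cen <- colSums(Um * x) / colSums(Um)
    moved <- max(abs(new_cen - cen))
    cen <- new_cen
    if (moved < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("fuzzy c-means did not converge within ", max_iter,
            " iterations (max centroid movement still >= ", tol, ")")
  ord <- order(cen)
  cen <- cen[ord]; U <- U[, ord, drop = FALSE]
  names(cen) <- c("csf", "gm", "wm")

  gs <- dim(vol$data)
  memberships <- lapply(1:3, function(k) {
    a <- array(0, gs); a[mask] <- U[, k]; a
  })
  names(memberships) <- c("csf", "gm", "wm")

  if (smoothing_weight > 0) {
    memberships <- lapply(memberships, function(a) {
      (1 - smoothing_weight) * a + smoothing_weight * .neighbour_mean(a)
    })
    tot <- memberships$csf + memberships$gm + memberships$wm
    tot[!mask] <- 1
    memberships <- lapply(memberships, function(a) { a[mask] <- a[mask] / tot[mask]; a })
  }

  structure(list(memberships = memberships, centroids = cen, mask = mask,
                 converged = converged, iterations = it,
                 voxel_size = vol$voxel_size),
            class = "fuzzy_membership")
}

# mean over the 6-connected neighbourhood (edge voxels use available neighbours)
.neighbour_mean <- function(a) {
  d <- dim(a)
  s <- array(0, d); n <- array(0, d)
  ix <- seq_len(d[1]); iy <- seq_len(d[2]); iz <- seq_len(d[3])
  add <- function(src_i, src_j, src_k, dst_i, dst_j, dst_k) {
    s[dst_i, dst_j, dst_k] <<- s[dst_i, dst_j, dst_k] + a[src_i, src_j, src_k]
    n[dst_i, dst_j, dst_k] <<- n[dst_i, dst_j, dst_k] + 1
  }
  add(ix[-1], iy, iz, ix[-d[1]], iy, iz); add(ix[-d[1]], iy, iz, ix[-1], iy, iz)
  add(ix, iy[-1], iz, ix, iy[-d[2]], iz); add(ix, iy[-d[2]], iz, ix, iy[-1], iz)
  add(ix, iy, iz[-1], ix, iy, iz[-d[3]]); add(ix, iy, iz[-d[3]], ix, iy, iz[-1])
  s / n
}

#' Hard labels from fuzzy memberships
#'
#' Assigns each brain voxel the class of maximal membership; exact ties go to
#' the lower-intensity class. Voxels outside the brain mask get label 0.
#'
#' @param f A [fuzzy_segment()] result.
#' @return A [tissue_label_map()].
#' @export
hard_labels <- function(f) {
  stopifnot(inherits(f, "fuzzy_membership"))
  M <- cbind(csf = f$memberships$csf[f$mask],
             gm = f$memberships$gm[f$mask],
             wm = f$memberships$wm[f$mask])
  cls <- max.col(M, ties.method = "first")  # column order = increasing intensity
  lab <- array(0L, dim(f$memberships$csf))
  lab[f$mask] <- cls
  tissue_label_map(lab, voxel_size = f$voxel_size)
}

#' Per-tissue intensity and volume statistics
#'
#' @param vol An [intensity_volume()].
#' @param labels A [tissue_label_map()] on the same grid.
#' @return Data frame with one row per tissue (`csf`, `gm`, `wm`): mean and
#'   median intensity, voxel count, and volume in mm^3 (count times voxel
#'   volume). Tissues with no voxels get `NA` statistics and `present =
#'   FALSE`.
#' @export
tissue_stats <- function(vol, labels) {
  stopifnot(inherits(vol, "intensity_volume"), inherits(labels, "tissue_label_map"))
  assert_same_grid(vol, labels, "volume and label map")
  vox_mm3 <- prod(labels$voxel_size)
  rows <- lapply(c("csf", "gm", "wm"), function(t) {
    v <- vol$data[labels$labels == TISSUE_CODES[[t]]]
    n <- length(v)
    data.frame(tissue = t,
               mean = if (n) mean(v) else NA_real_,
               median = if (n) stats::median(v) else NA_real_,
               n_voxels = n,
               volume_mm3 = n * vox_mm3,
               present = n > 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Restrict an ROI to its intended tissue
#'
#' Removes voxels whose hard segmentation label differs from the ROI's tissue
#' tag (e.g. CSF or vessel voxels inside a GM ROI). Reliable ROI medians need
#' enough voxels — on the order of 2000 for a deep-GM structure — so an error
#' is raised when fewer than `floor` voxels survive.
#'
#' @param roi An [roi_mask()].
#' @param labels A [tissue_label_map()] on the same grid.
#' @param floor Minimum surviving voxel count (default 100).
#' @return A cleaned [roi_mask()].
#' @export
clean_roi <- function(roi, labels, floor = 100L) {
  stopifnot(inherits(roi, "roi_mask"), inherits(labels, "tissue_label_map"))
  assert_same_grid(roi, labels, "ROI and label map")
  keep <- roi$mask & labels$labels == TISSUE_CODES[[roi$tissue]]
  n <- sum(keep)
  if (n < floor)
    stop("only ", n, " ", toupper(roi$tissue), " voxels survive ROI cleaning ",
         "(floor ", floor, "); ROI medians need on the order of 2000 voxels ",
         "to be reliable")
  roi_mask(keep, roi$tissue, roi$voxel_size)
}
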