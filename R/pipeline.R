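#' Default benchmark configuration
#'
#' A benchmark run generates one reference phantom plus `n_targets` copies
#' with fresh voxel noise and per-target intensity distortions, standardises
#' every target with every requested method, and evaluates the results at
#' the histogram, whole-image and boundary levels.
#'
#' @param out_dir Output directory for reports (created on run).
#' @return Named list of configuration values.
#' @export
default_config <- function(out_dir = "mristand-benchmark") {
  list(
    grid_shape = c(48L, 48L, 48L),
    n_targets = 5L,
    methods = c("phm", "nhm", "chm", "rls", "sps"),
    seed = 1L,
    intensity_min = 0, intensity_max = 4095,
    tissue_sds = c(csf = 130.9, gm = 75.9, wm = 58.5),
    slope_range = c(0.9, 1.1),
    offset_range = c(-150, 150),
    gm_window = c(1000, 2500),
    wm_window = c(3000, 3500),
    span_fraction = 0.01,
    chm_levels = 1024L,
    quantize = FALSE,
    out_dir = out_dir
  )
}

#' Read a benchmark configuration from YAML
#'
#' Keys missing from the file keep their [default_config()] values.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (k in names(user)) cfg[[k]] <- user[[k]]
  cfg$grid_shape <- as.integer(cfg$grid_shape)
  cfg$n_targets <- as.integer(cfg$n_targets)
  cfg$seed <- as.integer(cfg$seed)
  tsd <- unlist(cfg$tissue_sds)
  if (is.null(names(tsd)) || !all(c("csf", "gm", "wm") %in% names(tsd)))
    names(tsd) <- c("csf", "gm", "wm")[seq_along(tsd)]
  cfg$tissue_sds <- tsd
  cfg
}

#' Validate a benchmark configuration
#'
#' Never mutates state; returns a character vector of human-readable issues
#' (empty when the configuration is valid).
#'
#' @param cfg Configuration list (see [default_config()]).
#' @return Character vector of issues.
#' @export
validate_config <- function(cfg) {
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)
  known <- c("phm", "nhm", "chm", "rls", "sps", "identity")
  if (is.null(cfg$methods) || !length(cfg$methods))
    add("no standardisation methods requested")
  else if (!all(cfg$methods %in% known))
    add(paste0("unknown methods: ",
               paste(setdiff(cfg$methods, known), collapse = ", ")))
  if (is.null(cfg$n_targets) || cfg$n_targets < 1)
    add("n_targets must be at least 1")
  if (is.null(cfg$grid_shape) || length(cfg$grid_shape) != 3L ||
      any(cfg$grid_shape < 16L))
    add("grid_shape must be three integers >= 16")
  if (!is.null(cfg$intensity_min) && !is.null(cfg$intensity_max) &&
      cfg$intensity_min >= cfg$intensity_max)
    add("intensity_min must be < intensity_max")
  if (!is.null(cfg$gm_window) && !is.null(cfg$wm_window) &&
      cfg$gm_window[2] >= cfg$wm_window[1])
    add("GM mode window must lie entirely below the WM window")
  if (!is.null(cfg$reference_path) && !file.exists(cfg$reference_path))
    add(paste0("reference path does not exist: ", cfg$reference_path))
  if (is.null(cfg$seed)) add("seed is required for a reproducible run")
  if (is.null(cfg$out_dir)) add("out_dir is required")
  issues
}

#' Run the phantom benchmark
#'
#' Generates one reference phantom and `n_targets` targets (same geometry,
#' fresh voxel noise, per-target random linear distortion), standardises
#' every target with every configured method, and writes to `cfg$out_dir`:
#' `metrics.csv` (one row per target x method x region x metric, native
#' values included), `tests.csv` (Wilcoxon signed-rank comparisons of native
#' vs standardised errors across targets, when `n_targets >= 5`),
#' `transforms/` (per target x method transform JSON) and `manifest.json`
#' (config and seeds). Reruns with the same config are byte-identical.
#'
#' @param cfg Configuration list; see [default_config()] and
#'   [validate_config()].
#' @return Invisibly, a list with `metrics` and `tests` data frames and the
#'   output directory.
#' @export
run_benchmark <- function(cfg = default_config()) {
  issues <- validate_config(cfg)
  if (length(issues))
    stop("invalid configuration:\n  - ", paste(issues, collapse = "\n  - "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(cfg$out_dir, "transforms"), showWarnings = FALSE)

  stage <- "phantom generation"
  result <- tryCatch({
    gmin <- min(cfg$grid_shape)
    base_spec <- function(seed) phantom_spec(
      grid_shape = cfg$grid_shape, tissue_sds = cfg$tissue_sds,
      hypothalamus_radius_vox = max(2L, round(gmin / 8)),
      wm_shell_radius_vox = max(4L, round(gmin * 3 / 16)),
      intensity_min = cfg$intensity_min, intensity_max = cfg$intensity_max,
      seed = seed)
    set.seed(cfg$seed)
    seeds <- sample.int(.Machine$integer.max %/% 2L, cfg$n_targets + 1L)
    ms <- stats::runif(cfg$n_targets, cfg$slope_range[1], cfg$slope_range[2])
    ns <- stats::runif(cfg$n_targets, cfg$offset_range[1], cfg$offset_range[2])

    ref <- generate_phantom(base_spec(seeds[cfg$n_targets + 1L]))
    ref_rois <- phantom_rois(ref$labels)
    ref_seg <- hard_labels(fuzzy_segment(ref$volume))
    ref_gm_cdf <- cumulative_distribution(
      compute_histogram(ref$volume, labels = ref_seg, tissue = "gm"))
    ref_wm_cdf <- cumulative_distribution(
      compute_histogram(ref$volume, labels = ref_seg, tissue = "wm"))

    metrics <- list()
    emit <- function(target, method, region, metric, value)
      metrics[[length(metrics) + 1L]] <<- data.frame(
        target = target, method = method, region = region, metric = metric,
        value = value, stringsAsFactors = FALSE)

    eval_volume <- function(vol, labels, target_id, method) {
      for (tis in c("gm", "wm")) {
        cdf <- cumulative_distribution(
          compute_histogram(vol, labels = labels, tissue = tis))
        ref_cdf <- if (tis == "gm") ref_gm_cdf else ref_wm_cdf
        # degenerate (e.g. noiseless) histograms can have disjoint supports
        e <- tryCatch(cdf_abs_error(cdf, ref_cdf),
                      error = function(err) list(average_abs_error = NA_real_,
                                                 maximum_abs_error = NA_real_))
        emit(target_id, method, paste0("whole_brain_", tis),
             "cdf_average_abs_error", e$average_abs_error)
        emit(target_id, method, paste0("whole_brain_", tis),
             "cdf_maximum_abs_error", e$maximum_abs_error)
        emit(target_id, method, paste0("whole_brain_", tis),
             "voxelwise_abs_difference",
             voxelwise_intensity_difference(ref$volume, vol, ref_seg, labels, tis))
      }
      emit(target_id, method, "hypothalamus_interface", "boundary_intensity",
           interface_boundary_intensity(vol, labels))
    }

    for (i in seq_len(cfg$n_targets)) {
      stage <- paste0("target ", i)
      ph <- generate_phantom(base_spec(seeds[i]))
      dst <- distortion_spec("linear", offset = ns[i], slope = ms[i])
      tgt <- apply_distortion(ph$volume, dst)
      tgt_rois <- phantom_rois(ph$labels)
      tgt_seg <- hard_labels(fuzzy_segment(tgt))
      eval_volume(tgt, tgt_seg, i, "native")
      for (m in cfg$methods) {
        stage <- paste0("target ", i, ", method ", m)
        std <- standardize_volume(tgt, ref$volume, method = m,
                                  target_labels = tgt_seg,
                                  reference_labels = ref_seg,
                                  target_rois = tgt_rois,
                                  reference_rois = ref_rois,
                                  span_fraction = cfg$span_fraction,
                                  gm_window = cfg$gm_window,
                                  wm_window = cfg$wm_window,
                                  levels = cfg$chm_levels)
        out_vol <- std$volume
        if (isTRUE(cfg$quantize))
          out_vol$data <- pmin(pmax(round(out_vol$data), cfg$intensity_min),
                               cfg$intensity_max)
        std_seg <- hard_labels(fuzzy_segment(out_vol))
        eval_volume(out_vol, std_seg, i, m)
        write_transform(std$transform,
                        file.path(cfg$out_dir, "transforms",
                                  sprintf("target%02d_%s.json", i, m)))
      }
    }
    metrics <- do.call(rbind, metrics)

    stage <- "summary statistics"
    tests <- NULL
    if (cfg$n_targets >= 5L) {
      rows <- list()
      for (m in setdiff(unique(metrics$method), "native"))
        for (reg in unique(metrics$region))
          for (met in unique(metrics$metric[metrics$region == reg])) {
            if (met == "boundary_intensity") next
            nat <- metrics$value[metrics$method == "native" &
                                 metrics$region == reg & metrics$metric == met]
            val <- metrics$value[metrics$method == m &
                                 metrics$region == reg & metrics$metric == met]
            wt <- tryCatch(wilcoxon_signed_rank(nat, val), error = function(e) NULL)
            if (is.null(wt)) next
            rows[[length(rows) + 1L]] <- data.frame(
              method = m, region = reg, metric = met,
              median_native = stats::median(nat), median_standardised = stats::median(val),
              Z = wt$statistic, p = wt$p_two_tailed, r = wt$effect_size,
              stringsAsFactors = FALSE)
          }
      tests <- do.call(rbind, rows)
    }

    utils::write.csv(metrics, file.path(cfg$out_dir, "metrics.csv"),
                     row.names = FALSE)
    if (!is.null(tests))
      utils::write.csv(tests, file.path(cfg$out_dir, "tests.csv"),
                       row.names = FALSE)
    manifest <- list(package = "mristand",
                     version = as.character(utils::packageVersion("mristand")),
                     seed = cfg$seed, phantom_seeds = seeds,
                     distortion_slopes = ms, distortion_offsets = ns,
                     config = cfg[setdiff(names(cfg), "out_dir")])
    writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                             digits = NA, pretty = TRUE)),
               file.path(cfg$out_dir, "manifest.json"))
    list(metrics = metrics, tests = tests, out_dir = cfg$out_dir)
  }, error = function(e) {
    stop("benchmark failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
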