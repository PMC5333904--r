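# Shared fixtures, built once per test run.

# small default phantom (64^3, seed 1) used by several files
.fx <- new.env(parent = emptyenv())

fx_phantom <- function() {
  if (is.null(.fx$phantom))
    .fx$phantom <- generate_phantom(phantom_spec(seed = 1))
  .fx$phantom
}

# noiseless variant: every tissue voxel exactly at its mean
fx_phantom_noiseless <- function() {
  if (is.null(.fx$noiseless))
    .fx$noiseless <- generate_phantom(
      phantom_spec(tissue_sds = c(csf = 0, gm = 0, wm = 0), seed = 1))
  .fx$noiseless
}

# a tiny volume from a numeric vector/array, for arithmetic-level tests
tiny_volume <- function(values, dims = c(length(values), 1, 1), ...) {
  intensity_volume(array(values, dim = dims), ...)
}

# label map matching tiny_volume layout
tiny_labels <- function(codes, dims = c(length(codes), 1, 1), ...) {
  tissue_label_map(array(as.integer(codes), dim = dims), ...)
}

# deterministic near-ideal Gaussian sample: stratified inverse-CDF draws
strat_norm <- function(n, mean, sd) stats::qnorm(stats::ppoints(n), mean, sd)
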