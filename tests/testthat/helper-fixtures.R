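# Shared fixture builders. Smaller grids than the package defaults keep the
# suite fast; geometry proportions stay the same.

test_spec <- function(...) {
  args <- list(...)
  defaults <- list(grid_size = 96L, pixel_spacing = 1.5, endo_radius = 20,
                   epi_radius = 30, infarct_extent = 120, seed = 1L)
  do.call(phantom_spec, utils::modifyList(defaults, args))
}

# Polar map + largest-arc midpoint ROI for a slice.
mid_remote_roi <- function(slice, width = 45, rim_fraction = 0.15) {
  polar <- polar_parameterize(slice$endo_contour, slice$epi_contour, slice$myo_mask)
  arcs <- remote_arcs(slice$truth_infarct_mask, polar)
  sz <- candidate_sizes(arcs, width)
  stopifnot(nrow(sz) >= 1)
  list(polar = polar, arcs = arcs,
       roi = sector_roi(polar, sz$center_angle[1], width, rim_fraction))
}

# Synthetic bin-exact polar map: one "pixel" column per 1-degree bin, four
# transmural rows. Lets inclusion-filter boundaries be tested exactly,
# without rasterization holes.
bin_polar <- function(n_rows = 4L) {
  theta <- matrix(rep(0:359 + 0.5, each = n_rows), n_rows, 360)
  depth <- matrix(rep(seq(0, 1, length.out = n_rows), times = 360), n_rows, 360)
  myo <- matrix(TRUE, n_rows, 360)
  structure(list(theta = theta, depth = depth, myo_mask = myo, centroid = c(0, 0)),
            class = "polar_map")
}

# Truth mask on a bin_polar grid from a list of [start, end) degree intervals.
bin_truth <- function(intervals, n_rows = 4L) {
  m <- matrix(FALSE, n_rows, 360)
  for (iv in intervals) {
    cols <- which((0:359 + 0.5) >= iv[1] & (0:359 + 0.5) < iv[2])
    m[, cols] <- TRUE
  }
  m
}

# Hand-built arc set (for candidate_* unit cases).
make_arcs <- function(start, length) {
  arcs <- data.frame(start = start, end = start + length, length = length)
  structure(list(arcs = arcs, coverage = sum(length),
                 largest = which.max(length), bin_width = 1),
            class = "arc_set")
}

# Matched pair of Fig.2-style slices differing only in remote_sd. The
# overestimation channel at low sigma is the coil-sensitivity bump over
# remote myocardium away from the ROI (at 90 deg; ROI sits mid-remote at
# 180 deg, infarct at 0 deg); the underestimation channel at high sigma is
# the overlap between the heterogeneous infarct distribution and the raised
# threshold.
fig2_spec <- function(remote_sd, seed) {
  test_spec(
    grid_size = 128L, infarct_center_angle = 0, infarct_extent = 120,
    transmurality = 1, remote_mean = 0.15, remote_sd = remote_sd,
    infarct_mean = 0.45, infarct_sd = 0.10,
    bias_amplitude = 0.4, bias_scale = 10, bias_angle = 90,
    noise_model = "gaussian", seed = seed
  )
}
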