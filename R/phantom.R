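## Synthetic short-axis LGE phantom: annular myocardium with a hyper-enhanced
## infarct sector, optional dark microvascular-obstruction (MVO) core,
## site-dependent remote signal variability, magnitude-image noise models and
## a smooth multiplicative coil-sensitivity bias field.

#' Phantom slice specification
#'
#' Parametric description of one synthetic short-axis LGE slice. All
#' intensities are on a normalized 0-1 scale; the remote (nulled) myocardium
#' sits near but not at zero (imperfect nulling), and the infarct is
#' hyper-enhanced. Defaults describe a 128 x 128, 1.5 mm/pixel slice with a
#' 20/30 mm endo/epicardial annulus and a transmural 90-degree infarct.
#'
#' The site-dependent signal-variability construct lives in `remote_sd`:
#' values of roughly 0.013-0.026 span the range observed across CMR vendors
#' on the same normalized scale.
#'
#' @param grid_size pixels per side of the square grid.
#' @param pixel_spacing mm per pixel.
#' @param center (x, y) pixel coordinates of the LV center; default grid center.
#' @param endo_radius,epi_radius endocardial/epicardial radii in mm.
#' @param infarct_center_angle infarct sector center, degrees in `[0, 360)`.
#' @param infarct_extent circumferential extent of the infarct, degrees in
#'   `[0, 360]`.
#' @param transmurality fraction in `(0, 1]` of wall thickness infarcted,
#'   measured from the endocardium.
#' @param mvo_fraction fraction in `[0, 1)` of the infarct area forming a
#'   dark subendocardial MVO core.
#' @param remote_mean,remote_sd mean and SD of remote-tissue intensity.
#' @param infarct_mean,infarct_sd mean and SD of infarcted-tissue intensity;
#'   `infarct_sd > 0` models the tissue heterogeneity that makes infarct and
#'   remote intensity distributions overlap in clinical images.
#' @param mvo_mean intensity of the MVO core; default `remote_mean`
#'   (MVO appears nulled-dark).
#' @param noise_model one of `"gaussian"`, `"none"`, `"rician"`,
#'   `"noncentral_chi"`.
#' @param coil_count receiver coil count (noncentral_chi only).
#' @param bias_amplitude fractional peak modulation of the multiplicative
#'   coil-sensitivity field, in `[0, 1)`; default 0 (off).
#' @param bias_scale spatial scale (mm) of the bias bump.
#' @param bias_angle angular position (degrees) of the bias bump center,
#'   placed at mid-wall radius.
#' @param seed integer RNG seed; generation is deterministic given the spec.
#' @param site_label free-text site/vendor tag.
#' @return a validated `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = 128L,
                         pixel_spacing = 1.5,
                         center = NULL,
                         endo_radius = 20,
                         epi_radius = 30,
                         infarct_center_angle = 0,
                         infarct_extent = 90,
                         transmurality = 1,
                         mvo_fraction = 0,
                         remote_mean = 0.15,
                         remote_sd = 0.02,
                         infarct_mean = 0.45,
                         infarct_sd = 0.08,
                         mvo_mean = NULL,
                         noise_model = c("gaussian", "none", "rician", "noncentral_chi"),
                         coil_count = 1L,
                         bias_amplitude = 0,
                         bias_scale = 12,
                         bias_angle = 90,
                         seed = 1L,
                         site_label = "site1") {
  noise_model <- match.arg(noise_model)
  if (is.null(center)) center <- rep((grid_size - 1) / 2, 2)
  if (is.null(mvo_mean)) mvo_mean <- remote_mean
  spec <- structure(
    list(
      grid_size = as.integer(grid_size), pixel_spacing = pixel_spacing,
      center = as.numeric(center),
      endo_radius = endo_radius, epi_radius = epi_radius,
      infarct_center_angle = infarct_center_angle %% 360,
      infarct_extent = infarct_extent, transmurality = transmurality,
      mvo_fraction = mvo_fraction,
      remote_mean = remote_mean, remote_sd = remote_sd,
      infarct_mean = infarct_mean, infarct_sd = infarct_sd,
      mvo_mean = mvo_mean,
      noise_model = noise_model, coil_count = as.integer(coil_count),
      bias_amplitude = bias_amplitude, bias_scale = bias_scale,
      bias_angle = bias_angle %% 360,
      seed = as.integer(seed), site_label = site_label
    ),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (!(epi_radius > endo_radius && endo_radius > 0)) {
      stop("invalid spec: need epi_radius > endo_radius > 0 (got epi_radius = ",
           epi_radius, ", endo_radius = ", endo_radius, ")")
    }
    r_px <- epi_radius / pixel_spacing
    if (center[1] - r_px < 0 || center[2] - r_px < 0 ||
        center[1] + r_px > grid_size - 1 || center[2] + r_px > grid_size - 1) {
      stop("invalid spec: annulus exceeds the grid (epi_radius too large for grid_size/center)")
    }
    if (!(infarct_extent >= 0 && infarct_extent <= 360)) {
      stop("invalid spec: infarct_extent must be in [0, 360] degrees")
    }
    if (!(transmurality > 0 && transmurality <= 1)) {
      stop("invalid spec: transmurality must be in (0, 1]")
    }
    if (!(mvo_fraction >= 0 && mvo_fraction < 1)) {
      stop("invalid spec: mvo_fraction must be in [0, 1)")
    }
    if (!(infarct_mean > remote_mean)) {
      stop("invalid spec: infarct_mean must exceed remote_mean (hyper-enhancement)")
    }
    for (f in c("remote_mean", "infarct_mean", "mvo_mean")) {
      v <- spec[[f]]
      if (v < 0 || v > 1) stop("invalid spec: ", f, " must be in [0, 1]")
    }
    if (remote_sd < 0 || infarct_sd < 0) stop("invalid spec: negative intensity SD")
    if (!(bias_amplitude >= 0 && bias_amplitude < 1)) {
      stop("invalid spec: bias_amplitude must be in [0, 1)")
    }
    if (coil_count < 1) stop("invalid spec: coil_count must be >= 1")
  })
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "phantom_spec: %dpx @ %.2g mm | annulus %g-%g mm | infarct %g deg @ %g deg, transmurality %g, MVO %g\n",
    x$grid_size, x$pixel_spacing, x$endo_radius, x$epi_radius,
    x$infarct_extent, x$infarct_center_angle, x$transmurality, x$mvo_fraction
  ))
  cat(sprintf(
    "  remote %.3f +/- %.3f | infarct %.3f +/- %.3f | noise %s | bias %.2f | seed %d | %s\n",
    x$remote_mean, x$remote_sd, x$infarct_mean, x$infarct_sd,
    x$noise_model, x$bias_amplitude, x$seed, x$site_label
  ))
  invisible(x)
}

#' Draw magnitude-image noise samples
#'
#' Vectorized over `clean_value` (and `sd`). `gaussian` adds N(0, sd^2).
#' `rician` returns `sqrt((clean + n1)^2 + n2^2)` with independent Gaussian
#' `n1, n2` — the magnitude of complex Gaussian noise around the signal, as in
#' single-coil magnitude MRI. `noncentral_chi` extends this to `2 * coil_count`
#' Gaussian components with the signal carried by one, the magnitude-image
#' distribution for multi-coil (sum-of-squares) reconstruction. `sd = 0` (or
#' model `"none"`) returns the clean values unchanged.
#'
#' @param clean_value numeric vector of noiseless intensities.
#' @param sd noise standard deviation(s), recycled against `clean_value`.
#' @param model one of `"none"`, `"gaussian"`, `"rician"`, `"noncentral_chi"`.
#' @param coil_count coils for `noncentral_chi` (>= 1).
#' @return numeric vector of noisy intensities (not clipped).
#' @export
sample_noise <- function(clean_value, sd, model = c("gaussian", "none", "rician", "noncentral_chi"),
                         coil_count = 1L) {
  model <- match.arg(model)
  if (any(sd < 0)) stop("negative noise sd")
  n <- length(clean_value)
  sd <- rep_len(sd, n)
  if (model == "none") return(clean_value)
  out <- switch(model,
    gaussian = clean_value + rnorm(n, 0, sd),
    rician = sqrt((clean_value + rnorm(n, 0, sd))^2 + rnorm(n, 0, sd)^2),
    noncentral_chi = {
      if (coil_count < 1) stop("coil_count must be >= 1 for noncentral_chi")
      acc <- (clean_value + rnorm(n, 0, sd))^2
      for (k in seq_len(2L * as.integer(coil_count) - 1L)) {
        acc <- acc + rnorm(n, 0, sd)^2
      }
      sqrt(acc)
    }
  )
  # exact zero-noise identity (avoids sqrt round-off in magnitude models)
  z <- sd == 0
  if (any(z)) out[z] <- clean_value[z]
  out
}

#' Generate one phantom slice
#'
#' Deterministic given the spec (including its seed). Pipeline: rasterize the
#' annulus analytically (pixel centers against the exact circles), paint
#' remote / infarct / MVO class means, apply the multiplicative bias field,
#' add tissue-class noise within the myocardium, clip to `[0, 1]`. The
#' background (air and blood pool) is left at zero and carries no noise; the
#' analysis only ever reads myocardial pixels. Contours are exact circles
#' sampled as 256-vertex polygons.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_slice`: list with `image`, `endo_contour`,
#'   `epi_contour`, `myo_mask`, `truth_infarct_mask` (MVO included, matching
#'   the clinical convention that MVO is part of the infarct),
#'   `truth_mvo_mask`, `spec`, `site_label`.
#' @export
generate_slice <- function(spec) {
  spec <- validate_phantom_spec(spec)
  gs <- spec$grid_size
  g <- pixel_grid(c(gs, gs))
  dx <- (g$x - spec$center[1]) * spec$pixel_spacing
  dy <- (g$y - spec$center[2]) * spec$pixel_spacing
  r <- sqrt(dx^2 + dy^2)
  theta <- (atan2(dy, dx) * 180 / pi) %% 360

  myo <- r >= spec$endo_radius & r < spec$epi_radius
  depth <- (r - spec$endo_radius) / (spec$epi_radius - spec$endo_radius)
  infarct <- myo &
    angle_dist(theta, spec$infarct_center_angle) <= spec$infarct_extent / 2 &
    depth <= spec$transmurality
  if (spec$infarct_extent == 0) infarct[] <- FALSE

  mvo <- matrix(FALSE, gs, gs)
  n_inf <- sum(infarct)
  if (spec$mvo_fraction > 0 && n_inf > 0) {
    k <- round(spec$mvo_fraction * n_inf)
    if (k > 0) {
      idx <- which(infarct)
      # innermost (lowest transmural depth) infarct pixels; theta tie-break
      ord <- idx[order(depth[idx], theta[idx])]
      mvo[ord[seq_len(k)]] <- TRUE
    }
  }

  clean <- matrix(0, gs, gs)
  clean[myo] <- spec$remote_mean
  clean[infarct] <- spec$infarct_mean
  clean[mvo] <- spec$mvo_mean

  if (spec$bias_amplitude > 0) {
    mid_r <- (spec$endo_radius + spec$epi_radius) / 2 / spec$pixel_spacing
    bc <- spec$center + mid_r * c(cos(spec$bias_angle * pi / 180),
                                  sin(spec$bias_angle * pi / 180))
    d2 <- ((g$x - bc[1])^2 + (g$y - bc[2])^2) * spec$pixel_spacing^2
    bump <- exp(-d2 / (2 * spec$bias_scale^2))
    bump[d2 > (3 * spec$bias_scale)^2] <- 0  # truncated profile
    clean <- clean * (1 + spec$bias_amplitude * bump)
  }

  image <- clean
  if (spec$noise_model != "none") {
    sd_map <- matrix(0, gs, gs)
    sd_map[myo] <- spec$remote_sd
    sd_map[infarct & !mvo] <- spec$infarct_sd
    idx <- which(myo)
    image[idx] <- withr::with_seed(
      spec$seed,
      sample_noise(clean[idx], sd_map[idx], spec$noise_model, spec$coil_count)
    )
  }
  image <- pmin(pmax(image, 0), 1)

  r_px <- c(spec$endo_radius, spec$epi_radius) / spec$pixel_spacing
  structure(
    list(
      image = image,
      endo_contour = circle_contour(spec$center, r_px[1]),
      epi_contour = circle_contour(spec$center, r_px[2]),
      myo_mask = myo,
      truth_infarct_mask = infarct,
      truth_mvo_mask = mvo,
      spec = spec,
      site_label = spec$site_label
    ),
    class = "phantom_slice"
  )
}

#' @export
print.phantom_slice <- function(x, ...) {
  cat(sprintf(
    "phantom_slice [%s]: %d x %d, myocardium %d px, infarct %d px (%.1f%%), MVO %d px\n",
    x$site_label, nrow(x$image), ncol(x$image), sum(x$myo_mask),
    sum(x$truth_infarct_mask),
    100 * sum(x$truth_infarct_mask) / max(sum(x$myo_mask), 1L),
    sum(x$truth_mvo_mask)
  ))
  invisible(x)
}

# Resolve a template field that may be a fixed value or a (min, max) range.
draw_field <- function(value) {
  if (length(value) == 2L && is.numeric(value)) runif(1, value[1], value[2]) else value
}

#' Generate a multi-site phantom cohort
#'
#' Emulates a multi-site, multi-vendor cohort: each site supplies a
#' `phantom_spec` template (fields such as `infarct_center_angle`,
#' `infarct_extent`, `transmurality`, `mvo_fraction` and the intensity
#' parameters may be given as `c(min, max)` ranges, drawn uniformly per slice)
#' and a slice count. Reproducible per-slice seeds are derived from
#' `master_seed`: all per-slice seeds are drawn without replacement from
#' `1..(2^31 - 2)` under `master_seed`, then template ranges are resolved
#' slice by slice in order, so the whole cohort is a pure function of
#' (`site_specs`, `master_seed`).
#'
#' @param site_specs list; each element a list with `template` (named list of
#'   [phantom_spec()] arguments, ranges allowed) and `count` (slices, >= 1).
#'   A `label` element overrides `template$site_label`.
#' @param master_seed integer.
#' @return list of `phantom_slice`; each carries `slice_id` ("<site>_<i>").
#' @export
generate_cohort <- function(site_specs, master_seed) {
  if (!length(site_specs)) stop("empty site list")
  counts <- vapply(site_specs, function(s) as.integer(s$count), integer(1))
  if (any(is.na(counts)) || any(counts < 1)) stop("every site needs count >= 1")
  total <- sum(counts)

  specs <- withr::with_seed(as.integer(master_seed), {
    seeds <- sample.int(2147483646L, total)
    k <- 0L
    out <- vector("list", total)
    for (s in site_specs) {
      tmpl <- s$template
      if (!is.null(s$label)) tmpl$site_label <- s$label
      for (i in seq_len(s$count)) {
        k <- k + 1L
        drawn <- lapply(tmpl, draw_field)
        drawn$seed <- seeds[k]
        out[[k]] <- do.call(phantom_spec, drawn)
      }
    }
    out
  })

  slices <- lapply(specs, generate_slice)
  k <- 0L
  for (s in seq_along(site_specs)) {
    for (i in seq_len(site_specs[[s]]$count)) {
      k <- k + 1L
      slices[[k]]$slice_id <- sprintf("%s_%03d", slices[[k]]$site_label, i)
    }
  }
  slices
}
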