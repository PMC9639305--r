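## ---- angle helpers ---------------------------------------------------------

#' Absolute circular distance between angles, in degrees
#'
#' @param a,b angles in degrees (any range); recycled.
#' @return distance in `[0, 180]`.
#' @keywords internal
angle_dist <- function(a, b) {
  abs(((a - b + 180) %% 360) - 180)
}

#' Circular mean of angles in degrees
#' @keywords internal
circular_mean_deg <- function(theta) {
  rad <- theta * pi / 180
  (atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi) %% 360
}

## ---- contours --------------------------------------------------------------

#' Construct a contour from vertex coordinates
#'
#' A contour is an ordered, implicitly closed simple polygon in 0-based pixel
#' coordinates, stored as an n x 2 matrix with columns `x` and `y`.
#'
#' @param xy numeric matrix or data.frame with two columns (x, y), at least 3 rows.
#' @return a `contour` object.
#' @export
as_contour <- function(xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L || nrow(xy) < 3L || !is.numeric(xy) || anyNA(xy)) {
    stop("a contour needs a numeric n x 2 matrix with n >= 3 and no missing values")
  }
  colnames(xy) <- c("x", "y")
  structure(xy, class = c("contour", class(xy)))
}

#' Circular contour sampled as a polygon
#'
#' @param center length-2 numeric, (x, y) center in pixel coordinates.
#' @param radius radius in pixels.
#' @param n_vertices number of polygon vertices (default 256).
#' @return a `contour`.
#' @export
circle_contour <- function(center, radius, n_vertices = 256L) {
  if (radius <= 0) stop("radius must be positive")
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  as_contour(cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang)))
}

#' Area centroid of a polygon (shoelace formula)
#' @keywords internal
polygon_centroid <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps) stop("degenerate polygon: zero area")
  c(sum((x + xn) * cross), sum((y + yn) * cross)) / (6 * a)
}

# Radius-vs-angle interpolator for a star-shaped polygon about a given origin.
# Returns a function mapping angles (degrees, [0, 360)) to polygon radius.
contour_radius_fun <- function(contour, origin) {
  dx <- contour[, 1] - origin[1]
  dy <- contour[, 2] - origin[2]
  r <- sqrt(dx^2 + dy^2)
  if (any(r <= 0)) stop("contour passes through the polar origin; malformed contour")
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  o <- order(ang)
  ang <- ang[o]; r <- r[o]
  if (anyDuplicated(ang)) {
    keep <- !duplicated(ang)
    ang <- ang[keep]; r <- r[keep]
  }
  # pad for circular interpolation
  ang_p <- c(ang[length(ang)] - 360, ang, ang[1] + 360)
  r_p <- c(r[length(r)], r, r[1])
  function(theta) stats::approx(ang_p, r_p, xout = theta, rule = 2)$y
}

# closed loop for mgcv::in.out
close_loop <- function(v) rbind(v, v[1, , drop = FALSE])

# 0-based pixel-center coordinate grids for an nr x nc matrix laid out as
# m[y + 1, x + 1]
pixel_grid <- function(grid_shape) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  list(
    x = matrix(rep(seq_len(nc) - 1, each = nr), nr, nc),
    y = matrix(rep(seq_len(nr) - 1, times = nc), nr, nc)
  )
}

## ---- rasterization and polar map -------------------------------------------

#' Rasterize the myocardial annulus between two contours
#'
#' A pixel belongs to the myocardium iff its center lies strictly inside the
#' epicardial contour and not strictly inside the endocardial contour
#' (i.e. outside-or-on endo). Pixel centers sit at integer 0-based positions.
#'
#' @param endo,epi endocardial and epicardial [as_contour()] polygons;
#'   `endo` must lie strictly inside `epi`.
#' @param grid_shape integer length-2, matrix dimensions (rows, cols).
#' @return logical matrix of `grid_shape`.
#' @export
rasterize_myocardium <- function(endo, epi, grid_shape) {
  endo <- as_contour(endo); epi <- as_contour(epi)
  if (nrow(endo) == nrow(epi) && all(endo == epi)) {
    stop("degenerate input: endo and epi contours are identical")
  }
  inside <- mgcv::in.out(close_loop(unclass(epi)), unclass(endo))
  if (!all(inside)) {
    stop("contours intersect: endocardial contour is not strictly inside the epicardial contour")
  }
  g <- pixel_grid(grid_shape)
  pts <- cbind(as.vector(g$x), as.vector(g$y))
  in_epi <- mgcv::in.out(close_loop(unclass(epi)), pts)
  in_endo <- mgcv::in.out(close_loop(unclass(endo)), pts)
  matrix(in_epi & !in_endo, grid_shape[1], grid_shape[2])
}

#' Polar (circumferential angle, transmural depth) parameterization
#'
#' Assigns every myocardial pixel a circumferential angle `theta` (degrees in
#' `[0, 360)`, counter-clockwise from the +x axis about the epicardial-contour
#' area centroid) and a transmural depth in `[0, 1]` (0 at the endocardium,
#' 1 at the epicardium), computed as `(r - r_endo(theta)) / (r_epi(theta) -
#' r_endo(theta))` with contour radii linearly interpolated at the pixel's
#' angle, then clipped to `[0, 1]`.
#'
#' @param endo,epi contours as in [rasterize_myocardium()].
#' @param myo_mask logical matrix; the myocardium mask.
#' @return a `polar_map`: list with matrices `theta` and `depth` (NA outside
#'   the myocardium), the `myo_mask`, and the `centroid` used.
#' @export
polar_parameterize <- function(endo, epi, myo_mask) {
  endo <- as_contour(endo); epi <- as_contour(epi)
  centroid <- polygon_centroid(epi)
  r_endo_at <- contour_radius_fun(endo, centroid)
  r_epi_at <- contour_radius_fun(epi, centroid)

  g <- pixel_grid(dim(myo_mask))
  idx <- which(myo_mask)
  dx <- g$x[idx] - centroid[1]
  dy <- g$y[idx] - centroid[2]
  th <- (atan2(dy, dx) * 180 / pi) %% 360
  r <- sqrt(dx^2 + dy^2)
  re <- r_endo_at(th)
  rp <- r_epi_at(th)
  if (any(rp <= re)) {
    stop("malformed contours: epicardial radius not larger than endocardial radius along some ray")
  }
  depth <- pmin(pmax((r - re) / (rp - re), 0), 1)

  theta_m <- matrix(NA_real_, nrow(myo_mask), ncol(myo_mask))
  depth_m <- theta_m
  theta_m[idx] <- th
  depth_m[idx] <- depth
  structure(
    list(theta = theta_m, depth = depth_m, myo_mask = myo_mask, centroid = centroid),
    class = "polar_map"
  )
}

## ---- sector ROIs and remote arcs -------------------------------------------

#' Sector region of interest with transmural rim exclusion
#'
#' The ROI is the set of myocardial pixels whose circumferential angle lies
#' within `width/2` of `center_angle` (wrapping across 0/360) and whose
#' transmural depth lies in `[rim_fraction, 1 - rim_fraction]`. The default
#' rim exclusion of 15% on each side drops most endocardial and epicardial
#' boundary pixels from the remote statistics.
#'
#' @param polar a [polar_parameterize()] map.
#' @param center_angle sector center, degrees.
#' @param width sector angular width in `(0, 360]` degrees.
#' @param rim_fraction fraction of wall thickness excluded at each rim,
#'   in `[0, 0.5)`; default 0.15.
#' @return logical ROI mask. Errors with condition class
#'   `nsdremote_empty_roi` (carrying `pixel_count = 0`) if no pixel qualifies.
#' @export
sector_roi <- function(polar, center_angle, width, rim_fraction = 0.15) {
  if (!(width > 0 && width <= 360)) stop("width must be in (0, 360] degrees")
  if (!(rim_fraction >= 0 && rim_fraction < 0.5)) stop("rim_fraction must be in [0, 0.5)")
  sel <- polar$myo_mask &
    angle_dist(polar$theta, center_angle) <= width / 2 &
    polar$depth >= rim_fraction & polar$depth <= 1 - rim_fraction
  sel[is.na(sel)] <- FALSE
  if (!any(sel)) {
    stop(errorCondition(
      sprintf("empty sector ROI at center %.1f deg, width %.1f deg", center_angle, width),
      pixel_count = 0L, class = c("nsdremote_empty_roi", "error", "condition")
    ))
  }
  sel
}

#' Infarction-free circumferential arcs
#'
#' Divides the circumference into `bin_width`-degree bins; a bin is infarcted
#' if at least one reference-infarct pixel falls in it. Returns the maximal
#' runs of non-infarcted bins as an arc set.
#'
#' @param truth_infarct_mask logical matrix, reference infarct.
#' @param polar a `polar_map` aligned with the mask.
#' @param bin_width bin width in degrees; must divide 360 (default 1).
#' @return an `arc_set`: list with `arcs` (data.frame `start`, `end`, `length`
#'   in degrees; `end = start + length` may exceed 360 for wrapping arcs),
#'   `coverage` (total remote degrees), `largest` (row index of the longest
#'   arc, NA if empty), and `bin_width`.
#' @export
remote_arcs <- function(truth_infarct_mask, polar, bin_width = 1) {
  if (360 %% bin_width != 0) stop("bin_width must divide 360")
  if (!identical(dim(truth_infarct_mask), dim(polar$theta))) {
    stop("mask and polar map dimensions differ")
  }
  nb <- as.integer(360 / bin_width)
  th <- polar$theta[truth_infarct_mask]
  th <- th[!is.na(th)]
  infarcted <- logical(nb)
  if (length(th)) infarcted[unique(floor(th / bin_width)) + 1L] <- TRUE
  # bins with no myocardial pixel at all (rasterization holes at coarse
  # grids) inherit the status of the circularly nearest populated bin, so
  # holes inside an infarct sector do not masquerade as remote arcs
  th_myo <- polar$theta[polar$myo_mask]
  has_myo <- logical(nb)
  if (length(th_myo)) has_myo[unique(floor(th_myo / bin_width)) + 1L] <- TRUE
  if (any(!has_myo) && any(has_myo)) {
    ne <- which(has_myo)
    for (b in which(!has_myo)) {
      d <- pmin((ne - b) %% nb, (b - ne) %% nb)
      infarcted[b] <- infarcted[ne[which.min(d)]]
    }
  }
  remote <- !infarcted

  arcs <- data.frame(start = numeric(0), end = numeric(0), length = numeric(0))
  if (all(remote)) {
    arcs <- data.frame(start = 0, end = 360, length = 360)
  } else if (any(remote)) {
    # rotate so the run structure is linear (position 1 infarcted)
    shift <- which(!remote)[1]
    rot <- remote[c(shift:nb, seq_len(shift - 1L))]
    r <- rle(rot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    start_bin <- ((starts[keep] - 1L + shift - 1L) %% nb)
    arcs <- data.frame(
      start = start_bin * bin_width,
      length = r$lengths[keep] * bin_width
    )
    arcs$end <- arcs$start + arcs$length
    arcs <- arcs[order(arcs$start), c("start", "end", "length")]
    rownames(arcs) <- NULL
  }
  structure(
    list(
      arcs = arcs,
      coverage = sum(arcs$length),
      largest = if (nrow(arcs)) which.max(arcs$length) else NA_integer_,
      bin_width = bin_width
    ),
    class = "arc_set"
  )
}

largest_arc <- function(arcs) {
  if (!nrow(arcs$arcs)) return(NULL)
  arcs$arcs[arcs$largest, ]
}

#' Slice inclusion filter
#'
#' A slice is analyzable when its reference infarct covers at least 10% of the
#' circumference (>= 36 degrees of infarcted bins) and at least 50% of the
#' circumference is contiguously infarction-free (largest remote arc >= 180
#' degrees).
#'
#' @inheritParams remote_arcs
#' @return list with `included` (logical), `infarct_coverage_deg`,
#'   `infarct_coverage_pct`, `largest_remote_deg`, `largest_remote_pct`, and
#'   the computed `arcs`.
#' @export
slice_includable <- function(truth_infarct_mask, polar, bin_width = 1) {
  arcs <- remote_arcs(truth_infarct_mask, polar, bin_width)
  infarct_deg <- 360 - arcs$coverage
  big <- largest_arc(arcs)
  big_deg <- if (is.null(big)) 0 else big$length
  list(
    included = infarct_deg >= 36 && big_deg >= 180,
    infarct_coverage_deg = infarct_deg,
    infarct_coverage_pct = 100 * infarct_deg / 360,
    largest_remote_deg = big_deg,
    largest_remote_pct = 100 * big_deg / 360,
    arcs = arcs
  )
}

#' Candidate ROI center angles within the largest remote arc
#'
#' A center is admissible when the whole sector of width `roi_width` fits
#' inside the largest remote arc. If at least `max_positions` centers fit at
#' `min_step` spacing, `max_positions` centers are spread evenly over the
#' admissible span; otherwise as many as fit at exactly `min_step` spacing are
#' returned, centered in the span.
#'
#' @param arcs an [remote_arcs()] arc set.
#' @param roi_width sector width in degrees (default 45).
#' @param min_step minimum spacing between centers in degrees (default 10).
#' @param max_positions maximum number of positions (default 7).
#' @return numeric vector of center angles in `[0, 360)`, ordered along the
#'   arc; `numeric(0)` when no center is admissible.
#' @export
candidate_positions <- function(arcs, roi_width = 45, min_step = 10, max_positions = 7L) {
  if (roi_width <= 0) stop("roi_width must be positive")
  big <- largest_arc(arcs)
  if (is.null(big)) return(numeric(0))
  span <- big$length - roi_width
  if (span < 0) return(numeric(0))
  lo <- big$start + roi_width / 2
  n_fit <- floor(span / min_step) + 1
  centers <- if (n_fit >= max_positions) {
    if (max_positions == 1L) lo + span / 2 else seq(lo, lo + span, length.out = max_positions)
  } else {
    offset <- (span - (n_fit - 1) * min_step) / 2
    lo + offset + min_step * (seq_len(n_fit) - 1)
  }
  centers %% 360
}

#' Candidate ROI sizes fitting the largest remote arc
#'
#' @param arcs an [remote_arcs()] arc set.
#' @param size_grid candidate widths in degrees; default 15 to 105 in steps
#'   of 15 (seven sizes bracketing the 45-degree baseline).
#' @return data.frame with columns `width` and `center_angle` (the largest
#'   arc's midpoint); zero rows when nothing fits.
#' @export
candidate_sizes <- function(arcs, size_grid = seq(15, 105, by = 15)) {
  if (!length(size_grid)) stop("size_grid must be non-empty")
  big <- largest_arc(arcs)
  if (is.null(big)) return(data.frame(width = numeric(0), center_angle = numeric(0)))
  fit <- size_grid[size_grid <= big$length]
  data.frame(width = fit, center_angle = rep((big$start + big$length / 2) %% 360, length(fit)))
}
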