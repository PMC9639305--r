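## The five error-source experiments: remote-ROI position, ROI size, the n-SD
## multiplier, spurious-pixel handling, and signal-variability regimes; plus
## the per-slice optimal-n search and the accuracy/precision statistics
## (mean error in scar percentage units; coefficient of variation = SD of the
## error divided by the reference infarct size, per slice).

#' Study configuration
#'
#' @param varied_factor which factor the study varies.
#' @param baseline_n SD multiplier held fixed while other factors vary
#'   (default 3.5).
#' @param baseline_width ROI width in degrees held fixed (default 45).
#' @param n_grid multipliers for the n-SD study (default 2..8 step 1).
#' @param size_grid ROI widths for the size study (default 15..105 step 15).
#' @param min_step minimum spacing between ROI positions, degrees (default 10).
#' @param max_positions maximum ROI positions per slice (default 7).
#' @param rim_fraction transmural rim excluded from ROIs (default 0.15).
#' @param remove_spurious use the "no-spurious" variant? (default FALSE).
#' @param min_island,connectivity island-removal settings.
#' @param bin_width circumference bin width in degrees (default 1).
#' @param master_seed optional seed recorded with results.
#' @return a `study_config` list.
#' @export
study_config <- function(varied_factor = c("roi_position", "roi_size", "n_sd", "spurious_removal"),
                         baseline_n = 3.5,
                         baseline_width = 45,
                         n_grid = 2:8,
                         size_grid = seq(15, 105, by = 15),
                         min_step = 10,
                         max_positions = 7L,
                         rim_fraction = 0.15,
                         remove_spurious = FALSE,
                         min_island = 10L,
                         connectivity = 8L,
                         master_seed = NULL) {
  varied_factor <- match.arg(varied_factor)
  stopifnot(length(n_grid) >= 1, length(size_grid) >= 1,
            baseline_n > 0, baseline_width > 0)
  structure(
    list(varied_factor = varied_factor, baseline_n = baseline_n,
         baseline_width = baseline_width, n_grid = n_grid,
         size_grid = size_grid, min_step = min_step,
         max_positions = as.integer(max_positions),
         rim_fraction = rim_fraction, remove_spurious = remove_spurious,
         min_island = as.integer(min_island),
         connectivity = as.integer(connectivity), master_seed = master_seed),
    class = "study_config"
  )
}

# Geometry bundle for one slice: myocardium, polar map, remote arcs,
# inclusion diagnostics, reference size.
slice_geometry <- function(slice, bin_width = 1) {
  myo <- slice$myo_mask
  if (is.null(myo)) {
    myo <- rasterize_myocardium(slice$endo_contour, slice$epi_contour, dim(slice$image))
  }
  polar <- polar_parameterize(slice$endo_contour, slice$epi_contour, myo)
  truth <- slice$truth_infarct_mask
  inc <- NULL
  reference_pct <- NA_real_
  if (!is.null(truth)) {
    inc <- slice_includable(truth, polar, bin_width)
    reference_pct <- infarct_fraction(truth, myo)
  }
  list(myo = myo, polar = polar, truth = truth, inc = inc,
       arcs = if (!is.null(inc)) inc$arcs else NULL,
       reference_pct = reference_pct)
}

slice_label <- function(slice, i) {
  if (!is.null(slice$slice_id)) slice$slice_id else sprintf("slice_%03d", i)
}

# Run one segmentation and emit an outcome row (or NULL on empty ROI).
outcome_row <- function(slice_id, site, level, center, width, image, geom, params) {
  roi <- tryCatch(
    sector_roi(geom$polar, center, width),
    nsdremote_empty_roi = function(e) NULL
  )
  if (is.null(roi)) return(NULL)
  res <- segment_slice(image, geom$myo, roi, params)
  data.frame(
    slice_id = slice_id, site_label = site, factor_level = level,
    center_angle = center, roi_width = width, n = params$n,
    measured_pct = res$infarct_fraction_pct,
    reference_pct = geom$reference_pct,
    error_pct_units = res$infarct_fraction_pct - geom$reference_pct,
    threshold = res$threshold, roi_pixels = res$stats$pixel_count,
    removed_pixels = res$removed_pixels,
    stringsAsFactors = FALSE
  )
}

# Shared study loop: plan_fun(slice, geom) returns a data.frame of
# (factor_level, center_angle, width, n) rows to segment.
run_factor_study <- function(slices, config, plan_fun) {
  outcomes <- list()
  excluded <- list()
  for (i in seq_along(slices)) {
    sl <- slices[[i]]
    id <- slice_label(sl, i)
    geom <- slice_geometry(sl)
    if (is.null(geom$inc)) {
      excluded[[length(excluded) + 1L]] <- data.frame(slice_id = id, reason = "no reference mask")
      next
    }
    if (!geom$inc$included) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        slice_id = id,
        reason = sprintf("inclusion filter: infarct %.1f%% of circumference, largest remote arc %.0f deg",
                         geom$inc$infarct_coverage_pct, geom$inc$largest_remote_deg)
      )
      next
    }
    plan <- plan_fun(sl, geom)
    if (is.null(plan) || !nrow(plan)) {
      excluded[[length(excluded) + 1L]] <- data.frame(slice_id = id, reason = "no admissible ROI")
      next
    }
    for (j in seq_len(nrow(plan))) {
      params <- seg_params(plan$n[j], config$remove_spurious,
                           config$min_island, config$connectivity)
      row <- outcome_row(id, sl$site_label, plan$factor_level[j],
                         plan$center_angle[j], plan$width[j], sl$image, geom, params)
      if (!is.null(row)) outcomes[[length(outcomes) + 1L]] <- row
    }
  }
  outcomes <- if (length(outcomes)) do.call(rbind, outcomes) else NULL
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(slice_id = character(0), reason = character(0))
  if (is.null(outcomes)) stop("no slice produced any outcome (all excluded)")
  list(summary = summarize_outcomes(outcomes), outcomes = outcomes, excluded = excluded)
}

#' Study 1: impact of remote-ROI placement
#'
#' A fixed-width ROI (45 degrees) is shifted over the infarction-free
#' circumference in steps of at least `min_step` degrees, up to
#' `max_positions` positions per slice, with `n` fixed at `baseline_n`.
#'
#' @param slices list of `phantom_slice` (or loaded bundles with reference
#'   masks).
#' @param config a [study_config()].
#' @return list with `summary` ([summarize_outcomes()]), `outcomes`
#'   (one row per ROI), and `excluded` (slices dropped, with reasons).
#' @export
run_position_study <- function(slices, config = study_config("roi_position")) {
  run_factor_study(slices, config, function(sl, geom) {
    centers <- candidate_positions(geom$arcs, config$baseline_width,
                                   config$min_step, config$max_positions)
    if (!length(centers)) return(NULL)
    data.frame(factor_level = centers, center_angle = centers,
               width = config$baseline_width, n = config$baseline_n)
  })
}

#' Study 2: impact of remote-ROI size
#'
#' ROI widths from `size_grid` that fit the largest remote arc, centered at
#' the arc midpoint, with `n` fixed at `baseline_n`.
#'
#' @inheritParams run_position_study
#' @return as [run_position_study()].
#' @export
run_size_study <- function(slices, config = study_config("roi_size")) {
  run_factor_study(slices, config, function(sl, geom) {
    sz <- candidate_sizes(geom$arcs, config$size_grid)
    if (!nrow(sz)) return(NULL)
    data.frame(factor_level = sz$width, center_angle = sz$center_angle,
               width = sz$width, n = config$baseline_n)
  })
}

# Diametrically-opposed center, clamped to the nearest admissible center of
# the largest remote arc when the sector would not fit there.
diametric_center <- function(arcs, infarct_center, width) {
  big <- largest_arc(arcs)
  if (is.null(big) || big$length < width) return(NA_real_)
  target <- (infarct_center + 180) %% 360
  rel <- (target - big$start) %% 360
  if (rel >= width / 2 && rel <= big$length - width / 2) return(target)
  lo <- (big$start + width / 2) %% 360
  hi <- (big$start + big$length - width / 2) %% 360
  if (angle_dist(target, lo) <= angle_dist(target, hi)) lo else hi
}

infarct_center_angle_of <- function(truth, polar, bin_width = 1) {
  th <- polar$theta[truth]
  th <- th[!is.na(th)]
  if (!length(th)) return(NA_real_)
  bins <- unique(floor(th / bin_width)) * bin_width + bin_width / 2
  circular_mean_deg(bins)
}

#' Study 3: impact of the n-SD multiplier
#'
#' A 45-degree ROI diametrically opposed to the infarct (falling back to the
#' nearest admissible center of the largest remote arc when needed), with `n`
#' varied over `config$n_grid` (default 2..8 in steps of 1, 7 segmentations
#' per slice).
#'
#' @inheritParams run_position_study
#' @return as [run_position_study()].
#' @export
run_nsd_study <- function(slices, config = study_config("n_sd")) {
  run_factor_study(slices, config, function(sl, geom) {
    ic <- infarct_center_angle_of(geom$truth, geom$polar)
    ctr <- diametric_center(geom$arcs, ic, config$baseline_width)
    if (is.na(ctr)) return(NULL)
    data.frame(factor_level = config$n_grid, center_angle = ctr,
               width = config$baseline_width, n = config$n_grid)
  })
}

#' Study 4: naive vs no-spurious variants (paired)
#'
#' Both variants are run on the same mid-remote 45-degree ROI per slice at
#' `baseline_n`, so the comparison is paired pixel for pixel. Island removal
#' only deletes, so the naive measured size is always >= the no-spurious one.
#'
#' @inheritParams run_position_study
#' @return list with `naive` and `no_spurious` ([summarize_outcomes()]
#'   summaries), `paired_mean_diff` (mean naive - no-spurious size, percentage
#'   units), `outcomes` (with a `variant` column), and `excluded`.
#' @export
run_spurious_comparison <- function(slices, config = study_config("spurious_removal")) {
  cfg_naive <- config; cfg_naive$remove_spurious <- FALSE
  cfg_clean <- config; cfg_clean$remove_spurious <- TRUE
  plan <- function(sl, geom) {
    sz <- candidate_sizes(geom$arcs, config$baseline_width)
    if (!nrow(sz)) return(NULL)
    data.frame(factor_level = "mid-remote", center_angle = sz$center_angle[1],
               width = config$baseline_width, n = config$baseline_n)
  }
  res_n <- run_factor_study(slices, cfg_naive, plan)
  res_c <- run_factor_study(slices, cfg_clean, plan)
  res_n$outcomes$variant <- "naive"
  res_c$outcomes$variant <- "no_spurious"
  merged <- merge(res_n$outcomes[, c("slice_id", "measured_pct")],
                  res_c$outcomes[, c("slice_id", "measured_pct")],
                  by = "slice_id", suffixes = c("_naive", "_no_spurious"))
  list(
    naive = res_n$summary,
    no_spurious = res_c$summary,
    paired_mean_diff = mean(merged$measured_pct_naive - merged$measured_pct_no_spurious),
    outcomes = rbind(res_n$outcomes, res_c$outcomes),
    excluded = res_n$excluded
  )
}

#' Per-slice optimal n
#'
#' Grid search for the multiplier whose measured infarct size is closest to
#' the reference size (ties resolve to the smallest n). The search uses the
#' naive variant (no island removal).
#'
#' @param image numeric matrix.
#' @param myo_mask,roi_mask logical masks.
#' @param reference_pct reference infarct size, percent of myocardium (> 0).
#' @param n_grid search grid (default 0.1..15 step 0.1).
#' @return list with `n_star`, `measured_pct` (at `n_star`), and `degenerate`
#'   (TRUE when the optimum is pinned at a grid end).
#' @export
optimal_n_per_slice <- function(image, myo_mask, roi_mask, reference_pct,
                                n_grid = seq(0.1, 15, by = 0.1)) {
  if (!is.finite(reference_pct) || reference_pct <= 0) {
    stop("reference_pct must be positive (zero-reference slices are excluded upstream)")
  }
  st <- remote_stats(image, roi_mask)
  x <- sort(image[myo_mask])
  n_myo <- length(x)
  thresholds <- st$mu + n_grid * st$sigma
  counts <- n_myo - findInterval(thresholds, x)
  measured <- 100 * counts / n_myo
  k <- which.min(abs(measured - reference_pct))
  list(
    n_star = n_grid[k],
    measured_pct = measured[k],
    degenerate = k == 1L || k == length(n_grid)
  )
}

#' Optimal-n study over a cohort
#'
#' Runs [optimal_n_per_slice()] with a fixed mid-remote 45-degree ROI on
#' every includable slice and aggregates overall and per site.
#'
#' @inheritParams run_position_study
#' @param n_grid search grid passed to [optimal_n_per_slice()].
#' @return `optimal_n_result`: list with `per_slice` data.frame, `mean`,
#'   `sd`, `per_site` data.frame, `excluded`.
#' @export
run_optimal_n_study <- function(slices, config = study_config("n_sd"),
                                n_grid = seq(0.1, 15, by = 0.1)) {
  rows <- list(); excluded <- list()
  for (i in seq_along(slices)) {
    sl <- slices[[i]]
    id <- slice_label(sl, i)
    geom <- slice_geometry(sl)
    if (is.null(geom$inc) || !geom$inc$included || geom$reference_pct <= 0) {
      excluded[[length(excluded) + 1L]] <- data.frame(slice_id = id, reason = "filtered")
      next
    }
    sz <- candidate_sizes(geom$arcs, config$baseline_width)
    if (!nrow(sz)) {
      excluded[[length(excluded) + 1L]] <- data.frame(slice_id = id, reason = "no admissible ROI")
      next
    }
    roi <- sector_roi(geom$polar, sz$center_angle[1], config$baseline_width,
                      config$rim_fraction)
    opt <- optimal_n_per_slice(sl$image, geom$myo, roi, geom$reference_pct, n_grid)
    rows[[length(rows) + 1L]] <- data.frame(
      slice_id = id, site_label = sl$site_label, n_star = opt$n_star,
      measured_pct = opt$measured_pct, reference_pct = geom$reference_pct,
      degenerate = opt$degenerate, stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("no includable slice for the optimal-n study")
  per_slice <- do.call(rbind, rows)
  agg <- stats::aggregate(n_star ~ site_label, per_slice,
                          function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  per_site <- data.frame(site_label = agg$site_label,
                         mean = agg$n_star[, "mean"], sd = agg$n_star[, "sd"],
                         n = agg$n_star[, "n"])
  structure(
    list(per_slice = per_slice, mean = mean(per_slice$n_star),
         sd = stats::sd(per_slice$n_star), per_site = per_site,
         excluded = if (length(excluded)) do.call(rbind, excluded) else NULL),
    class = "optimal_n_result"
  )
}

#' @export
print.optimal_n_result <- function(x, ...) {
  cat(sprintf("optimal n-SD: %.2f +/- %.2f over %d slices\n",
              x$mean, x$sd, nrow(x$per_slice)))
  invisible(x)
}

#' Signal-variability report per site
#'
#' Per slice, the whole image is min-max normalized to `[0, 1]` and the
#' remote-ROI intensity SD is taken as the slice's signal variability
#' (arbitrary units); values are aggregated as mean +/- SD per site label.
#'
#' @param slices list of slices (reference masks required for ROI placement).
#' @param roi_width ROI width in degrees (default 45, mid-remote).
#' @param rim_fraction transmural rim exclusion (default 0.15).
#' @return `signal_variability_report`: list with `per_slice` and `per_group`
#'   data.frames.
#' @export
signal_variability_report <- function(slices, roi_width = 45, rim_fraction = 0.15) {
  rows <- list()
  for (i in seq_along(slices)) {
    sl <- slices[[i]]
    rng <- range(sl$image)
    if (rng[2] <= rng[1]) stop("constant image: min-max normalization undefined for slice ",
                               slice_label(sl, i))
    norm <- (sl$image - rng[1]) / (rng[2] - rng[1])
    geom <- slice_geometry(sl)
    if (is.null(geom$arcs)) next
    sz <- candidate_sizes(geom$arcs, roi_width)
    if (!nrow(sz)) next
    roi <- sector_roi(geom$polar, sz$center_angle[1], roi_width, rim_fraction)
    rows[[length(rows) + 1L]] <- data.frame(
      slice_id = slice_label(sl, i), site_label = sl$site_label,
      remote_sigma = stats::sd(norm[roi]), stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("no slice with an admissible remote ROI")
  per_slice <- do.call(rbind, rows)
  agg <- stats::aggregate(remote_sigma ~ site_label, per_slice,
                          function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  per_group <- data.frame(site_label = agg$site_label,
                          mean = agg$remote_sigma[, "mean"],
                          sd = agg$remote_sigma[, "sd"],
                          n = agg$remote_sigma[, "n"])
  structure(list(per_slice = per_slice, per_group = per_group),
            class = "signal_variability_report")
}

#' @export
print.signal_variability_report <- function(x, ...) {
  cat("remote signal variability (normalized units) per group:\n")
  print(x$per_group, row.names = FALSE)
  invisible(x)
}

#' Aggregate outcomes into accuracy and precision statistics
#'
#' Accuracy: mean error (measured - reference, scar percentage units) +/- SD,
#' pooled over all ROIs, plus the absolute difference of medians. Precision:
#' per-slice coefficient of variation — SD of the slice's errors across the
#' varied factor divided by the slice's reference size, as a percent — then
#' mean +/- SD across slices. Slices contributing fewer than two ROIs are
#' kept in the error statistics but dropped from the CoV (their `cov_slices`
#' count reflects this).
#'
#' @param outcomes data.frame with at least `slice_id`, `measured_pct`,
#'   `reference_pct`, `error_pct_units`.
#' @return a `study_summary` list: `mean_error`, `sd_error`, `cov_mean`,
#'   `cov_sd`, `median_abs_diff`, `slice_count`, `roi_count`, `cov_slices`,
#'   `per_slice_cov`.
#' @export
summarize_outcomes <- function(outcomes) {
  stopifnot(nrow(outcomes) >= 1)
  err <- outcomes$error_pct_units
  by_slice <- split(outcomes, outcomes$slice_id)
  cov <- vapply(by_slice, function(d) {
    if (nrow(d) < 2L) return(NA_real_)
    100 * stats::sd(d$error_pct_units) / d$reference_pct[1]
  }, numeric(1))
  cov_ok <- cov[!is.na(cov)]
  structure(
    list(
      mean_error = mean(err),
      sd_error = if (length(err) > 1L) stats::sd(err) else 0,
      cov_mean = if (length(cov_ok)) mean(cov_ok) else NA_real_,
      cov_sd = if (length(cov_ok) > 1L) stats::sd(cov_ok) else NA_real_,
      median_abs_diff = abs(stats::median(outcomes$measured_pct) -
                              stats::median(outcomes$reference_pct)),
      slice_count = length(by_slice),
      roi_count = nrow(outcomes),
      cov_slices = length(cov_ok),
      per_slice_cov = cov
    ),
    class = "study_summary"
  )
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf(
    "study_summary: mean error %.2f +/- %.2f %%-units | CoV %.1f +/- %.1f %% | %d slices, %d ROIs\n",
    x$mean_error, x$sd_error, x$cov_mean, x$cov_sd, x$slice_count, x$roi_count
  ))
  invisible(x)
}
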