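## The "n-SD from remote" method: remote-ROI statistics, the mu + n*sigma
## threshold, whole-myocardium classification, optional spurious-pixel
## removal, and infarct size as a percentage of slice myocardium.

#' Remote-ROI intensity statistics
#'
#' @param image numeric matrix.
#' @param roi_mask logical matrix, the remote ROI (subset of the myocardium).
#' @param min_roi_pixels minimum pixel count for a meaningful sigma estimate
#'   (default 10).
#' @return `remote_stats`: list with `mu` (arithmetic mean), `sigma` (sample
#'   SD, denominator N - 1), `pixel_count`.
#' @export
remote_stats <- function(image, roi_mask, min_roi_pixels = 10L) {
  v <- image[roi_mask]
  if (length(v) < min_roi_pixels) {
    stop("remote ROI has ", length(v), " pixels; at least ", min_roi_pixels,
         " are required for a stable sigma estimate")
  }
  structure(
    list(mu = mean(v), sigma = stats::sd(v), pixel_count = length(v)),
    class = "remote_stats"
  )
}

#' The n-SD threshold
#'
#' `threshold = mu + n * sigma`: the intensity above which a myocardial pixel
#' is called hyper-enhanced.
#'
#' @param stats a [remote_stats()] object (or any list with `mu`, `sigma`).
#' @param n SD multiplier, positive real (fractional allowed).
#' @return threshold intensity.
#' @export
nsd_threshold <- function(stats, n) {
  if (!is.numeric(n) || n <= 0) stop("n must be a positive number")
  stats$mu + n * stats$sigma
}

#' Threshold classification over the myocardium
#'
#' Pixels strictly above the threshold are hyper-enhanced; ties resolve to
#' non-infarct. Pixels outside the myocardium are always FALSE.
#'
#' @param image numeric matrix.
#' @param myo_mask logical myocardium mask.
#' @param threshold finite intensity.
#' @return logical matrix.
#' @export
classify <- function(image, myo_mask, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  myo_mask & (image > threshold)
}

# Connected-component labeling on a logical matrix (4- or 8-connectivity),
# iterative frontier expansion over 1-based linear indices.
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- if (connectivity == 4L) {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else if (connectivity == 8L) {
    cbind(dr = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
          dc = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
  } else stop("connectivity must be 4 or 8")
  lab <- matrix(0L, nr, nc)
  next_lab <- 0L
  for (seed in which(mask)) {
    if (lab[seed] != 0L) next
    next_lab <- next_lab + 1L
    frontier <- seed
    lab[seed] <- next_lab
    while (length(frontier)) {
      r <- ((frontier - 1L) %% nr) + 1L
      c0 <- ((frontier - 1L) %/% nr) + 1L
      cand_r <- rep(r, times = nrow(offs)) + rep(offs[, "dr"], each = length(frontier))
      cand_c <- rep(c0, times = nrow(offs)) + rep(offs[, "dc"], each = length(frontier))
      ok <- cand_r >= 1L & cand_r <= nr & cand_c >= 1L & cand_c <= nc
      cand <- unique((cand_c[ok] - 1L) * nr + cand_r[ok])
      cand <- cand[mask[cand] & lab[cand] == 0L]
      lab[cand] <- next_lab
      frontier <- cand
    }
  }
  lab
}

#' Remove spurious supra-threshold islands
#'
#' Deletes connected components smaller than `min_island` pixels — the
#' "no-spurious" variant of the method; the "naive" variant skips this step.
#'
#' @param mask logical matrix.
#' @param min_island components with fewer pixels than this are removed
#'   (default 10, i.e. islands of < 10 pixels go).
#' @param connectivity 4 or 8 (default 8).
#' @return list with `mask` (cleaned) and `removed_count`.
#' @export
remove_spurious <- function(mask, min_island = 10L, connectivity = 8L) {
  if (min_island < 1) stop("min_island must be >= 1")
  if (!any(mask)) return(list(mask = mask, removed_count = 0L))
  lab <- label_components(mask, as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L])
  small <- which(sizes < min_island)
  if (!length(small)) return(list(mask = mask, removed_count = 0L))
  drop <- lab %in% small
  out <- mask
  out[drop] <- FALSE
  list(mask = out, removed_count = sum(drop))
}

#' Infarct size as percent of slice myocardium
#'
#' Pure pixel-count ratio; no intensity weighting.
#'
#' @param infarct_mask,myo_mask logical matrices, `infarct_mask` a subset of
#'   `myo_mask`.
#' @return percentage in `[0, 100]`.
#' @export
infarct_fraction <- function(infarct_mask, myo_mask) {
  n_myo <- sum(myo_mask)
  if (n_myo == 0L) stop("empty myocardium mask")
  if (any(infarct_mask & !myo_mask)) stop("infarct mask extends outside the myocardium")
  100 * sum(infarct_mask) / n_myo
}

#' Segmentation parameters for the n-SD method
#'
#' @param n SD multiplier (> 0, fractional allowed).
#' @param remove_spurious drop islands smaller than `min_island`? (the
#'   "no-spurious" variant; default FALSE = "naive").
#' @param min_island island-size cutoff in pixels (default 10).
#' @param connectivity 4 or 8 (default 8).
#' @return a `seg_params` list.
#' @export
seg_params <- function(n, remove_spurious = FALSE, min_island = 10L, connectivity = 8L) {
  if (!is.numeric(n) || n <= 0) stop("n must be positive")
  if (min_island < 1) stop("min_island must be >= 1")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(
    list(n = n, remove_spurious = isTRUE(remove_spurious),
         min_island = as.integer(min_island), connectivity = as.integer(connectivity)),
    class = "seg_params"
  )
}

#' Segment one slice with "n-SD from remote"
#'
#' remote statistics -> `mu + n*sigma` threshold -> whole-myocardium
#' classification -> optional island removal -> infarct fraction. Dark MVO
#' pixels are not rescued: by construction the method misses them.
#'
#' @param image numeric matrix.
#' @param myo_mask logical myocardium mask.
#' @param roi_mask logical remote ROI mask.
#' @param params a [seg_params()].
#' @return `seg_result`: list with `infarct_mask`, `threshold`,
#'   `infarct_fraction_pct`, `removed_pixels`, `stats` (the [remote_stats()]),
#'   and `params`.
#' @export
segment_slice <- function(image, myo_mask, roi_mask, params) {
  stats <- remote_stats(image, roi_mask)
  thr <- nsd_threshold(stats, params$n)
  m <- classify(image, myo_mask, thr)
  removed <- 0L
  if (isTRUE(params$remove_spurious)) {
    rs <- remove_spurious(m, params$min_island, params$connectivity)
    m <- rs$mask
    removed <- rs$removed_count
  }
  structure(
    list(
      infarct_mask = m,
      threshold = thr,
      infarct_fraction_pct = infarct_fraction(m, myo_mask),
      removed_pixels = removed,
      stats = stats,
      params = params
    ),
    class = "seg_result"
  )
}

#' @export
print.seg_result <- function(x, ...) {
  cat(sprintf(
    "seg_result: n = %g, threshold = %.4f, infarct %.2f%% of myocardium, %d spurious px removed\n",
    x$params$n, x$threshold, x$infarct_fraction_pct, x$removed_pixels
  ))
  invisible(x)
}
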