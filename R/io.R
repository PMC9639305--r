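## File formats, configuration, CLI entry points and run manifests.
## Images and label masks travel as plain TSV grids (lossless for masks,
## float-precision for images) with a JSON sidecar holding contours and the
## generating spec; cohort configs are JSON.

label_codes <- c(background = 0L, myocardium = 1L, infarct = 2L, mvo = 3L)

# Recursively sort names so the config hash is stable under key reordering.
canonicalize <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && any(nzchar(names(x)))) x <- x[order(names(x))]
    lapply(x, canonicalize)
  } else x
}

# 32-bit FNV-1a of the canonical (name-sorted) JSON serialization, kept exact
# in doubles: the XOR only touches the low byte (bytes < 256) and the prime
# multiplication is split into 16-bit halves mod 2^32.
config_hash <- function(config) {
  s <- jsonlite::toJSON(canonicalize(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(enc2utf8(as.character(s)))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

write_matrix_tsv <- function(m, path, integer = FALSE) {
  df <- as.data.frame(if (integer) matrix(as.integer(m), nrow(m)) else m)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

read_matrix_tsv <- function(path, integer = FALSE) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = if (integer) "integer" else "numeric"))
  dimnames(m) <- NULL
  m
}

contour_to_list <- function(ct) list(x = ct[, 1], y = ct[, 2])
contour_from_list <- function(l) as_contour(cbind(l$x, l$y))

#' Write a slice bundle to disk
#'
#' Three sibling files per slice: `<id>_image.tsv` (intensity grid),
#' `<id>_labels.tsv` (0 background, 1 myocardium, 2 infarct, 3 MVO) and
#' `<id>_meta.json` (contours, spec, site label). Masks and contours round
#' trip losslessly; image values to double precision as printed.
#'
#' @param slice a `phantom_slice` (or compatible list).
#' @param dir output directory (created if missing).
#' @param id file-name stem; defaults to the slice's `slice_id`.
#' @return invisibly, the three file paths.
#' @export
write_slice_bundle <- function(slice, dir, id = slice$slice_id) {
  if (is.null(id)) stop("slice has no id; pass `id` explicitly")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(id, c("_image.tsv", "_labels.tsv", "_meta.json")))
  write_matrix_tsv(format(slice$image, digits = 17, trim = TRUE, scientific = TRUE),
                   paths[1])
  labels <- matrix(0L, nrow(slice$image), ncol(slice$image))
  labels[slice$myo_mask] <- label_codes[["myocardium"]]
  if (!is.null(slice$truth_infarct_mask)) labels[slice$truth_infarct_mask] <- label_codes[["infarct"]]
  if (!is.null(slice$truth_mvo_mask)) labels[slice$truth_mvo_mask] <- label_codes[["mvo"]]
  write_matrix_tsv(labels, paths[2], integer = TRUE)
  meta <- list(
    id = id,
    site_label = slice$site_label,
    has_reference = !is.null(slice$truth_infarct_mask),
    endo_contour = contour_to_list(slice$endo_contour),
    epi_contour = contour_to_list(slice$epi_contour),
    spec = if (!is.null(slice$spec)) unclass(slice$spec) else NULL
  )
  jsonlite::write_json(meta, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a slice bundle
#'
#' Reconstructs the in-memory slice from the files written by
#' [write_slice_bundle()]. A missing labels file is allowed for externally
#' supplied images: the slice loads with no reference mask (segmentation
#' only; the myocardium is rasterized from the contours) and
#' `truth_infarct_mask` is NULL.
#'
#' @param image_path path to `<id>_image.tsv`.
#' @param meta_path,labels_path sibling paths; derived from `image_path` when
#'   NULL.
#' @return a `phantom_slice`-compatible list.
#' @export
read_slice_bundle <- function(image_path, meta_path = NULL, labels_path = NULL) {
  stem <- sub("_image\\.tsv$", "", image_path)
  if (is.null(meta_path)) meta_path <- paste0(stem, "_meta.json")
  if (is.null(labels_path)) labels_path <- paste0(stem, "_labels.tsv")
  if (!file.exists(image_path)) stop("missing image file: ", image_path)
  if (!file.exists(meta_path)) stop("missing meta file: ", meta_path)
  image <- read_matrix_tsv(image_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  endo <- contour_from_list(meta$endo_contour)
  epi <- contour_from_list(meta$epi_contour)
  slice <- list(
    image = image, endo_contour = endo, epi_contour = epi,
    spec = meta$spec, site_label = meta$site_label, slice_id = meta$id
  )
  if (file.exists(labels_path)) {
    labels <- read_matrix_tsv(labels_path, integer = TRUE)
    if (!identical(dim(labels), dim(image))) {
      stop("shape mismatch between ", image_path, " and ", labels_path)
    }
    slice$myo_mask <- labels >= label_codes[["myocardium"]]
    if (isTRUE(meta$has_reference)) {
      slice$truth_infarct_mask <- labels >= label_codes[["infarct"]]
      slice$truth_mvo_mask <- labels == label_codes[["mvo"]]
    }
  } else {
    slice$myo_mask <- rasterize_myocardium(endo, epi, dim(image))
  }
  structure(slice, class = "phantom_slice")
}

#' Load every slice bundle in a directory
#'
#' @param dir directory of bundles.
#' @return list of slices, ordered by id.
#' @export
load_cohort <- function(dir) {
  imgs <- sort(list.files(dir, pattern = "_image\\.tsv$", full.names = TRUE))
  if (!length(imgs)) stop("no slice bundles (*_image.tsv) found in ", dir)
  lapply(imgs, read_slice_bundle)
}

#' Read and validate a cohort configuration file
#'
#' JSON schema: `{"master_seed": int, "sites": [{"label": chr, "count": int,
#' "template": {phantom_spec fields, two-element arrays as ranges}}]}`.
#' Angles are degrees; intensities are on the normalized 0-1 scale.
#'
#' @param path JSON file.
#' @return validated config list.
#' @export
read_cohort_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(cfg$master_seed)) stop("config error: field 'master_seed' is required")
  if (is.null(cfg$sites) || !length(cfg$sites)) {
    stop("config error: field 'sites' must be a non-empty list")
  }
  for (i in seq_along(cfg$sites)) {
    s <- cfg$sites[[i]]
    for (f in c("label", "count", "template")) {
      if (is.null(s[[f]])) stop("config error: sites[", i, "] is missing field '", f, "'")
    }
    if (s$count < 1) stop("config error: sites[", i, "]$count must be >= 1")
    tmpl <- s$template
    tmpl <- lapply(tmpl, function(v) if (is.list(v)) unlist(v) else v)
    cfg$sites[[i]]$template <- tmpl
    # surface invalid-spec errors with the offending site named, at fixed
    # values (ranges resolved at their midpoint for validation)
    probe <- lapply(tmpl, function(v) if (is.numeric(v) && length(v) == 2L) mean(v) else v)
    probe$site_label <- s$label
    tryCatch(do.call(phantom_spec, probe),
             error = function(e) stop("config error in sites[", i, "] ('", s$label,
                                      "'): ", conditionMessage(e), call. = FALSE))
  }
  cfg
}

#' Generate a phantom cohort from a config file
#'
#' Writes one slice bundle per generated slice plus `manifest.json` (config
#' hash, master seed, package version, file list, timestamp). Rerunning with
#' the same config produces byte-identical image and label files (the
#' manifest's timestamp differs).
#'
#' @param config_path JSON config (see [read_cohort_config()]).
#' @param out_dir output directory.
#' @return invisibly, the manifest list.
#' @export
cli_phantom_generate <- function(config_path, out_dir) {
  cfg <- read_cohort_config(config_path)
  site_specs <- lapply(cfg$sites, function(s) {
    list(template = s$template, count = s$count, label = s$label)
  })
  slices <- generate_cohort(site_specs, cfg$master_seed)
  files <- character(0)
  for (sl in slices) {
    files <- c(files, write_slice_bundle(sl, out_dir))
  }
  manifest <- list(
    config_hash = config_hash(cfg),
    master_seed = cfg$master_seed,
    package_version = as.character(utils::packageVersion("nsdremote")),
    files = basename(files),
    n_slices = length(slices),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

summary_to_list <- function(s) {
  s <- unclass(s)
  s$per_slice_cov <- NULL
  s
}

#' Run studies over a cohort directory
#'
#' Applies the slice-inclusion filter, runs the requested studies and writes,
#' per study, `<study>_outcomes.csv` plus a combined `summary.json`; excluded
#' slices and reasons go to `run.log`.
#'
#' @param cohort_dir directory of slice bundles.
#' @param study one or more of `"position"`, `"size"`, `"nsd"`, `"spurious"`,
#'   `"optimal-n"`, `"signal-variability"`, or `"all"`.
#' @param out_dir results directory.
#' @param config a [study_config()].
#' @return invisibly, the list of study results.
#' @export
cli_study_run <- function(cohort_dir, study = "all", out_dir,
                          config = study_config()) {
  all_studies <- c("position", "size", "nsd", "spurious", "optimal-n", "signal-variability")
  study <- if ("all" %in% study) all_studies else match.arg(study, all_studies, several.ok = TRUE)
  slices <- load_cohort(cohort_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  results <- list()
  summaries <- list()

  log_excluded <- function(tag, excl) {
    if (!is.null(excl) && nrow(excl)) {
      log_lines <<- c(log_lines, sprintf("[%s] excluded %s: %s", tag,
                                         excl$slice_id, excl$reason))
    }
  }
  write_outcomes <- function(tag, outcomes) {
    utils::write.csv(outcomes, file.path(out_dir, paste0(tag, "_outcomes.csv")),
                     row.names = FALSE)
  }

  for (st in study) {
    if (st == "position") {
      r <- run_position_study(slices, config)
      write_outcomes("position", r$outcomes); log_excluded("position", r$excluded)
      summaries$position <- summary_to_list(r$summary)
    } else if (st == "size") {
      r <- run_size_study(slices, config)
      write_outcomes("size", r$outcomes); log_excluded("size", r$excluded)
      summaries$size <- summary_to_list(r$summary)
    } else if (st == "nsd") {
      r <- run_nsd_study(slices, config)
      write_outcomes("nsd", r$outcomes); log_excluded("nsd", r$excluded)
      summaries$nsd <- summary_to_list(r$summary)
    } else if (st == "spurious") {
      r <- run_spurious_comparison(slices, config)
      write_outcomes("spurious", r$outcomes); log_excluded("spurious", r$excluded)
      summaries$spurious <- list(naive = summary_to_list(r$naive),
                                 no_spurious = summary_to_list(r$no_spurious),
                                 paired_mean_diff = r$paired_mean_diff)
    } else if (st == "optimal-n") {
      r <- run_optimal_n_study(slices, config)
      utils::write.csv(r$per_slice, file.path(out_dir, "optimal_n_per_slice.csv"),
                       row.names = FALSE)
      summaries$optimal_n <- list(mean = r$mean, sd = r$sd,
                                  per_site = r$per_site)
    } else if (st == "signal-variability") {
      r <- signal_variability_report(slices, config$baseline_width, config$rim_fraction)
      utils::write.csv(r$per_slice, file.path(out_dir, "signal_variability_per_slice.csv"),
                       row.names = FALSE)
      summaries$signal_variability <- list(per_group = r$per_group)
    }
    results[[st]] <- r
  }

  if (!length(results)) stop("empty cohort after filtering: no study could run")
  jsonlite::write_json(summaries, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(results)
}
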