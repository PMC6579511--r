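MANIFEST_SCHEMA_VERSION <- 1L

#' Write an imaging session to disk
#'
#' Writes one multi-page 16-bit TIFF per trial, the ROI mask (single-page
#' TIFF), and a JSON manifest holding the frame rate, per-trial stimulus
#' metadata and file names, the seed, and — for synthetic sessions — the
#' ground-truth block (per-frame true shifts and realized amplitudes).
#'
#' @param trials list of `synthetic_trial` or [trial_movie()] objects (e.g.
#'   from [make_imaging_session()]).
#' @param dir output directory (created if missing).
#' @param roi_mask logical matrix; defaults to the session's `roi_mask`
#'   attribute when present.
#' @param seed seed recorded in the manifest.
#' @return the manifest path, invisibly.
#' @export
write_session <- function(trials, dir, roi_mask = attr(trials, "roi_mask"),
                          seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  is_syn <- vapply(trials, inherits, logical(1), "synthetic_trial")
  movies <- lapply(seq_along(trials), function(i)
    if (is_syn[i]) trials[[i]]$movie else trials[[i]])
  files <- sprintf("trial_%03d.tif", seq_along(movies))
  for (i in seq_along(movies))
    write_movie(movies[[i]], file.path(dir, files[i]))
  roi_file <- NULL
  if (!is.null(roi_mask)) {
    roi_file <- "roi_mask.tif"
    write_roi_mask(roi_mask, file.path(dir, roi_file))
  }
  man <- list(
    schema_version = MANIFEST_SCHEMA_VERSION,
    frame_rate = movies[[1]]$frame_rate,
    seed = seed,
    roi_file = roi_file,
    trials = lapply(seq_along(movies), function(i) {
      m <- movies[[i]]
      list(file = files[i], stimulus = m$stimulus, dose = m$dose,
           fly_id = m$fly_id, trial_label = m$trial_label,
           onset_frame = m$onset_frame, offset_frame = m$offset_frame,
           n_frames = n_frames(m))
    }))
  if (any(is_syn))
    man$truth <- lapply(trials[is_syn], function(t) list(
      trial_label = t$movie$trial_label,
      true_amplitude = t$truth$true_amplitude,
      true_shifts = unname(t$truth$true_shifts)))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read an imaging session from a manifest
#'
#' Validates the schema version, that every listed trial file exists, and
#' that each stack's frame count matches the manifest before returning the
#' movies. Mismatches raise errors naming the offending trial.
#'
#' @param path manifest file, or a directory containing `manifest.json`.
#' @return list with `trials` (list of [trial_movie()]), `roi` (logical
#'   mask or `NULL`), and `manifest` (parsed JSON).
#' @export
read_session <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  if (!file.exists(path)) stop_ft("manifest not found: %s", path)
  man <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(man$schema_version) ||
      man$schema_version != MANIFEST_SCHEMA_VERSION)
    stop_ft("unsupported manifest schema version: %s",
            man$schema_version %||% "missing")
  dir <- dirname(path)
  trials <- lapply(man$trials, function(tr) {
    f <- file.path(dir, tr$file)
    if (!file.exists(f)) stop_ft("trial '%s': file %s does not exist",
                                 tr$trial_label, tr$file)
    frames <- read_movie(f)
    if (dim(frames)[3] != tr$n_frames)
      stop_ft("trial '%s': %d frames on disk but manifest says %d",
              tr$trial_label, dim(frames)[3], tr$n_frames)
    trial_movie(frames, frame_rate = man$frame_rate,
                onset_frame = tr$onset_frame, offset_frame = tr$offset_frame,
                stimulus = tr$stimulus, dose = tr$dose %||% NA_real_,
                fly_id = tr$fly_id, trial_label = tr$trial_label)
  })
  roi <- NULL
  if (!is.null(man$roi_file)) {
    rf <- file.path(dir, man$roi_file)
    if (!file.exists(rf)) stop_ft("ROI mask file missing: %s", man$roi_file)
    roi <- read_roi_mask(rf)
  }
  list(trials = trials, roi = roi, manifest = man)
}
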