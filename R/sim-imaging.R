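#' Simulation parameters for synthetic taste-imaging trials
#'
#' Describes a two-photon imaging protocol of the kind used for labellar
#' taste sensory neurons: single-plane grayscale movies (default 256x256
#' pixels at 3.5 Hz), a 2 s tastant stimulus preceded by at least 20 baseline
#' frames, at least three trials per stimulus, GCaMP6f-like transients with
#' trial-to-trial variability and multiplicative adaptation across repeated
#' presentations, slow rigid x-y drift with frame jitter, and photon +
#' read-out noise.
#'
#' @param frame_height,frame_width frame size in pixels.
#' @param frame_rate scan rate in Hz (the protocol this emulates uses 3-4 Hz).
#' @param stimulus_duration tastant presentation, seconds.
#' @param n_baseline_frames pre-stimulus frames (>= 20; the first 20 before
#'   onset define F0 downstream).
#' @param n_post_frames frames after stimulus offset.
#' @param n_trials_per_stimulus trials per stimulus in a session (>= 3).
#' @param roi_spec list with `center` (row, col), `radius` (pixels) and
#'   `soft_edge` (pixels; 0 = hard disc) describing the axonal-projection
#'   region that carries signal.
#' @param amplitude_schedule named numeric vector mapping stimulus label to
#'   true peak dF/F0 amplitude (fraction; 1.2 = 120%).
#' @param trial_cv lognormal coefficient of variation of amplitude across
#'   trials.
#' @param adaptation_factor multiplicative amplitude decay per preceding
#'   trial of the same stimulus, in (0, 1].
#' @param transient_rise_tau,transient_decay_tau kernel time constants,
#'   seconds (GCaMP6f-like defaults).
#' @param drift_per_frame length-2 `(dx, dy)` mean drift per frame, pixels.
#' @param jitter_sd per-frame random-walk jitter sd, pixels.
#' @param photon_gain detector counts per photon (0 disables photon noise).
#' @param read_noise_sd Gaussian read noise sd, counts (0 disables).
#' @param baseline_intensity mean baseline fluorescence, counts.
#' @param background_contrast amplitude of the static smooth background
#'   texture (fraction of baseline) that gives frames registrable structure.
#' @param roi_baseline_contrast resting brightness of the axonal projection
#'   above the surround (fraction of baseline); the projection is visible
#'   before stimulation, which is what makes manual ROI drawing and
#'   registration possible in real recordings.
#' @return an object of class `imaging_sim_params`.
#' @export
imaging_sim_params <- function(frame_height = 256L, frame_width = 256L,
                               frame_rate = 3.5, stimulus_duration = 2,
                               n_baseline_frames = 20L, n_post_frames = 13L,
                               n_trials_per_stimulus = 3L,
                               roi_spec = NULL,
                               amplitude_schedule = c(water = 0, aa_1 = 1.2,
                                                      aa_5 = 1.1,
                                                      sucrose_500 = 2.4),
                               trial_cv = 0.2, adaptation_factor = 0.9,
                               transient_rise_tau = 0.1,
                               transient_decay_tau = 0.4,
                               drift_per_frame = c(0.02, 0.02),
                               jitter_sd = 0.05,
                               photon_gain = 2, read_noise_sd = 4,
                               baseline_intensity = 1000,
                               background_contrast = 0.3,
                               roi_baseline_contrast = 0.5) {
  if (is.null(roi_spec))
    roi_spec <- list(center = c(frame_height / 2, frame_width / 2),
                     radius = round(min(frame_height, frame_width) / 8),
                     soft_edge = 0)
  roi_spec$soft_edge <- roi_spec$soft_edge %||% 0
  p <- structure(list(
    frame_height = as.integer(frame_height),
    frame_width = as.integer(frame_width),
    frame_rate = frame_rate, stimulus_duration = stimulus_duration,
    n_baseline_frames = as.integer(n_baseline_frames),
    n_post_frames = as.integer(n_post_frames),
    n_trials_per_stimulus = as.integer(n_trials_per_stimulus),
    roi_spec = roi_spec, amplitude_schedule = amplitude_schedule,
    trial_cv = trial_cv, adaptation_factor = adaptation_factor,
    transient_rise_tau = transient_rise_tau,
    transient_decay_tau = transient_decay_tau,
    drift_per_frame = drift_per_frame, jitter_sd = jitter_sd,
    photon_gain = photon_gain, read_noise_sd = read_noise_sd,
    baseline_intensity = baseline_intensity,
    background_contrast = background_contrast,
    roi_baseline_contrast = roi_baseline_contrast),
    class = "imaging_sim_params")
  validate_imaging_sim_params(p)
}

validate_imaging_sim_params <- function(p) {
  if (p$frame_rate <= 0) stop_ft("frame_rate must be > 0")
  if (p$stimulus_duration <= 0) stop_ft("stimulus_duration must be > 0")
  if (any(p$amplitude_schedule < 0)) stop_ft("amplitudes must be >= 0")
  if (is.null(names(p$amplitude_schedule)))
    stop_ft("amplitude_schedule must be a named vector")
  if (p$adaptation_factor <= 0 || p$adaptation_factor > 1)
    stop_ft("adaptation_factor must be in (0, 1]")
  if (p$n_baseline_frames < 20L)
    stop_ft("n_baseline_frames must be >= 20 (F0 uses 20 pre-stimulus frames)")
  if (p$transient_rise_tau <= 0 || p$transient_decay_tau <= 0)
    stop_ft("transient time constants must be positive")
  r <- p$roi_spec
  if (r$center[1] - r$radius < 1 || r$center[1] + r$radius > p$frame_height ||
      r$center[2] - r$radius < 1 || r$center[2] + r$radius > p$frame_width)
    stop_ft("ROI must lie strictly inside the frame bounds")
  if (n_stimulus_frames(p) < 2L)
    stop_ft("stimulus window must span at least 2 frames")
  p
}

n_stimulus_frames <- function(p)
  max(2L, as.integer(round(p$stimulus_duration * p$frame_rate)))

n_total_frames <- function(p)
  p$n_baseline_frames + n_stimulus_frames(p) + p$n_post_frames

#' Calcium transient kernel (normalized step response)
#'
#' Fluorescence response of a two-time-constant indicator to a sustained
#' tastant stimulus of length `duration`: saturating rise
#' `1 - exp(-t/tau_rise)` while the stimulus is on, exponential decay with
#' `tau_decay` after offset, normalized so its maximum (at stimulus offset)
#' is exactly 1. With a fast rise (default tau 0.1 s) the kernel plateaus at
#' ~1 for most of a 2 s stimulus, so the peak dF/F0 statistic reads out the
#' amplitude without sampling bias at 3-4 Hz scan rates.
#'
#' @param t time since stimulus onset, seconds (vectorized; t < 0 gives 0).
#' @param duration stimulus duration, seconds.
#' @param rise_tau,decay_tau time constants, seconds.
#' @return kernel values in `[0, 1]`.
#' @export
gcamp_kernel <- function(t, duration = 2, rise_tau = 0.1, decay_tau = 0.4) {
  if (rise_tau <= 0 || decay_tau <= 0) stop_ft("kernel taus must be positive")
  peak <- 1 - exp(-duration / rise_tau)
  k <- numeric(length(t))
  on <- t >= 0 & t <= duration
  post <- t > duration
  k[on] <- (1 - exp(-t[on] / rise_tau)) / peak
  k[post] <- exp(-(t[post] - duration) / decay_tau)
  k
}

# soft-edged disc weight image in [0,1]; hard disc when soft_edge == 0
roi_weight_image <- function(h, w, center, radius, soft_edge = 0) {
  d <- sqrt(outer((seq_len(h) - center[1])^2,
                  (seq_len(w) - center[2])^2, `+`))
  if (soft_edge <= 0) (d <= radius) * 1
  else 1 / (1 + exp((d - radius) / soft_edge))
}

# static smooth texture: sum of gaussian bumps (fixed per fly, gives the
# registration stage structure to lock on to)
background_pattern <- function(h, w, contrast, seed, n_bumps = 6L) {
  if (contrast <= 0) return(matrix(0, h, w))
  with_seed(seed, {
    bg <- matrix(0, h, w)
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (i in seq_len(n_bumps)) {
      cy <- runif(1, 0.15 * h, 0.85 * h)
      cx <- runif(1, 0.15 * w, 0.85 * w)
      sd <- runif(1, 0.05, 0.15) * min(h, w)
      amp <- runif(1, 0.3, 1)
      bg <- bg + amp * exp(-((rows - cy)^2 + (cols - cx)^2) / (2 * sd^2))
    }
    contrast * bg / max(bg)
  })
}

#' Generate one synthetic imaging trial with ground truth
#'
#' Builds a noise- and motion-corrupted movie of a fluorescent axonal
#' projection responding to one tastant presentation. Inside the ROI the
#' ideal signal is `baseline * (1 + a * k(t))` where `k(t)` is
#' [gcamp_kernel()] and the realized amplitude is
#' `a = schedule[stimulus] * adaptation_factor^trial_index * LN(1, trial_cv)`
#' (`LN` a mean-1 lognormal). Frames are rigidly translated by a cumulative
#' drift + jitter random walk (periodic Fourier resampling, so registration
#' round-trips are exact), then Poisson photon noise and Gaussian read noise
#' are added. The returned object carries a ground-truth manifest (per-frame
#' true shifts, realized amplitude, true ROI mask, stimulus window).
#'
#' @param params an [imaging_sim_params()] object.
#' @param stimulus stimulus label; must name an entry of the amplitude
#'   schedule.
#' @param trial_index 0-based count of preceding same-stimulus trials
#'   (drives adaptation).
#' @param seed integer seed; the trial is deterministic given
#'   `(params, stimulus, trial_index, seed)`.
#' @param start_shift drift state `(dx, dy)` at trial start (used by
#'   [make_imaging_session()] to share one drift process across trials).
#' @param background optional precomputed background texture matrix.
#' @param fly_id,trial_label identifiers stored in the movie metadata.
#' @return a `synthetic_trial`: list with `movie` (a `trial_movie`) and
#'   `truth` (`true_shifts`, `true_amplitude`, `roi_mask`,
#'   `stimulus_onset_frame`, `stimulus_offset_frame`, `end_shift`).
#' @export
make_imaging_trial <- function(params, stimulus, trial_index = 0L, seed = 1L,
                               start_shift = c(0, 0), background = NULL,
                               fly_id = "fly1", trial_label = NULL) {
  validate_imaging_sim_params(params)
  if (trial_index < 0) stop_ft("trial_index must be >= 0")
  if (!stimulus %in% names(params$amplitude_schedule))
    stop_ft("stimulus '%s' not in amplitude_schedule", stimulus)
  h <- params$frame_height; w <- params$frame_width
  n <- n_total_frames(params)
  onset <- params$n_baseline_frames + 1L
  offset <- params$n_baseline_frames + n_stimulus_frames(params)

  base_amp <- unname(params$amplitude_schedule[stimulus]) *
    params$adaptation_factor^trial_index
  if (is.null(background))
    background <- background_pattern(h, w, params$background_contrast,
                                     substream_seed(seed, "background"))
  roi_w <- roi_weight_image(h, w, params$roi_spec$center,
                            params$roi_spec$radius, params$roi_spec$soft_edge)
  roi_mask <- roi_w >= 0.5

  with_seed(substream_seed(seed, paste("trial", stimulus, trial_index)), {
    amp <- if (params$trial_cv > 0 && base_amp > 0) {
      sdlog <- sqrt(log(1 + params$trial_cv^2))
      base_amp * rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else base_amp

    # cumulative drift: random walk continued from start_shift
    steps_x <- params$drift_per_frame[1] + rnorm(n, 0, params$jitter_sd)
    steps_y <- params$drift_per_frame[2] + rnorm(n, 0, params$jitter_sd)
    if (params$jitter_sd == 0 && all(params$drift_per_frame == 0)) {
      shifts <- matrix(rep(start_shift, each = n), n, 2)
    } else {
      shifts <- cbind(start_shift[1] + cumsum(steps_x),
                      start_shift[2] + cumsum(steps_y))
    }
    colnames(shifts) <- c("dx", "dy")

    tmid <- (seq_len(n) - 0.5) / params$frame_rate
    kt <- gcamp_kernel(tmid - params$n_baseline_frames / params$frame_rate,
                       params$stimulus_duration, params$transient_rise_tau,
                       params$transient_decay_tau)
    frames <- array(0, dim = c(h, w, n))
    base_img <- params$baseline_intensity *
      (1 + background + params$roi_baseline_contrast * roi_w)
    for (i in seq_len(n)) {
      # fractional change of the local baseline structure, so the ROI-mean
      # dF/F0 equals amp * k(t) whatever the background texture
      ideal <- base_img * (1 + amp * kt[i] * roi_w)
      if (any(shifts[i, ] != 0))
        ideal <- shift_frame(ideal, shifts[i, 1], shifts[i, 2])
      if (params$photon_gain > 0)
        ideal <- params$photon_gain *
          rpois(h * w, pmax(ideal, 0) / params$photon_gain)
      if (params$read_noise_sd > 0)
        ideal <- ideal + rnorm(h * w, 0, params$read_noise_sd)
      frames[, , i] <- ideal
    }

    movie <- trial_movie(frames, frame_rate = params$frame_rate,
                         onset_frame = onset, offset_frame = offset,
                         stimulus = stimulus, fly_id = fly_id,
                         trial_label = trial_label %||%
                           sprintf("%s_t%d", stimulus, trial_index))
    structure(list(
      movie = movie,
      truth = list(true_shifts = shifts, true_amplitude = amp,
                   roi_mask = roi_mask, stimulus_onset_frame = onset,
                   stimulus_offset_frame = offset,
                   end_shift = shifts[n, ])),
      class = "synthetic_trial")
  })
}

#' Generate a full synthetic imaging session
#'
#' Runs [make_imaging_trial()] over a stimulus presentation order (the
#' protocol this emulates presents each stimulus in at least three trials,
#' concentrations in ascending order), sharing one cumulative drift process
#' and one background texture across trials so the session behaves like a
#' single continuous recording. `stimulus_order` is expanded trial-by-trial:
#' each element is presented `n_trials_per_stimulus` times consecutively,
#' and adaptation indexes the number of preceding trials of the same
#' stimulus.
#'
#' @param params an [imaging_sim_params()] object.
#' @param stimulus_order character vector of stimulus labels.
#' @param seed integer seed; sessions are bit-identical given
#'   `(params, stimulus_order, seed)`.
#' @param fly_id identifier stored with every trial.
#' @return list of `synthetic_trial` objects, with attributes `roi_mask` and
#'   `fly_id`.
#' @export
make_imaging_session <- function(params, stimulus_order, seed = 1L,
                                 fly_id = "fly1") {
  if (length(stimulus_order) == 0) stop_ft("stimulus_order must be non-empty")
  validate_imaging_sim_params(params)
  labels <- rep(stimulus_order, each = params$n_trials_per_stimulus)
  idx_within <- unlist(lapply(stimulus_order, function(s)
    seq_len(params$n_trials_per_stimulus) - 1L))
  # adaptation counts all preceding presentations of the same stimulus label
  adapt_index <- integer(length(labels))
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(labels)) {
    k <- get0(labels[i], envir = seen, ifnotfound = 0L)
    adapt_index[i] <- k
    assign(labels[i], k + 1L, envir = seen)
  }
  trial_labels <- sprintf("%s_trial%d", labels, idx_within + 1L)
  if (anyDuplicated(trial_labels)) stop_ft("duplicate trial identifiers")

  background <- background_pattern(params$frame_height, params$frame_width,
                                   params$background_contrast,
                                   substream_seed(seed, paste0("bg_", fly_id)))
  shift_state <- c(0, 0)
  trials <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    tr <- make_imaging_trial(params, labels[i], trial_index = adapt_index[i],
                             seed = substream_seed(seed, paste0("s", i)),
                             start_shift = shift_state,
                             background = background, fly_id = fly_id,
                             trial_label = trial_labels[i])
    shift_state <- tr$truth$end_shift
    trials[[i]] <- tr
  }
  structure(trials, roi_mask = trials[[1]]$truth$roi_mask, fly_id = fly_id)
}
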