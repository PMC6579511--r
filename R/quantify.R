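#' Extract the mean-ROI intensity trace from a movie
#'
#' Average pixel intensity within the ROI for each frame — the ROI is drawn
#' around the area of axonal projections and supplied as a boolean mask
#' (this pipeline never segments automatically).
#'
#' @param movie a [trial_movie()] (or `synthetic_trial`).
#' @param roi logical matrix, `TRUE` inside the ROI.
#' @return an object of class `raw_trace`: list with `values` (counts per
#'   frame), `frame_rate`, `onset_frame`, `offset_frame`.
#' @export
roi_trace <- function(movie, roi) {
  if (inherits(movie, "synthetic_trial")) movie <- movie$movie
  if (!is.logical(roi)) roi <- roi >= 0.5
  if (!all(dim(roi) == dim(movie$frames)[1:2]))
    stop_ft("ROI mask shape does not match the frames")
  if (!any(roi)) stop_ft("empty ROI mask")
  mat <- matrix(movie$frames, prod(dim(roi)), n_frames(movie))
  structure(list(values = colMeans(mat[as.vector(roi), , drop = FALSE]),
                 frame_rate = movie$frame_rate,
                 onset_frame = movie$onset_frame,
                 offset_frame = movie$offset_frame),
            class = "raw_trace")
}

#' Compute the dF/F0 trace
#'
#' The baseline signal F0 is the mean of the `n_baseline` frames immediately
#' preceding stimulus onset (20 by convention), and every frame's dF/F0 is
#' `(F - F0) / F0`. By construction the mean dF/F0 over the baseline frames
#' is exactly zero.
#'
#' @param trace a [roi_trace()] result (or any list with `values`,
#'   `frame_rate`, `onset_frame`, `offset_frame`).
#' @param n_baseline number of pre-stimulus frames averaged into F0.
#' @return an object of class `dff_trace`: `dff` (fractional; 0.15 = 15%),
#'   `f0`, `baseline_frames`, `stimulus_frames`, `frame_rate`.
#' @export
compute_dff <- function(trace, n_baseline = 20L) {
  v <- trace$values
  onset <- trace$onset_frame
  if (onset - 1L < n_baseline)
    stop_ft("need %d pre-stimulus frames, have %d", n_baseline, onset - 1L)
  baseline_frames <- (onset - n_baseline):(onset - 1L)
  if (any(!is.finite(v[baseline_frames])))
    stop_ft("non-finite values in the baseline window")
  f0 <- mean(v[baseline_frames])
  if (f0 <= 0) stop_ft("baseline F0 must be positive (got %g)", f0)
  structure(list(dff = (v - f0) / f0, f0 = f0,
                 baseline_frames = baseline_frames,
                 stimulus_frames = onset:trace$offset_frame,
                 frame_rate = trace$frame_rate),
            class = "dff_trace")
}

#' Peak stimulus response of a dF/F0 trace
#'
#' The peak response is the mean of the two highest *consecutive* dF/F0
#' frames during tastant presentation: the maximum over all consecutive
#' frame pairs within the stimulus window of their average. On exact ties
#' the earliest pair wins. Using a two-frame mean rather than the single
#' maximum frame makes the statistic robust to one-frame noise spikes; it is
#' always at most the single-frame maximum and at least the window mean.
#'
#' @param dff a [compute_dff()] result.
#' @param extend_s optional post-stimulus extension of the window, seconds
#'   (default 0: presentation frames only).
#' @return peak dF/F0 as a fraction (0.15 = 15%).
#' @export
peak_response <- function(dff, extend_s = 0) {
  win <- dff$stimulus_frames
  if (extend_s > 0) {
    extra <- round(extend_s * dff$frame_rate)
    win <- c(win, max(win) + seq_len(extra))
    win <- win[win <= length(dff$dff)]
  }
  x <- dff$dff[win]
  if (length(x) < 2L) stop_ft("need >= 2 frames in the stimulus window")
  if (any(!is.finite(x))) stop_ft("non-finite dF/F0 in the stimulus window")
  pair_means <- (x[-length(x)] + x[-1]) / 2
  pair_means[which.max(pair_means)]   # which.max returns the first maximum
}

#' Integrated dF/F0 response
#'
#' Time-integral of dF/F0 over a response window, in dF/F0-seconds: the sum
#' of per-frame values divided by the frame rate. Because frames sample the
#' midpoint of each acquisition interval this is the midpoint rule, accurate
#' to O(1/frame_rate^2) for smooth transients. The default window is the
#' stimulus presentation plus 2 s post-stimulus, capturing indicator decay
#' after valve closure.
#'
#' @param dff a [compute_dff()] result.
#' @param window integer frame indices, or `NULL` for the default.
#' @param post_s post-stimulus extension used when `window` is `NULL`.
#' @return integral in dF/F0 x seconds.
#' @export
integrated_response <- function(dff, window = NULL, post_s = 2) {
  if (is.null(window)) {
    extra <- round(post_s * dff$frame_rate)
    window <- c(dff$stimulus_frames, max(dff$stimulus_frames) + seq_len(extra))
    window <- window[window <= length(dff$dff)]
  }
  if (any(window < 1L | window > length(dff$dff)))
    stop_ft("window outside the trace")
  x <- dff$dff[window]
  if (any(!is.finite(x))) stop_ft("non-finite dF/F0 in the response window")
  sum(x) / dff$frame_rate
}

#' Average a per-trial statistic over included trials
#'
#' Mean across the trials of one fly x stimulus, honoring the trial
#' exclusion rule: trials are only dropped when the tastant failed to make
#' proper contact (a QC flag supplied by the experimenter, never inferred).
#'
#' @param values numeric per-trial statistics.
#' @param included logical inclusion flags (default: all included).
#' @return list with `mean` and `n_included`.
#' @export
fly_average <- function(values, included = rep(TRUE, length(values))) {
  stopifnot(length(values) == length(included))
  if (!any(included)) stop_ft("all trials excluded: no data to average")
  list(mean = mean(values[included]), n_included = sum(included))
}

#' Classify a fly as responding to a tastant
#'
#' A fly responds to a tastant if its average peak response across at least
#' three trials exceeds its average peak response to water by at least the
#' threshold `theta` (inclusive). `theta` is in absolute dF/F0 fraction:
#' the default 0.15 is 15 percentage points of dF/F0, with 0.10 and 0.20 as
#' the conventional alternatives. A relative mode
#' (`mean_peak >= water * (1 + theta)`) is available but off by default.
#'
#' @param mean_peak,water_mean_peak trial-averaged peak dF/F0 (fractions).
#' @param theta threshold (default 0.15).
#' @param n_trials,n_water_trials trial counts behind each mean (must be at
#'   least 3 when supplied).
#' @param fly_id,stimulus identifiers carried into the result.
#' @param relative if `TRUE`, use the relative rule.
#' @return an object of class `responder_call`.
#' @export
classify_responder <- function(mean_peak, water_mean_peak, theta = 0.15,
                               n_trials = NULL, n_water_trials = NULL,
                               fly_id = NA_character_,
                               stimulus = NA_character_, relative = FALSE) {
  for (n in c(n_trials, n_water_trials))
    if (!is.null(n) && n < 3L)
      stop_ft("responder calls need >= 3 included trials (got %d)", n)
  is_resp <- if (relative) mean_peak >= water_mean_peak * (1 + theta)
             else mean_peak - water_mean_peak >= theta
  structure(list(fly_id = fly_id, stimulus = stimulus,
                 mean_peak = mean_peak, water_mean_peak = water_mean_peak,
                 threshold = theta, is_responder = is_resp),
            class = "responder_call")
}

#' Quantify a registered session into per-trial statistics
#'
#' Runs [roi_trace()], [compute_dff()], [peak_response()] and
#' [integrated_response()] over every trial of a session.
#'
#' @param trials list of [trial_movie()] / `registration_result` /
#'   `synthetic_trial` objects.
#' @param roi logical ROI mask.
#' @param n_baseline baseline frames for F0 (default 20).
#' @param peak_extend_s,integrate_post_s window options passed through.
#' @param included logical per-trial inclusion flags (delivery-failure QC).
#' @return data.frame: fly_id, stimulus, trial_label, f0, peak, integrated,
#'   included.
#' @export
quantify_session <- function(trials, roi, n_baseline = 20L,
                             peak_extend_s = 0, integrate_post_s = 2,
                             included = rep(TRUE, length(trials))) {
  movies <- lapply(trials, function(t) {
    if (inherits(t, "registration_result")) t$movie
    else if (inherits(t, "synthetic_trial")) t$movie
    else t
  })
  rows <- lapply(seq_along(movies), function(i) {
    m <- movies[[i]]
    d <- compute_dff(roi_trace(m, roi), n_baseline)
    data.frame(fly_id = m$fly_id, stimulus = m$stimulus,
               trial_label = m$trial_label, f0 = d$f0,
               peak = peak_response(d, peak_extend_s),
               integrated = integrated_response(d, post_s = integrate_post_s),
               included = included[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-fly responder table over a set of thresholds
#'
#' Aggregates per-trial peaks to fly x stimulus means (included trials
#' only), then applies the responder rule against each fly's own water
#' response at every threshold in `thetas`. Stimuli with fewer than three
#' included trials are reported with `NA` calls.
#'
#' @param trial_stats data.frame from [quantify_session()].
#' @param water_label stimulus label of the water control.
#' @param thetas thresholds to evaluate (dF/F0 fractions).
#' @return data.frame: fly_id, stimulus, mean_peak, n_trials,
#'   water_mean_peak, and one logical `responder_<theta>` column per
#'   threshold.
#' @export
responder_table <- function(trial_stats, water_label = "water",
                            thetas = c(0.10, 0.15, 0.20)) {
  if (!water_label %in% trial_stats$stimulus)
    stop_ft("no '%s' trials: responder calls need a water reference",
            water_label)
  agg <- function(df) {
    fa <- fly_average(df$peak, df$included)
    data.frame(mean_peak = fa$mean, n_trials = fa$n_included)
  }
  keys <- unique(trial_stats[c("fly_id", "stimulus")])
  per_fly <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- trial_stats$fly_id == keys$fly_id[i] &
      trial_stats$stimulus == keys$stimulus[i]
    cbind(keys[i, , drop = FALSE], agg(trial_stats[sel, ]))
  }))
  out <- per_fly[per_fly$stimulus != water_label, ]
  water <- per_fly[per_fly$stimulus == water_label,
                   c("fly_id", "mean_peak", "n_trials")]
  names(water)[2:3] <- c("water_mean_peak", "n_water_trials")
  out <- merge(out, water, by = "fly_id", sort = FALSE)
  for (th in thetas) {
    ok <- out$n_trials >= 3L & out$n_water_trials >= 3L
    col <- rep(NA, nrow(out))
    col[ok] <- (out$mean_peak[ok] - out$water_mean_peak[ok]) >= th
    out[[sprintf("responder_%.2f", th)]] <- col
  }
  rownames(out) <- NULL
  out
}
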