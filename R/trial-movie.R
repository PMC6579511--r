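#' Construct a trial movie
#'
#' Container for one trial's frame stack plus its stimulus timing. Frames
#' are a numeric `height x width x n_frames` array; frame indices are
#' 1-based and the stimulus window includes both `onset_frame` and
#' `offset_frame`.
#'
#' @param frames numeric 3-d array `(row, col, frame)`.
#' @param frame_rate acquisition rate, Hz.
#' @param onset_frame,offset_frame first and last frame of tastant
#'   presentation.
#' @param stimulus stimulus label.
#' @param dose optional numeric concentration.
#' @param fly_id,trial_label identifiers.
#' @return an object of class `trial_movie`.
#' @export
trial_movie <- function(frames, frame_rate, onset_frame, offset_frame,
                        stimulus = "unknown", dose = NA_real_,
                        fly_id = NA_character_, trial_label = NA_character_) {
  if (length(dim(frames)) != 3L) stop_ft("frames must be a 3-d array")
  if (frame_rate <= 0) stop_ft("frame_rate must be > 0")
  n <- dim(frames)[3]
  onset_frame <- as.integer(onset_frame); offset_frame <- as.integer(offset_frame)
  if (onset_frame < 1L || offset_frame > n || offset_frame <= onset_frame - 1L)
    stop_ft("invalid stimulus window [%d, %d] for %d frames",
            onset_frame, offset_frame, n)
  structure(list(frames = frames, frame_rate = frame_rate,
                 onset_frame = onset_frame, offset_frame = offset_frame,
                 stimulus = stimulus, dose = dose, fly_id = fly_id,
                 trial_label = trial_label),
            class = "trial_movie")
}

#' @export
print.trial_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<trial_movie> %dx%d px, %d frames @ %.2f Hz, stimulus '%s' frames %d-%d\n",
              d[1], d[2], d[3], x$frame_rate, x$stimulus,
              x$onset_frame, x$offset_frame))
  invisible(x)
}

n_frames <- function(movie) dim(movie$frames)[3]
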