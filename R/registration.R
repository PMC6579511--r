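#' Estimate a sub-pixel rigid shift by upsampled cross-correlation
#'
#' Finds the translation `(dx, dy)` that best aligns `target` onto
#' `reference`, to a precision of `1/upsample` pixel, using the single-step
#' DFT method: the cross-correlation peak is located on the pixel grid via
#' FFT, then refined by evaluating the inverse DFT of the cross-power
#' spectrum on a `1/upsample`-spaced grid in a small neighborhood of the
#' coarse peak (a matrix-multiply DFT, so no large zero-padded transforms
#' are needed). Both images are mean-subtracted first; boundaries are
#' periodic.
#'
#' The returned shift satisfies `target ~ shift_frame(reference, dx, dy)`;
#' apply `shift_frame(target, -dx, -dy)` to register.
#'
#' @param reference,target numeric matrices of identical shape.
#' @param upsample integer >= 1; subpixel precision is `1/upsample` px.
#' @return an object of class `shift`: list with `dx`, `dy` (pixels, `dx`
#'   along columns, `dy` along rows) and `error_metric` (normalized
#'   cross-correlation residual in `[0, 1]`, 0 = perfect match).
#' @export
estimate_shift <- function(reference, target, upsample = 20L) {
  if (!is.matrix(reference) || !is.matrix(target) ||
      !all(dim(reference) == dim(target)))
    stop_ft("reference and target must be matrices of identical shape")
  if (upsample < 1) stop_ft("upsample must be >= 1")
  if (stats::sd(reference) == 0 || stats::sd(target) == 0)
    stop_ft("constant (zero-variance) image: cross-correlation undefined")
  reference <- reference - mean(reference)
  target <- target - mean(target)
  xcorr_shift(Conj(stats::fft(reference)), stats::fft(target),
              sum(reference^2), sum(target^2),
              nrow(reference), ncol(reference), as.integer(upsample))
}

# core: Fr_conj = Conj(fft(mean-subtracted reference)), Ft = fft(target)
xcorr_shift <- function(Fr_conj, Ft, ssq_r, ssq_t, h, w, upsample) {
  P <- Ft * Fr_conj
  cc <- stats::fft(P, inverse = TRUE) / (h * w)
  peak <- arrayInd(which.max(abs(cc)), dim(cc))
  dy <- peak[1] - 1L; dx <- peak[2] - 1L
  if (dy > h / 2) dy <- dy - h
  if (dx > w / 2) dx <- dx - w
  peak_val <- abs(cc[peak[1], peak[2]])

  if (upsample > 1L) {
    # refine on a (1/upsample)-spaced grid spanning >= +-0.75 px around the
    # coarse peak (integer peak is within 0.5 px of the optimum); odd window
    # so the grid contains the coarse peak itself and self-alignment is exact
    nwin <- 2L * ceiling(0.75 * upsample) + 1L
    roff <- dy - (nwin - 1) / (2 * upsample)
    coff <- dx - (nwin - 1) / (2 * upsample)
    out <- dftups(P, nwin, nwin, upsample, roff, coff, h, w) / (h * w)
    p2 <- arrayInd(which.max(abs(out)), dim(out))
    dy <- roff + (p2[1] - 1) / upsample
    dx <- coff + (p2[2] - 1) / upsample
    peak_val <- abs(out[p2[1], p2[2]])
  }
  err <- sqrt(max(0, 1 - peak_val^2 / (ssq_r * ssq_t)))
  structure(list(dx = dx, dy = dy, error_metric = err), class = "shift")
}

# matrix-multiply inverse DFT of P on an (nor x noc) grid with spacing
# 1/usfac starting at (roff, coff) pixels
dftups <- function(P, nor, noc, usfac, roff, coff, h, w) {
  fy <- fft_freq(h); fx <- fft_freq(w)
  yy <- roff + (0:(nor - 1)) / usfac
  xx <- coff + (0:(noc - 1)) / usfac
  Kr <- exp(2i * pi * outer(yy, fy))      # nor x h
  Kc <- exp(2i * pi * outer(fx, xx))      # w x noc
  Kr %*% P %*% Kc
}

#' @export
print.shift <- function(x, ...) {
  cat(sprintf("<shift> dx = %.4f, dy = %.4f px (residual %.3g)\n",
              x$dx, x$dy, x$error_metric))
  invisible(x)
}

#' Translate an image by a (sub-pixel) rigid shift
#'
#' Moves image content by `(dx, dy)` pixels (`dx` along columns, `dy` along
#' rows) using a Fourier phase shift with periodic boundaries — the same
#' resampling the synthetic-movie generator uses, so shift/unshift
#' round-trips are exact to floating-point precision and integer shifts
#' reproduce index rolling exactly.
#'
#' @param frame numeric matrix.
#' @param dx,dy shift in pixels; alternatively `dx` may be a `shift` object.
#' @return shifted matrix of the same shape.
#' @export
shift_frame <- function(frame, dx, dy = NULL) {
  if (inherits(dx, "shift")) { dy <- dx$dy; dx <- dx$dx }
  if (!is.finite(dx) || !is.finite(dy)) stop_ft("shift must be finite")
  if (dx == 0 && dy == 0) return(frame)
  h <- nrow(frame); w <- ncol(frame)
  ph <- exp(-2i * pi * (outer(fft_freq(h) * dy, rep(1, w)) +
                          outer(rep(1, h), fft_freq(w) * dx)))
  Re(stats::fft(stats::fft(frame) * ph, inverse = TRUE)) / (h * w)
}

#' Register an imaging session within and across trials
#'
#' Builds one reference image and rigidly registers every frame of every
#' trial against it, correcting x-y motion both within and across trials.
#' The default reference is the mean of the first trial's pre-stimulus
#' baseline frames; alternatives are each trial's own first frame
#' (`"per-trial"`, which registers within trials only), the mean over all
#' frames of all trials (`"global-mean"`), or a caller-supplied matrix
#' (`reference=`, policy `"external"`).
#'
#' @param trials list of [trial_movie()] objects (or `synthetic_trial`s,
#'   whose movies are extracted).
#' @param policy reference policy.
#' @param upsample sub-pixel precision `1/upsample` px (default 20).
#' @param reference optional external reference matrix.
#' @return list of `registration_result` objects, each with `movie`
#'   (registered), `shifts` (data.frame: frame, dx, dy, error_metric) and
#'   `reference_descriptor`.
#' @export
register_session <- function(trials,
                             policy = c("first-baseline", "per-trial",
                                        "global-mean", "external"),
                             upsample = 20L, reference = NULL) {
  policy <- match.arg(policy)
  if (length(trials) == 0) stop_ft("need at least one trial")
  trials <- lapply(trials, function(t)
    if (inherits(t, "synthetic_trial")) t$movie else t)
  dims <- vapply(trials, function(t) dim(t$frames)[1:2], integer(2))
  if (any(dims != dims[, 1])) stop_ft("mismatched frame shapes across trials")
  h <- dims[1, 1]; w <- dims[2, 1]

  if (!is.null(reference)) policy <- "external"
  ref_desc <- policy
  if (policy == "first-baseline") {
    m1 <- trials[[1]]
    nb <- m1$onset_frame - 1L
    if (nb < 1L) stop_ft("first trial has no baseline frames for the reference")
    reference <- apply(m1$frames[, , seq_len(nb), drop = FALSE], c(1, 2), mean)
    ref_desc <- sprintf("mean of first trial's %d baseline frames", nb)
  } else if (policy == "global-mean") {
    acc <- matrix(0, h, w); ntot <- 0L
    for (t in trials) {
      acc <- acc + rowSums(t$frames, dims = 2)
      ntot <- ntot + n_frames(t)
    }
    reference <- acc / ntot
    ref_desc <- sprintf("mean of all %d frames", ntot)
  } else if (policy == "external") {
    if (is.null(reference) || !all(dim(reference) == c(h, w)))
      stop_ft("external policy needs a reference matrix of matching shape")
    ref_desc <- "external reference"
  }

  register_one <- function(movie, ref) {
    ref <- ref - mean(ref)
    Frc <- Conj(stats::fft(ref)); ssq_r <- sum(ref^2)
    n <- n_frames(movie)
    out <- movie$frames
    log <- data.frame(frame = seq_len(n), dx = 0, dy = 0, error_metric = 0)
    for (i in seq_len(n)) {
      fr <- movie$frames[, , i]
      frc <- fr - mean(fr)
      s <- xcorr_shift(Frc, stats::fft(frc), ssq_r, sum(frc^2), h, w,
                       as.integer(upsample))
      out[, , i] <- shift_frame(fr, -s$dx, -s$dy)
      log$dx[i] <- s$dx; log$dy[i] <- s$dy; log$error_metric[i] <- s$error_metric
    }
    movie$frames <- out
    structure(list(movie = movie, shifts = log,
                   reference_descriptor = ref_desc),
              class = "registration_result")
  }

  lapply(trials, function(t) {
    ref <- if (policy == "per-trial") t$frames[, , 1] else reference
    register_one(t, ref)
  })
}
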