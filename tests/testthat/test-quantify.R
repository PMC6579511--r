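mk_trace <- function(values, onset = 21L, offset = 27L, rate = 3.5) {
  structure(list(values = values, frame_rate = rate, onset_frame = onset,
                 offset_frame = offset), class = "raw_trace")
}
mk_dff <- function(window, rate = 3.5) {
  # dff trace whose stimulus window holds `window`, zero baseline
  structure(list(dff = c(rep(0, 20), window), f0 = 100,
                 baseline_frames = 1:20,
                 stimulus_frames = 20 + seq_along(window),
                 frame_rate = rate), class = "dff_trace")
}

test_that("roi_trace averages mask pixels per frame", {
  fr <- array(100, c(4, 4, 3))
  m <- trial_movie(fr, 3.5, 2, 3)
  mask <- matrix(TRUE, 4, 4)
  expect_equal(roi_trace(m, mask)$values, rep(100, 3))

  fr[, , 1] <- 0; fr[1, 1, 1] <- 10; fr[2, 2, 1] <- 30
  m2 <- trial_movie(fr, 3.5, 2, 3)
  mask2 <- matrix(FALSE, 4, 4); mask2[1, 1] <- mask2[2, 2] <- TRUE
  expect_equal(roi_trace(m2, mask2)$values[1], 20)
  expect_error(roi_trace(m2, matrix(FALSE, 4, 4)), "empty ROI")
  expect_error(roi_trace(m2, matrix(TRUE, 5, 5)), "shape")
})

test_that("compute_dff uses the 20 immediately preceding frames as F0", {
  tr <- mk_trace(c(rep(100, 20), rep(120, 10)))
  d <- compute_dff(tr)
  expect_equal(d$f0, 100)
  expect_equal(d$dff[21], 0.20)
  expect_equal(mean(d$dff[d$baseline_frames]), 0)   # exact by construction

  expect_equal(compute_dff(mk_trace(rep(7, 30)))$dff, rep(0, 30))
  expect_equal(compute_dff(mk_trace(c(rep(90, 10), rep(110, 10),
                                      rep(150, 10))))$f0, 100)
  expect_error(compute_dff(mk_trace(rep(1, 30), onset = 10L)), "pre-stimulus")
  expect_error(compute_dff(mk_trace(c(rep(0, 20), rep(1, 10)))), "positive")
})

test_that("peak_response is the best consecutive-pair mean, first on ties", {
  expect_equal(peak_response(mk_dff(c(0.1, 0.5, 0.4, 0.2))), 0.45)
  expect_equal(peak_response(mk_dff(rep(0.3, 5))), 0.3)
  # tie: pairs (1,0) and (0,1) both average 0.5; strictly below the
  # single-frame max of 1.0
  expect_equal(peak_response(mk_dff(c(1.0, 0.0, 0.0, 1.0))), 0.5)
  expect_error(peak_response(mk_dff(0.5)), ">= 2 frames")
})

test_that("peak is bounded above by the single-frame max and matches the oracle", {
  set.seed(11)
  for (i in 1:50) {
    x <- rnorm(sample(3:10, 1))
    pk <- peak_response(mk_dff(x))
    expect_lte(pk, max(x))
    expect_equal(pk, brute_peak(x))
  }
  # on unimodal windows (the transient shape the assay produces) the peak
  # also dominates the window mean; for arbitrary oscillating windows it
  # need not (e.g. c(1, -1, 1)), so the bound is only asserted here
  for (i in 1:20) {
    n <- sample(4:10, 1)
    x <- runif(1, 0.2, 2) *
      gcamp_kernel((seq_len(n) - 0.5) / 3.5, duration = runif(1, 0.5, 2))
    pk <- peak_response(mk_dff(x))
    expect_gte(pk, mean(x))
    expect_lte(pk, max(x))
  }
  # constant window: peak, max, and mean coincide
  x <- rep(0.42, 6)
  expect_equal(peak_response(mk_dff(x)), max(x))
})

test_that("integrated_response is the frame sum over the rate", {
  expect_equal(integrated_response(mk_dff(rep(0, 7))), 0)
  # 0.5 dff held over a 2 s window: 7 frames at 3.5 Hz
  d <- mk_dff(rep(0.5, 7))
  expect_equal(integrated_response(d, window = d$stimulus_frames), 1.0)
  # analytic kernel integral vs midpoint discretization, O(1/rate^2)
  rate <- 3.5
  tmid <- (seq_len(200) - 0.5) / rate
  k <- gcamp_kernel(tmid, duration = 2, rise_tau = 0.1, decay_tau = 0.4)
  num <- sum(k) / rate
  analytic <- integrate(gcamp_kernel, 0, 60, duration = 2,
                        rise_tau = 0.1, decay_tau = 0.4)$value
  expect_equal(num, analytic, tolerance = 1 / rate^2)
  expect_error(integrated_response(mk_dff(rep(0, 5)), window = 100:200),
               "outside")
})

test_that("fly_average honors the delivery-failure exclusion rule", {
  expect_equal(fly_average(c(0.2, 0.4))$mean, 0.3)
  fa <- fly_average(c(0.2, 0.4, 9.9), included = c(TRUE, TRUE, FALSE))
  expect_equal(fa$mean, 0.3)
  expect_equal(fa$n_included, 2)
  expect_error(fly_average(c(1, 2), included = c(FALSE, FALSE)), "excluded")
})

test_that("responder rule is inclusive at the threshold", {
  expect_true(classify_responder(0.26, 0.10)$is_responder)
  expect_true(classify_responder(0.25, 0.10)$is_responder)   # boundary
  expect_false(classify_responder(0.24, 0.10)$is_responder)
  expect_error(classify_responder(0.5, 0.1, n_trials = 2), ">= 3")
})

test_that("responder sets are nested across thresholds", {
  set.seed(13)
  for (rep in 1:20) {
    mean_peaks <- runif(30, 0, 0.5)
    water <- runif(30, 0, 0.2)
    calls <- lapply(c(0.10, 0.15, 0.20), function(th)
      which(mean_peaks - water >= th))
    expect_true(all(calls[[3]] %in% calls[[2]]))
    expect_true(all(calls[[2]] %in% calls[[1]]))
  }
  # through responder_table on a synthetic session
  p <- tiny_params(noise = TRUE, trial_cv = 0.2)
  ses <- make_imaging_session(p, c("water", "aa_1", "aa_5"), seed = 17)
  ts <- quantify_session(ses, attr(ses, "roi_mask"))
  rt <- responder_table(ts)
  expect_true(all(which(rt$responder_0.20) %in% which(rt$responder_0.15)))
  expect_true(all(which(rt$responder_0.15) %in% which(rt$responder_0.10)))
})

test_that("quantified traces track the ground-truth kernel", {
  p <- tiny_params(noise = TRUE)
  tr <- make_imaging_trial(p, "aa_5", seed = 23)
  d <- compute_dff(roi_trace(tr, tr$truth$roi_mask))
  tmid <- (seq_along(d$dff) - 0.5) / p$frame_rate
  expected <- tr$truth$true_amplitude *
    gcamp_kernel(tmid - p$n_baseline_frames / p$frame_rate)
  expect_lt(max(abs(d$dff - expected)), 0.05)   # inside the noise envelope
})

test_that("non-finite frames in the analysis windows are rejected", {
  v <- c(rep(100, 20), rep(120, 10)); v[24] <- NA
  d <- compute_dff(mk_trace(v))
  expect_error(peak_response(d), "non-finite")
  expect_error(integrated_response(d), "non-finite")
  v2 <- c(rep(100, 20), rep(120, 10)); v2[5] <- Inf
  expect_error(compute_dff(mk_trace(v2)), "non-finite")
})
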