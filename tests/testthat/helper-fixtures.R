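# shared fixtures and independent oracles

# small, fast imaging params; noise/motion switched off unless asked for
tiny_params <- function(size = 48L, noise = FALSE, drift = FALSE,
                        schedule = c(water = 0, aa_1 = 0.5, aa_5 = 1.0),
                        trial_cv = 0, ...) {
  imaging_sim_params(
    frame_height = size, frame_width = size,
    amplitude_schedule = schedule, trial_cv = trial_cv,
    photon_gain = if (noise) 2 else 0,
    read_noise_sd = if (noise) 4 else 0,
    drift_per_frame = if (drift) c(0.05, 0.03) else c(0, 0),
    jitter_sd = if (drift) 0.05 else 0, ...)
}

# smooth random test image (low-pass filtered white noise)
smooth_image <- function(n = 32L, seed = 1L, cutoff = 2000) {
  set.seed(seed)
  x <- matrix(rnorm(n * n), n, n)
  fr <- (0:(n - 1)) / n; fr[fr > 0.5] <- fr[fr > 0.5] - 1
  filt <- exp(-outer(fr^2, fr^2, `+`) * cutoff)
  Re(fft(fft(x) * filt, inverse = TRUE)) / n^2
}

# integer-shift oracle: roll array indices
roll_image <- function(m, dx, dy) {
  h <- nrow(m); w <- ncol(m)
  m[((seq_len(h) - 1 - dy) %% h) + 1, ((seq_len(w) - 1 - dx) %% w) + 1]
}

# exhaustive integer-shift cross-correlation argmax
brute_int_shift <- function(ref, tgt) {
  h <- nrow(ref); w <- ncol(ref)
  ref <- ref - mean(ref); tgt <- tgt - mean(tgt)
  best <- c(0, 0); bestv <- -Inf
  for (dy in seq_len(h) - 1) for (dx in seq_len(w) - 1) {
    v <- sum(ref * roll_image(tgt, -dx, -dy))
    if (v > bestv) { bestv <- v; best <- c(dx, dy) }
  }
  best[best > c(w, h) / 2] <- best[best > c(w, h) / 2] - c(w, h)[best > c(w, h) / 2]
  best
}

# brute-force peak oracle: enumerate all consecutive pairs
brute_peak <- function(x) {
  best <- -Inf
  for (i in seq_len(length(x) - 1)) best <- max(best, (x[i] + x[i + 1]) / 2)
  best
}

# independent RM-ANOVA oracle via base aov() Error strata (QR projections)
aov_oracle <- function(data, response, unit, within, between = NULL) {
  data[[unit]] <- factor(data[[unit]])
  data[[within]] <- factor(data[[within]])
  if (is.null(between)) {
    form <- stats::as.formula(sprintf("%s ~ %s + Error(%s/%s)",
                                      response, within, unit, within))
    s <- summary(stats::aov(form, data = data))
    werr <- s[[2]][[1]]
    data.frame(effect = c("within", "subject", "error"),
               ss = c(werr["Sum Sq"][[1]][1], s[[1]][[1]]["Sum Sq"][[1]][1],
                      werr["Sum Sq"][[1]][2]),
               df = c(werr["Df"][[1]][1], s[[1]][[1]]["Df"][[1]][1],
                      werr["Df"][[1]][2]),
               f = c(werr["F value"][[1]][1], NA, NA))
  } else {
    data[[between]] <- factor(data[[between]])
    form <- stats::as.formula(sprintf("%s ~ %s * %s + Error(%s/%s)",
                                      response, between, within, unit, within))
    s <- summary(stats::aov(form, data = data))
    bet <- s[[1]][[1]]; wit <- s[[2]][[1]]
    data.frame(effect = c("between", "subject(between)", "within",
                          "interaction", "error(within)"),
               ss = c(bet["Sum Sq"][[1]], wit["Sum Sq"][[1]]),
               df = c(bet["Df"][[1]], wit["Df"][[1]]),
               f = c(bet["F value"][[1]][1], NA, wit["F value"][[1]][1:2], NA))
  }
}

# random balanced RM designs for oracle sweeps
random_rm_design <- function(seed, two_way = FALSE) {
  set.seed(seed)
  k <- sample(2:5, 1)
  if (two_way) {
    G <- sample(2:3, 1); n <- sample(3:4, 1)
    d <- expand.grid(unit = seq_len(G * n), w = factor(seq_len(k)))
    d$b <- factor(rep(rep(seq_len(G), each = n), k))
    d$unit <- factor(d$unit)
    d$y <- rnorm(nrow(d), mean = as.numeric(d$b) + 0.3 * as.numeric(d$w))
  } else {
    N <- sample(3:8, 1)
    d <- expand.grid(unit = factor(seq_len(N)), w = factor(seq_len(k)))
    d$y <- rnorm(nrow(d), mean = 0.4 * as.numeric(d$w))
  }
  d
}

# 53-trial directional dataset consistent with the printed 72%/28%/0%
# summary (the unique integer partition: 38 toward, 15 neither, 0 away)
directional_53 <- function() {
  data.frame(
    fly_id = sprintf("fly%d", rep_len(1:9, 53)),
    side_stimulated = rep_len(c("L", "R"), 53),
    outcome = c(rep("toward", 38), rep("neither", 15)),
    stringsAsFactors = FALSE)
}
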