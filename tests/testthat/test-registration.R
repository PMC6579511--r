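test_that("estimate_shift recovers exact, sub-pixel, and integer shifts", {
  A <- smooth_image(48, seed = 2)
  s0 <- estimate_shift(A, A, 100)
  expect_identical(c(s0$dx, s0$dy), c(0, 0))

  s <- estimate_shift(A, shift_frame(A, 2.30, -1.70), 100)
  expect_lt(abs(s$dx - 2.30), 0.05)
  expect_lt(abs(s$dy + 1.70), 0.05)

  B <- roll_image(A, 3, 5)
  s1 <- estimate_shift(A, B, 1)
  expect_equal(c(s1$dx, s1$dy), c(3, 5))
  expect_equal(brute_int_shift(A, B), c(3, 5))   # exhaustive oracle agrees

  expect_error(estimate_shift(matrix(1, 8, 8), A[1:8, 1:8]), "zero-variance")
  expect_error(estimate_shift(A, A[1:8, 1:8]), "identical shape")
})

test_that("estimate_shift is anti-symmetric within 1/upsample", {
  for (seed in 1:4) {
    A <- smooth_image(32, seed = seed)
    B <- shift_frame(A, runif(1, -3, 3), runif(1, -3, 3))
    u <- 20
    ab <- estimate_shift(A, B, u); ba <- estimate_shift(B, A, u)
    expect_lt(abs(ab$dx + ba$dx), 1 / u + 1e-9)
    expect_lt(abs(ab$dy + ba$dy), 1 / u + 1e-9)
  }
})

test_that("upsampled estimates match brute-force grid search on 32x32", {
  set.seed(4)
  u <- 4L
  A <- smooth_image(32, seed = 7)
  for (true_shift in list(c(1.25, -0.5), c(-2.75, 1.75))) {
    B <- shift_frame(A, true_shift[1], true_shift[2])
    est <- estimate_shift(A, B, u)
    # oracle: evaluate correlation on the (1/u)-spaced grid around the peak
    Ac <- A - mean(A); Bc <- B - mean(B)
    grid <- seq(-3, 3, by = 1 / u)
    best <- c(NA, NA); bestv <- -Inf
    for (dx in grid) for (dy in grid) {
      v <- sum(Ac * shift_frame(Bc, -dx, -dy))
      if (v > bestv) { bestv <- v; best <- c(dx, dy) }
    }
    expect_lt(abs(est$dx - best[1]), 1 / u + 1e-9)
    expect_lt(abs(est$dy - best[2]), 1 / u + 1e-9)
  }
})

test_that("shift_frame round-trips and matches the roll oracle", {
  A <- smooth_image(32, seed = 3)
  expect_identical(shift_frame(A, 0, 0), A)
  rt <- shift_frame(shift_frame(A, 1.37, -2.21), -1.37, 2.21)
  expect_lt(max(abs(rt - A)) / max(abs(A)), 1e-6)
  expect_equal(shift_frame(A, 4, -3), roll_image(A, 4, -3), tolerance = 1e-12)
  expect_error(shift_frame(A, NA, 1), "finite")
})

test_that("register_session recovers known drifts and is quiet without them", {
  p <- tiny_params(size = 48, noise = TRUE, drift = FALSE,
                   schedule = c(water = 0, aa = 0.8))
  still <- make_imaging_session(p, c("water", "aa"), seed = 21)
  reg <- register_session(still, upsample = 20)
  expect_true(all(abs(unlist(lapply(reg, function(r)
    c(r$shifts$dx, r$shifts$dy)))) < 0.1))

  pd <- tiny_params(size = 48, noise = TRUE, drift = TRUE,
                    schedule = c(water = 0, aa = 0.8))
  ses <- make_imaging_session(pd, c("water", "aa"), seed = 22)
  regd <- register_session(ses, upsample = 20)
  refoff <- colMeans(ses[[1]]$truth$true_shifts[1:20, ])
  err <- unlist(lapply(seq_along(ses), function(i) {
    est <- cbind(regd[[i]]$shifts$dx, regd[[i]]$shifts$dy)
    abs(est - sweep(ses[[i]]$truth$true_shifts, 2, refoff))
  }))
  expect_lt(mean(err), 0.1)
})

test_that("registration reduces mean squared error to the reference", {
  p <- tiny_params(size = 48, noise = TRUE, drift = TRUE,
                   schedule = c(aa = 1.0))
  ses <- make_imaging_session(p, "aa", seed = 30)
  nb <- ses[[1]]$movie$onset_frame - 1
  ref <- apply(ses[[1]]$movie$frames[, , 1:nb], c(1, 2), mean)
  reg <- register_session(ses, upsample = 20)
  mse <- function(movie) mean(vapply(seq_len(dim(movie$frames)[3]),
    function(i) mean((movie$frames[, , i] - ref)^2), numeric(1)))
  for (i in seq_along(ses))
    expect_lte(mse(reg[[i]]$movie), mse(ses[[i]]$movie))
})

test_that("fixed external reference makes shifts order-invariant", {
  p <- tiny_params(size = 32, noise = TRUE, drift = TRUE,
                   schedule = c(water = 0, aa = 0.5))
  ses <- make_imaging_session(p, c("water", "aa"), seed = 31)
  ref <- apply(ses[[1]]$movie$frames[, , 1:10], c(1, 2), mean)
  r1 <- register_session(ses, reference = ref, upsample = 10)
  r2 <- register_session(rev(ses), reference = ref, upsample = 10)
  expect_identical(r1[[1]]$shifts, rev(r2)[[1]]$shifts)
  expect_identical(r1[[4]]$shifts, rev(r2)[[4]]$shifts)
})

test_that("register_session validates its inputs", {
  p <- tiny_params(size = 32, schedule = c(a = 0.5))
  tr <- make_imaging_trial(p, "a", seed = 1)
  p2 <- tiny_params(size = 48, schedule = c(a = 0.5))
  tr2 <- make_imaging_trial(p2, "a", seed = 1)
  expect_error(register_session(list(tr, tr2)), "mismatched")
  expect_error(register_session(list()), "at least one")
})
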