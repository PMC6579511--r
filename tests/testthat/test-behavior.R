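per_row <- function(fly, t1, t2, check = TRUE, dose = 1, group = "g1") {
  data.frame(group_id = group, fly_id = fly, state = "starved_2d",
             tastant = "acetic_acid", dose = dose, trial1 = t1, trial2 = t2,
             sucrose500_check = check, stringsAsFactors = FALSE)
}

test_that("a positive on either of the two trials scores positive", {
  expect_true(score_per_test(FALSE, TRUE))
  expect_false(score_per_test(FALSE, FALSE))
  expect_true(score_per_test(TRUE, TRUE))
  expect_error(score_per_test(NA, TRUE), "must be set")
  # monotone: upgrading a trial never flips positive -> negative
  for (t1 in c(FALSE, TRUE)) for (t2 in c(FALSE, TRUE)) {
    if (score_per_test(t1, t2)) {
      expect_true(score_per_test(TRUE, t2))
      expect_true(score_per_test(t1, TRUE))
    }
  }
})

test_that("the 500 mM sucrose exclusion only removes unresponsive failures", {
  ds <- rbind(per_row("f1", FALSE, FALSE, check = FALSE),
              per_row("f2", FALSE, FALSE, check = TRUE),
              per_row("f3", TRUE, FALSE, check = FALSE))
  out <- apply_qc(ds, "wildtype_starved")
  expect_setequal(unique(out$fly_id), c("f2", "f3"))
  expect_equal(attr(out, "exclusions")$fly_id, "f1")
  # comparison policy retains the same fly
  out2 <- apply_qc(ds, "compare_groups")
  expect_setequal(unique(out2$fly_id), c("f1", "f2", "f3"))
  # idempotence
  expect_equal(apply_qc(out, "wildtype_starved"), out, ignore_attr = TRUE)
  expect_error(apply_qc(ds, "nonsense"), "arg")
})

test_that("exclusion is fly-level across all dose rows", {
  ds <- rbind(per_row("f1", FALSE, FALSE, check = FALSE, dose = 0),
              per_row("f1", FALSE, FALSE, check = FALSE, dose = 5))
  out <- apply_qc(ds, "wildtype_starved")
  expect_equal(nrow(out), 0)
})

test_that("group_fraction computes the percent of positive flies", {
  g <- do.call(rbind, lapply(1:15, function(i)
    per_row(sprintf("f%d", i), i <= 3, FALSE)))
  s <- group_fraction(g)
  expect_equal(s$percent_per, 20)
  expect_equal(s$n_flies, 15)
  g0 <- do.call(rbind, lapply(1:15, function(i)
    per_row(sprintf("f%d", i), FALSE, FALSE)))
  expect_equal(group_fraction(g0)$percent_per, 0)
  expect_error(group_fraction(g0[0, ]), "at least one")
  # metamorphic: appending a positive fly never lowers the percentage
  set.seed(5)
  for (i in 1:10) {
    n <- sample(5:19, 1)
    g <- do.call(rbind, lapply(seq_len(n), function(j)
      per_row(sprintf("f%d", j), runif(1) < 0.4, runif(1) < 0.4)))
    before <- group_fraction(g)$percent_per
    after <- group_fraction(rbind(g, per_row("fnew", TRUE, TRUE)))$percent_per
    expect_gte(after, before)
  }
})

test_that("group percentages recover the generative test-level probability", {
  p <- behavior_sim_params(n_groups = 50, states = "starved_2d", doses = 5)
  ds <- make_per_dataset(p, seed = 31)
  gs <- summarize_per_groups(ds)
  expect_equal(nrow(gs), 50)
  target <- per_test_prob(p, "starved_2d", 5)
  n_fly <- sum(tapply(ds$fly_id, ds$group_id, function(f) length(unique(f))))
  se <- sqrt(target * (1 - target) / n_fly)
  expect_lt(abs(mean(gs$percent_per) / 100 - target), 3 * se)
})

test_that("directional_summary reports integer percentages of PER trials", {
  s <- directional_summary(directional_53())
  expect_equal(unname(s$percent["toward"]), 72)
  expect_equal(unname(s$percent["neither"]), 28)
  expect_equal(unname(s$percent["away"]), 0)
  expect_equal(sum(s$counts), 53)
  expect_equal(sum(s$fractions), 1)
  expect_equal(s$n_flies, 9)

  all_toward <- data.frame(fly_id = "f1", outcome = rep("toward", 7))
  expect_equal(unname(directional_summary(all_toward)$percent["toward"]), 100)
  half <- data.frame(fly_id = "f1", outcome = c("toward", "neither"))
  expect_equal(unname(directional_summary(half)$percent[c("toward", "neither")]),
               c(50, 50))
  expect_error(directional_summary(
    data.frame(outcome = "sideways")), "unknown outcome")
})

test_that("directional fractions are permutation-invariant and sum to 1", {
  set.seed(8)
  d <- make_directional_dataset(40, 0.6, 0.3, seed = 3)
  s1 <- directional_summary(d)
  s2 <- directional_summary(d[sample(nrow(d)), ])
  expect_identical(s1$counts, s2$counts)
  expect_equal(sum(s1$fractions), 1)
})
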