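test_that("identical responses give F = 0, p = 1 (0/0 guarded)", {
  d <- expand.grid(unit = factor(1:4), w = factor(1:3))
  d$y <- 5
  fit <- rm_anova(d, "y", "unit", "w")
  expect_equal(fit$f[fit$effect == "within"], 0)
  expect_equal(fit$p[fit$effect == "within"], 1)
  d$b <- factor(rep(1:2, 6))
  fit2 <- rm_anova(d, "y", "unit", "w", "b")
  expect_true(all(fit2$f[!is.na(fit2$f)] == 0))
  expect_true(all(fit2$p[!is.na(fit2$p)] == 1))
})

test_that("two within levels reduce to the paired t-test", {
  set.seed(21)
  d <- expand.grid(unit = factor(1:7), w = factor(1:2))
  d$y <- rnorm(14, mean = as.numeric(d$w))
  fit <- rm_anova(d, "y", "unit", "w")
  tt <- t.test(d$y[d$w == 1], d$y[d$w == 2], paired = TRUE)
  expect_equal(fit$f[fit$effect == "within"], unname(tt$statistic^2))
  expect_equal(fit$p[fit$effect == "within"], tt$p.value)
})

test_that("sums of squares match the independent aov projection oracle", {
  for (seed in 1:12) {
    for (two_way in c(FALSE, TRUE)) {
      d <- random_rm_design(seed + 100 * two_way, two_way = two_way)
      fit <- if (two_way) rm_anova(d, "y", "unit", "w", "b")
             else rm_anova(d, "y", "unit", "w")
      ora <- if (two_way) aov_oracle(d, "y", "unit", "w", "b")
             else aov_oracle(d, "y", "unit", "w")
      expect_equal(fit$ss, ora$ss, tolerance = 1e-9)
      expect_equal(fit$df, ora$df)
      expect_equal(fit$f[!is.na(ora$f)], ora$f[!is.na(ora$f)],
                   tolerance = 1e-9)
    }
  }
})

test_that("SS conservation and df bookkeeping hold exactly", {
  for (seed in 1:8) {
    two_way <- seed %% 2 == 0
    d <- random_rm_design(seed + 500, two_way = two_way)
    fit <- if (two_way) rm_anova(d, "y", "unit", "w", "b")
           else rm_anova(d, "y", "unit", "w")
    expect_equal(sum(fit$ss), sum((d$y - mean(d$y))^2), tolerance = 1e-9)
    expect_equal(sum(fit$df), nrow(d) - 1)
  }
})

test_that("one-way RM is invariant to within-level relabeling", {
  d <- random_rm_design(3)
  fit1 <- rm_anova(d, "y", "unit", "w")
  d2 <- d
  # reverse the label order; the decomposition must not change
  d2$w <- factor(d2$w, levels = rev(levels(d2$w)))
  fit2 <- rm_anova(d2, "y", "unit", "w")
  expect_equal(fit1$ss, fit2$ss)
  expect_equal(fit1$f, fit2$f)
})

test_that("incomplete or unbalanced designs are rejected, not guessed", {
  d <- random_rm_design(4)
  expect_error(rm_anova(d[-1, ], "y", "unit", "w"), "incomplete|unbalanced")
  d2 <- random_rm_design(5, two_way = TRUE)
  drop_unit <- levels(d2$unit)[1]
  expect_error(rm_anova(d2[d2$unit != drop_unit, ], "y", "unit", "w", "b"),
               "incomplete|unequal|unbalanced")
  expect_error(rm_anova(d, "nope", "unit", "w"), "not in data")
})

test_that("bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 5), 1.0)
  expect_equal(bonferroni(c(0.2, 0.04)), c(0.4, 0.08))  # m defaults to length
  expect_equal(bonferroni(0.03), 0.03)                  # m = 1: identity
  expect_error(bonferroni(c(0.1, 0.2), 1), ">=")
})

test_that("bonferroni post-tests cover pairs x levels with pooled error", {
  set.seed(33)
  d <- random_rm_design(9, two_way = TRUE)
  fit <- rm_anova(d, "y", "unit", "w", "b")
  pt <- bonferroni_posttests(fit)
  G <- length(unique(d$b)); k <- length(unique(d$w))
  expect_equal(nrow(pt), choose(G, 2) * k)
  expect_true(all(pt$p_adj >= pt$p_raw - 1e-15))
  expect_true(all(pt$p_adj <= 1))
  expect_equal(pt$p_adj, pmin(1, nrow(pt) * pt$p_raw))
})

test_that("dunnett with one comparison reduces to the paired t-test", {
  set.seed(41)
  d <- expand.grid(unit = factor(1:8), w = factor(c("ctrl", "a")))
  d$y <- rnorm(16)
  fit <- rm_anova(d, "y", "unit", "w")
  dn <- dunnett(fit, control = "ctrl", n_mc = 1e5, seed = 2)
  expect_equal(nrow(dn), 1)
  expect_lt(abs(dn$p_adj - dn$p_raw), 0.005)
  tt <- t.test(d$y[d$w == "a"], d$y[d$w == "ctrl"], paired = TRUE)
  expect_equal(dn$p_raw, tt$p.value, tolerance = 1e-9)
})

test_that("dunnett adjusted p grows with the number of comparisons", {
  df <- 12; t_obs <- 2.0
  ps <- vapply(1:4, function(k) {
    maxt <- flytaste:::dunnett_null_maxt(k, df, 5e4, seed = 7)
    mean(maxt >= t_obs)
  }, numeric(1))
  expect_true(all(diff(ps) >= 0))
  # spot-check the k = 1 null against the analytic |t| tail
  expect_lt(abs(ps[1] - 2 * pt(t_obs, df, lower.tail = FALSE)), 0.01)
})

test_that("dunnett demands the one-way design and a real control", {
  d <- random_rm_design(6, two_way = TRUE)
  fit2 <- rm_anova(d, "y", "unit", "w", "b")
  expect_error(dunnett(fit2, control = "1"), "one-way")
  d1 <- random_rm_design(7)
  fit1 <- rm_anova(d1, "y", "unit", "w")
  expect_error(dunnett(fit1, control = "zzz"), "not found")
})

test_that("power_audit rejects at close to alpha under the null and grows with n", {
  null_p <- behavior_sim_params(
    n_groups = 3, states = c("fed", "starved_2d"),
    hunger_gain_appetitive = c(fed = 0, starved_1d = 0, starved_2d = 0),
    hunger_gain_aversive = c(fed = 0, starved_1d = 0, starved_2d = 0))
  rate <- power_audit(null_p, "interaction", n_sims = 200, seed = 3)
  expect_lt(abs(rate - 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
  # monotone power: more groups never hurt, for the real effect
  eff2 <- behavior_sim_params(n_groups = 2, states = c("fed", "starved_2d"))
  eff4 <- behavior_sim_params(n_groups = 4, states = c("fed", "starved_2d"))
  p2 <- power_audit(eff2, "interaction", n_sims = 100, seed = 4)
  p4 <- power_audit(eff4, "interaction", n_sims = 100, seed = 4)
  expect_gte(p4, p2 - 0.1)
  expect_error(power_audit(null_p, n_sims = 10), ">= 100")
})
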