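#' Repeated-measures ANOVA (one-way within; two-way mixed)
#'
#' Classical balanced sums-of-squares decomposition, computed from scratch.
#' With only a within-subject factor (one-way RM): effects are the within
#' factor (df `k-1`), subjects (df `N-1`) and their interaction as the error
#' term (df `(N-1)(k-1)`); `F = MS_within / MS_error`. With a between-subject
#' factor (two-way mixed, the design used when comparing fed and starved
#' groups across a concentration series): effects are between (tested
#' against subjects-within-groups), within, and between x within interaction
#' (both tested against the within-subject error). Sphericity is assumed, as
#' is conventional for this assay's analyses; data must be complete and
#' balanced (every unit measured at every within level, equal group sizes)
#' or the fit is rejected.
#'
#' Degenerate guard: an effect with zero sum of squares reports `F = 0`,
#' `p = 1` even when the error SS is also zero.
#'
#' @param data data.frame in long format.
#' @param response,unit,within,between column names; `between = NULL` gives
#'   the one-way RM analysis.
#' @return an `anova_table`: data.frame with columns effect, ss, df, ms, f,
#'   p, carrying the design as attributes for post-tests.
#' @export
rm_anova <- function(data, response, unit, within, between = NULL) {
  for (col in c(response, unit, within, between))
    if (!col %in% names(data)) stop_ft("column '%s' not in data", col)
  y <- data[[response]]
  if (any(!is.finite(y))) stop_ft("non-finite responses")
  u <- factor(data[[unit]]); w <- factor(data[[within]])
  N <- nlevels(u); k <- nlevels(w)
  if (N < 2L) stop_ft("need >= 2 units")
  if (k < 2L) stop_ft("need >= 2 within-factor levels")
  tab <- table(u, w)
  if (any(tab != 1L))
    stop_ft("incomplete or unbalanced repeated measures: every unit must be measured exactly once at every within level")

  M <- mean(y)
  ss_total <- sum((y - M)^2)
  subj_mean <- tapply(y, u, mean)
  w_mean <- tapply(y, w, mean)
  ss_within <- N * sum((w_mean - M)^2)

  if (is.null(between)) {
    ss_subj <- k * sum((subj_mean - M)^2)
    ss_err <- ss_total - ss_within - ss_subj
    df_w <- k - 1L; df_s <- N - 1L; df_e <- df_s * df_w
    tab_out <- rbind(
      anova_row("within", ss_within, df_w, TRUE, ss_err / df_e, df_e),
      anova_row("subject", ss_subj, df_s, FALSE, NA, NA),
      anova_row("error", ss_err, df_e, FALSE, NA, NA))
    design <- list(type = "one-way-rm", k = k, N = N,
                   within_levels = levels(w), within_means = w_mean,
                   ms_error = ss_err / df_e, df_error = df_e,
                   unit = unit, within = within, response = response,
                   data = data)
  } else {
    b <- factor(data[[between]])
    G <- nlevels(b)
    if (G < 2L) stop_ft("between factor needs >= 2 levels")
    unit_group <- tapply(as.character(b), u, function(x) unique(x))
    if (any(lengths(unit_group) != 1L))
      stop_ft("each unit must belong to exactly one between-factor level")
    gsize <- table(factor(unlist(unit_group), levels = levels(b)))
    if (length(unique(gsize)) != 1L)
      stop_ft("unequal group sizes: the balanced mixed ANOVA is rejected")
    n <- as.integer(gsize[1])

    g_mean <- tapply(y, b, mean)
    cell_mean <- tapply(y, list(b, w), mean)      # G x k
    ss_between <- n * k * sum((g_mean - M)^2)
    ss_subj <- k * sum((subj_mean - g_mean[unlist(unit_group)[levels(u)]])^2)
    inter_dev <- sweep(sweep(cell_mean, 1, g_mean), 2, w_mean) + M
    ss_inter <- n * sum(inter_dev^2)
    ss_werr <- ss_total - ss_between - ss_subj - ss_within - ss_inter
    df_b <- G - 1L; df_s <- N - G; df_w <- k - 1L
    df_i <- df_b * df_w; df_we <- df_s * df_w
    tab_out <- rbind(
      anova_row("between", ss_between, df_b, TRUE, ss_subj / df_s, df_s),
      anova_row("subject(between)", ss_subj, df_s, FALSE, NA, NA),
      anova_row("within", ss_within, df_w, TRUE, ss_werr / df_we, df_we),
      anova_row("interaction", ss_inter, df_i, TRUE, ss_werr / df_we, df_we),
      anova_row("error(within)", ss_werr, df_we, FALSE, NA, NA))
    design <- list(type = "two-way-mixed", k = k, N = N, G = G, n = n,
                   within_levels = levels(w), between_levels = levels(b),
                   within_means = w_mean, group_means = g_mean,
                   cell_means = cell_mean,
                   ms_subject = ss_subj / df_s, df_subject = df_s,
                   ss_subject = ss_subj,
                   ms_error = ss_werr / df_we, df_error = df_we,
                   ss_error = ss_werr,
                   unit = unit, within = within, between = between,
                   response = response, data = data)
  }
  structure(tab_out, class = c("anova_table", "data.frame"), design = design)
}

# one effect row; F/p only for tested effects, with the 0/0 guard
anova_row <- function(effect, ss, df, test, err_ms, err_df) {
  ms <- if (df > 0) ss / df else NA_real_
  f <- p <- NA_real_
  if (test) {
    if (ss <= 1e-300) { f <- 0; p <- 1 }
    else if (err_ms == 0) { f <- Inf; p <- 0 }
    else {
      f <- ms / err_ms
      p <- stats::pf(f, df, err_df, lower.tail = FALSE)
    }
  }
  data.frame(effect = effect, ss = ss, df = df, ms = ms, f = f, p = p,
             stringsAsFactors = FALSE)
}

#' Bonferroni adjustment
#'
#' `adjusted = min(1, m * raw)` for a family of `m` comparisons.
#'
#' @param raw_ps raw p-values.
#' @param m family size (>= number of comparisons; default
#'   `length(raw_ps)`).
#' @return adjusted p-values.
#' @export
bonferroni <- function(raw_ps, m = length(raw_ps)) {
  if (m < length(raw_ps)) stop_ft("m must be >= number of comparisons")
  pmin(1, m * raw_ps)
}

#' Bonferroni post-tests after a repeated-measures ANOVA
#'
#' For the two-way mixed design: between-group comparisons at each within
#' level (the conventional follow-up when comparing, e.g., fed vs starved
#' dose-response curves), using the pooled error
#' `MS = (SS_subject + SS_error) / (df_subject + df_error)` and a family of
#' (group pairs) x (within levels) comparisons. For the one-way RM design:
#' all pairwise within-level paired comparisons on the RM error MS.
#'
#' @param fit an `anova_table` from [rm_anova()].
#' @param alpha significance level for the `significant` flag.
#' @return data.frame of class `post_tests`: comparison, level, diff, t, df,
#'   p_raw, p_adj, significant.
#' @export
bonferroni_posttests <- function(fit, alpha = 0.05) {
  d <- attr(fit, "design")
  rows <- list()
  if (d$type == "two-way-mixed") {
    ms_pool <- (d$ss_subject + d$ss_error) / (d$df_subject + d$df_error)
    df_pool <- d$df_subject + d$df_error
    pairs <- utils::combn(d$between_levels, 2, simplify = FALSE)
    for (lev in d$within_levels) for (pr in pairs) {
      diff <- d$cell_means[pr[1], lev] - d$cell_means[pr[2], lev]
      se <- sqrt(ms_pool * 2 / d$n)
      t <- diff / se
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = sprintf("%s vs %s", pr[1], pr[2]), level = lev,
        diff = diff, t = t, df = df_pool,
        p_raw = 2 * stats::pt(abs(t), df_pool, lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  } else {
    pairs <- utils::combn(d$within_levels, 2, simplify = FALSE)
    for (pr in pairs) {
      diff <- d$within_means[pr[1]] - d$within_means[pr[2]]
      se <- sqrt(2 * d$ms_error / d$N)
      t <- diff / se
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = sprintf("%s vs %s", pr[1], pr[2]), level = NA_character_,
        diff = diff, t = t, df = d$df_error,
        p_raw = 2 * stats::pt(abs(t), d$df_error, lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni(out$p_raw, nrow(out))
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  class(out) <- c("post_tests", "data.frame")
  out
}

# cached draw of the Dunnett null: max over k correlated |t| variates,
# T_j = (z_j - z_0) / sqrt(2 * s2), s2 ~ chisq(df)/df (corr(T_j, T_j') = 0.5)
dunnett_null_maxt <- function(k, df, n_mc, seed) {
  key <- sprintf("dunnett_%d_%d_%d_%d", k, df, n_mc, seed)
  cached <- get0(key, envir = .flytaste_cache)
  if (!is.null(cached)) return(cached)
  maxt <- with_seed(substream_seed(seed, key), {
    z0 <- stats::rnorm(n_mc)
    s <- sqrt(stats::rchisq(n_mc, df) / df)
    m <- matrix(stats::rnorm(n_mc * k), n_mc, k)
    matrixStats_rowMax(abs((m - z0) / sqrt(2)) / s)
  })
  assign(key, maxt, envir = .flytaste_cache)
  maxt
}

matrixStats_rowMax <- function(m) do.call(pmax, asplit(m, 2))

#' Dunnett's many-to-one post-test after one-way RM ANOVA
#'
#' Compares every non-control within level to the control level (e.g., each
#' acid concentration to the 0% water baseline), with family-wise error
#' control from the joint null distribution of the `k` correlated t
#' statistics (pairwise correlation 0.5 under sphericity). The max-|t| null
#' is approximated by seeded Monte Carlo (default 1e5 draws, adjusted-p
#' tolerance ~ +-0.005) and cached per `(k, df, n_mc, seed)`.
#'
#' @param fit a one-way RM `anova_table` from [rm_anova()].
#' @param control control level of the within factor.
#' @param n_mc Monte-Carlo draws.
#' @param seed integer seed for the null table.
#' @param alpha significance level.
#' @return data.frame of class `post_tests`: comparison, diff, t, df,
#'   p_raw, p_adj, significant.
#' @export
dunnett <- function(fit, control, n_mc = 1e5, seed = 1L, alpha = 0.05) {
  d <- attr(fit, "design")
  if (d$type != "one-way-rm")
    stop_ft("dunnett() follows the one-way RM analysis")
  if (!control %in% d$within_levels)
    stop_ft("control level '%s' not found", control)
  others <- setdiff(d$within_levels, control)
  if (length(others) == 0) stop_ft("no comparisons: only the control level")
  if (d$df_error <= 0) stop_ft("zero error df")
  se <- sqrt(2 * d$ms_error / d$N)
  diff <- d$within_means[others] - d$within_means[control]
  t <- as.numeric(diff / se)
  maxt <- dunnett_null_maxt(length(others), d$df_error, n_mc, seed)
  p_raw <- 2 * stats::pt(abs(t), d$df_error, lower.tail = FALSE)
  # the true family-wise p dominates the per-comparison p; clamping keeps
  # that invariant through Monte-Carlo noise in the tails
  p_adj <- pmax(vapply(abs(t), function(tt) mean(maxt >= tt), numeric(1)),
                p_raw)
  out <- data.frame(
    comparison = sprintf("%s vs %s", others, control),
    diff = as.numeric(diff), t = t, df = d$df_error,
    p_raw = 2 * stats::pt(abs(t), d$df_error, lower.tail = FALSE),
    p_adj = p_adj, significant = p_adj < alpha, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("post_tests", "data.frame")
  out
}

#' Fit the standard two-way mixed analysis to a PER group summary
#'
#' Convenience wrapper: group percentages as the response, group as the
#' unit, dose as the within factor, state (or any other column) as the
#' between factor. An optional arcsine-square-root transform of the
#' percentages is available for variance stabilization but is off by
#' default, matching the conventional untransformed analysis.
#'
#' @param groups data.frame from [summarize_per_groups()].
#' @param between between-unit column (default `"state"`).
#' @param transform `"none"` or `"asin_sqrt"`.
#' @return an `anova_table`.
#' @export
per_anova <- function(groups, between = "state",
                      transform = c("none", "asin_sqrt")) {
  transform <- match.arg(transform)
  if (transform == "asin_sqrt")
    groups$percent_per <- asin(sqrt(groups$percent_per / 100))
  rm_anova(groups, response = "percent_per", unit = "group_id",
           within = "dose", between = between)
}

#' Simulation audit of detection rate through the full pipeline
#'
#' Repeatedly generates synthetic PER datasets, summarizes them to group
#' percentages, fits the two-way mixed RM-ANOVA, and reports the fraction of
#' simulations in which the requested effect is significant at `alpha`.
#' With a null generator (all hunger gains zero) this audits the type-I
#' error; with the default calibration it measures power for the
#' state x dose interaction that constitutes the hunger-dependent switch.
#'
#' @param params a [behavior_sim_params()] object.
#' @param effect which ANOVA effect to monitor.
#' @param n_sims number of simulated experiments (>= 100 for a stable rate).
#' @param alpha significance level.
#' @param seed master seed.
#' @return rejection rate (fraction in `[0, 1]`), with attribute `mc_se`.
#' @export
power_audit <- function(params = behavior_sim_params(),
                        effect = c("interaction", "between", "within"),
                        n_sims = 200L, alpha = 0.05, seed = 1L) {
  effect <- match.arg(effect)
  if (n_sims < 100L) stop_ft("n_sims must be >= 100")
  rej <- vapply(seq_len(n_sims), function(i) {
    ds <- make_per_dataset(params, seed = substream_seed(seed, paste0("pa", i)))
    fit <- per_anova(summarize_per_groups(ds))
    fit$p[fit$effect == effect] < alpha
  }, logical(1))
  rate <- mean(rej)
  structure(rate, mc_se = sqrt(rate * (1 - rate) / n_sims))
}

#' @export
print.anova_table <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (%s)\n", attr(x, "design")$type))
  df <- as.data.frame(x)
  df$ss <- signif(df$ss, 6); df$ms <- signif(df$ms, 6)
  df$f <- signif(df$f, 5); df$p <- signif(df$p, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
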