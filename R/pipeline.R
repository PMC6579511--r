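#' Pipeline configuration
#'
#' Bundles every stage's tunable parameters. The defaults mirror the
#' protocol constants the analysis is built around: 20 baseline frames for
#' F0, a 2 s stimulus window, at least three trials per stimulus, and a
#' responder threshold of 0.15 dF/F0 (15 percentage points).
#'
#' @param registration list: `policy` (see [register_session()]),
#'   `upsample`.
#' @param quantify list: `n_baseline`, `theta`, `thetas`, `peak_extend_s`,
#'   `integrate_post_s`, `water_label`.
#' @param behavior list: `qc_policy` (see [apply_qc()]).
#' @param stats list: `design`, `posthoc`, `alpha`, `n_mc`, `seed`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(registration = list(),
                            quantify = list(),
                            behavior = list(),
                            stats = list()) {
  merge_defaults <- function(given, defaults) {
    bad <- setdiff(names(given), names(defaults))
    if (length(bad)) stop_ft("unknown config field(s): %s",
                             paste(bad, collapse = ", "))
    utils::modifyList(defaults, given)
  }
  structure(list(
    registration = merge_defaults(registration,
      list(policy = "first-baseline", upsample = 20L)),
    quantify = merge_defaults(quantify,
      list(n_baseline = 20L, theta = 0.15, thetas = c(0.10, 0.15, 0.20),
           peak_extend_s = 0, integrate_post_s = 2, water_label = "water")),
    behavior = merge_defaults(behavior, list(qc_policy = "compare_groups")),
    stats = merge_defaults(stats,
      list(design = "two-way-rm", between = "state", posthoc = "bonferroni",
           alpha = 0.05, n_mc = 1e5, seed = 1L))),
    class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the imaging pipeline on a session
#'
#' register -> quantify -> responder classification, writing per-trial and
#' per-fly CSV tables, the shift log, and a machine-readable JSON summary
#' stamped with the config hash and seed so a rerun with the stored
#' configuration reproduces it.
#'
#' @param session a session directory/manifest path (see [read_session()])
#'   or a list of trials; `roi` may override the session's mask.
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @param roi optional logical ROI mask.
#' @return (invisibly) list with `trial_stats`, `responders`, `shift_log`,
#'   `summary`.
#' @export
run_pipeline <- function(session, out_dir, config = pipeline_config(),
                         roi = NULL) {
  if (is.character(session)) session <- read_session(session)
  if (!is.null(session$trials)) {
    trials <- session$trials
    roi <- roi %||% session$roi
  } else trials <- session
  if (is.null(roi))
    stop_ft("no ROI mask: supply `roi` or a session with a roi_file")

  reg <- register_session(trials, policy = config$registration$policy,
                          upsample = config$registration$upsample)
  shift_log <- do.call(rbind, lapply(seq_along(reg), function(i)
    cbind(trial = reg[[i]]$movie$trial_label, reg[[i]]$shifts)))

  q <- config$quantify
  trial_stats <- quantify_session(reg, roi, n_baseline = q$n_baseline,
                                  peak_extend_s = q$peak_extend_s,
                                  integrate_post_s = q$integrate_post_s)
  responders <- responder_table(trial_stats, water_label = q$water_label,
                                thetas = q$thetas)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trial_stats, file.path(out_dir, "trial_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(responders, file.path(out_dir, "responders.csv"),
                   row.names = FALSE)
  utils::write.csv(shift_log, file.path(out_dir, "shift_log.csv"),
                   row.names = FALSE)
  summary <- list(config_hash = config_hash(config),
                  seed = config$stats$seed,
                  n_trials = nrow(trial_stats),
                  n_flies = length(unique(trial_stats$fly_id)),
                  stimuli = sort(unique(trial_stats$stimulus)),
                  mean_peak_by_stimulus = lapply(
                    split(trial_stats$peak, trial_stats$stimulus), mean),
                  responder_fraction = lapply(
                    responders[grep("^responder_", names(responders))],
                    function(col) mean(col, na.rm = TRUE)))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(trial_stats = trial_stats, responders = responders,
                 shift_log = shift_log, summary = summary))
}

#' Run the PER behavioral pipeline on a dataset
#'
#' QC -> group summaries -> repeated-measures ANOVA -> post-tests, writing
#' group percentages, the ANOVA table, the post-test table, and a JSON
#' summary.
#'
#' @param dataset PER data.frame (see [make_per_dataset()] schema) or a CSV
#'   path.
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @return (invisibly) list with `groups`, `fit`, `posthoc`, `summary`.
#' @export
run_per_pipeline <- function(dataset, out_dir, config = pipeline_config()) {
  if (is.character(dataset))
    dataset <- utils::read.csv(dataset, stringsAsFactors = FALSE)
  ds <- apply_qc(dataset, policy = config$behavior$qc_policy)
  groups <- summarize_per_groups(ds)
  st <- config$stats
  if (st$design == "two-way-rm") {
    fit <- rm_anova(groups, response = "percent_per", unit = "group_id",
                    within = "dose", between = st$between)
    posthoc <- if (st$posthoc == "bonferroni")
      bonferroni_posttests(fit, alpha = st$alpha) else NULL
  } else {
    fit <- rm_anova(groups, response = "percent_per", unit = "group_id",
                    within = "dose")
    posthoc <- if (st$posthoc == "dunnett")
      dunnett(fit, control = as.character(min(groups$dose)), n_mc = st$n_mc,
              seed = st$seed, alpha = st$alpha)
    else if (st$posthoc == "bonferroni")
      bonferroni_posttests(fit, alpha = st$alpha) else NULL
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(groups, file.path(out_dir, "groups.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(fit), file.path(out_dir, "anova.csv"),
                   row.names = FALSE)
  if (!is.null(posthoc))
    utils::write.csv(posthoc, file.path(out_dir, "posthoc.csv"),
                     row.names = FALSE)
  excl <- attr(ds, "exclusions")
  summary <- list(config_hash = config_hash(config), seed = st$seed,
                  n_groups = length(unique(groups$group_id)),
                  n_excluded_flies = nrow(excl),
                  effects = stats::setNames(as.list(fit$p), fit$effect))
  jsonlite::write_json(summary, file.path(out_dir, "per_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(groups = groups, fit = fit, posthoc = posthoc,
                 summary = summary))
}
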