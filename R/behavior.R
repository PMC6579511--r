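#' Score a two-trial PER test
#'
#' Each test consists of two brief applications of the solution; a full
#' proboscis extension on at least one of the two trials is a positive
#' response. Partial extensions never count and must not be coded as
#' `TRUE` upstream.
#'
#' @param trial1,trial2 logical full-extension outcomes (vectorized).
#' @return logical: positive test.
#' @export
score_per_test <- function(trial1, trial2) {
  if (any(is.na(trial1)) || any(is.na(trial2)))
    stop_ft("both trial outcomes must be set")
  trial1 | trial2
}

#' Apply the assay's exclusion rules to a PER dataset
#'
#' Two policies mirror the assay's conventions:
#' \describe{
#'   \item{`wildtype_starved`}{Flies that respond to no taste stimulus are
#'     given 500 mM sucrose at the end of the assay; healthy starved
#'     wild-type flies always respond to concentrated sugar, so a fly that
#'     is negative on every stimulus *and* fails the sucrose check is
#'     excluded as unhealthy. All-negative flies that pass the check are
#'     retained.}
#'   \item{`compare_groups`}{For experiments comparing groups (fed vs
#'     starved, genotypes), flies are excluded only if flagged very sick
#'     (optional logical `sick` column); the sucrose rule is not applied.}
#' }
#' Exclusion is fly-level: an excluded fly is removed from every dose row.
#' The operation is idempotent.
#'
#' @param dataset a PER data.frame (see [make_per_dataset()] for the
#'   schema).
#' @param policy exclusion policy.
#' @return the filtered data.frame; attribute `exclusions` lists removed
#'   fly_ids with the reason.
#' @export
apply_qc <- function(dataset, policy = c("wildtype_starved",
                                         "compare_groups")) {
  policy <- match.arg(policy)
  excl <- data.frame(fly_id = character(), reason = character(),
                     stringsAsFactors = FALSE)
  if (policy == "wildtype_starved") {
    if (is.null(dataset$sucrose500_check))
      stop_ft("wildtype_starved policy needs a sucrose500_check column")
    pos <- score_per_test(dataset$trial1, dataset$trial2)
    by_fly <- tapply(pos, dataset$fly_id, any)
    check <- tapply(dataset$sucrose500_check, dataset$fly_id, all)
    bad <- names(by_fly)[!by_fly & !check[names(by_fly)]]
    if (length(bad))
      excl <- data.frame(fly_id = bad,
                         reason = "no response to any stimulus nor 500 mM sucrose",
                         stringsAsFactors = FALSE)
  } else {
    if (!is.null(dataset$sick)) {
      bad <- unique(dataset$fly_id[dataset$sick])
      if (length(bad))
        excl <- data.frame(fly_id = bad, reason = "very sick",
                           stringsAsFactors = FALSE)
    }
  }
  out <- dataset[!dataset$fly_id %in% excl$fly_id, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

#' Percentage of flies showing PER in one group
#'
#' One group of 15-20 flies is a single statistical data point: the percent
#' of its flies scoring positive on the two-trial test.
#'
#' @param tests data.frame of one group x tastant x dose (columns trial1,
#'   trial2, and optionally group_id, state, tastant, dose).
#' @return one-row data.frame: group_id, state, tastant, dose, n_flies,
#'   percent_per (full precision; format with [format_percent()] to match
#'   conventional integer reporting).
#' @export
group_fraction <- function(tests) {
  if (nrow(tests) == 0) stop_ft("group_fraction needs at least one fly")
  pos <- score_per_test(tests$trial1, tests$trial2)
  data.frame(group_id = (tests$group_id %||% NA_character_)[1],
             state = (tests$state %||% NA_character_)[1],
             tastant = (tests$tastant %||% NA_character_)[1],
             dose = (tests$dose %||% NA_real_)[1],
             n_flies = nrow(tests),
             percent_per = 100 * mean(pos), stringsAsFactors = FALSE)
}

#' Summarize a PER dataset to group x dose percentages
#'
#' Applies [group_fraction()] to every group x tastant x dose cell; the
#' result is the unit-level table fed to [rm_anova()].
#'
#' @param dataset PER data.frame (post-QC).
#' @return data.frame, one row per group x tastant x dose.
#' @export
summarize_per_groups <- function(dataset) {
  key <- interaction(dataset$group_id, dataset$tastant, dataset$dose,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(dataset, key), group_fraction))
  out <- out[order(out$state, out$group_id, out$tastant, out$dose), ]
  rownames(out) <- NULL
  out
}

#' Format a percentage the way group summaries are conventionally reported
#'
#' @param x percentage(s), full precision.
#' @return integer-rounded percentage(s).
#' @export
format_percent <- function(x) round(x)

#' Summarize directional-PER trials
#'
#' Tallies full-PER trials by whether the proboscis extended toward the
#' stimulated side, away from it, or neither, and reports each outcome as a
#' fraction and as a nearest-integer percentage of all PER trials.
#'
#' @param trials a `directional_dataset` (data.frame with an `outcome`
#'   column in \{toward, away, neither\}).
#' @return list of class `directional_summary`: `n_trials`, `n_flies`,
#'   `counts`, `fractions`, `percent` (named, nearest integer).
#' @export
directional_summary <- function(trials) {
  if (nrow(trials) == 0) stop_ft("no PER trials to summarize")
  bad <- setdiff(unique(trials$outcome), c("toward", "away", "neither"))
  if (length(bad)) stop_ft("unknown outcome label(s): %s",
                           paste(bad, collapse = ", "))
  counts <- vapply(c("toward", "away", "neither"),
                   function(o) sum(trials$outcome == o), integer(1))
  n <- sum(counts)
  structure(list(n_trials = n,
                 n_flies = length(unique(trials$fly_id %||% NA)),
                 counts = counts, fractions = counts / n,
                 percent = round(100 * counts / n)),
            class = "directional_summary")
}

#' @export
print.directional_summary <- function(x, ...) {
  cat(sprintf("Directional PER: %d trials, %d flies\n", x$n_trials, x$n_flies))
  for (o in names(x$counts))
    cat(sprintf("  %-8s %3d trials  (%d%%)\n", o, x$counts[o], x$percent[o]))
  invisible(x)
}
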