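#' Simulation parameters for synthetic PER datasets
#'
#' Generates binary proboscis-extension outcomes under a two-pathway
#' dose-response model: an appetitive (sugar-pathway) drive and an aversive
#' (bitter-pathway) drive both increase with tastant dose, and hunger
#' multiplies the appetitive gain up while dividing the aversive gain down.
#' The per-trial response probability of a fly is
#' `plogis(baseline_logit + fly_offset + g_app(state) * A(dose) -
#' g_av(state) * B(dose))`, where `fly_offset ~ N(0, sigma_fly)` is a
#' fly-level latent responsiveness shared by the two trials of every test
#' (trials are conditionally independent given the fly). With the default
#' calibration the fed dose-response to an acid-like tastant stays flat and
#' low while the 2-day-starved curve rises steeply — the hunger-dependent
#' valence switch the analysis pipeline is designed to detect (~86% of
#' 2-day-starved flies positive at the top dose, <5% of fed flies).
#'
#' @param n_groups groups per state (each group is one statistical unit).
#' @param group_size_range flies per group, sampled uniformly (15-20 by the
#'   assay's convention).
#' @param states character vector of hunger states.
#' @param doses tastant concentrations; 0 is the water baseline.
#' @param appetitive_drive,aversive_drive monotone increasing functions of
#'   dose, returning values in `[0, 1]` (default saturating `d / (d + 2)`).
#' @param hunger_gain_appetitive,hunger_gain_aversive named multipliers per
#'   state; appetitive gains must be non-decreasing and aversive gains
#'   non-increasing with starvation.
#' @param baseline_logit log-odds of the water-response floor (default
#'   `qlogis(0.05)`).
#' @param sigma_fly sd of the fly-level latent logit offset.
#' @param sucrose_check_rate probability that a healthy fly passes the
#'   500 mM sucrose responsiveness check.
#' @return an object of class `behavior_sim_params`.
#' @export
behavior_sim_params <- function(n_groups = 4L, group_size_range = c(15L, 20L),
                                states = c("fed", "starved_1d", "starved_2d"),
                                doses = c(0, 1, 5, 10),
                                appetitive_drive = function(d) d / (d + 2),
                                aversive_drive = function(d) d / (d + 2),
                                hunger_gain_appetitive = c(fed = 0.5,
                                                           starved_1d = 3,
                                                           starved_2d = 4.5),
                                hunger_gain_aversive = c(fed = 3,
                                                         starved_1d = 1.2,
                                                         starved_2d = 0.4),
                                baseline_logit = stats::qlogis(0.05),
                                sigma_fly = 0.5,
                                sucrose_check_rate = 0.95) {
  if (!all(states %in% names(hunger_gain_appetitive)) ||
      !all(states %in% names(hunger_gain_aversive)))
    stop_ft("hunger gains must be named for every state")
  if (is.unsorted(hunger_gain_appetitive[states]))
    stop_ft("appetitive gain must be non-decreasing with starvation")
  if (is.unsorted(rev(hunger_gain_aversive[states])))
    stop_ft("aversive gain must be non-increasing with starvation")
  if (group_size_range[1] > group_size_range[2] || group_size_range[1] < 1)
    stop_ft("invalid group_size_range")
  structure(list(n_groups = as.integer(n_groups),
                 group_size_range = as.integer(group_size_range),
                 states = states, doses = doses,
                 appetitive_drive = appetitive_drive,
                 aversive_drive = aversive_drive,
                 hunger_gain_appetitive = hunger_gain_appetitive,
                 hunger_gain_aversive = hunger_gain_aversive,
                 baseline_logit = baseline_logit, sigma_fly = sigma_fly,
                 sucrose_check_rate = sucrose_check_rate),
            class = "behavior_sim_params")
}

# generative per-trial P(PER) for a fly with latent offset `off`
per_trial_prob <- function(params, state, dose, off = 0) {
  stats::plogis(params$baseline_logit + off +
                  params$hunger_gain_appetitive[[state]] *
                  params$appetitive_drive(dose) -
                  params$hunger_gain_aversive[[state]] *
                  params$aversive_drive(dose))
}

#' Generative test-level P(PER) under the simulator
#'
#' Probability that a fly scores positive on a two-trial test (at least one
#' of two conditionally independent trials), integrating over the fly-level
#' latent offset by quadrature on a fine grid. Useful as the analytic
#' target in recovery tests.
#'
#' @param params a [behavior_sim_params()] object.
#' @param state,dose condition.
#' @return scalar probability.
#' @export
per_test_prob <- function(params, state, dose) {
  if (params$sigma_fly == 0)
    return(1 - (1 - per_trial_prob(params, state, dose))^2)
  z <- seq(-6, 6, length.out = 2001)
  wgt <- stats::dnorm(z); wgt <- wgt / sum(wgt)
  p <- per_trial_prob(params, state, dose, z * params$sigma_fly)
  sum(wgt * (1 - (1 - p)^2))
}

#' Generate a synthetic PER dataset
#'
#' Simulates the full assay layout: for every state, `n_groups` groups of
#' 15-20 flies, every fly tested at every dose with two trials per test.
#' Each fly carries a latent responsiveness offset shared across its trials
#' and doses; the 500 mM sucrose end-of-assay check is drawn from the same
#' offset. The generative per-trial probability of every record is stored in
#' the `truth` attribute.
#'
#' @param params a [behavior_sim_params()] object.
#' @param seed integer seed (bit-identical output for identical inputs).
#' @param tastant label stored in the records.
#' @return data.frame of class `per_dataset` with columns group_id, fly_id,
#'   state, tastant, dose, trial1, trial2, sucrose500_check; attributes
#'   `truth` (per-record generative p) and `params`.
#' @export
make_per_dataset <- function(params = behavior_sim_params(), seed = 1L,
                             tastant = "acetic_acid") {
  with_seed(substream_seed(seed, "per_dataset"), {
    rows <- list(); truths <- list(); k <- 0L
    for (state in params$states) {
      for (g in seq_len(params$n_groups)) {
        gid <- sprintf("%s_g%d", state, g)
        n_fly <- sample(params$group_size_range[1]:params$group_size_range[2], 1)
        offs <- stats::rnorm(n_fly, 0, params$sigma_fly)
        p_check <- stats::plogis(stats::qlogis(params$sucrose_check_rate) + offs)
        check <- stats::runif(n_fly) < p_check
        for (f in seq_len(n_fly)) {
          p <- vapply(params$doses, function(d)
            per_trial_prob(params, state, d, offs[f]), numeric(1))
          t1 <- stats::runif(length(p)) < p
          t2 <- stats::runif(length(p)) < p
          k <- k + 1L
          rows[[k]] <- data.frame(
            group_id = gid, fly_id = sprintf("%s_f%d", gid, f), state = state,
            tastant = tastant, dose = params$doses, trial1 = t1, trial2 = t2,
            sucrose500_check = check[f], stringsAsFactors = FALSE)
          truths[[k]] <- p
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- unlist(truths)
    attr(out, "params") <- params
    class(out) <- c("per_dataset", "data.frame")
    out
  })
}

#' Generate a synthetic directional-PER dataset
#'
#' Trials in which a starved fly showing full PER was stimulated on one
#' leg; the outcome records whether the proboscis extended toward the
#' stimulated side, away from it, or neither. Outcomes are multinomial with
#' the given probabilities; stimulated sides alternate L/R.
#'
#' @param n_trials number of full-PER trials.
#' @param p_toward,p_neither outcome probabilities
#'   (`p_toward + p_neither <= 1`; the remainder is `away`).
#' @param seed integer seed.
#' @param n_flies number of flies the trials are spread over.
#' @return data.frame of class `directional_dataset` with columns fly_id,
#'   side_stimulated, outcome; attribute `truth`.
#' @export
make_directional_dataset <- function(n_trials, p_toward, p_neither = 0,
                                     seed = 1L, n_flies = max(1L,
                                       ceiling(n_trials / 6))) {
  if (p_toward < 0 || p_neither < 0 || p_toward + p_neither > 1)
    stop_ft("need p_toward + p_neither <= 1 with both non-negative")
  if (n_trials == 0) {
    out <- data.frame(fly_id = character(), side_stimulated = character(),
                      outcome = character(), stringsAsFactors = FALSE)
  } else {
    out <- with_seed(substream_seed(seed, "directional"), {
      outcome <- sample(c("toward", "neither", "away"), n_trials,
                        replace = TRUE,
                        prob = c(p_toward, p_neither, 1 - p_toward - p_neither))
      data.frame(fly_id = sprintf("fly%d", rep_len(seq_len(n_flies), n_trials)),
                 side_stimulated = rep_len(c("L", "R"), n_trials),
                 outcome = outcome, stringsAsFactors = FALSE)
    })
  }
  attr(out, "truth") <- c(toward = p_toward, neither = p_neither,
                          away = 1 - p_toward - p_neither)
  class(out) <- c("directional_dataset", "data.frame")
  out
}
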