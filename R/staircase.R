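# Two-interval forced-choice adaptive staircase simulation. The transformed
# staircase decreases the modulation amplitude after three consecutive
# correct responses and increases it after any incorrect response, with
# multiplicative steps (1.6 for the first five trials, 1.3 thereafter). It
# terminates at the tenth reversal and the threshold is the geometric mean
# of the last eight reversal amplitudes; the rule converges on the
# 0.5^(1/3) ~ 79.4%-correct point of the psychometric function.

#' Staircase configuration
#'
#' @param n_down consecutive correct responses required before an amplitude
#'   decrease (an incorrect response always produces an increase).
#' @param step_factor_early multiplicative step factor for the first
#'   `early_trials` trials.
#' @param step_factor_late step factor thereafter.
#' @param early_trials number of trials using the early step factor.
#' @param n_reversals_stop reversals at which the staircase terminates.
#' @param n_reversals_used trailing reversals entering the threshold.
#' @param max_trials safety cap on trial count.
#' @return an object of class `"staircase_config"`.
#' @export
staircase_config <- function(n_down = 3, step_factor_early = 1.6,
                             step_factor_late = 1.3, early_trials = 5,
                             n_reversals_stop = 10, n_reversals_used = 8,
                             max_trials = 200) {
  if (step_factor_early <= 1 || step_factor_late <= 1) {
    texmod_error("texmod_invalid_argument", "step factors must exceed 1")
  }
  if (n_reversals_used > n_reversals_stop) {
    texmod_error("texmod_invalid_argument",
                 "`n_reversals_used` cannot exceed `n_reversals_stop`")
  }
  stopifnot_scalar_positive(max_trials, "max_trials")
  structure(
    list(n_down = as.integer(n_down),
         step_factor_early = step_factor_early,
         step_factor_late = step_factor_late,
         early_trials = as.integer(early_trials),
         n_reversals_stop = as.integer(n_reversals_stop),
         n_reversals_used = as.integer(n_reversals_used),
         max_trials = as.integer(max_trials)),
    class = "staircase_config"
  )
}

#' Synthetic 2IFC observer
#'
#' A simulated participant with a Weibull psychometric function:
#' `p(correct) = guess + (1 - guess - lapse) * (1 - exp(-(a / tau)^k))`.
#'
#' @param threshold_scale Weibull scale `tau` (modulation units, > 0).
#' @param slope Weibull slope `k` (> 0).
#' @param guess_rate lower asymptote; 0.5 for 2IFC.
#' @param lapse_rate lapse probability (in `[0, 0.5)`).
#' @return an object of class `"synthetic_observer"`.
#' @export
synthetic_observer <- function(threshold_scale, slope, guess_rate = 0.5,
                               lapse_rate = 0.02) {
  stopifnot_scalar_positive(threshold_scale, "threshold_scale")
  stopifnot_scalar_positive(slope, "slope")
  if (lapse_rate < 0 || lapse_rate >= 0.5) {
    texmod_error("texmod_invalid_argument", "`lapse_rate` must be in [0, 0.5)")
  }
  structure(
    list(threshold_scale = threshold_scale, slope = slope,
         guess_rate = guess_rate, lapse_rate = lapse_rate),
    class = "synthetic_observer"
  )
}

#' Probability of a correct response
#'
#' @param obs a [synthetic_observer()].
#' @param amplitude modulation amplitude(s), >= 0.
#' @return probability (vectorized over `amplitude`); monotone
#'   non-decreasing, equal to the guess rate at zero amplitude and
#'   approaching `1 - lapse_rate` as amplitude grows.
#' @export
observer_p_correct <- function(obs, amplitude) {
  stopifnot(inherits(obs, "synthetic_observer"))
  if (any(amplitude < 0)) {
    texmod_error("texmod_invalid_argument", "`amplitude` must be >= 0")
  }
  obs$guess_rate + (1 - obs$guess_rate - obs$lapse_rate) *
    (1 - exp(-(amplitude / obs$threshold_scale)^obs$slope))
}

#' Amplitude at which the staircase rule converges
#'
#' The n-down/1-up transformed rule converges where
#' `p(correct) = 0.5^(1/n_down)` (79.4% for the 3-down rule); this returns
#' that amplitude by inverting the observer's Weibull function.
#'
#' @param obs a [synthetic_observer()].
#' @param n_down the down rule (3 by default).
#' @return amplitude in modulation units.
#' @export
observer_convergence_amplitude <- function(obs, n_down = 3) {
  p <- 0.5^(1 / n_down)
  frac <- (p - obs$guess_rate) / (1 - obs$guess_rate - obs$lapse_rate)
  if (frac <= 0 || frac >= 1) {
    texmod_error("texmod_invalid_argument",
                 "convergence level outside the observer's attainable range")
  }
  obs$threshold_scale * (-log(1 - frac))^(1 / obs$slope)
}

#' Geometric-mean threshold from reversal amplitudes
#'
#' @param reversal_amplitudes reversal amplitudes in trial order.
#' @param n_used number of trailing reversals to average (geometrically).
#' @return the threshold estimate.
#' @export
threshold_from_reversals <- function(reversal_amplitudes, n_used = 8) {
  if (length(reversal_amplitudes) < n_used) {
    texmod_error("texmod_invalid_argument", sprintf(
      "need at least %d reversals, got %d", n_used,
      length(reversal_amplitudes)))
  }
  geometric_mean(utils::tail(reversal_amplitudes, n_used))
}

#' Run one adaptive staircase
#'
#' Simulates the transformed up-down staircase against a synthetic observer.
#' Amplitude moves multiplicatively: divided by the step factor after
#' `n_down` consecutive correct responses (the streak counter then resets),
#' multiplied by it after any incorrect response. A reversal is a trial at
#' which the direction of amplitude change flips; the staircase stops at
#' `n_reversals_stop` reversals and the threshold is the geometric mean of
#' the last `n_reversals_used` reversal amplitudes. Uses R's global RNG.
#'
#' @param obs a [synthetic_observer()].
#' @param cfg a [staircase_config()].
#' @param start_amplitude initial amplitude; by default a random value in a
#'   small range above threshold (3 x the observer scale, jittered +/-20%).
#' @return a list of class `"staircase_run"` with `threshold`,
#'   `reversal_amplitudes`, and a `trials` data frame (`trial`, `amplitude`,
#'   `correct`, `reversal`).
#' @export
run_staircase <- function(obs, cfg = staircase_config(),
                          start_amplitude = NULL) {
  stopifnot(inherits(obs, "synthetic_observer"),
            inherits(cfg, "staircase_config"))
  if (is.null(start_amplitude)) {
    start_amplitude <- 3 * obs$threshold_scale * stats::runif(1, 0.8, 1.2)
  }
  stopifnot_scalar_positive(start_amplitude, "start_amplitude")

  amp <- start_amplitude
  streak <- 0L
  last_dir <- 0L
  reversals <- numeric(0)
  trial_amp <- numeric(cfg$max_trials)
  trial_correct <- logical(cfg$max_trials)
  trial_rev <- logical(cfg$max_trials)
  n_trials <- 0L
  done <- FALSE

  for (t in seq_len(cfg$max_trials)) {
    correct <- stats::runif(1) < observer_p_correct(obs, amp)
    change <- 0L
    if (correct) {
      streak <- streak + 1L
      if (streak == cfg$n_down) {
        change <- -1L
        streak <- 0L
      }
    } else {
      streak <- 0L
      change <- 1L
    }
    reversal <- change != 0L && last_dir != 0L && change != last_dir
    n_trials <- t
    trial_amp[t] <- amp
    trial_correct[t] <- correct
    trial_rev[t] <- reversal
    if (reversal) reversals <- c(reversals, amp)
    if (length(reversals) >= cfg$n_reversals_stop) {
      done <- TRUE
      break
    }
    if (change != 0L) {
      step <- if (t <= cfg$early_trials) cfg$step_factor_early else cfg$step_factor_late
      amp <- amp * step^change
      last_dir <- change
    }
  }

  trials <- data.frame(trial = seq_len(n_trials),
                       amplitude = trial_amp[seq_len(n_trials)],
                       correct = trial_correct[seq_len(n_trials)],
                       reversal = trial_rev[seq_len(n_trials)])
  if (!done) {
    texmod_error("texmod_nonconvergence", sprintf(
      "staircase reached max_trials = %d with %d of %d reversals",
      cfg$max_trials, length(reversals), cfg$n_reversals_stop),
      trials = trials, reversal_amplitudes = reversals)
  }
  structure(
    list(threshold = threshold_from_reversals(reversals, cfg$n_reversals_used),
         reversal_amplitudes = reversals, trials = trials,
         start_amplitude = start_amplitude),
    class = "staircase_run"
  )
}

#' Convergence level of the staircase procedure
#'
#' Runs many replicate staircases against one observer and evaluates the
#' observer's percent correct at the across-replicate mean threshold —
#' an empirical check that the 3-down/1-up rule tracks the ~79%-correct
#' point.
#'
#' @param obs a [synthetic_observer()].
#' @param cfg a [staircase_config()].
#' @param n_reps number of replicate staircases.
#' @return a list with `thresholds` (per replicate), `mean_threshold`,
#'   `p_correct` and `percent_correct` at the mean threshold.
#' @export
estimate_convergence_level <- function(obs, cfg = staircase_config(),
                                       n_reps = 500) {
  thresholds <- vapply(seq_len(n_reps),
                       function(i) run_staircase(obs, cfg)$threshold,
                       numeric(1))
  mean_thr <- mean(thresholds)
  p <- observer_p_correct(obs, mean_thr)
  list(thresholds = thresholds, mean_threshold = mean_thr,
       p_correct = p, percent_correct = 100 * p)
}
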