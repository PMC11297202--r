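# Synthetic threshold-data generation. The generator is a forward model of
# the analysis: each (texture, task) condition is governed by a "true" DoG
# filter, model sensitivities are computed by convolution, and thresholds
# are their reciprocals perturbed by multiplicative lognormal noise (or
# measured end-to-end by the simulated staircase). Detection regimes use a
# broad, low-peak-frequency filter so that the square wave's larger energy
# yields the SQ < SN < CS threshold ordering; discrimination regimes use a
# narrow, high-peak-frequency filter so that edge-carrying waveforms (SQ,
# CS) dominate at low modulation frequencies.

#' Factorial study design
#'
#' @param texture_types texture modulation types.
#' @param waveforms waveform kinds measured per condition.
#' @param frequencies modulation frequencies, cycles per image.
#' @param tasks task names.
#' @param n_participants number of simulated participants.
#' @param thresholds_per_condition replicate thresholds per condition
#'   (between 3 and 6 in the study protocol).
#' @return an object of class `"study_design"`. The default design has
#'   5 x 3 x 4 = 60 conditions per task and 5 x 2 x 3 = 30 fit groups.
#' @export
study_design <- function(texture_types = c("OM", "OVM", "LM", "CM", "CVM"),
                         waveforms = c("SN", "SQ", "CS"),
                         frequencies = c(1, 2, 4, 8),
                         tasks = c("detection", "discrimination"),
                         n_participants = 3,
                         thresholds_per_condition = 3) {
  if (thresholds_per_condition < 1) {
    texmod_error("texmod_invalid_argument",
                 "`thresholds_per_condition` must be >= 1")
  }
  structure(
    list(texture_types = texture_types, waveforms = waveforms,
         frequencies = frequencies, tasks = tasks,
         n_participants = as.integer(n_participants),
         thresholds_per_condition = as.integer(thresholds_per_condition)),
    class = "study_design"
  )
}

#' Full factorial condition grid
#'
#' @param design a [study_design()].
#' @return a data frame in deterministic order with columns `task`,
#'   `texture_type`, `waveform`, `frequency_cpi`; the default design yields
#'   60 rows per task.
#' @export
generate_condition_grid <- function(design = study_design()) {
  g <- expand.grid(frequency_cpi = design$frequencies,
                   waveform = design$waveforms,
                   texture_type = design$texture_types,
                   task = design$tasks,
                   stringsAsFactors = FALSE)
  g[, c("task", "texture_type", "waveform", "frequency_cpi")]
}

#' Default generating filter parameters
#'
#' One true DoG parameter set per (texture type, task). Non-CVM detection
#' conditions share a broad filter (peak ~2.6 cpi) whose steep high-frequency
#' attenuation of the waveform harmonics reproduces the energy-driven
#' SQ < SN < CS threshold ordering at every study frequency; non-CVM
#' discrimination conditions share a narrow filter (peak ~12 cpi) that
#' favours the edge-carrying SQ and CS waveforms at low modulation
#' frequencies. CVM conditions use a narrow filter (peak ~10 cpi) for both
#' tasks, with the fixed 1 : 1/2 : 1/3 scaling of CS : SQ : SN
#' sensitivities. These regimes are documented package defaults chosen to
#' produce the qualitative structure of real threshold data; they are not
#' estimates of any participant's filter.
#'
#' @return a data frame with columns `texture_type`, `task`, `alpha`,
#'   `beta`, `gamma`, `delta`.
#' @export
default_true_params <- function() {
  textures <- c("OM", "OVM", "LM", "CM", "CVM")
  out <- expand.grid(texture_type = textures,
                     task = c("detection", "discrimination"),
                     stringsAsFactors = FALSE)
  out$alpha <- 100
  broad <- out$task == "detection" & out$texture_type != "CVM"
  narrow <- out$task == "discrimination" & out$texture_type != "CVM"
  out$beta <- ifelse(broad, 0.6, 1)
  out$gamma <- ifelse(broad, 12, ifelse(narrow, 2, 2.5))
  out$delta <- ifelse(broad, 1.8, 4)
  out
}

#' Generator scenario
#'
#' @param true_params data frame as returned by [default_true_params()]
#'   giving the generating DoG parameters per (texture type, task).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   noise applied to each replicate threshold.
#' @param cvm_scaling apply the fixed CS : SQ : SN = 1 : 1/2 : 1/3
#'   sensitivity scaling to CVM conditions (the SQ and SN rows are then the
#'   scaled CS row rather than independent convolution outputs).
#' @param observer_slope Weibull slope of the synthetic observers used by
#'   [generate_via_staircase()].
#' @param seed optional integer seed applied before generation.
#' @return an object of class `"generator_scenario"`.
#' @export
generator_scenario <- function(true_params = default_true_params(),
                               noise_cv = 0.1, cvm_scaling = TRUE,
                               observer_slope = 4, seed = NULL) {
  if (noise_cv < 0) {
    texmod_error("texmod_invalid_argument", "`noise_cv` must be >= 0")
  }
  needed <- c("texture_type", "task", "alpha", "beta", "gamma", "delta")
  if (!all(needed %in% names(true_params))) {
    texmod_error("texmod_invalid_argument", sprintf(
      "`true_params` must have columns %s", paste(needed, collapse = ", ")))
  }
  structure(
    list(true_params = true_params, noise_cv = noise_cv,
         cvm_scaling = cvm_scaling, observer_slope = observer_slope,
         seed = seed),
    class = "generator_scenario"
  )
}

# Look up the generating parameters for one (texture, task).
scenario_params <- function(scenario, texture, task) {
  tp <- scenario$true_params
  row <- tp[tp$texture_type == texture & tp$task == task, , drop = FALSE]
  if (nrow(row) != 1L) {
    texmod_error("texmod_invalid_scenario", sprintf(
      "scenario has %d parameter rows for (%s, %s); need exactly 1",
      nrow(row), texture, task))
  }
  p <- dog_params(row$alpha, row$beta, row$gamma, row$delta)
  if (p$delta <= 1 || p$beta * p$delta^2 <= 1) {
    texmod_error("texmod_invalid_scenario", sprintf(
      "generating parameters for (%s, %s) have no defined peak frequency",
      texture, task))
  }
  p
}

# Model sensitivity matrix (waveforms x frequencies) for one group, with
# the CVM scaling rule applied when requested.
scenario_sensitivities <- function(scenario, design, texture, task,
                                   grid = filter_grid()) {
  p <- scenario_params(scenario, texture, task)
  if (texture == "CVM" && scenario$cvm_scaling) {
    cs <- predict_sensitivities(p, "CS", design$frequencies, grid)["CS", ]
    scale <- c(CS = 1, SQ = 0.5, SN = 1 / 3)
    s <- t(vapply(design$waveforms, function(k) {
      if (!k %in% names(scale)) {
        texmod_error("texmod_invalid_scenario", sprintf(
          "no CVM scale factor for waveform %s", k))
      }
      scale[[k]] * cs
    }, cs))
    dimnames(s) <- list(design$waveforms, as.character(design$frequencies))
    s
  } else {
    predict_sensitivities(p, design$waveforms, design$frequencies, grid)
  }
}

sdlog_from_cv <- function(cv) sqrt(log(1 + cv^2))

#' Generate a synthetic threshold table
#'
#' For every (participant, task, texture, waveform, frequency) cell, draws
#' `thresholds_per_condition` replicate thresholds as the reciprocal model
#' sensitivity times multiplicative lognormal noise, and records their mean
#' and standard error — the same summary the experimental protocol produces
#' from repeated staircases.
#'
#' @param scenario a [generator_scenario()].
#' @param design a [study_design()].
#' @param grid a [filter_grid()].
#' @return a data frame of threshold records with columns `participant`,
#'   `task`, `texture_type`, `waveform`, `frequency_cpi`, `threshold`, `se`,
#'   `n_staircases`.
#' @export
generate_thresholds <- function(scenario, design = study_design(),
                                grid = filter_grid()) {
  stopifnot(inherits(scenario, "generator_scenario"),
            inherits(design, "study_design"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  sdlog <- sdlog_from_cv(scenario$noise_cv)
  rows <- list()
  for (task in design$tasks) {
    for (texture in design$texture_types) {
      s <- scenario_sensitivities(scenario, design, texture, task, grid)
      for (pp in seq_len(design$n_participants)) {
        for (k in design$waveforms) {
          for (f in as.character(design$frequencies)) {
            base <- 1 / s[k, f]
            reps <- base * stats::rlnorm(design$thresholds_per_condition,
                                         meanlog = 0, sdlog = sdlog)
            rows[[length(rows) + 1L]] <- data.frame(
              participant = sprintf("S%d", pp), task = task,
              texture_type = texture, waveform = k,
              frequency_cpi = as.numeric(f),
              threshold = mean(reps),
              se = if (length(reps) > 1) stats::sd(reps) / sqrt(length(reps)) else NA_real_,
              n_staircases = length(reps))
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate thresholds end-to-end through the simulated staircase
#'
#' The slower, fully mechanistic variant of [generate_thresholds()]: each
#' replicate threshold comes from running the adaptive staircase against a
#' synthetic Weibull observer whose 79.4%-correct amplitude equals the
#' reciprocal model sensitivity for that condition.
#'
#' @inheritParams generate_thresholds
#' @param cfg a [staircase_config()].
#' @return a threshold-record data frame as in [generate_thresholds()].
#' @export
generate_via_staircase <- function(scenario, design = study_design(),
                                   cfg = staircase_config(),
                                   grid = filter_grid()) {
  stopifnot(inherits(scenario, "generator_scenario"),
            inherits(design, "study_design"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  rows <- list()
  for (task in design$tasks) {
    for (texture in design$texture_types) {
      s <- scenario_sensitivities(scenario, design, texture, task, grid)
      for (pp in seq_len(design$n_participants)) {
        for (k in design$waveforms) {
          for (f in as.character(design$frequencies)) {
            target <- 1 / s[k, f]
            # Scale tau so the observer's 79.4%-correct point sits at the
            # model threshold.
            probe <- synthetic_observer(1, scenario$observer_slope)
            tau <- target / observer_convergence_amplitude(probe, cfg$n_down)
            obs <- synthetic_observer(tau, scenario$observer_slope)
            reps <- tryCatch(
              vapply(seq_len(design$thresholds_per_condition),
                     function(i) run_staircase(obs, cfg)$threshold,
                     numeric(1)),
              texmod_nonconvergence = function(e) {
                texmod_error("texmod_nonconvergence", sprintf(
                  "staircase failed to converge for %s/%s/%s/%s cpi: %s",
                  task, texture, k, f, conditionMessage(e)))
              })
            rows[[length(rows) + 1L]] <- data.frame(
              participant = sprintf("S%d", pp), task = task,
              texture_type = texture, waveform = k,
              frequency_cpi = as.numeric(f),
              threshold = mean(reps),
              se = if (length(reps) > 1) stats::sd(reps) / sqrt(length(reps)) else NA_real_,
              n_staircases = length(reps))
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Write / read threshold records as CSV
#'
#' @param records a threshold-record data frame.
#' @param path file path.
#' @return `path` invisibly (write) or the validated data frame (read).
#' @export
write_thresholds_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_thresholds_csv
#' @export
read_thresholds_csv <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant", "task", "texture_type", "waveform",
              "frequency_cpi", "threshold")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    texmod_error("texmod_invalid_argument", sprintf(
      "threshold table is missing column(s): %s",
      paste(missing, collapse = ", ")))
  }
  records
}
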