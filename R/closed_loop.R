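# Semi-automated programming loop: acquire a response map at the current
# setting, classify it; if non-optimal, predict the optimal parameters from
# the latent features, snap the contact to the lead, and re-acquire -
# terminating when a setting is classified optimal or the iteration budget is
# exhausted. Here the "patient" is the synthetic simulator; in the intended
# clinical workflow the confirmation point after each classification is where
# the attending clinician sets the parameters.

#' Safety bounds for proposed settings
#'
#' @param voltage,frequency admissible `c(min, max)` ranges proposals are
#'   clipped to.
#' @export
setting_bounds <- function(voltage = c(0.5, 8), frequency = c(80, 160)) {
  stopifnot(diff(voltage) > 0, diff(frequency) > 0)
  list(voltage = voltage, frequency = frequency)
}

#' Propose the next stimulation setting from latent features
#'
#' Runs the fold-ensemble regressors, clips voltage and frequency to the
#' safety bounds, and snaps the predicted contact location to the nearest
#' lead centroid (Euclidean distance; ties go to the lower-index, deepest
#' contact). Pulse width is carried over unchanged.
#'
#' @param latent 1 x d latent feature matrix of the current map.
#' @param models a `folded_models` object with trained regressors.
#' @param grid contact centroid matrix (rows ordered along the lead).
#' @param bounds a [setting_bounds()].
#' @param pulse_width pulse width (microseconds) carried over.
#' @return a [stim_setting()] (with the prediction in
#'   `attr(, "raw_prediction")`).
#' @export
propose_next_setting <- function(latent, models, grid,
                                 bounds = setting_bounds(),
                                 pulse_width = 60) {
  pred <- ensemble_predictions(models, latent)[1, ]
  v <- min(max(pred["voltage"], bounds$voltage[1]), bounds$voltage[2])
  f <- min(max(pred["frequency"], bounds$frequency[1]), bounds$frequency[2])
  d2 <- colSums((t(grid) - pred[c("x", "y", "z")])^2)
  contact <- grid[which.min(d2), ]
  out <- stim_setting(v, f, pulse_width, contact, is_optimal = FALSE,
                      freq_band = bounds$frequency)
  attr(out, "raw_prediction") <- pred
  out
}

#' Patient simulator for the closed loop
#'
#' Wraps a synthetic patient as a map-rendering oracle: given any admissible
#' setting it returns the (noisy) response map, deterministically under the
#' stored seed. The default initial setting is a mid-range sub-therapeutic
#' probe at the planned (optimal) contact with a standard 130 Hz frequency -
#' the synthetic analogue of a clinician's starting parameters.
#'
#' @param patient a patient from [sample_cohort()].
#' @param spec the matching [cohort_spec()].
#' @param noise_sd map noise level.
#' @param seed base seed; iteration i renders with `seed + i`.
#' @return list of class `patient_simulator` with `render(setting, i)`,
#'   `initial_setting`, `contact_grid`, and the hidden `patient`.
#' @export
make_patient_simulator <- function(patient, spec, noise_sd = spec$noise_sd,
                                   seed = 1) {
  init <- stim_setting(
    voltage = mean(spec$sub_range) * patient$optimal$voltage,
    frequency = 130, pulse_width = spec$pulse_width,
    contact = patient$optimal$contact, is_optimal = FALSE,
    freq_band = spec$freq_band)
  structure(list(
    render = function(setting, i = 0) {
      render_response_map(patient, setting, spec, noise_sd = noise_sd,
                          seed = seed + i)
    },
    initial_setting = init,
    contact_grid = patient$contact_grid,
    patient = patient),
    class = "patient_simulator")
}

#' Run the closed-loop parameter optimization against a simulator
#'
#' Iterates render -> preprocess -> encode -> classify; a classification
#' probability at or above the threshold terminates with outcome
#' `"optimal-found"`, otherwise the regressors propose the next setting. The
#' iteration budget is enforced unconditionally (`"budget-exhausted"`).
#'
#' @param simulator a [make_patient_simulator()] (any list with `render`,
#'   `initial_setting`, `contact_grid`).
#' @param models a `folded_models` object (autoencoder + heads).
#' @param max_iterations hard iteration budget.
#' @param threshold classifier decision threshold.
#' @param bounds a [setting_bounds()].
#' @param initial_setting override of the simulator's initial setting.
#' @param classify_fn,propose_fn overrides for the classifier / proposer
#'   (used to force degenerate traces in tests); signatures
#'   `classify_fn(latent)` -> probability and
#'   `propose_fn(latent, models, grid, bounds, pulse_width)` -> setting.
#' @return list of class `loop_trace`: one entry per iteration with the
#'   setting, classifier probability, proposed next setting, and outcome.
#' @export
run_loop <- function(simulator, models, max_iterations = 5, threshold = 0.5,
                     bounds = setting_bounds(), initial_setting = NULL,
                     classify_fn = NULL, propose_fn = propose_next_setting) {
  stopifnot(max_iterations >= 1)
  target_shape <- models$ae$config$input_shape
  if (is.null(classify_fn)) {
    classify_fn <- function(latent) ensemble_probability(models, latent)
  }
  setting <- initial_setting %||% simulator$initial_setting
  states <- list()
  for (i in seq_len(max_iterations)) {
    map <- simulator$render(setting, i)
    vol <- preprocess_for_ae(map, target_shape)
    latent <- ae_encode(models$ae, vol)
    prob <- classify_fn(latent)
    state <- list(iteration = i, setting = setting, probability = prob,
                  terminated = FALSE, outcome = NA_character_,
                  proposed = NULL)
    if (prob >= threshold) {
      state$terminated <- TRUE
      state$outcome <- "optimal-found"
      states[[i]] <- state
      break
    }
    if (i == max_iterations) {
      state$terminated <- TRUE
      state$outcome <- "budget-exhausted"
      states[[i]] <- state
      break
    }
    setting <- propose_fn(latent, models, simulator$contact_grid, bounds,
                          setting$pulse_width)
    state$proposed <- setting
    states[[i]] <- state
  }
  structure(states, class = "loop_trace")
}

#' @export
print.loop_trace <- function(x, ...) {
  for (s in x) {
    cat(sprintf("iter %d: %.2f V / %.0f Hz @ (%.1f, %.1f, %.1f) mm  p=%.3f%s\n",
                s$iteration, s$setting$voltage, s$setting$frequency,
                s$setting$contact[1], s$setting$contact[2],
                s$setting$contact[3], s$probability,
                if (s$terminated) paste0("  -> ", s$outcome) else ""))
  }
  invisible(x)
}

#' Outcome of a loop trace
#' @param trace a `loop_trace`.
#' @return `"optimal-found"` or `"budget-exhausted"`.
#' @export
loop_outcome <- function(trace) trace[[length(trace)]]$outcome

#' Closed-loop success rate over a set of held-out simulated patients
#'
#' @param patients list of patients (e.g. a fresh [sample_cohort()]).
#' @param spec their [cohort_spec()].
#' @param models trained `folded_models`.
#' @param max_iterations,threshold loop settings.
#' @param seed base seed; patient j simulates with `seed + 100 * j`.
#' @return list with `success_rate`, per-patient `outcomes` and `iterations`.
#' @export
closed_loop_experiment <- function(patients, spec, models,
                                   max_iterations = 5, threshold = 0.5,
                                   seed = 1) {
  res <- lapply(seq_along(patients), function(j) {
    sim <- make_patient_simulator(patients[[j]], spec, seed = seed + 100 * j)
    trace <- run_loop(sim, models, max_iterations, threshold)
    list(outcome = loop_outcome(trace), iterations = length(trace))
  })
  outcomes <- vapply(res, `[[`, "", "outcome")
  list(success_rate = mean(outcomes == "optimal-found"),
       outcomes = outcomes,
       iterations = vapply(res, `[[`, 0L, "iterations"))
}
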