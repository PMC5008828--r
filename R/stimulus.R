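# Calcium pulse-train and dopamine transient generator.
#
# All downstream analyses are driven from these synthetic inputs; there is no
# external data dependency. Conventions: the "start time" of an input is the
# start of its first pulse, the input interval is
# delta_t = t_dopamine - t_calcium (start-to-start; positive = dopamine after
# calcium), and the inter-trial interval (ITI) is measured calcium-onset to
# calcium-onset.

#' Calcium pulse train
#'
#' Ten glutamate-triggered calcium pulses at 10 Hz by default, each a
#' difference of two exponentials; the per-pulse amplitude is auto-scaled so
#' the summed train peaks at `peak` uM over the basal level. Rise/decay time
#' constants emulate fast NMDAR-type calcium transients and are configurable.
#'
#' @param n_pulses Number of pulses (>= 1).
#' @param frequency Pulse rate, Hz.
#' @param peak Maximum of the summed train, uM.
#' @param basal Basal intracellular calcium, uM (0.060 = 60 nM).
#' @param rise_tau,decay_tau Per-pulse rise and decay time constants, s.
#' @return A `calcium_train` object.
#' @export
calcium_train <- function(n_pulses = 10, frequency = 10, peak = 5,
                          basal = 0.060, rise_tau = 0.005, decay_tau = 0.030) {
  stopifnot(n_pulses >= 1, frequency > 0, peak > basal, basal >= 0,
            rise_tau > 0, decay_tau > rise_tau)
  tr <- structure(list(n_pulses = as.integer(n_pulses), frequency = frequency,
                       peak = peak, basal = basal, rise_tau = rise_tau,
                       decay_tau = decay_tau, pulse_amp = 1),
                  class = "calcium_train")
  # scale per-pulse amplitude so the summed train tops out at `peak`
  tg <- seq(0, n_pulses / frequency + 10 * decay_tau, by = rise_tau / 5)
  raw <- .train_shape(tr, tg)
  tr$pulse_amp <- (peak - basal) / max(raw)
  tr
}

# internal: summed unscaled pulse shape, onset at t = 0
.train_shape <- function(tr, t) {
  out <- numeric(length(t))
  for (k in seq_len(tr$n_pulses)) {
    tk <- t - (k - 1) / tr$frequency
    on <- tk > 0
    out[on] <- out[on] + (exp(-tk[on] / tr$decay_tau) - exp(-tk[on] / tr$rise_tau))
  }
  out
}

#' Dopamine transient
#'
#' A 1.5 uM, 1.0 s dopamine transient over a 20 nM basal by default: a plateau
#' with fast exponential edges (instantaneous square edges would create
#' integrator discontinuity artifacts).
#'
#' @param amplitude Peak dopamine, uM.
#' @param duration Plateau duration, s.
#' @param basal Basal dopamine, uM.
#' @param edge_tau Edge time constant, s.
#' @return A `dopamine_transient` object.
#' @export
dopamine_transient <- function(amplitude = 1.5, duration = 1.0,
                               basal = 0.020, edge_tau = 0.010) {
  stopifnot(amplitude >= 0, basal >= 0, duration > 0, edge_tau > 0)
  # amplitudes at or below basal yield a flat trace (sub-threshold rows of
  # the input-strength grids)
  structure(list(amplitude = amplitude, duration = duration, basal = basal,
                 edge_tau = edge_tau),
            class = "dopamine_transient")
}

#' Trial schedule
#'
#' @param n_trials Number of (calcium, dopamine) trials.
#' @param iti Inter-trial interval, s, calcium-onset to calcium-onset
#'   (required > 0 when `n_trials > 1`).
#' @param delta_t Input interval per trial, s: `t_dopamine - t_calcium`
#'   (recycled across trials). Positive = dopamine follows calcium.
#' @return A `trial_schedule` object.
#' @export
trial_schedule <- function(n_trials = 1, iti = 100, delta_t = 1) {
  stopifnot(n_trials >= 1)
  if (n_trials > 1 && !(iti > 0)) stop("iti must be > 0 for n_trials > 1")
  structure(list(n_trials = as.integer(n_trials), iti = iti,
                 delta_t = rep_len(delta_t, n_trials)),
            class = "trial_schedule")
}

#' Stimulus protocol
#'
#' Combines a calcium train, an optional dopamine transient and a trial
#' schedule into the complete forcing protocol for [simulate()].
#'
#' @param calcium A [calcium_train()].
#' @param dopamine A [dopamine_transient()] or `NULL` (calcium-alone protocol;
#'   dopamine trace stays at the basal level given by `dopamine_basal`).
#' @param schedule A [trial_schedule()].
#' @param t_calcium Onset (s) of the first trial's calcium train.
#' @param total_duration Optional protocol duration used for validation.
#' @param dopamine_basal Basal dopamine used when `dopamine` is `NULL`, uM.
#' @return A `stimulus_protocol` object.
#' @export
stimulus_protocol <- function(calcium = calcium_train(),
                              dopamine = dopamine_transient(),
                              schedule = trial_schedule(),
                              t_calcium = 20, total_duration = NULL,
                              dopamine_basal = 0.020) {
  stopifnot(inherits(calcium, "calcium_train"),
            is.null(dopamine) || inherits(dopamine, "dopamine_transient"),
            inherits(schedule, "trial_schedule"))
  train_len <- calcium$n_pulses / calcium$frequency
  if (schedule$n_trials > 1) {
    span <- train_len + max(abs(schedule$delta_t)) +
      if (is.null(dopamine)) 0 else dopamine$duration
    if (schedule$iti <= span)
      warning("trials overlap: iti = ", schedule$iti, " s <= trial span ",
              signif(span, 3), " s")
  }
  structure(list(calcium = calcium, dopamine = dopamine, schedule = schedule,
                 t_calcium = t_calcium, total_duration = total_duration,
                 dopamine_basal = if (is.null(dopamine)) dopamine_basal
                                  else dopamine$basal),
            class = "stimulus_protocol")
}

#' Per-trial input onsets
#'
#' @param protocol A [stimulus_protocol()].
#' @return data.frame with `trial`, `t_calcium`, `t_dopamine` (NA if no
#'   dopamine input).
#' @export
trial_onsets <- function(protocol) {
  s <- protocol$schedule
  tca <- protocol$t_calcium + (seq_len(s$n_trials) - 1) * s$iti
  tda <- if (is.null(protocol$dopamine)) rep(NA_real_, s$n_trials)
         else tca + s$delta_t
  data.frame(trial = seq_len(s$n_trials), t_calcium = tca, t_dopamine = tda)
}

#' Evaluate the input traces on a time grid
#'
#' @param protocol A [stimulus_protocol()].
#' @param grid Numeric time grid (s), covering all trial onsets.
#' @return List with `calcium` and `dopamine` concentration vectors (uM).
#' @export
build_traces <- function(protocol, grid) {
  on <- trial_onsets(protocol)
  if (max(grid) < max(on$t_calcium, on$t_dopamine, na.rm = TRUE))
    stop("time grid too short: does not cover all trial onsets")
  ca <- rep(protocol$calcium$basal, length(grid))
  for (t0 in on$t_calcium)
    ca <- ca + protocol$calcium$pulse_amp * .train_shape(protocol$calcium, grid - t0)
  da <- rep(protocol$dopamine_basal, length(grid))
  if (!is.null(protocol$dopamine)) {
    d <- protocol$dopamine
    for (t0 in on$t_dopamine) {
      tk <- grid - t0
      rise <- tk >= 0 & tk <= d$duration
      fall <- tk > d$duration
      h <- max(d$amplitude - d$basal, 0)
      da[rise] <- da[rise] + h * (1 - exp(-tk[rise] / d$edge_tau))
      plateau_end <- h * (1 - exp(-d$duration / d$edge_tau))
      da[fall] <- da[fall] + plateau_end * exp(-(tk[fall] - d$duration) / d$edge_tau)
    }
  }
  list(calcium = ca, dopamine = da)
}

#' Re-space the calcium train at a new frequency
#'
#' Keeps the per-pulse shape and amplitude and the pulse count; only the pulse
#' spacing changes, so the summed peak may differ from the original through
#' pulse overlap.
#'
#' @param protocol A [stimulus_protocol()].
#' @param new_frequency New pulse rate, Hz (> 0).
#' @return A new `stimulus_protocol`.
#' @export
frequency_variant <- function(protocol, new_frequency) {
  stopifnot(new_frequency > 0)
  ca <- protocol$calcium
  ca$frequency <- new_frequency   # pulse_amp deliberately unchanged
  protocol$calcium <- ca
  protocol
}

#' Constant basal-input protocol
#'
#' Holds calcium and dopamine at their basal levels; used for steady-state
#' location and as the pre-stimulus condition.
#'
#' @param ca_basal,da_basal Basal levels, uM.
#' @return A `stimulus_protocol` with no pulses.
#' @export
basal_protocol <- function(ca_basal = 0.060, da_basal = 0.020) {
  p <- stimulus_protocol(
    calcium = calcium_train(basal = ca_basal, peak = ca_basal + 1e-12 + 1),
    dopamine = NULL, schedule = trial_schedule(1),
    t_calcium = 0, dopamine_basal = da_basal)
  p$calcium$pulse_amp <- 0   # no pulse: flat basal trace
  p
}

# internal: solver sampling times -- dense across pulse structure, coarse
# elsewhere (forcings are linearly interpolated between these points)
sampling_times <- function(protocol, t_end) {
  on <- trial_onsets(protocol)
  dense <- numeric(0)
  if (protocol$calcium$pulse_amp > 0) {
    span <- protocol$calcium$n_pulses / protocol$calcium$frequency +
      12 * protocol$calcium$decay_tau
    for (t0 in on$t_calcium)
      dense <- c(dense, seq(t0, t0 + span, by = 0.001))
  }
  if (!is.null(protocol$dopamine)) {
    d <- protocol$dopamine
    for (t0 in on$t_dopamine)
      dense <- c(dense, seq(t0, t0 + d$duration + 12 * d$edge_tau, by = 0.001))
  }
  tt <- sort(unique(c(0, t_end, seq(0, t_end, by = 0.05), dense)))
  tt[tt >= 0 & tt <= t_end]
}
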