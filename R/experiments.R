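# In-silico experiment suite: delta-t response curves, mutant comparisons,
# CaMKII amplitude analysis, inter-trial refractoriness, input-strength
# robustness grids, and one-at-a-time parameter sensitivity.

#' Activation area of an observable
#'
#' Trapezoidal integral of the observable's excursion above its pre-stimulus
#' basal over a time window, floored at zero pointwise (uM s).
#'
#' @param result A [simulate()] result.
#' @param model The model simulated.
#' @param observable_name Observable (see [striatal_observables()]).
#' @param window Numeric `c(start, end)` in seconds, within the simulated span.
#' @param basal Basal level to subtract; default the observable's value at the
#'   window start... use the pre-stimulus value at `t = 0` of the trace.
#' @return Area in uM s.
#' @export
activation_area <- function(result, model, observable_name, window,
                            basal = NULL) {
  y <- observable(result, model, observable_name)
  t <- result$time
  if (window[1] < t[1] - 1e-9 || window[2] > t[length(t)] + 1e-9)
    stop("window outside the simulated span")
  if (is.null(basal)) basal <- y[1]
  sel <- t >= window[1] & t <= window[2]
  yy <- pmax(y[sel] - basal, 0)
  tt <- t[sel]
  sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2)
}

# internal: one standard single-trial run from the cached basal state
run_trial <- function(model, delta_t, window_len = 100,
                      dopamine_amplitude = 1.5, calcium_frequency = 10,
                      max_step = 0.01, grid_dt = 0.02) {
  t_ca <- 20
  pr <- standard_protocol(delta_t = delta_t, t_calcium = t_ca,
                          dopamine_amplitude = dopamine_amplitude,
                          calcium_frequency = calcium_frequency)
  lead <- if (!is.na(delta_t) && delta_t < 0) -delta_t else 0
  t_end <- t_ca + window_len + lead + 5
  r <- simulate(model, pr, t_end = t_end, max_step = max_step, grid_dt = grid_dt,
                init = model_basal(model))
  list(result = r, window = c(t_ca, t_ca + window_len))
}

#' Input-interval (delta-t) response curve
#'
#' For each delta-t, simulates one standard trial and integrates the
#' pSubstrate activation area; areas are normalized to the calcium-alone
#' baseline (the same calcium train with no dopamine), so 1 means "no
#' dopamine effect".
#'
#' @param variant Variant name or [variant_spec()].
#' @param delta_t_values Numeric vector of input intervals (s).
#' @param window_len Integration window length after calcium onset (s).
#' @param dopamine_amplitude Dopamine peak (uM).
#' @param calcium_frequency Calcium pulse rate (Hz).
#' @param model Optional pre-built model (overrides `variant`).
#' @param max_step Solver step cap (s).
#' @return A `dt_response_curve`: data.frame (`delta_t`, `area`,
#'   `normalized_area`) with the baseline area in attribute `baseline_area`.
#' @export
dt_sweep <- function(variant = "WT", delta_t_values = seq(-6, 8, by = 0.5),
                     window_len = 100, dopamine_amplitude = 1.5,
                     calcium_frequency = 10, model = NULL, max_step = 0.01) {
  if (is.null(model)) model <- build_model(variant)
  base <- run_trial(model, NA, window_len, dopamine_amplitude, calcium_frequency,
                    max_step = max_step)
  base_area <- activation_area(base$result, model, "pSubstrate", base$window)
  areas <- vapply(delta_t_values, function(dt) {
    tr <- run_trial(model, dt, window_len, dopamine_amplitude, calcium_frequency,
                    max_step = max_step)
    activation_area(tr$result, model, "pSubstrate", tr$window)
  }, 0)
  out <- data.frame(delta_t = delta_t_values, area = areas,
                    normalized_area = areas / base_area)
  attr(out, "baseline_area") <- base_area
  attr(out, "variant") <- attr(model, "variant")
  class(out) <- c("dt_response_curve", "data.frame")
  out
}

#' CaMKII amplitude versus delta-t
#'
#' Maximum over time of total active CaMKII per delta-t, normalized to the
#' amplitude with calcium alone.
#'
#' @inheritParams dt_sweep
#' @param variants Character vector of variant names.
#' @return data.frame (`variant`, `delta_t`, `normalized_amplitude`).
#' @export
camkii_amplitude_curve <- function(variants = c("WT", "NO_ARPP21"),
                                   delta_t_values = seq(-4, 4, by = 1),
                                   window_len = 40, max_step = 0.01) {
  out <- list()
  for (v in variants) {
    model <- build_model(v)
    base <- run_trial(model, NA, window_len, max_step = max_step)
    amp0 <- max(observable(base$result, model, "active_CaMKII"))
    amps <- vapply(delta_t_values, function(dt) {
      tr <- run_trial(model, dt, window_len, max_step = max_step)
      max(observable(tr$result, model, "active_CaMKII"))
    }, 0)
    out[[v]] <- data.frame(variant = v, delta_t = delta_t_values,
                           normalized_amplitude = amps / amp0)
  }
  do.call(rbind, out)
}

#' Two-trial refractoriness curve
#'
#' REF(t) = 1 - (second-trial activation area at ITI = t) /
#' (second-trial activation area at ITI = reference), with the second-trial
#' window anchored at the second trial's calcium onset. Trials at the
#' reference ITI (100 s) are treated as fully separated, so REF(reference)
#' is 0 by construction.
#'
#' @param variant Variant name or [variant_spec()].
#' @param iti_values Inter-trial intervals to probe (s).
#' @param reference_iti Reference ITI (s).
#' @param delta_t Per-trial input interval (s).
#' @param window_len Per-trial integration window (s), capped at the ITI.
#' @param max_step Solver step cap (s).
#' @return A data.frame (`iti`, `area2`, `ref`) with `reference_area`
#'   attribute.
#' @export
refractoriness <- function(variant = "WT", iti_values = c(5, 10, 20, 30, 50, 100),
                           reference_iti = 100, delta_t = 1, window_len = 100,
                           max_step = 0.01) {
  model <- if (inherits(variant, "network_model")) variant else build_model(variant)
  itis <- sort(unique(c(iti_values, reference_iti)))
  area2 <- vapply(itis, function(iti) {
    second_trial_area(model, iti, delta_t, window_len, max_step)
  }, 0)
  ref_area <- area2[itis == reference_iti]
  if (ref_area <= 0) stop("zero reference-trial activation area")
  out <- data.frame(iti = itis, area2 = area2, ref = 1 - area2 / ref_area)
  out <- out[out$iti %in% iti_values, ]
  attr(out, "reference_area") <- ref_area
  attr(out, "variant") <- attr(model, "variant")
  out
}

second_trial_area <- function(model, iti, delta_t = 1, window_len = 100,
                              max_step = 0.01) {
  t_ca <- 20
  t2 <- t_ca + iti
  t_end <- t2 + window_len + 5
  pr2 <- stimulus_protocol(calcium = calcium_train(),
                           dopamine = dopamine_transient(),
                           schedule = trial_schedule(2, iti = iti, delta_t = delta_t),
                           t_calcium = t_ca)
  pr1 <- stimulus_protocol(calcium = calcium_train(),
                           dopamine = dopamine_transient(),
                           schedule = trial_schedule(1, delta_t = delta_t),
                           t_calcium = t_ca)
  b <- model_basal(model)
  r2 <- simulate(model, pr2, t_end = t_end, max_step = max_step, grid_dt = 0.02,
                 init = b)
  r1 <- simulate(model, pr1, t_end = t_end, max_step = max_step, grid_dt = 0.02,
                 init = b)
  # the second trial's own activation: excess of the two-trial trace over the
  # matching single-trial trace, so the decaying first-trial response neither
  # bleeds into nor masks the second-trial window
  y <- observable(r2, model, "pSubstrate") - observable(r1, model, "pSubstrate")
  sel <- r2$time >= t2 & r2$time <= t2 + window_len
  yy <- pmax(y[sel], 0); tt <- r2$time[sel]
  sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2)
}

#' Multi-trial substrate responses
#'
#' Simulates `n_trials` identical (calcium + dopamine) trials and integrates
#' the pSubstrate area per trial (window = one ITI, anchored at each trial's
#' calcium onset), normalized to trial 1.
#'
#' @param variant Variant name or [variant_spec()].
#' @param n_trials Number of trials (>= 2).
#' @param iti Inter-trial interval (s).
#' @param delta_t Per-trial input interval (s).
#' @param tail_len Extra integration time after the last trial (s).
#' @param max_step Solver step cap (s).
#' @return data.frame (`trial`, `area`, `normalized_area`).
#' @export
multi_trial <- function(variant = "WT", n_trials = 10, iti = 10, delta_t = 1,
                        tail_len = 60, max_step = 0.01) {
  stopifnot(n_trials >= 2)
  model <- if (inherits(variant, "network_model")) variant else build_model(variant)
  t_ca <- 20
  pr <- stimulus_protocol(calcium = calcium_train(),
                          dopamine = dopamine_transient(),
                          schedule = trial_schedule(n_trials, iti = iti,
                                                    delta_t = delta_t),
                          t_calcium = t_ca)
  t_end <- t_ca + (n_trials - 1) * iti + tail_len
  b <- model_basal(model)
  # counterfactual ladder: trial k's own activation is the excess of the
  # k-trial trace over the (k-1)-trial trace in trial k's window
  traces <- lapply(0:n_trials, function(k) {
    if (k == 0) return(NULL)
    prk <- stimulus_protocol(calcium = calcium_train(),
                             dopamine = dopamine_transient(),
                             schedule = trial_schedule(k, iti = iti,
                                                       delta_t = delta_t),
                             t_calcium = t_ca)
    r <- simulate(model, prk, t_end = t_end, max_step = max_step,
                  grid_dt = 0.02, init = b)
    observable(r, model, "pSubstrate")
  })
  tt_grid <- seq(0, t_end, by = 0.02)
  areas <- vapply(seq_len(n_trials), function(k) {
    t0 <- t_ca + (k - 1) * iti
    t1 <- min(t0 + iti, t_end)
    prev <- if (k == 1) traces[[2]][1] else traces[[k]]   # k=1: flat basal
    y <- traces[[k + 1]] - prev
    sel <- tt_grid >= t0 & tt_grid <= t1
    yy <- pmax(y[sel], 0); tw <- tt_grid[sel]
    sum(diff(tw) * (yy[-1] + yy[-length(yy)]) / 2)
  }, 0)
  data.frame(trial = seq_len(n_trials), area = areas,
             normalized_area = areas / areas[1])
}

#' Input-strength robustness grid
#'
#' Full-factorial delta-t sweeps across dopamine amplitudes or calcium
#' frequencies. Every cell is normalized to its own calcium-alone baseline
#' (same calcium input, no dopamine).
#'
#' @param axis `"dopamine_amplitude"` (uM values) or `"calcium_frequency"`
#'   (Hz values).
#' @param values Axis values (positive).
#' @param delta_t_values Input intervals (s).
#' @param variant Variant name.
#' @param window_len Integration window (s).
#' @param max_step Solver step cap (s).
#' @return data.frame (`axis_value`, `delta_t`, `normalized_area`).
#' @export
robustness_grid <- function(axis = c("dopamine_amplitude", "calcium_frequency"),
                            values = NULL, delta_t_values = c(-4, -2, -1, 0, 1, 2, 4),
                            variant = "WT", window_len = 100, max_step = 0.01) {
  axis <- match.arg(axis)
  if (is.null(values))
    values <- if (axis == "dopamine_amplitude")
      c(0.01, 0.03, 0.1, 0.3, 1, 1.5, 3) else c(5, 10, 20, 40)
  stopifnot(all(values > 0))
  model <- build_model(variant)
  out <- list()
  for (v in values) {
    amp <- if (axis == "dopamine_amplitude") v else 1.5
    freq <- if (axis == "calcium_frequency") v else 10
    sw <- dt_sweep(model = model, delta_t_values = delta_t_values,
                   window_len = window_len, dopamine_amplitude = amp,
                   calcium_frequency = freq, max_step = max_step)
    out[[length(out) + 1L]] <- data.frame(axis = axis, axis_value = v,
                                          delta_t = sw$delta_t,
                                          normalized_area = sw$normalized_area)
  }
  do.call(rbind, out)
}

#' One-at-a-time parameter sensitivity scan
#'
#' Perturbs each model parameter up and down by `perturbation` (fractional,
#' e.g. 0.2) or by a factor (`mode = "fold"`, e.g. 2), reruns the delta-t
#' sweep, and reports the fractional change of the normalized pSubstrate area
#' per delta-t, together with per-parameter means over the `delta_t >= 0` and
#' `delta_t < 0` regimes and ranked top-k tables.
#'
#' @param perturbation Fractional perturbation (0.2) or fold factor (2).
#' @param mode `"fraction"`: multipliers `1 +/- perturbation`; `"fold"`:
#'   multipliers `perturbation` and `1/perturbation`.
#' @param delta_t_values Input intervals (s).
#' @param variant Variant name.
#' @param parameters Optional subset of parameter names to scan (default all).
#' @param window_len Integration window (s).
#' @param max_step Solver step cap (s); the scan default is coarser than the
#'   single-run default because only area ratios between identically capped
#'   runs are compared.
#' @param top_k Size of the ranked lists.
#' @return List with `changes` (long data.frame: parameter, direction,
#'   delta_t, fractional_change), `summary` (per parameter: mean_pos,
#'   mean_neg, score_pos, score_neg), `top_pos`, `top_neg` (ranked
#'   parameter names), `base` (the unperturbed sweep).
#' @export
sensitivity_scan <- function(perturbation = 0.2, mode = c("fraction", "fold"),
                             delta_t_values = c(-2, -1, 1, 2),
                             variant = "WT", parameters = NULL,
                             window_len = 70, max_step = 0.1, top_k = 15) {
  mode <- match.arg(mode)
  model <- build_model(variant)
  mult <- if (mode == "fraction") c(up = 1 + perturbation, down = 1 - perturbation)
          else c(up = perturbation, down = 1 / perturbation)
  if (is.null(parameters)) parameters <- names(model_parameters(model))
  base <- dt_sweep(model = model, delta_t_values = delta_t_values,
                   window_len = window_len, max_step = max_step)
  base_b <- model_basal(model)
  rows <- list()
  for (pn in parameters) {
    for (dir in names(mult)) {
      sw <- tryCatch({
        mp <- apply_scaling(model, setNames(mult[[dir]], pn))
        # warm-start the perturbed basal state from the unperturbed one --
        # but only for rate perturbations: a total-amount (TA_) perturbation
        # changes a conserved quantity, which a warm start would undo
        key <- model_key(mp)
        if (is.null(.msn_cache[[key]]) && !startsWith(pn, "TA_")) {
          ssp <- steady_state(mp, basal_protocol(), init = base_b,
                              tol = 1e-7, t_max = 3000)
          .msn_cache[[key]] <- ssp$state
        }
        dt_sweep(model = mp, delta_t_values = delta_t_values,
                 window_len = window_len, max_step = max_step)
      }, error = function(e) NULL)
      fc <- if (is.null(sw)) rep(NA_real_, length(delta_t_values))
            else (sw$normalized_area - base$normalized_area) / base$normalized_area
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = pn, direction = dir, delta_t = delta_t_values,
        fractional_change = fc)
    }
  }
  changes <- do.call(rbind, rows)
  agg <- function(dir, sel) {
    d <- changes[changes$direction == dir & sel(changes$delta_t), ]
    tapply(d$fractional_change, d$parameter, mean, na.rm = TRUE)
  }
  pos_up <- agg("up", function(x) x >= 0); pos_dn <- agg("down", function(x) x >= 0)
  neg_up <- agg("up", function(x) x < 0);  neg_dn <- agg("down", function(x) x < 0)
  pn <- names(pos_up)
  summary <- data.frame(
    parameter = pn,
    mean_pos_up = as.vector(pos_up), mean_pos_down = as.vector(pos_dn[pn]),
    mean_neg_up = as.vector(neg_up[pn]), mean_neg_down = as.vector(neg_dn[pn]))
  summary$score_pos <- pmax(abs(summary$mean_pos_up), abs(summary$mean_pos_down))
  summary$score_neg <- pmax(abs(summary$mean_neg_up), abs(summary$mean_neg_down))
  list(changes = changes, summary = summary,
       top_pos = summary$parameter[order(-summary$score_pos)][seq_len(min(top_k, nrow(summary)))],
       top_neg = summary$parameter[order(-summary$score_neg)][seq_len(min(top_k, nrow(summary)))],
       base = base)
}

#' Write a trajectory to a tidy TSV
#'
#' Long format (`time`, `species`, `value`) with a `#`-prefixed metadata
#' header recording the variant and solver settings.
#'
#' @param result A [simulate()] result.
#' @param file Output path.
#' @param species Optional species subset.
#' @param meta Named character vector of extra metadata lines.
#' @export
write_trajectory <- function(result, file, species = NULL, meta = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# msnsig trajectory; n_time=", length(result$time)), con)
  for (nm in names(meta)) writeLines(paste0("# ", nm, "=", meta[[nm]]), con)
  df <- as.data.frame(result, species = species)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
}
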