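# Molecular-phenotype harness: executable encodings of the experimental
# constraints used to calibrate the striatal model (basal levels, slice
# pharmacology fold-changes, kinetic time-series parameterizations, dose
# responses), with log2 simulated-vs-experimental divergence scoring.

#' Fit a monoexponential to a trace
#'
#' Least-squares fit of `y = a * exp(-k t) + c`. For `direction = "decay"`
#' the fit starts at the trace maximum; for `"rise"` at the minimum (the
#' fitted `a` is then negative). Five log-spaced rate starts guard against
#' local minima; the best fit is returned.
#'
#' @param time,value Numeric vectors (s, uM or any fixed unit).
#' @param direction `"decay"` or `"rise"`.
#' @return List with `k` (1/s), `a`, `c`, and `residual` (RMS).
#' @export
fit_monoexponential <- function(time, value, direction = c("decay", "rise")) {
  direction <- match.arg(direction)
  stopifnot(length(time) == length(value), length(time) >= 5)
  i0 <- if (direction == "decay") which.max(value) else which.min(value)
  if (i0 > length(value) - 4)
    stop("trace does not ", if (direction == "decay") "decay" else "rise",
         ": extremum at the end of the trace")
  tt <- time[i0:length(time)] - time[i0]
  yy <- value[i0:length(value)]
  span <- yy[1] - yy[length(yy)]
  if (direction == "decay" && span <= 0) stop("trace does not decay")
  if (direction == "rise" && span >= 0) stop("trace does not rise")
  best <- NULL
  for (k0 in exp(seq(log(0.02), log(50), length.out = 5)) / max(tt)) {
    fit <- tryCatch(minpack.lm::nlsLM(
      yy ~ a * exp(-k * tt) + c,
      start = list(a = span, k = k0 * max(tt), c = yy[length(yy)]),
      lower = c(-Inf, 1e-8, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)), error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("monoexponential fit failed")
  co <- coef(best$fit)
  list(k = unname(co["k"]), a = unname(co["a"]), c = unname(co["c"]),
       residual = sqrt(best$rss / length(yy)))
}

#' Fit a difference of two exponentials
#'
#' Least-squares fit of `y = A (exp(-k1 t) - exp(-k2 t)) + c` with `k2 > k1`
#' (rise-then-decay). Fails on traces that are not rise-then-decay or when
#' the two rates collapse onto each other.
#'
#' @param time,value Numeric vectors; `time` measured from the stimulus onset.
#' @return List with `k1`, `k2` (1/s, `k2 > k1`), `A`, `c`, `residual`.
#' @export
fit_diff_exponentials <- function(time, value) {
  stopifnot(length(time) == length(value), length(time) >= 6)
  im <- which.max(value)
  if (im <= 2 || im > length(value) - 2 || im > 0.5 * length(value))
    stop("trace is not rise-then-decay")
  t0 <- time - time[1]
  best <- NULL
  tpk <- t0[im]
  for (f in c(0.2, 0.5, 1, 2, 5)) {
    k2s <- 2 / tpk * f; k1s <- k2s / 6
    fit <- tryCatch(minpack.lm::nlsLM(
      value ~ A * (exp(-k1 * t0) - exp(-k2 * t0)) + c,
      start = list(A = max(value) - value[1], k1 = k1s, k2 = k2s, c = value[1]),
      lower = c(-Inf, 1e-8, 1e-8, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 300)), error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("difference-of-exponentials fit failed")
  co <- coef(best$fit)
  k <- sort(c(co[["k1"]], co[["k2"]]))
  if (abs(k[2] - k[1]) / k[2] < 1e-3)
    stop("degenerate fit: the two rate constants coincide")
  list(k1 = k[1], k2 = k[2], A = unname(co["A"]), c = unname(co["c"]),
       residual = sqrt(best$rss / length(value)))
}

#' Fit a Hill curve to a dose response
#'
#' Least-squares fit of `r = r_max d^h / (K^h + d^h)`.
#'
#' @param dose,response Numeric vectors (>= 5 doses spanning the half-maximal
#'   dose); the response must be monotone non-decreasing in dose.
#' @return List with `h` (Hill coefficient), `K` (half-maximal dose, same
#'   units as `dose`), `r_max`, `residual`.
#' @export
fit_hill <- function(dose, response) {
  stopifnot(length(dose) == length(response), length(dose) >= 5)
  o <- order(dose); dose <- dose[o]; response <- response[o]
  if (any(diff(response) < -0.02 * max(response)))
    stop("non-monotone dose response")
  best <- NULL
  Kg <- dose[which.min(abs(response - max(response) / 2))]
  for (h0 in c(0.5, 1, 1.5, 2, 3)) {
    fit <- tryCatch(minpack.lm::nlsLM(
      response ~ rmax * dose^h / (K^h + dose^h),
      start = list(rmax = max(response), h = h0, K = Kg),
      lower = c(1e-12, 0.1, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 300)), error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("Hill fit failed")
  co <- coef(best$fit)
  list(h = unname(co["h"]), K = unname(co["K"]), r_max = unname(co["rmax"]),
       residual = sqrt(best$rss / length(dose)))
}

# --- internal: model cache for basal states -------------------------------

.msn_cache <- new.env(parent = emptyenv())

model_key <- function(model) {
  ps <- vapply(model$reactions, function(r) r$kf + 3.17 * r$kr, 0)
  paste(attr(model, "variant"), nrow(model$species),
        format(sum(ps), digits = 15), format(sum(ps^2), digits = 15),
        format(sum(model$species$initial), digits = 15))
}

#' Basal steady state of a striatal model (cached)
#'
#' @param model A [build_model()] result.
#' @return Named concentration vector at the basal steady state (Ca 60 nM,
#'   DA 20 nM).
#' @export
model_basal <- function(model) {
  key <- model_key(model)
  if (!is.null(.msn_cache[[key]])) return(.msn_cache[[key]])
  ss <- steady_state(model, basal_protocol(), tol = 1e-7, t_max = 8000)
  if (!ss$converged && ss$residual > 1e-5)
    stop("basal steady state did not converge (residual ", signif(ss$residual, 2), ")")
  .msn_cache[[key]] <- ss$state
  ss$state
}

obs_value <- function(state, model, name) {
  sp <- striatal_observables(model)[[name]]
  if (!length(sp)) return(0)
  sum(state[sp])
}

# --- phenotype specifications ---------------------------------------------

#' The molecular-phenotype table
#'
#' One row per phenotypic variable: phenotype name, marker, target value (or
#' range), target type (`abs` uM, `fold` over basal, `rate` 1/s, `hill_h`,
#' `hill_K` uM), and the in-silico treatment that realizes it.
#'
#' @param with_arpp21 Include the ARPP-21 variables (dropped for the
#'   NO_ARPP21 model).
#' @return data.frame of phenotype specifications.
#' @export
phenotype_specs <- function(with_arpp21 = TRUE) {
  s <- read.csv(text = 'phenotype,variable,marker,type,target,target_hi,treatment
Basal,cAMP_basal,cAMP,abs_range,0.03,0.09,basal
Basal,pT34_basal,pDARPP32_T34,abs,0.4,NA,basal
Basal,pT75_basal,pDARPP32_T75,abs,12,NA,basal
Basal,pS55_basal,pARPP21_S55,abs,0.7,NA,basal
ReceptorGProtein,gprot_k,active_Golf,rate_range,10,100,gprotein_rise
SliceDA,pT34_sliceDA,pDARPP32_T34,fold,11,NA,slice_da
SliceDA,pT75_sliceDA,pDARPP32_T75,fold,0.5,NA,slice_da
SliceDA,pS55_sliceDA,pARPP21_S55,fold,7,NA,slice_da
SliceCa,pT34_sliceCa,pDARPP32_T34,fold,0.5,NA,slice_ca
SliceCa,pT75_sliceCa,pDARPP32_T75,fold,0.5,NA,slice_ca
SlicePKADynamics,cAMP_highDA,cAMP,abs,10,NA,slice_da
SlicePKADynamics,akar_k1,pAKAR,rate_k1,0.043,NA,da_transient
SlicePKADynamics,akar_k2,pAKAR,rate_k2,0.227,NA,da_transient
SlicePDE10Inhibition,pT34_pde10i,pDARPP32_T34,fold,2,NA,pde10_inhibition
PDEKinetics,pde_k,cAMP,rate,0.508,NA,pde_decay
CaMKIIDynamics,camkii_k,active_CaMKII,rate,0.166,NA,ca_train
DoseResponse,pka_hill_h,active_PKA,hill_h,1.4,NA,pka_dose
DoseResponse,pka_hill_K,active_PKA,hill_K,0.5278,NA,pka_dose
DoseResponse,cam_hill_h,available_CaMCa4,hill_h,1,NA,cam_dose
DoseResponse,cam_hill_K,available_CaMCa4,hill_K,6.29,NA,cam_dose
', stringsAsFactors = FALSE)
  if (!with_arpp21) s <- s[!s$variable %in% c("pS55_basal", "pS55_sliceDA"), ]
  s
}

# --- treatments -----------------------------------------------------------

# dopamine-only transient protocol (flat calcium at basal)
dopamine_only_protocol <- function(onset = 20, amplitude = 1.5, duration = 1) {
  p <- stimulus_protocol(
    calcium = calcium_train(), dopamine = dopamine_transient(amplitude, duration),
    schedule = trial_schedule(1, delta_t = 0), t_calcium = onset)
  p$calcium$pulse_amp <- 0
  p
}

#' Standard single-trial protocol
#'
#' The default experiment input: one 10-pulse 10 Hz calcium train (peak 5 uM)
#' with or without a 1.5 uM / 1 s dopamine transient at `delta_t` s after the
#' calcium onset.
#'
#' @param delta_t Input interval (s), `t_dopamine - t_calcium`; `NA` for
#'   calcium alone.
#' @param t_calcium Calcium onset (s).
#' @param dopamine_amplitude Dopamine peak, uM.
#' @param calcium_frequency Calcium pulse rate, Hz (pulse shape fixed at the
#'   10 Hz calibration, see [frequency_variant()]).
#' @return A [stimulus_protocol()].
#' @export
standard_protocol <- function(delta_t = 1, t_calcium = 20,
                              dopamine_amplitude = 1.5, calcium_frequency = 10) {
  dop <- if (is.na(delta_t)) NULL else dopamine_transient(amplitude = dopamine_amplitude)
  p <- stimulus_protocol(
    calcium = calcium_train(), dopamine = dop,
    schedule = trial_schedule(1, delta_t = if (is.na(delta_t)) 0 else delta_t),
    t_calcium = t_calcium)
  if (calcium_frequency != 10) p <- frequency_variant(p, calcium_frequency)
  p
}

run_treatment <- function(model, treatment, params = NULL) {
  basal <- model_basal(model)
  switch(treatment,
    basal = list(kind = "state", state = basal),
    slice_da = {
      r <- simulate(model, basal_protocol(da_basal = 10), t_end = 300,
                    max_step = 0.05, grid_dt = 0.5, init = basal)
      list(kind = "state", state = r$concentrations[nrow(r$concentrations), ])
    },
    slice_ca = {
      r <- simulate(model, basal_protocol(ca_basal = 1.0), t_end = 600,
                    max_step = 0.1, grid_dt = 1, init = basal)
      list(kind = "state", state = r$concentrations[nrow(r$concentrations), ])
    },
    pde10_inhibition = {
      m2 <- set_parameters(model, c(kcat_PDE10_cAMP = 0))
      r <- simulate(m2, basal_protocol(), t_end = 600, max_step = 0.1,
                    grid_dt = 1, init = basal)
      list(kind = "state", state = r$concentrations[nrow(r$concentrations), ])
    },
    gprotein_rise = {
      r <- simulate(model, basal_protocol(da_basal = 10), t_end = 1.5,
                    max_step = 0.002, grid_dt = 0.002, init = basal)
      list(kind = "trace", time = r$time, result = r)
    },
    da_transient = {
      pr <- dopamine_only_protocol(onset = 20)
      r <- simulate(model, pr, t_end = 140, max_step = 0.01, grid_dt = 0.02,
                    init = basal)
      list(kind = "trace", time = r$time, result = r, onset = 20)
    },
    pde_decay = {
      m2 <- set_parameters(model, c(kcat_AC5_basal = 0, kcat_AC5_Golf = 0))
      r <- simulate(m2, basal_protocol(), t_end = 15, max_step = 0.01,
                    grid_dt = 0.02, init = c(basal, c(cAMP = 50)))
      list(kind = "trace", time = r$time, result = r)
    },
    ca_train = {
      pr <- standard_protocol(delta_t = NA, t_calcium = 5)
      r <- simulate(model, pr, t_end = 40, max_step = 0.01, grid_dt = 0.02,
                    init = basal)
      list(kind = "trace", time = r$time, result = r)
    },
    stop("unknown treatment '", treatment, "'"))
}

# steady-state dose responses evaluated on isolated subnetworks ("protein +
# ligand" in vitro setting): PKA holoenzyme vs clamped cAMP, calmodulin
# loading vs clamped calcium.
pka_dose_response <- function(model, doses = NULL) {
  if (is.null(doses)) doses <- exp(seq(log(0.02), log(30), length.out = 12))
  rx <- model$reactions
  tot <- model$moieties$PKA$total
  sub <- network_model(
    list(species_def("cAMP", initial = 0, clamped = TRUE),
         species_def("PKA", initial = tot), species_def("PKAc2"),
         species_def("PKAc4"), species_def("PKAr1"), species_def("PKAr"),
         species_def("PKAc")),
    list(reaction("b1", c(PKA = 1, cAMP = 2), c(PKAc2 = 1),
                  rx$pka_camp1$kf, rx$pka_camp1$kr),
         reaction("b2", c(PKAc2 = 1, cAMP = 2), c(PKAc4 = 1),
                  rx$pka_camp2$kf, rx$pka_camp2$kr),
         reaction("rel1", c(PKAc4 = 1), c(PKAr1 = 1, PKAc = 1),
                  rx$pka_diss1$kf, rx$pka_diss1$kr),
         reaction("rel2", c(PKAr1 = 1), c(PKAr = 1, PKAc = 1),
                  rx$pka_diss2$kf, rx$pka_diss2$kr)))
  resp <- vapply(doses, function(d) {
    ss <- steady_state(sub, clamp = c(cAMP = d), tol = 1e-9, chunk = 300)
    unname(ss$state["PKAc"]) / (2 * tot)
  }, 0)
  list(dose = doses, response = resp)
}

cam_dose_response <- function(model, doses = NULL) {
  if (is.null(doses)) doses <- exp(seq(log(0.2), log(200), length.out = 12))
  rx <- model$reactions
  sub <- network_model(
    list(species_def("Ca", "input", 0, clamped = TRUE),
         species_def("CaM", initial = 10), species_def("CaMCa2"),
         species_def("CaMCa4")),
    list(reaction("s1", c(CaM = 1, Ca = 1), c(CaMCa2 = 1),
                  rx$cam_ca$kf, rx$cam_ca$kr),
         reaction("s2", c(CaMCa2 = 1, Ca = 1), c(CaMCa4 = 1),
                  rx$cam2_ca$kf, rx$cam2_ca$kr)))
  resp <- vapply(doses, function(d) {
    ss <- steady_state(sub, clamp = c(Ca = d), tol = 1e-9, chunk = 50)
    unname(ss$state["CaMCa4"] / 10)
  }, 0)
  list(dose = doses, response = resp)
}

#' Evaluate one phenotypic variable
#'
#' Runs the in-silico treatment for one row of [phenotype_specs()] and
#' returns the simulated value on the target's scale.
#'
#' @param model A striatal [build_model()] result.
#' @param spec One-row data.frame from [phenotype_specs()].
#' @return List with `simulated`, `experimental` (target, or range), `log2_ratio`,
#'   `band` (`"within30"`, `"within80"`, `"outside"`).
#' @export
evaluate_phenotype <- function(model, spec) {
  stopifnot(nrow(spec) == 1)
  basal <- model_basal(model)
  sim <- switch(spec$type,
    abs = , abs_range = , fold = {
      tr <- run_treatment(model, spec$treatment)
      v <- obs_value(tr$state, model, spec$marker)
      if (spec$type == "fold") v / obs_value(basal, model, spec$marker) else v
    },
    rate = , rate_range = {
      tr <- run_treatment(model, spec$treatment)
      y <- observable(tr$result, model, spec$marker)
      if (spec$treatment == "gprotein_rise")
        fit_monoexponential(tr$time, y, "rise")$k
      else
        fit_monoexponential(tr$time, y, "decay")$k
    },
    rate_k1 = , rate_k2 = {
      tr <- run_treatment(model, spec$treatment)
      sel <- tr$time >= tr$onset
      fit <- fit_diff_exponentials(tr$time[sel] - tr$onset,
                                   observable(tr$result, model, spec$marker)[sel])
      if (spec$type == "rate_k1") fit$k1 else fit$k2
    },
    hill_h = , hill_K = {
      dr <- if (spec$treatment == "pka_dose") pka_dose_response(model)
            else cam_dose_response(model)
      fit <- fit_hill(dr$dose, dr$response)
      if (spec$type == "hill_h") fit$h else fit$K
    },
    stop("unknown phenotype type ", spec$type))
  is_range <- spec$type %in% c("abs_range", "rate_range")
  if (is_range) {
    lo <- spec$target; hi <- spec$target_hi
    ratio <- if (sim < lo) sim / lo else if (sim > hi) sim / hi else 1
    expv <- (lo + hi) / 2
  } else {
    ratio <- sim / spec$target
    expv <- spec$target
  }
  l2 <- log2(ratio)
  band <- if (abs(l2) <= log2(1.3)) "within30"
          else if (abs(l2) <= log2(1.8)) "within80" else "outside"
  list(simulated = sim, experimental = expv, log2_ratio = l2, band = band)
}

#' Full phenotype divergence table
#'
#' Evaluates every phenotypic variable (skipping ARPP-21 rows for models
#' without ARPP-21) and classifies each simulated-vs-experimental divergence
#' into the +/-30% and +/-80% bands.
#'
#' @param model A striatal [build_model()] result.
#' @return data.frame with one row per variable: `phenotype`, `variable`,
#'   `simulated`, `experimental`, `log2_ratio`, `band`.
#' @export
divergence_table <- function(model) {
  with_a21 <- "A21" %in% model$species$name
  specs <- phenotype_specs(with_arpp21 = with_a21)
  out <- lapply(seq_len(nrow(specs)), function(i) {
    r <- evaluate_phenotype(model, specs[i, ])
    data.frame(phenotype = specs$phenotype[i], variable = specs$variable[i],
               simulated = r$simulated, experimental = r$experimental,
               log2_ratio = r$log2_ratio, band = r$band,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
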