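# Stiff ODE integration of a network_model with time-varying clamped inputs.

MSN_MAXP <- 4096

# internal: pack a compiled network into the fixed-length parms vector
# understood by the C right-hand side. When `use_forcings` is FALSE the
# input species are constant clamps (held at their initial value) instead of
# following the interpolated forcing channels.
pack_network <- function(comp, extra_clamped = integer(0), use_forcings = TRUE) {
  i_ca <- if (use_forcings) match("Ca", comp$names, nomatch = 0L) else 0L
  i_da <- if (use_forcings) match("DA", comp$names, nomatch = 0L) else 0L
  cl <- sort(unique(c(comp$clamped, extra_clamped)))
  cl <- setdiff(cl, c(i_ca, i_da))
  body <- as.vector(t(cbind(comp$R, comp$P, comp$kf, comp$kr)))
  p <- c(comp$n_sp, comp$n_rx, i_ca, i_da, length(cl), cl, body)
  if (length(p) > MSN_MAXP)
    stop("network too large for the compiled engine (", length(p),
         " > ", MSN_MAXP, " packed values)")
  c(p, numeric(MSN_MAXP - length(p)))
}

# internal: forcing matrices (time, value) for the two input channels.
# Sampled densely where the stimulus is structured, coarsely elsewhere.
input_forcings <- function(stimulus, t_end) {
  if (is.null(stimulus)) {
    m <- cbind(c(0, t_end), c(0, 0))
    return(list(ca = m, da = m))
  }
  tt <- sampling_times(stimulus, t_end)
  tr <- build_traces(stimulus, tt)
  list(ca = cbind(tt, tr$calcium), da = cbind(tt, tr$dopamine))
}

#' Simulate a reaction network
#'
#' Integrates the mass-action ODE system with a stiff variable-order BDF
#' solver (\code{deSolve} lsodes, sparse Jacobian) under a maximum internal
#' step, with
#' calcium/dopamine inputs prescribed by a [stimulus_protocol()] and optional
#' additional constant clamps.
#'
#' @param model A [network_model()].
#' @param stimulus A [stimulus_protocol()], or `NULL` for no time-varying
#'   inputs (clamped input species then stay at their initial value only if
#'   also listed in `clamp`; otherwise they are held at 0).
#' @param t_end End time in seconds.
#' @param max_step Maximum internal solver step (s). The 0.01 s default bounds
#'   interpolation error across the fast calcium pulses; smooth protocols
#'   (constant clamps) may use a larger cap.
#' @param grid_dt Output grid spacing (s).
#' @param init Optional named vector of initial concentrations overriding the
#'   model's; missing species keep the model value.
#' @param clamp Optional named numeric vector: extra species held constant at
#'   the given concentrations (e.g. cAMP dose clamps).
#' @param rtol,atol Relative / absolute solver tolerances.
#' @param engine `"C"` (compiled, default) or `"R"` (reference implementation).
#' @return A `simulation_result`: list with `time`, `concentrations` (matrix,
#'   one column per species), `input_trace` (data.frame `time`, `Ca`, `DA`),
#'   and `solver_stats`.
#' @export
simulate <- function(model, stimulus = NULL, t_end, max_step = 0.01,
                     grid_dt = 0.01, init = NULL, clamp = NULL,
                     rtol = 1e-6, atol = 1e-9, engine = c("C", "R")) {
  engine <- match.arg(engine)
  stopifnot(inherits(model, "network_model"), t_end > 0)
  comp <- compile_network(model)
  y0 <- comp$initial
  names(y0) <- comp$names
  if (!is.null(init)) {
    bad <- setdiff(names(init), comp$names)
    if (length(bad)) stop("init has unknown species: ", paste(bad, collapse = ", "))
    y0[names(init)] <- init
  }
  extra_cl <- integer(0)
  if (!is.null(clamp)) {
    bad <- setdiff(names(clamp), comp$names)
    if (length(bad)) stop("clamp has unknown species: ", paste(bad, collapse = ", "))
    y0[names(clamp)] <- clamp
    extra_cl <- match(names(clamp), comp$names)
  }
  i_ca <- match("Ca", comp$names, nomatch = 0L)
  i_da <- match("DA", comp$names, nomatch = 0L)
  forc <- input_forcings(stimulus, t_end)
  if (!is.null(stimulus)) {
    if (i_ca > 0) y0[i_ca] <- forc$ca[1, 2]
    if (i_da > 0) y0[i_da] <- forc$da[1, 2]
  }
  times <- seq(0, t_end, by = grid_dt)

  if (engine == "C") {
    out <- deSolve::ode(
      y = y0, times = times, func = "msn_rhs",
      parms = pack_network(comp, extra_cl, use_forcings = !is.null(stimulus)),
      dllname = "msnsig", initfunc = "msn_init", initforc = "msn_forc",
      forcings = list(forc$ca, forc$da),
      method = "lsodes", rtol = rtol, atol = atol, hmax = max_step,
      maxsteps = 50000
    )
  } else {
    cl <- sort(unique(c(comp$clamped, extra_cl)))
    use_forc <- !is.null(stimulus)
    ca_f <- stats::approxfun(forc$ca[, 1], forc$ca[, 2], rule = 2)
    da_f <- stats::approxfun(forc$da[, 1], forc$da[, 2], rule = 2)
    fn <- function(t, y, p) {
      if (use_forc && i_ca > 0) y[i_ca] <- ca_f(t)
      if (use_forc && i_da > 0) y[i_da] <- da_f(t)
      d <- rhs_r(comp, y)
      d[cl] <- 0
      if (i_ca > 0) d[i_ca] <- 0
      if (i_da > 0) d[i_da] <- 0
      list(d)
    }
    out <- deSolve::ode(y = y0, times = times, func = fn, parms = NULL,
                        method = "lsodes", rtol = rtol, atol = atol,
                        hmax = max_step, maxsteps = 50000)
  }
  if (attr(out, "istate")[1] < 0)
    stop("solver failed near t = ", max(out[, 1]), " s")
  conc <- out[, -1, drop = FALSE]
  colnames(conc) <- comp$names
  if (anyNA(conc)) stop("NaN in simulated state")
  neg <- min(conc)
  if (neg < -1e-6)
    warning("negative excursion of ", signif(neg, 3), " uM clamped to 0")
  # clamped inputs follow the requested stimulus exactly on the output grid
  it <- data.frame(time = times, Ca = NA_real_, DA = NA_real_)
  if (is.null(stimulus)) {
    if (i_ca > 0) conc[, i_ca] <- y0[i_ca]
    if (i_da > 0) conc[, i_da] <- y0[i_da]
  }
  if (!is.null(stimulus)) {
    tr <- build_traces(stimulus, times)
    it$Ca <- tr$calcium; it$DA <- tr$dopamine
    if (i_ca > 0) conc[, i_ca] <- tr$calcium
    if (i_da > 0) conc[, i_da] <- tr$dopamine
  }
  conc[conc < 0] <- 0
  structure(list(time = times, concentrations = conc, input_trace = it,
                 solver_stats = c(steps = unname(attr(out, "istate")[3]),
                                  min_conc = neg),
                 species = comp$names),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> ", length(x$time), " time points, ",
      ncol(x$concentrations), " species, t = [",
      x$time[1], ", ", x$time[length(x$time)], "] s\n", sep = "")
  invisible(x)
}

#' Tidy trajectory export
#'
#' @param x A `simulation_result`.
#' @param species Optional subset of species names.
#' @param ... Unused.
#' @return Long-format data.frame with columns `time`, `species`, `value`.
#' @export
as.data.frame.simulation_result <- function(x, species = NULL, ...) {
  sp <- if (is.null(species)) colnames(x$concentrations) else species
  data.frame(
    time = rep(x$time, times = length(sp)),
    species = rep(sp, each = length(x$time)),
    value = as.vector(x$concentrations[, sp, drop = FALSE])
  )
}

#' Locate the steady state under constant (basal) inputs
#'
#' Integrates in successive windows under a constant-input stimulus until the
#' scaled residual `max |dX/dt| / max(X, 1e-6)` drops below `tol` (1/s), or
#' `t_max` is reached. Long smooth integration is used rather than
#' root-finding; it is robust for this stiff, conservation-constrained system.
#'
#' @param model A [network_model()].
#' @param basal_stimulus A constant-level [stimulus_protocol()] (e.g.
#'   [basal_protocol()]), or `NULL`.
#' @param clamp Optional extra constant clamps (named vector, uM).
#' @param init Optional initial state override.
#' @param tol Residual tolerance (1/s).
#' @param t_max Maximum integration time (s).
#' @param chunk Window length per convergence check (s).
#' @return List with `state` (named concentrations), `converged`, `residual`,
#'   and `t` (time integrated).
#' @export
steady_state <- function(model, basal_stimulus = NULL, clamp = NULL,
                         init = NULL, tol = 1e-8, t_max = 1e4, chunk = 400) {
  comp <- compile_network(model)
  state <- comp$initial
  names(state) <- comp$names
  if (!is.null(init)) state[names(init)] <- init
  if (length(model$reactions) == 0L)
    return(list(state = state, converged = TRUE, residual = 0, t = 0))
  t_done <- 0
  residual <- Inf
  repeat {
    res <- simulate(model, basal_stimulus, t_end = chunk, max_step = chunk / 50,
                    grid_dt = chunk / 50, init = state, clamp = clamp,
                    rtol = 1e-8, atol = 1e-12)
    state <- res$concentrations[nrow(res$concentrations), ]
    t_done <- t_done + chunk
    d <- rate_vector(model, state)
    if (!is.null(clamp)) d[names(clamp)] <- 0
    residual <- max(abs(d) / pmax(state, 1e-6))
    if (residual < tol || t_done >= t_max) break
  }
  list(state = state, converged = residual < tol, residual = residual, t = t_done)
}
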