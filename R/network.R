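#' Define a chemical species
#'
#' Species are the state variables of a [network_model()]. Concentrations are
#' in micromolar throughout the package; compartment tags are bookkeeping only
#' (the model is a single well-mixed volume).
#'
#' @param name Species identifier (unique within a model).
#' @param compartment One of `"cytosol"`, `"PSD"`, `"input"`.
#' @param initial Initial concentration in uM; must be `>= 0`.
#' @param clamped Logical; `TRUE` for input species (calcium, dopamine) whose
#'   concentration is prescribed by the stimulus rather than by reactions.
#' @return A `species_def` object.
#' @export
species_def <- function(name, compartment = "cytosol", initial = 0, clamped = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  compartment <- match.arg(compartment, c("cytosol", "PSD", "input"))
  if (!is.finite(initial) || initial < 0)
    stop("initial concentration of '", name, "' must be finite and >= 0")
  structure(list(name = name, compartment = compartment,
                 initial = as.numeric(initial), clamped = isTRUE(clamped)),
            class = "species_def")
}

#' Define a mass-action reaction
#'
#' Reactions follow the elementary mass-action rate law
#' `flux = kf * prod(reactant^stoich) - kr * prod(product^stoich)`.
#' Irreversible reactions have `kr = 0`. Per-species stoichiometries are
#' restricted to 1 or 2 (all reactions in the striatal network are uni- or
#' bimolecular per side, except catalytic-subunit release which is 1 + 2).
#'
#' @param id Reaction identifier.
#' @param reactants,products Named numeric vectors, species name -> stoichiometry.
#'   Products may be empty (degradation).
#' @param kf Forward rate constant (`1/s` for first order, `1/(uM s)` for
#'   second order). Must be `>= 0`.
#' @param kr Backward rate constant; `0` marks an irreversible reaction.
#' @param kf_name,kr_name Optional parameter names used for sensitivity scans
#'   and scaling; default `kf_<id>` / `kr_<id>`.
#' @return A `mass_action_reaction` object.
#' @export
reaction <- function(id, reactants, products, kf, kr = 0,
                     kf_name = NULL, kr_name = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  chk_side <- function(x, what) {
    if (length(x) == 0L) return(numeric(0))
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("reaction '", id, "': ", what, " must be a named vector")
    if (any(!x %in% c(1, 2)))
      stop("reaction '", id, "': stoichiometries are restricted to 1 and 2")
    if (anyDuplicated(names(x)))
      stop("reaction '", id, "': duplicated species in ", what)
    x
  }
  reactants <- chk_side(reactants, "reactants")
  products  <- chk_side(products, "products")
  if (!is.finite(kf) || kf < 0 || !is.finite(kr) || kr < 0)
    stop("reaction '", id, "': rate constants must be finite and >= 0")
  if (sum(reactants) > 3 || sum(products) > 3)
    stop("reaction '", id, "': at most three molecules per side")
  structure(list(id = id, reactants = reactants, products = products,
                 kf = as.numeric(kf), kr = as.numeric(kr),
                 kf_name = if (is.null(kf_name)) paste0("kf_", id) else kf_name,
                 kr_name = if (is.null(kr_name)) paste0("kr_", id) else kr_name),
            class = "mass_action_reaction")
}

is_reversible <- function(rx) rx$kr > 0

#' Assemble a reaction network model
#'
#' @param species List of [species_def()] objects.
#' @param reactions List of [reaction()] objects.
#' @param moieties Named list of conserved moieties; each element is a list
#'   with `members` (named numeric vector of per-species weights, typically 1)
#'   and optionally `total` (uM). If `total` is omitted it is computed from
#'   the initial concentrations.
#' @param cycles Named list of closed reversible-reaction loops used for
#'   detailed-balance checks; each element is a list with `ids` (reaction ids,
#'   in loop order) and `dirs` (+1/-1 orientation of each reaction in the loop).
#' @param provenance Optional data.frame (`parameter`, `source`) recording the
#'   origin of each parameter value.
#' @return A `network_model` object.
#' @export
network_model <- function(species, reactions, moieties = list(),
                          cycles = list(), provenance = NULL) {
  stopifnot(all(vapply(species, inherits, TRUE, "species_def")),
            all(vapply(reactions, inherits, TRUE, "mass_action_reaction")))
  sp <- data.frame(
    name        = vapply(species, `[[`, "", "name"),
    compartment = vapply(species, `[[`, "", "compartment"),
    initial     = vapply(species, `[[`, 0, "initial"),
    clamped     = vapply(species, `[[`, TRUE, "clamped"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(sp$name))
    stop("duplicated species names: ",
         paste(unique(sp$name[duplicated(sp$name)]), collapse = ", "))
  ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicated reaction ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  names(reactions) <- ids
  for (rx in reactions) {
    ref <- c(names(rx$reactants), names(rx$products))
    bad <- setdiff(ref, sp$name)
    if (length(bad))
      stop("reaction '", rx$id, "' references undeclared species: ",
           paste(bad, collapse = ", "))
  }
  moieties <- lapply(moieties, function(m) {
    bad <- setdiff(names(m$members), sp$name)
    if (length(bad))
      stop("moiety references unknown species: ", paste(bad, collapse = ", "))
    if (is.null(m$total))
      m$total <- sum(m$members * sp$initial[match(names(m$members), sp$name)])
    m
  })
  structure(list(species = sp, reactions = reactions, moieties = moieties,
                 cycles = cycles, provenance = provenance),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat("<network_model> ", nrow(x$species), " species, ",
      length(x$reactions), " reactions, ",
      length(x$moieties), " conserved moieties\n", sep = "")
  invisible(x)
}

#' Model parameters as a named vector
#'
#' Returns every addressable parameter: forward/backward rate constants of all
#' reactions (under their parameter names; shared names appear once) plus one
#' `TA_<moiety>` total-amount parameter per conserved moiety.
#'
#' @param model A [network_model()].
#' @return Named numeric vector.
#' @export
model_parameters <- function(model) {
  out <- numeric(0)
  for (rx in model$reactions) {
    out[rx$kf_name] <- rx$kf
    if (rx$kr > 0) out[rx$kr_name] <- rx$kr
  }
  for (nm in names(model$moieties)) {
    m <- model$moieties[[nm]]
    if (isFALSE(m$scan)) next       # bookkeeping duplicate of another total
    out[paste0("TA_", nm)] <- m$total
  }
  out
}

#' Scale parameters of a model
#'
#' Returns a copy of the model with the given parameters multiplied by the
#' given factors. Rate-constant parameters rescale every reaction that carries
#' the name; `TA_<moiety>` parameters rescale the initial concentrations of the
#' moiety's member species proportionally (and the recorded total).
#'
#' @param model A [network_model()].
#' @param scale_factors Named numeric vector, parameter name -> multiplier (> 0).
#' @return The scaled `network_model`.
#' @export
apply_scaling <- function(model, scale_factors) {
  if (length(scale_factors) == 0L) return(model)
  if (is.null(names(scale_factors)) || any(!nzchar(names(scale_factors))))
    stop("scale_factors must be a named vector")
  if (any(!is.finite(scale_factors) | scale_factors <= 0))
    stop("multipliers must be finite and > 0")
  known <- names(model_parameters(model))
  bad <- setdiff(names(scale_factors), known)
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  for (pn in names(scale_factors)) {
    f <- scale_factors[[pn]]
    if (startsWith(pn, "TA_") && pn %in% paste0("TA_", names(model$moieties))) {
      mn <- sub("^TA_", "", pn)
      members <- model$moieties[[mn]]$members
      i <- match(names(members), model$species$name)
      model$species$initial[i] <- model$species$initial[i] * f
      # keep every declared total consistent with the (pre-equilibration)
      # initial state, including overlapping bookkeeping moieties
      for (k in seq_along(model$moieties)) {
        mm <- model$moieties[[k]]
        j <- match(names(mm$members), model$species$name)
        model$moieties[[k]]$total <- sum(mm$members * model$species$initial[j])
      }
    } else {
      for (ri in seq_along(model$reactions)) {
        rx <- model$reactions[[ri]]
        if (identical(rx$kf_name, pn)) model$reactions[[ri]]$kf <- rx$kf * f
        if (rx$kr > 0 && identical(rx$kr_name, pn))
          model$reactions[[ri]]$kr <- model$reactions[[ri]]$kr * f
      }
    }
  }
  model
}

# internal: compile network to flat index arrays used by both RHS engines
compile_network <- function(model) {
  sp <- model$species
  n_sp <- nrow(sp)
  idx <- function(nm) match(nm, sp$name)
  n_rx <- length(model$reactions)
  slot <- function(side) {
    # expand stoichiometry into up to 3 index slots (0 = empty)
    out <- integer(3)
    k <- 1L
    for (j in seq_along(side)) {
      for (r in seq_len(side[[j]])) { out[k] <- idx(names(side)[j]); k <- k + 1L }
    }
    out
  }
  R <- matrix(0L, n_rx, 3); P <- matrix(0L, n_rx, 3)
  kf <- numeric(n_rx); kr <- numeric(n_rx)
  S <- matrix(0, n_sp, n_rx, dimnames = list(sp$name, names(model$reactions)))
  for (i in seq_len(n_rx)) {
    rx <- model$reactions[[i]]
    R[i, ] <- slot(rx$reactants); P[i, ] <- slot(rx$products)
    kf[i] <- rx$kf; kr[i] <- rx$kr
    ir <- idx(names(rx$reactants)); ip <- idx(names(rx$products))
    S[ir, i] <- S[ir, i] - rx$reactants
    S[ip, i] <- S[ip, i] + rx$products
  }
  clamped <- which(sp$clamped)
  S[clamped, ] <- 0
  list(n_sp = n_sp, n_rx = n_rx, R = R, P = P, kf = kf, kr = kr, S = S,
       clamped = clamped, names = sp$name, initial = sp$initial)
}

# internal: pure-R right-hand side on a compiled network
rhs_r <- function(comp, state) {
  s <- pmax(state, 0)
  s1 <- c(1, s)                       # index 0 -> factor 1 via offset
  fwd <- comp$kf * s1[comp$R[, 1] + 1L] * s1[comp$R[, 2] + 1L] * s1[comp$R[, 3] + 1L]
  bwd <- comp$kr * s1[comp$P[, 1] + 1L] * s1[comp$P[, 2] + 1L] * s1[comp$P[, 3] + 1L]
  as.vector(comp$S %*% (fwd - bwd))
}

#' Evaluate the mass-action rate vector
#'
#' Computes `d[X]/dt` for every species at the given state. Clamped input
#' species get derivative 0 (they are forcing functions). Small negative
#' concentrations (solver round-off) are clamped to 0 before evaluation.
#'
#' @param model A [network_model()].
#' @param state Named numeric vector of concentrations (uM) covering every
#'   model species.
#' @return Named numeric vector of time derivatives (uM/s).
#' @export
rate_vector <- function(model, state) {
  comp <- compile_network(model)
  if (is.null(names(state)))
    stop("state must be a named concentration vector")
  bad <- setdiff(names(state), comp$names)
  if (length(bad))
    stop("unknown species in state: ", paste(bad, collapse = ", "))
  miss <- setdiff(comp$names, names(state))
  if (length(miss))
    stop("state is missing species: ", paste(miss, collapse = ", "))
  d <- rhs_r(comp, state[comp$names])
  names(d) <- comp$names
  d
}

#' Check moiety conservation along a trajectory
#'
#' For each declared conserved moiety, computes the maximum relative drift
#' `max_t |sum_i w_i x_i(t) - total| / total` over the simulated trajectory.
#' Under pure mass action with clamped inputs this drift is solver error only
#' and should be far below 1e-6.
#'
#' @param model A [network_model()].
#' @param result A [simulate()] result for this model.
#' @return Named numeric vector of per-moiety maximum relative drifts.
#' @export
conservation_check <- function(model, result) {
  stopifnot(inherits(result, "simulation_result"))
  conc <- result$concentrations
  out <- numeric(length(model$moieties))
  names(out) <- names(model$moieties)
  for (nm in names(model$moieties)) {
    m <- model$moieties[[nm]]
    bad <- setdiff(names(m$members), colnames(conc))
    if (length(bad))
      stop("moiety '", nm, "' references unknown species: ",
           paste(bad, collapse = ", "))
    tot <- as.vector(conc[, names(m$members), drop = FALSE] %*% m$members)
    out[nm] <- max(abs(tot - m$total)) / m$total
  }
  out
}

#' Detailed-balance check on a closed reaction cycle
#'
#' Computes the product of equilibrium constants `prod (kf_i/kr_i)^dir_i`
#' around a closed loop of reversible reactions. A thermodynamically
#' consistent cycle gives 1 (within `tol`).
#'
#' @param model A [network_model()].
#' @param cycle Either the name of a cycle declared in the model, or a list
#'   with `ids` (reaction ids in loop order) and `dirs` (orientation +1/-1).
#' @param tol Tolerance on `|ratio - 1|` for the `pass` flag.
#' @return List with `ratio` (dimensionless loop product) and `pass` (logical).
#' @export
detailed_balance_check <- function(model, cycle, tol = 1e-6) {
  if (is.character(cycle) && length(cycle) == 1L) {
    if (!cycle %in% names(model$cycles))
      stop("no cycle named '", cycle, "' declared in the model")
    cycle <- model$cycles[[cycle]]
  }
  ids <- cycle$ids
  dirs <- if (is.null(cycle$dirs)) rep(1, length(ids)) else cycle$dirs
  stopifnot(length(ids) == length(dirs), length(ids) >= 2L)
  ratio <- 1
  for (i in seq_along(ids)) {
    rx <- model$reactions[[ids[i]]]
    if (is.null(rx)) stop("unknown reaction id '", ids[i], "'")
    if (rx$kr <= 0)
      stop("reaction '", ids[i], "' is irreversible; cycle must be reversible")
    ratio <- ratio * (rx$kf / rx$kr)^dirs[i]
  }
  list(ratio = ratio, pass = abs(ratio - 1) <= tol)
}
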