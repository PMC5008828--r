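# Shared fixtures built in code: small closed-form toy networks and cached
# striatal models / sweeps (the package's own basal-state cache makes repeated
# model_basal calls cheap within one test session).

toy_binding_model <- function(kf = 1, kr = 1, a0 = 1, b0 = 1) {
  network_model(
    list(species_def("A", initial = a0), species_def("B", initial = b0),
         species_def("AB")),
    list(reaction("bind", c(A = 1, B = 1), c(AB = 1), kf = kf, kr = kr)),
    moieties = list(Atot = list(members = c(A = 1, AB = 1)),
                    Btot = list(members = c(B = 1, AB = 1))))
}

toy_decay_model <- function(k = 0.166, a0 = 2) {
  network_model(
    list(species_def("A", initial = a0)),
    list(reaction("decay", c(A = 1), numeric(0), kf = k)))
}

# three-reaction loop A->B->C->A as reversible pairs with Keq = (2, 3, 1/6);
# the loop product is 1 by construction
toy_cycle_model <- function(break_it = FALSE) {
  network_model(
    list(species_def("A", initial = 1), species_def("B"), species_def("C")),
    list(reaction("ab", c(A = 1), c(B = 1), kf = 2, kr = 1),
         reaction("bc", c(B = 1), c(C = 1), kf = 3, kr = 1),
         reaction("ca", c(C = 1), c(A = 1), kf = 1, kr = if (break_it) 3 else 6)),
    cycles = list(loop = list(ids = c("ab", "bc", "ca"), dirs = c(1, 1, 1))))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

wt_model <- function() cached("wt", build_model("WT"))

wt_sweep <- function() cached("wt_sweep",
  dt_sweep(model = wt_model(), delta_t_values = c(-6, -4, -2, -1, 1, 2, 4, 6, 8)))

noa_sweep <- function() cached("noa_sweep",
  dt_sweep("NO_ARPP21", delta_t_values = c(-6, -4, -2, -1, 1, 2, 4, 6, 8)))

a21_sweep <- function() cached("a21_sweep",
  dt_sweep("A21S55A", delta_t_values = c(-6, -4, -2, -1, 1, 2, 4, 6, 8)))

at_dt <- function(sweep, dt) sweep$normalized_area[match(dt, sweep$delta_t)]
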