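test_that("reversible binding reaches the closed-form equilibrium", {
  # kf (1-x)^2 = kr x  =>  x = (3 - sqrt(5)) / 2 for kf = kr = 1, A0 = B0 = 1
  m <- toy_binding_model(kf = 1, kr = 1)
  r <- simulate(m, NULL, t_end = 100, max_step = 0.05, grid_dt = 0.1)
  ab <- r$concentrations[nrow(r$concentrations), "AB"]
  expect_equal(unname(ab), (3 - sqrt(5)) / 2, tolerance = 1e-5)
})

test_that("zero rate constants leave the trajectory at the initial state", {
  m <- toy_binding_model(kf = 0, kr = 0, a0 = 0.3, b0 = 1.1)
  r <- simulate(m, NULL, t_end = 10, max_step = 0.1, grid_dt = 0.5)
  expect_true(all(abs(r$concentrations[, "A"] - 0.3) < 1e-12))
  expect_true(all(abs(r$concentrations[, "B"] - 1.1) < 1e-12))
})

test_that("first-order decay reproduces the CaMKII-deactivation rate fixture", {
  # k = 0.166 1/s (tau = 6 s), recovered from the trajectory within 1%
  m <- toy_decay_model(k = 0.166, a0 = 2)
  r <- simulate(m, NULL, t_end = 30, max_step = 0.01, grid_dt = 0.05)
  fit <- fit_monoexponential(r$time, r$concentrations[, "A"])
  expect_equal(fit$k, 0.166, tolerance = 0.01)
})

test_that("compiled and reference R engines agree", {
  m <- toy_binding_model(kf = 2, kr = 0.5)
  p <- stimulus_protocol(t_calcium = 2)   # exercise the forcing path too
  mc <- network_model(
    list(species_def("Ca", "input", 0.06, clamped = TRUE),
         species_def("X", initial = 1), species_def("XCa")),
    list(reaction("b", c(Ca = 1, X = 1), c(XCa = 1), kf = 1, kr = 1)))
  for (case in list(list(m, NULL), list(mc, p))) {
    rC <- simulate(case[[1]], case[[2]], t_end = 8, max_step = 0.01,
                   grid_dt = 0.05, engine = "C")
    rR <- simulate(case[[1]], case[[2]], t_end = 8, max_step = 0.01,
                   grid_dt = 0.05, engine = "R")
    expect_lt(max(abs(rC$concentrations - rR$concentrations)), 5e-5)
  }
})

test_that("simulate is deterministic and respects the grid-refinement property", {
  m <- wt_model()
  b <- model_basal(m)
  p <- standard_protocol(delta_t = 1)
  r1 <- simulate(m, p, t_end = 30, max_step = 0.01, init = b)
  r2 <- simulate(m, p, t_end = 30, max_step = 0.01, init = b)
  expect_identical(r1$concentrations, r2$concentrations)
  rh <- simulate(m, p, t_end = 30, max_step = 0.005, init = b)
  rel <- max(abs(r1$concentrations - rh$concentrations) /
               pmax(abs(rh$concentrations), 1e-3))
  expect_lt(rel, 1e-4)
})

test_that("clamped inputs follow the stimulus exactly on the output grid", {
  mc <- network_model(
    list(species_def("Ca", "input", 0.06, clamped = TRUE),
         species_def("DA", "input", 0.02, clamped = TRUE),
         species_def("X", initial = 1), species_def("XCa")),
    list(reaction("b", c(Ca = 1, X = 1), c(XCa = 1), kf = 1, kr = 1)))
  p <- stimulus_protocol(t_calcium = 3)
  r <- simulate(mc, p, t_end = 10, max_step = 0.01, grid_dt = 0.01)
  tr <- build_traces(p, r$time)
  expect_identical(unname(r$concentrations[, "Ca"]), tr$calcium)
  expect_identical(unname(r$concentrations[, "DA"]), tr$dopamine)
})

test_that("steady_state finds equilibria and handles edge cases", {
  ss <- steady_state(toy_binding_model())
  expect_true(ss$converged)
  expect_equal(unname(ss$state["AB"]), (3 - sqrt(5)) / 2, tolerance = 1e-6)
  # no reactions: initial state returned immediately
  m0 <- network_model(list(species_def("A", initial = 2)), list())
  ss0 <- steady_state(m0)
  expect_true(ss0$converged)
  expect_equal(ss0$t, 0)
  expect_equal(unname(ss0$state["A"]), 2)
})

test_that("solver failure paths raise informative errors", {
  m <- toy_binding_model()
  expect_error(simulate(m, NULL, t_end = 5, clamp = c(Z = 1)), "unknown species")
  expect_error(simulate(m, NULL, t_end = 5, init = c(Q = 1)), "unknown species")
})
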