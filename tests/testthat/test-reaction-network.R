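test_that("mass-action rate vector matches the elementary rate law", {
  m <- toy_binding_model(kf = 1, kr = 1)
  d <- rate_vector(m, c(A = 1, B = 1, AB = 0))
  expect_equal(unname(d["AB"]), 1)
  expect_equal(unname(d["A"]), -1)
  expect_equal(unname(d["B"]), -1)

  # zero rate constants give zero derivatives
  d0 <- rate_vector(toy_binding_model(kf = 0, kr = 0), c(A = 1, B = 1, AB = 0.5))
  expect_true(all(d0 == 0))

  # first-order irreversible conversion conserves mass
  m2 <- network_model(
    list(species_def("A", initial = 3), species_def("B")),
    list(reaction("conv", c(A = 1), c(B = 1), kf = 2)))
  d2 <- rate_vector(m2, c(A = 3, B = 0))
  expect_equal(unname(d2["B"]), 6)
  expect_equal(unname(d2["A"] + d2["B"]), 0)
})

test_that("rate_vector validates state, clamps inputs and small negatives", {
  m <- toy_binding_model()
  expect_error(rate_vector(m, c(A = 1, B = 1)), "missing species")
  expect_error(rate_vector(m, c(A = 1, B = 1, AB = 0, Z = 1)), "Z")
  # tiny negative concentration treated as 0
  d <- rate_vector(m, c(A = -1e-12, B = 1, AB = 0))
  expect_equal(unname(d["AB"]), 0)
  # clamped input species get derivative 0
  mc <- network_model(
    list(species_def("Ca", "input", 0.06, clamped = TRUE),
         species_def("X", initial = 1), species_def("XCa")),
    list(reaction("b", c(Ca = 1, X = 1), c(XCa = 1), kf = 1, kr = 1)))
  dc <- rate_vector(mc, c(Ca = 2, X = 1, XCa = 0))
  expect_equal(unname(dc["Ca"]), 0)
  expect_equal(unname(dc["XCa"]), 2)
})

test_that("rate_vector is linear in each rate constant", {
  m <- toy_binding_model(kf = 0.7, kr = 0.3)
  st <- c(A = 0.4, B = 1.7, AB = 0.9)
  d1 <- rate_vector(m, st)
  d2 <- rate_vector(apply_scaling(m, c(kf_bind = 2)), st)
  # doubling kf exactly doubles the forward contribution
  fwd <- 0.7 * 0.4 * 1.7
  expect_equal(unname(d2["AB"] - d1["AB"]), fwd)
})

test_that("structural validation rejects bad models", {
  expect_error(species_def("A", initial = -1), ">= 0")
  expect_error(reaction("r", c(A = 3), c(B = 1), kf = 1), "restricted to 1 and 2")
  expect_error(reaction("r", c(A = 1), c(B = 1), kf = -1), ">= 0")
  expect_error(network_model(list(species_def("A")),
                             list(reaction("r", c(A = 1), c(B = 1), kf = 1))),
               "undeclared")
  expect_error(network_model(
    list(species_def("A"), species_def("A")), list()), "duplicated")
})

test_that("conservation_check reports drift and detects broken moieties", {
  m <- toy_binding_model()
  r <- simulate(m, NULL, t_end = 50, max_step = 0.05, grid_dt = 0.1)
  expect_lt(max(conservation_check(m, r)), 1e-8)
  # deliberately drop a member: huge apparent drift
  m$moieties$Atot$members <- c(A = 1)
  expect_gt(conservation_check(m, r)["Atot"], 1e-3)
})

test_that("detailed balance holds on a consistent loop and fails when broken", {
  db <- detailed_balance_check(toy_cycle_model(), "loop")
  expect_equal(db$ratio, 1, tolerance = 1e-12)
  expect_true(db$pass)
  db2 <- detailed_balance_check(toy_cycle_model(break_it = TRUE), "loop")
  expect_equal(db2$ratio, 2, tolerance = 1e-12)
  expect_false(db2$pass)
  # irreversible reactions are rejected
  m <- network_model(
    list(species_def("A", initial = 1), species_def("B")),
    list(reaction("ab", c(A = 1), c(B = 1), kf = 1)))
  expect_error(detailed_balance_check(m, list(ids = c("ab", "ab"), dirs = c(1, -1))),
               "irreversible")
})

test_that("apply_scaling rescales rate constants and moiety totals", {
  m <- toy_binding_model()
  expect_error(apply_scaling(m, c(nope = 2)), "unknown")
  m1 <- apply_scaling(m, c(kf_bind = 1))
  expect_equal(m1$reactions$bind$kf, m$reactions$bind$kf)
  m2 <- apply_scaling(m, c(TA_Atot = 0.8))
  expect_equal(m2$species$initial[m2$species$name == "A"], 0.8)
  expect_equal(m2$moieties$Atot$total, 0.8)
  # conservation still holds after rescaling
  r <- simulate(m2, NULL, t_end = 20, max_step = 0.05, grid_dt = 0.1)
  expect_lt(max(conservation_check(m2, r)), 1e-8)
})
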