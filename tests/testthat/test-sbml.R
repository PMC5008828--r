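test_that("SBML round trip preserves structure and rate constants exactly", {
  m <- toy_binding_model(kf = 1.23456789012345, kr = 0.000712345678901)
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f, "toy")
  m2 <- read_sbml(f)
  expect_equal(nrow(m2$species), nrow(m$species))
  expect_equal(length(m2$reactions), length(m$reactions))
  # rate constants identical in decimal-string form (and bitwise)
  expect_identical(sprintf("%.17g", m2$reactions$bind$kf),
                   sprintf("%.17g", m$reactions$bind$kf))
  expect_identical(m2$reactions$bind$kr, m$reactions$bind$kr)
  expect_identical(m2$species$initial, m$species$initial)
})

test_that("the full striatal model survives an SBML round trip", {
  m <- wt_model()
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f, "striatal_wt")
  m2 <- read_sbml(f)
  expect_equal(nrow(m2$species), nrow(m$species))
  expect_equal(length(m2$reactions), length(m$reactions))
  k1 <- unlist(lapply(m$reactions, function(r) c(r$kf, r$kr)))
  k2 <- unlist(lapply(m2$reactions, function(r) c(r$kf, r$kr)))
  expect_identical(unname(k1), unname(k2))
  expect_identical(m2$species$clamped, m$species$clamped)
  # identical dynamics: same rate vector at the initial state
  st <- setNames(m$species$initial, m$species$name)
  expect_equal(rate_vector(m2, st), rate_vector(m, st), tolerance = 1e-14)
})
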