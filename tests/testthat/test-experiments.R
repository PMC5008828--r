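test_that("activation_area integrates excursions above basal", {
  m <- wt_model()
  b <- model_basal(m)
  r <- simulate(m, basal_protocol(), t_end = 20, max_step = 0.1, grid_dt = 0.1,
                init = b)
  # constant-at-basal trace: area 0
  expect_lt(activation_area(r, m, "pSubstrate", c(0, 20)), 1e-4)
  expect_error(activation_area(r, m, "pSubstrate", c(0, 50)), "window")
  # rectangular excursion of height 1 for 10 s: area 10 (synthetic trace)
  fake <- r
  fake$concentrations[, "pSub"] <- fake$concentrations[1, "pSub"] +
    as.numeric(r$time >= 5 & r$time < 15)
  expect_equal(activation_area(fake, m, "pSubstrate", c(0, 20)), 10,
               tolerance = 0.02)
})

test_that("normalization identity: no dopamine input gives area ratio 1", {
  m <- wt_model()
  sw <- dt_sweep(model = m, delta_t_values = 1, dopamine_amplitude = 0.020)
  # dopamine 'transient' at the basal level is no input at all
  expect_equal(sw$normalized_area, 1, tolerance = 0.02)
})

test_that("dopamine gates the substrate response (interval curve structure)", {
  sw <- wt_sweep()
  expect_gt(at_dt(sw, 1), 1.3)                       # gating
  expect_gt(at_dt(sw, 1), at_dt(sw, -1))             # order bias
  expect_lt(at_dt(sw, -4), at_dt(sw, -1))            # declines away from 0
  expect_lt(at_dt(sw, 8), at_dt(sw, 2))
})

test_that("REF(reference) is exactly zero and guards divide-by-zero", {
  rw <- refractoriness("WT", iti_values = c(30, 100))
  expect_identical(rw$ref[rw$iti == 100], 0)
})

test_that("the robustness grid keeps sub-threshold rows flat", {
  rg <- robustness_grid("dopamine_amplitude", values = c(0.01, 1.5),
                        delta_t_values = c(-2, 1))
  low <- rg[rg$axis_value == 0.01, ]
  expect_true(all(abs(low$normalized_area - 1) < 0.05))
  hi <- rg[rg$axis_value == 1.5, ]
  expect_gt(hi$normalized_area[hi$delta_t == 1], 1.3)
})

test_that("sensitivity scan reports zero change for a unit perturbation", {
  ss <- sensitivity_scan(parameters = "kf_CaM_Ca", delta_t_values = c(-1, 1),
                         perturbation = 1e-12)
  expect_true(all(abs(ss$changes$fractional_change) < 1e-4))
})

test_that("trajectory writer emits tidy TSV with a metadata header", {
  m <- toy_binding_model()
  r <- simulate(m, NULL, t_end = 1, max_step = 0.05, grid_dt = 0.5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(r, f, species = "AB", meta = c(variant = "toy"))
  lines <- readLines(f)
  expect_true(any(grepl("^# variant=toy", lines)))
  df <- read.delim(f, comment.char = "#")
  expect_named(df, c("time", "species", "value"))
  expect_true(all(df$species == "AB"))
})
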