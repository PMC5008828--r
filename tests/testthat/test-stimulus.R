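test_that("default traces match the stated amplitudes and timing", {
  p <- stimulus_protocol(t_calcium = 10)   # delta_t = 1 s by default
  g <- seq(0, 30, by = 0.001)
  tr <- build_traces(p, g)
  # calcium: 60 nM basal, train peaks at 5 uM within 1%
  expect_equal(tr$calcium[which.min(abs(g - 5))], 0.060, tolerance = 1e-6)
  expect_equal(max(tr$calcium), 5, tolerance = 0.01)
  # pulse starts spaced at 0.1 s from t = 10
  on <- trial_onsets(p)
  expect_equal(on$t_calcium, 10)
  # dopamine: onset 1 s after calcium onset, 20 nM basal before
  expect_equal(on$t_dopamine, 11)
  expect_equal(tr$dopamine[which.min(abs(g - 10.5))], 0.020, tolerance = 1e-6)
  expect_equal(max(tr$dopamine), 1.5, tolerance = 0.01)
  # plateau ~1 s: still high at 11.9 s, decayed by 12.2 s
  expect_gt(tr$dopamine[which.min(abs(g - 11.9))], 1.4)
  expect_lt(tr$dopamine[which.min(abs(g - 12.2))], 0.1)
})

test_that("calcium-alone protocols keep dopamine at basal", {
  p <- stimulus_protocol(dopamine = NULL, t_calcium = 5)
  tr <- build_traces(p, seq(0, 20, by = 0.01))
  expect_true(all(tr$dopamine == 0.020))
})

test_that("traces are translation-equivariant in the protocol onset", {
  g <- seq(0, 40, by = 0.002)
  p1 <- stimulus_protocol(t_calcium = 10)
  p2 <- stimulus_protocol(t_calcium = 17)
  tr1 <- build_traces(p1, g)
  tr2 <- build_traces(p2, g + 7)
  expect_equal(tr1$calcium, tr2$calcium, tolerance = 1e-12)
  expect_equal(tr1$dopamine, tr2$dopamine, tolerance = 1e-12)
})

test_that("train integral is proportional to pulse count when non-overlapping", {
  g <- seq(0, 60, by = 0.002)
  p5 <- stimulus_protocol(calcium_train(n_pulses = 5, frequency = 2), NULL,
                          trial_schedule(1), t_calcium = 5)
  tr5 <- build_traces(p5, g)
  p10 <- p5
  p10$calcium$n_pulses <- 10L   # same pulse amplitude, twice the pulses
  tr10 <- build_traces(p10, g)
  i5 <- sum(tr5$calcium - 0.06) * 0.002
  i10 <- sum(tr10$calcium - 0.06) * 0.002
  expect_equal(i10 / i5, 2, tolerance = 0.01)
})

test_that("swapping the sign of delta_t mirrors the onset order only", {
  pp <- stimulus_protocol(schedule = trial_schedule(1, delta_t = 2), t_calcium = 20)
  pn <- stimulus_protocol(schedule = trial_schedule(1, delta_t = -2), t_calcium = 20)
  op <- trial_onsets(pp); on <- trial_onsets(pn)
  expect_gt(op$t_dopamine, op$t_calcium)   # positive: dopamine after calcium
  expect_lt(on$t_dopamine, on$t_calcium)
  expect_equal(abs(op$t_dopamine - op$t_calcium),
               abs(on$t_dopamine - on$t_calcium))
})

test_that("frequency_variant re-spaces pulses with unchanged per-pulse shape", {
  p <- stimulus_protocol(t_calcium = 10)
  p20 <- frequency_variant(p, 20)
  expect_equal(p20$calcium$n_pulses, 10L)
  expect_equal(p20$calcium$frequency, 20)
  expect_equal(p20$calcium$pulse_amp, p$calcium$pulse_amp)
  expect_identical(frequency_variant(p, 10)$calcium, p$calcium)
  # overlap raises the summed peak: 40 Hz vs 5 Hz with identical pulses
  g <- seq(0, 30, by = 5e-4)
  hi <- max(build_traces(frequency_variant(p, 40), g)$calcium)
  lo <- max(build_traces(frequency_variant(p, 5), g)$calcium)
  expect_gt(hi, lo)
})

test_that("multi-trial schedules place calcium onsets at the ITI spacing", {
  p <- stimulus_protocol(schedule = trial_schedule(3, iti = 20, delta_t = 1),
                         t_calcium = 10)
  on <- trial_onsets(p)
  expect_equal(on$t_calcium, c(10, 30, 50))
  expect_equal(on$t_dopamine, c(11, 31, 51))
  expect_error(trial_schedule(2, iti = 0), "iti")
  expect_error(build_traces(p, seq(0, 20, by = 0.1)), "too short")
})
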