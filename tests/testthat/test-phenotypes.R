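test_that("curve fitters recover synthetic parameters to < 1%", {
  t <- seq(0, 30, by = 0.05)
  # monoexponential decay
  f1 <- fit_monoexponential(t, 2 * exp(-0.5 * t) + 0.1)
  expect_equal(f1$k, 0.5, tolerance = 1e-3)
  # monoexponential rise
  f1r <- fit_monoexponential(t, 1 - 0.8 * exp(-2 * t), "rise")
  expect_equal(f1r$k, 2, tolerance = 1e-2)
  # difference of exponentials
  f2 <- fit_diff_exponentials(t, 1 * (exp(-0.05 * t) - exp(-0.2 * t)) + 0.02)
  expect_equal(f2$k1, 0.05, tolerance = 0.01)
  expect_equal(f2$k2, 0.2, tolerance = 0.01)
  # Hill
  d <- exp(seq(log(0.05), log(20), length.out = 8))
  f3 <- fit_hill(d, 3 * d^2 / (1 + d^2))
  expect_equal(f3$h, 2, tolerance = 0.01)
  expect_equal(f3$K, 1, tolerance = 0.01)
})

test_that("fitters reject degenerate traces", {
  t <- seq(0, 10, by = 0.1)
  expect_error(fit_monoexponential(t, 1 + t), "does not decay")
  expect_error(fit_diff_exponentials(t, rev(exp(-0.2 * t) - exp(-1 * t))),
               "rise-then-decay")
  expect_error(fit_hill(c(1, 2, 3, 4, 5), c(1, 0.5, 1, 0.2, 1)), "monotone")
})

test_that("band classification is a pure threshold function of the log2 ratio", {
  classify <- function(r) {
    l2 <- abs(log2(r))
    if (l2 <= log2(1.3)) "within30" else if (l2 <= log2(1.8)) "within80" else "outside"
  }
  expect_equal(classify(1.29), "within30")
  expect_equal(classify(1 / 1.29), "within30")
  expect_equal(classify(1.31), "within80")
  expect_equal(classify(1.79), "within80")
  expect_equal(classify(1.81), "outside")
  expect_equal(classify(1), "within30")
})

test_that("fold-change phenotypes are invariant to the concentration unit", {
  # the fold target does not depend on expressing the marker in nM vs uM
  m <- wt_model()
  b <- model_basal(m)
  marker <- striatal_observables(m)$pDARPP32_T34
  v_uM <- sum(b[marker]); v_nM <- sum(b[marker] * 1000)
  expect_equal(v_nM / (v_uM * 1000), 1)
})

test_that("the basal phenotypic variables sit at their targets", {
  m <- wt_model()
  b <- model_basal(m)
  ob <- function(n) sum(b[striatal_observables(m)[[n]]])
  expect_gt(ob("cAMP"), 0.03); expect_lt(ob("cAMP"), 0.09)
  expect_equal(ob("pDARPP32_T34"), 0.4, tolerance = 0.3)
  expect_equal(ob("pDARPP32_T75"), 12, tolerance = 0.3)
  expect_equal(ob("pARPP21_S55"), 0.7, tolerance = 0.3)
})

test_that("isolated dose responses reproduce the Hill parameterizations", {
  m <- wt_model()
  dr <- msnsig:::pka_dose_response(m)
  fp <- fit_hill(dr$dose, dr$response)
  expect_equal(fp$h, 1.4, tolerance = 0.3)
  expect_equal(fp$K, 0.5278, tolerance = 0.3)
  dc <- msnsig:::cam_dose_response(m)
  fc <- fit_hill(dc$dose, dc$response)
  expect_equal(fc$h, 1, tolerance = 0.3)
  expect_equal(fc$K, 6.29, tolerance = 0.3)
})

test_that("a deliberately miscalibrated model is flagged outside the bands", {
  p <- striatal_parameters()
  p[["kcat_AC5_Golf"]] <- p[["kcat_AC5_Golf"]] * 10
  p[["kcat_AC5_basal"]] <- p[["kcat_AC5_basal"]] * 10
  m <- build_model("WT", params = p)
  spec <- phenotype_specs()[1, ]    # basal cAMP (range 30-90 nM)
  r <- evaluate_phenotype(m, spec)
  expect_equal(r$band, "outside")
})
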