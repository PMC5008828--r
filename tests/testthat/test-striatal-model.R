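test_that("the packaged wild-type network is structurally sound", {
  m <- wt_model()
  expect_s3_class(m, "network_model")
  # totals the study fixes: ARPP-21 20 uM, DARPP-32 50 uM
  expect_equal(m$moieties$ARPP21$total, 20)
  expect_equal(m$moieties$DARPP32$total, 50)
  # every declared calmodulin-target thermodynamic cycle closes
  for (cy in names(m$cycles)) {
    db <- detailed_balance_check(m, cy)
    expect_true(db$pass, label = paste("cycle", cy))
    expect_equal(db$ratio, 1, tolerance = 1e-6)
  }
  # missing parameters are reported by name
  p <- striatal_parameters()
  expect_error(build_model("WT", params = p[-match("kf_CaM_Ca", names(p))]),
               "kf_CaM_Ca")
})

test_that("variants implement the mutations by construction", {
  m <- wt_model()
  mna <- build_model("NO_ARPP21")
  # species sets differ exactly by the ARPP-21-containing species
  diff <- setdiff(m$species$name, mna$species$name)
  expect_true(all(grepl("A21", diff)))
  expect_false(any(grepl("A21", mna$species$name)))
  # T34A: no reaction produces Thr-34-phosphorylated DARPP-32
  mt <- build_model("D32T34A")
  makes_p34 <- vapply(mt$reactions, function(r) "D32p34" %in% names(r$products), TRUE)
  expect_false(any(makes_p34))
  # S55A: no reaction produces Ser-55-phosphorylated ARPP-21
  ma <- build_model("A21S55A")
  makes_p55 <- vapply(ma$reactions, function(r) "A21p55" %in% names(r$products), TRUE)
  expect_false(any(makes_p55))
  # calmodulin overexpression scales the calmodulin total
  mc <- build_model("CAM_OVEREXPRESS")
  expect_equal(mc$moieties$CaM$total, 3 * m$moieties$CaM$total)
})

test_that("basal steady state converges and moieties are conserved in use", {
  m <- wt_model()
  b <- model_basal(m)
  d <- rate_vector(m, b)
  expect_lt(max(abs(d) / pmax(b, 1e-6)), 1e-6)
  r <- simulate(m, standard_protocol(delta_t = 1), t_end = 60, init = b)
  expect_lt(max(conservation_check(m, r)), 1e-6)
})

test_that("active PP1 stays high without dopamine and dips with it", {
  m <- wt_model()
  ca <- msnsig:::run_trial(m, NA, window_len = 60)
  pp1 <- observable(ca$result, m, "active_PP1")
  # no inhibition without dopamine: never drops below 95% of basal
  expect_gt(min(pp1) / pp1[1], 0.95)
  both <- msnsig:::run_trial(m, 1, window_len = 60)
  pp1b <- observable(both$result, m, "active_PP1")
  expect_lt(min(pp1b) / pp1b[1], 0.5)
})

test_that("phospho-ARPP-21 rises only after dopamine and re-basals in ~30 s", {
  m <- wt_model()
  b <- model_basal(m)
  ca <- msnsig:::run_trial(m, NA, window_len = 60)
  ps_ca <- observable(ca$result, m, "pARPP21_S55")
  # calcium alone shifts phospho-ARPP-21 only transiently and modestly
  # (calmodulin-bound phospho-ARPP-21 is protected from PP2A during the train)
  expect_lt(max(abs(ps_ca / ps_ca[1] - 1)), 0.3)
  expect_lt(abs(ps_ca[length(ps_ca)] / ps_ca[1] - 1), 0.05)
  r <- simulate(m, msnsig:::dopamine_only_protocol(onset = 20), t_end = 60,
                max_step = 0.01, grid_dt = 0.1, init = b)
  ps <- observable(r, m, "pARPP21_S55")
  peak <- max(ps) - ps[1]
  expect_gt(peak, 2)                                   # strong transient
  expect_lt(ps[r$time == 50] - ps[1], 0.25 * peak)     # back near basal by +30 s
})

test_that("CaMKII deactivates with a ~6 s time constant after the train", {
  m <- wt_model()
  b <- model_basal(m)
  r <- simulate(m, standard_protocol(delta_t = NA, t_calcium = 5), t_end = 40,
                max_step = 0.01, grid_dt = 0.02, init = b)
  fit <- fit_monoexponential(r$time, observable(r, m, "active_CaMKII"))
  expect_gt(fit$k, 1 / 9)   # tau in [4, 9] s
  expect_lt(fit$k, 1 / 4)
})

test_that("scaling a moiety total keeps it conserved thereafter", {
  m <- apply_scaling(wt_model(), c(TA_CaM = 0.8))
  expect_equal(m$moieties$CaM$total, 0.8 * wt_model()$moieties$CaM$total)
  r <- simulate(m, basal_protocol(), t_end = 20, max_step = 0.05, grid_dt = 0.1)
  expect_lt(conservation_check(m, r)["CaM"], 1e-6)
})
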