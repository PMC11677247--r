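test_that("EFD-to-velocity conversion follows the plane-wave balance", {
  expect_equal(efd_to_velocity(0.15), 1.96, tolerance = 0.005)
  # square-root law
  expect_equal(efd_to_velocity(0.4) / efd_to_velocity(0.1), 2,
               tolerance = 1e-9)
  expect_equal(efd_to_velocity(0.5) / efd_to_velocity(0.01), sqrt(50),
               tolerance = 1e-9)
  expect_warning(eswt_protocol(EFD = 0.6), "outside the studied")
})

test_that("the applicator waveform realizes the pulse-train contract", {
  p <- eswt_protocol(EFD = 0.15)
  expect_equal(applicator_waveform(0, p), 0)
  expect_equal(applicator_waveform(p$t_rise, p), p$V)
  expect_equal(applicator_waveform(p$t_rise + p$t_hold / 2, p), p$V)
  # five pulses delivered over 5 us: count forward-stroke bursts
  tt <- seq(0, 5e-6, by = 1e-10)
  v <- applicator_waveform(tt, p)
  on <- v > 0.5 * p$V
  bursts <- sum(diff(c(FALSE, on)) == 1)
  expect_equal(bursts, 5)
  # nothing after the train
  expect_equal(applicator_waveform(5.2e-6, p), 0)
  # with retraction the period displacement integral vanishes
  u <- sum(v) * 1e-10
  expect_lt(abs(u), 1e-3 * p$V * (p$t_hold + p$t_rise) * 5)
  # forward-only variant keeps a net displacement per pulse
  p1 <- eswt_protocol(EFD = 0.15, retract = FALSE)
  v1 <- applicator_waveform(tt, p1)
  expect_equal(sum(v1) * 1e-10, 5 * p1$V * (4 * p1$t_rise / pi + p1$t_hold),
               tolerance = 1e-3)
})

test_that("delivered energy flux matches the request within 15 percent", {
  for (efd in c(0.02, 0.15, 0.41)) {
    p <- eswt_protocol(EFD = efd)
    expect_equal(delivered_efd(p), efd, tolerance = 0.15)
  }
})

test_that("protocol constructors validate their inputs", {
  expect_error(physio_protocol(target = -5), "positive")
  expect_error(physio_protocol(v = 0), "positive")
  expect_error(eswt_protocol(), "EFD or V")
  expect_error(eswt_protocol(V = 1, t_rise = 0.6e-6, t_hold = 0.6e-6),
               "longer than the period")
  expect_error(eswt_protocol(V = 1, t_hold = 0.5e-6, t_recover = 0.6e-6),
               "recovery stroke")
})

test_that("physiological ramp reaches its target quasi-statically", {
  run <- fix_physio_500()
  expect_true(run$ramp_reached)
  # smoothed reaction is monotone non-decreasing during the ramp
  Fs <- run$F_ramp_smooth
  expect_true(all(diff(Fs[seq_len(which.max(Fs))]) > -0.5))
  # stop displacement consistent with the secant stiffness definition
  expect_equal(run$stiffness_kN_mm,
               100 / run$u_ramp_at_target / 1e6, tolerance = 1e-12)
})

test_that("ramp stop displacement scales linearly with the target", {
  run1 <- fix_physio_500()
  run2 <- fixture("physio500_200", function() {
    simulate_physio(fix_model_500(), physio_protocol(target = 200))
  })
  expect_equal(run2$u_ramp_at_target / run1$u_ramp_at_target, 2,
               tolerance = 0.05)
})

test_that("the ramp aborts with a diagnostic when the target is unreachable", {
  # a soft 0.25 mm^2 column cannot carry 100 N within a 20 um ramp
  mat <- fix_materials()[["Granulation"]]
  chain <- column_chain_model(mat, 6, 500e-6)
  chain$region[1] <- "base"
  expect_error(
    simulate_physio(chain, physio_protocol(target = 100, u_max = 2e-5)),
    "not reached")
})
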