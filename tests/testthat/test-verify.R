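# Analytic-oracle property suite for the engine and pore coupling.

test_that("homogeneous blocks recover their drained moduli within 3 percent", {
  for (mat in c("Cortical", "Cancellous")) {
    r <- fixture(paste0("modulus_", mat), function() modulus_recovery(mat))
    expect_lt(r$E_err, 0.03)
    expect_lt(r$nu_err, 0.03)
  }
})

test_that("a P-wave front travels at the bulk speed within 5 percent", {
  w <- fixture("wave", wave_speed_check)
  expect_lt(w$rel_err, 0.05)
  expect_equal(w$cp_theory, 4377, tolerance = 1e-3)
})

test_that("undamped elastic dynamics conserve energy and momentum", {
  e <- fixture("energy", energy_drift_check)
  expect_lt(e$drift, 0.01)
  expect_lt(e$momentum_dev, 1e-10)
})

test_that("the verification suite aggregates its oracles", {
  res <- verify_suite(c("undrained"))
  expect_true(all(res$pass))
  expect_error(verify_suite("nonsense"), "unknown")
})
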