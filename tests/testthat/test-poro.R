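test_that("pair transmissibility uses harmonic permeability and seals metal", {
  mats <- fix_materials()
  A <- 1e-8; L <- 4e-4; V <- 4.5e-11
  # equal permeabilities: harmonic mean is the common value
  t_eq <- pair_transmissibility(mats[["Cancellous"]], mats[["Cancellous"]],
                                pore_fluid(), A, L, V)
  expect_equal(t_eq, (3.7e-16 / 1e-3) * A / (L * V), tolerance = 1e-12)
  # cortical-cancellous: harmonic mean ~ 2e-20
  t_cc <- pair_transmissibility(mats[["Cortical"]], mats[["Cancellous"]],
                                pore_fluid(), A, L, V)
  k_h <- t_cc * 1e-3 * L * V / A
  expect_equal(k_h, 2.0e-20, tolerance = 1e-3)
  # implant-shell pairs are impermeable
  expect_equal(pair_transmissibility(mats[["Ti-6Al-4V"]],
                                     mats[["Primary matrix"]],
                                     pore_fluid(), A, L, V), 0)
})

test_that("pore pressure rate vanishes for uniform pressure at rest", {
  P <- rep(5e4, 6)
  pairs <- cbind(1:5, 2:6)
  r <- pore_pressure_rate(P, rep(0, 6), pairs, rep(1e-5, 5),
                          rep(0.8, 6), rep(3e9, 6))
  expect_equal(max(abs(r)), 0)
  # a gradient drives flux down-gradient
  P2 <- c(1e5, rep(0, 5))
  r2 <- pore_pressure_rate(P2, rep(0, 6), pairs, rep(1e-5, 5),
                           rep(0.8, 6), rep(3e9, 6))
  expect_lt(r2[1], 0)
  expect_gt(r2[2], 0)
})

test_that("undrained loading reproduces dP = -alpha M deps_v", {
  mats <- fix_materials()
  # closed form on table inputs
  expect_equal(undrained_pressure(mats[["Cancellous"]], -1e-4),
               263.7e3, tolerance = 1e-3)
  # engine path: exact at full coordination
  u <- undrained_check()
  expect_lt(u$rel_err, 1e-8)
  expect_lt(u$spread, 1e-7)
})

test_that("effective mean stress combines total stress and pore pressure", {
  expect_equal(effective_mean_stress(-1e6, 0.78, 0.5e6), -0.61e6)
  expect_equal(effective_mean_stress(-1e6, 0.78, 0), -1e6)      # dry
  expect_equal(effective_mean_stress(-1e6, 0, 2e6), -1e6)       # metal
})

test_that("sealed fluid mass is conserved and drained pressure decays", {
  mat <- consolidation_test_material()
  chain <- column_chain_model(mat, 16, 500e-6)
  n <- nrow(chain$positions)
  bc <- osseowave:::default_bc(n)
  bc$code <- rep(7L, n)  # freeze mechanics: pure exchange
  set.seed(42)
  P0 <- runif(n, 0, 1e5)
  dt <- stable_dt(chain)
  out <- run_engine(chain, bc = bc, dt = dt, n_steps = 1000, damping = 0,
                    poro = TRUE, record_every = 1000, P0 = P0)
  # sealed boundaries: sum V P / M conserved (uniform V, M)
  expect_equal(sum(out$P), sum(P0), tolerance = 1e-8)
  # now drain the top: pressure decays toward zero everywhere
  bc$drained[n] <- TRUE
  out2 <- run_engine(chain, bc = bc, dt = dt, n_steps = 60000, damping = 0,
                     poro = TRUE, record_every = 10000, P0 = P0)
  expect_lt(max(abs(out2$P)), 0.02 * max(P0))
})

test_that("consolidation follows the Terzaghi series", {
  tz <- fixture("terzaghi", terzaghi_check)
  expect_lt(tz$rms_err, 0.05)
  # drained boundary pinned at zero, monotone profile toward depth
  pr <- tz$profile
  expect_equal(pr$P[which.min(pr$zeta)], 0)
  expect_true(all(diff(pr$P[order(pr$zeta)]) >= -1))
})

test_that("diffusion sub-cycling engages when the explicit limit is hit", {
  mat <- consolidation_test_material(k_perm = 3e-13)  # very fast draining
  chain <- column_chain_model(mat, 8, 500e-6)
  n <- nrow(chain$positions)
  bc <- osseowave:::default_bc(n)
  bc$code <- rep(7L, n)
  out <- run_engine(chain, bc = bc, dt = stable_dt(chain), n_steps = 10,
                    damping = 0, poro = TRUE, record_every = 10,
                    P0 = rep(1e4, n))
  expect_gt(out$nsub, 1)
})
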