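test_that("pair normal strain follows its definition", {
  mat <- fix_materials()[["Cancellous"]]
  chain <- column_chain_model(mat, 2, 250e-6)
  pos <- chain$positions
  pos[2, 3] <- pos[2, 3] + 2.5e-6  # 250 um -> 252.5 um
  kin <- pair_kinematics(chain, pos)
  expect_equal(kin$eps_n[1], 0.01, tolerance = 1e-12)
  # undeformed lattice: all strains zero
  m <- fix_block()
  kin0 <- pair_kinematics(m)
  expect_lt(max(abs(kin0$eps_n)), 1e-12)
})

test_that("rigid-body motion produces no strain and no stress", {
  m <- fix_block()
  ctr <- colMeans(m$positions)
  # finite rigid rotation of the whole model
  th <- 0.3
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  pos <- sweep(sweep(m$positions, 2, ctr) %*% t(R), 2, ctr, "+")
  Om <- c(0, 0, 0.7)
  vel <- t(apply(sweep(pos, 2, ctr), 1, function(r)
    c(Om[2] * r[3] - Om[3] * r[2],
      Om[3] * r[1] - Om[1] * r[3],
      Om[1] * r[2] - Om[2] * r[1])))
  om <- matrix(Om, nrow(pos), 3, byrow = TRUE)
  kin <- pair_kinematics(m, pos, vel = vel, omega = om, dt = 1e-8)
  expect_lt(max(abs(kin$eps_n)), 1e-10)
  expect_lt(max(abs(kin$gamma)), 1e-10)
  cs <- closure_stress(m, eps_n = kin$eps_n, gamma = kin$gamma,
                       normal = kin$normal)
  expect_lt(max(abs(cs$stress)), 1)  # <= 1 Pa on GPa-scale moduli
})

test_that("uniform isotropic pair strain hits the mean-stress fixed point", {
  m <- fix_block()
  eps <- 1e-4
  cs <- closure_stress(m, eps_n = rep(eps, nrow(m$pairs)))
  K <- m$props$G[1]  # placeholder replaced below
  K <- m$props$K[1]
  deg <- tabulate(c(m$pairs[, 1], m$pairs[, 2]), nbins = nrow(m$positions))
  int <- deg == 12
  expect_equal(mean(cs$sbar[int]), 3 * K * eps, tolerance = 1e-10)
  expect_lt(max(cs$vm[int]) / (3 * K * eps), 1e-8)  # hydrostatic: no vM
  # zero strain, zero pressure: zero pair stress
  cs0 <- closure_stress(m, eps_n = rep(0, nrow(m$pairs)))
  expect_lt(max(abs(cs0$sig_n)), 1e-12)
})

test_that("von Mises and mean stress utilities follow their definitions", {
  hydro <- matrix(c(-2e6, -2e6, -2e6, 0, 0, 0), 1)
  expect_equal(von_mises(hydro), 0)
  expect_equal(mean_stress(hydro), -2e6)
  uni <- matrix(c(0, 0, 5e6, 0, 0, 0), 1)
  expect_equal(von_mises(uni), 5e6)
})

test_that("radial return caps the von Mises stress at yield", {
  pr <- plastic_return(120e6, 80e6)  # overloaded metal element
  expect_equal(pr$vm, 80e6)
  expect_equal(pr$scale, 80 / 120, tolerance = 1e-12)
  expect_equal(plastic_return(60e6, 80e6)$vm, 60e6)  # below yield
  expect_equal(plastic_return(5e9, Inf)$scale, 1)    # tissues never rescale
})

test_that("stable timestep follows the Courant rule", {
  fake <- list(d = 250e-6, props = list(cp = c(3000, 5744)))
  expect_equal(stable_dt(fake), 0.2 * 250e-6 / 5744, tolerance = 1e-12)
  expect_equal(stable_dt(fake), 8.7e-9, tolerance = 0.01)
  fake2 <- fake
  fake2$d <- 500e-6
  expect_equal(stable_dt(fake2), 2 * stable_dt(fake))
  expect_error(stable_dt(fake, C = 0), "positive")
})

test_that("an isolated pair oscillates at its static spring frequency", {
  mat <- fix_materials()[["Cortical"]]
  chain <- column_chain_model(mat, 2, 400e-6)
  chain$props$trans[] <- 0
  # static spring constant from a small imposed strain
  eps <- 1e-6
  cs <- closure_stress(chain, eps_n = eps)
  k_pair <- chain$A_pair * cs$sig_n[1] / (eps * chain$d)
  mu <- chain$props$mass[1] / 2
  f_th <- sqrt(k_pair / mu) / (2 * pi)
  # free vibration at dt = stable_dt/10
  dt <- stable_dt(chain) / 10
  v0 <- rbind(c(0, 0, 0.01), c(0, 0, -0.01))
  out <- run_engine(chain, dt = dt, n_steps = 4000, damping = 0,
                    poro = FALSE, record_every = 1, vel0 = v0)
  ke <- out$KE
  # KE minima occur twice per period
  mins <- which(diff(sign(diff(ke))) > 0) + 1
  T_meas <- 2 * mean(diff(mins)) * dt
  expect_equal(1 / T_meas, f_th, tolerance = 0.01)
  # Newton's third law: total momentum constant to machine precision
  mom <- out$momentum
  scale <- sum(chain$props$mass * 0.01)
  expect_lt(max(abs(mom$pz - mom$pz[1])), 1e-12 * scale)
})

test_that("zero forces give uniform linear motion", {
  mat <- fix_materials()[["Cortical"]]
  chain <- column_chain_model(mat, 3, 400e-6)
  chain$props$trans[] <- 0
  v0 <- matrix(rep(c(0.01, 0.002, -0.005), each = 3), 3, 3)
  dt <- stable_dt(chain)
  out <- run_engine(chain, dt = dt, n_steps = 500, damping = 0,
                    poro = FALSE, record_every = 500, vel0 = v0)
  expect_equal(out$pos[, 1] - chain$positions[, 1],
               rep(0.01 * 500 * dt, 3), tolerance = 1e-9)
  expect_equal(max(abs(out$vm)), 0, tolerance = 1)
})

test_that("interior stress balances an applied boundary stress", {
  mat <- consolidation_test_material()
  chain <- column_chain_model(mat, 12, 500e-6)
  chain$props$trans[] <- 0
  n <- nrow(chain$positions)
  bc <- osseowave:::default_bc(n)
  bc$code <- rep(3L, n)
  bc$code[1] <- 7L
  bc$ext_fz[n] <- -1e6 * chain$A_pair  # 1 MPa on the top facet
  dt <- stable_dt(chain)
  out <- run_engine(chain, bc = bc, dt = dt, n_steps = 6000, damping = 0.3,
                    poro = FALSE, record_every = 6000)
  expect_equal(mean(out$stress[4:9, 3]), -1e6, tolerance = 0.05)
})

test_that("local damping decays a single oscillator monotonically", {
  mat <- fix_materials()[["Cortical"]]
  chain <- column_chain_model(mat, 2, 400e-6)
  chain$props$trans[] <- 0
  v0 <- rbind(c(0, 0, 0.01), c(0, 0, -0.01))
  dt <- stable_dt(chain) / 4
  out <- run_engine(chain, dt = dt, n_steps = 6000, damping = 0.3,
                    poro = FALSE, record_every = 20, vel0 = v0)
  E <- out$KE + out$U_pair
  # total energy decays (allow tiny numerical wiggle between samples)
  expect_lt(E[length(E)], 0.02 * E[1])
  expect_true(all(diff(E) < 1e-3 * E[1]))
  expect_error(run_engine(chain, dt = dt, n_steps = 1, damping = 1),
               "damping")
})
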