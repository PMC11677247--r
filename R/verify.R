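#' Analytic verification drivers
#'
#' Each driver runs the engine on a small configuration with a closed-form
#' oracle: static modulus recovery under affine boundary conditions, P-wave
#' first arrival, exact undrained pore-pressure response, and Terzaghi
#' one-dimensional consolidation.
#'
#' @name verify
NULL

#' Homogeneous FCC block model
#'
#' A rectangular block of a single material, mainly for verification runs.
#'
#' @param material an `osseo_material` or a name in the package table.
#' @param n_cells conventional FCC cells per axis (length 1 or 3).
#' @param d element diameter, m.
#' @param materials material table (used when `material` is a name).
#' @param fluid pore fluid.
#' @return an `osseo_model`-compatible list.
#' @export
homogeneous_block_model <- function(material = "Cortical", n_cells = 6,
                                    d = 400e-6,
                                    materials = load_material_table(),
                                    fluid = attr(materials, "fluid")) {
  if (is.character(material)) material <- materials[[material]]
  stopifnot(!is.null(material))
  n_cells <- rep_len(n_cells, 3)
  a <- d * sqrt(2)
  L <- n_cells * a
  pos <- fcc_sites(c(0, 0, 0), L, a)
  nb <- cpp_neighbor_pairs(pos, 1.05 * d)
  n <- nrow(pos)
  dm <- derived_moduli(material)
  b <- suppressWarnings(biot_constants(material, fluid))
  M_fin <- if (is.finite(b$M)) b$M else 0
  cp_courant <- sqrt((dm$K + 4 * dm$G / 3 + b$alpha^2 * M_fin) / material$rho)
  V_elem <- d^3 / sqrt(2)
  A_pair <- V_elem / (2 * d)
  deg <- tabulate(c(nb$pairs[, 1], nb$pairs[, 2]), nbins = n)
  A_pairs <- A_pair * (12 / pmax(deg[nb$pairs[, 1]], 1) +
                         12 / pmax(deg[nb$pairs[, 2]], 1)) / 2
  trans <- if (material$is_metal) numeric(nrow(nb$pairs)) else
    (material$k_perm / fluid$eta_f) * A_pairs / (nb$r0 * V_elem)
  model <- list(
    positions = pos, d = d, region = rep("bulk", n),
    material = rep(material$name, n), pairs = nb$pairs, r0 = nb$r0,
    spec = list(Lx = L[1], Ly = L[2], Lz = L[3], d = d, phase = 1L,
                seed = 1L),
    fluid = fluid, V_elem = V_elem, A_pair = A_pair,
    props = list(
      G = rep(dm$G, n), K = rep(dm$K, n), alpha = rep(b$alpha, n),
      M = rep(if (is.finite(b$M)) b$M else 0, n),
      rho = rep(material$rho, n), mass = rep(material$rho * V_elem, n),
      sigma_y = rep(if (material$is_metal) material$sigma_y else Inf, n),
      is_metal = rep(material$is_metal, n),
      k_perm = rep(material$k_perm, n), theta = rep(material$theta, n),
      cp = rep(cp_courant, n), trans = trans, A_pairs = A_pairs))
  class(model) <- "osseo_model"
  model
}

boundary_mask <- function(model, tol_frac = 0.3) {
  a <- model$d * sqrt(2)
  tol <- tol_frac * a
  p <- model$positions
  out <- rep(FALSE, nrow(p))
  for (k in 1:3) {
    out <- out | p[, k] < min(p[, k]) + tol | p[, k] > max(p[, k]) - tol
  }
  out
}

#' Static modulus recovery
#'
#' Applies a quasi-static uniaxial-strain compression through affine
#' boundary conditions on every boundary element, reads the interior
#' uniaxial-strain stiffnesses C11 and C12, and converts them to the
#' effective Young's modulus and Poisson ratio of the drained skeleton.
#'
#' @param material material name or record.
#' @param n_cells FCC cells per axis.
#' @param d element diameter, m.
#' @param strain applied axial strain magnitude.
#' @param n_transits load duration in wave-transit times (plus as many to
#'   settle).
#' @param materials material table.
#' @return list `E`, `nu`, `E_err`, `nu_err` (relative errors vs the input),
#'   `C11`, `C12`.
#' @export
modulus_recovery <- function(material = "Cortical", n_cells = 7, d = 400e-6,
                             strain = 5e-4, n_transits = 12,
                             materials = load_material_table()) {
  mat <- if (is.character(material)) materials[[material]] else material
  model <- homogeneous_block_model(mat, n_cells, d, materials)
  n <- nrow(model$positions)
  dm <- derived_moduli(mat)
  L <- model$spec$Lz
  t_load <- n_transits * L / dm$cp
  rate <- strain / t_load
  ctr <- colMeans(model$positions)
  bmask <- boundary_mask(model)
  bc <- default_bc(n)
  bc$code[bmask] <- BC_FIXED
  bc$v_bc <- cbind(0, 0, -rate * (model$positions[, 3] - ctr[3]))
  bc$v_bc[!bmask, ] <- 0
  bc$hold_t <- t_load
  dt <- stable_dt(model)
  n_steps <- ceiling(2.2 * t_load / dt)
  out <- run_engine(model, bc = bc, dt = dt, n_steps = n_steps,
                    damping = 0.3, poro = FALSE, record_every = n_steps)
  a <- model$d * sqrt(2)
  p <- model$positions
  interior <- p[, 1] > min(p[, 1]) + 1.6 * a & p[, 1] < max(p[, 1]) - 1.6 * a &
    p[, 2] > min(p[, 2]) + 1.6 * a & p[, 2] < max(p[, 2]) - 1.6 * a &
    p[, 3] > min(p[, 3]) + 1.6 * a & p[, 3] < max(p[, 3]) - 1.6 * a
  # realized interior strain tensor, least-squares fitted from pair normal
  # strains (the boundary layer absorbs part of the nominal affine strain,
  # so the stress is compared with the strain the interior actually carries)
  kin <- pair_kinematics(model, out$pos)
  pint <- interior[model$pairs[, 1]] & interior[model$pairs[, 2]]
  nn <- kin$normal[pint, , drop = FALSE]
  X <- cbind(nn[, 1]^2, nn[, 2]^2, nn[, 3]^2,
             2 * nn[, 1] * nn[, 2], 2 * nn[, 1] * nn[, 3],
             2 * nn[, 2] * nn[, 3])
  epsv6 <- stats::lm.fit(X, kin$eps_n[pint])$coefficients
  sig6 <- colMeans(out$stress[interior, , drop = FALSE])
  tr_e <- sum(epsv6[1:3])
  tr_s <- sum(sig6[1:3])
  e_dev <- epsv6 - c(rep(tr_e / 3, 3), 0, 0, 0)
  s_dev <- sig6 - c(rep(tr_s / 3, 3), 0, 0, 0)
  dot6 <- function(u, v) sum(u[1:3] * v[1:3]) + 2 * sum(u[4:6] * v[4:6])
  K_meas <- (tr_s / 3) / tr_e
  G_meas <- dot6(s_dev, e_dev) / (2 * dot6(e_dev, e_dev))
  E_meas <- 9 * K_meas * G_meas / (3 * K_meas + G_meas)
  nu_meas <- (3 * K_meas - 2 * G_meas) / (2 * (3 * K_meas + G_meas))
  list(E = E_meas, nu = nu_meas,
       E_err = abs(E_meas - mat$E) / mat$E,
       nu_err = abs(nu_meas - mat$nu) / mat$nu,
       K = K_meas, G = G_meas, strain_fit = epsv6)
}

#' P-wave first-arrival speed
#'
#' A small velocity step applied to the -X face propagates down a laterally
#' confined bar; the arrival time at two gauge planes gives the wave speed,
#' compared with `sqrt((K + 4G/3)/rho)`. Gauges read interior elements and
#' the detection threshold sits above the small-amplitude precursor carried
#' by the surface-element skin, so the bulk front is measured.
#'
#' @param material material name or record (default copper).
#' @param n_cells cells along the bar.
#' @param cross cells across the bar.
#' @param d element diameter, m.
#' @param v0 step velocity, m/s.
#' @param threshold arrival detection fraction of `v0`.
#' @param materials material table.
#' @return list `cp_measured`, `cp_theory`, `rel_err`.
#' @export
wave_speed_check <- function(material = "Cu", n_cells = 30, cross = 9,
                             d = 400e-6, v0 = 0.05, threshold = 0.2,
                             materials = load_material_table()) {
  mat <- if (is.character(material)) materials[[material]] else material
  model <- homogeneous_block_model(mat, c(n_cells, cross, cross), d, materials)
  n <- nrow(model$positions)
  dm <- derived_moduli(mat)
  p <- model$positions
  a <- model$d * sqrt(2)
  face <- p[, 1] < min(p[, 1]) + 0.3 * a
  bc <- default_bc(n)
  # lateral rollers: plane-wave (uniaxial strain) propagation at the bulk
  # P-wave speed rather than the thin-bar speed sqrt(E/rho)
  on_yf <- p[, 2] < min(p[, 2]) + 0.3 * a | p[, 2] > max(p[, 2]) - 0.3 * a
  on_zf <- p[, 3] < min(p[, 3]) + 0.3 * a | p[, 3] > max(p[, 3]) - 0.3 * a
  bc$code <- ifelse(on_yf, BC_VY, 0L) + ifelse(on_zf, BC_VZ, 0L)
  bc$code[face] <- bc$code[face] + BC_VX
  bc$v_bc <- cbind(rep(v0, n), 0, 0)
  # gauges read interior elements of a plane (the under-coordinated surface
  # skin responds slightly differently from the bulk)
  core <- p[, 2] > min(p[, 2]) + 1.1 * a & p[, 2] < max(p[, 2]) - 1.1 * a &
    p[, 3] > min(p[, 3]) + 1.1 * a & p[, 3] < max(p[, 3]) - 1.1 * a
  gauge_at <- function(xg) {
    xs <- sort(unique(round(p[, 1] / (a / 2)) * a / 2))
    x0 <- xs[which.min(abs(xs - xg))]
    which(abs(p[, 1] - x0) < 0.1 * a & core)
  }
  Lx <- max(p[, 1]) - min(p[, 1])
  g1 <- gauge_at(min(p[, 1]) + Lx / 3)
  g2 <- gauge_at(min(p[, 1]) + 2 * Lx / 3)
  x1 <- mean(p[g1, 1]); x2 <- mean(p[g2, 1])
  dt <- stable_dt(model)
  t_end <- (0.85 * Lx) / dm$cp
  out <- run_engine(model, bc = bc, dt = dt, n_steps = ceiling(t_end / dt),
                    damping = 0, poro = FALSE, record_every = 1,
                    gauges = list(as.integer(g1), as.integer(g2)))
  arrive <- function(v) {
    idx <- which(v >= threshold * v0)[1]
    if (is.na(idx) || idx < 2) stop("wave did not arrive at a gauge", call. = FALSE)
    # linear interpolation of the crossing time
    f <- (threshold * v0 - v[idx - 1]) / (v[idx] - v[idx - 1])
    (idx - 1 + f) * dt
  }
  t1 <- arrive(out$gauges[[1]])
  t2 <- arrive(out$gauges[[2]])
  cp_meas <- (x2 - x1) / (t2 - t1)
  list(cp_measured = cp_meas, cp_theory = dm$cp,
       rel_err = abs(cp_meas - dm$cp) / dm$cp)
}

#' Exact undrained response
#'
#' Moves every element affinely through an isotropic compression with
#' sealed pores (no Darcy exchange) and compares the engine's pore pressure
#' with `dP = -alpha M deps_v`.
#'
#' @param material material name or record.
#' @param eps_v applied volumetric strain (negative = compression).
#' @param n_cells,d geometry controls.
#' @param materials material table.
#' @return list `P_measured`, `P_theory`, `rel_err`.
#' @export
undrained_check <- function(material = "Cancellous", eps_v = -1e-4,
                            n_cells = 4, d = 400e-6,
                            materials = load_material_table()) {
  mat <- if (is.character(material)) materials[[material]] else material
  model <- homogeneous_block_model(mat, n_cells, d, materials)
  model$props$trans[] <- 0  # sealed
  n <- nrow(model$positions)
  dt <- stable_dt(model)
  n_steps <- 200L
  rate <- (eps_v / 3) / (n_steps * dt)  # linear strain rate per axis
  ctr <- colMeans(model$positions)
  bc <- default_bc(n)
  bc$code[] <- BC_FIXED
  bc$v_bc <- rate * sweep(model$positions, 2, ctr)
  out <- run_engine(model, bc = bc, dt = dt, n_steps = n_steps,
                    damping = 0, poro = TRUE, record_every = n_steps)
  P_th <- undrained_pressure(mat, eps_v, model$fluid)
  # full-coordination elements: the strain fit (hence the storage term) is
  # exact there; rank-deficient edge fits are minimum-norm approximations
  deg <- tabulate(c(model$pairs[, 1], model$pairs[, 2]), nbins = n)
  P_me <- mean(out$P[deg == 12])
  list(P_measured = P_me, P_theory = P_th,
       rel_err = abs(P_me - P_th) / abs(P_th),
       spread = diff(range(out$P[deg == 12])) / abs(P_th))
}

#' Synthetic consolidation-test material
#'
#' A fast-draining stand-in used by the Terzaghi driver: tabulated tissue
#' permeabilities put consolidation times far beyond desk-scale step
#' budgets, and the analytic solution is permeability-invariant in the
#' dimensionless time, so a synthetic permeability verifies the same
#' physics.
#'
#' @param k_perm intrinsic permeability, m2.
#' @return an `osseo_material`.
#' @export
consolidation_test_material <- function(k_perm = 1e-14) {
  new_material("Consolidation test (synthetic)", rho = 1500, E = 1e9,
               nu = 0.3, Ks = 1e10, theta = 0.5, k_perm = k_perm)
}

#' One-dimensional column (chain) model
#'
#' A vertical chain of elements with purely axial bonds, element volume
#' `d^3` and facet area `d^2`: the exact one-dimensional discretization of
#' a laterally confined column (no free-surface skin). The pair closure
#' reduces to the confined modulus `K + 4G/3` and the Darcy exchange to the
#' continuum diffusion operator.
#'
#' @param material an `osseo_material`.
#' @param n_elem number of elements in the chain.
#' @param d element diameter, m.
#' @param fluid pore fluid.
#' @return an `osseo_model`-compatible list.
#' @export
column_chain_model <- function(material, n_elem = 32, d = 500e-6,
                               fluid = pore_fluid()) {
  n <- as.integer(n_elem)
  pos <- cbind(0, 0, (seq_len(n) - 0.5) * d)
  colnames(pos) <- c("x", "y", "z")
  pairs <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
  r0 <- rep(d, n - 1)
  dm <- derived_moduli(material)
  b <- suppressWarnings(biot_constants(material, fluid))
  M_fin <- if (is.finite(b$M)) b$M else 0
  cp_courant <- sqrt((dm$K + 4 * dm$G / 3 + b$alpha^2 * M_fin) / material$rho)
  V_elem <- d^3
  A_pair <- d^2
  trans <- (material$k_perm / fluid$eta_f) * A_pair / (r0 * V_elem)
  model <- list(
    positions = pos, d = d, region = rep("bulk", n),
    material = rep(material$name, n), pairs = pairs, r0 = r0,
    spec = list(Lx = d, Ly = d, Lz = n * d, d = d, phase = 1L, seed = 1L),
    fluid = fluid, V_elem = V_elem, A_pair = A_pair,
    props = list(
      G = rep(dm$G, n), K = rep(dm$K, n), alpha = rep(b$alpha, n),
      M = rep(M_fin, n), rho = rep(material$rho, n),
      mass = rep(material$rho * V_elem, n),
      sigma_y = rep(Inf, n), is_metal = rep(FALSE, n),
      k_perm = rep(material$k_perm, n), theta = rep(material$theta, n),
      cp = rep(cp_courant, n), trans = trans,
      A_pairs = rep(A_pair, n - 1),
      # axial-bond chain: volumetric fit weight is 1/2 per bond, so the
      # many-body closure constant is half the FCC value
      fb_scale = rep(0.5, n)))
  class(model) <- "osseo_model"
  model
}

#' Terzaghi consolidation benchmark
#'
#' A laterally confined saturated column is loaded by a constant top force
#' with a drained top surface; the excess pore-pressure profile at the
#' target dimensionless time is compared with the analytic series. The
#' column is the one-dimensional chain discretization of
#' [column_chain_model()].
#'
#' @param Tv dimensionless consolidation time at which to compare.
#' @param n_z elements along the column.
#' @param d element diameter, m.
#' @param sigma0 applied total stress, Pa.
#' @param mat column material (default the synthetic fast-draining one).
#' @param damping local damping (strong, quasi-static regime).
#' @return list with `rms_err` (RMS profile error as a fraction of the
#'   initial pressure), `P0_theory`, profile data.frame, `nsub`.
#' @export
terzaghi_check <- function(Tv = 0.3, n_z = 32, d = 500e-6, sigma0 = 0.5e6,
                           mat = consolidation_test_material(),
                           damping = 0.3) {
  fluid <- pore_fluid()
  model <- column_chain_model(mat, n_elem = n_z, d = d, fluid = fluid)
  n <- nrow(model$positions)
  p <- model$positions
  bc <- default_bc(n)
  bc$code <- rep(BC_VX + BC_VY, n)  # axial motion only
  bc$code[1] <- BC_FIXED            # sealed, fixed bottom
  bc$ext_fz[n] <- -sigma0 * model$A_pair
  bc$drained[n] <- TRUE             # loaded, drained top
  cv <- consolidation_coefficient(mat, fluid)
  H <- p[n, 3] - p[1, 3] + d / 2
  t_end <- Tv * H^2 / cv
  dt <- stable_dt(model)
  out <- run_engine(model, bc = bc, dt = dt, n_steps = ceiling(t_end / dt),
                    damping = damping, poro = TRUE, record_every = 1000)
  dm <- derived_moduli(mat)
  b <- biot_constants(mat, fluid)
  Kc <- dm$K + 4 * dm$G / 3
  P0 <- b$alpha * b$M / (Kc + b$alpha^2 * b$M) * sigma0
  zeta <- p[n, 3] - p[, 3]
  t_real <- out$steps_run * dt
  Pth <- P0 * terzaghi_profile(zeta, t_real, H, cv)
  rms <- sqrt(mean((out$P - Pth)^2)) / P0
  list(rms_err = rms, P0_theory = P0, nsub = out$nsub,
       profile = data.frame(zeta = zeta, P = out$P, P_theory = Pth),
       Tv = cv * t_real / H^2)
}

#' Elastic energy-conservation probe
#'
#' A free homogeneous block given a long-wavelength initial velocity field
#' evolves with no damping; total (kinetic + reconstructed strain) energy
#' drift is reported.
#'
#' @param material material name or record.
#' @param n_cells,d geometry controls.
#' @param n_steps steps at `dt = stable_dt / 2`.
#' @param v_amp velocity amplitude, m/s.
#' @return list `drift` (relative), `E0`, `E_end`, and momentum deviation.
#' @export
energy_drift_check <- function(material = "Cortical", n_cells = 6,
                               d = 400e-6, n_steps = 10000, v_amp = 0.01) {
  model <- homogeneous_block_model(material, n_cells, d)
  n <- nrow(model$positions)
  z <- model$positions[, 3]
  vel0 <- cbind(v_amp * sin(pi * (z - min(z)) / (max(z) - min(z))), 0,
                v_amp * sin(pi * (z - min(z)) / (max(z) - min(z))))
  dt <- stable_dt(model) / 2
  out <- run_engine(model, dt = dt, n_steps = n_steps, damping = 0,
                    poro = FALSE, record_every = 50, vel0 = vel0)
  E <- out$KE + out$U_pair
  mom <- out$momentum
  p0 <- c(mom$px[1], mom$py[1], mom$pz[1])
  pd <- max(abs(mom$px - p0[1]), abs(mom$py - p0[2]), abs(mom$pz - p0[3]))
  scale <- sum(model$props$mass) * v_amp
  list(drift = abs(E[length(E)] - E[1]) / E[1], E0 = E[1],
       E_end = E[length(E)], momentum_dev = pd / scale)
}

#' Run the analytic verification suite
#'
#' @param suites which oracles to run.
#' @return data.frame `suite`, `metric`, `tol`, `pass`.
#' @export
verify_suite <- function(suites = c("modulus", "wave", "undrained",
                                    "terzaghi", "energy")) {
  rows <- list()
  add <- function(name, metric, tol)
    rows[[length(rows) + 1]] <<- data.frame(
      suite = name, metric = metric, tol = tol, pass = metric <= tol)
  for (s in suites) {
    if (s == "modulus") {
      r <- modulus_recovery("Cortical")
      add("modulus E", r$E_err, 0.03)
      add("modulus nu", r$nu_err, 0.03)
    } else if (s == "wave") {
      add("wave speed", wave_speed_check()$rel_err, 0.05)
    } else if (s == "undrained") {
      add("undrained dP", undrained_check()$rel_err, 1e-8)
    } else if (s == "terzaghi") {
      add("terzaghi rms", terzaghi_check()$rms_err, 0.05)
    } else if (s == "energy") {
      add("energy drift", energy_drift_check()$drift, 0.01)
    } else {
      stop(sprintf("unknown verification suite '%s'", s), call. = FALSE)
    }
  }
  do.call(rbind, rows)
}
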