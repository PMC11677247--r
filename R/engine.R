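#' Explicit-dynamics engine interface
#'
#' The compiled core integrates Newton-Euler motion of the bonded FCC
#' element lattice. Pair response follows the many-body closure
#' `sigma_n = 2G eps_n + (1 - 2G/(3K)) sigma_eff - alpha P` per element side
#' (harmonic-style combination across dissimilar pairs), where
#' `sigma_eff = K eps_v` is the effective (skeleton) mean stress evaluated
#' from the element's local strain tensor, least-squares fitted from its
#' pair normal strains each step (tension-positive stress,
#' compression-positive pore pressure). The fit is exact for affine
#' deformation at any coordination number, so the closure reproduces
#' isotropic linear poroelasticity in the uniform limit, free surfaces
#' included. Element stress tensors follow from the fitted strain through
#' the material law.
#'
#' @name engine
NULL

# bc bitmask codes used by the compiled core
BC_FREE <- 0L; BC_VX <- 1L; BC_VY <- 2L; BC_VZ <- 4L
BC_FIXED <- 7L; BC_WAVE <- 8L; BC_RAMP <- 16L

#' Stable explicit timestep
#'
#' `dt = C * d / max(cp)` over the materials present (Courant condition on
#' the fastest P-wave crossing one element).
#'
#' @param model an `osseo_model` (or any list with `d` and `props$cp`).
#' @param C Courant safety factor, default 0.2.
#' @return timestep in seconds.
#' @export
stable_dt <- function(model, C = 0.2) {
  if (!is.numeric(C) || C <= 0) stop("Courant factor C must be positive", call. = FALSE)
  C * model$d / max(model$props$cp)
}

#' Pair kinematics
#'
#' Normal strain `(r - r0)/r0` (tension positive) and the shear-strain
#' increment implied by the relative tangential slip of the contact points
#' (element rotations included; rigid-body motion produces none).
#'
#' @param model an `osseo_model`.
#' @param positions current positions (defaults to reference positions).
#' @param vel,omega element velocities and spins (N x 3).
#' @param gamma accumulated pair shear strain vectors (M x 3).
#' @param dt increment over which slip velocities act, s.
#' @return list `eps_n`, `r`, `normal`, `gamma`.
#' @export
pair_kinematics <- function(model, positions = model$positions,
                            vel = NULL, omega = NULL, gamma = NULL, dt = 0) {
  n <- nrow(model$positions)
  m <- nrow(model$pairs)
  if (is.null(vel)) vel <- matrix(0, n, 3)
  if (is.null(omega)) omega <- matrix(0, n, 3)
  if (is.null(gamma)) gamma <- matrix(0, m, 3)
  cpp_kinematics_step(positions, model$pairs, model$r0, gamma, vel, omega, dt)
}

#' Element stress state from pair strains
#'
#' Evaluates the pair closure and the strain-fit element stress tensors on
#' a given pair strain state.
#'
#' @param model an `osseo_model`.
#' @param eps_n pair normal strains.
#' @param gamma pair shear strain vectors (M x 3).
#' @param normal pair unit normals; defaults to reference geometry.
#' @param P pore pressures (Pa, compression positive).
#' @return list `sbar`, `vm`, `eps_v`, `sig_n`, `tau`, `stress`
#'   (N x 6: xx yy zz xy xz yz).
#' @export
closure_stress <- function(model, eps_n, gamma = NULL, normal = NULL,
                           P = NULL) {
  n <- nrow(model$positions)
  m <- nrow(model$pairs)
  if (is.null(gamma)) gamma <- matrix(0, m, 3)
  if (is.null(P)) P <- numeric(n)
  if (is.null(normal)) {
    kin <- pair_kinematics(model)
    normal <- kin$normal
    r_now <- kin$r
  } else {
    r_now <- model$r0 * (1 + eps_n)
  }
  A_pairs <- if (!is.null(model$props$A_pairs)) model$props$A_pairs
    else rep(model$A_pair, m)
  fb <- if (!is.null(model$props$fb_scale)) model$props$fb_scale else rep(1, n)
  cpp_closure_stress(model$pairs, r_now, normal, eps_n, gamma,
                     model$props$G, model$props$K, model$props$alpha, P,
                     model$props$sigma_y, A_pairs, fb, model$V_elem, n)
}

#' Radial-return plastic correction
#'
#' If the von Mises stress exceeds the yield stress, deviatoric stresses are
#' scaled by `sigma_y / vm` (mean stress unchanged). Materials without a
#' yield stress (tissues, `sigma_y = Inf`) are never rescaled.
#'
#' @param vm von Mises stress, Pa.
#' @param sigma_y yield stress, Pa (`Inf` for non-plastic materials).
#' @return list `scale` (deviatoric scaling factor) and `vm` (corrected).
#' @export
plastic_return <- function(vm, sigma_y) {
  scale <- ifelse(is.finite(sigma_y) & vm > sigma_y, sigma_y / vm, 1)
  list(scale = scale, vm = vm * scale)
}

#' Mean stress and von Mises stress of packed tensors
#'
#' @param stress N x 6 matrix (xx, yy, zz, xy, xz, yz).
#' @return numeric vector.
#' @export
mean_stress <- function(stress) rowMeans(stress[, 1:3, drop = FALSE])

#' @rdname mean_stress
#' @export
von_mises <- function(stress) {
  s <- stress
  sqrt(pmax(0, 0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                        (s[, 3] - s[, 1])^2) +
              3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2)))
}

default_drivers <- function() {
  list(wave_V = 0, wave_t_rise = 1e-8, wave_t_hold = 1e-7,
       wave_t_rec = 3e-7, wave_V_rec = 0,
       wave_period = 1e-6, wave_n_pulses = 0L,
       ramp_v = 0, ramp_t_start = 0, ramp_target = 0, ramp_u_max = 0.5e-3,
       ramp_smooth_steps = 1L, ramp_hold_steps = 0L)
}

default_bc <- function(n) {
  list(code = integer(n), v_bc = matrix(0, n, 3), hold_t = Inf,
       ext_fz = numeric(n), drained = logical(n), absorb_c = numeric(n))
}

#' Low-level engine run
#'
#' Assembles the boundary-condition, driver and control structures and runs
#' the compiled explicit integrator. Higher-level drivers
#' ([simulate_eswt()], [simulate_physio()]) are built on this.
#'
#' @param model an `osseo_model`.
#' @param bc boundary conditions (see `default_bc`); modified entries may be
#'   passed in `...` style via the `bc` list.
#' @param drivers loading drivers (see `default_drivers`).
#' @param dt timestep, s; default [stable_dt()].
#' @param n_steps number of steps.
#' @param damping local non-viscous damping coefficient in [0, 1).
#' @param poro enable pore-fluid coupling.
#' @param record_every sampling cadence in steps.
#' @param zone_idx element indices whose fields are recorded each sample.
#' @param gauges list of element index vectors; mean x-velocity is recorded.
#' @param vel0 initial velocities (N x 3).
#' @param P0 initial pore pressures.
#' @return raw run list from the compiled core (fields, histories, trackers).
#' @export
run_engine <- function(model, bc = NULL, drivers = NULL,
                       dt = stable_dt(model), n_steps,
                       damping = 0, poro = TRUE,
                       record_every = 10, zone_idx = integer(0),
                       gauges = list(), vel0 = NULL, P0 = NULL) {
  n <- nrow(model$positions)
  bc_full <- default_bc(n)
  if (!is.null(bc)) bc_full[names(bc)] <- bc
  dr_full <- default_drivers()
  if (!is.null(drivers)) dr_full[names(drivers)] <- drivers
  if (damping < 0 || damping >= 1)
    stop("damping coefficient must be in [0, 1)", call. = FALSE)
  props <- list(G = model$props$G, K = model$props$K,
                alpha = model$props$alpha, M = model$props$M,
                mass = model$props$mass, sigma_y = model$props$sigma_y,
                trans = model$props$trans, is_metal = model$props$is_metal,
                A_pairs = if (!is.null(model$props$A_pairs)) model$props$A_pairs
                  else rep(model$A_pair, nrow(model$pairs)),
                fb_scale = if (!is.null(model$props$fb_scale))
                  model$props$fb_scale else rep(1, n),
                H_scale = if (!is.null(model$props$H_scale))
                  model$props$H_scale else rep(1, nrow(model$pairs)),
                V_elem = model$V_elem, d = model$d)
  ctrl <- list(dt = dt, n_steps = as.integer(n_steps), damping = damping,
               poro = poro,
               record_every = as.integer(record_every),
               zone_idx = as.integer(zone_idx), gauges = gauges,
               record_zone = length(zone_idx) > 0, vel0 = vel0, P0 = P0)
  dr_full$wave_n_pulses <- as.integer(dr_full$wave_n_pulses)
  dr_full$ramp_smooth_steps <- as.integer(dr_full$ramp_smooth_steps)
  dr_full$ramp_hold_steps <- as.integer(dr_full$ramp_hold_steps)
  out <- cpp_run(model$positions, model$pairs, model$r0, props, bc_full,
                 dr_full, ctrl)
  out$dt <- dt
  out
}

#' Simulate a shock-wave exposure
#'
#' Drives the applicator plate along +X with the ESWT pulse-train waveform;
#' the base layer is held fixed. ESWT runs use zero bulk damping. The
#' lateral block faces are cuts through the surrounding mandible, so they
#' carry impedance-matched absorbing dashpots by default (radiation into
#' the bone beyond the segment); the gingival top surface stays free. The
#' face patch bonded to the applicator is excluded from the absorber.
#'
#' @param model an `osseo_model` (must contain applicator elements).
#' @param protocol an [eswt_protocol()].
#' @param t_extra extra simulated time after the last pulse, s.
#' @param absorbing absorb outgoing waves on the lateral cut faces.
#' @param dt,record_every numerical controls.
#' @return an `osseo_run` with zone field samples and shear trackers.
#' @export
simulate_eswt <- function(model, protocol = eswt_protocol(EFD = 0.15),
                          t_extra = 1e-6, absorbing = TRUE,
                          dt = stable_dt(model),
                          record_every = 5) {
  n <- nrow(model$positions)
  bc <- default_bc(n)
  app <- which(model$region == "applicator")
  if (length(app) == 0) stop("model has no applicator elements", call. = FALSE)
  bc$code[app] <- BC_WAVE
  bc$code[model$region == "base"] <- BC_FIXED
  if (isTRUE(absorbing)) {
    p <- model$positions
    sp <- model$spec
    tol <- 0.45 * model$d
    face <- (p[, 1] < tol | p[, 1] > sp$Lx - model$d |
               p[, 2] < tol | p[, 2] > sp$Ly - tol) &
      model$region != "applicator" & model$region != "base"
    # keep the source path live: no dashpots where the plate is bonded
    ap <- p[app, , drop = FALSE]
    near_plate <- p[, 1] > sp$Lx - model$d &
      p[, 2] > min(ap[, 2]) - model$d & p[, 2] < max(ap[, 2]) + model$d &
      p[, 3] > min(ap[, 3]) - model$d & p[, 3] < max(ap[, 3]) + model$d
    face <- face & !near_plate
    Z <- model$props$rho * model$props$cp
    bc$absorb_c[face] <- Z[face] * model$d^2
  }
  drivers <- list(wave_V = protocol$V, wave_t_rise = protocol$t_rise,
                  wave_t_hold = protocol$t_hold,
                  wave_t_rec = protocol$t_recover,
                  wave_V_rec = protocol$V_rec,
                  wave_period = protocol$period,
                  wave_n_pulses = protocol$n_pulses)
  t_total <- protocol$n_pulses * protocol$period + t_extra
  zone <- shell_zone_mask(model)
  out <- run_engine(model, bc = bc, drivers = drivers, dt = dt,
                    n_steps = ceiling(t_total / dt), damping = 0,
                    poro = TRUE,
                    record_every = record_every, zone_idx = zone)
  out$zone_idx <- zone
  out$zone_alpha <- model$props$alpha[zone]
  out$protocol <- protocol
  out$model_summary <- summarize_model(model)
  class(out) <- "osseo_run"
  out
}

#' Simulate physiological (occlusal) loading
#'
#' The whole top element layer moves down at the protocol ramp velocity
#' until the (smoothed) reaction force reaches the target, after which the
#' layer is held fixed. Physiological runs use local damping 0.05 to reach
#' the quasi-static regime; the reaction history is smoothed over a short
#' window before target-crossing detection, and the secant displacement is
#' corrected for the half-window lag of that running mean.
#'
#' @param model an `osseo_model`.
#' @param protocol a [physio_protocol()].
#' @param damping local damping coefficient.
#' @param dt,record_every numerical controls.
#' @return an `osseo_run` with force/displacement histories and
#'   `stiffness_kN_mm`, the secant stiffness at the target.
#' @export
simulate_physio <- function(model, protocol = physio_protocol(target = 100),
                            damping = 0.05, dt = stable_dt(model),
                            record_every = 20) {
  if (protocol$v <= 0) stop("ramp velocity must be positive", call. = FALSE)
  n <- nrow(model$positions)
  bc <- default_bc(n)
  zmax <- max(model$positions[model$region != "applicator", 3])
  dz <- if (!is.null(model$pitch)) model$pitch[3] else model$d / sqrt(2)
  top <- which(model$positions[, 3] > zmax - 0.45 * dz &
                 model$region != "applicator")
  bc$code[top] <- BC_RAMP
  bc$code[model$region == "base"] <- BC_FIXED
  smooth_w <- max(1L, as.integer(round(protocol$t_smooth / dt)))
  drivers <- list(ramp_v = -protocol$v, ramp_t_start = protocol$t_start,
                  ramp_target = protocol$target, ramp_u_max = protocol$u_max,
                  ramp_smooth_steps = smooth_w,
                  ramp_hold_steps = smooth_w)
  n_steps <- ceiling((protocol$u_max / protocol$v + protocol$t_start) / dt) + 10L
  zone <- tryCatch(shell_zone_mask(model), error = function(e) integer(0))
  out <- run_engine(model, bc = bc, drivers = drivers, dt = dt,
                    n_steps = n_steps, damping = damping,
                    poro = TRUE,
                    record_every = record_every, zone_idx = zone)
  if (!isTRUE(out$ramp_reached))
    stop(sprintf("physiological target %g N not reached within %g mm ramp",
                 protocol$target, protocol$u_max * 1e3), call. = FALSE)
  # correct the secant displacement for the running-mean lag (window/2)
  u_sec <- out$u_ramp_at_target <- out$u_at_target -
    protocol$v * (smooth_w - 1) / 2 * dt
  out$stiffness_kN_mm <- protocol$target / u_sec / 1e6
  out$top_idx <- top
  out$zone_idx <- zone
  out$zone_alpha <- model$props$alpha[zone]
  out$protocol <- protocol
  out$model_summary <- summarize_model(model)
  class(out) <- "osseo_run"
  out
}

summarize_model <- function(model) {
  list(n = nrow(model$positions), d = model$d, phase = model$spec$phase,
       regions = table(model$region))
}

#' @export
print.osseo_run <- function(x, ...) {
  cat(sprintf("<osseo_run> %d elements, %d steps, dt = %.3g s\n",
              x$model_summary$n, x$steps_run, x$dt))
  if (!is.null(x$stiffness_kN_mm))
    cat(sprintf("  secant stiffness %.3f kN/mm at %g N\n",
                x$stiffness_kN_mm, x$protocol$target))
  if (!is.null(x$max_zone_pair_shear))
    cat(sprintf("  max peri-implant pair shear strain %.4g %%\n",
                100 * x$max_zone_pair_shear))
  invisible(x)
}
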