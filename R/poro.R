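#' Biot pore-fluid coupling
#'
#' Pore pressure per element evolves with the volumetric strain rate
#' (storage term) and inter-element Darcy exchange:
#' `dP_i/dt = M_i (-alpha_i deps_v/dt + sum_j T_ij (P_j - P_i))`,
#' with compression-positive pressure. The pressure feeds back into the
#' effective mean stress `sigma_eff = sigma_bar + alpha P` used by the pair
#' closure. Metals carry no pore pressure and are impermeable.
#'
#' @name poro
NULL

#' Two-point Darcy transmissibility of a pair
#'
#' `T = (k_harm / eta_f) A_pair / (L V)`, with `k_harm` the harmonic mean of
#' the two intrinsic permeabilities. Pairs involving a metal element
#' (implant, applicator) are impermeable (`T = 0`).
#'
#' @param m1,m2 `osseo_material` records of the two elements.
#' @param fluid an `osseo_fluid`.
#' @param A_pair contact facet area, m2.
#' @param L center distance, m.
#' @param V element volume, m3.
#' @return transmissibility, 1/(Pa s).
#' @export
pair_transmissibility <- function(m1, m2, fluid = pore_fluid(),
                                  A_pair, L, V) {
  if (m1$is_metal || m2$is_metal) return(0)
  k_h <- 2 * m1$k_perm * m2$k_perm / max(m1$k_perm + m2$k_perm, 1e-300)
  (k_h / fluid$eta_f) * A_pair / (L * V)
}

#' Pore-pressure rate
#'
#' Reference (vectorized R) evaluation of the storage equation; the
#' compiled engine integrates the same expression explicitly with automatic
#' diffusion sub-cycling.
#'
#' @param P pore pressures, Pa.
#' @param deps_v_dt volumetric strain rates, 1/s.
#' @param pairs two-column pair index matrix.
#' @param trans pair transmissibilities, 1/(Pa s).
#' @param alpha,M Biot coefficient and modulus per element.
#' @return dP/dt per element, Pa/s.
#' @export
pore_pressure_rate <- function(P, deps_v_dt, pairs, trans, alpha, M) {
  n <- length(P)
  flux <- numeric(n)
  if (nrow(pairs) > 0) {
    f <- trans * (P[pairs[, 2]] - P[pairs[, 1]])
    flux <- as.numeric(
      tapply(c(f, -f), factor(c(pairs[, 1], pairs[, 2]), levels = 1:n),
             sum, default = 0))
  }
  M * (-alpha * deps_v_dt + flux)
}

#' Effective mean stress
#'
#' `sigma_eff = sigma_bar + alpha P` with tension-positive mean stress and
#' compression-positive pore pressure.
#'
#' @param sbar total mean stress, Pa.
#' @param alpha Biot coefficient.
#' @param P pore pressure, Pa.
#' @return effective mean stress, Pa.
#' @export
effective_mean_stress <- function(sbar, alpha, P) sbar + alpha * P

#' Undrained pressure response
#'
#' Instantaneous (no-flow) pore-pressure change under a volumetric strain
#' increment: `dP = -alpha M deps_v`.
#'
#' @param m an `osseo_material`.
#' @param deps_v volumetric strain increment (negative in compression).
#' @param fluid an `osseo_fluid`.
#' @return pressure change, Pa.
#' @export
undrained_pressure <- function(m, deps_v, fluid = pore_fluid()) {
  b <- biot_constants(m, fluid)
  -b$alpha * b$M * deps_v
}

#' Consolidation coefficient
#'
#' `c_v = (k/eta) (K + 4G/3) M / ((K + 4G/3) + alpha^2 M)` of a saturated
#' material column under uniaxial strain.
#'
#' @param m an `osseo_material`.
#' @param fluid an `osseo_fluid`.
#' @return consolidation coefficient, m2/s.
#' @export
consolidation_coefficient <- function(m, fluid = pore_fluid()) {
  dm <- derived_moduli(m)
  b <- biot_constants(m, fluid)
  Kc <- dm$K + 4 * dm$G / 3
  (m$k_perm / fluid$eta_f) * Kc * b$M / (Kc + b$alpha^2 * b$M)
}

#' Terzaghi one-dimensional consolidation series
#'
#' Analytic excess-pressure profile `P(zeta, t)/P0` for a column drained at
#' `zeta = 0` and sealed at `zeta = H`.
#'
#' @param zeta depth below the drained boundary, m.
#' @param t time since load application, s.
#' @param H drainage path length, m.
#' @param cv consolidation coefficient, m2/s.
#' @param n_terms series terms.
#' @return normalized excess pressure in [0, 1].
#' @export
terzaghi_profile <- function(zeta, t, H, cv, n_terms = 200) {
  out <- numeric(length(zeta))
  Tv <- cv * t / H^2
  for (m in 0:(n_terms - 1)) {
    Mm <- (2 * m + 1) * pi / 2
    out <- out + (2 / Mm) * sin(Mm * zeta / H) * exp(-Mm^2 * Tv)
  }
  out
}
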