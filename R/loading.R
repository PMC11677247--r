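#' Loading protocols
#'
#' Two boundary-condition protocols drive the model: an extracorporeal
#' shock-wave (ESWT) pulse train applied through the copper applicator
#' plate, and a displacement-controlled physiological ramp on the occlusal
#' surface with a force target (100 N rest, 200 N mastication).
#'
#' @name loading
NULL

#' Convert energy flux density to peak applicator velocity
#'
#' Plane-wave energy balance `V = sqrt(EFD / (Z tau_eff))` with
#' `Z = rho cp` the acoustic impedance of the applicator material. The
#' effective pulse duration `tau_eff` used in the conversion is
#' configuration-exposed (default: the pulse period, 1 us).
#'
#' @param EFD energy flux density, mJ/mm2.
#' @param applicator applicator material (default copper from the package
#'   table).
#' @param tau_eff effective pulse duration, s.
#' @return peak velocity, m/s.
#' @export
efd_to_velocity <- function(EFD, applicator = NULL, tau_eff = 1e-6) {
  stopifnot(EFD > 0, tau_eff > 0)
  if (is.null(applicator)) applicator <- load_material_table()[["Cu"]]
  Z <- applicator$rho * derived_moduli(applicator)$cp
  sqrt((EFD * 1000) / (Z * tau_eff))  # 1 mJ/mm2 = 1000 J/m2
}

#' ESWT pulse-train protocol
#'
#' Within each period the prescribed applicator velocity rises as a
#' half-sine over `t_rise`, holds the peak for `t_hold`, and mirrors back
#' down over `t_rise` (the forward therapeutic stroke). By default a slower
#' recovery half-sine of equal displacement follows, so the head carries no
#' net displacement per period (a hand-held applicator oscillates; it does
#' not ratchet into the tissue). `n_pulses` periods total. The peak
#' velocity is set directly or derived from the energy flux density.
#'
#' @param EFD energy flux density, mJ/mm2 (studied range 0.01-0.5; a value
#'   outside it only warns).
#' @param V peak applicator velocity, m/s (overrides `EFD`).
#' @param t_rise velocity rise time, s.
#' @param t_hold peak hold time, s.
#' @param t_recover recovery-stroke duration, s; the default uses
#'   essentially the whole inter-pulse interval (the physical return of the
#'   hand-held head is far slower than the pulse itself, so the model
#'   return is made as slow as the pulse period permits).
#' @param retract include the recovery stroke (`FALSE` gives the one-sided
#'   forward-only waveform, which leaves a static indentation).
#' @param period pulse period (start-to-start), s.
#' @param n_pulses number of pulses.
#' @param tau_eff effective pulse duration for the EFD conversion, s.
#' @param applicator applicator material for the impedance.
#' @return an `osseo_eswt_protocol`.
#' @export
eswt_protocol <- function(EFD = NULL, V = NULL, t_rise = 0.01e-6,
                          t_hold = 0.1e-6,
                          t_recover = period - 2 * t_rise - t_hold - 0.05e-6,
                          retract = TRUE, period = 1e-6, n_pulses = 5,
                          tau_eff = 1e-6, applicator = NULL) {
  stopifnot(t_rise > 0, t_hold >= 0, period > 0, n_pulses >= 1)
  if (2 * t_rise + t_hold >= period)
    stop("pulse (2 t_rise + t_hold) longer than the period", call. = FALSE)
  if (retract && (t_recover <= 0 ||
                    2 * t_rise + t_hold + t_recover > period))
    stop("recovery stroke does not fit in the period", call. = FALSE)
  if (is.null(V)) {
    if (is.null(EFD)) stop("give either EFD or V", call. = FALSE)
    if (EFD < 0.01 || EFD > 0.5)
      warning(sprintf("EFD = %g mJ/mm2 outside the studied 0.01-0.5 range", EFD),
              call. = FALSE)
    V <- efd_to_velocity(EFD, applicator, tau_eff)
  }
  # recovery amplitude returning the forward-stroke displacement
  disp <- V * (4 * t_rise / pi + t_hold)
  V_rec <- if (retract) disp * pi / (2 * t_recover) else 0
  structure(list(EFD = EFD, V = V, t_rise = t_rise, t_hold = t_hold,
                 t_recover = t_recover, V_rec = V_rec, retract = retract,
                 period = period, n_pulses = as.integer(n_pulses),
                 tau_eff = tau_eff),
            class = "osseo_eswt_protocol")
}

#' Prescribed applicator velocity waveform
#'
#' @param t time(s), s (vectorized).
#' @param protocol an [eswt_protocol()].
#' @return velocity along +X, m/s.
#' @export
applicator_waveform <- function(t, protocol) {
  p <- protocol
  v <- numeric(length(t))
  active <- t >= 0 & t < p$n_pulses * p$period
  tp <- t[active] %% p$period
  va <- numeric(length(tp))
  up <- tp < p$t_rise
  va[up] <- p$V * sin(pi * tp[up] / (2 * p$t_rise))
  hold <- tp >= p$t_rise & tp < p$t_rise + p$t_hold
  va[hold] <- p$V
  down <- tp >= p$t_rise + p$t_hold & tp < 2 * p$t_rise + p$t_hold
  va[down] <- p$V * sin(pi * (2 * p$t_rise + p$t_hold - tp[down]) / (2 * p$t_rise))
  if (!is.null(p$V_rec) && p$V_rec != 0) {
    t_on <- 2 * p$t_rise + p$t_hold
    rec <- tp >= t_on & tp < t_on + p$t_recover
    va[rec] <- -p$V_rec * sin(pi * (tp[rec] - t_on) / p$t_recover)
  }
  v[active] <- va
  v
}

#' Delivered energy flux density of one pulse
#'
#' Estimates `Z * integral(v^2 dt)` over the forward (therapeutic) stroke,
#' with the documented shape correction `tau_eff / (t_rise + t_hold)`
#' (the half-sine ramps integrate to exactly one rise time in total, so the
#' forward stroke's effective on-time is `t_rise + t_hold`). The recovery
#' stroke models the slow return of the head and is not part of the
#' delivered pulse energy.
#'
#' @param protocol an [eswt_protocol()].
#' @param applicator applicator material for the impedance.
#' @param n_t quadrature points over the forward stroke.
#' @return delivered EFD, mJ/mm2.
#' @export
delivered_efd <- function(protocol, applicator = NULL, n_t = 20001) {
  if (is.null(applicator)) applicator <- load_material_table()[["Cu"]]
  Z <- applicator$rho * derived_moduli(applicator)$cp
  t_on <- 2 * protocol$t_rise + protocol$t_hold
  tt <- seq(0, t_on, length.out = n_t)
  v <- applicator_waveform(tt, protocol)
  J <- sum((v[-1]^2 + v[-n_t]^2) / 2) * (t_on / (n_t - 1))
  corr <- protocol$tau_eff / (protocol$t_rise + protocol$t_hold)
  Z * J * corr / 1000
}

#' Physiological loading protocol
#'
#' The occlusal boundary moves down at `v` until the reaction reaches the
#' target force (100 N rest, 200 N mastication), then is held fixed.
#'
#' @param target target reaction force, N.
#' @param v ramp speed, m/s.
#' @param t_start half-sine velocity start-up time, s (quasi-static driver).
#' @param t_smooth reaction-force smoothing window, s.
#' @param u_max abort displacement if the target is never reached, m.
#' @return an `osseo_physio_protocol`.
#' @export
physio_protocol <- function(target = 100, v = 0.1, t_start = 5e-6,
                            t_smooth = 5e-6, u_max = 0.5e-3) {
  if (!(target > 0)) stop("target force must be positive", call. = FALSE)
  if (!(v > 0)) stop("ramp velocity must be positive", call. = FALSE)
  structure(list(target = target, v = v, t_start = t_start,
                 t_smooth = t_smooth, u_max = u_max),
            class = "osseo_physio_protocol")
}
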