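#' Mechanobiological classification
#'
#' Threshold rules mapping the local mechanical state (mean stress, shear
#' strain, pore-fluid pressure) to tissue-differentiation fates:
#' osteoblast differentiation (intramembranous ossification) under small
#' stresses with low shear; fibroblast differentiation under tensile mean
#' stress above 0.15 MPa (0.7 MPa most favorable); chondrocyte
#' differentiation (endochondral route) under compressive stresses between
#' 0.15 and 2 MPa; no osteo/chondrogenesis below 3 kPa; cell migration
#' requires interstitial fluid pressure between 20 kPa and 2 MPa (68 kPa
#' most favorable); distortional strain between 0.05 and 1.1 % favors
#' fibrous/cartilaginous tissue.
#'
#' @name mechanobio
NULL

FATE_LEVELS <- c("quiescent", "osteogenic", "chondrogenic", "fibrogenic",
                 "overload")
TRANSPORT_LEVELS <- c("none", "sufficient", "optimal")

#' Mechanobiological thresholds
#'
#' All stresses in Pa (tension-positive mean stress, compression-positive
#' pore pressure), strains as fractions.
#'
#' @param osteo_min lower stress magnitude for any differentiation (3 kPa).
#' @param osteo_max osteogenic stress ceiling (0.15 MPa; 0.2 MPa is the
#'   applied-reading alternative).
#' @param chondro_max compressive limit of the chondrogenic band (2 MPa).
#' @param shear_split shear-strain split between osteogenic and
#'   fibro/chondrogenic response (5 %).
#' @param fibro_tension_min,fibro_tension_opt tensile onset and optimum of
#'   fibroblast differentiation (0.15, 0.7 MPa).
#' @param transport_min,transport_max,transport_opt pore-pressure band and
#'   optimum for cell migration (20 kPa, 2 MPa, 68 kPa).
#' @param transport_opt_factor width factor of the optimal band around
#'   `transport_opt`.
#' @param distortion_lo,distortion_hi,distortion_opt auxiliary distortional
#'   strain band (0.05 %, 1.1 %, 0.5 %).
#' @return an `osseo_thresholds` list.
#' @export
mechanobio_thresholds <- function(osteo_min = 3e3, osteo_max = 0.15e6,
                                  chondro_max = 2e6, shear_split = 0.05,
                                  fibro_tension_min = 0.15e6,
                                  fibro_tension_opt = 0.7e6,
                                  transport_min = 20e3, transport_max = 2e6,
                                  transport_opt = 68e3,
                                  transport_opt_factor = 2,
                                  distortion_lo = 0.05e-2,
                                  distortion_hi = 1.1e-2,
                                  distortion_opt = 0.5e-2) {
  stopifnot(osteo_min < osteo_max, osteo_max < chondro_max,
            transport_min < transport_opt, transport_opt < transport_max)
  structure(as.list(environment()), class = "osseo_thresholds")
}

#' Classify tissue-differentiation fate
#'
#' Decision order (tension-positive mean stress `sbar`, shear strain `shear`
#' as a fraction): magnitudes below 3 kPa are quiescent; tensile stress
#' beyond the osteogenic ceiling is fibrogenic; compression beyond 2 MPa is
#' overload; compression between the ceiling and 2 MPa is chondrogenic;
#' within the osteogenic band, shear at or below 5 % gives osteogenic,
#' larger shear gives chondrogenic (compressive side) or fibrogenic
#' (tensile side). Band boundaries are closed on the osteogenic side.
#'
#' @param sbar mean stress, Pa (vectorized).
#' @param shear shear strain, fraction (vectorized, recycled).
#' @param th an [mechanobio_thresholds()].
#' @return factor with levels quiescent, osteogenic, chondrogenic,
#'   fibrogenic, overload.
#' @export
classify_fate <- function(sbar, shear, th = mechanobio_thresholds()) {
  n <- max(length(sbar), length(shear))
  sbar <- rep_len(sbar, n)
  shear <- rep_len(shear, n)
  stopifnot(all(is.finite(sbar)), all(is.finite(shear)))
  out <- character(n)
  quiet <- abs(sbar) < th$osteo_min
  tens <- !quiet & sbar > th$osteo_max
  over <- !quiet & sbar < -th$chondro_max
  comp <- !quiet & !over & sbar < -th$osteo_max
  band <- !quiet & !tens & !over & !comp
  out[quiet] <- "quiescent"
  out[tens] <- "fibrogenic"
  out[over] <- "overload"
  out[comp] <- "chondrogenic"
  out[band & shear <= th$shear_split] <- "osteogenic"
  hi <- band & shear > th$shear_split
  out[hi & sbar < 0] <- "chondrogenic"
  out[hi & sbar >= 0] <- "fibrogenic"
  factor(out, levels = FATE_LEVELS)
}

#' Classify cell-transport adequacy from pore pressure
#'
#' Pressure within 20 kPa - 2 MPa is sufficient for cell migration;
#' additionally, pressures within a factor `transport_opt_factor` of the
#' 68 kPa optimum are flagged optimal.
#'
#' @param P pore pressure, Pa (compression positive; vectorized).
#' @param th an [mechanobio_thresholds()].
#' @return factor with levels none, sufficient, optimal.
#' @export
classify_transport <- function(P, th = mechanobio_thresholds()) {
  stopifnot(all(is.finite(P)))
  out <- rep("none", length(P))
  suff <- P >= th$transport_min & P <= th$transport_max
  out[suff] <- "sufficient"
  f <- th$transport_opt_factor
  out[suff & P >= th$transport_opt / f & P <= th$transport_opt * f] <- "optimal"
  factor(out, levels = TRANSPORT_LEVELS)
}

#' Auxiliary distortional-strain band
#'
#' Flags shear strains inside the 0.05-1.1 % band that contributes to
#' fibrous/cartilaginous tissue formation.
#'
#' @param shear shear strain, fraction.
#' @param th an [mechanobio_thresholds()].
#' @return logical vector.
#' @export
distortion_band <- function(shear, th = mechanobio_thresholds()) {
  shear >= th$distortion_lo & shear <= th$distortion_hi
}

#' Compressive boundary of the osteogenic fate
#'
#' Bisects the classifier over compressive mean-stress magnitude (at fixed
#' shear strain) until the osteogenic/non-osteogenic boundary is located.
#'
#' @param th an [mechanobio_thresholds()].
#' @param shear shear strain at which to probe, fraction.
#' @param tol bisection tolerance, Pa.
#' @return boundary magnitude, Pa (compressive).
#' @export
osteogenic_compressive_boundary <- function(th = mechanobio_thresholds(),
                                            shear = 0.01, tol = 1) {
  lo <- th$osteo_min  # osteogenic side
  hi <- th$chondro_max * 2  # safely beyond any osteogenic response
  if (classify_fate(-lo, shear, th) != "osteogenic")
    stop("no osteogenic response at the lower probe", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (classify_fate(-mid, shear, th) == "osteogenic") lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Time-averaged zone fractions of a label field
#'
#' Per time sample, the fraction of zone elements carrying each label; the
#' reported value is the arithmetic mean over samples. Fractions below the
#' reporting floor (default 5 %) are displayed as "<5%".
#'
#' @param labels factor matrix (samples x zone elements) or a single factor
#'   vector (one sample).
#' @param levels label levels; defaults to the levels of `labels`.
#' @param floor reporting floor as a fraction.
#' @return data.frame `label`, `fraction`, `display`; per-sample fractions
#'   in attribute `"per_sample"`.
#' @export
zone_fractions <- function(labels, levels = NULL, floor = 0.05) {
  if (is.factor(labels) || (is.character(labels) && !is.matrix(labels)))
    labels <- matrix(as.character(labels), nrow = 1)
  if (is.matrix(labels) && !is.character(labels))
    labels <- matrix(as.character(labels), nrow(labels), ncol(labels))
  if (is.null(levels)) levels <- sort(unique(as.character(labels)))
  if (nrow(labels) < 1 || ncol(labels) < 1)
    stop("need at least one sample and one zone element", call. = FALSE)
  per <- t(apply(labels, 1, function(row) {
    tab <- table(factor(row, levels = levels))
    as.numeric(tab) / length(row)
  }))
  if (length(levels) == 1) per <- t(per)
  colnames(per) <- levels
  frac <- colMeans(per)
  disp <- ifelse(frac < floor, sprintf("<%g%%", 100 * floor),
                 sprintf("%.1f%%", 100 * frac))
  out <- data.frame(label = levels, fraction = unname(frac),
                    display = unname(disp), row.names = NULL)
  attr(out, "per_sample") <- per
  out
}

#' Fate report of a simulation run
#'
#' Classifies the recorded peri-implant zone samples of an `osseo_run` into
#' tissue fates and transport adequacy and reports time-averaged volume
#' fractions.
#'
#' @param run an `osseo_run` with recorded zone fields.
#' @param th an [mechanobio_thresholds()].
#' @param floor reporting floor.
#' @param use_effective_stress classify on effective rather than total mean
#'   stress.
#' @param alpha,P zone Biot coefficients and pressures (taken from the run
#'   when `use_effective_stress`).
#' @return an `osseo_fate_report`: list with `fates`, `transport`
#'   (data.frames from [zone_fractions()]), `n_zone`, `n_samples`.
#' @export
fate_report <- function(run, th = mechanobio_thresholds(), floor = 0.05,
                        use_effective_stress = FALSE) {
  sb <- run$zone_sbar
  sh <- run$zone_shear
  P <- run$zone_P
  if (is.null(sb) || nrow(sb) == 0)
    stop("run has no recorded zone samples", call. = FALSE)
  if (use_effective_stress) {
    al <- if (!is.null(run$zone_alpha)) run$zone_alpha else 1
    sb <- sb + sweep(P, 2, rep_len(al, ncol(P)), "*")
  }
  ns <- nrow(sb)
  fates <- matrix(NA_character_, ns, ncol(sb))
  trans <- matrix(NA_character_, ns, ncol(sb))
  for (s in seq_len(ns)) {
    fates[s, ] <- as.character(classify_fate(sb[s, ], sh[s, ], th))
    trans[s, ] <- as.character(classify_transport(P[s, ], th))
  }
  fr <- zone_fractions(fates, levels = FATE_LEVELS, floor = floor)
  tr <- zone_fractions(trans, levels = TRANSPORT_LEVELS, floor = floor)
  suff <- sum(tr$fraction[tr$label %in% c("sufficient", "optimal")])
  out <- list(fates = fr, transport = tr, transport_sufficient = suff,
              n_zone = ncol(sb), n_samples = ns)
  class(out) <- "osseo_fate_report"
  out
}

#' @export
print.osseo_fate_report <- function(x, ...) {
  cat(sprintf("<fate report> %d zone elements, %d time samples\n",
              x$n_zone, x$n_samples))
  cat("tissue fates (time-averaged zone volume fractions):\n")
  print(x$fates, row.names = FALSE)
  cat(sprintf("transport (P in 20 kPa - 2 MPa): %.1f%% of zone\n",
              100 * x$transport_sufficient))
  invisible(x)
}
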