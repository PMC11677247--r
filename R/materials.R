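#' Material and fluid property registry
#'
#' Tissues are isotropic drained-elastic skeletons with Biot pore-fluid
#' coupling; metals (implant, applicator) are elastoplastic and non-porous.
#' Properties are stored internally in SI units (Pa, kg/m3, m2); the shipped
#' table file uses GPa / MPa as in the source tables and is converted on load.
#'
#' @name materials
NULL

.TISSUE_FIELDS <- c("name", "rho", "E", "nu", "Ks", "theta", "k")
.METAL_FIELDS <- c("name", "rho", "E", "nu", "sigma_y")

new_material <- function(name, rho, E, nu, Ks, theta, k_perm,
                         sigma_y = NA_real_, is_metal = FALSE) {
  m <- list(name = name, rho = rho, E = E, nu = nu, Ks = Ks,
            theta = theta, k_perm = k_perm, sigma_y = sigma_y,
            is_metal = is_metal)
  class(m) <- "osseo_material"
  validate_material(m)
  m
}

validate_material <- function(m) {
  stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
  if (!is.character(m$name) || !nzchar(m$name)) stopf("material needs a name")
  chk <- function(cond, what)
    if (!isTRUE(cond)) stopf("material '%s': non-physical %s", m$name, what)
  chk(is.finite(m$rho) && m$rho > 0, "density")
  chk(is.finite(m$E) && m$E > 0, "Young's modulus")
  chk(is.finite(m$nu) && m$nu > 0 && m$nu < 0.5, "Poisson ratio (need 0 < nu < 0.5)")
  chk(is.finite(m$Ks) && m$Ks > 0, "solid-grain bulk modulus")
  chk(is.finite(m$theta) && m$theta >= 0 && m$theta < 1, "porosity")
  chk(is.finite(m$k_perm) && m$k_perm >= 0, "permeability")
  K <- m$E / (3 * (1 - 2 * m$nu))
  if (K > m$Ks * (1 + 1e-12))
    stopf("material '%s': drained bulk modulus K=%.4g Pa exceeds grain modulus Ks=%.4g Pa",
          m$name, K, m$Ks)
  invisible(m)
}

#' @export
print.osseo_material <- function(x, ...) {
  cat(sprintf("<material> %s: rho=%g kg/m3, E=%g GPa, nu=%g", x$name,
              x$rho, x$E / 1e9, x$nu))
  if (x$is_metal) cat(sprintf(", sigma_y=%g MPa", x$sigma_y / 1e6))
  else cat(sprintf(", Ks=%g GPa, theta=%g, k=%g m2", x$Ks / 1e9, x$theta, x$k_perm))
  cat("\n")
  invisible(x)
}

#' Load the tissue/metal material table
#'
#' Reads a structured YAML table (tissue rows with `rho, E, nu, Ks, theta, k`;
#' metal rows with `rho, E, nu, sigma_y`) in table units (GPa, MPa, kg/m3, m2)
#' and returns a named list of SI-unit material records. With no argument the
#' table shipped with the package is used.
#'
#' @param path path to a YAML material table, or a list already parsed from one.
#' @return named list of `osseo_material` records plus attribute `fluid`
#'   (list `Kf`, `rho_f`, `eta_f` in SI units).
#' @export
load_material_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "materials.yaml", package = "osseowave")
  }
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(cfg$tissues) || is.null(cfg$metals))
    stop("material table must contain 'tissues' and 'metals' sections", call. = FALSE)
  need <- function(row, fields, kind) {
    miss <- setdiff(fields, names(row))
    if (length(miss))
      stop(sprintf("%s row '%s': missing field(s) %s", kind,
                   if (is.null(row$name)) "<unnamed>" else row$name,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  mats <- list()
  for (row in cfg$tissues) {
    need(row, .TISSUE_FIELDS, "tissue")
    mats[[row$name]] <- new_material(row$name, row$rho, row$E * 1e9, row$nu,
                                     row$Ks * 1e9, row$theta, row$k)
  }
  for (row in cfg$metals) {
    need(row, .METAL_FIELDS, "metal")
    mats[[row$name]] <- new_material(row$name, row$rho, row$E * 1e9, row$nu,
                                     # metals: treated as non-porous; Ks is
                                     # irrelevant, set >= K so validation holds
                                     Ks = 1e15, theta = 0, k_perm = 0,
                                     sigma_y = row$sigma_y * 1e6, is_metal = TRUE)
  }
  fl <- cfg$fluid
  if (is.null(fl)) fl <- list(Kf = 2.4, rho_f = 1000, eta_f = 1e-3)
  attr(mats, "fluid") <- pore_fluid(Kf = fl$Kf * 1e9, rho_f = fl$rho_f,
                                    eta_f = fl$eta_f)
  class(mats) <- "osseo_material_table"
  mats
}

#' Pore fluid description
#'
#' @param Kf fluid bulk modulus, Pa.
#' @param rho_f fluid density, kg/m3.
#' @param eta_f dynamic viscosity, Pa s.
#' @return list with class `osseo_fluid`.
#' @export
pore_fluid <- function(Kf = 2.4e9, rho_f = 1000, eta_f = 1e-3) {
  stopifnot(Kf > 0, rho_f > 0, eta_f > 0)
  structure(list(Kf = Kf, rho_f = rho_f, eta_f = eta_f), class = "osseo_fluid")
}

#' Derived elastic moduli and wave speed
#'
#' Standard isotropic identities: `G = E/(2(1+nu))`, `K = E/(3(1-2nu))`,
#' `cp = sqrt((K + 4G/3)/rho)` (P-wave speed of the drained skeleton).
#'
#' @param m an `osseo_material`.
#' @return list `G`, `K`, `cp` (SI units).
#' @export
derived_moduli <- function(m) {
  if (m$nu >= 0.5) stop("nu >= 0.5: incompressible limit not supported", call. = FALSE)
  G <- m$E / (2 * (1 + m$nu))
  K <- m$E / (3 * (1 - 2 * m$nu))
  cp <- sqrt((K + 4 * G / 3) / m$rho)
  list(G = G, K = K, cp = cp)
}

#' Biot coefficient and Biot modulus
#'
#' `alpha = 1 - K/Ks` and `1/M = theta/Kf + (alpha - theta)/Ks`. Metals are
#' non-porous and return `alpha = 0` with an effectively rigid storage
#' modulus. A handful of tabulated soft tissues have `alpha` marginally below
#' their porosity (a mild inconsistency of the published grain moduli); this
#' is reported as a warning, not an error, as long as the storage modulus
#' stays positive.
#'
#' @param m an `osseo_material`.
#' @param f an `osseo_fluid` (defaults to physiological salt water).
#' @return list `alpha`, `M` (Pa).
#' @export
biot_constants <- function(m, f = pore_fluid()) {
  if (m$is_metal) return(list(alpha = 0, M = Inf))
  K <- derived_moduli(m)$K
  alpha <- 1 - K / m$Ks
  invM <- m$theta / f$Kf + (alpha - m$theta) / m$Ks
  if (invM <= 0)
    stop(sprintf("material '%s': non-positive Biot storage modulus", m$name),
         call. = FALSE)
  if (alpha < m$theta - 1e-12)
    warning(sprintf("material '%s': Biot alpha (%.4f) below porosity (%.4f)",
                    m$name, alpha, m$theta), call. = FALSE)
  list(alpha = alpha, M = 1 / invM)
}

#' Region-to-material map for an osseointegration phase
#'
#' Phase 1 (osteoconduction): the peri-implant shell is filled with the
#' primary matrix (blood clot with fibrin fibers). Phase 2 (osteoinduction):
#' granulation tissue with a thin (0.25 mm) fibrous interface directly at the
#' implant. Phase 3 (remodeling): woven bone, with the fibrous interface kept
#' by default (configurable off).
#'
#' @param phase integer 1, 2 or 3.
#' @param fibrous_interface keep the 0.25 mm fibrous interface layer in
#'   phase 3 (ignored in phases 1-2).
#' @return named character vector mapping region labels to material names.
#' @export
phase_material_map <- function(phase, fibrous_interface = TRUE) {
  if (!(is.numeric(phase) && length(phase) == 1 && phase %in% 1:3))
    stop("phase must be 1, 2 or 3", call. = FALSE)
  map <- c(gingiva = "Gingiva", cortical = "Cortical", cancellous = "Cancellous",
           implant = "Ti-6Al-4V", applicator = "Cu",
           dentin = "Dentin", PDL = "PDL", base = "Cancellous")
  map["shell"] <- switch(phase, "Primary matrix", "Granulation", "Woven bone")
  map["fibrous_interface"] <- if (phase == 1) map[["shell"]]
    else if (phase == 3 && !fibrous_interface) map[["shell"]]
    else "Fibrous"
  map
}
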