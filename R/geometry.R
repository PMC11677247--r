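#' Synthetic model geometry
#'
#' Builds the particle packing and region labels of a layered mandibular
#' block with a cylindrical implant: gingiva over cortical over cancellous
#' tissue, a titanium implant inside a peri-implant healing shell, a fixed
#' base layer, and a copper shock-wave applicator plate beside the +X face.
#' Coordinates: Z vertical (occlusal load along -Z), X is the applicator
#' motion axis, origin at the block base corner, lengths in meters.
#'
#' @name geometry
NULL

#' Model geometry specification
#'
#' Defaults give the scaled desk benchmark: a 6 x 6 x 8 mm block with a
#' 2 mm radius implant and a 2.5 mm outer-radius healing shell (0.5 mm gap).
#' Full-scale layer thicknesses (gingiva 400 um, cortical 600 um), the
#' 0.25 mm fibrous interface and the 0.3 mm applicator plate thickness are
#' kept at their physical values at every scale.
#'
#' @param Lx,Ly,Lz block dimensions, m.
#' @param d automaton (element) diameter, m.
#' @param t_gingiva,t_cortical layer thicknesses from the top surface, m.
#' @param r_implant,L_implant implant radius and length (from the top), m.
#' @param r_shell outer radius of the peri-implant shell, m.
#' @param t_fibrous thickness of the fibrous interface sublayer (phases 2-3), m.
#' @param w_applicator applicator plate side; `NULL` = full-scale 7 mm,
#'   shrunk proportionally when the block face cannot hold it.
#' @param t_applicator applicator plate thickness, m.
#' @param applicator_z plate center height; `NULL` = implant mid-depth.
#' @param include_teeth add simplified dentin/PDL tooth cylinders.
#' @param phase osseointegration phase 1, 2 or 3.
#' @param fibrous_interface keep the fibrous interface in phase 3.
#' @param smooth_interfaces blend element properties across tissue interfaces
#'   by sub-cell volume fractions (reduces staircase discretization error).
#' @param seed integer seed recorded with the model.
#' @return an `osseo_spec` list.
#' @export
model_spec <- function(Lx = 6e-3, Ly = 6e-3, Lz = 8e-3, d = 400e-6,
                       t_gingiva = 400e-6, t_cortical = 600e-6,
                       r_implant = 2e-3, L_implant = 4e-3, r_shell = 2.5e-3,
                       t_fibrous = 0.25e-3,
                       w_applicator = NULL, t_applicator = 0.3e-3,
                       applicator_z = NULL,
                       include_teeth = FALSE, phase = 1,
                       fibrous_interface = TRUE, smooth_interfaces = TRUE,
                       seed = 1L) {
  spec <- list(Lx = Lx, Ly = Ly, Lz = Lz, d = d,
               t_gingiva = t_gingiva, t_cortical = t_cortical,
               r_implant = r_implant, L_implant = L_implant,
               r_shell = r_shell, t_fibrous = t_fibrous,
               w_applicator = w_applicator, t_applicator = t_applicator,
               applicator_z = applicator_z,
               include_teeth = include_teeth, phase = as.integer(phase),
               fibrous_interface = fibrous_interface,
               smooth_interfaces = smooth_interfaces, seed = as.integer(seed))
  class(spec) <- "osseo_spec"
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  if (!(spec$d > 0)) stop("element diameter must be positive", call. = FALSE)
  if (!(spec$r_shell > spec$r_implant))
    stop("shell outer radius must exceed implant radius", call. = FALSE)
  if (spec$t_gingiva + spec$t_cortical >= spec$Lz)
    stop("gingiva + cortical layers do not fit inside the block", call. = FALSE)
  if (!(spec$phase %in% 1:3)) stop("phase must be 1, 2 or 3", call. = FALSE)
  if (min(spec$Lx, spec$Ly, spec$Lz) < 3 * spec$d)
    stop("block smaller than 3 element diameters in some axis", call. = FALSE)
  if (2 * spec$r_shell > min(spec$Lx, spec$Ly))
    stop("shell does not fit inside the block", call. = FALSE)
  invisible(spec)
}

#' FCC lattice sites inside a half-open box
#'
#' Conventional-cell generation: 4 sites per cubic cell of edge `a`, sites
#' with coordinates in `[lo, hi)`.
#'
#' @param lo,hi numeric length-3 box corners, m.
#' @param a conventional lattice constant, m (`a = d * sqrt(2)` for spheres
#'   of diameter `d` in contact).
#' @return matrix of site coordinates (one row per site).
#' @export
fcc_sites <- function(lo, hi, a) {
  stopifnot(length(lo) == 3, length(hi) == 3, a > 0, all(hi > lo))
  offs <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
  idx <- lapply(1:3, function(k) {
    seq(floor(lo[k] / a) - 1L, ceiling(hi[k] / a) + 1L)
  })
  grid <- as.matrix(expand.grid(i = idx[[1]], j = idx[[2]], k = idx[[3]]))
  pos <- do.call(rbind, lapply(seq_len(nrow(offs)), function(r) {
    sweep(grid, 2, offs[r, ], "+") * a
  }))
  eps <- 1e-9 * a
  keep <- pos[, 1] >= lo[1] - eps & pos[, 1] < hi[1] - eps &
          pos[, 2] >= lo[2] - eps & pos[, 2] < hi[2] - eps &
          pos[, 3] >= lo[3] - eps & pos[, 3] < hi[3] - eps
  pos <- pos[keep, , drop = FALSE]
  colnames(pos) <- c("x", "y", "z")
  pos[order(pos[, 3], pos[, 2], pos[, 1]), , drop = FALSE]
}

#' Lattice plane pitches of a model specification
#'
#' Per-axis plane spacing: the natural FCC spacing `d/sqrt(2)` stretched by
#' at most a couple of percent so each block dimension is an exact integer
#' number of plane slabs. Every discretization of the same specification
#' then represents exactly the same physical box (no half-plane
#' quantization of the realized geometry).
#'
#' @param spec an `osseo_spec`.
#' @return numeric length-3 pitch vector, m.
#' @export
lattice_pitches <- function(spec) {
  h0 <- spec$d / sqrt(2)
  L <- c(spec$Lx, spec$Ly, spec$Lz)
  L / pmax(round(L / h0), 3)
}

# FCC sites on a per-axis stretched lattice with planes at (i + 1/2) * h
fcc_sites_pitched <- function(lo, hi, h) {
  stopifnot(length(lo) == 3, length(hi) == 3, length(h) == 3, all(h > 0))
  offs <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
  a <- 2 * h
  idx <- lapply(1:3, function(k) {
    seq(floor(lo[k] / a[k]) - 1L, ceiling(hi[k] / a[k]) + 1L)
  })
  grid <- as.matrix(expand.grid(i = idx[[1]], j = idx[[2]], k = idx[[3]]))
  pos <- do.call(rbind, lapply(seq_len(nrow(offs)), function(r) {
    sweep(sweep(grid, 2, offs[r, ], "+"), 2, a, "*")
  }))
  pos <- sweep(pos, 2, h / 2, "+")
  eps <- 1e-9 * max(a)
  keep <- pos[, 1] >= lo[1] - eps & pos[, 1] < hi[1] - eps &
          pos[, 2] >= lo[2] - eps & pos[, 2] < hi[2] - eps &
          pos[, 3] >= lo[3] - eps & pos[, 3] < hi[3] - eps
  pos <- pos[keep, , drop = FALSE]
  colnames(pos) <- c("x", "y", "z")
  pos[order(pos[, 3], pos[, 2], pos[, 1]), , drop = FALSE]
}

#' Build the particle packing of a model specification
#'
#' FCC lattice of touching spheres of diameter `d` filling the block (on
#' the [lattice_pitches()] lattice), plus the applicator plate sites
#' continuing the same lattice beyond the +X face. Neighbor pairs are
#' lattice contacts (center distance <= 1.05 d).
#'
#' @param spec an `osseo_spec`.
#' @return list `positions`, `pairs` (two-column index matrix), `r0`
#'   (reference pair distances), `n_block` (block sites come first),
#'   `pitch` (per-axis plane spacing).
#' @export
build_packing <- function(spec) {
  validate_spec(spec)
  h <- lattice_pitches(spec)
  pos <- fcc_sites_pitched(c(0, 0, 0), c(spec$Lx, spec$Ly, spec$Lz), h)
  app <- make_applicator(spec)
  n_block <- nrow(pos)
  if (nrow(app$positions) > 0) pos <- rbind(pos, app$positions)
  nb <- cpp_neighbor_pairs(pos, 1.05 * spec$d)
  list(positions = pos, pairs = nb$pairs, r0 = nb$r0, n_block = n_block,
       applicator_scaled = app$scaled, pitch = h)
}

# distance from an interior (implant) point to the implant surface
implant_inside_distance <- function(pts, spec) {
  rho <- sqrt((pts[, 1] - spec$Lx / 2)^2 + (pts[, 2] - spec$Ly / 2)^2)
  z_apex <- spec$Lz - spec$L_implant
  pmax(pmin(spec$r_implant - rho, pts[, 3] - z_apex), 0)
}

# distance from an exterior (tissue) point to the implant solid
implant_outside_distance <- function(pts, spec) {
  rho <- sqrt((pts[, 1] - spec$Lx / 2)^2 + (pts[, 2] - spec$Ly / 2)^2)
  z_apex <- spec$Lz - spec$L_implant
  dr <- pmax(rho - spec$r_implant, 0)
  dz <- pmax(z_apex - pts[, 3], 0)
  sqrt(dr^2 + dz^2)
}

# region of each point; applicator handled separately (sites beyond +X face)
region_at <- function(pts, spec, metals = TRUE) {
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  depth <- spec$Lz - z
  reg <- rep("cancellous", length(x))
  reg[depth <= spec$t_gingiva + 1e-12] <- "gingiva"
  reg[depth > spec$t_gingiva + 1e-12 &
      depth <= spec$t_gingiva + spec$t_cortical + 1e-12] <- "cortical"
  if (isTRUE(spec$include_teeth)) {
    for (cx in c(spec$Lx / 4, 3 * spec$Lx / 4)) {
      rr <- sqrt((x - cx)^2 + (y - spec$Ly / 2)^2)
      tooth <- z >= spec$Lz - spec$L_implant
      r_t <- min(1.5e-3, spec$Lx / 8)
      reg[tooth & rr <= r_t + 0.2e-3] <- "PDL"
      reg[tooth & rr <= r_t] <- "dentin"
    }
  }
  # distance to the implant solid (cylinder, flat apex, rounded edge)
  rho <- sqrt((x - spec$Lx / 2)^2 + (y - spec$Ly / 2)^2)
  z_apex <- spec$Lz - spec$L_implant
  dr <- pmax(rho - spec$r_implant, 0)
  dz <- pmax(z_apex - z, 0)
  dist <- sqrt(dr^2 + dz^2)
  gap <- spec$r_shell - spec$r_implant
  inside <- rho <= spec$r_implant & z >= z_apex
  shell <- !inside & dist <= gap + 1e-12
  reg[shell] <- "shell"
  if (spec$phase == 2 || (spec$phase == 3 && isTRUE(spec$fibrous_interface))) {
    reg[shell & dist <= spec$t_fibrous + 1e-12] <- "fibrous_interface"
  }
  if (metals) reg[inside] <- "implant"
  reg
}

#' Assign region labels to packed positions
#'
#' Top-down along Z: gingiva slab, cortical slab, cancellous below; implant
#' cylinder and the surrounding shell annulus (with the 0.25 mm fibrous
#' interface sublayer in phases 2-3); the lowest element layer is the fixed
#' base; sites beyond the +X face are the applicator.
#'
#' @param positions site matrix from [build_packing()].
#' @param spec the `osseo_spec`.
#' @return character vector of region labels.
#' @export
label_regions <- function(positions, spec) {
  reg <- region_at(positions, spec)
  reg[positions[, 1] > spec$Lx - 1e-12] <- "applicator"
  base <- positions[, 3] <= min(positions[, 3]) + 0.1 * spec$d
  reg[base & reg != "applicator"] <- "base"
  reg
}

#' Applicator plate element set
#'
#' A square copper plate (full scale 7 x 7 x 0.3 mm) adjacent to the +X
#' block face, occupying FCC sites that continue the tissue lattice, so
#' plate-tissue pairs exist at exactly their reference distance (no initial
#' contact force). On scaled blocks the plate side is shrunk proportionally
#' and the `scaled` flag records it.
#'
#' @param spec an `osseo_spec`.
#' @return list `positions`, `width` (realized side), `scaled` flag.
#' @export
make_applicator <- function(spec) {
  h <- lattice_pitches(spec)
  w_full <- 7e-3
  w <- spec$w_applicator
  if (is.null(w)) w <- min(w_full, min(spec$Ly, spec$Lz) / 2)
  scaled <- w < w_full
  zc <- spec$applicator_z
  if (is.null(zc)) zc <- spec$Lz - spec$L_implant / 2
  zc <- min(max(zc, w / 2), spec$Lz - w / 2 - 1e-12)
  box <- fcc_sites_pitched(
    c(spec$Lx, 0, 0),
    c(spec$Lx + spec$t_applicator + spec$d, spec$Ly, spec$Lz), h)
  if (nrow(box) == 0)
    return(list(positions = box, width = w, scaled = scaled))
  xs <- sort(unique(round(box[, 1] / (h[1] / 2)))) * h[1] / 2
  x0 <- xs[1]
  keep_x <- box[, 1] <= x0 + spec$t_applicator + 1e-12
  if (!any(keep_x)) keep_x <- abs(box[, 1] - x0) < 1e-12  # single-layer fallback
  if (spec$t_applicator < spec$d && sum(abs(xs - x0) <= spec$t_applicator) < 2)
    warning("applicator plate thinner than one element diameter at this ",
            "discretization; using a single element layer", call. = FALSE)
  keep <- keep_x &
    abs(box[, 2] - spec$Ly / 2) <= w / 2 + 1e-12 &
    abs(box[, 3] - zc) <= w / 2 + 1e-12
  list(positions = box[keep, , drop = FALSE], width = w, scaled = scaled)
}

#' Peri-implant zone mask
#'
#' Indices of elements in the peri-implant zone (shell plus fibrous
#' interface), the denominator of all reported volume fractions.
#'
#' @param model an `osseo_model`.
#' @return integer element indices.
#' @export
shell_zone_mask <- function(model) {
  idx <- which(model$region %in% c("shell", "fibrous_interface"))
  if (length(idx) == 0) stop("peri-implant zone is empty", call. = FALSE)
  idx
}

#' Build a complete simulation model
#'
#' Packs the geometry, labels regions, assigns phase materials and derives
#' all per-element mechanical and poroelastic constants. With
#' `smooth_interfaces` the elastic/poroelastic constants of tissue elements
#' are volume-fraction blends over a 3 x 3 x 3 sub-cell sample (Reuss
#' weighting for moduli, harmonic for permeability); metal elements stay
#' pure and tissue blends exclude metal regions.
#'
#' @param spec an `osseo_spec`.
#' @param materials material table from [load_material_table()].
#' @return an `osseo_model`.
#' @export
build_model <- function(spec, materials = load_material_table()) {
  pk <- build_packing(spec)
  pos <- pk$positions
  n <- nrow(pos)
  region <- label_regions(pos, spec)
  map <- phase_material_map(spec$phase, spec$fibrous_interface)
  mat_name <- unname(map[region])
  if (anyNA(mat_name)) stop("unmapped region label", call. = FALSE)
  fluid <- attr(materials, "fluid")

  per <- function(field) vapply(materials, `[[`, numeric(1), field)
  mprop <- data.frame(name = names(materials), rho = per("rho"), E = per("E"),
                      nu = per("nu"), Ks = per("Ks"), theta = per("theta"),
                      k = per("k_perm"),
                      sigma_y = vapply(materials, function(m)
                        if (m$is_metal) m$sigma_y else Inf, numeric(1)),
                      is_metal = vapply(materials, `[[`, logical(1), "is_metal"),
                      row.names = NULL)
  mi <- match(mat_name, mprop$name)
  E <- mprop$E[mi]; nu <- mprop$nu[mi]; rho <- mprop$rho[mi]
  Ks <- mprop$Ks[mi]; theta <- mprop$theta[mi]; kperm <- mprop$k[mi]
  sigy <- mprop$sigma_y[mi]; metal <- mprop$is_metal[mi]

  if (isTRUE(spec$smooth_interfaces)) {
    h <- spec$d / 2^(1 / 6)  # cube of the element cell volume d^3/sqrt(2)
    offs <- as.matrix(expand.grid(u = c(-1, 0, 1) / 3, v = c(-1, 0, 1) / 3,
                                  w = c(-1, 0, 1) / 3)) * h
    tiss <- which(!metal & region != "applicator" & pos[, 1] <= spec$Lx)
    if (length(tiss)) {
      invE <- invKs <- invk <- nu_s <- rho_s <- th_s <- wsum <- numeric(length(tiss))
      for (r in seq_len(nrow(offs))) {
        sub <- sweep(pos[tiss, , drop = FALSE], 2, offs[r, ], "+")
        sreg <- region_at(sub, spec)
        smat <- unname(map[sreg])
        smi <- match(smat, mprop$name)
        ok <- !mprop$is_metal[smi] &
          sub[, 3] >= 0 & sub[, 3] <= spec$Lz &
          sub[, 1] >= 0 & sub[, 1] <= spec$Lx &
          sub[, 2] >= 0 & sub[, 2] <= spec$Ly
        w <- as.numeric(ok)
        wsum <- wsum + w
        invE <- invE + w / mprop$E[smi]
        invKs <- invKs + w / mprop$Ks[smi]
        invk <- invk + w / pmax(mprop$k[smi], 1e-30)
        nu_s <- nu_s + w * mprop$nu[smi]
        rho_s <- rho_s + w * mprop$rho[smi]
        th_s <- th_s + w * mprop$theta[smi]
      }
      has <- wsum > 0
      ti <- tiss[has]
      E[ti] <- wsum[has] / invE[has]
      Ks[ti] <- wsum[has] / invKs[has]
      kperm[ti] <- wsum[has] / invk[has]
      nu[ti] <- nu_s[has] / wsum[has]
      rho[ti] <- rho_s[has] / wsum[has]
      theta[ti] <- th_s[has] / wsum[has]
    }
  }

  V_latt <- 2 * prod(pk$pitch)  # element cell volume of the pitched lattice
  G <- E / (2 * (1 + nu))
  K <- E / (3 * (1 - 2 * nu))
  alpha <- ifelse(metal, 0, 1 - K / Ks)
  invM <- ifelse(metal, 0, theta / fluid$Kf + (alpha - theta) / Ks)
  if (any(invM < 0 & !metal))
    invM[invM < 0 & !metal] <- theta[invM < 0 & !metal] / fluid$Kf
  Mb <- ifelse(metal, 0, 1 / invM)
  # Courant speed: undrained P-wave (Biot-stiffened) where pores are active
  cp <- sqrt((K + 4 * G / 3 + alpha^2 * Mb) / rho)

  V_elem <- V_latt
  A_pair <- V_elem / (2 * spec$d)
  # per-pair facet areas with surface correction: bonds of under-coordinated
  # (surface) elements represent proportionally larger Voronoi facets, so an
  # element's total facet area equals its full surface share at any depth
  i <- pk$pairs[, 1]; j <- pk$pairs[, 2]
  deg <- tabulate(c(i, j), nbins = n)
  A_pairs <- A_pair * (12 / pmax(deg[i], 1) + 12 / pmax(deg[j], 1)) / 2
  # two-point Darcy transmissibility per pair (zero across/into metal)
  k_h <- 2 * kperm[i] * kperm[j] / pmax(kperm[i] + kperm[j], 1e-300)
  trans <- (k_h / fluid$eta_f) * A_pairs / (pk$r0 * V_elem)
  trans[metal[i] | metal[j]] <- 0
  # series-spring partition of implant-tissue bonds at the analytic implant
  # surface: the soft segment length follows the true surface position, so
  # the realized implant radius varies continuously with discretization
  H_scale <- rep(1, nrow(pk$pairs))
  imp <- region == "implant"
  iface <- xor(imp[i], imp[j])
  if (any(iface)) {
    im <- ifelse(imp[i[iface]], i[iface], j[iface])
    ti <- ifelse(imp[i[iface]], j[iface], i[iface])
    din <- implant_inside_distance(pos[im, , drop = FALSE], spec)
    dout <- implant_outside_distance(pos[ti, , drop = FALSE], spec)
    f <- pmin(pmax(din / pmax(din + dout, 1e-12), 0.05), 0.95)
    Xm <- 2 * G[im]
    Xt <- 2 * G[ti]
    H_scale[iface] <- (0.5 / Xm + 0.5 / Xt) / (f / Xm + (1 - f) / Xt)
  }

  model <- list(
    positions = pos, d = spec$d, region = region, material = mat_name,
    pairs = pk$pairs, r0 = pk$r0, spec = spec, fluid = fluid,
    applicator_scaled = pk$applicator_scaled, pitch = pk$pitch,
    V_elem = V_elem, A_pair = A_pair,
    props = list(G = G, K = K, alpha = alpha, M = Mb, rho = rho,
                 mass = rho * V_elem, sigma_y = sigy, is_metal = metal,
                 k_perm = kperm, theta = theta, cp = cp, trans = trans,
                 A_pairs = A_pairs, H_scale = H_scale))
  class(model) <- "osseo_model"
  model
}

#' @export
print.osseo_model <- function(x, ...) {
  cat(sprintf("<osseo_model> %d elements (d = %g um), %d pairs, phase %d\n",
              nrow(x$positions), x$d * 1e6, nrow(x$pairs), x$spec$phase))
  print(table(x$region))
  invisible(x)
}
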