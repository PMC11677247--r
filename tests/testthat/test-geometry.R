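test_that("FCC site generation matches direct enumeration", {
  a <- 1e-3
  pos <- fcc_sites(c(0, 0, 0), c(2 * a, 2 * a, 2 * a), a)
  expect_equal(nrow(pos), 32)  # 4 sites/cell x 8 cells, half-open box
  # nearest-neighbor distance is d = a/sqrt(2); none closer than 0.95 d
  dmat <- as.matrix(dist(pos))
  diag(dmat) <- Inf
  expect_gte(min(dmat), 0.95 * a / sqrt(2))
  expect_equal(min(dmat), a / sqrt(2), tolerance = 1e-12)
})

test_that("interior elements have 12 lattice contacts", {
  m <- fix_block()
  deg <- tabulate(c(m$pairs[, 1], m$pairs[, 2]), nbins = nrow(m$positions))
  p <- m$positions
  a <- m$d * sqrt(2)
  interior <- apply(p, 1, function(r)
    all(r > apply(p, 2, min) + 0.8 * a & r < apply(p, 2, max) - 0.8 * a))
  expect_true(all(deg[interior] == 12))
  # brute-force distance scan on one interior element
  i <- which(interior)[1]
  dists <- sqrt(rowSums(sweep(p, 2, p[i, ])^2))
  expect_equal(sum(dists > 0 & dists <= 1.05 * m$d), 12)
  # neighbor list symmetric by construction (i < j each pair once)
  expect_true(all(m$pairs[, 1] < m$pairs[, 2]))
})

test_that("region labels partition the block with the stated layers", {
  m <- fix_model_500()
  sp <- m$spec
  expect_equal(sum(table(m$region)), nrow(m$positions))  # exhaustive
  p <- m$positions
  depth <- sp$Lz - p[, 3]
  rad <- sqrt((p[, 1] - sp$Lx / 2)^2 + (p[, 2] - sp$Ly / 2)^2)
  # a shallow element outside the shell is gingiva
  i <- which(depth < 0.35e-3 & rad > sp$r_shell + m$d &
               p[, 1] < sp$Lx & m$region != "base")[1]
  expect_equal(m$region[i], "gingiva")
  # radial distance 2.2 mm inside the implant depth range is shell (phase 1)
  j <- which(abs(rad - 2.2e-3) < 0.2e-3 & depth > 1.5e-3 &
               depth < sp$L_implant - 0.5e-3)[1]
  expect_equal(m$region[j], "shell")
  # the lowest layer is the fixed base
  expect_true(all(m$region[p[, 3] < min(p[, 3]) + 0.1 * m$d] %in%
                    c("base", "applicator")))
  # phase 2 adds the fibrous interface inside the shell
  m2 <- suppressWarnings(build_model(model_spec(d = 500e-6, phase = 2),
                                     fix_materials()))
  expect_true(any(m2$region == "fibrous_interface"))
  expect_true(all(c("shell", "fibrous_interface") %in% m2$region))
})

test_that("packing is deterministic and refines as d^-3", {
  s <- model_spec(d = 500e-6)
  p1 <- suppressWarnings(build_packing(s))
  p2 <- suppressWarnings(build_packing(s))
  expect_identical(p1$positions, p2$positions)
  expect_identical(p1$pairs, p2$pairs)
  s2 <- model_spec(d = 250e-6)
  p3 <- build_packing(s2)
  ratio <- nrow(p3$positions) / nrow(p1$positions)
  expect_gt(ratio, 6)   # halving d multiplies N by ~8
  expect_lt(ratio, 10)
})

test_that("applicator plate realizes the stated footprint", {
  # full-scale block carries the full 7 x 7 x 0.3 mm plate
  big <- model_spec(Lx = 20e-3, Ly = 20e-3, Lz = 16e-3, d = 500e-6,
                    L_implant = 8e-3)
  app <- suppressWarnings(make_applicator(big))
  expect_false(app$scaled)
  expect_equal(app$width, 7e-3)
  expect_lte(diff(range(app$positions[, 2])), 7e-3)
  expect_gte(diff(range(app$positions[, 2])), 7e-3 - 2 * big$d)
  expect_lte(diff(range(app$positions[, 1])), 20e-3 + 0.3e-3 + big$d)
  # scaled benchmark shrinks the plate proportionally and flags it
  bench <- model_spec(d = 400e-6)
  app2 <- make_applicator(bench)
  expect_true(app2$scaled)
  expect_equal(app2$width, 3e-3)
  # plate thinner than one element diameter: warning + single layer
  expect_warning(make_applicator(model_spec(d = 500e-6)), "single element")
  # no initial contact force: plate pairs sit at their reference distance
  m <- fix_model_500()
  kin <- pair_kinematics(m)
  app_idx <- which(m$region == "applicator")
  touches <- m$pairs[, 1] %in% app_idx | m$pairs[, 2] %in% app_idx
  expect_true(any(touches))  # bonded to the tissue face
  expect_lt(max(abs(kin$eps_n[touches])), 1e-12)
})

test_that("peri-implant zone mask covers shell plus fibrous interface", {
  m <- fix_model_500()
  z1 <- shell_zone_mask(m)
  expect_setequal(z1, which(m$region == "shell"))
  m2 <- suppressWarnings(build_model(model_spec(d = 500e-6, phase = 2),
                                     fix_materials()))
  z2 <- shell_zone_mask(m2)
  expect_setequal(z2, which(m2$region %in% c("shell", "fibrous_interface")))
  expect_length(intersect(z2, which(m2$region == "implant")), 0)
})

test_that("region volumes agree with the analytic slabs", {
  m <- fix_model_500()
  sp <- m$spec
  V <- m$V_elem
  # gingiva slab minus the implant+shell disc
  vg <- sum(m$region == "gingiva") * V
  vg_th <- (sp$Lx * sp$Ly - pi * sp$r_shell^2) * sp$t_gingiva
  expect_equal(vg, vg_th, tolerance = 0.2)
  vc <- sum(m$region == "cortical") * V
  vc_th <- (sp$Lx * sp$Ly - pi * sp$r_shell^2) * sp$t_cortical
  expect_equal(vc, vc_th, tolerance = 0.2)
  # implant cylinder
  vi <- sum(m$region == "implant") * V
  vi_th <- pi * sp$r_implant^2 * sp$L_implant
  expect_equal(vi, vi_th, tolerance = 0.1)
  # total bookkeeping: block volume
  vtot <- sum(m$region != "applicator") * V
  expect_equal(vtot, sp$Lx * sp$Ly * sp$Lz, tolerance = 0.05)
})

test_that("invalid specifications are rejected", {
  expect_error(model_spec(d = -1), "positive")
  expect_error(model_spec(r_shell = 1e-3, r_implant = 2e-3), "exceed")
  expect_error(model_spec(Lx = 1e-3), "3 element diameters|shell")
  expect_error(model_spec(phase = 5), "phase")
  expect_error(model_spec(t_gingiva = 5e-3, t_cortical = 4e-3), "fit")
})
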