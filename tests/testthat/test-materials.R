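test_that("material table round-trips the tabulated tissue values", {
  mats <- fix_materials()
  cort <- mats[["Cortical"]]
  expect_equal(cort$E, 14.7e9)
  expect_equal(cort$nu, 0.32)
  expect_equal(cort$Ks, 17.0e9)
  expect_equal(cort$theta, 0.04)
  expect_equal(cort$k_perm, 1.0e-20)
  expect_equal(cort$rho, 1850)
  woven <- mats[["Woven bone"]]
  expect_equal(woven$E, 1.2e9)
  expect_equal(woven$nu, 0.30)
  expect_equal(woven$k_perm, 1.0e-16)
  ti <- mats[["Ti-6Al-4V"]]
  expect_equal(ti$E, 107.1e9)
  expect_equal(ti$nu, 0.31)
  expect_equal(ti$sigma_y, 800e6)
  expect_true(ti$is_metal)
  cu <- mats[["Cu"]]
  expect_equal(cu$sigma_y, 80e6)
  expect_equal(cu$rho, 8950)
  fl <- attr(mats, "fluid")
  expect_equal(fl$Kf, 2.4e9)
  expect_equal(fl$rho_f, 1000)
  expect_equal(fl$eta_f, 1e-3)
  # primary matrix and fibrous stay distinct names with identical rows
  pm <- mats[["Primary matrix"]]
  fb <- mats[["Fibrous"]]
  expect_equal(pm$E, fb$E)
  expect_equal(pm$k_perm, fb$k_perm)
})

test_that("derived moduli follow the isotropic identities", {
  mats <- fix_materials()
  dm <- derived_moduli(mats[["Cortical"]])
  expect_equal(dm$K, 13.611e9, tolerance = 1e-4)
  expect_equal(dm$G, 5.568e9, tolerance = 1e-3)
  cu <- derived_moduli(mats[["Cu"]])
  expect_equal(cu$K, 116.04e9, tolerance = 1e-3)
  expect_equal(cu$G, 41.57e9, tolerance = 1e-3)
  expect_equal(cu$cp, 4377, tolerance = 1e-3)
  # identity closure for every material
  for (m in mats) {
    d <- derived_moduli(m)
    expect_equal(9 * d$K * d$G / (3 * d$K + d$G), m$E, tolerance = 1e-12)
  }
  # nu = 0 limit
  m0 <- new_material("nu0 (synthetic)", 1000, 1e9, 1e-9, 1e10, 0.1, 1e-15)
  d0 <- derived_moduli(m0)
  expect_equal(d0$K, m0$E / 3, tolerance = 1e-6)
  expect_equal(d0$G, m0$E / 2, tolerance = 1e-6)
})

test_that("Biot constants match the closed forms on table inputs", {
  mats <- fix_materials()
  b <- biot_constants(mats[["Cancellous"]])
  expect_equal(b$alpha, 0.7840, tolerance = 1e-4)
  expect_equal(b$M, 3.364e9, tolerance = 1e-3)
  bc <- biot_constants(mats[["Cortical"]])
  expect_equal(bc$alpha, 0.1994, tolerance = 1e-3)
  # metals carry no pore coupling
  bm <- biot_constants(mats[["Ti-6Al-4V"]])
  expect_equal(bm$alpha, 0)
  # K -> 0 limit gives alpha -> 1
  tiny <- new_material("tinyK (synthetic)", 1000, 1e3, 0.3, 1e10, 0.1, 1e-15)
  expect_equal(biot_constants(tiny)$alpha, 1, tolerance = 1e-6)
  # all tabulated tissues give physical alpha and positive storage modulus
  for (nm in setdiff(names(mats), c("Ti-6Al-4V", "Cu"))) {
    bb <- suppressWarnings(biot_constants(mats[[nm]]))
    expect_true(bb$alpha > 0 && bb$alpha <= 1)
    expect_true(bb$M > 0)
  }
  # theta <= alpha holds for the stiff-grain rows
  for (nm in c("Dentin", "Cortical", "Cancellous", "Granulation")) {
    bb <- biot_constants(mats[[nm]])
    expect_gte(bb$alpha, mats[[nm]]$theta)
  }
  # the soft rows with alpha marginally below porosity warn, not error
  expect_warning(biot_constants(mats[["Fibrous"]]), "porosity")
})

test_that("non-physical material rows are rejected with the row name", {
  expect_error(new_material("badnu", 1000, 1e9, 0.6, 1e10, 0.1, 1e-15),
               "badnu")
  expect_error(new_material("badK", 1000, 60e9, 0.32, 17e9, 0.1, 1e-15),
               "exceeds grain modulus")
  expect_error(derived_moduli(list(nu = 0.5)), "incompressible")
  tbl <- list(tissues = list(list(name = "X", rho = 1000, E = 1)),
              metals = list())
  expect_error(load_material_table(tbl), "missing field")
})

test_that("phase material maps follow the healing sequence", {
  m1 <- phase_material_map(1)
  expect_equal(unname(m1["shell"]), "Primary matrix")
  expect_equal(unname(m1["fibrous_interface"]), "Primary matrix")
  m2 <- phase_material_map(2)
  expect_equal(unname(m2["shell"]), "Granulation")
  expect_equal(unname(m2["fibrous_interface"]), "Fibrous")
  m3 <- phase_material_map(3)
  expect_equal(unname(m3["shell"]), "Woven bone")
  expect_equal(unname(m3["fibrous_interface"]), "Fibrous")
  m3b <- phase_material_map(3, fibrous_interface = FALSE)
  expect_equal(unname(m3b["fibrous_interface"]), "Woven bone")
  expect_equal(unname(m1["implant"]), "Ti-6Al-4V")
  expect_equal(unname(m1["applicator"]), "Cu")
  expect_error(phase_material_map(4), "phase")
})
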