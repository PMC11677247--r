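# Independent truth-table implementation of the fate rules, written as a
# flat rule list (the package classifier uses vectorized masking).
fate_oracle <- function(sbar, shear, th = mechanobio_thresholds()) {
  out <- character(length(sbar))
  for (i in seq_along(sbar)) {
    s <- sbar[i]; g <- shear[i]
    out[i] <-
      if (abs(s) < th$osteo_min) "quiescent"
      else if (s > th$osteo_max) "fibrogenic"
      else if (s < -th$chondro_max) "overload"
      else if (s < -th$osteo_max) "chondrogenic"
      else if (g <= th$shear_split) "osteogenic"
      else if (s < 0) "chondrogenic"
      else "fibrogenic"
  }
  out
}

test_that("classifier reproduces the published example states", {
  expect_equal(as.character(classify_fate(-0.10e6, 0.01)), "osteogenic")
  expect_equal(as.character(classify_fate(0.7e6, 0.01)), "fibrogenic")
  expect_equal(as.character(classify_fate(-1.0e6, 0.06)), "chondrogenic")
  expect_equal(as.character(classify_fate(-1e3, 0.01)), "quiescent")
  expect_equal(as.character(classify_fate(-2.5e6, 0.01)), "overload")
})

test_that("band boundaries close on the osteogenic side", {
  th <- mechanobio_thresholds()
  # compressive osteogenic ceiling: exactly 0.15 MPa stays osteogenic
  expect_equal(as.character(classify_fate(-0.15e6, 0.01)), "osteogenic")
  expect_equal(as.character(classify_fate(-0.15e6 - 1, 0.01)), "chondrogenic")
  expect_equal(as.character(classify_fate(0.15e6, 0.01)), "osteogenic")
  expect_equal(as.character(classify_fate(0.15e6 + 1, 0.01)), "fibrogenic")
  # quiescence below 3 kPa, osteogenic at exactly 3 kPa
  expect_equal(as.character(classify_fate(3e3 - 1e-3, 0.01)), "quiescent")
  expect_equal(as.character(classify_fate(-3e3, 0.01)), "osteogenic")
  # shear split at exactly 5 percent stays osteogenic
  expect_equal(as.character(classify_fate(-0.1e6, 0.05)), "osteogenic")
  expect_equal(as.character(classify_fate(-0.1e6, 0.0501)), "chondrogenic")
  # chondrogenic band extends to 2 MPa compression inclusive
  expect_equal(as.character(classify_fate(-2e6, 0.06)), "chondrogenic")
  # bisection locates the compressive osteogenic boundary at the threshold
  b <- osteogenic_compressive_boundary(th, shear = 0.01, tol = 1)
  expect_equal(b, 0.15e6, tolerance = 1e-5)
})

test_that("classifier agrees with the independent truth table", {
  set.seed(7)
  n <- 1e5
  sbar <- runif(n, -3e6, 1.5e6)
  shear <- runif(n, 0, 0.08)
  got <- as.character(classify_fate(sbar, shear))
  expect_identical(got, fate_oracle(sbar, shear))
})

test_that("transport classification follows the pressure band", {
  expect_equal(as.character(classify_transport(68e3)), "optimal")
  expect_equal(as.character(classify_transport(10e3)), "none")
  expect_equal(as.character(classify_transport(3e6)), "none")
  expect_equal(as.character(classify_transport(20e3)), "sufficient")
  expect_equal(as.character(classify_transport(2e6)), "sufficient")
  expect_equal(as.character(classify_transport(19.999e3)), "none")
  # optimal band spans a factor two around 68 kPa
  expect_equal(as.character(classify_transport(34e3)), "optimal")
  expect_equal(as.character(classify_transport(136e3)), "optimal")
  expect_equal(as.character(classify_transport(137e3)), "sufficient")
})

test_that("distortional band flags 0.05 to 1.1 percent strain", {
  expect_true(distortion_band(0.005))
  expect_false(distortion_band(0.0004))
  expect_false(distortion_band(0.02))
})

test_that("fate fractions partition and average over time", {
  # constant field: 30 of 150 fibrogenic -> 0.2
  lab <- matrix("osteogenic", 4, 150)
  lab[, 1:30] <- "fibrogenic"
  fr <- zone_fractions(lab, levels = osseowave:::FATE_LEVELS)
  expect_equal(fr$fraction[fr$label == "fibrogenic"], 0.2)
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-12)
  # alternating field: half samples 0.1, half 0.3 -> mean 0.2
  lab2 <- matrix("osteogenic", 4, 100)
  lab2[1:2, 1:10] <- "chondrogenic"
  lab2[3:4, 1:30] <- "chondrogenic"
  fr2 <- zone_fractions(lab2)
  expect_equal(fr2$fraction[fr2$label == "chondrogenic"], 0.2)
  # fractions below the 5 percent floor display as "<5%"
  lab3 <- matrix("osteogenic", 1, 100)
  lab3[1, 1:2] <- "overload"
  fr3 <- zone_fractions(lab3, levels = osseowave:::FATE_LEVELS)
  expect_equal(fr3$display[fr3$label == "overload"], "<5%")
  expect_equal(fr3$fraction[fr3$label == "overload"], 0.02)
  # single fully-labeled sample gives fraction one
  fr4 <- zone_fractions(rep("osteogenic", 20))
  expect_equal(fr4$fraction, 1)
})

test_that("raising the osteogenic ceiling only grows the osteogenic set", {
  set.seed(11)
  sbar <- runif(2e4, -3e6, 1.5e6)
  shear <- runif(2e4, 0, 0.08)
  lo <- classify_fate(sbar, shear, mechanobio_thresholds(osteo_max = 0.15e6))
  hi <- classify_fate(sbar, shear, mechanobio_thresholds(osteo_max = 0.20e6))
  expect_true(all(which(lo == "osteogenic") %in% which(hi == "osteogenic")))
  expect_gt(sum(hi == "osteogenic"), sum(lo == "osteogenic"))
})

test_that("fate reports from simulation runs partition exactly", {
  run <- fix_eswt_500()
  rep <- fate_report(run)
  expect_equal(sum(rep$fates$fraction), 1, tolerance = 1e-12)
  expect_equal(rep$n_zone, length(run$zone_idx))
  expect_true(rep$transport_sufficient >= 0 && rep$transport_sufficient <= 1)
  # effective-stress variant is also a valid partition
  rep2 <- fate_report(run, use_effective_stress = TRUE)
  expect_equal(sum(rep2$fates$fraction), 1, tolerance = 1e-12)
})
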