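test_that("SRK/T constant mapping and axial-length correction", {
  cst <- lens_constants("srkt", a_const = 118.4)
  eye <- eye_biometry(al_mm = 24.0, acd_mm = 3.2, km_d = 43.5)
  # ACD-constant = 0.62467 A - 68.747; offset = ACD-constant - 3.336
  expect_equal(0.62467 * 118.4 - 68.747, 5.213928, tolerance = 1e-9)
  r <- keratometry_to_radius(43.5)
  elp <- elp_srkt(cst, eye)
  cw <- -5.41 + 0.58412 * 24.0 + 0.098 * 43.5     # LCOR = AL below 24.2
  h <- r - sqrt(r^2 - cw^2 / 4)
  expect_equal(elp$elp_mm, h + 1.877928, tolerance = 1e-9)
  expect_equal(elp$l_opt_mm, 24.0 + 0.65696 - 0.02029 * 24.0,
               tolerance = 1e-12)
  expect_equal(elp$dc_d, 1000 * 0.333 / r, tolerance = 1e-12)
  # above the branch point the quadratic remapping engages
  long_eye <- eye_biometry(al_mm = 26, acd_mm = 3.4, km_d = 43.5)
  elp_long <- elp_srkt(cst, long_eye)
  lcor <- -3.446 + 1.716 * 26 - 0.0237 * 26^2
  expect_lt(lcor, 26)
  cw_long <- -5.41 + 0.58412 * lcor + 0.098 * 43.5
  expect_equal(elp_long$elp_mm, r - sqrt(r^2 - cw_long^2 / 4) + 1.877928,
               tolerance = 1e-9)
})

test_that("Holladay 1 corneal-dome geometry rules", {
  cst <- lens_constants("holladay1", sf_mm = 1.79)
  # AL = 23.45 puts the corneal chord exactly at 12.5 mm
  eye <- eye_biometry(al_mm = 23.45, acd_mm = 3.2, km_d = 43.5)
  r <- keratometry_to_radius(43.5)
  elp <- elp_holladay1(cst, eye)
  expect_equal(elp$elp_mm, 0.56 + r - sqrt(r^2 - 12.5^2 / 4) + 1.79,
               tolerance = 1e-9)
  # long eye: chord capped at 13.5 (uncapped would be 13.859)
  long_eye <- eye_biometry(al_mm = 26, acd_mm = 3.4, km_d = 43.5)
  expect_equal(12.5 * 26 / 23.45, 13.8592750533, tolerance = 1e-6)
  expect_equal(elp_holladay1(cst, long_eye)$elp_mm,
               0.56 + r - sqrt(r^2 - 13.5^2 / 4) + 1.79, tolerance = 1e-9)
  # steep cornea: radius floored at 7 mm (337.5/49.6 = 6.80)
  steep <- eye_biometry(al_mm = 23.45, acd_mm = 3.2, km_d = 337.5 / 6.8)
  expect_equal(elp_holladay1(cst, steep)$elp_mm,
               0.56 + 7 - sqrt(7^2 - 12.5^2 / 4) + 1.79, tolerance = 1e-9)
  expect_equal(elp_holladay1(cst, eye)$l_opt_mm, 23.65, tolerance = 1e-12)
})

test_that("Hoffer Q tangent model, clamps and vergence offsets", {
  cst <- lens_constants("hofferq", pacd_mm = 5.722)
  tan_deg <- function(x) tan(x * pi / 180)
  # at AL = 23.5 the linear term vanishes
  eye <- eye_biometry(al_mm = 23.5, acd_mm = 3.2, km_d = 44.2)
  elp <- elp_hofferq(cst, eye)
  expected <- 5.722 + 0 + tan_deg(44.2)^2 -
    0.1 * (23.5 - 23.5)^2 * tan_deg(0.1 * (23.5 - 23.5)^2) - 0.99166
  expect_equal(elp$elp_mm, expected + 0.05, tolerance = 1e-9)
  expect_equal(elp$l_opt_mm, 23.5)
  expect_equal(elp$dc_d, 44.2)
  # independent transcription at AL = 23.9 (long-eye branch)
  eye2 <- eye_biometry(al_mm = 23.9, acd_mm = 3.2, km_d = 44.2)
  expected2 <- 5.722 + 0.3 * (23.9 - 23.5) + tan_deg(44.2)^2 +
    0.1 * (-1) * (23.5 - 23.9)^2 * tan_deg(0.1 * (23.5 - 23.9)^2) - 0.99166
  expect_equal(elp_hofferq(cst, eye2)$elp_mm, expected2 + 0.05,
               tolerance = 1e-6)
  # ceiling rule: AL = 32 enters the ELP expression as 31
  eye3 <- eye_biometry(al_mm = 32, acd_mm = 3.6, km_d = 41)
  expected3 <- 5.722 + 0.3 * (31 - 23.5) + tan_deg(41)^2 +
    0.1 * (-1) * (23.5 - 31)^2 * tan_deg(0.1 * (23.5 - 31)^2) - 0.99166
  expect_equal(elp_hofferq(cst, eye3)$elp_mm, expected3 + 0.05,
               tolerance = 1e-9)
  expect_equal(elp_hofferq(cst, eye3)$l_opt_mm, 32)  # AL itself unclamped
  # short-eye branch uses (M, G) = (+1, 28)
  eye4 <- eye_biometry(al_mm = 21, acd_mm = 2.8, km_d = 46)
  expected4 <- 5.722 + 0.3 * (21 - 23.5) + tan_deg(46)^2 +
    0.1 * (23.5 - 21)^2 * tan_deg(0.1 * (28 - 21)^2) - 0.99166
  expect_equal(elp_hofferq(cst, eye4)$elp_mm, expected4 + 0.05,
               tolerance = 1e-9)
})

test_that("Haigis lens position is linear in ACD and AL", {
  cst <- lens_constants("haigis", haigis_a0 = -0.737)
  eye <- eye_biometry(al_mm = 24.15, acd_mm = 3.24, km_d = 43.86)
  elp <- elp_haigis(cst, eye)
  expect_equal(elp$elp_mm, 2.974, tolerance = 1e-9)
  expect_equal(elp$l_opt_mm, 24.15)
  expect_equal(elp$dc_d, 1000 * 0.3315 / keratometry_to_radius(43.86),
               tolerance = 1e-12)
  # partial derivative wrt ACD is a1 exactly
  eye_d <- eye_biometry(al_mm = 24.15, acd_mm = 3.24 + 0.5, km_d = 43.86)
  expect_equal(elp_haigis(cst, eye_d)$elp_mm - elp$elp_mm, 0.4 * 0.5,
               tolerance = 1e-12)
  # aqueous-depth variant uses the AD column
  elp_ad <- elp_haigis(cst, eye, acd_source = "ad")
  expect_equal(elp_ad$elp_mm - elp$elp_mm, 0.4 * (eye$ad_mm - eye$acd_mm),
               tolerance = 1e-12)
  # a degenerate all-zero constant produces ELP 0, which the vergence
  # stage must reject as non-physical
  zero <- lens_constants("haigis", haigis_a0 = 0, haigis_a1 = 0,
                         haigis_a2 = 0)
  expect_error(predict_refraction("haigis", zero, eye, 21), "failed")
})

test_that("all four formulas match the independent oracle transcriptions", {
  eyes <- reference_eyes()
  oracles <- list(
    srkt = function(e, p) oracle_srkt(119, e$al_mm, e$km_d, p),
    holladay1 = function(e, p) oracle_holladay1(1.79, e$al_mm, e$km_d, p),
    hofferq = function(e, p) oracle_hofferq(5.59, e$al_mm, e$km_d, p),
    haigis = function(e, p) oracle_haigis(1.902, 0.4, 0.1, e$acd_mm,
                                          e$al_mm, e$km_d, p))
  for (fid in iol_formulas()) {
    for (ref in eyes) {
      got <- predict_refraction(fid, default_constants(fid), ref$eye,
                                ref$power)
      expect_equal(got, oracles[[fid]](ref$eye, ref$power),
                   tolerance = 1e-6,
                   label = paste(fid, "at AL", ref$eye$al_mm))
    }
  }
  # frozen oracle values for the average reference eye
  avg <- eyes$average
  expect_equal(predict_refraction("srkt", default_constants("srkt"),
                                  avg$eye, avg$power),
               -0.118376561, tolerance = 1e-6)
  expect_equal(predict_refraction("haigis", default_constants("haigis"),
                                  avg$eye, avg$power),
               0.575556843, tolerance = 1e-6)
})

test_that("predictions are strictly monotone in power and lens constant", {
  eyes <- random_eyes(1000, seed = 31)
  powers <- seq(0, 30, by = 0.5)
  for (fid in iol_formulas()) {
    cst <- default_constants(fid)
    lo <- predict_refraction(fid, cst, eyes, 12)
    hi <- predict_refraction(fid, cst, eyes, 12.5)
    expect_true(all(hi < lo), label = paste(fid, "decreasing in power"))
    # a larger constant means a more posterior lens, a more hyperopic
    # prediction
    bump <- switch(fid, srkt = 0.5, 0.25)
    up <- predict_refraction(fid, set_constant_value(cst,
                                                     constant_value(cst) + bump),
                             eyes, 21)
    base <- predict_refraction(fid, cst, eyes, 21)
    expect_true(all(up > base), label = paste(fid, "increasing in constant"))
  }
  # fine power grid on the average eye
  avg <- reference_eyes()$average$eye
  for (fid in iol_formulas()) {
    r <- predict_refraction(fid, default_constants(fid), avg, powers)
    expect_true(all(diff(r) < 0))
  }
})

test_that("emmetropic round-trip holds for every formula on random eyes", {
  eyes <- random_eyes(50, seed = 7)
  params <- optical_params()
  for (fid in iol_formulas()) {
    elp <- iolstrat:::formula_elp(fid, default_constants(fid), eyes, params)
    p <- emmetropic_power(params, elp)
    resid <- predict_refraction(fid, default_constants(fid), eyes, p)
    expect_lt(max(abs(resid)), 1e-9)
  }
})

test_that("constant/formula mismatches and unknown ids are rejected", {
  eye <- reference_eyes()$average$eye
  expect_error(predict_refraction("srkt", default_constants("haigis"), eye, 21),
               "srkt")
  expect_error(iolstrat:::formula_elp("barrett", default_constants("srkt"),
                                      eye),
               "unknown formula")
  expect_error(lens_constants("srkt"), "a_const")
  expect_error(lens_constants("srkt", a_const = 109), "110")
})
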