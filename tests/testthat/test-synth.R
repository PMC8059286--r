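test_that("biometry draws are reproducible and respect the configuration", {
  cfg <- generator_config(n_patients = 100, seed = 8)
  a <- sample_biometry(cfg, "female", 500, seed = 99)
  b <- sample_biometry(cfg, "female", 500, seed = 99)
  expect_identical(a, b)
  c <- sample_biometry(cfg, "female", 500, seed = 100)
  expect_false(identical(a, c))
  # aqueous depth is derived, not drawn
  expect_equal(a$ad_mm, a$acd_mm - a$cct_um / 1000, tolerance = 1e-12)
  # truncation bounds hold row-wise
  bounds <- default_biometry_bounds()
  for (v in c("al_mm", "acd_mm", "km_d", "lt_mm", "wtw_mm", "cct_um",
              "ast_d")) {
    expect_true(all(a[[v]] >= bounds[[v]][1] & a[[v]] <= bounds[[v]][2]),
                label = v)
  }
})

test_that("degenerate zero-spread marginals collapse to the means", {
  marg <- default_biometry_marginals()
  for (g in c("female", "male")) {
    marg[[g]] <- lapply(marg[[g]], function(ms) c(ms[1], 0))
  }
  cfg <- generator_config(n_patients = 10, biometry = marg, seed = 4)
  d <- sample_biometry(cfg, "male", 50, seed = 1)
  expect_equal(unique(d$al_mm), marg$male$al_mm[1], tolerance = 1e-9)
  expect_equal(unique(d$km_d), marg$male$km_d[1], tolerance = 1e-9)
})

test_that("sample moments converge to the configured gender marginals", {
  cfg <- generator_config(seed = 1)
  n <- 20000
  f <- sample_biometry(cfg, "female", n, seed = 61)
  m <- sample_biometry(cfg, "male", n, seed = 62)
  marg <- default_biometry_marginals()
  # SE ~ 0.01; allow 5 SE
  expect_lt(abs(mean(f$al_mm) - marg$female$al_mm[1]), 0.05)
  expect_lt(abs(mean(m$al_mm) - marg$male$al_mm[1]), 0.05)
  expect_lt(abs(stats::sd(f$al_mm) - marg$female$al_mm[2]), 0.05)
  expect_lt(abs(mean(f$km_d) - marg$female$km_d[1]), 0.06)
  # configured correlations survive truncation approximately
  expect_lt(abs(stats::cor(f$al_mm, f$acd_mm) - 0.45), 0.05)
  expect_lt(abs(stats::cor(f$al_mm, f$km_d) + 0.30), 0.05)
})

test_that("inconsistent truncation bounds raise a configuration error", {
  marg <- default_biometry_marginals()
  bounds <- default_biometry_bounds()
  bounds$al_mm <- c(23.8, 24.0)    # female mean inside, male mean outside
  expect_error(generator_config(bounds = bounds), "male mean")
})

test_that("power selection hits the target and rounds with myopic bias", {
  eyes <- random_eyes(200, seed = 12)
  cst <- default_constants("srkt")
  p_exact <- assign_iol_power(eyes, "srkt", cst, target_refraction = 0,
                              step = 0)
  resid <- predict_refraction("srkt", cst, eyes, p_exact)
  expect_lt(max(abs(resid)), 1e-9)
  # non-plano target
  p_myo <- assign_iol_power(eyes, "srkt", cst, target_refraction = -0.5,
                            step = 0)
  resid_myo <- predict_refraction("srkt", cst, eyes, p_myo)
  expect_lt(max(abs(resid_myo + 0.5)), 1e-9)
  # 0.5 D step: residual refraction bounded by a quarter-diopter IOL step
  p_round <- assign_iol_power(eyes, "srkt", cst, step = 0.5)
  expect_true(all(abs(p_round / 0.5 - round(p_round / 0.5)) < 1e-9))
  r_round <- predict_refraction("srkt", cst, eyes, p_round)
  step_effect <- abs(predict_refraction("srkt", cst, eyes, p_round + 0.5) -
                       r_round)
  expect_true(all(abs(r_round) <= 0.55 * step_effect + 1e-9))
  # midpoint ties round to the higher power (myopic side)
  expect_equal(iolstrat:::round_half_up(21.25, 0.5), 21.5)
  expect_equal(iolstrat:::round_half_up(-0.25, 0.5), 0)
  expect_equal(iolstrat:::round_half_up(21.1, 0.5), 21)
  expect_equal(iolstrat:::round_half_up(21.74, 0.5), 21.5)
})

test_that("postoperative refraction model injects offset and noise as specified", {
  eyes <- random_eyes(300, seed = 14)
  cst <- default_constants("srkt")
  p <- assign_iol_power(eyes, "srkt", cst, step = 0.5)
  # no offset, no noise: pipeline SPE is zero at the true constant
  withr::with_seed(1, {
    r0 <- simulate_postop_refraction(eyes, p, "srkt", cst, offset_d = 0,
                                     noise_sd = 0)
  })
  pred <- predict_refraction("srkt", cst, eyes, p)
  expect_lt(max(abs(pred - r0$postop_se_d)), 1e-12)
  expect_equal(r0$postop_se_d,
               r0$postop_sphere_d + r0$postop_cyl_d / 2, tolerance = 1e-12)
  # a male hyperopic-skew offset shifts every SPE by exactly +0.10
  withr::with_seed(1, {
    rm_ <- simulate_postop_refraction(eyes, p, "srkt", cst, offset_d = -0.10,
                                      noise_sd = 0)
  })
  expect_equal(pred - rm_$postop_se_d, rep(-0.10, nrow(eyes)),
               tolerance = 1e-12)
  # noisy strata concentrate near the injected offsets
  withr::with_seed(2, {
    rn <- simulate_postop_refraction(eyes, p, "srkt", cst, offset_d = 0.07,
                                     noise_sd = 0.4)
  })
  spe <- pred - rn$postop_se_d
  expect_lt(abs(mean(spe) - 0.07), 3 * 0.4 / sqrt(nrow(eyes)))
})

test_that("whole-cohort generation is deterministic with expected shape", {
  cfg <- generator_config(n_patients = 400, seed = 23)
  s1 <- generate_cohort(cfg)
  s2 <- generate_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$truth, s2$truth)
  # bilateral fraction drives the eye count: E = n (1 + p)
  expect_equal(nrow(s1$cohort),
               round(400 * (1 + cfg$prob_bilateral)), tolerance = 0.08)
  # every eye has a ground-truth row
  expect_equal(paste(s1$cohort$patient_id, s1$cohort$eye),
               paste(s1$truth$patient_id, s1$truth$eye))
  # the generated table passes validation untouched
  v <- validate_cohort(s1$cohort)
  expect_equal(nrow(v$records), nrow(s1$cohort))
  expect_equal(nrow(v$rejections), 0)
  # fellow eyes are highly correlated within patients
  both <- names(which(table(s1$cohort$patient_id) == 2))
  od <- s1$cohort[s1$cohort$patient_id %in% both & s1$cohort$eye == "OD", ]
  os <- s1$cohort[s1$cohort$patient_id %in% both & s1$cohort$eye == "OS", ]
  od <- od[order(od$patient_id), ]
  os <- os[order(os$patient_id), ]
  expect_gt(stats::cor(od$al_mm, os$al_mm), 0.75)
})

test_that("cohort CSV round-trips losslessly through the validators", {
  cfg <- generator_config(n_patients = 60, seed = 37)
  sc <- generate_cohort(cfg)
  tmp <- withr::local_tempdir()
  path <- file.path(tmp, "cohort.csv")
  write_cohort_csv(sc, path)
  expect_true(file.exists(paste0(path, ".truth.json")))
  expect_true(file.exists(paste0(path, ".config.json")))
  back <- read_cohort_csv(path)
  v <- validate_cohort(back)
  expect_equal(nrow(v$records), nrow(sc$cohort))
  expect_equal(nrow(v$rejections), 0)
  expect_equal(back$postop_se_d, sc$cohort$postop_se_d, tolerance = 1e-9)
  # regeneration writes byte-identical output
  path2 <- file.path(tmp, "cohort2.csv")
  write_cohort_csv(generate_cohort(cfg), path2)
  expect_identical(readLines(path), readLines(path2))
})
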