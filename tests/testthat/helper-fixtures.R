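# Small deterministic cohort rows for validation and splitting tests.
# Refraction fields are self-consistent (SE = sphere + cyl/2); biometry sits
# at unremarkable adult values.

flat_cohort <- function(n = 10, patient_ids = sprintf("P%03d", seq_len(n)),
                        eye = rep("OD", n),
                        gender = rep(c("female", "male"), length.out = n)) {
  sph <- rep(-0.5, n)
  cyl <- rep(0.5, n)
  data.frame(
    patient_id = patient_ids, eye = eye, gender = gender,
    age_years = 70, al_mm = 23.65, acd_mm = 3.2, ad_mm = 3.2 - 0.55,
    cct_um = 550, lt_mm = 4.5, km_d = 43.5, ast_d = 0.9, wtw_mm = 12.1,
    iol_power_d = 21, postop_sphere_d = sph, postop_cyl_d = cyl,
    postop_se_d = sph + cyl / 2,
    stringsAsFactors = FALSE)
}

# three reference eyes spanning short / average / long geometry
reference_eyes <- function() {
  list(
    short = list(eye = eye_biometry(al_mm = 21.5, acd_mm = 2.8, km_d = 46),
                 power = 28),
    average = list(eye = eye_biometry(al_mm = 23.65, acd_mm = 3.2, km_d = 43.5),
                   power = 21),
    long = list(eye = eye_biometry(al_mm = 26.5, acd_mm = 3.6, km_d = 41.5),
                power = 14))
}

# random valid eyes for property checks; keratometry flattens with axial
# length as in real eyes, keeping the corneal-height geometry well posed
random_eyes <- function(n, seed = 1) {
  withr::with_seed(seed, {
    al <- runif(n, 20.5, 29.5)
    eye_biometry(al_mm = al,
                 acd_mm = runif(n, 2.3, 4.2),
                 km_d = runif(n, 40.5, 46) - 1.2 * (al - 24),
                 cct_um = runif(n, 480, 620),
                 lt_mm = runif(n, 3.8, 5.3),
                 ast_d = runif(n, 0, 3),
                 wtw_mm = runif(n, 11, 13.2))
  })
}
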