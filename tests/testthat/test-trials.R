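small_mother_scenario <- function(seed = 11, iiv = list(cl = 0.35, v = 0.25),
                                  physiology = physiology_config()) {
  cal <- get_calibration()
  scenario_config(
    name = "small_mother",
    population = population_spec(3, c(25, 25), proportion_female = 1,
                                 seed = seed),
    reg = maternal_regimen(),
    ontogeny = list(MAOA = "maoa_none", CYP2D6 = "maoa_none"),
    drug = cal$drug, disposition = cal$disposition,
    milk_mode = "observed_mp", n_trials = 2, seed = seed,
    physiology = physiology, iiv_cv = iiv
  )
}

test_that("virtual studies are reproducible under a fixed seed", {
  sc <- small_mother_scenario()
  a <- run_trial_set(sc)
  b <- run_trial_set(sc)
  expect_identical(a$pooled, b$pooled)
  expect_identical(a$subjects, b$subjects)
  c_ <- run_trial_set(sc, seed = 12)
  expect_false(identical(a$pooled, c_$pooled))
})

test_that("with no variability every subject is the typical subject", {
  cfg <- physiology_config(adult_cv_height = 0, adult_cv_weight = 0)
  sc <- small_mother_scenario(iiv = list(cl = 0, v = 0), physiology = cfg)
  ts <- run_trial_set(sc)
  expect_equal(ts$per_trial$cmax_min, ts$per_trial$cmax_median, tolerance = 1e-12)
  expect_equal(ts$per_trial$cmax_max, ts$per_trial$cmax_median, tolerance = 1e-12)
  expect_equal(ts$per_trial$auc_min, ts$per_trial$auc_max, tolerance = 1e-12)
})

test_that("pooled percentiles are ordered and summaries carry every subject", {
  sc <- small_mother_scenario()
  ts <- run_trial_set(sc)
  expect_lte(ts$pooled$cmax[["p5"]], ts$pooled$cmax[["median"]])
  expect_lte(ts$pooled$cmax[["median"]], ts$pooled$cmax[["p95"]])
  expect_equal(nrow(ts$subjects), 2 * 3)
  expect_true(all(ts$per_trial$cmax_min <= ts$per_trial$cmax_median &
                    ts$per_trial$cmax_median <= ts$per_trial$cmax_max))
})

test_that("relative exposure is the percent ratio of pooled medians", {
  sc <- small_mother_scenario()
  ts <- run_trial_set(sc)
  rel <- relative_exposure(ts, ts)
  expect_equal(unname(rel), c(100, 100))
  half <- ts
  half$pooled$cmax[["median"]] <- ts$pooled$cmax[["median"]] / 2
  expect_equal(relative_exposure(half, ts)[["cmax_pct"]], 50)
})

test_that("exposure decreases with enzyme maturation and increases with binding", {
  # ontogeny fraction: higher fraction of adult activity -> lower exposure
  idd <- 2.98
  s <- typical_subject(0.5)
  cmaxes <- vapply(c(0.2, 0.5, 1), function(f) {
    om <- list(MAOA = ontogeny_profile(f_birth = f, age50 = 1e9),
               CYP2D6 = ontogeny_profile(f_birth = f, age50 = 1e9))
    typical_infant_cmax(s, idd, ontogeny = om)
  }, numeric(1))
  expect_true(all(diff(cmaxes) < 0))
  # fu: larger AAG fold -> smaller fu -> higher exposure
  cmax_fold <- vapply(c(1, 2, 4), function(f) {
    typical_infant_cmax(s, idd, aag_fold = f)
  }, numeric(1))
  expect_true(all(diff(cmax_fold) > 0))
})
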