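# With no peripheral compartment the model has the textbook one-compartment
# oral solution; it serves as the analytic oracle for the ODE solver.
one_cpt_oral <- function(t, dose_bioavail, ka, cl, v) {
  k <- cl / v
  dose_bioavail * ka / (v * (ka - k)) * (exp(-k * t) - exp(-ka * t))
}

test_that("ODE solution matches the closed-form one-compartment oral solution", {
  p <- model_params(ka = 1.3, fa = 0.8, v_central = 10, v_peripheral = 0,
                    q_inter = 0, cl_int_scaled = c(MAOA = 5), q_hepatic = 50)
  reg <- regimen(100, 24, 1)
  prof <- simulate_profile(p, reg, weight = 1, duration = 48, dt = 0.1)
  expected <- one_cpt_oral(prof$times, p$fa * 100 * p$f_hepatic, p$ka,
                           p$cl_hepatic, p$v_central)
  expect_lt(max(abs(prof$conc - expected)) / max(expected), 1e-3)
})

test_that("concentrations scale linearly with dose", {
  p <- model_params(ka = 1, fa = 1, v_central = 12, v_peripheral = 8,
                    q_inter = 2, cl_int_scaled = c(MAOA = 4, CYP2D6 = 1),
                    q_hepatic = 60)
  prof1 <- simulate_profile(p, regimen(250, 24, 3), 2, duration = 96, dt = 0.1)
  prof2 <- simulate_profile(p, regimen(500, 24, 3), 2, duration = 96, dt = 0.1)
  expect_lt(max(abs(prof2$conc - 2 * prof1$conc)) / max(prof2$conc), 1e-6)
})

test_that("a multiple-dose profile is the superposition of shifted single doses", {
  p <- model_params(ka = 1, fa = 1, v_central = 100, v_peripheral = 66,
                    q_inter = 8, cl_int_scaled = c(MAOA = 25, CYP2D6 = 3),
                    q_hepatic = 85)
  multi <- simulate_profile(p, regimen(500, 24, 14), 55, duration = 336,
                            dt = 0.1)
  single <- simulate_profile(p, regimen(500, 24, 1), 55, duration = 336,
                             dt = 0.1)
  shift_by <- function(k) {
    idx <- match(round(multi$times - 24 * k, 10), round(single$times, 10))
    out <- single$conc[idx]
    out[is.na(out)] <- 0
    out
  }
  super <- Reduce(`+`, lapply(0:13, shift_by))
  expect_lt(max(abs(multi$conc - super)) / max(multi$conc), 1e-3)
})

test_that("mass is conserved across gut, compartments, first-pass and elimination", {
  p <- model_params(ka = 1, fa = 0.9, v_central = 100, v_peripheral = 66,
                    q_inter = 8, cl_int_scaled = c(MAOA = 25, CYP2D6 = 3),
                    q_hepatic = 85)
  reg <- regimen(500, 24, 14)
  prof <- simulate_profile(p, reg, 55, duration = 336, dt = 0.1)
  st <- attr(prof, "states")
  total <- st$gut + st$central + st$peripheral + st$eliminated
  dose <- p$fa * 500 * 55
  # lsoda reports the state at an event time before applying the event, so a
  # dose counts once the clock is strictly past it
  given <- dose * vapply(st$time, function(t) sum((0:13) * 24 < t), numeric(1))
  err <- abs(total - given) / attr(prof, "dosed_fa")
  expect_lt(max(err), 1e-3)
})

test_that("PK metrics are exact on constant and triangular profiles and converge on grids", {
  t <- seq(0, 24, by = 0.5)
  const <- concentration_profile(t, rep(5, length(t)))
  m <- pk_metrics(const, c(0, 24))
  expect_equal(m$cmax, 5)
  expect_equal(m$auc_tau, 5 * 24)
  expect_equal(m$cavg, 5)
  tri <- concentration_profile(c(0, 12, 24), c(0, 10, 0))
  m2 <- pk_metrics(tri, c(0, 24))
  expect_equal(m2$auc_tau, 120) # trapezoid equals the exact triangle area
  expect_equal(m2$tmax, 12)
  # ODE output AUC is grid-converged
  p <- model_params(ka = 1, fa = 1, v_central = 100, v_peripheral = 66,
                    q_inter = 8, cl_int_scaled = c(MAOA = 28), q_hepatic = 85)
  coarse <- simulate_profile(p, regimen(500, 24, 2), 55, duration = 48, dt = 0.1)
  fine <- simulate_profile(p, regimen(500, 24, 2), 55, duration = 48, dt = 0.01)
  a1 <- pk_metrics(coarse, c(24, 48))$auc_tau
  a2 <- pk_metrics(fine, c(24, 48))$auc_tau
  expect_lt(abs(a1 - a2) / a2, 5e-4)
  expect_error(pk_metrics(coarse, c(40, 60)), "outside the profile span")
  expect_error(pk_metrics(coarse, c(10, 10)), "increasing pair")
})

test_that("scaled clearance honours ontogeny, the low-extraction limit and AAG", {
  cal <- get_calibration()
  s <- typical_subject(0.5)
  # zero enzyme activity -> zero hepatic clearance
  om0 <- list(MAOA = ontogeny_profile(f_birth = 0, age50 = 1e9),
              CYP2D6 = ontogeny_profile(f_birth = 0, age50 = 1e9))
  sc0 <- scaled_clearance(s, cal$drug, om0)
  expect_lt(sc0$cl_hepatic, 1e-6)
  # low-extraction limit: CL_h ~ fu_b * sum(CL_int)
  d <- cal$drug
  d$cl_int_by_pathway <- d$cl_int_by_pathway / 1000
  sc <- scaled_clearance(s, d, infant_ontogeny())
  expect_equal(sc$cl_hepatic, sum(sc$cl_int_scaled), tolerance = 1e-3)
  # four-fold AAG cuts fu and hepatic clearance
  sc1 <- scaled_clearance(s, cal$drug, infant_ontogeny(), aag_fold = 1)
  sc4 <- scaled_clearance(s, cal$drug, infant_ontogeny(), aag_fold = 4)
  expect_lt(sc4$fu_plasma, sc1$fu_plasma)
  expect_lt(sc4$cl_hepatic, sc1$cl_hepatic)
})

test_that("adult calibration reproduces the observed day-14 maternal exposure", {
  cal <- get_calibration()
  expect_equal(cal$achieved[["cmax"]], 129, tolerance = 5e-3)
  expect_equal(cal$achieved[["auc"]], 988, tolerance = 5e-3)
  # steady-state identity: apparent oral clearance = daily dose / AUC_tau
  expect_equal(cal$cl_over_f_per_kg, 500 / 988, tolerance = 5e-3)
  # pathway split follows fraction metabolized
  expect_equal(unname(cal$drug$cl_int_by_pathway / sum(cal$drug$cl_int_by_pathway)),
               unname(cal$drug$fm_by_pathway), tolerance = 1e-9)
  expect_error(calibrate_adult(target_cmax = -1), "positive")
})

test_that("calibrated pediatric scaling brackets the observed school-age exposures", {
  cal <- get_calibration()
  # daily dosing for 7 days in the four observed pediatric cohorts;
  # printed day-7 Cmax values are 113, 127, 106 and 112 ng/mL
  cohorts <- list(c(age = 2.5, dose = 420, printed = 113),
                  c(age = 6, dose = 500, printed = 127),
                  c(age = 10, dose = 440, printed = 106),
                  c(age = 13, dose = 460, printed = 112))
  for (co in cohorts) {
    s <- typical_subject(co[["age"]])
    pars <- subject_model_params(s, cal$drug, cal$disposition,
                                 infant_ontogeny())
    prof <- simulate_profile(pars, regimen(co[["dose"]], 24, 7), s$weight,
                             duration = 168, dt = 0.1)
    cmax <- pk_metrics(prof, c(144, 168))$cmax
    expect_gt(cmax / co[["printed"]], 1 / 1.5)
    expect_lt(cmax / co[["printed"]], 1.5)
  }
})
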