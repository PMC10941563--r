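# Shared fixtures: the calibrated model and the virtual studies are expensive,
# so they are built lazily once per test run and reused across files.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- maker()
  .fixtures[[key]]
}

get_calibration <- function() cached("cal", function() calibrate_adult())

get_mother_summary <- function() cached("mother", function() {
  run_trial_set(scenario_mother_lactation(get_calibration()))
})

get_infant_summary <- function(idd = 2.98) {
  cached(sprintf("infant_%g", idd), function() {
    run_trial_set(scenario_infant(get_calibration(), idd = idd))
  })
}

get_neonate_summary <- function(maoa) {
  cached(sprintf("neonate_%s", maoa), function() {
    run_trial_set(scenario_neonate(get_calibration(), maoa = maoa))
  })
}

# typical (median) subject of a given age: growth-curve anthropometry, unit
# between-subject multipliers
typical_subject <- function(age, sex = "male", config = physiology_config()) {
  if (age < 18) {
    h <- height_for_age(age, sex)
    w <- weight_for_height_age(h, age, sex)
  } else {
    h <- config$adult_height_mean[[sex]]
    w <- config$adult_weight_mean[[sex]]
  }
  lw <- liver_weight(age, w, config)
  subject(age = age, sex = sex, height = h, weight = w, liver_weight = lw,
          hepatic_blood_flow = hepatic_blood_flow(lw, config),
          aag = aag_for_age(age, config))
}

infant_ontogeny <- function() list(MAOA = "maoa_none", CYP2D6 = "cyp2d6_default")

# day-14 Cmax of a typical subject under an infant feeding regimen
typical_infant_cmax <- function(subj, idd, ontogeny = infant_ontogeny(),
                                aag_fold = 1, dt = 0.1) {
  cal <- get_calibration()
  pars <- subject_model_params(subj, cal$drug, cal$disposition, ontogeny,
                               aag_fold = aag_fold)
  prof <- simulate_profile(pars, feeding_regimen(idd), subj$weight,
                           duration = 336, dt = dt)
  pk_metrics(prof, day14_window())$cmax
}

get_maternal_truth_profile <- function() cached("mother_profile", function() {
  cal <- get_calibration()
  ref <- reference_mother()
  om <- list(MAOA = ontogeny_profile(none = TRUE),
             CYP2D6 = ontogeny_profile(none = TRUE))
  pars <- subject_model_params(ref, cal$drug, cal$disposition, om)
  simulate_profile(pars, maternal_regimen(), ref$weight, duration = 336,
                   dt = 0.1)
})
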