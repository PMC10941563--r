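#' Scenario configuration
#'
#' A validated bundle of everything one virtual study needs: population,
#' regimen, ontogeny assignment, drug and disposition parameters, milk mode,
#' assessment window and seeds. Validation reports every faulty field before
#' any computation.
#'
#' @param name Scenario label.
#' @param population A `population_spec`.
#' @param reg A `regimen`.
#' @param ontogeny Named list pathway -> preset name or `ontogeny_profile`,
#'   covering every pathway of `drug`.
#' @param drug A `drug_parameters` with calibrated `cl_int_by_pathway`.
#' @param disposition List with `vc_per_kg`, `vp_per_kg`, `q_per_kg` (from
#'   [calibrate_adult()]).
#' @param milk_mode `"observed_mp"`, `"predicted_mp"` or `"fixed_idd"`.
#' @param mp_value M/P ratio used when `milk_mode = "observed_mp"`.
#' @param idd Infant daily dose (ug/kg/day) when `milk_mode = "fixed_idd"`.
#' @param n_trials Number of virtual trials.
#' @param aag_fold AAG multiplier (sensitivity scans).
#' @param duration,dt,window Simulation span (h), grid (h), assessment window.
#' @param physiology A `physiology_config`.
#' @param iiv_cv Between-subject lognormal CVs, list(cl=, v=).
#' @param seed Base seed.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(name, population, reg, ontogeny, drug, disposition,
                            milk_mode = c("fixed_idd", "observed_mp", "predicted_mp"),
                            mp_value = 0.34, idd = NULL,
                            n_trials = 10, aag_fold = 1,
                            duration = 336, dt = 0.1, window = day14_window(),
                            physiology = physiology_config(),
                            iiv_cv = list(cl = 0.35, v = 0.25),
                            seed = 20231212) {
  milk_mode <- match.arg(milk_mode)
  problems <- character()
  if (!inherits(population, "population_spec")) {
    problems <- c(problems, "population: not a population_spec")
  }
  if (!inherits(reg, "regimen")) problems <- c(problems, "reg: not a regimen")
  if (!inherits(drug, "drug_parameters")) {
    problems <- c(problems, "drug: not a drug_parameters")
  } else if (is.null(drug$cl_int_by_pathway)) {
    problems <- c(problems, "drug: cl_int_by_pathway not set (run calibrate_adult)")
  }
  om <- tryCatch(resolve_ontogeny_map(ontogeny), error = function(e) e)
  if (inherits(om, "error")) {
    problems <- c(problems, paste0("ontogeny: ", conditionMessage(om)))
  } else if (inherits(drug, "drug_parameters") &&
             !is.null(drug$cl_int_by_pathway) &&
             length(setdiff(names(drug$cl_int_by_pathway), names(om)))) {
    problems <- c(problems, "ontogeny: does not cover every drug pathway")
  }
  if (!all(c("vc_per_kg", "vp_per_kg", "q_per_kg") %in% names(disposition))) {
    problems <- c(problems, "disposition: needs vc_per_kg, vp_per_kg, q_per_kg")
  }
  if (milk_mode == "fixed_idd" && is.null(idd)) {
    problems <- c(problems, "idd: required when milk_mode is fixed_idd")
  }
  if (aag_fold <= 0) problems <- c(problems, "aag_fold: must be positive")
  if (duration <= 0 || dt <= 0) problems <- c(problems, "duration/dt: must be positive")
  if (length(problems)) {
    stop("invalid scenario config:\n  - ", paste(problems, collapse = "\n  - "))
  }
  structure(
    list(name = name, population = population, regimen = reg, ontogeny = om,
         drug = drug, disposition = disposition, milk_mode = milk_mode,
         mp_value = mp_value, idd = idd, n_trials = n_trials,
         aag_fold = aag_fold, duration = duration, dt = dt, window = window,
         physiology = physiology, iiv_cv = iiv_cv, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

adult_ontogeny <- function(drug) {
  om <- lapply(drug$fm_by_pathway, function(...) ontogeny_profile(none = TRUE))
  names(om) <- names(drug$fm_by_pathway)
  om
}

#' Shipped maternal lactation scenario
#'
#' Ten trials of 20 women aged 18-40 years receiving 0.5 mg/kg primaquine
#' once daily for 14 days; milk concentrations follow the observed M/P of
#' 0.34.
#'
#' @param calib Output of [calibrate_adult()].
#' @param seed Base seed.
#' @param n_trials,n_per_trial Study size (defaults 10 x 20).
#' @param dt Simulation grid (h).
#' @return A `scenario_config`.
#' @export
scenario_mother_lactation <- function(calib, seed = 101, n_trials = 10,
                                      n_per_trial = 20, dt = 0.1) {
  scenario_config(
    name = "mother_lactation",
    population = population_spec(n_per_trial, c(18, 40), proportion_female = 1,
                                 seed = seed),
    reg = maternal_regimen(),
    ontogeny = adult_ontogeny(calib$drug),
    drug = calib$drug, disposition = calib$disposition,
    milk_mode = "observed_mp", mp_value = 0.34,
    n_trials = n_trials, dt = dt, seed = seed
  )
}

#' Shipped breastfed-infant scenario (>= 28 days old)
#'
#' Ten trials of 20 infants (33% girls) aged 1.5-22 months receiving the
#' infant daily dose over six feeds 4 h apart for 14 days, with the default
#' CYP2D6 ontogeny and adult-level MAO-A activity per gram of liver.
#'
#' @param calib Output of [calibrate_adult()].
#' @param idd Infant daily dose, ug/kg/day (2.98 average, 9.07 highest).
#' @param seed Base seed.
#' @param n_trials,n_per_trial Study size (defaults 10 x 20).
#' @param dt Simulation grid (h).
#' @return A `scenario_config`.
#' @export
scenario_infant <- function(calib, idd = 2.98, seed = 202, n_trials = 10,
                            n_per_trial = 20, dt = 0.1) {
  scenario_config(
    name = sprintf("infant_idd_%.3g", idd),
    population = population_spec(n_per_trial, c(0.125, 1.83),
                                 proportion_female = 0.33, seed = seed),
    reg = feeding_regimen(idd),
    ontogeny = list(MAOA = "maoa_none", CYP2D6 = "cyp2d6_default"),
    drug = calib$drug, disposition = calib$disposition,
    milk_mode = "fixed_idd", idd = idd,
    n_trials = n_trials, dt = dt, seed = seed
  )
}

#' Shipped neonate scenario (< 28 days old)
#'
#' Ten trials of 20 neonates aged 0-28 days receiving the average infant daily
#' dose over six 4-hourly feeds, under a chosen MAO-A ontogeny assumption
#' (`"maoa_none"` or `"maoa_slow"`); CYP2D6 keeps its default ontogeny.
#'
#' @param calib Output of [calibrate_adult()].
#' @param maoa `"maoa_none"` or `"maoa_slow"`.
#' @param idd Infant daily dose, ug/kg/day.
#' @param seed Base seed.
#' @param n_trials,n_per_trial Study size (defaults 10 x 20).
#' @param dt Simulation grid (h).
#' @return A `scenario_config`.
#' @export
scenario_neonate <- function(calib, maoa = c("maoa_none", "maoa_slow"),
                             idd = 2.98, seed = 303, n_trials = 10,
                             n_per_trial = 20, dt = 0.1) {
  maoa <- match.arg(maoa)
  scenario_config(
    name = sprintf("neonate_%s", maoa),
    population = population_spec(n_per_trial, c(0, 28 / 365.25),
                                 proportion_female = 0.5, seed = seed),
    reg = feeding_regimen(idd),
    ontogeny = list(MAOA = maoa, CYP2D6 = "cyp2d6_default"),
    drug = calib$drug, disposition = calib$disposition,
    milk_mode = "fixed_idd", idd = idd,
    n_trials = n_trials, dt = dt, seed = seed
  )
}

#' Run a scenario and collect its artifact bundle
#'
#' Executes the virtual study, optionally writes the subject-level table
#' (CSV), the summary (JSON if jsonlite is available) and a plain-text run
#' log, and returns everything invisibly-friendly in one list.
#'
#' @param config A `scenario_config`.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List with `summary` (a `trial_summary`), `config` and `log`.
#' @export
run_scenario <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  ts <- run_trial_set(config)
  log <- c(
    sprintf("scenario: %s", config$name),
    sprintf("seed: %d", config$seed),
    sprintf("trials: %d x %d subjects", ts$n_trials, ts$n_per_trial),
    sprintf("regimen: %g ug/kg q%gh x %d", config$regimen$dose_per_kg,
            config$regimen$interval, config$regimen$n_doses),
    sprintf("milk mode: %s", config$milk_mode),
    sprintf("aag_fold: %g", config$aag_fold),
    sprintf("grid: dt %g h, duration %g h, window [%g, %g] h", config$dt,
            config$duration, config$window[1], config$window[2]),
    sprintf("package: lactpbpk %s",
            as.character(utils::packageVersion("lactpbpk")))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(ts$subjects,
                     file.path(out_dir, paste0(config$name, "_subjects.csv")),
                     row.names = FALSE)
    writeLines(log, file.path(out_dir, paste0(config$name, "_run.log")))
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(
        list(per_trial = ts$per_trial, pooled = ts$pooled,
             n_trials = ts$n_trials, n_per_trial = ts$n_per_trial,
             seed = ts$seed),
        file.path(out_dir, paste0(config$name, "_summary.json")),
        auto_unbox = TRUE, digits = NA)
    }
  }
  list(summary = ts, config = config, log = log)
}

#' One-parameter sensitivity scan over a scenario
#'
#' Re-runs a scenario per grid point with everything else (including seeds)
#' fixed. Supported parameters:
#' * `"aag_fold"`: multiplies every subject's AAG; outcome columns are the
#'   pooled median Cmax/AUC and, when a maternal `reference` summary is given,
#'   the relative exposure in percent;
#' * `"milk_ph"` / `"milk_fat"`: milk composition scans; outcome is the
#'   predicted M/P ratio (no population simulation involved);
#' * `"intake"`: milk intake in mL/kg/day; outcome is the IDD implied by the
#'   scenario's M/P value and a supplied maternal average concentration.
#'
#' @param config A `scenario_config`.
#' @param parameter One of `"aag_fold"`, `"milk_ph"`, `"milk_fat"`, `"intake"`.
#' @param grid Non-empty numeric grid.
#' @param reference Optional maternal `trial_summary` (for relative exposure).
#' @param maternal_cavg Maternal Cavg (ng/mL), used by the `"intake"` scan.
#' @param milk Base `milk_composition` for milk scans (mature milk preset).
#' @return A data frame, one row per grid point.
#' @export
sensitivity_scan <- function(config, parameter = c("aag_fold", "milk_ph",
                                                   "milk_fat", "intake"),
                             grid, reference = NULL, maternal_cavg = NULL,
                             milk = milk_preset("mature")) {
  parameter <- match.arg(parameter)
  if (length(grid) < 1) stop("sensitivity grid must be non-empty")
  fu_pp <- postpartum_fu(config$drug)
  rows <- lapply(grid, function(g) {
    switch(parameter,
      aag_fold = {
        cfg <- config
        cfg$aag_fold <- g
        ts <- run_trial_set(cfg)
        out <- data.frame(parameter = parameter, value = g,
                          cmax_median = ts$pooled$cmax[["median"]],
                          auc_median = ts$pooled$auc[["median"]])
        if (!is.null(reference)) {
          rel <- relative_exposure(ts, reference)
          out$rel_cmax_pct <- rel[["cmax_pct"]]
          out$rel_auc_pct <- rel[["auc_pct"]]
        }
        out
      },
      milk_ph = {
        m <- milk_composition(g, milk$fat_fraction, milk$ph_plasma,
                              milk$protein_ratio)
        data.frame(parameter = parameter, value = g,
                   mp_ratio = mp_ratio(config$drug, m, fu_pp)$mp_ratio)
      },
      milk_fat = {
        m <- milk_composition(milk$ph_milk, g, milk$ph_plasma,
                              milk$protein_ratio)
        data.frame(parameter = parameter, value = g,
                   mp_ratio = mp_ratio(config$drug, m, fu_pp)$mp_ratio)
      },
      intake = {
        if (is.null(maternal_cavg)) {
          stop("intake scan needs maternal_cavg (ng/mL)")
        }
        data.frame(parameter = parameter, value = g,
                   idd = idd_from_mp(config$mp_value, maternal_cavg, g))
      }
    )
  })
  do.call(rbind, rows)
}
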