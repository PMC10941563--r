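#' Physiology configuration
#'
#' Collects the config-defined anthropometry and organ-scaling choices used to
#' build virtual subjects: adult height/weight means and coefficients of
#' variation, pediatric growth-curve CVs, the liver-weight allometry, hepatic
#' blood flow per kg liver, the AAG maturation curve, and the hepatic
#' metabolic-capacity maturation applied to intrinsic clearance per gram of
#' liver.
#'
#' Defaults (units in parentheses):
#' * adult means: female 160 cm / 55 kg, male 172 cm / 70 kg, with lognormal
#'   CVs of 10% (height) and 20% (weight);
#' * pediatric CVs: 4% height, 15% weight around the growth curves;
#' * liver weight (kg) = 0.07665 * weight^0.70 (1.5 kg for a 70-kg adult,
#'   ~5% of body weight at birth falling to ~2.2% in adults);
#' * hepatic blood flow (L/h) = 66 * liver weight (kg);
#' * AAG (g/L) = 0.7 * (0.45 + 0.55 * a/(a + 35)) with a = postnatal weeks;
#' * hepatic capacity fraction = 0.35 + 0.65 * a^1.6/(a^1.6 + 6^1.6).
#'
#' @param ... Named overrides of any default listed above.
#' @return A list of class `physiology_config`.
#' @export
physiology_config <- function(...) {
  cfg <- list(
    adult_height_mean = c(female = 160, male = 172),   # cm
    adult_weight_mean = c(female = 55, male = 70),     # kg
    adult_cv_height = 0.10,
    adult_cv_weight = 0.20,
    child_cv_height = 0.04,
    child_cv_weight = 0.15,
    liver_coef = 0.07665,      # kg per kg^liver_exp body weight
    liver_exp = 0.70,
    qh_per_kg_liver = 66,      # L/h per kg liver
    aag_adult = 0.7,           # g/L
    aag_birth_fraction = 0.45,
    aag_age50_weeks = 35,
    aag_hill = 1,
    capacity_birth_fraction = 0.35,
    capacity_age50_weeks = 6,
    capacity_hill = 1.6
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown physiology_config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "physiology_config")
}

WEEKS_PER_YEAR <- 365.25 / 7

#' Height-for-age growth curves (under 18 years)
#'
#' Evaluates the sex-specific polynomial height curves fitted to pediatric
#' growth data: degree 7 in age for boys, degree 8 for girls. Valid for
#' 0 <= age < 18 years; adults are handled by fixed sex-specific means in
#' [sample_subject()].
#'
#' @param age Age in years, in `[0, 18)`. Vectorized.
#' @param sex `"male"` or `"female"`.
#' @return Height in cm.
#' @export
height_for_age <- function(age, sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (any(age < 0)) stop("age must be non-negative")
  if (any(age >= 18)) stop("height_for_age applies to ages below 18 years")
  if (sex == "male") {
    0.0000176179 * age^7 - 0.00119874 * age^6 + 0.0323848 * age^5 -
      0.444112 * age^4 + 3.2946 * age^3 - 13.2191 * age^2 +
      33.75 * age + 45.62152
  } else {
    -0.00000151027 * age^8 + 0.000121261 * age^7 - 0.0040023 * age^6 +
      0.070179 * age^5 - 0.708233 * age^4 + 4.1872 * age^3 -
      14.3393 * age^2 + 33.84778 * age + 40.535477
  }
}

#' Weight from height and age (under 18 years)
#'
#' Sex-specific pediatric weight model combining an age-saturating term, an
#' exponential height term, and a small linear age term:
#' boys `6.026*(1 - exp(-1.2*age)) + exp(0.0209*height) + 0.023*age`,
#' girls `4.054*(1 - exp(-1.57*age)) + exp(0.0224*height) + 0.019*age`.
#'
#' @param height Height in cm; positive. Vectorized with `age`.
#' @param age Age in years, in `[0, 18)`.
#' @param sex `"male"` or `"female"`.
#' @return Weight in kg.
#' @export
weight_for_height_age <- function(height, age, sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (any(height <= 0)) stop("height must be positive")
  if (any(age < 0)) stop("age must be non-negative")
  if (any(age >= 18)) stop("weight_for_height_age applies to ages below 18 years")
  if (sex == "male") {
    6.026 * (1 - exp(-1.2 * age)) + exp(0.0209 * height) + 0.023 * age
  } else {
    4.054 * (1 - exp(-1.57 * age)) + exp(0.0224 * height) + 0.019 * age
  }
}

#' Liver weight from body weight
#'
#' Allometric liver mass, `liver_coef * weight^liver_exp`. With the default
#' coefficients a 70-kg adult carries a 1.5-kg liver while the liver fraction
#' of body weight is substantially higher in infancy (about 5% at birth).
#'
#' @param age Age in years (retained in the signature for alternative
#'   age-dependent allometries; the default formula depends on weight only).
#' @param weight Body weight in kg; positive.
#' @param config A `physiology_config`.
#' @return Liver weight in kg.
#' @export
liver_weight <- function(age, weight, config = physiology_config()) {
  if (any(weight <= 0)) stop("weight must be positive")
  if (any(age < 0)) stop("age must be non-negative")
  config$liver_coef * weight^config$liver_exp
}

#' Hepatic blood flow from liver mass
#'
#' @param liver_kg Liver weight in kg.
#' @param config A `physiology_config`.
#' @return Hepatic blood flow in L/h (perfusion-scaled, default 66 L/h per kg
#'   liver, i.e. ~1.1 mL/min/g).
#' @export
hepatic_blood_flow <- function(liver_kg, config = physiology_config()) {
  if (any(liver_kg <= 0)) stop("liver mass must be positive")
  config$qh_per_kg_liver * liver_kg
}

#' AAG concentration for age
#'
#' Monotone non-decreasing maturation of alpha-1-acid glycoprotein from a
#' neonatal fraction of the adult level to the adult 0.7 g/L:
#' `aag_adult * (f0 + (1 - f0) * a^h / (a^h + a50^h))` with `a` the postnatal
#' age in weeks.
#'
#' @param age Age in years; non-negative. Vectorized.
#' @param config A `physiology_config`.
#' @return AAG concentration in g/L.
#' @export
aag_for_age <- function(age, config = physiology_config()) {
  if (any(age < 0)) stop("age must be non-negative")
  a <- age * WEEKS_PER_YEAR
  f0 <- config$aag_birth_fraction
  h <- config$aag_hill
  a50 <- config$aag_age50_weeks
  config$aag_adult * (f0 + (1 - f0) * a^h / (a^h + a50^h))
}

#' Hepatic metabolic capacity maturation
#'
#' System-level maturation of intrinsic clearance per gram of liver (the
#' microsomal/mitochondrial protein content of hepatic tissue), applied
#' multiplicatively to every metabolic pathway on top of the pathway-specific
#' enzyme ontogeny. Fraction of the adult capacity:
#' `c0 + (1 - c0) * a^h / (a^h + a50^h)` with `a` in postnatal weeks.
#'
#' @param age Age in years; non-negative. Vectorized.
#' @param config A `physiology_config`.
#' @return Fraction of adult capacity in `[c0, 1)`.
#' @export
hepatic_capacity <- function(age, config = physiology_config()) {
  if (any(age < 0)) stop("age must be non-negative")
  a <- age * WEEKS_PER_YEAR
  c0 <- config$capacity_birth_fraction
  h <- config$capacity_hill
  a50 <- config$capacity_age50_weeks
  c0 + (1 - c0) * a^h / (a^h + a50^h)
}

#' Virtual population specification
#'
#' @param n_subjects Number of subjects per trial.
#' @param age_range Two-element numeric, years, ordered.
#' @param proportion_female Fraction of females in `[0, 1]`.
#' @param seed Integer seed making the population reproducible.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(n_subjects, age_range, proportion_female = 0.5,
                            seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be at least 1")
  if (length(age_range) != 2 || age_range[1] > age_range[2]) {
    stop("age_range must be an ordered pair of years")
  }
  if (age_range[1] < 0) stop("ages must be non-negative")
  if (proportion_female < 0 || proportion_female > 1) {
    stop("proportion_female must be in [0, 1]")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), age_range = as.numeric(age_range),
         proportion_female = proportion_female, seed = as.integer(seed)),
    class = "population_spec"
  )
}

lognormal_deviate <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = 0, sd = sdlog)) # median 1
}

#' Sample one virtual subject
#'
#' Draws age uniformly on the spec's range and sex as Bernoulli(proportion
#' female). Children (<18 y) get height from the sex-specific growth curve and
#' weight from the height/age model, each with a lognormal CV; adults use the
#' fixed sex-specific means with their own lognormal CVs. Liver weight,
#' hepatic blood flow and AAG follow from the physiology config, and
#' between-subject lognormal multipliers for intrinsic clearance and volume
#' are attached as `iiv`.
#'
#' Sampling consumes the current RNG stream; seed it (or use
#' [sample_population()], which seeds from the spec) for reproducibility.
#'
#' @param spec A `population_spec`.
#' @param config A `physiology_config`.
#' @param iiv_cv Named list with `cl` and `v` lognormal CVs for the
#'   between-subject multipliers (defaults 35% and 25%).
#' @return A list of class `subject`.
#' @export
sample_subject <- function(spec, config = physiology_config(),
                           iiv_cv = list(cl = 0.35, v = 0.25)) {
  stopifnot(inherits(spec, "population_spec"))
  age <- stats::runif(1, spec$age_range[1], spec$age_range[2])
  sex <- if (stats::runif(1) < spec$proportion_female) "female" else "male"
  if (age < 18) {
    height <- height_for_age(age, sex) * lognormal_deviate(1, config$child_cv_height)
    weight <- weight_for_height_age(height, age, sex) *
      lognormal_deviate(1, config$child_cv_weight)
  } else {
    height <- config$adult_height_mean[[sex]] *
      lognormal_deviate(1, config$adult_cv_height)
    weight <- config$adult_weight_mean[[sex]] *
      lognormal_deviate(1, config$adult_cv_weight)
  }
  liver <- liver_weight(age, weight, config)
  subject(
    age = age, sex = sex, height = height, weight = weight,
    liver_weight = liver,
    hepatic_blood_flow = hepatic_blood_flow(liver, config),
    aag = aag_for_age(age, config),
    iiv = c(cl = lognormal_deviate(1, iiv_cv$cl),
            v = lognormal_deviate(1, iiv_cv$v))
  )
}

#' Construct a virtual subject
#'
#' @param age Years. @param sex "male"/"female". @param height cm.
#' @param weight kg. @param liver_weight kg. @param hepatic_blood_flow L/h.
#' @param aag g/L. @param iiv named multipliers (`cl`, `v`).
#' @return A list of class `subject`.
#' @export
subject <- function(age, sex, height, weight, liver_weight,
                    hepatic_blood_flow, aag, iiv = c(cl = 1, v = 1)) {
  if (age < 0 || age > 60) stop("age must be in [0, 60] years")
  vals <- c(height = height, weight = weight, liver_weight = liver_weight,
            hepatic_blood_flow = hepatic_blood_flow, aag = aag)
  if (any(vals <= 0)) stop("all physical quantities must be positive")
  if (liver_weight >= weight) stop("liver_weight must be below body weight")
  structure(
    list(age = age, sex = sex, height = height, weight = weight,
         liver_weight = liver_weight, hepatic_blood_flow = hepatic_blood_flow,
         aag = aag, iiv = iiv),
    class = "subject"
  )
}

#' Sample a full population reproducibly
#'
#' Seeds the RNG from `spec$seed` and draws `spec$n_subjects` subjects.
#'
#' @inheritParams sample_subject
#' @return List of `subject` objects.
#' @export
sample_population <- function(spec, config = physiology_config(),
                              iiv_cv = list(cl = 0.35, v = 0.25)) {
  set.seed(spec$seed)
  lapply(seq_len(spec$n_subjects), function(i) sample_subject(spec, config, iiv_cv))
}

#' Reference adult mother used for model calibration
#'
#' A typical postpartum subject: 29-year-old female at the adult population
#' means (160 cm, 55 kg), adult AAG of 0.7 g/L, unit between-subject
#' multipliers.
#'
#' @param config A `physiology_config`.
#' @return A `subject`.
#' @export
reference_mother <- function(config = physiology_config()) {
  w <- config$adult_weight_mean[["female"]]
  lw <- liver_weight(29, w, config)
  subject(
    age = 29, sex = "female",
    height = config$adult_height_mean[["female"]], weight = w,
    liver_weight = lw, hepatic_blood_flow = hepatic_blood_flow(lw, config),
    aag = config$aag_adult
  )
}
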