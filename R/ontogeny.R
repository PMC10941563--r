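#' Enzyme ontogeny profile
#'
#' Describes the maturation of one metabolic pathway as a fraction of adult
#' activity per gram of liver: `f_birth + (1 - f_birth) * a^hill / (a^hill +
#' age50^hill)` with `a` the postnatal age in weeks. A profile with
#' `none = TRUE` is the constant-1 "no ontogeny" case (adult activity at all
#' ages).
#'
#' @param f_birth Fraction of adult activity at birth, in `[0, 1]`.
#' @param age50 Postnatal age (weeks) at half-maturation; positive.
#' @param hill Hill steepness; positive.
#' @param none If `TRUE`, the profile is constant 1 at all ages.
#' @return A list of class `ontogeny_profile`.
#' @export
ontogeny_profile <- function(f_birth = 0, age50 = 1, hill = 1, none = FALSE) {
  if (!none) {
    if (f_birth < 0 || f_birth > 1) stop("f_birth must be in [0, 1]")
    if (age50 <= 0) stop("age50 must be positive")
    if (hill <= 0) stop("hill must be positive")
  }
  structure(list(f_birth = f_birth, age50 = age50, hill = hill, none = none),
            class = "ontogeny_profile")
}

#' Named ontogeny presets
#'
#' * `"cyp2d6_default"`: fast postnatal maturation (f_birth 0.05, half-
#'   maturation 2 weeks, hill 1), the shape used for CYP2D6 by default.
#' * `"maoa_none"`: no ontogeny -- adult MAO-A activity per gram of liver at
#'   all ages.
#' * `"maoa_slow"`: slow maturation (f_birth 0.2, half-maturation 60 weeks,
#'   hill 1), the conservative MAO-A scenario.
#'
#' @param name Preset name.
#' @return An `ontogeny_profile`.
#' @export
ontogeny_preset <- function(name) {
  switch(name,
    cyp2d6_default = ontogeny_profile(f_birth = 0.05, age50 = 2, hill = 1),
    maoa_none = ontogeny_profile(none = TRUE),
    maoa_slow = ontogeny_profile(f_birth = 0.2, age50 = 60, hill = 1),
    stop("unknown ontogeny preset: ", name)
  )
}

#' Fraction of adult enzyme activity at a given age
#'
#' @param age Age in years; non-negative. Vectorized.
#' @param profile An `ontogeny_profile` (or a preset name).
#' @return Fraction of adult activity in `[0, 1]`, monotone non-decreasing in
#'   age, approaching 1 as age grows.
#' @export
fraction_adult <- function(age, profile) {
  if (is.character(profile)) profile <- ontogeny_preset(profile)
  stopifnot(inherits(profile, "ontogeny_profile"))
  if (any(age < 0)) stop("age must be non-negative")
  if (profile$none) return(rep(1, length(age)))
  a <- age * WEEKS_PER_YEAR
  h <- profile$hill
  profile$f_birth + (1 - profile$f_birth) * a^h / (a^h + profile$age50^h)
}

#' Resolve an ontogeny map
#'
#' Turns a named list of presets/profiles (one per pathway) into a list of
#' `ontogeny_profile` objects, validating preset names.
#'
#' @param map Named list: pathway -> preset name or `ontogeny_profile`.
#' @return Named list of `ontogeny_profile` objects.
#' @export
resolve_ontogeny_map <- function(map) {
  out <- lapply(map, function(p) {
    if (is.character(p)) ontogeny_preset(p) else p
  })
  ok <- vapply(out, inherits, logical(1), what = "ontogeny_profile")
  if (!all(ok)) stop("ontogeny map entries must be preset names or ontogeny_profile objects")
  out
}
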