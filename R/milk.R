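#' Milk composition
#'
#' @param ph_milk Milk pH, in `[6.5, 8]`.
#' @param fat_fraction Milk fat volume fraction, in `[0, 0.2)`.
#' @param ph_plasma Plasma pH (default 7.4).
#' @param protein_ratio Milk/plasma binding-protein scalar: the bound/free
#'   ratio in skim milk relative to plasma. Calibrated once for primaquine via
#'   [calibrate_protein_ratio()].
#' @return A list of class `milk_composition`.
#' @export
milk_composition <- function(ph_milk, fat_fraction, ph_plasma = 7.4,
                             protein_ratio = 0) {
  if (ph_milk < 6.5 || ph_milk > 8) stop("ph_milk must be in [6.5, 8]")
  if (fat_fraction < 0 || fat_fraction >= 0.2) {
    stop("fat_fraction must be in [0, 0.2)")
  }
  if (protein_ratio < 0) stop("protein_ratio must be non-negative")
  structure(
    list(ph_milk = ph_milk, fat_fraction = fat_fraction,
         ph_plasma = ph_plasma, protein_ratio = protein_ratio),
    class = "milk_composition"
  )
}

#' Named milk composition presets
#'
#' Colostrum (pH 7.6, 2% fat, 1-4 days postpartum), transitional milk
#' (pH 7.44, 4% fat, 5-30 days) and mature milk (pH 7.2, 4% fat, >30 days).
#'
#' @param name Preset name.
#' @param protein_ratio Binding-protein scalar to attach (see
#'   [calibrate_protein_ratio()]).
#' @return A `milk_composition`.
#' @export
milk_preset <- function(name, protein_ratio = primaquine_protein_ratio()) {
  switch(name,
    colostrum = milk_composition(7.6, 0.02, protein_ratio = protein_ratio),
    transitional = milk_composition(7.44, 0.04, protein_ratio = protein_ratio),
    mature = milk_composition(7.2, 0.04, protein_ratio = protein_ratio),
    stop("unknown milk preset: ", name)
  )
}

#' Un-ionized fraction of a monoprotic base
#'
#' Henderson-Hasselbalch neutral-species fraction, `1 / (1 + 10^(pka - pH))`;
#' strictly increasing in pH for a base.
#'
#' @param ph Medium pH. Vectorized.
#' @param pka_base Basic dissociation constant.
#' @return Fraction un-ionized in `(0, 1)`.
#' @export
unionized_fraction <- function(ph, pka_base) {
  1 / (1 + 10^(pka_base - ph))
}

#' Milk-to-plasma concentration ratio (phase-distribution model)
#'
#' Predicts the milk-to-plasma (M/P) ratio of a passively diffusing drug by
#' equilibrating the unbound, un-ionized species between plasma and the two
#' milk phases:
#'
#' * skim phase: ion trapping plus skim protein binding,
#'   `skim = fu_plasma * (1 + 10^(pka - pH_milk)) /
#'          ((1 + 10^(pka - pH_plasma)) * fu_skim)`,
#'   with `fu_skim` derived from `fu_plasma` by scaling the bound/free ratio
#'   with the milk/plasma `protein_ratio`;
#' * fat phase: `fat = fu_plasma * unionized_fraction(pH_plasma) * K_fat`,
#'   with the milk-fat partition coefficient `K_fat = 10^(0.99*logP - 0.88)`;
#'
#' and mixing them by fat volume fraction:
#' `M/P = (1 - fat_fraction) * skim + fat_fraction * fat`.
#'
#' @param drug A `drug_parameters` object.
#' @param milk A `milk_composition`.
#' @param fu_plasma Fraction unbound in maternal plasma, in `(0, 1]`.
#' @return A list of class `milk_transfer_result` with `mp_ratio`,
#'   `skim_conc_ratio` and `fat_conc_ratio`.
#' @export
mp_ratio <- function(drug, milk, fu_plasma) {
  stopifnot(inherits(drug, "drug_parameters"), inherits(milk, "milk_composition"))
  if (!(fu_plasma > 0 && fu_plasma <= 1)) stop("fu_plasma must be in (0, 1]")
  bound_free_plasma <- (1 - fu_plasma) / fu_plasma
  fu_skim <- 1 / (1 + milk$protein_ratio * bound_free_plasma)
  skim <- fu_plasma * (1 + 10^(drug$pka_base - milk$ph_milk)) /
    ((1 + 10^(drug$pka_base - milk$ph_plasma)) * fu_skim)
  k_fat <- 10^(0.99 * drug$logp - 0.88)
  fat <- fu_plasma * unionized_fraction(milk$ph_plasma, drug$pka_base) * k_fat
  structure(
    list(
      mp_ratio = (1 - milk$fat_fraction) * skim + milk$fat_fraction * fat,
      skim_conc_ratio = skim,
      fat_conc_ratio = fat
    ),
    class = "milk_transfer_result"
  )
}

#' Calibrate the milk binding-protein scalar
#'
#' Solves for the single unprinted scalar of the phase-distribution model, the
#' milk/plasma binding-protein ratio, so that the predicted M/P ratio equals a
#' target at a stated milk composition. For primaquine the anchor is the
#' predicted M/P of 0.47 in mature milk (pH 7.2, 4% fat) at the postpartum
#' plasma unbound fraction; the scalar is then frozen for all other
#' compositions.
#'
#' @param drug A `drug_parameters`.
#' @param target_mp M/P ratio to reproduce.
#' @param ph_milk,fat_fraction Milk composition of the anchor.
#' @param fu_plasma Maternal plasma unbound fraction at the anchor.
#' @return The calibrated protein ratio (non-negative scalar).
#' @export
calibrate_protein_ratio <- function(drug, target_mp = 0.47, ph_milk = 7.2,
                                    fat_fraction = 0.04,
                                    fu_plasma = postpartum_fu(drug)) {
  f <- function(pr) {
    milk <- milk_composition(ph_milk, fat_fraction, protein_ratio = pr)
    mp_ratio(drug, milk, fu_plasma)$mp_ratio - target_mp
  }
  # milk protein binding raises total milk concentration, so M/P increases
  # with protein_ratio; a free-drug-only prediction already above the target
  # would need negative binding
  if (f(0) > 0) stop("target M/P unreachable: prediction without milk binding already exceeds target")
  stats::uniroot(f, c(0, 1e3), tol = 1e-12)$root
}

#' Postpartum plasma unbound fraction
#'
#' Fraction unbound at the postpartum (non-pregnancy) AAG level of 0.7 g/L,
#' from the drug's single-site binding model.
#'
#' @param drug A `drug_parameters`.
#' @param aag_postpartum Postpartum AAG (g/L), default 0.7.
#' @return Fraction unbound.
#' @export
postpartum_fu <- function(drug, aag_postpartum = 0.7) {
  fu_at_aag(binding_model_for(drug), aag_postpartum)
}

#' Calibrated primaquine milk binding-protein scalar
#'
#' The frozen value of [calibrate_protein_ratio()] for the default primaquine
#' parameters (anchor M/P 0.47 at pH 7.2, 4% fat, postpartum fu).
#'
#' @return Scalar, ~0.0159.
#' @export
primaquine_protein_ratio <- function() {
  calibrate_protein_ratio(primaquine_parameters())
}

#' Infant daily dose from milk exposure
#'
#' `IDD (ug/kg/day) = M/P * maternal average plasma concentration (ng/mL) *
#' milk intake (mL/kg/day) / 1000`.
#'
#' @param mp Milk-to-plasma ratio.
#' @param maternal_cavg Maternal average plasma concentration, ng/mL.
#' @param milk_intake Milk consumption, mL/kg/day (150 by convention; 200 for
#'   the conservative early-infancy case).
#' @return Infant daily dose in ug/kg/day.
#' @export
idd_from_mp <- function(mp, maternal_cavg, milk_intake = 150) {
  if (mp < 0 || maternal_cavg < 0 || milk_intake <= 0) {
    stop("inputs must be non-negative (intake positive)")
  }
  mp * maternal_cavg * milk_intake / 1000
}

#' Infant daily dose from a cumulative milk dose
#'
#' @param cumulative_dose Total dose consumed over the course, mg/kg.
#' @param days Duration in days (>= 1).
#' @return Daily dose in ug/kg/day, `1000 * cumulative_dose / days`.
#' @export
idd_from_cumulative <- function(cumulative_dose, days) {
  if (days < 1) stop("days must be at least 1")
  if (cumulative_dose < 0) stop("cumulative_dose must be non-negative")
  1000 * cumulative_dose / days
}

#' Relative infant daily dose
#'
#' @param idd Infant daily dose, ug/kg/day.
#' @param maternal_dose Maternal weight-normalized daily dose, ug/kg/day.
#' @return RIDD in percent, `100 * idd / maternal_dose`.
#' @export
ridd <- function(idd, maternal_dose) {
  if (maternal_dose <= 0) stop("maternal_dose must be positive")
  if (idd < 0) stop("idd must be non-negative")
  100 * idd / maternal_dose
}

#' Dose per feed
#'
#' @param idd Infant daily dose, ug/kg/day.
#' @param n_feeds Feeds per day (>= 1).
#' @return Per-feed dose in ug/kg.
#' @export
per_feed_dose <- function(idd, n_feeds) {
  if (n_feeds < 1) stop("n_feeds must be at least 1")
  idd / n_feeds
}
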