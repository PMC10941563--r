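# Milk-model expectations below 1e-6 tolerance were recomputed independently
# with 30-digit arithmetic from the phase-distribution equations and frozen.

test_that("un-ionized fraction follows Henderson-Hasselbalch for a base", {
  expect_equal(unionized_fraction(10.4, 10.4), 0.5)
  expect_equal(unionized_fraction(7.4, 10.4), 0.000999000999001,
               tolerance = 1e-9)
  ph <- seq(6.5, 8, by = 0.05)
  expect_true(all(diff(unionized_fraction(ph, 10.4)) > 0))
})

test_that("binding-protein scalar calibrates to the anchor M/P and is frozen", {
  pq <- primaquine_parameters()
  pr <- calibrate_protein_ratio(pq)
  expect_equal(pr, 0.0159412047742, tolerance = 1e-6)
  milk <- milk_composition(7.2, 0.04, protein_ratio = pr)
  expect_equal(mp_ratio(pq, milk, postpartum_fu(pq))$mp_ratio, 0.47,
               tolerance = 1e-9)
})

test_that("M/P is insensitive to fat and strongly pH dependent, as a base should be", {
  pq <- primaquine_parameters()
  pr <- primaquine_protein_ratio()
  fu <- postpartum_fu(pq)
  mp_at <- function(ph, fat) {
    mp_ratio(pq, milk_composition(ph, fat, protein_ratio = pr), fu)$mp_ratio
  }
  expect_equal(mp_at(7.2, 0.02), 0.47903158, tolerance = 1e-6)
  expect_equal(round(mp_at(7.2, 0.02), 2), 0.48)
  expect_equal(round(mp_at(7.2, 0.05), 2), 0.47)
  expect_lt(abs(mp_at(7.2, 0.02) - mp_at(7.2, 0.05)), 0.02)
  # ion trapping: strictly decreasing in milk pH for a base
  phs <- seq(7.0, 7.8, by = 0.02)
  mps <- vapply(phs, mp_at, numeric(1), fat = 0.04)
  expect_true(all(diff(mps) < 0))
})

test_that("milk phases mix by fat fraction and a neutral unbound drug equilibrates to 1", {
  pq <- primaquine_parameters()
  res <- mp_ratio(pq, milk_preset("mature"), postpartum_fu(pq))
  expect_equal(res$mp_ratio,
               0.96 * res$skim_conc_ratio + 0.04 * res$fat_conc_ratio,
               tolerance = 1e-12)
  # pKa far below both pH values, no binding, no fat -> M/P = 1
  neutral <- drug_parameters("neutral-like", pka_base = 2, logp = 0,
                             fu_plasma_ref = 1, aag_ref = 0.6,
                             fm_by_pathway = c(MAOA = 1))
  milk0 <- milk_composition(7.2, 0, protein_ratio = 0)
  expect_equal(mp_ratio(neutral, milk0, 1)$mp_ratio, 1, tolerance = 1e-3)
  expect_error(mp_ratio(pq, milk0, 0), "fu_plasma")
})

test_that("infant daily dose arithmetic is exact", {
  expect_equal(idd_from_mp(0.34, 41.2, 150), 2.1012, tolerance = 1e-12)
  expect_equal(idd_from_mp(0, 41.2, 150), 0)
  # intake 200 vs 150 scales the IDD by exactly 4/3
  expect_equal(idd_from_mp(0.34, 41.2, 200) / idd_from_mp(0.34, 41.2, 150),
               4 / 3, tolerance = 1e-12)
  expect_equal(idd_from_cumulative(0.127, 14), 127 / 14, tolerance = 1e-12)
  expect_equal(idd_from_cumulative(0, 14), 0)
  # round trip daily dose -> cumulative course dose
  expect_equal(idd_from_cumulative(2.98 * 14 / 1000, 14), 2.98,
               tolerance = 1e-12)
  expect_equal(ridd(2.98, 500), 0.596, tolerance = 1e-12)
  expect_equal(ridd(0, 500), 0)
  expect_equal(ridd(9.07, 500), 1.814, tolerance = 1e-12)
  expect_equal(per_feed_dose(2.98, 6), 2.98 / 6, tolerance = 1e-12)
  expect_equal(per_feed_dose(3.3, 1), 3.3)
  expect_error(ridd(1, 0), "positive")
  expect_error(per_feed_dose(1, 0), "n_feeds")
  expect_error(idd_from_cumulative(1, 0), "days")
})
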