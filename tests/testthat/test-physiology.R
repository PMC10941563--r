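# Expected heights/weights below were evaluated independently from the growth
# polynomial coefficients with 30-digit arithmetic (mpmath) and frozen here.

test_that("height-for-age polynomials match a high-precision oracle", {
  boys <- rbind(
    c(0, 45.62152), c(0.5, 59.5768064323273), c(1, 69.0341116779),
    c(2, 80.4579773312), c(5, 101.9976059375), c(10, 130.61052)
  )
  girls <- rbind(
    c(0, 40.535477), c(0.5, 54.3558089367646), c(1, 63.58922045073),
    c(2, 75.04442457888), c(5, 97.70325590625), c(10, 127.136277)
  )
  for (i in seq_len(nrow(boys))) {
    expect_equal(height_for_age(boys[i, 1], "male"), boys[i, 2],
                 tolerance = 1e-9)
  }
  for (i in seq_len(nrow(girls))) {
    expect_equal(height_for_age(girls[i, 1], "female"), girls[i, 2],
                 tolerance = 1e-9)
  }
  expect_error(height_for_age(-1, "male"), "non-negative")
  expect_error(height_for_age(18, "male"), "below 18")
})

test_that("weight model matches its closed form and saturates with age", {
  # at age 0 only the exponential height term survives
  expect_equal(weight_for_height_age(45.62152, 0, "male"), 2.59474894948127,
               tolerance = 1e-9)
  expect_equal(weight_for_height_age(40.535477, 0, "female"),
               2.47934567539918, tolerance = 1e-9)
  expect_equal(weight_for_height_age(height_for_age(10, "male"), 10, "male"),
               21.5851685200953, tolerance = 1e-9)
  # school-age mass lands in a plausible growth-chart range
  w10 <- weight_for_height_age(height_for_age(10, "male"), 10, "male")
  expect_gt(w10, 20)
  expect_lt(w10, 35)
  # the age-saturating term approaches its constant (6.026 boys, 4.054 girls)
  h <- 150
  res_boy <- weight_for_height_age(h, 17, "male") - exp(0.0209 * h) - 0.023 * 17
  expect_equal(res_boy, 6.026, tolerance = 1e-6)
  res_girl <- weight_for_height_age(h, 17, "female") - exp(0.0224 * h) - 0.019 * 17
  expect_equal(res_girl, 4.054, tolerance = 1e-6)
  expect_error(weight_for_height_age(0, 5, "male"), "positive")
})

test_that("liver allometry gives an adult 1.5-kg liver and infant enrichment", {
  expect_equal(liver_weight(30, 70), 1.5, tolerance = 1e-3)
  # per-kg liver mass is higher in infants than adults
  expect_gt(liver_weight(0.5, 6) / 6, liver_weight(30, 70) / 70)
  # strictly increasing in weight
  w <- seq(3, 80, by = 1)
  expect_true(all(diff(liver_weight(30, w)) > 0))
  expect_gt(hepatic_blood_flow(1.5), hepatic_blood_flow(0.2))
})

test_that("AAG and hepatic capacity mature monotonically to adult levels", {
  ages <- seq(0, 40, by = 0.05)
  aag <- aag_for_age(ages)
  expect_true(all(diff(aag) >= 0))
  expect_equal(aag_for_age(0), 0.45 * 0.7, tolerance = 1e-12)
  expect_equal(aag_for_age(30), 0.7, tolerance = 0.02)
  cap <- hepatic_capacity(ages)
  expect_true(all(diff(cap) >= 0))
  expect_equal(hepatic_capacity(0), 0.35, tolerance = 1e-12)
  expect_gt(hepatic_capacity(30), 0.99)
  expect_true(all(cap <= 1))
})

test_that("population sampling is reproducible and respects subject invariants", {
  spec <- population_spec(50, c(0.125, 1.83), proportion_female = 0.33,
                          seed = 42)
  p1 <- sample_population(spec)
  p2 <- sample_population(spec)
  expect_identical(p1, p2)
  for (s in p1) {
    expect_true(s$age >= 0.125 && s$age <= 1.83)
    expect_true(all(c(s$height, s$weight, s$liver_weight,
                      s$hepatic_blood_flow, s$aag) > 0))
    expect_lt(s$liver_weight, s$weight)
  }
})

test_that("sampled sex and age distributions match the specification", {
  spec <- population_spec(10000, c(18, 40), proportion_female = 0.33,
                          seed = 7)
  pop <- sample_population(spec)
  frac_f <- mean(vapply(pop, function(s) s$sex == "female", logical(1)))
  sd_binom <- sqrt(0.33 * 0.67 / 10000)
  expect_lt(abs(frac_f - 0.33), 3 * sd_binom)
  ages <- vapply(pop, `[[`, numeric(1), "age")
  sd_unif <- (40 - 18) / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(ages) - 29), 3 * sd_unif)
})
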