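flat_profile <- function(level, t_end = 336) {
  t <- seq(0, t_end, by = 1)
  concentration_profile(t, rep(level, length(t)))
}

test_that("a zero error model returns the interpolated truth uncensored", {
  prof <- get_maternal_truth_profile()
  times <- lactation_sampling_times()
  obs <- synth_observations(prof, times, error = list(cv_prop = 0, sd_add = 0),
                            lloq = 0, seed = 1)
  truth <- approx(prof$times, prof$conc, xout = times)$y
  expect_equal(obs$conc_ng_ml, truth, tolerance = 1e-12)
  expect_false(any(obs$blq))
})

test_that("observations below the LLOQ are flagged BLQ and withheld", {
  # infant-like truth (~0.14 ng/mL) against a 1 ng/mL assay: everything BLQ
  prof <- flat_profile(0.14)
  obs <- synth_observations(prof, lactation_sampling_times(), lloq = 1,
                            seed = 3)
  expect_true(all(obs$blq))
  expect_true(all(is.na(obs$conc_ng_ml)))
  # quantified values always sit at or above the LLOQ
  prof2 <- flat_profile(2)
  obs2 <- synth_observations(prof2, lactation_sampling_times(), lloq = 1,
                             seed = 4)
  q <- obs2$conc_ng_ml[!obs2$blq]
  expect_true(all(q >= 1))
  expect_error(synth_observations(prof2, c(0, 2), lloq = -1), "lloq")
  expect_error(synth_observations(prof2, c(-5, 2)), "span")
})

test_that("the error model is unbiased before censoring", {
  prof <- flat_profile(20)
  reps <- vapply(1:2000, function(i) {
    synth_observations(prof, 10, lloq = 0, seed = 10000 + i)$conc_ng_ml
  }, numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 20), 3 * se)
})

test_that("dense noiseless milk sampling recovers the generating IDD", {
  prof <- get_maternal_truth_profile()
  milk <- concentration_profile(prof$times, prof$conc * 0.34)
  w <- day14_window()
  dense <- seq(w[1], w[2], by = 0.1)
  obs <- synth_observations(milk, dense, error = list(cv_prop = 0, sd_add = 0),
                            lloq = 0, seed = 1, matrix = "milk")
  rec <- recover_idd(obs, intake = 150)
  truth <- idd_from_mp(0.34, pk_metrics(prof, w)$cavg, 150)
  expect_equal(rec, truth, tolerance = 0.02)
  # halving the intake halves the estimate
  expect_equal(recover_idd(obs, 75) / rec, 0.5, tolerance = 1e-12)
})

test_that("an all-BLQ observation set cannot support IDD estimation", {
  prof <- flat_profile(0.1)
  obs <- synth_observations(prof, lactation_sampling_times(), lloq = 1,
                            seed = 5, matrix = "milk")
  expect_error(recover_idd(obs), "at least two quantified")
})

test_that("observation sets serialize with their LLOQ and seed header", {
  prof <- flat_profile(30)
  obs <- synth_observations(prof, lactation_sampling_times(), lloq = 1,
                            seed = 8, matrix = "milk")
  path <- withr::local_tempfile(fileext = ".csv")
  write_observation_set(obs, path)
  lines <- readLines(path)
  expect_true(any(grepl("lloq_ng_ml: 1", lines)))
  expect_true(any(grepl("seed: 8", lines)))
  df <- read.csv(path, comment.char = "#")
  expect_equal(nrow(df), nrow(obs))
  expect_true(all(c("subject_id", "matrix", "time_h", "conc_ng_ml",
                    "blq_flag") %in% names(df)))
})
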