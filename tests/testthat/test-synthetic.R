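test_that("time-course generation is seeded, baselined and noise-true", {
  d1 <- generate_timecourse("MRC5", noise_sd = 0.2, n_reps = 3, seed = 5)
  d2 <- generate_timecourse("MRC5", noise_sd = 0.2, n_reps = 3, seed = 5)
  expect_identical(d1$data, d2$data)
  d3 <- generate_timecourse("MRC5", noise_sd = 0.2, n_reps = 3, seed = 6)
  expect_false(identical(d1$data, d3$data))

  clean <- generate_timecourse("MRC5", noise_sd = 0, n_reps = 1, seed = 1)
  at0 <- subset(clean$data, time == 0)
  expect_true(all(at0$log2fc == 0))  # baseline is the pre-stimulus steady
  tnc <- subset(clean$data, gene == "TNC")
  expect_true(all(diff(tnc$log2fc[order(tnc$time)]) >= 0))

  expect_error(generate_timecourse("MRC5", protocol = dox_step(10, 0, 5),
                                   times = c(0, 10)), "span")
  expect_error(generate_timecourse("nope"), "unknown preset")
})

test_that("noise-free data scores exactly the likelihood constant", {
  d <- generate_timecourse("IMR90", noise_sd = 0, n_reps = 2, seed = 3)
  sigma <- 0.25
  n <- nrow(d$data)
  expect_equal(nll_objective(imr90_preset$params, d, sigma),
               n * log(sigma * sqrt(2 * pi)), tolerance = 1e-8)
  # doubling sigma with zero residual shifts it by n log 2
  expect_equal(nll_objective(imr90_preset$params, d, 2 * sigma) -
                 nll_objective(imr90_preset$params, d, sigma),
               n * log(2), tolerance = 1e-8)
})

test_that("dose-response activates only at the highest dose", {
  d <- generate_dose_response(noise_sd = 0, n_reps = 1, seed = 1)
  w <- reshape(d$data[, c("dose", "gene", "fold_change")],
               idvar = "dose", timevar = "gene", direction = "wide")
  names(w) <- c("dose", "Twist1", "TNC")
  expect_equal(w$Twist1[w$dose == 0], 1)
  expect_equal(w$TNC[w$dose == 0], 1)
  # fold changes are monotone in dose, noise-free
  expect_true(all(diff(w$Twist1) >= 0))
  expect_true(all(diff(w$TNC) >= 0))
  active <- w$Twist1 > 2 & w$TNC > 2
  expect_identical(w$dose[active], 5)

  # seeded reproducibility with noise
  n1 <- generate_dose_response(noise_sd = 0.2, seed = 9)
  n2 <- generate_dose_response(noise_sd = 0.2, seed = 9)
  expect_identical(n1$data, n2$data)
})

test_that("single-cell snapshots are concordant, bimodal mixtures", {
  snap <- generate_single_cell_snapshot(ref_params, 4, n_cells = 2000,
                                        cell_to_cell_cv = 0.2,
                                        fraction_on = 0.5, seed = 2)
  df <- snap$data
  expect_identical(nrow(df), 2000L)
  expect_true(all(df$Twist1 >= 0 & df$Prrx1 >= 0 & df$TNC >= 0))

  # within-cell concordance: gating TNC at the geometric mid-point between
  # the two states reproduces the generating ON/OFF class exactly (the
  # state gap dwarfs the cell-to-cell noise), and the Twist1 gate agrees
  # for virtually every cell
  tnc_hi <- df$TNC > sqrt(snap$off_state[3] * snap$on_state[3])
  expect_identical(tnc_hi, df$state == "ON")
  tw_hi <- df$Twist1 > sqrt(snap$off_state[1] * snap$on_state[1])
  expect_gt(mean(tw_hi == tnc_hi), 0.99)

  # each marginal is bimodal on the log scale
  for (g in c("Twist1", "Prrx1", "TNC")) {
    expect_gt(bimodality_coefficient(log(df[[g]])), 5 / 9)
  }

  # gating at the unstable fixed point's TNC recovers the ON fraction
  # within binomial error (3 s.e.; moderate cell-to-cell noise so the gate
  # sits clear of both mixture components)
  tight <- generate_single_cell_snapshot(ref_params, 4, n_cells = 2000,
                                         cell_to_cell_cv = 0.1,
                                         fraction_on = 0.5, seed = 2)
  est <- mean(tight$data$TNC > tight$threshold_tnc)
  expect_lt(abs(est - 0.5), 3 * sqrt(0.25 / 2000))

  off <- generate_single_cell_snapshot(ref_params, 4, n_cells = 200,
                                       fraction_on = 0, seed = 3)
  expect_true(all(off$data$state == "OFF"))
  expect_lt(max(off$data$TNC), snap$threshold_tnc)

  # a monostable stimulus is rejected with the bistable window in the
  # message
  expect_error(generate_single_cell_snapshot(ref_params, 9, seed = 1),
               "bistable window")
  expect_error(generate_single_cell_snapshot(ref_params, 4,
                                             fraction_on = 1.5),
               "fraction_on")
})
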