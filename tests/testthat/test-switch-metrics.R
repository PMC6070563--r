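test_that("hysteresis metrics capture the reference switch", {
  h <- hysteresis(ref_params, mode = "dox", method = "continuation")
  expect_false(h$monostable)
  expect_gt(h$theta_on, h$theta_off)
  expect_gt(h$width, 0)
  expect_true(h$reversible)
  expect_lt(abs(h$delta_tnc), 1e-3)

  # relax engine agrees
  hr <- hysteresis(ref_params, seq(0, 10, length.out = 51), mode = "dox",
                   method = "relax")
  expect_equal(hr$theta_on, h$theta_on)
  expect_equal(hr$theta_off, h$theta_off)
  expect_equal(hr$delta_tnc, h$delta_tnc, tolerance = 1e-3)

  # ablated feedback: no hysteresis at all
  h0 <- hysteresis(update_params(ref_params, v_feedback = 0), mode = "dox",
                   method = "continuation")
  expect_true(h0$monostable)
  expect_identical(h0$delta_tnc, 0)
  expect_identical(h0$width, 0)

  # strong feedback: the active state persists at zero stimulus
  h80 <- hysteresis(update_params(ref_params, v_feedback = 80),
                    mode = "dox", method = "continuation")
  expect_gt(h80$delta_tnc, 1e-3)
  expect_false(h80$reversible)
  expect_true(is.na(h80$theta_off))
})

test_that("quasi-static delta-TNC matches a slow-ramp integration", {
  # irreversible dox case: ramp dox up and back down very slowly and
  # compare the terminal TNC shift with the quasi-static value
  p <- update_params(ref_params, v_feedback = 80)
  h <- hysteresis(p, mode = "dox", method = "continuation")
  ramp <- pfl_protocol("dox", data.frame(
    t_start = c(0, 400), t_end = c(400, 800),
    level_start = c(0, 10), level_end = c(10, 0)))
  init <- basal_state(p, "dox")
  traj <- simulate_pfl(p, ramp, times = seq(0, 800, 10), init = init)
  final <- relax_to_steady(p, 0, "dox",
                           init = as.numeric(traj[nrow(traj),
                                                  c("Twist1", "Prrx1",
                                                    "TNC")]))
  slow <- final$state[["TNC"]] - init[["TNC"]]
  expect_equal(h$delta_tnc, slow, tolerance = 0.02)
})

test_that("pulse irreversibility reproduces the injection-model anchors", {
  expect_identical(delta_tnc_for_pulse(inj_params, 0), 0)
  # (km_feedback, v_feedback) = (5, 30): latches on for a pulse of 3
  expect_gt(delta_tnc_for_pulse(inj_params, 3), 1e-3)
  # (10, 15): returns to baseline for any pulse amplitude
  rev_p <- update_params(inj_params, km_feedback = 10, v_feedback = 15)
  for (amp in c(0.5, 3, 20)) {
    expect_lt(abs(delta_tnc_for_pulse(rev_p, amp)), 1e-3)
  }
  expect_identical(classify_phase(inj_params, "tnc_injection"), "II")
  expect_identical(classify_phase(rev_p, "tnc_injection"), "I")
  expect_identical(
    classify_phase(update_params(ref_params, v_feedback = 0), "dox"), "I")
})

test_that("delta-TNC is non-negative across random parameter draws", {
  set.seed(23)
  for (i in 1:6) {
    p <- jitter_params(inj_params, 0.25)
    d <- delta_tnc_for_pulse(p, 3)
    expect_gte(d, -1e-3)
  }
})

test_that("phase diagrams split the plane into the two phases", {
  pd <- phase_diagram(
    ref_params,
    list(name = "v_feedback", values = seq(0, 100, length.out = 8)),
    list(name = "vmax_dox_over_deg_Tw", values = seq(1, 20, length.out = 8)),
    mode = "dox")
  expect_identical(sort(unique(as.vector(pd$phase))), c("I", "II"))
  expect_identical(pd$phase[8, 8], "II")  # high feedback, stable Twist1
  expect_identical(pd$phase[1, 1], "I")

  # a 1x1 diagram reduces to the phase classifier
  one <- phase_diagram(
    inj_params,
    list(name = "km_feedback", values = 5),
    list(name = "v_feedback", values = 30),
    mode = "tnc_injection")
  expect_identical(as.vector(one$phase), classify_phase(inj_params,
                                                        "tnc_injection"))

  # the fast engine agrees with the explicit quasi-static sweep
  for (v in c(10, 40, 80)) {
    p <- update_params(ref_params, v_feedback = v)
    fast <- phase_diagram(p, list(name = "v_feedback", values = v),
                          list(name = "deg_Tw", values = 1),
                          mode = "dox")$delta_tnc[1, 1]
    full <- hysteresis(p, mode = "dox", method = "continuation")$delta_tnc
    expect_equal(fast, full, tolerance = 0.02 * max(full, 1e-3))
  }

  expect_error(phase_diagram(ref_params,
                             list(name = "not_a_param", values = 1:2),
                             list(name = "deg_Tw", values = 1:2)),
               "not a kinetic parameter")

  # deterministic: identical inputs give identical diagrams
  again <- phase_diagram(
    inj_params,
    list(name = "km_feedback", values = 5),
    list(name = "v_feedback", values = 30),
    mode = "tnc_injection")
  expect_identical(one$delta_tnc, again$delta_tnc)
})

test_that("hysteresis width grows with feedback at a stable threshold", {
  wc <- hysteresis_width_curve(ref_params, seq(10, 90, by = 10),
                               mode = "dox")
  closed <- wc[!wc$open_ended & !is.na(wc$theta_on), ]
  expect_gt(nrow(closed), 1)
  # width non-decreasing (allowing grid-resolution ties) until open-ended
  expect_true(all(diff(closed$width) > -0.26))
  # the activation threshold stays within 20% before the open-ended regime
  expect_lt(diff(range(closed$theta_on)) / max(closed$theta_on), 0.2)
  # ablated feedback: no width
  w0 <- hysteresis_width_curve(ref_params, c(0, 5), mode = "dox")
  expect_identical(w0$width[1], 0)
  # irreversible regime flagged open-ended
  expect_true(any(wc$open_ended))
})
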