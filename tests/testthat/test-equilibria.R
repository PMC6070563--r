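test_that("the open cascade has exactly one stable fixed point", {
  p <- update_params(ref_params, v_feedback = 0)
  for (s in c(0, 1, 4, 10)) {
    fp <- find_fixed_points(p, s, "dox")
    expect_identical(nrow(fp), 1L)
    expect_true(fp$stable)
    expect_equal(as.numeric(fp[1, c("Twist1", "Prrx1", "TNC")]),
                 unname(open_cascade_steady(p, s)), tolerance = 1e-8)
  }
})

test_that("the reference model is bistable at intermediate dox", {
  fp <- find_fixed_points(ref_params, 4, "dox")
  expect_identical(nrow(fp), 3L)
  expect_identical(fp$stable, c(TRUE, FALSE, TRUE))
  expect_true(all(diff(fp$Twist1) > 0))
  # residual check: each root solves the steady-state system
  for (i in 1:3) {
    st <- as.numeric(fp[i, c("Twist1", "Prrx1", "TNC")])
    expect_lt(max(abs(pfl_rhs(st, 4, ref_params, "dox"))), 1e-6)
  }

  # brute-force relaxation from the 27-point grid finds exactly these two
  # stable states
  grid <- init_grid_27(ref_params)
  ends <- t(apply(grid, 1, function(y0) {
    as.numeric(relax_to_steady(ref_params, 4, "dox", init = y0)$state)
  }))
  stable <- fp[fp$stable, ]
  for (i in seq_len(nrow(ends))) {
    dist <- abs(ends[i, 1] - stable$Twist1) / pmax(stable$Twist1, 1e-9)
    expect_lt(min(dist), 1e-4)
  }
  # both basins are represented
  expect_identical(sort(unique(round(ends[, 1], 2))),
                   sort(round(stable$Twist1, 2)))
})

test_that("the origin is a fixed point when production is fully silenced", {
  p <- pfl_params(basal_Tw = 0, basal_P = 0, basal_T = 0, vmax_dox = 0)
  fp <- find_fixed_points(p, 0, "dox")
  expect_true(any(abs(fp$Twist1) < 1e-9 & abs(fp$TNC) < 1e-9))
})

test_that("sweeps trace monotone branches that agree across engines", {
  grid <- seq(0, 10, length.out = 41)
  # no feedback: up and down sweeps coincide
  p0 <- update_params(ref_params, v_feedback = 0)
  up0 <- response_sweep(p0, grid, "up", "dox", "continuation")
  dn0 <- response_sweep(p0, grid, "down", "dox", "continuation")
  expect_equal(up0$TNC, dn0$TNC, tolerance = 1e-6)

  up <- response_sweep(ref_params, grid, "up", "dox", "continuation")
  expect_true(all(diff(up$TNC) > -1e-9))
  # the up-sweep jumps abruptly at the activation threshold
  expect_gt(max(up$TNC[-1] / pmax(up$TNC[-41], 1e-12)), 2)

  upr <- response_sweep(ref_params, grid, "up", "dox", "relax")
  expect_equal(up$TNC, upr$TNC, tolerance = 1e-4)

  # down-sweep dominance: the upper branch persists
  dn <- response_sweep(ref_params, grid, "down", "dox", "continuation",
                       init = as.numeric(up[41, c("Twist1", "Prrx1",
                                                  "TNC")]))
  expect_true(all(dn$TNC >= up$TNC - 1e-6))
})

test_that("stable-branch count stays in {1, 2} across random draws", {
  set.seed(11)
  for (i in 1:10) {
    p <- jitter_params(ref_params, 0.3)
    for (s in c(0, 3, 8)) {
      fp <- find_fixed_points(p, s, "dox")
      expect_true(sum(fp$stable) %in% c(1L, 2L))
      expect_true(all(fp$stable == (fp$leading_eigenvalue < 0)))
    }
  }
})

test_that("every stable root is an attractor of nearby states", {
  fp <- find_fixed_points(ref_params, 4, "dox")
  for (i in which(fp$stable)) {
    st <- as.numeric(fp[i, c("Twist1", "Prrx1", "TNC")])
    r <- relax_to_steady(ref_params, 4, "dox", init = st * 1.02 + 1e-4)
    expect_true(r$converged)
    expect_equal(as.numeric(r$state), st, tolerance = 1e-4)
  }
})

test_that("feedback sharpens the dose-response steepness", {
  g <- ultrasensitivity_gain(ref_params, seq(0, 10, length.out = 81),
                             mode = "dox", method = "continuation")
  expect_gt(g$n_eff, g$n_eff_control)
  expect_gt(g$n_eff_control, 1)

  # a jump spanning both crossings is reported as infinitely steep
  gi <- ultrasensitivity_gain(inj_params, seq(0, 3, length.out = 41),
                              mode = "tnc_injection",
                              method = "continuation")
  expect_true(gi$discontinuous)
  expect_identical(gi$n_eff, Inf)

  # a flat branch has no defined gain (without feedback the injection
  # stimulus has no route into the loop)
  expect_error(
    ultrasensitivity_gain(update_params(inj_params, v_feedback = 0),
                          seq(0, 3, length.out = 11),
                          mode = "tnc_injection", method = "continuation"),
    "flat")
})
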