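test_that("hill satisfies its algebraic identities and domain checks", {
  for (n in c(1, 2, 4, 7.5)) {
    expect_identical(hill(0, 3, n), 0)
    expect_equal(hill(3, 3, n), 0.5)
  }
  expect_equal(hill(2, 1, 4), 16 / 17)
  expect_error(hill(1, 0, 2), "K")
  expect_error(hill(1, -1, 2), "K")
  expect_error(hill(1, 2, 0.5), "n")
  expect_error(hill(-1, 2, 2), "x")
  # monotone, bounded in [0, 1)
  x <- seq(0, 50, length.out = 200)
  y <- hill(x, 2.5, 3)
  expect_true(all(diff(y) >= 0))
  expect_true(all(y >= 0 & y < 1))
})

test_that("the rhs respects the loop wiring", {
  p0 <- pfl_params(basal_Tw = 0, basal_P = 0, basal_T = 0)
  expect_equal(unname(pfl_rhs(c(0, 0, 0), 0, p0, "dox")), c(0, 0, 0))

  # feedback ablation: dTw/dt independent of TNC
  p <- update_params(ref_params, v_feedback = 0)
  d1 <- pfl_rhs(c(1, 1, 0.1), 3, p, "dox")
  d2 <- pfl_rhs(c(1, 1, 7.3), 3, p, "dox")
  expect_equal(d1[["Twist1"]], d2[["Twist1"]])

  # injection mode senses endogenous plus exogenous TNC and no dox drive
  da <- pfl_rhs(c(1, 1, 1), 2, inj_params, "tnc_injection")
  db <- pfl_rhs(c(1, 1, 3), 0, inj_params, "tnc_injection")
  expect_equal(da[["Twist1"]], db[["Twist1"]])

  expect_error(pfl_rhs(c(-1, 0, 0), 0, ref_params), "non-negative")
})

test_that("rhs matches a finite-difference check of the trajectory", {
  proto <- dox_step(5, 0, 2)
  init <- c(2, 1, 0.5)
  dt <- 1e-3
  traj <- simulate_pfl(ref_params, proto, times = c(0, dt, 2 * dt),
                       init = init)
  # central difference approximates the derivative at the midpoint t = dt
  fd <- (as.numeric(traj[3, c("Twist1", "Prrx1", "TNC")]) -
           as.numeric(traj[1, c("Twist1", "Prrx1", "TNC")])) / (2 * dt)
  mid <- as.numeric(traj[2, c("Twist1", "Prrx1", "TNC")])
  expect_equal(fd, unname(pfl_rhs(mid, 5, ref_params, "dox")),
               tolerance = 1e-4)
})

test_that("integration is exact on degenerate inputs and deterministic", {
  pz <- pfl_params(basal_Tw = 0, basal_P = 0, basal_T = 0, vmax_dox = 0,
                   v_feedback = 0, vmax_TwP = 0, vmax_PT = 0)
  traj <- simulate_pfl(pz, dox_step(3, 0, 10), times = 0:10,
                       init = c(0, 0, 0))
  expect_true(all(as.matrix(traj[, c("Twist1", "Prrx1", "TNC")]) == 0))

  # starting at a verified stable fixed point, the trajectory is constant
  fp <- find_fixed_points(ref_params, 4, "dox")
  st <- fp[fp$stable, ][1, ]
  traj <- simulate_pfl(ref_params, dox_step(4, 0, 50), times = seq(0, 50, 5),
                       init = as.numeric(st[c("Twist1", "Prrx1", "TNC")]))
  expect_equal(traj$TNC, rep(st$TNC, nrow(traj)), tolerance = 1e-7)

  t1 <- simulate_pfl(ref_params, dox_step(8, 0, 15), times = seq(0, 15, 0.5))
  t2 <- simulate_pfl(ref_params, dox_step(8, 0, 15), times = seq(0, 15, 0.5))
  expect_identical(t1, t2)

  expect_error(simulate_pfl(ref_params, dox_step(8, 0, 5), times = 0:10),
               "span")
  expect_error(simulate_pfl(ref_params, dox_step(8, 0, 5),
                            times = c(0, 0, 1)), "increasing")
})

test_that("a super-threshold step lands on the high equilibrium branch", {
  traj <- simulate_pfl(ref_params, dox_step(10, 0, 120),
                       times = seq(0, 120, 2))
  fp <- find_fixed_points(ref_params, 10, "dox")
  high <- fp[fp$stable, ]
  high <- high[nrow(high), ]
  expect_equal(traj$TNC[nrow(traj)], high$TNC, tolerance = 0.01)
})

test_that("trajectories stay non-negative for random parameters", {
  set.seed(42)
  for (i in 1:5) {
    p <- jitter_params(ref_params, 0.3)
    traj <- simulate_pfl(p, dox_step(6, 1, 15), times = seq(0, 15, 0.25),
                         init = c(0, 0, 0))
    expect_true(all(as.matrix(traj[, c("Twist1", "Prrx1", "TNC")]) >= -1e-10))
  }
})

test_that("relaxation finds the steady states the root scan predicts", {
  # already at a fixed point: returned unchanged
  fp <- find_fixed_points(ref_params, 0, "dox")
  st <- as.numeric(fp[1, c("Twist1", "Prrx1", "TNC")])
  r <- relax_to_steady(ref_params, 0, "dox", init = st)
  expect_true(r$converged)
  expect_equal(as.numeric(r$state), st, tolerance = 1e-6)

  # bistable stimulus: low and high initials reach the two stable roots
  fp <- find_fixed_points(ref_params, 4, "dox")
  stable <- fp[fp$stable, ]
  lo <- relax_to_steady(ref_params, 4, "dox", init = c(0, 0, 0))
  hi <- relax_to_steady(ref_params, 4, "dox", init = c(50, 10, 5))
  expect_equal(as.numeric(lo$state), as.numeric(stable[1, 1:3]),
               tolerance = 1e-5)
  expect_equal(as.numeric(hi$state), as.numeric(stable[2, 1:3]),
               tolerance = 1e-5)
  expect_gt(hi$state[["TNC"]], lo$state[["TNC"]])
})

test_that("without feedback the steady state is unique from any initial", {
  p <- update_params(ref_params, v_feedback = 0)
  expected <- open_cascade_steady(p, 5)
  grid <- init_grid_27(p)
  for (i in seq_len(nrow(grid))) {
    r <- relax_to_steady(p, 5, "dox", init = grid[i, ])
    expect_true(r$converged)
    expect_equal(as.numeric(r$state), unname(expected), tolerance = 1e-6)
  }
})
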