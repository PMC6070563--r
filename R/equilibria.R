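# At equilibrium P and T are explicit functions of Tw, reducing the 3-D
# steady-state system to a scalar self-consistency equation in Tw.
cascade_steady <- function(params, Tw) {
  p <- unclass(params)
  P <- (p[["basal_P"]] +
          p[["vmax_TwP"]] * hill(Tw, p[["km_TwP"]], p[["n_TwP"]])) /
    p[["deg_P"]]
  T <- (p[["basal_T"]] +
          p[["vmax_PT"]] * hill(P, p[["km_PT"]], p[["n_PT"]])) /
    p[["deg_T"]]
  list(P = P, T = T)
}

#' Find all fixed points of the loop at a constant stimulus
#'
#' Reduces the 3-D equilibrium system to a 1-D self-consistency equation in
#' Twist1 (Prrx1 and TNC are explicit functions of Twist1 at equilibrium),
#' scans a bracketed grid for sign changes, polishes each root with
#' [stats::uniroot()], de-duplicates, and classifies stability from the
#' eigenvalues of the full 3x3 Jacobian. Production is bounded and
#' degradation linear, so every equilibrium satisfies
#' `Tw <= (basal_Tw + vmax_dox + v_feedback) / deg_Tw`, which provides the
#' scan bracket. The loop is a monotone cascade: 1 to 3 fixed points exist.
#'
#' @inheritParams pfl_rhs
#' @param scan_points number of (log-spaced) scan grid points.
#' @param eps_root absolute tolerance passed to the root polisher.
#' @param eps_dup relative tolerance under which two roots are merged.
#' @return a `data.frame` of class `"pfl_fixed_points"`, sorted by `Twist1`,
#'   with columns `Twist1`, `Prrx1`, `TNC`, `stable`,
#'   `leading_eigenvalue` (largest real part of the Jacobian spectrum,
#'   1/day; `stable` is equivalent to it being negative).
#' @examples
#' pr <- pfl_preset("dox_reference")
#' find_fixed_points(pr$params, 4, "dox")  # bistable: stable/unstable/stable
#' @export
find_fixed_points <- function(params, stimulus,
                              mode = c("dox", "tnc_injection"),
                              scan_points = 2000, eps_root = 1e-9,
                              eps_dup = 1e-6) {
  mode <- match.arg(mode)
  validate_pfl_params(params)
  if (stimulus < 0) stop("stimulus must be >= 0")
  p <- unclass(params)
  drive <- if (mode == "dox") {
    p[["vmax_dox"]] * hill(stimulus, p[["km_dox"]], p[["n_dox"]])
  } else 0
  s_tnc <- if (mode == "dox") 0 else stimulus
  g <- function(Tw) {
    T <- cascade_steady(params, Tw)$T
    p[["basal_Tw"]] + drive +
      p[["v_feedback"]] * hill(T + s_tnc, p[["km_feedback"]],
                               p[["n_feedback"]]) -
      p[["deg_Tw"]] * Tw
  }
  ub <- (p[["basal_Tw"]] + p[["vmax_dox"]] + p[["v_feedback"]]) /
    p[["deg_Tw"]]
  ub <- max(ub, 1e-6)
  grid <- c(0, exp(seq(log(ub * 1e-9), log(ub * 1.0001),
                       length.out = scan_points)))
  gv <- g(grid)  # hill() and the cascade are vectorized
  roots <- numeric()
  for (i in seq_len(length(grid) - 1)) {
    if (gv[i] == 0) {
      roots <- c(roots, grid[i])
    } else if (gv[i] * gv[i + 1] < 0) {
      r <- stats::uniroot(g, c(grid[i], grid[i + 1]), tol = eps_root)$root
      roots <- c(roots, r)
    }
  }
  if (gv[length(gv)] == 0) roots <- c(roots, grid[length(grid)])
  if (!length(roots)) {
    stop("internal error: no equilibrium found (should be impossible for ",
         "valid parameters)")
  }
  roots <- sort(roots)
  keep <- c(TRUE, diff(roots) > eps_dup * pmax(roots[-length(roots)], 1e-12))
  roots <- roots[keep]
  rows <- lapply(roots, function(Tw) {
    cs <- cascade_steady(params, Tw)
    st <- c(Tw, cs$P, cs$T)
    J <- pfl_jacobian(st, stimulus, params, mode)
    lev <- max(Re(eigen(J, only.values = TRUE)$values))
    data.frame(Twist1 = Tw, Prrx1 = cs$P, TNC = cs$T,
               stable = lev < 0, leading_eigenvalue = lev)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  attr(df, "stimulus") <- stimulus
  attr(df, "mode") <- mode
  class(df) <- c("pfl_fixed_points", "data.frame")
  df
}

#' Quasi-static stimulus-response sweep
#'
#' Traverses a stimulus grid (increasing for `direction = "up"`, decreasing
#' for `"down"`), carrying the steady state of each point over as the seed of
#' the next — the quasi-static protocol that traces one hysteresis branch.
#'
#' Two equivalent engines are provided. `method = "relax"` relaxes the ODE to
#' steady state at each point ([relax_to_steady()] seeded with the previous
#' state). `method = "continuation"` follows the stable fixed-point branch
#' from [find_fixed_points()] (picking, at each grid point, the stable
#' equilibrium closest to the previous state), which is much faster and is
#' used for phase-diagram scans; the two agree in tests.
#'
#' @inheritParams find_fixed_points
#' @param stimulus_grid increasing, non-negative stimulus grid.
#' @param direction `"up"` or `"down"`.
#' @param method `"relax"` or `"continuation"`.
#' @param init optional seed state for the first traversed point; default is
#'   the lowest (up) or highest (down) stable fixed point there.
#' @param eps_ss,t_max relaxation controls (see [relax_to_steady()]).
#' @return a `data.frame` of class `"pfl_response"` in traversal order with
#'   columns `stimulus`, `Twist1`, `Prrx1`, `TNC`, `converged`.
#' @export
response_sweep <- function(params, stimulus_grid,
                           direction = c("up", "down"),
                           mode = c("dox", "tnc_injection"),
                           method = c("relax", "continuation"),
                           init = NULL, eps_ss = 1e-8, t_max = 5000,
                           scan_points = 2000) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  method <- match.arg(method)
  validate_pfl_params(params)
  if (is.unsorted(stimulus_grid, strictly = TRUE)) {
    stop("stimulus_grid must be strictly increasing")
  }
  if (any(stimulus_grid < 0)) stop("stimulus_grid must be non-negative")
  ord <- if (direction == "up") seq_along(stimulus_grid) else
    rev(seq_along(stimulus_grid))
  n <- length(stimulus_grid)
  Tw <- P <- T <- numeric(n)
  conv <- logical(n)
  state <- init
  for (k in seq_len(n)) {
    i <- ord[k]
    s <- stimulus_grid[i]
    if (method == "relax") {
      if (is.null(state)) {
        fp <- find_fixed_points(params, s, mode, scan_points = scan_points)
        st <- fp[fp$stable, , drop = FALSE]
        row <- if (direction == "up") 1 else nrow(st)
        state <- as.numeric(st[row, c("Twist1", "Prrx1", "TNC")])
      }
      r <- relax_to_steady(params, s, mode, init = state,
                           eps_ss = eps_ss, t_max = t_max)
      state <- as.numeric(r$state)
      conv[i] <- r$converged
    } else {
      fp <- find_fixed_points(params, s, mode, scan_points = scan_points)
      st <- fp[fp$stable, , drop = FALSE]
      if (is.null(state)) {
        row <- if (direction == "up") 1 else nrow(st)
      } else {
        # nearest stable branch in log-Twist1; after a saddle-node the
        # vanished branch's nearest survivor is the one the flow reaches
        d <- abs(log(pmax(st$Twist1, 1e-12)) - log(max(state[1], 1e-12)))
        row <- which.min(d)
      }
      state <- as.numeric(st[row, c("Twist1", "Prrx1", "TNC")])
      conv[i] <- TRUE
    }
    Tw[i] <- state[1]; P[i] <- state[2]; T[i] <- state[3]
  }
  # rows are assigned by grid index, so the table is in increasing-stimulus
  # order for both traversal directions
  df <- data.frame(stimulus = stimulus_grid, Twist1 = Tw, Prrx1 = P,
                   TNC = T, converged = conv)
  rownames(df) <- NULL
  attr(df, "direction") <- direction
  attr(df, "mode") <- mode
  attr(df, "method") <- method
  class(df) <- c("pfl_response", "data.frame")
  df
}

#' Effective Hill exponent of the stimulus-response curve
#'
#' Quantifies ultrasensitivity of the up-sweep TNC branch by the classic
#' steepness index `n_eff = log(81) / log(EC90 / EC10)`, where EC10/EC90 are
#' the stimulus levels at which TNC crosses 10% and 90% of its dynamic range
#' (linearly interpolated on the grid). The same index is computed for the
#' matched no-feedback control (`v_feedback = 0`); for the reference model
#' the loop is strictly more ultrasensitive than its open-cascade control.
#' A discontinuous jump spanning both crossings gives `n_eff = Inf`
#' (flagged `discontinuous`).
#'
#' @inheritParams response_sweep
#' @param stimulus_grid grid spanning sub- to super-threshold stimuli.
#' @return a list of class `"pfl_gain"`: `n_eff`, `ec10`, `ec90`,
#'   `discontinuous`, and the same fields with suffix `_control` for the
#'   `v_feedback = 0` cascade.
#' @export
ultrasensitivity_gain <- function(params, stimulus_grid,
                                  mode = c("dox", "tnc_injection"),
                                  method = c("relax", "continuation"),
                                  ...) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  one <- function(pp) {
    up <- response_sweep(pp, stimulus_grid, "up", mode, method, ...)
    y <- up$TNC
    rng <- range(y)
    if (diff(rng) <= 0) stop("flat response: gain undefined")
    cross <- function(level) {
      idx <- which(y[-1] >= level & y[-length(y)] < level)
      if (!length(idx)) return(c(NA_real_, NA_real_))
      i <- idx[1]
      w <- (level - y[i]) / (y[i + 1] - y[i])
      c(up$stimulus[i] * (1 - w) + up$stimulus[i + 1] * w, i)
    }
    c10 <- cross(rng[1] + 0.1 * diff(rng))
    c90 <- cross(rng[1] + 0.9 * diff(rng))
    if (is.na(c10[1]) || is.na(c90[1])) {
      stop("up-sweep does not span 10%-90% of its range: gain undefined")
    }
    # both crossings inside one grid interval: a discontinuous jump, so the
    # effective exponent is reported as infinite
    disc <- c90[2] == c10[2] || c90[1] <= c10[1]
    list(n_eff = if (disc) Inf else log(81) / log(c90[1] / c10[1]),
         ec10 = c10[1], ec90 = c90[1], discontinuous = disc)
  }
  res <- one(params)
  # in injection mode the stimulus acts only through the feedback term, so
  # the ablated control has no response and no defined gain
  ctrl <- if (mode == "dox") one(update_params(params, v_feedback = 0)) else
    list(n_eff = NA_real_, ec10 = NA_real_, ec90 = NA_real_,
         discontinuous = NA)
  out <- c(res, stats::setNames(ctrl, paste0(names(ctrl), "_control")))
  class(out) <- "pfl_gain"
  out
}

#' @export
print.pfl_gain <- function(x, ...) {
  cat("Effective Hill exponent (TNC up-sweep)\n")
  cat(sprintf("  with feedback:    n_eff = %s (EC10 = %.4g, EC90 = %.4g)%s\n",
              format(x$n_eff, digits = 4), x$ec10, x$ec90,
              if (x$discontinuous) " [discontinuous jump]" else ""))
  cat(sprintf("  no-feedback ctrl: n_eff = %s (EC10 = %.4g, EC90 = %.4g)\n",
              format(x$n_eff_control, digits = 4), x$ec10_control,
              x$ec90_control))
  invisible(x)
}

#' @export
print.pfl_fixed_points <- function(x, ...) {
  cat("<pfl_fixed_points> stimulus = ", attr(x, "stimulus"),
      " (mode: ", attr(x, "mode"), ")\n", sep = "")
  print.data.frame(as.data.frame(x), digits = 5)
  invisible(x)
}

#' Resting basal state of the loop
#'
#' The lowest stable fixed point at zero stimulus — the unstimulated
#' fibroblast state used as the pre-stimulus baseline by the synthetic-data
#' generators and the likelihood.
#'
#' @inheritParams find_fixed_points
#' @return a named state vector `c(Twist1, Prrx1, TNC)`.
#' @export
basal_state <- function(params, mode = c("dox", "tnc_injection")) {
  mode <- match.arg(mode)
  fp <- find_fixed_points(params, 0, mode)
  st <- fp[fp$stable, , drop = FALSE]
  stats::setNames(as.numeric(st[1, c("Twist1", "Prrx1", "TNC")]),
                  c("Twist1", "Prrx1", "TNC"))
}
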