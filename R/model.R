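#' Hill activation function
#'
#' `hill(x, K, n) = x^n / (K^n + x^n)`, the activation fraction used by every
#' regulatory term of the loop (for `n = 1` this is a Michaelis-Menten form).
#'
#' @param x input concentration (a.u.), vectorized, `>= 0`.
#' @param K half-saturation constant (a.u.), `> 0`.
#' @param n Hill coefficient, `>= 1`.
#' @return activation fraction in `[0, 1)`, monotone non-decreasing in `x`;
#'   `hill(K, K, n) == 0.5` for any `n`.
#' @examples
#' hill(2, 1, 4)  # 16/17
#' @export
hill <- function(x, K, n) {
  if (!is.finite(K) || K <= 0) stop("hill(): K must be > 0")
  if (!is.finite(n) || n < 1) stop("hill(): n must be >= 1")
  if (any(x < 0)) stop("hill(): x must be >= 0")
  # work on the ratio to stay finite for large x^n
  r <- (x / K)^n
  ifelse(is.infinite(r), 1, r / (1 + r))
}

# d/dx hill(x, K, n); finite at x = 0 (equals 1/K when n = 1, else 0)
hill_deriv <- function(x, K, n) {
  r <- (x / K)^n
  out <- ifelse(x > 0 & is.finite(r),
                n * r / (x * (1 + r)^2),
                0)
  if (n == 1) out[x == 0] <- 1 / K
  out[is.infinite(r)] <- 0
  out
}

#' Right-hand side of the loop ODE
#'
#' The three-variable model: doxycycline (or nothing, in injection mode)
#' drives Twist1 production; Twist1 activates Prrx1; Prrx1 activates TNC; TNC
#' feeds back on Twist1 production through a saturating term with strength
#' `v_feedback` and threshold `km_feedback`. All species decay linearly.
#'
#' \deqn{dTw/dt = basal_{Tw} + vmax_{dox} h(D; km_{dox}, n_{dox}) +
#'   v_{fb} h(T_{sensed}; km_{fb}, n_{fb}) - deg_{Tw} Tw}
#' \deqn{dP/dt = basal_P + vmax_{TwP} h(Tw; km_{TwP}, n_{TwP}) - deg_P P}
#' \deqn{dT/dt = basal_T + vmax_{PT} h(P; km_{PT}, n_{PT}) - deg_T T}
#'
#' In `"dox"` mode the stimulus is the doxycycline level `D` and the sensed
#' TNC is the endogenous `T`. In `"tnc_injection"` mode `D = 0` and the
#' feedback term senses `T + stimulus` (endogenous plus exogenous TNC).
#'
#' @param state numeric length-3 vector `c(Tw, P, T)` (a.u.), non-negative.
#' @param stimulus external input level (a.u.).
#' @param params a [pfl_params()] object.
#' @param mode `"dox"` or `"tnc_injection"`.
#' @return named derivative vector (a.u./day).
#' @export
pfl_rhs <- function(state, stimulus, params, mode = c("dox", "tnc_injection")) {
  mode <- match.arg(mode)
  if (length(state) != 3 || any(!is.finite(state))) {
    stop("state must be three finite concentrations")
  }
  if (any(state < 0)) stop("state components must be non-negative")
  p <- unclass(params)
  if (mode == "dox") {
    D <- stimulus
    T_sensed <- state[[3]]
  } else {
    D <- 0
    T_sensed <- state[[3]] + stimulus
  }
  dTw <- p[["basal_Tw"]] +
    p[["vmax_dox"]] * hill(D, p[["km_dox"]], p[["n_dox"]]) +
    p[["v_feedback"]] * hill(T_sensed, p[["km_feedback"]], p[["n_feedback"]]) -
    p[["deg_Tw"]] * state[[1]]
  dP <- p[["basal_P"]] +
    p[["vmax_TwP"]] * hill(state[[1]], p[["km_TwP"]], p[["n_TwP"]]) -
    p[["deg_P"]] * state[[2]]
  dT <- p[["basal_T"]] +
    p[["vmax_PT"]] * hill(state[[2]], p[["km_PT"]], p[["n_PT"]]) -
    p[["deg_T"]] * state[[3]]
  c(Twist1 = dTw, Prrx1 = dP, TNC = dT)
}

#' Jacobian of the loop ODE
#'
#' Analytic 3x3 Jacobian of [pfl_rhs()] with respect to the state, used by
#' the stiff solver and for stability classification of fixed points.
#'
#' @inheritParams pfl_rhs
#' @return a 3x3 numeric matrix.
#' @export
pfl_jacobian <- function(state, stimulus, params,
                         mode = c("dox", "tnc_injection")) {
  mode <- match.arg(mode)
  p <- unclass(params)
  T_sensed <- if (mode == "dox") state[[3]] else state[[3]] + stimulus
  fb <- p[["v_feedback"]] *
    hill_deriv(T_sensed, p[["km_feedback"]], p[["n_feedback"]])
  twp <- p[["vmax_TwP"]] * hill_deriv(state[[1]], p[["km_TwP"]], p[["n_TwP"]])
  pt <- p[["vmax_PT"]] * hill_deriv(state[[2]], p[["km_PT"]], p[["n_PT"]])
  matrix(c(-p[["deg_Tw"]], 0, fb,
           twp, -p[["deg_P"]], 0,
           0, pt, -p[["deg_T"]]),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("Twist1", "Prrx1", "TNC"),
                         c("Twist1", "Prrx1", "TNC")))
}

# deSolve plumbing: state floored at 0 before evaluating the rhs so that
# solver undershoot (bounded by atol) cannot trip the domain checks.
rhs_desolve <- function(params, mode, stim_fun) {
  p <- unclass(params)
  function(t, y, parms) {
    y <- pmax(y, 0)
    s <- stim_fun(t)
    if (mode == "dox") {
      D <- s; Ts <- y[3]
    } else {
      D <- 0; Ts <- y[3] + s
    }
    dTw <- p[["basal_Tw"]] +
      p[["vmax_dox"]] * hill(D, p[["km_dox"]], p[["n_dox"]]) +
      p[["v_feedback"]] * hill(Ts, p[["km_feedback"]], p[["n_feedback"]]) -
      p[["deg_Tw"]] * y[1]
    dP <- p[["basal_P"]] +
      p[["vmax_TwP"]] * hill(y[1], p[["km_TwP"]], p[["n_TwP"]]) -
      p[["deg_P"]] * y[2]
    dT <- p[["basal_T"]] +
      p[["vmax_PT"]] * hill(y[2], p[["km_PT"]], p[["n_PT"]]) -
      p[["deg_T"]] * y[3]
    list(c(dTw, dP, dT))
  }
}

jac_desolve <- function(params, mode, stim_fun) {
  function(t, y, parms) {
    pfl_jacobian(pmax(y, 0), stim_fun(t), params, mode)
  }
}

#' Integrate the loop ODE under a stimulus protocol
#'
#' Stiff-safe numerical solution (`deSolve::lsoda` with the analytic
#' Jacobian), integrated segment by segment so that protocol discontinuities
#' coincide with solver restarts. Deterministic given identical inputs and
#' tolerances.
#'
#' @param params a [pfl_params()] object.
#' @param protocol a stimulus protocol from [dox_step()], [tnc_pulse()] or
#'   [pfl_protocol()].
#' @param times strictly increasing output time grid (days), within the
#'   protocol span.
#' @param init initial state `c(Tw, P, T)`; default is the lowest stable
#'   fixed point at the protocol's initial stimulus level (the resting basal
#'   state).
#' @param rtol,atol solver tolerances.
#' @return a `data.frame` of class `"pfl_trajectory"` with columns `time`,
#'   `stimulus`, `Twist1`, `Prrx1`, `TNC`.
#' @examples
#' pr <- pfl_preset("dox_reference")
#' traj <- simulate_pfl(pr$params, dox_step(10, 0, 20), times = 0:20)
#' @export
simulate_pfl <- function(params, protocol, times, init = NULL,
                         rtol = 1e-8, atol = 1e-10) {
  validate_pfl_params(params)
  stopifnot(inherits(protocol, "pfl_protocol"))
  if (rtol <= 0 || atol <= 0) stop("tolerances must be > 0")
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  span <- protocol_span(protocol)
  if (min(times) < span[1] - 1e-9 || max(times) > span[2] + 1e-9) {
    stop("times must lie within the protocol span [", span[1], ", ",
         span[2], "]")
  }
  mode <- protocol$mode
  stim_fun <- function(t) protocol_level(protocol, t)

  if (is.null(init)) {
    fp <- find_fixed_points(params, stim_fun(times[1]), mode)
    st <- fp[fp$stable, , drop = FALSE]
    init <- as.numeric(st[1, c("Twist1", "Prrx1", "TNC")])
  }
  if (any(init < 0)) stop("initial state components must be non-negative")

  segs <- protocol$segments
  # breakpoints inside the requested window
  brk <- sort(unique(c(times[1], segs$t_start, segs$t_end, max(times))))
  brk <- brk[brk >= times[1] & brk <= max(times)]
  func <- rhs_desolve(params, mode, stim_fun)
  jac <- jac_desolve(params, mode, stim_fun)
  y <- init
  rows <- list()
  for (i in seq_len(length(brk) - 1)) {
    t0 <- brk[i]; t1 <- brk[i + 1]
    tt <- unique(c(t0, times[times > t0 & times < t1], t1))
    if (length(tt) < 2) next
    out <- tryCatch(
      deSolve::lsoda(y, tt, func, parms = NULL, jacfunc = jac,
                     jactype = "fullusr", rtol = rtol, atol = atol),
      warning = function(w) {
        stop("integration failed near t = ", t0, ": ", conditionMessage(w))
      })
    if (attr(out, "istate")[1] < 0) {
      stop("integration failed near t = ", t0)
    }
    y <- pmax(as.numeric(out[nrow(out), 2:4]), 0)
    rows[[i]] <- out
  }
  m <- do.call(rbind, lapply(rows, function(o) o[-1, , drop = FALSE]))
  m <- rbind(c(times[1], init), m)
  keep <- m[, 1] %in% times & !duplicated(m[, 1])
  m <- m[keep, , drop = FALSE]
  df <- data.frame(time = m[, 1],
                   stimulus = stim_fun(m[, 1]),
                   Twist1 = pmax(m[, 2], 0),
                   Prrx1 = pmax(m[, 3], 0),
                   TNC = pmax(m[, 4], 0))
  rownames(df) <- NULL
  attr(df, "params") <- params
  attr(df, "protocol") <- protocol
  attr(df, "mode") <- mode
  class(df) <- c("pfl_trajectory", "data.frame")
  df
}

#' Relax to a steady state under constant stimulus
#'
#' Integrates the ODE from `init` in growing time chunks until the max-norm
#' of the right-hand side falls below `eps_ss` (default 1e-8 a.u./day) or the
#' horizon `t_max` is reached. Non-convergence is reported in the `converged`
#' flag, not as an error.
#'
#' @inheritParams pfl_rhs
#' @param init initial state.
#' @param eps_ss convergence threshold on `max(abs(pfl_rhs))` (a.u./day).
#' @param t_max integration horizon (days).
#' @param rtol,atol solver tolerances.
#' @return a list with `state` (named vector), `converged` (flag), and
#'   `time` (model days integrated).
#' @export
relax_to_steady <- function(params, stimulus, mode = c("dox", "tnc_injection"),
                            init = c(0, 0, 0), eps_ss = 1e-8, t_max = 5000,
                            rtol = 1e-8, atol = 1e-10) {
  mode <- match.arg(mode)
  validate_pfl_params(params)
  stim_fun <- function(t) rep(stimulus, length(t))
  func <- rhs_desolve(params, mode, stim_fun)
  jac <- jac_desolve(params, mode, stim_fun)
  y <- pmax(as.numeric(init), 0)
  t <- 0
  h <- 50
  repeat {
    d <- pfl_rhs(y, stimulus, params, mode)
    if (max(abs(d)) < eps_ss) {
      return(list(state = c(Twist1 = y[1], Prrx1 = y[2], TNC = y[3]),
                  converged = TRUE, time = t))
    }
    if (t >= t_max) {
      return(list(state = c(Twist1 = y[1], Prrx1 = y[2], TNC = y[3]),
                  converged = FALSE, time = t))
    }
    out <- deSolve::lsoda(y, c(0, h), func, parms = NULL, jacfunc = jac,
                          jactype = "fullusr", rtol = rtol, atol = atol)
    y <- pmax(as.numeric(out[nrow(out), 2:4]), 0)
    t <- t + h
    h <- min(h * 2, 800)
  }
}

#' @export
print.pfl_trajectory <- function(x, ...) {
  cat("<pfl_trajectory> ", nrow(x), " time points over [",
      min(x$time), ", ", max(x$time), "] days (mode: ",
      attr(x, "mode"), ")\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}
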