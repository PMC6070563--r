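# Locate the bracketing interval of an abrupt branch transition along a
# sweep. `values` is in increasing-stimulus order; returns the midpoint of
# the interval in which the adjacent-point ratio exceeds `jump_ratio`
# (rising = up-jump, falling = down-jump), or NA when no such interval
# exists. Grid resolution is the quoted uncertainty of the threshold.
locate_jump <- function(stimulus, values, jump_ratio, rising = TRUE) {
  v <- pmax(values, 1e-12)
  r <- v[-1] / v[-length(v)]
  idx <- if (rising) which(r > jump_ratio) else which(r < 1 / jump_ratio)
  if (!length(idx)) return(NA_real_)
  i <- if (rising) idx[which.max(r[idx])] else idx[which.min(r[idx])]
  (stimulus[i] + stimulus[i + 1]) / 2
}

#' Hysteresis analysis of an up-then-down stimulus sweep
#'
#' Runs a quasi-static up-sweep over `stimulus_grid` (which must start at 0
#' and extend past the activation threshold), then a down-sweep seeded from
#' the up-sweep's terminal state, and derives the switching metrics:
#'
#' * `theta_on` — stimulus at the up-sweep jump (midpoint of the bracketing
#'   grid interval; the grid spacing is its uncertainty),
#' * `theta_off` — stimulus at the down-sweep fall (`NA` when the active
#'   state persists all the way to zero stimulus),
#' * `width = theta_on - theta_off`,
#' * `delta_tnc = tnc_final - tnc_initial`, the irreversibility measure:
#'   TNC at zero stimulus after the excursion minus TNC at zero stimulus
#'   before it,
#' * `reversible` — `delta_tnc <= eps_rev`.
#'
#' If the up-sweep never jumps the result is flagged monostable: thresholds
#' are `NA` and `delta_tnc` is 0 by construction.
#'
#' @inheritParams response_sweep
#' @param stimulus_grid increasing grid starting at 0.
#' @param jump_ratio adjacent-point TNC ratio above which a transition is
#'   reported as a jump (a reporting convention; default 2).
#' @param eps_rev irreversibility tolerance separating "delta TNC = 0" from
#'   "> 0" (a.u.).
#' @param ... passed to [response_sweep()].
#' @return a list of class `"pfl_hysteresis"` with the metrics above plus
#'   the two branch objects `up` and `down` and `monostable`.
#' @examples
#' pr <- pfl_preset("dox_reference")
#' hysteresis(pr$params, seq(0, 10, length.out = 41), mode = "dox",
#'            method = "continuation")
#' @export
hysteresis <- function(params, stimulus_grid = NULL,
                       mode = c("dox", "tnc_injection"),
                       method = c("relax", "continuation"),
                       jump_ratio = 2, eps_rev = 1e-3, ...) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (is.null(stimulus_grid)) {
    stimulus_grid <- if (mode == "dox") seq(0, 10, length.out = 51) else
      seq(0, 3, length.out = 41)
  }
  if (abs(stimulus_grid[1]) > 1e-12) stop("stimulus_grid must start at 0")
  up <- response_sweep(params, stimulus_grid, "up", mode, method, ...)
  n <- nrow(up)
  top_state <- as.numeric(up[n, c("Twist1", "Prrx1", "TNC")])
  down <- response_sweep(params, stimulus_grid, "down", mode, method,
                         init = top_state, ...)
  theta_on <- locate_jump(up$stimulus, up$TNC, jump_ratio, rising = TRUE)
  theta_off <- locate_jump(down$stimulus, down$TNC, jump_ratio,
                           rising = TRUE)
  monostable <- is.na(theta_on)
  tnc_initial <- up$TNC[1]
  tnc_final <- down$TNC[1]
  delta_tnc <- if (monostable) 0 else tnc_final - tnc_initial
  width <- if (monostable) 0 else if (is.na(theta_off)) NA_real_ else
    theta_on - theta_off
  out <- list(theta_on = theta_on, theta_off = theta_off, width = width,
              tnc_initial = tnc_initial, tnc_final = tnc_final,
              delta_tnc = delta_tnc,
              reversible = delta_tnc <= eps_rev,
              monostable = monostable,
              eps_rev = eps_rev, up = up, down = down)
  class(out) <- "pfl_hysteresis"
  out
}

#' @export
print.pfl_hysteresis <- function(x, ...) {
  cat("<pfl_hysteresis>\n")
  cat(sprintf("  theta_on  = %s\n", format(x$theta_on, digits = 4)))
  cat(sprintf("  theta_off = %s%s\n", format(x$theta_off, digits = 4),
              if (is.na(x$theta_off) && !x$monostable)
                " (active state persists at zero stimulus)" else ""))
  cat(sprintf("  width     = %s\n", format(x$width, digits = 4)))
  cat(sprintf("  delta_tnc = %.6g (%s)\n", x$delta_tnc,
              if (x$reversible) "reversible" else "irreversible"))
  invisible(x)
}

#' Irreversibility of an exogenous-TNC pulse
#'
#' Sweeps the exogenous TNC stimulus quasi-statically from 0 up to `tnc_max`
#' and back to 0 and returns the change in *endogenous* TNC,
#' `TNC_final - TNC_initial`, at zero stimulus. Zero marks a reversible
#' pulse; a positive value means the loop latched on.
#'
#' @inheritParams hysteresis
#' @param tnc_max pulse amplitude (a.u.), `>= 0`.
#' @param n_grid number of sweep grid points.
#' @return the delta-TNC value (a.u.).
#' @export
delta_tnc_for_pulse <- function(params, tnc_max, mode = "tnc_injection",
                                n_grid = 41,
                                method = c("continuation", "relax"),
                                eps_rev = 1e-3, ...) {
  method <- match.arg(method)
  if (tnc_max < 0) stop("tnc_max must be >= 0")
  if (tnc_max == 0) return(0)
  h <- hysteresis(params, seq(0, tnc_max, length.out = n_grid), mode = mode,
                  method = method, eps_rev = eps_rev, ...)
  h$delta_tnc
}

#' Reversible / irreversible phase classification
#'
#' Phase I (reversible) iff the standard up-then-down sweep gives
#' `delta_tnc <= eps_rev`; Phase II (irreversible) otherwise. The standard
#' sweep spans stimulus 0 to `s_max` (default 10 in `"dox"` mode; the preset
#' pulse amplitude 3 in `"tnc_injection"` mode).
#'
#' @inheritParams hysteresis
#' @param s_max upper end of the standard sweep.
#' @return `"I"` or `"II"`.
#' @export
classify_phase <- function(params, mode = c("dox", "tnc_injection"),
                           s_max = NULL, n_grid = 41,
                           method = c("continuation", "relax"),
                           eps_rev = 1e-3, ...) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (is.null(s_max)) s_max <- if (mode == "dox") 10 else 3
  h <- hysteresis(params, seq(0, s_max, length.out = n_grid), mode = mode,
                  method = method, eps_rev = eps_rev, ...)
  if (h$reversible) "I" else "II"
}

# resolve a phase-diagram axis name to a parameter update function
axis_setter <- function(name) {
  if (name %in% pfl_param_names()) {
    function(p, value) {
      args <- list(p); args[[name]] <- value
      do.call(update_params, args)
    }
  } else if (name %in% c("vmax_dox_over_deg_Tw", "twist1_stability")) {
    # the Twist1 production/degradation ratio axis, realized by co-varying
    # vmax_dox at fixed deg_Tw
    function(p, value) update_params(p, vmax_dox = value * p[["deg_Tw"]])
  } else {
    stop("axis '", name, "' is not a kinetic parameter (or ",
         "'vmax_dox_over_deg_Tw')")
  }
}

# Quasi-static delta-TNC without tracing the whole sweep. The loop is a
# monotone cascade with a single fold: the up-sweep switches if and only if
# the low branch has vanished by s_max, and the down-sweep then parks on the
# high branch at zero stimulus if and only if the system is bistable there.
# Hence delta-TNC = (high - low TNC at stimulus 0) when both hold, else 0.
fast_delta_tnc <- function(params, mode, s_max, scan_points = 600) {
  fp0 <- find_fixed_points(params, 0, mode, scan_points = scan_points)
  st0 <- fp0[fp0$stable, , drop = FALSE]
  if (nrow(st0) < 2) return(0)
  fpm <- find_fixed_points(params, s_max, mode, scan_points = scan_points)
  if (sum(fpm$stable) >= 2) return(0)  # low branch persists: never switches
  st0$TNC[nrow(st0)] - st0$TNC[1]
}

#' Two-parameter irreversibility phase diagram
#'
#' Evaluates the delta-TNC irreversibility measure of the standard
#' up-then-down sweep on a 2-D parameter grid and labels each cell Phase I
#' (reversible, `delta_tnc <= eps_rev`) or Phase II (irreversible). Axes may
#' name any kinetic parameter, or `"vmax_dox_over_deg_Tw"` (alias
#' `"twist1_stability"`) for the Twist1 production/degradation ratio,
#' realized by co-varying `vmax_dox` at fixed `deg_Tw`.
#'
#' The default engine (`method = "fast"`) exploits the loop's single-fold
#' structure to evaluate each cell from two equilibrium scans (bistability
#' at zero stimulus plus loss of the low branch by `s_max`), keeping a full
#' 40x40 diagram to about a minute on one CPU; `"continuation"` and
#' `"relax"` trace the full quasi-static sweep instead and agree with it.
#'
#' @inheritParams classify_phase
#' @param base_params the base [pfl_params()] set.
#' @param axis1,axis2 lists `list(name =, values =)` with increasing grids.
#' @return a list of class `"pfl_phase_diagram"`: `axis1`, `axis2`,
#'   `delta_tnc` (matrix, rows = axis1), `phase` (character matrix `"I"` /
#'   `"II"`), `eps_rev`. `as.data.frame()` gives the long table
#'   (axis1, axis2, delta_tnc, phase).
#' @export
phase_diagram <- function(base_params, axis1, axis2,
                          mode = c("dox", "tnc_injection"), s_max = NULL,
                          n_grid = 41,
                          method = c("fast", "continuation", "relax"),
                          eps_rev = 1e-3, scan_points = 600) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  for (ax in list(axis1, axis2)) {
    if (!is.list(ax) || is.null(ax$name) || is.null(ax$values)) {
      stop("axes must be lists with 'name' and 'values'")
    }
  }
  set1 <- axis_setter(axis1$name)
  set2 <- axis_setter(axis2$name)
  if (is.null(s_max)) s_max <- if (mode == "dox") 10 else 3
  grid <- seq(0, s_max, length.out = n_grid)
  n1 <- length(axis1$values); n2 <- length(axis2$values)
  dt <- matrix(NA_real_, n1, n2)
  for (i in seq_len(n1)) {
    p1 <- set1(base_params, axis1$values[i])
    for (j in seq_len(n2)) {
      p <- set2(p1, axis2$values[j])
      dt[i, j] <- if (method == "fast") {
        fast_delta_tnc(p, mode, s_max, scan_points = scan_points)
      } else {
        hysteresis(p, grid, mode = mode, method = method,
                   eps_rev = eps_rev, scan_points = scan_points)$delta_tnc
      }
    }
  }
  phase <- ifelse(dt <= eps_rev, "I", "II")
  out <- list(axis1 = axis1, axis2 = axis2, delta_tnc = dt, phase = phase,
              eps_rev = eps_rev, mode = mode, s_max = s_max)
  class(out) <- "pfl_phase_diagram"
  out
}

#' @export
as.data.frame.pfl_phase_diagram <- function(x, ...) {
  df <- expand.grid(a1 = x$axis1$values, a2 = x$axis2$values,
                    KEEP.OUT.ATTRS = FALSE)
  names(df) <- c(x$axis1$name, x$axis2$name)
  df$delta_tnc <- as.vector(x$delta_tnc)
  df$phase <- as.vector(x$phase)
  df
}

#' @export
print.pfl_phase_diagram <- function(x, ...) {
  tab <- table(factor(x$phase, levels = c("I", "II")))
  cat("<pfl_phase_diagram> ", length(x$axis1$values), "x",
      length(x$axis2$values), " over (", x$axis1$name, ", ", x$axis2$name,
      ")\n  Phase I (reversible): ", tab[["I"]],
      " cells; Phase II (irreversible): ", tab[["II"]], " cells\n",
      sep = "")
  invisible(x)
}

#' Hysteresis width as a function of feedback strength
#'
#' Recomputes the hysteresis metrics across a grid of `v_feedback` values.
#' On the reference model the width grows with the feedback strength while
#' the activation threshold stays nearly fixed, until the loop becomes
#' irreversible; there `theta_off` is undefined and the width is reported as
#' `theta_on` (the sweep's whole reachable extent), flagged `open_ended`.
#'
#' @inheritParams classify_phase
#' @param v_feedback_grid increasing grid of feedback strengths.
#' @return a `data.frame` with columns `v_feedback`, `theta_on`,
#'   `theta_off`, `width`, `delta_tnc`, `open_ended`.
#' @export
hysteresis_width_curve <- function(base_params, v_feedback_grid,
                                   mode = c("dox", "tnc_injection"),
                                   s_max = NULL, n_grid = 81,
                                   method = c("continuation", "relax"),
                                   eps_rev = 1e-3, ...) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (is.unsorted(v_feedback_grid, strictly = TRUE)) {
    stop("v_feedback_grid must be increasing")
  }
  if (is.null(s_max)) s_max <- if (mode == "dox") 10 else 3
  grid <- seq(0, s_max, length.out = n_grid)
  rows <- lapply(v_feedback_grid, function(v) {
    h <- hysteresis(update_params(base_params, v_feedback = v), grid,
                    mode = mode, method = method, eps_rev = eps_rev, ...)
    open_ended <- !h$monostable && is.na(h$theta_off)
    width <- if (h$monostable) 0 else if (open_ended) h$theta_on else h$width
    data.frame(v_feedback = v, theta_on = h$theta_on,
               theta_off = h$theta_off, width = width,
               delta_tnc = h$delta_tnc, open_ended = open_ended)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
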