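# shared RNG discipline: every generator is a pure function of its
# arguments and `seed`; the caller's RNG state is left untouched.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

resolve_preset <- function(preset) {
  if (inherits(preset, "pfl_preset")) return(preset)
  if (is.character(preset) && length(preset) == 1) {
    nm <- c(MRC5 = "mrc5", mrc5 = "mrc5", IMR90 = "imr90", imr90 = "imr90",
            dox_reference = "dox_reference",
            dermal_injection = "dermal_injection")
    if (!preset %in% names(nm)) stop("unknown preset: ", preset)
    return(pfl_preset(nm[[preset]]))
  }
  stop("preset must be a preset name or a pfl_preset object")
}

#' Synthetic induction time-course dataset
#'
#' Simulates the doxycycline-induction experiment with a calibrated preset
#' (or custom parameters), converts the trajectory to log2 fold change over
#' the pre-stimulus baseline at the sampled days, and adds i.i.d. Gaussian
#' noise on the log2 scale per replicate — a stand-in for western-blot
#' densitometry fold-change measurements. Deterministic per seed.
#'
#' @param preset `"MRC5"`, `"IMR90"`, a [pfl_preset()], or a list
#'   `list(params =, dox_level =)` for custom parameters.
#' @param protocol stimulus protocol; default is a dox step at the preset's
#'   `dox_level` spanning the sample times.
#' @param times sample times (days); default `c(0, 1, 2, 3, 5, 8, 11, 15)`.
#' @param noise_sd Gaussian noise s.d. on the log2 scale.
#' @param n_reps replicates per time point.
#' @param seed RNG seed (recorded in the dataset).
#' @return a list of class `"pfl_timecourse_dataset"`: `cell_line`,
#'   `protocol`, `times`, `data` (`data.frame` with `time`, `gene`,
#'   `replicate`, `log2fc`), `noise_sd`, `seed`, `params`.
#' @examples
#' d <- generate_timecourse("MRC5", noise_sd = 0, n_reps = 1, seed = 1)
#' subset(d$data, gene == "TNC")
#' @export
generate_timecourse <- function(preset = "MRC5", protocol = NULL,
                                times = c(0, 1, 2, 3, 5, 8, 11, 15),
                                noise_sd = 0.2, n_reps = 3, seed = 1) {
  if (is.list(preset) && !inherits(preset, "pfl_preset") &&
      !is.null(preset$params)) {
    params <- preset$params
    dox_level <- if (!is.null(preset$dox_level)) preset$dox_level else 10
    label <- "custom"
  } else {
    pr <- resolve_preset(preset)
    params <- pr$params
    dox_level <- pr$dox_level
    label <- pr$label
  }
  if (is.null(protocol)) protocol <- dox_step(dox_level, 0, max(times))
  span <- protocol_span(protocol)
  if (min(times) < span[1] - 1e-9 || max(times) > span[2] + 1e-9) {
    stop("sample times fall outside the protocol span")
  }
  if (n_reps < 1) stop("n_reps must be >= 1")
  traj <- simulate_pfl(params, protocol, sort(unique(times)),
                       init = basal_state(params, protocol$mode))
  genes <- c("Twist1", "Prrx1", "TNC")
  base <- pmax(as.numeric(traj[1, genes]), 1e-12)
  clean <- lapply(seq_along(genes), function(g) {
    log2(pmax(traj[[genes[g]]], 1e-12) / base[g])
  })
  df <- with_local_seed(seed, {
    rows <- expand.grid(time = traj$time, gene = genes,
                        replicate = seq_len(n_reps),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mu <- unlist(clean)[match(paste(rows$gene, rows$time),
                             paste(rep(genes, each = nrow(traj)),
                                   rep(traj$time, length(genes))))]
    rows$log2fc <- mu + stats::rnorm(nrow(rows), 0, noise_sd)
    rows
  })
  out <- list(cell_line = label, protocol = protocol, times = traj$time,
              data = df, noise_sd = noise_sd, seed = seed, params = params)
  class(out) <- "pfl_timecourse_dataset"
  out
}

#' Synthetic exogenous-TNC dose-response dataset
#'
#' Applies each dose as a constant exogenous-TNC stimulus (dose in
#' micrograms times the preset's `dose_scale`), reads out the steady-state
#' (or fixed-horizon) Twist1 and endogenous-TNC levels, and reports fold
#' changes over the untreated baseline with log-normal noise. With the
#' calibrated dermal preset and the default dose panel
#' `{0, 0.1, 1, 2, 5}`, only the 5 ug dose activates the loop (both fold
#' changes > 2).
#'
#' @param preset `"dermal_injection"`, a [pfl_preset()], or a list
#'   `list(params =, dose_scale =)`.
#' @param doses dose panel (micrograms), non-negative increasing.
#' @param noise_sd Gaussian noise s.d. on the log2 scale.
#' @param n_reps replicates per dose.
#' @param seed RNG seed.
#' @param readout `"steady"` (default) or `"horizon"` (levels at
#'   `horizon` days).
#' @param horizon readout horizon in days for `readout = "horizon"`.
#' @return a list of class `"pfl_dose_response_dataset"`: `doses`, `data`
#'   (`data.frame` with `dose`, `gene` in Twist1/TNC, `replicate`,
#'   `fold_change`, `log2fc`), `noise_sd`, `seed`, `params`, `dose_scale`.
#' @export
generate_dose_response <- function(preset = "dermal_injection",
                                   doses = c(0, 0.1, 1, 2, 5),
                                   noise_sd = 0.2, n_reps = 3, seed = 1,
                                   readout = c("steady", "horizon"),
                                   horizon = 30) {
  readout <- match.arg(readout)
  if (is.list(preset) && !inherits(preset, "pfl_preset") &&
      !is.null(preset$params)) {
    params <- preset$params
    dose_scale <- if (!is.null(preset$dose_scale)) preset$dose_scale else 1
  } else {
    pr <- resolve_preset(preset)
    params <- pr$params
    dose_scale <- pr$dose_scale
  }
  if (any(doses < 0) || is.unsorted(doses)) {
    stop("doses must be non-negative and increasing")
  }
  fp0 <- find_fixed_points(params, 0, "tnc_injection")
  st0 <- fp0[fp0$stable, , drop = FALSE]
  base_state <- as.numeric(st0[1, c("Twist1", "Prrx1", "TNC")])
  level_at <- function(dose) {
    s <- dose * dose_scale
    if (readout == "steady") {
      r <- relax_to_steady(params, s, "tnc_injection", init = base_state)
      r$state
    } else {
      traj <- simulate_pfl(params,
                           pfl_protocol("tnc_injection",
                                        data.frame(t_start = 0,
                                                   t_end = horizon,
                                                   level_start = s,
                                                   level_end = s)),
                           times = c(0, horizon), init = base_state)
      unlist(traj[nrow(traj), c("Twist1", "Prrx1", "TNC")])
    }
  }
  levels <- t(vapply(doses, level_at, numeric(3)))
  base <- pmax(levels[1, c(1, 3)], 1e-12)  # dose 0 is the baseline
  genes <- c("Twist1", "TNC")
  clean <- rbind(log2(pmax(levels[, 1], 1e-12) / base[1]),
                 log2(pmax(levels[, 3], 1e-12) / base[2]))
  df <- with_local_seed(seed, {
    rows <- expand.grid(dose = doses, gene = genes,
                        replicate = seq_len(n_reps),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mu <- clean[cbind(match(rows$gene, genes), match(rows$dose, doses))]
    rows$log2fc <- mu + stats::rnorm(nrow(rows), 0, noise_sd)
    rows$fold_change <- 2^rows$log2fc
    rows
  })
  out <- list(doses = doses, data = df, noise_sd = noise_sd, seed = seed,
              params = params, dose_scale = dose_scale, readout = readout)
  class(out) <- "pfl_dose_response_dataset"
  out
}

#' Synthetic bimodal single-cell snapshot
#'
#' Emulates a single-cell triple-stain snapshot of a bistable population:
#' each cell is ON with probability `fraction_on`; its Twist1/Prrx1/TNC
#' intensities are the corresponding stable fixed point scaled by
#' independent log-normal cell-to-cell factors with coefficient of
#' variation `cell_to_cell_cv`. The three genes are therefore concordant
#' within every cell (all high or all low), and each marginal is bimodal.
#'
#' @inheritParams find_fixed_points
#' @param stimulus a stimulus level inside the bistable window (both stable
#'   states must exist); otherwise an error reports the window.
#' @param n_cells number of cells.
#' @param cell_to_cell_cv log-normal coefficient of variation.
#' @param fraction_on mixture weight of the ON state, in `[0, 1]`.
#' @param seed RNG seed.
#' @return a list of class `"pfl_single_cell_snapshot"`: `data`
#'   (`data.frame` with `cell`, `state` ("ON"/"OFF"), `Twist1`, `Prrx1`,
#'   `TNC`), `fraction_on`, `stimulus`, `threshold_tnc` (the unstable fixed
#'   point's TNC level, a natural ON/OFF gate), `seed`.
#' @export
generate_single_cell_snapshot <- function(params, stimulus, n_cells = 2000,
                                          cell_to_cell_cv = 0.2,
                                          fraction_on = 0.5, seed = 1,
                                          mode = c("dox", "tnc_injection")) {
  mode <- match.arg(mode)
  if (fraction_on < 0 || fraction_on > 1) {
    stop("fraction_on must be in [0, 1]")
  }
  fp <- find_fixed_points(params, stimulus, mode)
  st <- fp[fp$stable, , drop = FALSE]
  if (nrow(st) < 2) {
    # report the bistable window to guide the caller
    probe <- seq(0, if (mode == "dox") 10 else 5, length.out = 41)
    nst <- vapply(probe, function(s) {
      f <- find_fixed_points(params, s, mode, scan_points = 400)
      sum(f$stable)
    }, numeric(1))
    win <- range(probe[nst == 2])
    stop("stimulus ", stimulus, " is monostable; the bistable window is ",
         "approximately [", signif(win[1], 3), ", ", signif(win[2], 3), "]")
  }
  off_state <- as.numeric(st[1, c("Twist1", "Prrx1", "TNC")])
  on_state <- as.numeric(st[nrow(st), c("Twist1", "Prrx1", "TNC")])
  thr <- if (nrow(fp) == 3) fp$TNC[2] else
    exp(mean(log(c(off_state[3], on_state[3]))))
  sdlog <- sqrt(log(1 + cell_to_cell_cv^2))
  df <- with_local_seed(seed, {
    on <- stats::rbinom(n_cells, 1, fraction_on) == 1
    fac <- matrix(stats::rlnorm(3 * n_cells, -sdlog^2 / 2, sdlog),
                  ncol = 3)
    base <- rbind(off_state, on_state)[on + 1, , drop = FALSE]
    data.frame(cell = seq_len(n_cells),
               state = ifelse(on, "ON", "OFF"),
               Twist1 = base[, 1] * fac[, 1],
               Prrx1 = base[, 2] * fac[, 2],
               TNC = base[, 3] * fac[, 3])
  })
  out <- list(data = df, fraction_on = fraction_on, stimulus = stimulus,
              threshold_tnc = thr, seed = seed,
              off_state = off_state, on_state = on_state)
  class(out) <- "pfl_single_cell_snapshot"
  out
}
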