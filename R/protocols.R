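#' Stimulus protocols
#'
#' A protocol is a contiguous, non-overlapping list of time segments, each
#' with a start and end level (piecewise-constant when equal, linear ramp
#' otherwise). The external input is doxycycline in `"dox"` mode and
#' exogenous TNC in `"tnc_injection"` mode.
#'
#' @param mode `"dox"` or `"tnc_injection"`.
#' @param segments a `data.frame` with columns `t_start`, `t_end`,
#'   `level_start`, `level_end`; segments must be contiguous and levels
#'   non-negative.
#' @return a list of class `"pfl_protocol"` with elements `mode`, `segments`
#'   and `tnc_max` (the maximal level over the protocol).
#' @export
pfl_protocol <- function(mode = c("dox", "tnc_injection"), segments) {
  mode <- match.arg(mode)
  req <- c("t_start", "t_end", "level_start", "level_end")
  if (!is.data.frame(segments) || !all(req %in% names(segments))) {
    stop("segments must be a data.frame with columns ",
         paste(req, collapse = ", "))
  }
  segments <- segments[order(segments$t_start), req]
  if (any(segments$t_end <= segments$t_start)) {
    stop("each segment must have t_end > t_start")
  }
  if (nrow(segments) > 1) {
    gaps <- abs(segments$t_start[-1] - segments$t_end[-nrow(segments)])
    if (any(gaps > 1e-9)) stop("segments must be contiguous")
  }
  if (any(segments$level_start < 0) || any(segments$level_end < 0)) {
    stop("stimulus levels must be non-negative")
  }
  out <- list(mode = mode, segments = segments,
              tnc_max = max(segments$level_start, segments$level_end))
  class(out) <- "pfl_protocol"
  out
}

#' @rdname pfl_protocol
#' @param protocol a protocol object.
#' @return `protocol_span()`: the `c(start, end)` times covered.
#' @export
protocol_span <- function(protocol) {
  c(min(protocol$segments$t_start), max(protocol$segments$t_end))
}

#' Evaluate the stimulus level of a protocol
#'
#' @param protocol a [pfl_protocol()].
#' @param t time (days), vectorized; times outside the span are clamped to
#'   the nearest endpoint level.
#' @return stimulus level(s) (a.u.).
#' @export
protocol_level <- function(protocol, t) {
  segs <- protocol$segments
  vapply(t, function(ti) {
    if (ti <= segs$t_start[1]) return(segs$level_start[1])
    n <- nrow(segs)
    if (ti >= segs$t_end[n]) return(segs$level_end[n])
    i <- max(which(segs$t_start <= ti + 1e-12))
    w <- (ti - segs$t_start[i]) / (segs$t_end[i] - segs$t_start[i])
    w <- min(max(w, 0), 1)
    segs$level_start[i] * (1 - w) + segs$level_end[i] * w
  }, numeric(1))
}

#' Step doxycycline protocol
#'
#' Zero stimulus before `t_on`, constant `level` from `t_on` to `t_end` —
#' the Tet-ON induction protocol abstraction.
#'
#' @param level doxycycline level (a.u.), `>= 0`.
#' @param t_on onset time (days).
#' @param t_end end of the protocol span (days), `> t_on`.
#' @return a [pfl_protocol()] in `"dox"` mode.
#' @export
dox_step <- function(level, t_on = 0, t_end = 20) {
  if (level < 0) stop("level must be >= 0")
  if (t_end <= t_on) stop("t_end must exceed t_on")
  segs <- data.frame(t_start = t_on, t_end = t_end,
                     level_start = level, level_end = level)
  if (t_on > 0) {
    segs <- rbind(data.frame(t_start = 0, t_end = t_on,
                             level_start = 0, level_end = 0), segs)
  }
  pfl_protocol("dox", segs)
}

#' Trapezoidal exogenous-TNC pulse
#'
#' Stimulus ramps linearly from 0 to `tnc_max` over `t_rise`, holds for
#' `t_plateau`, ramps back to 0 over `t_fall`, then stays at 0 for `t_tail`
#' (so post-pulse relaxation can be simulated within the protocol span).
#' This is the single-dose injection abstraction.
#'
#' @param tnc_max peak exogenous TNC level (a.u.), `>= 0`.
#' @param t_rise,t_plateau,t_fall phase durations (days), `>= 0`.
#' @param t_tail post-pulse duration at zero stimulus (days).
#' @return a [pfl_protocol()] in `"tnc_injection"` mode.
#' @export
tnc_pulse <- function(tnc_max, t_rise = 1, t_plateau = 5, t_fall = 1,
                      t_tail = 20) {
  if (tnc_max < 0) stop("tnc_max must be >= 0")
  if (any(c(t_rise, t_plateau, t_fall, t_tail) < 0)) {
    stop("durations must be >= 0")
  }
  t1 <- t_rise; t2 <- t1 + t_plateau; t3 <- t2 + t_fall; t4 <- t3 + t_tail
  segs <- list()
  if (t_rise > 0) {
    segs <- c(segs, list(data.frame(t_start = 0, t_end = t1,
                                    level_start = 0, level_end = tnc_max)))
  }
  if (t_plateau > 0) {
    segs <- c(segs, list(data.frame(t_start = t1, t_end = t2,
                                    level_start = tnc_max,
                                    level_end = tnc_max)))
  }
  if (t_fall > 0) {
    segs <- c(segs, list(data.frame(t_start = t2, t_end = t3,
                                    level_start = tnc_max, level_end = 0)))
  }
  if (t_tail > 0) {
    segs <- c(segs, list(data.frame(t_start = t3, t_end = t4,
                                    level_start = 0, level_end = 0)))
  }
  if (!length(segs)) {
    segs <- list(data.frame(t_start = 0, t_end = 1,
                            level_start = tnc_max, level_end = tnc_max))
  }
  pfl_protocol("tnc_injection", do.call(rbind, segs))
}

#' Concatenate two protocols
#'
#' Appends `p2` after `p1` (its times shifted so it starts where `p1` ends).
#' Integrating the concatenation equals integrating the parts in sequence
#' with matched states.
#'
#' @param p1,p2 protocols with the same mode.
#' @return a [pfl_protocol()].
#' @export
concat_protocols <- function(p1, p2) {
  if (p1$mode != p2$mode) stop("protocols must share a mode")
  off <- protocol_span(p1)[2] - protocol_span(p2)[1]
  s2 <- p2$segments
  s2$t_start <- s2$t_start + off
  s2$t_end <- s2$t_end + off
  pfl_protocol(p1$mode, rbind(p1$segments, s2))
}

#' @export
print.pfl_protocol <- function(x, ...) {
  sp <- protocol_span(x)
  cat("<pfl_protocol> mode ", x$mode, ", span [", sp[1], ", ", sp[2],
      "] days, peak level ", x$tnc_max, "\n", sep = "")
  invisible(x)
}
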