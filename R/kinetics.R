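#' Induction delay of a gene along a trajectory
#'
#' First time at which a gene exceeds `fold_threshold` times its initial
#' (pre-stimulus steady) level, linearly interpolated between samples —
#' the model counterpart of "days until a 2-fold band appears on the blot".
#' Baselines below `floor` fall back to an absolute threshold of
#' `fold_threshold * floor`, guarding against division by a near-zero
#' initial level.
#'
#' @param traj a [simulate_pfl()] trajectory starting at the pre-stimulus
#'   steady state.
#' @param gene `"Twist1"`, `"Prrx1"` or `"TNC"`.
#' @param fold_threshold induction fold threshold (> 1); default 2.
#' @param floor absolute baseline floor (a.u.).
#' @return the delay in days, or `NA` (flagged by attribute
#'   `"crossed" = FALSE`) if the threshold is never crossed.
#' @export
induction_delay <- function(traj, gene = c("TNC", "Twist1", "Prrx1"),
                            fold_threshold = 2, floor = 1e-6) {
  gene <- match.arg(gene)
  if (fold_threshold <= 1) stop("fold_threshold must be > 1")
  y <- traj[[gene]]
  t <- traj$time
  baseline <- max(y[1], floor)
  thr <- fold_threshold * baseline
  if (y[1] >= thr) return(structure(0, crossed = TRUE))
  idx <- which(y[-1] >= thr & y[-length(y)] < thr)
  if (!length(idx)) return(structure(NA_real_, crossed = FALSE))
  i <- idx[1]
  w <- (thr - y[i]) / (y[i + 1] - y[i])
  structure(t[i] * (1 - w) + t[i + 1] * w, crossed = TRUE)
}

#' Activation order of the three genes
#'
#' Ranks Twist1, Prrx1 and TNC by their [induction_delay()]; genes that are
#' never induced are dropped; ties are broken by the loop order Twist1,
#' Prrx1, TNC.
#'
#' @inheritParams induction_delay
#' @return a character vector (possibly empty) of induced genes in order of
#'   activation.
#' @export
activation_order <- function(traj, fold_threshold = 2, floor = 1e-6) {
  genes <- c("Twist1", "Prrx1", "TNC")
  d <- vapply(genes, function(g) {
    as.numeric(induction_delay(traj, g, fold_threshold, floor))
  }, numeric(1))
  keep <- !is.na(d)
  genes <- genes[keep]
  # order() is stable, so listing order breaks ties
  genes[order(d[keep])]
}
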