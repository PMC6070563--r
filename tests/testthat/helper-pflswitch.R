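# shared fixtures: presets are read once per test run
ref_params <- pfl_preset("dox_reference")$params
inj_params <- pfl_preset("dermal_injection")$params
mrc5_preset <- pfl_preset("mrc5")
imr90_preset <- pfl_preset("imr90")

# closed-form steady state of the open cascade (v_feedback = 0):
# Tw, then P, then T solve sequentially
open_cascade_steady <- function(params, dox) {
  p <- unclass(params)
  Tw <- (p[["basal_Tw"]] +
           p[["vmax_dox"]] * hill(dox, p[["km_dox"]], p[["n_dox"]])) /
    p[["deg_Tw"]]
  P <- (p[["basal_P"]] +
          p[["vmax_TwP"]] * hill(Tw, p[["km_TwP"]], p[["n_TwP"]])) /
    p[["deg_P"]]
  T <- (p[["basal_T"]] +
          p[["vmax_PT"]] * hill(P, p[["km_PT"]], p[["n_PT"]])) /
    p[["deg_T"]]
  c(Twist1 = Tw, Prrx1 = P, TNC = T)
}

# 27-point grid of initial conditions spanning the reachable state box
init_grid_27 <- function(params) {
  p <- unclass(params)
  tops <- c((p[["basal_Tw"]] + p[["vmax_dox"]] + p[["v_feedback"]]) /
              p[["deg_Tw"]],
            (p[["basal_P"]] + p[["vmax_TwP"]]) / p[["deg_P"]],
            (p[["basal_T"]] + p[["vmax_PT"]]) / p[["deg_T"]])
  as.matrix(expand.grid(Tw = c(0, 0.3, 1) * tops[1],
                        P = c(0, 0.3, 1) * tops[2],
                        T = c(0, 0.3, 1) * tops[3]))
}

# random parameter jitter around a base set (log-normal factors on the
# non-Hill fields), used by property-style suites
jitter_params <- function(base, sd = 0.2) {
  p <- unclass(base)
  for (f in setdiff(pfl_param_names(),
                    c("n_dox", "n_feedback", "n_TwP", "n_PT"))) {
    p[[f]] <- p[[f]] * exp(stats::rnorm(1, 0, sd))
  }
  do.call(pfl_params, as.list(p))
}

# sample bimodality coefficient; > 5/9 suggests bimodality
bimodality_coefficient <- function(x) {
  n <- length(x)
  m <- mean(x); s <- stats::sd(x)
  z <- (x - m) / s
  g1 <- mean(z^3) * sqrt(n * (n - 1)) / (n - 2)
  g2 <- ((n + 1) * mean(z^4) - 3 * (n - 1)) * (n - 1) / ((n - 2) * (n - 3))
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}
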