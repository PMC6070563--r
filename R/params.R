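#' Kinetic parameters of the Twist1-Prrx1-TNC feedback loop
#'
#' Constructs the full rate-constant set of the three-gene positive feedback
#' loop ODE. Concentrations are in arbitrary units (a.u.), time in days, so
#' production rates are a.u./day and degradation rates 1/day.
#'
#' The canonical model has 18 constants. The packaged presets keep the
#' effective count at 16 by fixing `n_dox = 1` and tying `n_TwP = n_PT`;
#' both are ordinary fields here, not hard-wired constraints.
#'
#' @param basal_Tw,basal_P,basal_T basal production rates (a.u./day).
#' @param vmax_dox maximal doxycycline-driven Twist1 production, often written
#'   K_Tw+ (a.u./day).
#' @param km_dox half-saturation of the doxycycline input (a.u.).
#' @param n_dox Hill coefficient of the doxycycline input.
#' @param v_feedback maximal TNC-driven Twist1 production, the feedback
#'   strength V_TNC->Tw (a.u./day).
#' @param km_feedback TNC level for half-maximal feedback, K_m1 (a.u.).
#' @param n_feedback Hill coefficient of the feedback term.
#' @param vmax_TwP,km_TwP,n_TwP Twist1 -> Prrx1 activation parameters.
#' @param vmax_PT,km_PT,n_PT Prrx1 -> TNC activation parameters.
#' @param deg_Tw Twist1 degradation rate, often written K_Tw- (1/day).
#' @param deg_P,deg_T Prrx1/TNC degradation rates (1/day).
#'
#' @return A named numeric vector of class `"pfl_params"`.
#' @examples
#' p <- pfl_params(v_feedback = 80)
#' p["v_feedback"]
#' @seealso [pfl_preset()] for the packaged calibrated parameter sets,
#'   [read_params()]/[write_params()] for JSON serialization.
#' @export
pfl_params <- function(basal_Tw = 1,
                       basal_P = 0.1 / 9,
                       basal_T = 0.1 / 3,
                       vmax_dox = 10,
                       km_dox = 8,
                       n_dox = 1,
                       v_feedback = 40,
                       km_feedback = 5,
                       n_feedback = 4,
                       vmax_TwP = 10 / 9,
                       km_TwP = 5,
                       n_TwP = 4,
                       vmax_PT = 2,
                       km_PT = 9,
                       n_PT = 4,
                       deg_Tw = 1,
                       deg_P = 1 / 9,
                       deg_T = 1 / 3) {
  p <- c(basal_Tw = basal_Tw, basal_P = basal_P, basal_T = basal_T,
         vmax_dox = vmax_dox, km_dox = km_dox, n_dox = n_dox,
         v_feedback = v_feedback, km_feedback = km_feedback,
         n_feedback = n_feedback,
         vmax_TwP = vmax_TwP, km_TwP = km_TwP, n_TwP = n_TwP,
         vmax_PT = vmax_PT, km_PT = km_PT, n_PT = n_PT,
         deg_Tw = deg_Tw, deg_P = deg_P, deg_T = deg_T)
  class(p) <- "pfl_params"
  validate_pfl_params(p)
  p
}

#' @rdname pfl_params
#' @format NULL
#' @export
pfl_param_names <- function() {
  c("basal_Tw", "basal_P", "basal_T",
    "vmax_dox", "km_dox", "n_dox",
    "v_feedback", "km_feedback", "n_feedback",
    "vmax_TwP", "km_TwP", "n_TwP",
    "vmax_PT", "km_PT", "n_PT",
    "deg_Tw", "deg_P", "deg_T")
}

#' Validate a kinetic parameter set
#'
#' Checks the domain invariants: every rate non-negative, degradation rates
#' strictly positive, half-saturation constants strictly positive, Hill
#' coefficients at least 1.
#'
#' @param p a [pfl_params()] object (or named numeric vector with the same
#'   fields).
#' @return `p`, invisibly; stops with a message listing offending fields
#'   otherwise.
#' @export
validate_pfl_params <- function(p) {
  nm <- pfl_param_names()
  missing <- setdiff(nm, names(p))
  if (length(missing)) {
    stop("missing parameter fields: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(p), nm)
  if (length(extra)) {
    stop("unknown parameter fields: ", paste(extra, collapse = ", "))
  }
  bad <- character()
  v <- unclass(p)[nm]
  if (any(!is.finite(v))) bad <- c(bad, nm[!is.finite(v)])
  neg <- nm[v < 0 & is.finite(v)]
  bad <- c(bad, neg)
  for (f in c("deg_Tw", "deg_P", "deg_T", "km_dox", "km_feedback",
              "km_TwP", "km_PT")) {
    if (is.finite(v[[f]]) && v[[f]] <= 0) bad <- c(bad, f)
  }
  for (f in c("n_dox", "n_feedback", "n_TwP", "n_PT")) {
    if (is.finite(v[[f]]) && v[[f]] < 1) bad <- c(bad, f)
  }
  bad <- unique(bad)
  if (length(bad)) {
    stop("invalid kinetic parameters (non-negative rates, positive ",
         "degradation and half-saturation constants, Hill coefficients >= 1 ",
         "required): ", paste(bad, collapse = ", "))
  }
  invisible(p)
}

#' Modify fields of a parameter set
#'
#' @param p a [pfl_params()] object.
#' @param ... named replacement values, e.g. `v_feedback = 80`.
#' @return the modified, re-validated parameter set.
#' @export
update_params <- function(p, ...) {
  ov <- c(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), pfl_param_names())
    if (length(unknown)) {
      stop("unknown parameter fields: ", paste(unknown, collapse = ", "))
    }
    p[names(ov)] <- ov
  }
  validate_pfl_params(p)
  p
}

#' @export
print.pfl_params <- function(x, ...) {
  cat("Twist1-Prrx1-TNC loop kinetic parameters (a.u., days)\n")
  m <- matrix(unclass(x), ncol = 3, byrow = TRUE)
  rn <- matrix(names(x), ncol = 3, byrow = TRUE)
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-12s %-10.4g %-12s %-10.4g %-12s %-10.4g\n",
                rn[i, 1], m[i, 1], rn[i, 2], m[i, 2], rn[i, 3], m[i, 3]))
  }
  invisible(x)
}

PFL_SCHEMA_VERSION <- 1L

#' Read / write kinetic parameters as JSON
#'
#' Parameter files are schema-versioned JSON with a `parameters` block holding
#' the 18 named fields of [pfl_params()]. Unknown keys (top-level or within
#' `parameters`) are rejected with the offending names; parameters violating
#' the domain invariants are rejected by [validate_pfl_params()]. The
#' round-trip `write_params()` then `read_params()` is lossless.
#'
#' @param path file path.
#' @return `read_params()` returns a validated [pfl_params()] object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed_top <- c("schema_version", "label", "description", "mode",
                   "parameters", "stimulus")
  extra <- setdiff(names(doc), allowed_top)
  if (length(extra)) {
    stop("unknown keys in parameter file: ", paste(extra, collapse = ", "))
  }
  if (is.null(doc$schema_version) || doc$schema_version != PFL_SCHEMA_VERSION) {
    stop("unsupported or missing schema_version (expected ",
         PFL_SCHEMA_VERSION, ")")
  }
  if (is.null(doc$parameters)) stop("parameter file lacks a 'parameters' block")
  pv <- unlist(doc$parameters)
  extra <- setdiff(names(pv), pfl_param_names())
  if (length(extra)) {
    stop("unknown keys in 'parameters': ", paste(extra, collapse = ", "))
  }
  do.call(pfl_params, as.list(pv))
}

#' @rdname read_params
#' @param params a [pfl_params()] object to serialize.
#' @param label optional short name stored alongside the parameters.
#' @param description optional free-text note.
#' @param mode optional stimulus mode hint (`"dox"` or `"tnc_injection"`).
#' @param stimulus optional named list of stimulus metadata (e.g. `dox_level`,
#'   `dose_scale`, `tnc_max`).
#' @export
write_params <- function(params, path, label = NULL, description = NULL,
                         mode = NULL, stimulus = NULL) {
  validate_pfl_params(params)
  doc <- list(schema_version = PFL_SCHEMA_VERSION)
  if (!is.null(label)) doc$label <- label
  if (!is.null(description)) doc$description <- description
  if (!is.null(mode)) doc$mode <- mode
  doc$parameters <- as.list(unclass(params)[pfl_param_names()])
  if (!is.null(stimulus)) doc$stimulus <- stimulus
  # I(17) significant digits: the decimal text round-trips every double
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Packaged calibrated parameter presets
#'
#' Four parameter sets ship with the package, tuned once against the
#' qualitative and kinetic anchors of the fibroblast-activation study:
#'
#' * `"dox_reference"` — the reference doxycycline-induction model: bistable
#'   over an intermediate dox window, reversible hysteresis at the default
#'   feedback strength (`v_feedback = 40`), irreversible at `v_feedback = 80`.
#' * `"mrc5"` — identical to `"dox_reference"`; under a saturating dox step
#'   its noise-free TNC induction is delayed ~8 days (slow Prrx1/TNC
#'   turnover), mimicking MRC5-like kinetics.
#' * `"imr90"` — same equilibrium structure with faster Prrx1/TNC turnover;
#'   TNC induction delay ~4 days (IMR90-like).
#' * `"dermal_injection"` — the exogenous-TNC injection model for dermal
#'   fibroblasts: irreversible at `(km_feedback, v_feedback) = (5, 30)` for a
#'   pulse of amplitude 3, reversible at `(10, 15)` for any amplitude, and a
#'   dose-to-stimulus scale (`dose_scale`, a.u. per microgram) calibrated so
#'   that among doses {0, 0.1, 1, 2, 5} ug only 5 ug activates the loop.
#'
#' @param name preset name.
#' @return a list of class `"pfl_preset"` with elements `label`, `mode`,
#'   `params` ([pfl_params()]), `description`, and mode-specific stimulus
#'   metadata: `dox_level` (dox presets) or `dose_scale` and `tnc_max`
#'   (injection preset).
#' @examples
#' pr <- pfl_preset("dermal_injection")
#' pr$params["v_feedback"]
#' @export
pfl_preset <- function(name = c("dox_reference", "mrc5", "imr90",
                                "dermal_injection")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".json"),
                      package = "pflswitch", mustWork = TRUE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(label = doc$label, mode = doc$mode,
              params = read_params(path),
              description = doc$description)
  for (f in names(doc$stimulus)) out[[f]] <- doc$stimulus[[f]]
  class(out) <- "pfl_preset"
  out
}

#' @export
print.pfl_preset <- function(x, ...) {
  cat("<pfl_preset> ", x$label, " (mode: ", x$mode, ")\n", sep = "")
  if (!is.null(x$description)) cat("  ", x$description, "\n", sep = "")
  print(x$params)
  invisible(x)
}
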