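#' Genetic-algorithm estimation settings
#'
#' Hyperparameters of the global search used by [fit_pfl()]: a generational
#' genetic algorithm over log10-parameter space (tournament selection,
#' uniform crossover, Gaussian mutation, elitism), optionally followed by a
#' derivative-free local polish of the best individual.
#'
#' @param pop_size population size (>= 10).
#' @param generations number of generations.
#' @param crossover uniform-crossover probability per pair.
#' @param mutation per-gene mutation probability.
#' @param mutation_sd mutation step s.d., as a fraction of each parameter's
#'   log10 bound range.
#' @param elite number of elite individuals copied unchanged (>= 1 keeps the
#'   best-objective trace non-increasing).
#' @param tournament tournament size for selection.
#' @param local_polish run a Nelder-Mead refinement of the best individual.
#' @param polish_maxit iteration cap for the polish.
#' @param bounds_decades default half-width of the log10 search box around
#'   the base parameters.
#' @param seed RNG seed; the whole fit is reproducible given it.
#' @return a list of class `"pfl_estimation_config"`.
#' @export
estimation_config <- function(pop_size = 100, generations = 200,
                              crossover = 0.8, mutation = 0.1,
                              mutation_sd = 0.15, elite = 2,
                              tournament = 3, local_polish = TRUE,
                              polish_maxit = 300, bounds_decades = 2,
                              seed = 1) {
  if (pop_size < 10) stop("pop_size must be >= 10")
  if (elite < 0 || elite >= pop_size) stop("elite must be in [0, pop_size)")
  if (is.null(seed)) stop("seed must be set")
  out <- list(pop_size = as.integer(pop_size),
              generations = as.integer(generations),
              crossover = crossover, mutation = mutation,
              mutation_sd = mutation_sd, elite = as.integer(elite),
              tournament = as.integer(tournament),
              local_polish = isTRUE(local_polish),
              polish_maxit = as.integer(polish_maxit),
              bounds_decades = bounds_decades, seed = as.integer(seed))
  class(out) <- "pfl_estimation_config"
  out
}

# Predicted noise-free log2 fold changes for one dataset at `params`,
# aligned row-by-row with dataset$data.
predict_dataset <- function(params, dataset) {
  if (inherits(dataset, "pfl_timecourse_dataset")) {
    fp <- find_fixed_points(params, 0, dataset$protocol$mode,
                            scan_points = 500)
    st <- fp[fp$stable, , drop = FALSE]
    traj <- simulate_pfl(params, dataset$protocol,
                         sort(unique(dataset$times)),
                         init = as.numeric(st[1, c("Twist1", "Prrx1",
                                                   "TNC")]))
    genes <- c("Twist1", "Prrx1", "TNC")
    base <- pmax(as.numeric(traj[1, genes]), 1e-12)
    mu <- sapply(genes, function(g) log2(pmax(traj[[g]], 1e-12) /
                                           base[match(g, genes)]))
    key <- paste(dataset$data$gene, dataset$data$time)
    ref <- paste(rep(genes, each = nrow(traj)), rep(traj$time, 3))
    as.numeric(mu)[match(key, ref)]
  } else if (inherits(dataset, "pfl_dose_response_dataset")) {
    clean <- generate_dose_response(list(params = params,
                                         dose_scale = dataset$dose_scale),
                                    doses = dataset$doses, noise_sd = 0,
                                    n_reps = 1, seed = 1,
                                    readout = dataset$readout)
    key <- paste(dataset$data$gene, dataset$data$dose)
    ref <- paste(clean$data$gene, clean$data$dose)
    clean$data$log2fc[match(key, ref)]
  } else {
    stop("unsupported dataset type")
  }
}

#' Negative log-likelihood of datasets under the model
#'
#' Simulates each dataset's protocol noise-free, converts to log2 fold
#' change at the measured times/doses, and scores the observations under
#' i.i.d. Gaussian noise of standard deviation `noise_sd` (log2 units):
#' `sum((y_obs - y_sim)^2 / (2 sigma^2)) + n log(sigma sqrt(2 pi))`.
#' A failed simulation yields `+Inf` (the candidate is rejected, no error).
#'
#' @param params candidate [pfl_params()].
#' @param datasets a dataset from [generate_timecourse()] /
#'   [generate_dose_response()], or a list of them.
#' @param noise_sd assumed noise s.d. (log2 units), `> 0`.
#' @return the negative log-likelihood (finite for feasible candidates).
#' @export
nll_objective <- function(params, datasets, noise_sd = 0.2) {
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (inherits(datasets, c("pfl_timecourse_dataset",
                           "pfl_dose_response_dataset"))) {
    datasets <- list(datasets)
  }
  if (!length(datasets)) stop("datasets must be non-empty")
  tryCatch({
    nll <- 0
    for (d in datasets) {
      mu <- predict_dataset(params, d)
      r <- d$data$log2fc - mu
      nll <- nll + sum(r^2) / (2 * noise_sd^2) +
        length(r) * log(noise_sd * sqrt(2 * pi))
    }
    if (!is.finite(nll)) Inf else nll
  }, error = function(e) Inf)
}

#' Fit kinetic parameters by genetic algorithm with local refinement
#'
#' Maximum-likelihood estimation of a chosen subset of the kinetic
#' parameters: a genetic algorithm searches log10-parameter space inside
#' `bounds` (by default `bounds_decades` decades either side of
#' `base_params`), then a Nelder-Mead polish refines the best individual.
#' Initialization is log-uniform within bounds. Fully reproducible given
#' `config$seed`.
#'
#' @param datasets observation set(s), as for [nll_objective()].
#' @param config an [estimation_config()].
#' @param base_params full parameter set supplying the fixed (non-free)
#'   values and the bound centers.
#' @param free character vector of parameter names to estimate.
#' @param noise_sd assumed noise s.d. (log2 units).
#' @param bounds optional 2-row matrix (`low`/`high`) with one column per
#'   free parameter, on the natural scale.
#' @return a list of class `"pfl_fit"`: `params` (full best-fit set),
#'   `objective` (negative log-likelihood), `trace` (per-generation best
#'   objective, non-increasing), `free`, `converged`, `seed`, `config`.
#' @export
fit_pfl <- function(datasets, config = estimation_config(),
                    base_params = pfl_params(),
                    free = c("v_feedback", "km_feedback", "deg_Tw",
                             "vmax_dox"),
                    noise_sd = 0.2, bounds = NULL) {
  validate_pfl_params(base_params)
  if (!length(free)) stop("at least one free parameter is required")
  unknown <- setdiff(free, pfl_param_names())
  if (length(unknown)) stop("unknown free parameters: ",
                            paste(unknown, collapse = ", "))
  k <- length(free)
  if (is.null(bounds)) {
    ctr <- log10(pmax(unclass(base_params)[free], 1e-8))
    lo <- ctr - config$bounds_decades
    hi <- ctr + config$bounds_decades
  } else {
    if (!is.matrix(bounds) || nrow(bounds) != 2 || ncol(bounds) != k) {
      stop("bounds must be a 2 x length(free) matrix")
    }
    if (any(bounds[1, ] >= bounds[2, ]) || any(bounds[1, ] <= 0)) {
      stop("bounds must satisfy 0 < low < high")
    }
    lo <- log10(bounds[1, ]); hi <- log10(bounds[2, ])
  }
  span <- hi - lo
  obj_log <- function(x) {
    x <- pmin(pmax(x, lo), hi)
    cand <- base_params
    cand[free] <- 10^x
    cand <- tryCatch(validate_pfl_params(cand), error = function(e) NULL)
    if (is.null(cand)) return(Inf)
    nll_objective(cand, datasets, noise_sd)
  }
  res <- with_local_seed(config$seed, {
    pop <- matrix(stats::runif(config$pop_size * k), ncol = k)
    pop <- sweep(sweep(pop, 2, span, "*"), 2, lo, "+")
    fit <- apply(pop, 1, obj_log)
    if (all(!is.finite(fit))) stop("estimation failed: no feasible candidate")
    trace <- numeric(config$generations)
    for (gen in seq_len(config$generations)) {
      ord <- order(fit)
      elite_idx <- ord[seq_len(max(config$elite, 1))]
      # tournament selection
      pick <- function() {
        cand <- sample.int(config$pop_size, config$tournament)
        cand[which.min(fit[cand])]
      }
      n_child <- config$pop_size - config$elite
      children <- matrix(NA_real_, n_child, k)
      for (c1 in seq_len(n_child)) {
        a <- pop[pick(), ]; b <- pop[pick(), ]
        child <- if (stats::runif(1) < config$crossover) {
          m <- stats::runif(k) < 0.5
          ifelse(m, a, b)
        } else a
        mut <- stats::runif(k) < config$mutation
        child[mut] <- child[mut] +
          stats::rnorm(sum(mut), 0, config$mutation_sd * span[mut])
        children[c1, ] <- pmin(pmax(child, lo), hi)
      }
      pop <- rbind(pop[elite_idx[seq_len(config$elite)], , drop = FALSE],
                   children)
      fit <- c(fit[elite_idx[seq_len(config$elite)]],
               apply(children, 1, obj_log))
      trace[gen] <- min(fit)
    }
    best <- pop[which.min(fit), ]
    best_obj <- min(fit)
    polished <- FALSE
    if (config$local_polish) {
      op <- if (k == 1) {
        stats::optim(best, obj_log, method = "Brent", lower = lo,
                     upper = hi,
                     control = list(maxit = config$polish_maxit))
      } else {
        stats::optim(best, obj_log, method = "Nelder-Mead",
                     control = list(maxit = config$polish_maxit,
                                    reltol = 1e-10))
      }
      if (is.finite(op$value) && op$value <= best_obj) {
        best <- pmin(pmax(op$par, lo), hi)
        best_obj <- op$value
        polished <- op$convergence == 0
      }
    }
    list(best = best, best_obj = best_obj, trace = trace,
         polished = polished)
  })
  params <- base_params
  params[free] <- 10^res$best
  out <- list(params = validate_pfl_params(params),
              objective = res$best_obj, trace = res$trace, free = free,
              converged = res$polished || !config$local_polish,
              seed = config$seed, config = config)
  class(out) <- "pfl_fit"
  out
}

#' @export
print.pfl_fit <- function(x, ...) {
  cat("<pfl_fit> negative log-likelihood:", format(x$objective, digits = 6),
      "\n  free parameters:\n")
  for (f in x$free) {
    cat(sprintf("    %-12s %.5g\n", f, x$params[[f]]))
  }
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Validates the estimation pipeline: for each seed, generate a synthetic
#' time-course dataset from `true_params`, fit the `free` parameters, and
#' summarize the per-parameter relative errors across seeds.
#'
#' @param true_params generating [pfl_params()].
#' @param free parameters to estimate.
#' @param noise_sd noise s.d. of the generated data (log2 units), also used
#'   in the likelihood.
#' @param seeds integer vector; one replicate per seed (>= 3).
#' @param config an [estimation_config()] (its seed is combined with each
#'   replicate seed).
#' @param protocol,times,n_reps passed to [generate_timecourse()].
#' @param dox_level dox step level used when `protocol` is `NULL`.
#' @param identifiability_limit median relative error above which a
#'   parameter is flagged non-identifiable.
#' @return a list of class `"pfl_recovery"`: `summary` (`data.frame` with
#'   `parameter`, `median_rel_error`, `bias`, `identifiable`), `details`
#'   (per-seed relative errors), `fits`.
#' @export
recovery_experiment <- function(true_params, free, noise_sd = 0.2,
                                seeds = 1:10,
                                config = estimation_config(),
                                protocol = NULL,
                                times = c(0, 1, 2, 3, 5, 8, 11, 15),
                                n_reps = 3, dox_level = 10,
                                identifiability_limit = 1) {
  if (length(seeds) < 3) stop("at least 3 replicates are required")
  details <- list()
  fits <- list()
  for (s in seeds) {
    d <- generate_timecourse(list(params = true_params,
                                  dox_level = dox_level),
                             protocol = protocol, times = times,
                             noise_sd = noise_sd, n_reps = n_reps, seed = s)
    cfg <- config
    cfg$seed <- (config$seed * 1009L + as.integer(s)) %% .Machine$integer.max
    f <- tryCatch(fit_pfl(d, cfg, base_params = true_params, free = free,
                          noise_sd = max(noise_sd, 1e-3)),
                  error = function(e) NULL)
    fits[[as.character(s)]] <- f
    if (is.null(f)) next
    rel <- (unclass(f$params)[free] - unclass(true_params)[free]) /
      unclass(true_params)[free]
    details[[as.character(s)]] <- rel
  }
  if (!length(details)) stop("all fits failed")
  m <- do.call(rbind, details)
  summary <- data.frame(
    parameter = free,
    median_rel_error = apply(abs(m), 2, stats::median),
    bias = sign(apply(m, 2, stats::median)),
    row.names = NULL)
  summary$identifiable <- summary$median_rel_error <= identifiability_limit
  out <- list(summary = summary, details = m, fits = fits,
              noise_sd = noise_sd, seeds = seeds)
  class(out) <- "pfl_recovery"
  out
}

#' @export
print.pfl_recovery <- function(x, ...) {
  cat("<pfl_recovery> ", nrow(x$details), " replicates, noise_sd = ",
      x$noise_sd, " (log2)\n", sep = "")
  print.data.frame(x$summary, digits = 3)
  invisible(x)
}
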