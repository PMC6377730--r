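#' Configuration of the synthetic-data generator
#'
#' Encodes the pseudo-experimental protocol used for the bundled case
#' studies: trajectories simulated at the nominal parameters on an
#' equidistant grid, Gaussian noise with standard deviation 10% of the
#' nominal signal value, a detection threshold of 0.1 below which reported
#' values are recorded at the threshold, 10 fitting replicates with fixed
#' initial conditions and 10 cross-validation replicates with randomised
#' initial conditions.
#'
#' @param model optional [oscifitModel()]; supplies defaults for `points`
#'   (FHN 6, GO 20, RP 20, EO 14) and `horizon`.
#' @param noise_fraction noise standard deviation as a fraction of the
#'   nominal signal value (0.10).
#' @param detection_threshold measurement floor; reported values below it
#'   are recorded at the threshold. Use `-Inf` to disable censoring (e.g.
#'   for noise-free recovery experiments on signals that go negative).
#' @param sigma_floor smallest stored measurement standard deviation; keeps
#'   the weights finite where the nominal signal crosses zero.
#' @param n_fitting,n_crossval numbers of replicate datasets.
#' @param points data points per experiment.
#' @param horizon time horizon (grid spans `[0, horizon]`).
#' @param ic_perturbation multiplicative half-range for cross-validation
#'   initial conditions: each nonzero nominal IC is multiplied by
#'   Uniform(1 - p, 1 + p); zero ICs are perturbed additively by
#'   Uniform(0, 0.1).
#' @param seed master seed; per-replicate seeds derive from it
#'   deterministically.
#' @return list of class `oscifit_datagen_config`.
#' @export
dataGenConfig <- function(model = NULL, noise_fraction = 0.10,
                          detection_threshold = 0.1, sigma_floor = 0.01,
                          n_fitting = 10, n_crossval = 10,
                          points = NULL, horizon = NULL,
                          ic_perturbation = 0.5, seed = 1) {
  if (is.null(points)) points <- if (!is.null(model)) model$points else 10L
  if (is.null(horizon)) horizon <- if (!is.null(model)) model$horizon else 10
  stopifnot(noise_fraction >= 0, points >= 2)
  structure(list(noise_fraction = noise_fraction,
                 detection_threshold = detection_threshold,
                 sigma_floor = sigma_floor,
                 n_fitting = n_fitting, n_crossval = n_crossval,
                 points = points, horizon = horizon,
                 ic_perturbation = ic_perturbation, seed = seed),
            class = "oscifit_datagen_config")
}

replicate_seed <- function(master, r, stream = 0L) {
  (as.integer(master) + 7919L * as.integer(r) + 104729L * stream) %% 2147483647L
}

#' Apply the measurement-noise model to nominal signal values
#'
#' \eqn{\tilde y = y^* + \epsilon}, \eqn{\epsilon \sim N(0, (f |y^*|)^2)}
#' with noise fraction f; any value below the detection threshold is
#' recorded at the threshold (left-censoring at the limit of detection).
#' The stored standard deviation is \eqn{\max(f |y^*|,
#' \sigma_{floor})}. Uses the current RNG state: seed upstream for
#' reproducibility.
#'
#' @param y_star numeric vector of nominal (noise-free) signal values.
#' @param noise_fraction,detection_threshold,sigma_floor see
#'   [dataGenConfig()].
#' @return list with `value` (reported measurements) and `sigma`.
#' @export
addMeasurementNoise <- function(y_star, noise_fraction = 0.10,
                                detection_threshold = 0.1,
                                sigma_floor = 0.01) {
  sd_true <- noise_fraction * abs(y_star)
  value <- y_star + stats::rnorm(length(y_star), 0, sd_true)
  value <- pmax(value, detection_threshold)
  list(value = value, sigma = pmax(sd_true, sigma_floor))
}

generate_one <- function(model, theta, x0, config, variant, exp_id, seed) {
  times <- seq(0, config$horizon, length.out = config$points)
  traj <- simulateModel(model, theta, x0 = x0, times = times,
                        variant = variant)
  if (!traj$feasible)
    stop("integration failure at the nominal parameters; the nominal ",
         "point must be feasible")
  ov <- model$compiled$obs[[variant]]
  set.seed(seed)
  tabs <- lapply(seq_len(ov$ny), function(k) {
    m <- addMeasurementNoise(traj$obs[, k], config$noise_fraction,
                             config$detection_threshold, config$sigma_floor)
    data.frame(experiment = exp_id, observable = ov$names[k],
               time = times, value = m$value, sigma = m$sigma)
  })
  experimentData(do.call(rbind, tabs), stats::setNames(list(x0), exp_id),
                 variant)
}

#' Generate replicate fitting datasets at the nominal parameters
#'
#' Each replicate shares the model's nominal initial conditions and an
#' equidistant time grid over `[0, horizon]`; only the noise realisation
#' differs, with per-replicate seeds derived deterministically from the
#' master seed.
#'
#' @param model an [oscifitModel()].
#' @param config a [dataGenConfig()].
#' @param theta data-generating parameters (default: the model's nominal).
#' @param x0 initial conditions (default: the model's).
#' @param variant observation variant for the fitting data.
#' @return list of [experimentData()] objects, one per replicate.
#' @export
generateFittingData <- function(model, config = dataGenConfig(model),
                                theta = model$nominal, x0 = model$x0,
                                variant = "fitting") {
  if (is.null(theta)) stop("model has no nominal parameters; supply theta")
  lapply(seq_len(config$n_fitting), function(r)
    generate_one(model, theta, x0, config, variant, paste0("fit", r),
                 replicate_seed(config$seed, r, 0L)))
}

#' Generate cross-validation datasets with randomised initial conditions
#'
#' Each replicate perturbs the nominal initial conditions — nonzero entries
#' multiplicatively by Uniform(1-p, 1+p), zero entries additively by
#' Uniform(0, 0.1) — and measures the model's validation observation
#' variant (for the Goodwin and Repressilator problems this adds an extra
#' observable relative to fitting). Initial conditions whose simulation
#' fails are redrawn (at most 20 attempts).
#'
#' @inheritParams generateFittingData
#' @param variant observation variant (default `"validation"`, falling back
#'   to `"fitting"` when the model defines no validation variant).
#' @return list of [experimentData()] objects, one per replicate.
#' @export
generateCrossvalData <- function(model, config = dataGenConfig(model),
                                 theta = model$nominal, x0 = model$x0,
                                 variant = NULL) {
  if (is.null(theta)) stop("model has no nominal parameters; supply theta")
  if (is.null(variant))
    variant <- if ("validation" %in% names(model$observations))
      "validation" else "fitting"
  p <- config$ic_perturbation
  lapply(seq_len(config$n_crossval), function(r) {
    seed <- replicate_seed(config$seed, r, 1L)
    set.seed(seed)
    for (attempt in seq_len(20L)) {
      fac <- stats::runif(length(x0), 1 - p, 1 + p)
      add <- stats::runif(length(x0), 0, 0.1)
      x0r <- ifelse(x0 != 0, x0 * fac, add)
      d <- try(generate_one(model, theta, x0r, config, variant,
                            paste0("cv", r),
                            replicate_seed(config$seed, r, 2L + attempt)),
               silent = TRUE)
      if (!inherits(d, "try-error")) return(d)
    }
    stop("could not find feasible perturbed initial conditions after 20 ",
         "attempts")
  })
}
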