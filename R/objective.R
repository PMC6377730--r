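# Simulate one experiment at the union of its measurement times and return
# the simulated values aligned with the data rows. Returns NULL when the
# integration fails, together with the unsolved fraction.
simulate_for_data <- function(model, theta, data, experiment,
                              rtol = 1e-8, atol = 1e-10) {
  rows <- data$table$experiment == experiment
  tab <- data$table[rows, , drop = FALSE]
  tt <- sort(unique(c(0, tab$time)))
  traj <- simulateModel(model, theta, x0 = data$x0[[experiment]], times = tt,
                        variant = data$variant, rtol = rtol, atol = atol)
  if (!traj$feasible)
    return(list(ok = FALSE, frac = traj$frac_unsolved, rows = rows))
  ov <- model$compiled$obs[[data$variant]]
  ti <- match(tab$time, tt)
  oi <- match(tab$observable, ov$names)
  list(ok = TRUE, rows = rows, y = traj$obs[cbind(ti, oi)], traj = traj,
       time_index = ti, obs_index = oi, times = tt)
}

#' Weighted nonlinear least-squares cost
#'
#' Computes \eqn{Q_{NLS}(\theta) = \sum_{kji} ((y_{kji} -
#' \tilde y_{kji})/\sigma_{kji})^2 = r^T r}, simulating each experiment once
#' from its own initial conditions. An experiment whose simulation fails
#' contributes the infeasibility penalty (1e10 plus the unsolved fraction of
#' the horizon) instead of crashing, so global searches can traverse
#' non-integrable regions.
#'
#' @inheritParams simulateModel
#' @param data an [experimentData()] object.
#' @return list with `cost` (scalar \eqn{Q_{NLS}}) and `residuals` (the
#'   stacked weighted residual vector; `NULL` when any simulation failed).
#' @export
nlsCost <- function(model, theta, data, rtol = 1e-8, atol = 1e-10) {
  check_data_model(model, data)
  r <- numeric(nrow(data$table))
  penalty <- 0
  for (ex in names(data$x0)) {
    sim <- simulate_for_data(model, theta, data, ex, rtol, atol)
    if (!sim$ok) {
      penalty <- penalty + PENALTY_COST + sim$frac
      next
    }
    tab <- data$table[sim$rows, , drop = FALSE]
    r[sim$rows] <- (sim$y - tab$value) / tab$sigma
  }
  if (penalty > 0) return(list(cost = penalty, residuals = NULL))
  list(cost = sum(r * r), residuals = r)
}

#' Log-likelihood of the data under the Gaussian measurement model
#'
#' \eqn{\log L = -Q_{NLS}/2 - \sum_{kji} \log(\sigma_{kji}\sqrt{2\pi})};
#' maximising it is equivalent to minimising [nlsCost()] for fixed sigmas.
#'
#' @inheritParams nlsCost
#' @return scalar log-likelihood (`-Inf` when the simulation is infeasible).
#' @export
logLikelihood <- function(model, theta, data, rtol = 1e-8, atol = 1e-10) {
  q <- nlsCost(model, theta, data, rtol, atol)
  if (is.null(q$residuals)) return(-Inf)
  -q$cost / 2 - sum(log(data$table$sigma * sqrt(2 * pi)))
}

#' Tikhonov regularisation penalty
#'
#' \eqn{\Gamma(\theta) = (\theta - \theta^{ref})^T W^T W (\theta -
#' \theta^{ref})} with \eqn{W = diag(1/\theta^{ref}_i)}. The normalisation by
#' the reference makes the penalty invariant to the units of each parameter:
#' \eqn{\Gamma} only sees relative displacements from the reference.
#'
#' @param theta parameter vector.
#' @param theta_ref reference parameter vector (all entries non-zero).
#' @return scalar penalty \eqn{\Gamma \ge 0}, zero iff `theta == theta_ref`.
#' @export
regPenalty <- function(theta, theta_ref) {
  if (any(theta_ref == 0))
    stop("theta_ref must have no zero entries (W = diag(1/theta_ref))")
  z <- (theta - theta_ref) / theta_ref
  sum(z * z)
}

#' Regularised estimation cost
#'
#' \eqn{Q_R(\theta) = Q_{NLS}(\theta) + \alpha \Gamma(\theta)}; `alpha = 0`
#' recovers the plain weighted least-squares cost exactly.
#'
#' @inheritParams nlsCost
#' @param alpha non-negative regularisation weight.
#' @param theta_ref reference parameter vector.
#' @return list with `cost` (\eqn{Q_R}), `q_nls` and `penalty`
#'   (\eqn{\Gamma}).
#' @export
regCost <- function(model, theta, data, alpha, theta_ref,
                    rtol = 1e-8, atol = 1e-10) {
  stopifnot(alpha >= 0)
  q <- nlsCost(model, theta, data, rtol, atol)
  g <- regPenalty(theta, theta_ref)
  list(cost = q$cost + alpha * g, q_nls = q$cost, penalty = g)
}

#' Normalised root-mean-square error
#'
#' Each residual is normalised by the measured range of its own series (one
#' observable within one experiment), squared, summed over all series and
#' points, divided by the total number of points and square-rooted. Series
#' with zero measured range carry no scale information; they are excluded
#' with a warning and the point count reduced accordingly.
#'
#' @param simulated numeric vector of simulated values aligned with the rows
#'   of `data$table` (e.g. from the fitted model).
#' @param data an [experimentData()] object.
#' @return scalar NRMSE.
#' @export
nrmse <- function(simulated, data) {
  tab <- data$table
  stopifnot(length(simulated) == nrow(tab))
  key <- paste(tab$experiment, tab$observable, sep = "\r")
  rng <- tapply(tab$value, key, function(v) max(v) - min(v))
  series_range <- rng[key]
  keep <- series_range > 0
  if (!all(keep)) {
    warning("excluding ", sum(!keep), " point(s) from constant measured ",
            "series (zero range)")
  }
  if (!any(keep)) stop("all measured series are constant; NRMSE undefined")
  z <- (simulated[keep] - tab$value[keep]) / series_range[keep]
  sqrt(sum(z * z) / sum(keep))
}

#' NRMSE of a model fit
#'
#' Convenience wrapper: simulates every experiment in `data` at `theta` and
#' evaluates [nrmse()] on the pooled residuals. Experiments whose simulation
#' fails are scored against a large sentinel value and flagged with a
#' warning.
#'
#' @inheritParams nlsCost
#' @return scalar NRMSE.
#' @export
modelNrmse <- function(model, theta, data, rtol = 1e-8, atol = 1e-10) {
  check_data_model(model, data)
  y <- numeric(nrow(data$table))
  for (ex in names(data$x0)) {
    sim <- simulate_for_data(model, theta, data, ex, rtol, atol)
    if (!sim$ok) {
      warning("infeasible simulation for experiment '", ex,
              "'; scored at the penalty sentinel")
      y[sim$rows] <- 1e5
    } else {
      y[sim$rows] <- sim$y
    }
  }
  nrmse(y, data)
}
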