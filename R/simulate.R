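# Sentinel cost assigned to parameter vectors whose initial value problem
# cannot be integrated; the fraction of the horizon left unsolved is added so
# that "almost integrable" points rank better than immediate blow-ups.
PENALTY_COST <- 1e10

# lsoda, with solver chatter (Fortran-level failure diagnostics) captured
# away: integration failure is an expected, handled outcome here.
quiet_lsoda <- function(y0, times, derivs, rtol, atol) {
  out <- NULL
  utils::capture.output({
    out <- try(suppressWarnings(suppressMessages(
      deSolve::lsoda(y0, times, derivs, parms = NULL,
                     rtol = rtol, atol = atol, maxsteps = 2000))),
      silent = TRUE)
  })
  out
}

eval_env <- function(y, theta, t) {
  vals <- c(as.list(y), as.list(theta))
  vals$t <- t
  vals
}

#' Simulate a model on a time grid
#'
#' Solves the initial value problem with a stiff-capable variable-step
#' integrator (`deSolve::lsoda`) and applies the observation map of the
#' requested variant at every grid point. Integration failures (blow-up,
#' step-size underflow) are not errors: the returned trajectory is flagged
#' infeasible and downstream cost functions convert it into a large penalty.
#'
#' @param model an [oscifitModel()].
#' @param theta parameter vector (named or in `model$params` order). Values
#'   outside the model bounds produce a warning, not an error.
#' @param x0 initial state at `times[1]` (default `model$x0`).
#' @param times strictly increasing time grid.
#' @param variant observation variant name.
#' @param rtol,atol integrator tolerances.
#' @return An object of class `oscifit_traj`: list with `times`,
#'   `states` (matrix, one column per state), `obs` (matrix, one column per
#'   observable), `feasible` flag and `frac_unsolved`.
#' @export
simulateModel <- function(model, theta, x0 = model$x0, times,
                          variant = "fitting", rtol = 1e-8, atol = 1e-10) {
  theta <- as_named_vec(theta, model$params, "theta")
  x0 <- as_named_vec(x0, model$states, "x0")
  if (any(theta < model$lower | theta > model$upper))
    warning("theta is outside the model bounds")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")

  ov <- model$compiled$obs[[variant]]
  if (is.null(ov)) stop("unknown observation variant: ", variant)

  if (length(times) == 1L) {
    states <- matrix(x0, 1L, dimnames = list(NULL, model$states))
    return(new_traj(times, states, obs_matrix(model, variant, states, theta,
                                              times), TRUE, 0))
  }

  plist <- as.list(theta)
  rhs_call <- model$compiled$rhs_call
  snames <- model$states
  derivs <- function(t, y, p) {
    vals <- c(as.list(y), plist)
    vals$t <- t
    list(eval(rhs_call, vals, baseenv()))
  }
  names(x0) <- snames
  out <- quiet_lsoda(x0, times, derivs, rtol, atol)

  if (inherits(out, "try-error") || !is.matrix(out) ||
      nrow(out) < length(times) || any(!is.finite(out))) {
    solved <- if (inherits(out, "try-error") || !is.matrix(out)) 0L else
      sum(cumprod(apply(is.finite(out), 1L, all)))
    frac <- 1 - solved / length(times)
    return(new_traj(times, NULL, NULL, FALSE, frac))
  }
  states <- out[, -1L, drop = FALSE]
  colnames(states) <- snames
  new_traj(times, states, obs_matrix(model, variant, states, theta, times),
           TRUE, 0)
}

new_traj <- function(times, states, obs, feasible, frac_unsolved) {
  structure(list(times = times, states = states, obs = obs,
                 feasible = feasible, frac_unsolved = frac_unsolved),
            class = "oscifit_traj")
}

#' @export
print.oscifit_traj <- function(x, ...) {
  if (!x$feasible) {
    cat(sprintf("<oscifit_traj> infeasible simulation (%.0f%% unsolved)\n",
                100 * x$frac_unsolved))
  } else {
    cat(sprintf("<oscifit_traj> %d time points, %d states, %d observables\n",
                length(x$times), ncol(x$states), ncol(x$obs)))
  }
  invisible(x)
}

# Vectorised evaluation of an observation variant on a state matrix.
obs_matrix <- function(model, variant, states, theta, times) {
  ov <- model$compiled$obs[[variant]]
  vals <- c(lapply(seq_along(model$states), function(j) states[, j]),
            as.list(theta))
  names(vals)[seq_along(model$states)] <- model$states
  vals$t <- times
  nt <- nrow(states)
  out <- matrix(NA_real_, nt, ov$ny, dimnames = list(NULL, ov$names))
  for (k in seq_len(ov$ny)) {
    v <- eval(ov$exprs[[k]], vals, baseenv())
    out[, k] <- if (length(v) == 1L) rep(v, nt) else v
  }
  out
}

#' Simulate a model together with its forward parametric sensitivities
#'
#' Integrates the forward sensitivity system
#' \eqn{dS/dt = (\partial f/\partial x) S + \partial f/\partial \theta},
#' \eqn{S(t_0) = 0}, jointly with the states, using the Jacobians derived
#' symbolically when the model was built. Observable sensitivities follow by
#' the chain rule
#' \eqn{dy/d\theta = (\partial g/\partial x) S + \partial g/\partial \theta}.
#'
#' @inheritParams simulateModel
#' @return list with elements `traj` (an `oscifit_traj`), `dx_dtheta`
#'   (`Nt x Nx x Ntheta` array) and `dy_dtheta` (`Nt x Ny x Ntheta` array).
#' @export
simulateSens <- function(model, theta, x0 = model$x0, times,
                         variant = "fitting", rtol = 1e-8, atol = 1e-10) {
  theta <- as_named_vec(theta, model$params, "theta")
  x0 <- as_named_vec(x0, model$states, "x0")
  nx <- length(model$states); np <- length(model$params)
  ov <- model$compiled$obs[[variant]]
  if (is.null(ov)) stop("unknown observation variant: ", variant)
  ny <- ov$ny

  plist <- as.list(theta)
  cmp <- model$compiled
  snames <- model$states

  if (length(times) == 1L) {
    states <- matrix(x0, 1L, dimnames = list(NULL, snames))
    dx <- array(0, c(1L, nx, np))
    return(list(traj = new_traj(times, states,
                                obs_matrix(model, variant, states, theta,
                                           times), TRUE, 0),
                dx_dtheta = dx,
                dy_dtheta = obs_sens(model, variant, states, theta, times, dx)))
  }

  derivs <- function(t, y, p) {
    x <- y[seq_len(nx)]
    vals <- c(as.list(x), plist)
    names(vals)[seq_len(nx)] <- snames
    vals$t <- t
    fx <- eval(cmp$rhs_call, vals, baseenv())
    A <- matrix(eval(cmp$dfdx_call, vals, baseenv()), nx, nx)
    B <- matrix(eval(cmp$dfdp_call, vals, baseenv()), nx, np)
    S <- matrix(y[-seq_len(nx)], nx, np)
    list(c(fx, A %*% S + B))
  }
  y0 <- c(x0, rep(0, nx * np))
  out <- quiet_lsoda(y0, times, derivs, rtol, atol)
  if (inherits(out, "try-error") || !is.matrix(out) ||
      nrow(out) < length(times) || any(!is.finite(out)))
    return(list(traj = new_traj(times, NULL, NULL, FALSE, 1),
                dx_dtheta = NULL, dy_dtheta = NULL))

  states <- out[, 1L + seq_len(nx), drop = FALSE]
  colnames(states) <- snames
  nt <- length(times)
  dx <- array(out[, -(1:(1 + nx)), drop = FALSE], c(nt, nx, np))
  list(traj = new_traj(times, states,
                       obs_matrix(model, variant, states, theta, times),
                       TRUE, 0),
       dx_dtheta = dx,
       dy_dtheta = obs_sens(model, variant, states, theta, times, dx))
}

obs_sens <- function(model, variant, states, theta, times, dx) {
  ov <- model$compiled$obs[[variant]]
  nx <- length(model$states); np <- length(model$params)
  ny <- ov$ny; nt <- nrow(states)
  dy <- array(0, c(nt, ny, np))
  for (i in seq_len(nt)) {
    vals <- eval_env(stats::setNames(states[i, ], model$states), theta,
                     times[i])
    dgdx <- matrix(eval(ov$dgdx_call, vals, baseenv()), ny, nx)
    dgdp <- matrix(eval(ov$dgdp_call, vals, baseenv()), ny, np)
    dy[i, , ] <- dgdx %*% matrix(dx[i, , ], nx, np) + dgdp
  }
  dy
}

#' Classify the long-run dynamics of a model as sustained, damped or steady
#'
#' Simulates over a long horizon, discards the first half as transient, and
#' inspects the peaks of one state in the remaining window. The trajectory is
#' classified `"sustained"` when at least 3 peaks remain and the last
#' peak-to-trough amplitude is at least 95% of the first; `"steady"` when the
#' residual amplitude is below 1e-6 of the signal scale; otherwise
#' `"damped"`. This is a pragmatic operational proxy for membership of the
#' set of sustained (limit-cycle) dynamics; it is deliberately conservative
#' near bifurcation boundaries, where slowly decaying transients are labelled
#' damped.
#'
#' @inheritParams simulateModel
#' @param horizon simulation end time; the default (`NULL`) uses 10 times the
#'   model's default horizon so that the window covers many putative periods.
#' @param state index (or name) of the state to analyse.
#' @param npoints number of grid points for the dense evaluation.
#' @return list with `classification` (`"sustained"`, `"damped"`, `"steady"`
#'   or `"infeasible"`) and `period` (mean peak-to-peak spacing, `NA` when
#'   fewer than two peaks survive).
#' @export
detectOscillations <- function(model, theta, x0 = model$x0, horizon = NULL,
                               state = 1L, npoints = 4000,
                               rtol = 1e-8, atol = 1e-10) {
  if (is.null(horizon)) horizon <- 10 * model$horizon
  times <- seq(0, horizon, length.out = npoints)
  traj <- simulateModel(model, theta, x0, times, rtol = rtol, atol = atol)
  if (!traj$feasible)
    return(list(classification = "infeasible", period = NA_real_))
  if (is.character(state)) state <- match(state, model$states)
  series <- traj$states[, state]

  win <- times > horizon / 2
  w <- series[win]; tw <- times[win]
  scale <- max(abs(series), 1e-12)
  if (max(w) - min(w) < 1e-6 * scale)
    return(list(classification = "steady", period = NA_real_))

  d <- diff(w)
  pk <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  tr <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  period <- if (length(pk) >= 2) mean(diff(tw[pk])) else NA_real_
  if (length(pk) >= 3 && length(tr) >= 3) {
    amp_first <- w[pk[1]] - w[tr[1]]
    amp_last <- w[pk[length(pk)]] - w[tr[length(tr)]]
    if (amp_first > 0 && amp_last / amp_first >= 0.95)
      return(list(classification = "sustained", period = period))
  }
  list(classification = "damped", period = period)
}
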