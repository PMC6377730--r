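# Residuals and analytic residual Jacobian for a dataset, as closures over
# (model, data). The Jacobian rows are dy/dtheta at each measurement point
# divided by sigma, i.e. the J of FIM = J^T J. Both functions return NULL
# components when integration fails.
model_resid_jac <- function(model, data, rtol = 1e-8, atol = 1e-10) {
  check_data_model(model, data)
  n <- nrow(data$table)
  np <- length(model$params)
  resid <- function(theta) {
    q <- nlsCost(model, theta, data, rtol, atol)
    if (is.null(q$residuals)) return(NULL)
    q$residuals
  }
  jac <- function(theta) {
    J <- matrix(NA_real_, n, np, dimnames = list(NULL, model$params))
    for (ex in names(data$x0)) {
      rows <- which(data$table$experiment == ex)
      tab <- data$table[rows, , drop = FALSE]
      tt <- sort(unique(c(0, tab$time)))
      sens <- simulateSens(model, theta, x0 = data$x0[[ex]], times = tt,
                           variant = data$variant, rtol = rtol, atol = atol)
      if (!sens$traj$feasible) return(NULL)
      ov <- model$compiled$obs[[data$variant]]
      ti <- match(tab$time, tt)
      oi <- match(tab$observable, ov$names)
      for (j in seq_len(np)) {
        slice <- matrix(sens$dy_dtheta[, , j], length(tt), ov$ny)
        J[rows, j] <- slice[cbind(ti, oi)] / tab$sigma
      }
    }
    J
  }
  list(resid = resid, jac = jac, n = n)
}

#' Post-fit statistics from the Fisher information matrix
#'
#' Computes, at a parameter estimate, the quantities usually reported after
#' a weighted least-squares calibration: NRMSE, per-observable R-squared, a
#' chi-squared test on the weighted residual sum, and FIM-based uncertainty
#' measures. The FIM is \eqn{J^T \Sigma^{-1} J} with J the observable
#' sensitivities at the measurement points; its (pseudo-)inverse
#' approximates the estimator covariance, from which 95% confidence
#' half-widths, coefficients of variation and the parameter correlation
#' matrix follow. A singular FIM is inverted by an eigenvalue-thresholded
#' pseudo-inverse with a warning, since near-singularity signals local
#' non-identifiability rather than a numerical accident.
#'
#' @inheritParams nlsCost
#' @param ci_quantile `"normal"` uses 1.96 for the 95% interval; `"t"` uses
#'   the t quantile with `n - N_theta` degrees of freedom.
#' @param chi2_dof degrees of freedom convention for the chi-squared test:
#'   `"n-p"` (default) or `"n"`.
#' @return An object of class `oscifit_fitstats`: list with `nrmse`,
#'   `r_squared` (per observable), `chi2_stat`, `chi2_dof`, `chi2_pvalue`,
#'   `fim`, `covariance`, `ci95`, `cv_percent`, `correlation`,
#'   `bounds_status` and `q_nls`.
#' @export
fitStatistics <- function(model, theta, data, rtol = 1e-8, atol = 1e-10,
                          ci_quantile = c("normal", "t"),
                          chi2_dof = c("n-p", "n")) {
  ci_quantile <- match.arg(ci_quantile)
  chi2_dof <- match.arg(chi2_dof)
  theta <- as_named_vec(theta, model$params, "theta")
  np <- length(model$params)
  n <- nrow(data$table)

  rj <- model_resid_jac(model, data, rtol, atol)
  J <- rj$jac(theta)
  if (is.null(J)) stop("cannot compute sensitivities: simulation infeasible ",
                       "at the supplied estimate")

  fim <- crossprod(J)
  eg <- eigen(fim, symmetric = TRUE)
  thresh <- 1e-12 * max(eg$values, 0)
  keep <- eg$values > thresh
  if (!all(keep))
    warning("FIM is singular to tolerance: parameters locally ",
            "non-identifiable; using pseudo-inverse")
  inv_vals <- ifelse(keep, 1 / eg$values, 0)
  covariance <- eg$vectors %*% (inv_vals * t(eg$vectors))
  dimnames(covariance) <- dimnames(fim)

  sd_par <- sqrt(pmax(diag(covariance), 0))
  qn <- if (ci_quantile == "normal") 1.96 else stats::qt(0.975, max(n - np, 1))
  ci95 <- qn * sd_par
  cv_percent <- 100 * sd_par / abs(theta)
  denom <- outer(sd_par, sd_par)
  correlation <- covariance / ifelse(denom > 0, denom, NA_real_)
  diag(correlation) <- 1

  # goodness of fit
  y <- numeric(n)
  for (ex in names(data$x0)) {
    sim <- simulate_for_data(model, theta, data, ex, rtol, atol)
    if (!sim$ok) stop("simulation infeasible at the supplied estimate")
    y[sim$rows] <- sim$y
  }
  tab <- data$table
  r <- (y - tab$value) / tab$sigma
  q_nls <- sum(r * r)
  dof <- if (chi2_dof == "n-p") n - np else n
  if (dof > 0) {
    chi2_pvalue <- stats::pchisq(q_nls, dof, lower.tail = FALSE)
  } else {
    warning("chi-squared test skipped: non-positive degrees of freedom")
    chi2_pvalue <- NA_real_
  }
  r_squared <- vapply(split(seq_len(n), tab$observable), function(idx) {
    ss_res <- sum((y[idx] - tab$value[idx])^2)
    ss_tot <- sum((tab$value[idx] - mean(tab$value[idx]))^2)
    if (ss_tot == 0) return(NA_real_)
    1 - ss_res / ss_tot
  }, numeric(1))

  bounds_status <- mapply(function(th, lo, hi, sc) {
    pos <- if (sc == "log10") {
      (log10(th) - log10(lo)) / (log10(hi) - log10(lo))
    } else {
      (th - lo) / (hi - lo)
    }
    if (pos <= 0.001) "Active at lower bound"
    else if (pos >= 0.999) "Active at upper bound"
    else "Bounds not active"
  }, theta, model$lower, model$upper, model$scale)

  structure(list(
    theta = theta, nrmse = nrmse(y, data), r_squared = r_squared,
    chi2_stat = q_nls, chi2_dof = if (dof > 0) dof else NA_integer_,
    chi2_pvalue = chi2_pvalue, fim = fim, covariance = covariance,
    ci95 = ci95, cv_percent = cv_percent, correlation = correlation,
    bounds_status = bounds_status, q_nls = q_nls, n = n),
    class = "oscifit_fitstats")
}

#' @export
print.oscifit_fitstats <- function(x, ...) {
  cat("<oscifit_fitstats>\n")
  cat(sprintf("  NRMSE %.4f | Q_NLS %.4g | chi2 p = %.3g (dof %s)\n",
              x$nrmse, x$q_nls, x$chi2_pvalue, x$chi2_dof))
  tab <- data.frame(estimate = signif(x$theta, 5),
                    ci95 = signif(x$ci95, 4),
                    cv_percent = signif(x$cv_percent, 4),
                    bounds = x$bounds_status)
  print(tab)
  invisible(x)
}
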