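#' Automatic tuning of the Tikhonov weight and reference parameter
#'
#' Derives the regularisation setting for the second estimation phase from
#' the phase-1 sampling archive:
#'
#' * the reference \eqn{\theta^{ref}_j} is the consensus of the good-fit
#'   region — the geometric mean (arithmetic for linear-scale parameters) of
#'   parameter j over its accepted set \eqn{S_j = \{i : \zeta_i \le
#'   \zeta^*_j\}} — clipped into the reduced bounds so the two phase-2
#'   constraints cannot conflict. Anchoring to the consensus rather than to
#'   the (possibly overfitted) phase-1 optimum is the default; set
#'   `theta_ref_mode = "phase1_optimum"` to anchor at \eqn{\hat\theta^I}.
#' * the weight \eqn{\alpha} makes the penalty at the edge of the acceptable
#'   region commensurate with the acceptable cost degradation:
#'   \eqn{\alpha = median_j(\zeta^*_j - \zeta_{best}) / \Gamma_{max}}, where
#'   \eqn{\Gamma_{max}} is the largest penalty over the union of accepted
#'   samples. When the accepted samples all coincide with the reference
#'   (\eqn{\Gamma_{max} < 10^{-12}}) no regularisation is needed and
#'   \eqn{\alpha = 0}.
#'
#' Because the penalty is normalised by \eqn{\theta^{ref}} (see
#' [regPenalty()]), the tuned \eqn{\alpha} is invariant under per-parameter
#' rescaling of units.
#'
#' @param archive an `oscifit_archive` from phase 1.
#' @param cutoffs an `oscifit_cutoffs` for this archive.
#' @param reduced an `oscifit_bounds` (reduced box).
#' @param theta_best the phase-1 estimate \eqn{\hat\theta^I}.
#' @param theta_ref_mode `"consensus"` (default) or `"phase1_optimum"`.
#' @return An object of class `oscifit_regularisation`: list with `alpha`,
#'   `theta_ref` and `gamma_max`.
#' @export
tuneRegularisation <- function(archive, cutoffs, reduced, theta_best,
                               theta_ref_mode = c("consensus",
                                                  "phase1_optimum")) {
  theta_ref_mode <- match.arg(theta_ref_mode)
  theta <- archive$theta
  cost <- archive$cost
  np <- ncol(theta)
  pnames <- colnames(theta)

  accepted <- lapply(seq_len(np), function(j)
    which(cost <= cutoffs$cutoff[j]))
  if (any(!lengths(accepted))) stop("empty accepted set")

  theta_ref <- if (theta_ref_mode == "phase1_optimum") {
    as_named_vec(theta_best, pnames, "theta_best")
  } else {
    vapply(seq_len(np), function(j) {
      v <- theta[accepted[[j]], j]
      if (all(v > 0)) exp(mean(log(v))) else mean(v)
    }, numeric(1))
  }
  names(theta_ref) <- pnames

  # keep the reference consistent with the reduced box
  theta_ref <- pmin(pmax(theta_ref, reduced$lower), reduced$upper)
  for (j in seq_len(np)) {
    if (theta_ref[j] == 0) {
      shift <- if (reduced$upper[j] > 0) {
        min(reduced$upper[j] * 1e-3, reduced$upper[j])
      } else reduced$lower[j] * 1e-3
      warning("theta_ref for '", pnames[j], "' is zero after clipping; ",
              "shifted to an interior point")
      theta_ref[j] <- shift
    }
  }

  union_acc <- unique(unlist(accepted))
  gamma_max <- max(apply(theta[union_acc, , drop = FALSE], 1L,
                         regPenalty, theta_ref = theta_ref))
  gap <- stats::median(cutoffs$cutoff - cutoffs$min_cost)
  if (gap < 0) stop("internal error: negative median cost gap")
  alpha <- if (gamma_max < 1e-12) 0 else gap / gamma_max

  structure(list(alpha = alpha, theta_ref = theta_ref,
                 gamma_max = gamma_max, mode = theta_ref_mode),
            class = "oscifit_regularisation")
}

#' @export
print.oscifit_regularisation <- function(x, ...) {
  cat(sprintf("<oscifit_regularisation> alpha = %.5g (mode %s)\n",
              x$alpha, x$mode))
  cat("  theta_ref:", paste(sprintf("%s=%.4g", names(x$theta_ref),
                                    x$theta_ref), collapse = ", "), "\n")
  invisible(x)
}
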