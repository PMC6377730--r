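#' Per-parameter cost cut-offs from a sampling archive
#'
#' For each parameter the archive is scanned in order of increasing cost and
#' the spread of the parameter (range in its search scale) over all points at
#' or below each candidate cost is computed. The spread-versus-log10(cost)
#' curve is flat while only the good-fit basin is included and blows up
#' towards the full box once clearly suboptimal samples are admitted; the
#' cut-off is placed at the knee of that curve — the candidate maximising the
#' perpendicular distance below the chord joining the curve's endpoints —
#' i.e. the largest cost before the spread explodes. Ties break towards the
#' smaller cost (conservative acceptance). Evaluations that hit the
#' infeasible-simulation penalty carry no information about the good-fit
#' region and are excluded from the candidate set.
#'
#' With fewer than `min_points` informative points, or when the costs span
#' less than one decade, the knee is unreliable and the rule falls back to
#' the cost at the 25th percentile for every parameter, with a warning.
#'
#' @param archive an `oscifit_archive` (from [essMinimize()]).
#' @param scale per-parameter search scale used to measure the spread
#'   (`"log10"` spreads are measured in decades). Defaults to log10 where
#'   the archived values are all positive and span more than two decades.
#' @param min_points minimum number of informative archive points for the
#'   knee rule.
#' @return An object of class `oscifit_cutoffs`: list with `cutoff` (named
#'   vector \eqn{\zeta^*_j}), `n_accepted` (points at or below each
#'   cut-off), and `method` (`"knee"` or `"percentile"`).
#' @export
costCutoffs <- function(archive, scale = NULL, min_points = 50) {
  theta <- archive$theta
  cost <- archive$cost
  np <- ncol(theta)
  pnames <- colnames(theta)
  ok <- is.finite(cost) & cost < 1e9    # drop penalty evaluations
  if (!any(ok)) stop("archive contains no informative evaluations")
  theta <- theta[ok, , drop = FALSE]
  cost <- cost[ok]
  if (is.null(scale))
    scale <- apply(theta, 2L, function(v)
      if (all(v > 0) && log10(max(v) / min(v)) > 2) "log10" else "linear")

  zmin <- min(cost)
  decades <- log10(max(cost) / max(zmin, .Machine$double.xmin))

  fallback <- function(reason) {
    warning("cost cut-offs fall back to the 25th cost percentile (",
            reason, ")")
    cut <- rep(stats::quantile(cost, 0.25, names = FALSE), np)
    names(cut) <- pnames
    new_cutoffs(cut, cost, "percentile")
  }
  if (length(cost) < min_points)
    return(fallback("fewer than min_points informative points"))
  if (!is.finite(decades) || decades <= 1)
    return(fallback("costs span no more than one decade"))

  ord <- order(cost)
  cs <- cost[ord]
  cut <- numeric(np)
  for (j in seq_len(np)) {
    v <- theta[ord, j]
    v <- if (scale[j] == "log10") log10(v) else v
    spread <- cummax(v) - cummin(v)
    # one candidate per unique cost: the spread at its last occurrence
    last <- !duplicated(cs, fromLast = TRUE)
    cand <- cs[last]
    x <- log10(cand)
    y <- spread[last]
    m <- length(x)
    if (m < 2) { cut[j] <- cs[1]; next }
    slope <- (y[m] - y[1]) / (x[m] - x[1])
    chord <- y[1] + slope * (x - x[1])
    dist <- (chord - y) / sqrt(1 + slope^2)   # positive below the chord
    k <- which.max(dist)                       # which.max takes first tie
    cut[j] <- cand[k]
  }
  names(cut) <- pnames
  new_cutoffs(cut, cost, "knee")
}

new_cutoffs <- function(cut, cost, method) {
  structure(list(cutoff = cut,
                 n_accepted = vapply(cut, function(z) sum(cost <= z),
                                     integer(1)),
                 min_cost = min(cost), method = method),
            class = "oscifit_cutoffs")
}

#' @export
print.oscifit_cutoffs <- function(x, ...) {
  cat(sprintf("<oscifit_cutoffs> (%s rule)\n", x$method))
  print(data.frame(cutoff = signif(x$cutoff, 5), accepted = x$n_accepted))
  invisible(x)
}

#' Reduce the parameter search box from the accepted archive samples
#'
#' For each parameter the hull of its values over the accepted set
#' \eqn{S_j = \{i : \zeta_i \le \zeta^*_j\}} is expanded by 10% of the hull
#' width on each side (measured in the parameter's search scale) and, for
#' log10-scaled parameters, snapped outward to the nearest integer powers of
#' ten (`snap_powers = FALSE` keeps the continuous bounds). The result is
#' intersected with the original box — the reduced box is never wider — and
#' minimally enlarged where needed so that the phase-1 estimate stays
#' strictly inside it.
#'
#' @param archive an `oscifit_archive`.
#' @param cutoffs an `oscifit_cutoffs` for this archive.
#' @param lower,upper the original bounds.
#' @param theta_best the phase-1 estimate \eqn{\hat\theta^I}.
#' @param scale per-parameter search scale (defaults as in [costCutoffs()]).
#' @param snap_powers snap log10-scaled bounds outward to powers of ten.
#' @return An object of class `oscifit_bounds`: list with `lower`, `upper`
#'   and the per-parameter accepted-sample counts.
#' @export
reduceBounds <- function(archive, cutoffs, lower, upper, theta_best,
                         scale = NULL, snap_powers = TRUE) {
  theta <- archive$theta
  cost <- archive$cost
  np <- ncol(theta)
  pnames <- colnames(theta)
  if (is.null(scale))
    scale <- ifelse(lower > 0 & upper / lower > 100, "log10", "linear")

  rlo <- lower; rup <- upper
  for (j in seq_len(np)) {
    acc <- which(cost <= cutoffs$cutoff[j])
    if (!length(acc)) {
      warning("empty accepted set for parameter '", pnames[j],
              "'; keeping its original bounds")
      next
    }
    v <- theta[acc, j]
    if (scale[j] == "log10") {
      lo <- log10(min(v)); hi <- log10(max(v))
      w <- hi - lo
      lo <- lo - 0.1 * w; hi <- hi + 0.1 * w
      if (snap_powers) { lo <- floor(lo); hi <- ceiling(hi) }
      lo <- 10^lo; hi <- 10^hi
    } else {
      lo <- min(v); hi <- max(v)
      w <- hi - lo
      lo <- lo - 0.1 * w; hi <- hi + 0.1 * w
    }
    # never wider than the original box
    lo <- max(lo, lower[j]); hi <- min(hi, upper[j])
    # the phase-1 estimate must stay interior (or on an original bound)
    tb <- theta_best[j]
    while (tb <= lo && lo > lower[j])
      lo <- if (scale[j] == "log10") max(lo / 10, lower[j]) else
        max(lo - max(w, abs(tb)) * 0.5, lower[j])
    while (tb >= hi && hi < upper[j])
      hi <- if (scale[j] == "log10") min(hi * 10, upper[j]) else
        min(hi + max(w, abs(tb)) * 0.5, upper[j])
    rlo[j] <- lo; rup[j] <- hi
  }
  structure(list(lower = rlo, upper = rup,
                 n_accepted = cutoffs$n_accepted, scale = scale),
            class = "oscifit_bounds")
}

#' @export
print.oscifit_bounds <- function(x, ...) {
  cat("<oscifit_bounds>\n")
  print(data.frame(lower = signif(x$lower, 5), upper = signif(x$upper, 5)))
  invisible(x)
}
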