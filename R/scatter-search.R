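#' Latin hypercube sample inside a box
#'
#' Stratified sample: for each coordinate the n draws fall one per stratum of
#' an equal-width partition of the interval. Sampling happens in the scale
#' the caller supplies the bounds in (the optimiser passes search-scale
#' bounds, i.e. log10 for wide-bounded positive parameters).
#'
#' @param lower,upper finite numeric bounds.
#' @param n number of points (rows).
#' @param seed optional integer seed for reproducibility.
#' @return `n x length(lower)` matrix of points inside the box.
#' @export
latinHypercube <- function(lower, upper, n, seed = NULL) {
  if (!all(is.finite(lower)) || !all(is.finite(upper)))
    stop("latinHypercube requires finite bounds")
  stopifnot(n >= 1, length(lower) == length(upper), all(lower < upper))
  if (!is.null(seed)) set.seed(seed)
  u <- lhs::randomLHS(n, length(lower))
  sweep(sweep(u, 2L, upper - lower, "*"), 2L, lower, "+")
}

#' Control settings for the enhanced scatter search
#'
#' @param max_evals total objective-evaluation budget (archive length).
#' @param refset_size size of the reference set (default
#'   `max(2*ceiling(sqrt(n_par)) + 2, 8)`, filled in at run time when `NULL`).
#' @param diverse_size size of the initial diversification set (default
#'   `max(10*n_par, 100)`, capped at half the budget).
#' @param local_enabled run gradient-based local refinements.
#' @param local_freq run a local search every this many combination rounds.
#' @param local_maxit iteration cap for each local search.
#' @param local_min_dist minimum normalised distance between local-search
#'   start points, to avoid re-polishing the same basin.
#' @param go_beyond continue along improving directions after a successful
#'   combination.
#' @param stagnation_iters rounds without improvement of the best cost
#'   before the non-best reference-set members are re-diversified.
#' @param cost_target value-to-reach: the search stops early once the best
#'   cost is at or below this (default `-Inf`, i.e. run the full budget).
#' @param seed integer seed; the full run is reproducible given it.
#' @return list of class `oscifit_ess_control`.
#' @export
essControl <- function(max_evals = 5000, refset_size = NULL,
                       diverse_size = NULL, local_enabled = TRUE,
                       local_freq = 5, local_maxit = 40,
                       local_min_dist = 0.02, go_beyond = TRUE,
                       stagnation_iters = 20, cost_target = -Inf,
                       seed = NULL) {
  ctl <- list(max_evals = max_evals, refset_size = refset_size,
              diverse_size = diverse_size, local_enabled = local_enabled,
              local_freq = local_freq, local_maxit = local_maxit,
              local_min_dist = local_min_dist, go_beyond = go_beyond,
              stagnation_iters = stagnation_iters,
              cost_target = cost_target, seed = seed)
  class(ctl) <- "oscifit_ess_control"
  ctl
}

new_archive <- function(np, pnames) {
  env <- new.env(parent = emptyenv())
  env$theta <- matrix(NA_real_, 256L, np, dimnames = list(NULL, pnames))
  env$cost <- rep(NA_real_, 256L)
  env$n <- 0L
  env
}

archive_push <- function(env, theta, cost) {
  n <- env$n + 1L
  if (n > nrow(env$theta)) {
    env$theta <- rbind(env$theta, matrix(NA_real_, nrow(env$theta),
                                         ncol(env$theta)))
    env$cost <- c(env$cost, rep(NA_real_, length(env$cost)))
  }
  env$theta[n, ] <- theta
  env$cost[n] <- cost
  env$n <- n
}

archive_finalise <- function(env) {
  theta <- env$theta[seq_len(env$n), , drop = FALSE]
  cost <- env$cost[seq_len(env$n)]
  structure(list(theta = theta, cost = cost,
                 best_index = if (env$n) which.min(cost) else NA_integer_),
            class = "oscifit_archive")
}

#' @export
print.oscifit_archive <- function(x, ...) {
  cat(sprintf("<oscifit_archive> %d evaluations, best cost %.6g\n",
              length(x$cost), min(x$cost)))
  invisible(x)
}

#' Write a sampling archive to CSV
#'
#' Columns `eval_index,cost,theta_<name>...`, one row per objective
#' evaluation in evaluation order.
#' @param archive an `oscifit_archive`.
#' @param file CSV path.
#' @export
writeArchive <- function(archive, file) {
  df <- data.frame(eval_index = seq_along(archive$cost),
                   cost = archive$cost)
  th <- as.data.frame(archive$theta)
  names(th) <- paste0("theta_", colnames(archive$theta))
  utils::write.csv(cbind(df, th), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

# search-scale transforms
to_search <- function(theta, scale) ifelse(scale == "log10", log10(theta), theta)
from_search <- function(z, scale) ifelse(scale == "log10", 10^z, z)

#' Bounded gradient-based local refinement of a least-squares objective
#'
#' Runs a trust-region (Levenberg-Marquardt class) nonlinear least-squares
#' descent from `theta0`, staying inside the box, using the analytic residual
#' Jacobian when one is supplied (the package derives it from forward
#' sensitivities). When no residual structure is available it falls back to a
#' bounded quasi-Newton descent on the scalar cost. The search operates in
#' search scale (log10 for wide-bounded parameters); every cost evaluation is
#' reported to `record` so callers can archive the iterates. The returned
#' cost never exceeds the cost at `theta0`.
#'
#' @param objective function `theta -> cost` (used for the fallback and for
#'   bookkeeping).
#' @param theta0 start point (inside the bounds, natural scale).
#' @param lower,upper bounds (natural scale).
#' @param scale per-parameter `"log10"`/`"linear"` search scale.
#' @param resid optional function `theta -> residual vector` (NULL on
#'   integration failure).
#' @param jac optional function `theta -> Jacobian of residuals` (NULL on
#'   failure).
#' @param maxit iteration cap.
#' @param record callback `function(theta, cost)` invoked at every cost
#'   evaluation.
#' @return list with `theta`, `cost` and `evals`.
#' @export
localRefine <- function(objective, theta0, lower, upper,
                        scale = rep("linear", length(theta0)),
                        resid = NULL, jac = NULL, maxit = 40,
                        record = function(theta, cost) NULL) {
  np <- length(theta0)
  z0 <- to_search(theta0, scale)
  lz <- to_search(lower, scale); uz <- to_search(upper, scale)
  best <- list(theta = theta0, cost = Inf)
  evals <- 0L

  note <- function(theta, cost) {
    record(theta, cost)
    evals <<- evals + 1L
    if (cost < best$cost) best <<- list(theta = theta, cost = cost)
  }

  if (!is.null(resid)) {
    r0 <- resid(theta0)
    nres <- if (is.null(r0)) 1L else length(r0)
    note(theta0, if (is.null(r0)) PENALTY_COST else sum(r0 * r0))
    fn <- function(z) {
      theta <- from_search(z, scale)
      r <- resid(theta)
      if (is.null(r)) {
        note(theta, PENALTY_COST)
        return(rep(sqrt(PENALTY_COST / nres), nres))
      }
      note(theta, sum(r * r))
      r
    }
    jfn <- if (!is.null(jac)) {
      function(z) {
        theta <- from_search(z, scale)
        J <- jac(theta)
        if (is.null(J)) return(matrix(0, nres, np))
        # chain rule to search scale: dtheta/dz = theta*ln10 on log10 axes
        dthdz <- ifelse(scale == "log10", theta * log(10), 1)
        sweep(J, 2L, dthdz, "*")
      }
    } else NULL
    fit <- try(suppressWarnings(minpack.lm::nls.lm(
      par = z0, lower = lz, upper = uz, fn = fn, jac = jfn,
      control = minpack.lm::nls.lm.control(maxiter = maxit))),
      silent = TRUE)
    if (inherits(fit, "try-error") && !is.null(jfn)) {
      warning("Jacobian-based refinement failed; falling back to ",
              "gradient-free descent")
      fit <- try(suppressWarnings(minpack.lm::nls.lm(
        par = z0, lower = lz, upper = uz, fn = fn,
        control = minpack.lm::nls.lm.control(maxiter = maxit))),
        silent = TRUE)
    }
  } else {
    note(theta0, objective(theta0))
    fz <- function(z) {
      theta <- from_search(z, scale)
      cost <- objective(theta)
      note(theta, cost)
      cost
    }
    try(suppressWarnings(stats::optim(
      z0, fz, method = "L-BFGS-B", lower = lz, upper = uz,
      control = list(maxit = maxit))), silent = TRUE)
  }
  list(theta = best$theta, cost = best$cost, evals = evals)
}

#' Enhanced scatter search global minimisation
#'
#' Hybrid metaheuristic over a box: a Latin-hypercube diversification set
#' seeds a reference set of high-quality and maximally diverse members;
#' members are pairwise combined inside biased hyper-rectangles (in search
#' scale), improving offspring replace their parents, a "go-beyond" rule
#' keeps stepping along improving directions, periodic gradient-based local
#' searches intensify around promising unexplored basins, and the non-best
#' members are re-diversified on stagnation. Every objective evaluation —
#' including those made inside local searches — is appended to the sampling
#' archive, which downstream bound-reduction and regularisation-tuning
#' steps consume. The run is reproducible given `control$seed`.
#'
#' @param objective function `theta -> cost` (natural scale). Infeasible
#'   points must be returned as large finite penalties, not errors.
#' @param lower,upper finite bounds (natural scale).
#' @param control an [essControl()] list.
#' @param scale per-parameter search scale; default log10 where positive
#'   bounds span more than two decades.
#' @param resid,jac optional residual function and Jacobian for the local
#'   solver (see [localRefine()]).
#' @return list with `theta` (best point ever evaluated), `cost`, `archive`
#'   (class `oscifit_archive`), `n_evals`, `n_local` and the `control` echo.
#' @export
essMinimize <- function(objective, lower, upper, control = essControl(),
                        scale = NULL, resid = NULL, jac = NULL) {
  np <- length(lower)
  stopifnot(length(upper) == np, all(is.finite(lower)), all(is.finite(upper)))
  pnames <- names(lower)
  if (is.null(pnames)) pnames <- paste0("p", seq_len(np))
  if (is.null(scale))
    scale <- ifelse(lower > 0 & upper / lower > 100, "log10", "linear")

  if (is.null(control$refset_size))
    control$refset_size <- max(2L * ceiling(sqrt(np)) + 2L, 8L)
  if (is.null(control$diverse_size))
    control$diverse_size <- max(10L * np, 100L)
  control$diverse_size <- min(control$diverse_size,
                              max(control$refset_size,
                                  floor(control$max_evals / 2)))
  if (control$max_evals <= control$diverse_size)
    stop("max_evals must exceed the diversification set size")
  if (!is.null(control$seed)) set.seed(control$seed)

  lz <- to_search(lower, scale); uz <- to_search(upper, scale)
  span <- uz - lz
  arch <- new_archive(np, pnames)
  n_local <- 0L

  best_cost_seen <- Inf
  evalz <- function(z) {
    theta <- stats::setNames(from_search(z, scale), pnames)
    cost <- objective(theta)
    archive_push(arch, theta, cost)
    if (cost < best_cost_seen) best_cost_seen <<- cost
    cost
  }
  budget_left <- function()
    arch$n < control$max_evals && best_cost_seen > control$cost_target

  # --- diversification ---------------------------------------------------
  Z <- latinHypercube(lz, uz, control$diverse_size)
  cost <- apply(Z, 1L, evalz)
  if (all(cost >= PENALTY_COST))
    stop("no feasible point found")

  # --- reference set: best half + maximally diverse half ------------------
  b <- control$refset_size
  h1 <- ceiling(b / 2)
  ord <- order(cost)
  ref_idx <- ord[seq_len(min(h1, length(ord)))]
  rest <- setdiff(seq_len(nrow(Z)), ref_idx)
  zn <- sweep(Z, 2L, span, "/")
  while (length(ref_idx) < b && length(rest)) {
    dmin <- vapply(rest, function(i) {
      min(sqrt(rowSums((zn[ref_idx, , drop = FALSE] -
                          matrix(zn[i, ], length(ref_idx), np,
                                 byrow = TRUE))^2)))
    }, numeric(1))
    pick <- rest[which.max(dmin)]
    ref_idx <- c(ref_idx, pick)
    rest <- setdiff(rest, pick)
  }
  refZ <- Z[ref_idx, , drop = FALSE]
  refC <- cost[ref_idx]

  local_starts <- matrix(numeric(0), 0L, np)

  run_local <- function(z_start) {
    n_local <<- n_local + 1L
    left <- control$max_evals - arch$n
    res <- localRefine(
      objective, stats::setNames(from_search(z_start, scale), pnames),
      lower, upper, scale = scale, resid = resid, jac = jac,
      maxit = min(control$local_maxit, max(2L, left)),
      record = function(theta, cost) {
        archive_push(arch, theta, cost)
        if (cost < best_cost_seen) best_cost_seen <<- cost
      })
    local_starts <<- rbind(local_starts, z_start / span)
    res
  }

  iter <- 0L
  stag <- 0L
  best_seen <- min(refC)

  while (budget_left()) {
    iter <- iter + 1L
    o <- order(refC)
    refZ <- refZ[o, , drop = FALSE]; refC <- refC[o]

    improved_any <- FALSE
    for (i in seq_len(b)) {
      if (!budget_left()) break
      best_child <- NULL; best_child_cost <- Inf
      for (j in seq_len(b)) {
        if (i == j || !budget_left()) next
        d <- (refZ[j, ] - refZ[i, ]) / 2
        beta <- (abs(j - i) - 1) / (b - 2)
        alpha <- if (i < j) 1 else -1
        c1 <- refZ[i, ] - d * (1 + alpha * beta)
        c2 <- refZ[i, ] + d * (1 - alpha * beta)
        child <- c1 + (c2 - c1) * stats::runif(np)
        child <- pmin(pmax(child, lz), uz)
        cc <- evalz(child)
        if (cc < best_child_cost) {
          best_child <- child; best_child_cost <- cc
        }
      }
      if (!is.null(best_child) && best_child_cost < refC[i]) {
        # go-beyond: keep stepping while the direction keeps paying off
        if (control$go_beyond) {
          step <- best_child - refZ[i, ]
          for (k in seq_len(8L)) {
            if (!budget_left()) break
            cand <- pmin(pmax(best_child + step, lz), uz)
            if (all(cand == best_child)) break
            cc <- evalz(cand)
            if (cc < best_child_cost) {
              best_child <- cand; best_child_cost <- cc
              step <- 2 * step
            } else break
          }
        }
        refZ[i, ] <- best_child; refC[i] <- best_child_cost
        improved_any <- TRUE
      }
    }

    # periodic local intensification from the best unrefined member
    if (control$local_enabled && budget_left() &&
        (iter %% control$local_freq == 1L || control$local_freq == 1L)) {
      for (i in order(refC)) {
        zc <- refZ[i, ] / span
        if (nrow(local_starts) == 0 ||
            min(sqrt(rowSums(sweep(local_starts, 2L, zc)^2))) >
              control$local_min_dist) {
          res <- run_local(refZ[i, ])
          zr <- pmin(pmax(to_search(res$theta, scale), lz), uz)
          worst <- which.max(refC)
          if (res$cost < refC[worst]) {
            refZ[worst, ] <- zr; refC[worst] <- res$cost
          }
          break
        }
      }
    }

    cur_best <- min(refC)
    if (cur_best < best_seen - abs(best_seen) * 1e-10) {
      stag <- 0L
      best_seen <- cur_best
    } else {
      stag <- stag + 1L
    }
    if (stag >= control$stagnation_iters && budget_left()) {
      keep <- which.min(refC)
      n_new <- b - 1L
      Znew <- latinHypercube(lz, uz, n_new)
      cnew <- apply(Znew, 1L, function(z)
        if (budget_left()) evalz(z) else Inf)
      refZ <- rbind(refZ[keep, , drop = FALSE], Znew)
      refC <- c(refC[keep], cnew)
      stag <- 0L
    }
  }

  archive <- archive_finalise(arch)
  bi <- archive$best_index
  list(theta = stats::setNames(archive$theta[bi, ], pnames),
       cost = archive$cost[bi], archive = archive,
       n_evals = length(archive$cost), n_local = n_local,
       control = control, scale = scale)
}
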