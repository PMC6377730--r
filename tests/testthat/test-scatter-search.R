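test_that("latin hypercube stratifies each coordinate", {
  # 1-D on [0,10]: sorted points fall one per unit stratum
  x <- latinHypercube(0, 10, 10, seed = 3)
  expect_true(all(floor(sort(x[, 1])) == 0:9))
  expect_true(all(x >= 0 & x <= 10))
  # single point inside the box
  p <- latinHypercube(c(-1, 5), c(1, 6), 1, seed = 1)
  expect_true(all(p >= c(-1, 5) & p <= c(1, 6)))
  # reproducible
  expect_identical(latinHypercube(c(0, 0), c(1, 1), 25, seed = 9),
                   latinHypercube(c(0, 0), c(1, 1), 25, seed = 9))
  expect_error(latinHypercube(0, Inf, 5), "finite")
})

test_that("local refinement solves linear and Rosenbrock least squares", {
  # linear least squares r = A theta - b: exact optimum
  A <- matrix(c(2, 0, 1, 1, 3, 1), 3, 2)
  b <- c(1, 2, 3)
  resid <- function(th) as.vector(A %*% th - b)
  jac <- function(th) A
  obj <- function(th) sum(resid(th)^2)
  r <- localRefine(obj, c(0, 0), c(-10, -10), c(10, 10),
                   resid = resid, jac = jac)
  exact <- as.vector(solve(crossprod(A), crossprod(A, b)))
  expect_equal(unname(r$theta), exact, tolerance = 1e-8)

  # start at a stationary point: stays there
  r2 <- localRefine(obj, exact, c(-10, -10), c(10, 10),
                    resid = resid, jac = jac)
  expect_equal(unname(r2$theta), exact, tolerance = 1e-8)

  # Rosenbrock in residual form from the classic start
  rr <- function(th) c(10 * (th[2] - th[1]^2), 1 - th[1])
  jj <- function(th) matrix(c(-20 * th[1], -1, 10, 0), 2, 2)
  oo <- function(th) sum(rr(th)^2)
  r3 <- localRefine(oo, c(-1.2, 1), c(-5, -5), c(5, 5),
                    resid = rr, jac = jj, maxit = 200)
  expect_lt(r3$cost, 1e-10)
  expect_equal(unname(r3$theta), c(1, 1), tolerance = 1e-4)

  # every recorded cost descends to no worse than the start
  costs <- c()
  r4 <- localRefine(oo, c(-1.2, 1), c(-5, -5), c(5, 5), resid = rr,
                    jac = jj, record = function(th, cc) costs <<- c(costs, cc))
  expect_lte(r4$cost, costs[1])
  expect_equal(length(costs), r4$evals)
})

test_that("scatter search finds convex and rugged optima reproducibly", {
  f <- function(th) (th[1] - 2)^2
  r <- essMinimize(f, c(p = 0), c(p = 10), essControl(max_evals = 300,
                                                      seed = 1))
  expect_equal(unname(r$theta), 2, tolerance = 1e-8)
  expect_lt(r$cost, 1e-8)

  # archive completeness and best-so-far monotonicity
  expect_equal(length(r$archive$cost), r$n_evals)
  expect_equal(length(r$archive$cost), 300)
  best_so_far <- cummin(r$archive$cost)
  expect_true(all(diff(best_so_far) <= 0))
  expect_equal(min(r$archive$cost), r$cost)
  # spot-check: archived costs are re-evaluable
  i <- c(1, 150, 300)
  expect_equal(r$archive$cost[i],
               apply(r$archive$theta[i, , drop = FALSE], 1, f))

  # determinism
  ras <- function(th) 20 + sum(th^2 - 10 * cos(2 * pi * th))
  lb <- c(x = -5.12, y = -5.12); ub <- c(x = 5.12, y = 5.12)
  r1 <- essMinimize(ras, lb, ub, essControl(max_evals = 1500, seed = 7))
  r2 <- essMinimize(ras, lb, ub, essControl(max_evals = 1500, seed = 7))
  expect_identical(r1$archive, r2$archive)
  expect_identical(r1$theta, r2$theta)
})

test_that("scatter search locates the Rastrigin global optimum", {
  ras <- function(th) 20 + sum(th^2 - 10 * cos(2 * pi * th))
  lb <- c(x = -5.12, y = -5.12); ub <- c(x = 5.12, y = 5.12)
  ok <- 0
  for (s in 1:10) {
    r <- essMinimize(ras, lb, ub, essControl(max_evals = 20000, seed = s))
    if (r$cost < 1e-6) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("scatter search beats equal-budget multi-start on a rugged 1-D", {
  # >= 5 local minima; global optimum at x = 0 with value 0
  f <- function(th) (th[1] / 10)^2 + 1 - cos(2 * pi * th[1] / 3)
  lb <- c(x = -15); ub <- c(x = 15)
  budget <- 600
  ess_hits <- 0; ms_hits <- 0
  for (s in 1:10) {
    r <- essMinimize(f, lb, ub, essControl(max_evals = budget, seed = s,
                                           local_freq = 2))
    if (r$cost < 1e-4) ess_hits <- ess_hits + 1
    # multi-start of the local solver with the same budget
    set.seed(s)
    used <- 0; best <- Inf
    while (used < budget) {
      th0 <- stats::runif(1, lb, ub)
      lr <- localRefine(f, th0, lb, ub, maxit = 20,
                        record = function(th, cc) used <<- used + 1)
      best <- min(best, lr$cost)
    }
    if (best < 1e-4) ms_hits <- ms_hits + 1
  }
  expect_gte(ess_hits, ms_hits)
  expect_gte(ess_hits, 8)
})

test_that("infeasible-everywhere objectives raise, penalties do not", {
  f_bad <- function(th) 1e10 + 0.5
  expect_error(essMinimize(f_bad, c(p = 0), c(p = 1),
                           essControl(max_evals = 120, seed = 1,
                                      local_enabled = FALSE)),
               "no feasible point")
})
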