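test_that("weighted NLS cost matches hand-computed residuals", {
  m <- decay_model()
  d <- noiseless_data(m, c(k = 1), sigma = 0.1)
  # perfect fit: zero cost
  expect_equal(nlsCost(m, c(k = 1), d)$cost, 0, tolerance = 1e-10)

  # single point y = 1.2 vs measurement 1.0, sigma 0.1 -> ((0.2)/0.1)^2 = 4
  tab <- data.frame(experiment = "e1", observable = "y", time = 0,
                    value = 1.0, sigma = 0.1)
  d1 <- experimentData(tab, c(x = 1.2))
  expect_equal(nlsCost(m, c(k = 1), d1)$cost, 4.0, tolerance = 1e-12)

  # stacked residuals across two experiments equal a brute-force sum
  tab2 <- rbind(
    data.frame(experiment = "e1", observable = "y", time = c(0, 1),
               value = c(0.9, exp(-1) + 0.2), sigma = c(0.1, 0.1)),
    data.frame(experiment = "e2", observable = "y", time = 1,
               value = exp(-0.5) - 0.05, sigma = 0.1))
  d2 <- experimentData(tab2, list(e1 = c(x = 1), e2 = c(x = 0.5)))
  got <- nlsCost(m, c(k = 1), d2)
  manual <- 0
  for (i in seq_len(nrow(tab2))) {
    x0 <- if (tab2$experiment[i] == "e1") 1 else 0.5
    y <- x0 * exp(-tab2$time[i])
    manual <- manual + ((y - tab2$value[i]) / tab2$sigma[i])^2
  }
  expect_equal(got$cost, manual, tolerance = 1e-6)
  expect_equal(sum(got$residuals^2), got$cost)
})

test_that("log-likelihood is the NLS cost in disguise", {
  m <- decay_model()
  d <- noiseless_data(m, c(k = 1), sigma = 1)
  n <- nResiduals(d)
  # perfect fit with unit sigmas
  expect_equal(logLikelihood(m, c(k = 1), d), -(n / 2) * log(2 * pi),
               tolerance = 1e-8)
  # single-point direct evaluation
  tab <- data.frame(experiment = "e1", observable = "y", time = 0,
                    value = 1.0, sigma = 0.1)
  d1 <- experimentData(tab, c(x = 1.2))
  expect_equal(logLikelihood(m, c(k = 1), d1), -2 - log(0.1 * sqrt(2 * pi)),
               tolerance = 1e-10)
  # argmax of logL coincides with argmin of Q_NLS on a grid
  dd <- noiseless_data(m, c(k = 1), sigma = 0.1)
  grid <- seq(0.5, 2, by = 0.1)
  q <- vapply(grid, function(k) nlsCost(m, c(k = k), dd)$cost, numeric(1))
  l <- vapply(grid, function(k) logLikelihood(m, c(k = k), dd), numeric(1))
  expect_equal(which.min(q), which.max(l))
})

test_that("Tikhonov penalty is reference-normalised", {
  expect_equal(regPenalty(c(1, 10), c(1, 10)), 0)
  # theta = 2*ref: every normalised term is 1 -> N_theta
  for (ref in list(c(1, 1), c(0.3, 200), c(5, 1e-4, 7))) {
    expect_equal(regPenalty(2 * ref, ref), length(ref))
  }
  # hand evaluation
  expect_equal(regPenalty(c(1.5, 5), c(1, 10)), 0.5)
  # invariance under joint rescaling of units
  set.seed(1)
  for (i in 1:10) {
    th <- stats::runif(4, 0.1, 10); ref <- stats::runif(4, 0.1, 10)
    cc <- stats::runif(4, 0.01, 100)
    expect_equal(regPenalty(th, ref), regPenalty(cc * th, cc * ref),
                 tolerance = 1e-10)
  }
  expect_error(regPenalty(c(1, 1), c(1, 0)), "zero")
})

test_that("regularised cost composes Q_NLS and the penalty", {
  m <- decay_model()
  d <- noiseless_data(m, c(k = 1), sigma = 0.1)
  set.seed(2)
  for (i in 1:20) {
    k <- stats::runif(1, 0.2, 5)
    q0 <- nlsCost(m, c(k = k), d)$cost
    expect_equal(regCost(m, c(k = k), d, alpha = 0,
                         theta_ref = c(k = 2))$cost, q0)
    expect_equal(regCost(m, c(k = k), d, alpha = 7,
                         theta_ref = c(k = k))$cost, q0)
  }
  # hand-composed case: Q_NLS = 4, Gamma = 0.25, alpha = 10 -> 6.5
  tab <- data.frame(experiment = "e1", observable = "y", time = 0,
                    value = 1.0, sigma = 0.1)
  d1 <- experimentData(tab, c(x = 1.2))
  rc <- regCost(m, c(k = 1), d1, alpha = 10, theta_ref = c(k = 2))
  expect_equal(rc$q_nls, 4)
  expect_equal(rc$penalty, 0.25)
  expect_equal(rc$cost, 4 + 10 * 0.25)
})

test_that("NRMSE normalises by the per-series measured range", {
  m <- decay_model()
  # hand-forced: measurements [0,1], predictions [0.5,1.5] -> 0.5
  tab <- data.frame(experiment = "e1", observable = "y", time = c(0, 1),
                    value = c(0, 1), sigma = 1)
  d <- experimentData(tab, c(x = 1))
  expect_equal(nrmse(c(0.5, 1.5), d), 0.5)
  expect_equal(nrmse(c(0, 1), d), 0)

  # two series of different ranges: brute-force double loop oracle
  tab2 <- rbind(
    data.frame(experiment = "e1", observable = "y", time = 0:3,
               value = c(0, 2, 4, 6), sigma = 1),
    data.frame(experiment = "e2", observable = "y", time = 0:2,
               value = c(10, 30, 50), sigma = 1))
  d2 <- experimentData(tab2, list(e1 = c(x = 1), e2 = c(x = 1)))
  sim <- c(0.5, 2.5, 3.5, 6.5, 12, 29, 49)
  acc <- 0
  for (i in 1:4) acc <- acc + ((sim[i] - tab2$value[i]) / 6)^2
  for (i in 5:7) acc <- acc + ((sim[i] - tab2$value[i]) / 40)^2
  expect_equal(nrmse(sim, d2), sqrt(acc / 7))

  # affine rescaling of a series' units leaves NRMSE unchanged
  tab3 <- tab2
  tab3$value <- tab3$value * 3.7 + 2
  d3 <- experimentData(tab3, list(e1 = c(x = 1), e2 = c(x = 1)))
  expect_equal(nrmse(sim * 3.7 + 2, d3), nrmse(sim, d2), tolerance = 1e-12)

  # constant series excluded with a warning
  tab4 <- rbind(tab2,
                data.frame(experiment = "e3", observable = "y", time = 0:1,
                           value = c(5, 5), sigma = 1))
  d4 <- experimentData(tab4, list(e1 = c(x = 1), e2 = c(x = 1),
                                  e3 = c(x = 1)))
  expect_warning(v <- nrmse(c(sim, 4, 6), d4), "zero range")
  expect_equal(v, nrmse(sim, d2))
})

test_that("the NLS cost of truth concentrates near the residual count", {
  # data simulated at theta* with N(0, sigma^2) noise and matching stored
  # sigma has E[Q_NLS(theta*)] = n
  m <- decay_model()
  times <- seq(0, 5, length.out = 25)
  traj <- simulateModel(m, c(k = 1), times = times)
  set.seed(42)
  reps <- 40
  q <- numeric(reps)
  for (r in seq_len(reps)) {
    sigma <- pmax(0.1 * abs(traj$obs[, 1]), 0.01)
    val <- traj$obs[, 1] + stats::rnorm(25, 0, sigma)
    tab <- data.frame(experiment = "e1", observable = "y", time = times,
                      value = val, sigma = sigma)
    d <- experimentData(tab, c(x = 1))
    q[r] <- nlsCost(m, c(k = 1), d)$cost
  }
  n <- 25
  expect_lt(abs(mean(q) - n), 3 * sqrt(2 * n / reps))
})

test_that("FIM statistics reproduce closed forms and flag rank deficiency", {
  # one-parameter decay: FIM and CI from an independent finite-difference J
  m <- decay_model()
  times <- seq(0, 5, length.out = 12)
  traj <- simulateModel(m, c(k = 1), times = times)
  sigma <- rep(0.2, 12)
  tab <- data.frame(experiment = "e1", observable = "y", time = times,
                    value = traj$obs[, 1], sigma = sigma)
  d <- experimentData(tab, c(x = 1))
  st <- fitStatistics(m, c(k = 1), d)
  h <- 1e-6
  yp <- simulateModel(m, c(k = 1 + h), times = times)$obs[, 1]
  ym <- simulateModel(m, c(k = 1 - h), times = times)$obs[, 1]
  Jfd <- (yp - ym) / (2 * h) / sigma
  fim_fd <- sum(Jfd^2)
  expect_equal(unname(st$fim[1, 1]), fim_fd, tolerance = 1e-4)
  expect_equal(unname(st$ci95), 1.96 / sqrt(fim_fd), tolerance = 1e-4)
  expect_equal(unname(st$cv_percent), 100 / sqrt(fim_fd), tolerance = 1e-4)
  expect_equal(st$nrmse, 0, tolerance = 1e-8)
  expect_equal(unname(st$r_squared), 1, tolerance = 1e-10)
  expect_equal(unname(st$bounds_status), "Bounds not active")

  # interchangeable parameters: correlation +/-1 and singularity warning
  md <- duplicated_param_model()
  dd <- noiseless_data(md, c(a = 1, b = 1))
  expect_warning(std <- fitStatistics(md, c(a = 1, b = 1), dd),
                 "non-identifiable")
  expect_equal(abs(std$correlation[1, 2]), 1, tolerance = 1e-8)
})

test_that("bounds status reports log-scale proximity to the box", {
  fhn <- caseStudy("fhn")
  d <- noiseless_data(fhn, points = 8, horizon = 20)
  st <- fitStatistics(fhn, c(a = 1e-5 * 1.001, b = 0.2, g = 3), d)
  expect_equal(unname(st$bounds_status),
               c("Active at lower bound", "Bounds not active",
                 "Bounds not active"))
})
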