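test_that("case-study registry matches the published problem structure", {
  fhn <- caseStudy("fhn")
  expect_setequal(fhn$params, c("a", "b", "g"))
  expect_length(fhn$states, 2)
  expect_length(fhn$observations$fitting, 1)
  expect_true(all(fhn$lower == 1e-5) && all(fhn$upper == 1e5))

  go <- caseStudy("go")
  expect_length(go$params, 8)
  expect_equal(names(go$observations$fitting), c("y1", "y2"))
  expect_length(go$observations$validation, 3)
  expect_equal(unname(go$lower[c("k1", "Ki")]), c(1e-3, 1e-3))
  expect_equal(unname(c(go$lower["n"], go$upper["n"])), c(1, 12))

  eo <- caseStudy("eo")
  expect_length(eo$params, 7)
  expect_true(all(eo$lower == 1e-3) && all(eo$upper == 1e3))

  expect_error(caseStudy("nope"), "no such case study")
  expect_warning(caseStudy("fhn", "validation"), "fitting variant")
  expect_warning(caseStudy("rp"), "ambiguous")
  rp <- suppressWarnings(caseStudy("rp"))
  expect_length(rp$states, 6)
  rp2 <- caseStudy("rp", rp_nominal_mapping = "swap")
  expect_equal(unname(rp2$nominal["n"]), 8.5)
})

test_that("simulation reproduces closed forms and degenerate grids", {
  m <- decay_model()
  # single-point grid: no integration, trajectory is x0
  tr0 <- simulateModel(m, c(k = 1), times = 0)
  expect_equal(unname(tr0$states[1, 1]), 1)
  # closed form x(1) = exp(-1)
  tr <- simulateModel(m, c(k = 1), times = c(0, 1))
  expect_equal(unname(tr$states[2, 1]), exp(-1), tolerance = 1e-6)
  # out-of-bounds parameters warn but simulate
  expect_warning(simulateModel(m, c(k = 100), times = c(0, 1)), "bounds")
  expect_error(simulateModel(m, c(k = 1), times = c(1, 0)),
               "strictly increasing")
})

test_that("FHN trajectory spikes and matches an independent integrator", {
  fhn <- caseStudy("fhn")
  times <- seq(0, 20, length.out = 50)
  tr <- simulateModel(fhn, fhn$nominal, times = times)
  expect_gte(sum(diff(sign(tr$obs[, 1])) != 0), 2)

  # independent high-accuracy oracle: a different integrator family at
  # much tighter tolerance
  rhs <- function(t, s, p) {
    V <- s[1]; R <- s[2]
    list(c(p["g"] * (V - V^3 / 3 + R),
           -(1 / p["g"]) * (V - p["a"] + p["b"] * R)))
  }
  ref <- deSolve::ode(c(-1, 1), times, rhs, fhn$nominal, method = "ode45",
                      rtol = 1e-12, atol = 1e-12)
  expect_equal(unname(tr$states[, 1]), unname(ref[, 2]), tolerance = 1e-5)
})

test_that("integrator tolerance tightening leaves observables stable", {
  for (nm in c("fhn", "go", "rp", "eo")) {
    m <- suppressWarnings(caseStudy(nm, rp_nominal_mapping = "swap"))
    times <- seq(0, m$horizon, length.out = 20)
    a <- simulateModel(m, m$nominal, times = times)
    b <- simulateModel(m, m$nominal, times = times,
                       rtol = 1e-9, atol = 1e-11)
    scale <- max(abs(a$obs))
    expect_lt(max(abs(a$obs - b$obs)) / scale, 1e-5)
  }
})

test_that("sensitivities match closed forms and finite differences", {
  m <- decay_model()
  s <- simulateSens(m, c(k = 1), times = c(0, 1))
  expect_equal(s$dx_dtheta[1, 1, 1], 0)                     # S(t0) = 0
  expect_equal(s$dx_dtheta[2, 1, 1], -exp(-1), tolerance = 1e-6)

  fhn <- caseStudy("fhn")
  times <- seq(0, 20, length.out = 10)
  # the finite-difference oracle needs tighter integration than the
  # package default, or its own truncation error dominates the comparison
  set.seed(4)
  for (draw in 1:20) {
    theta <- fhn$nominal * exp(stats::runif(3, -0.3, 0.3))
    s <- simulateSens(fhn, theta, times = times, rtol = 1e-10, atol = 1e-12)
    if (!s$traj$feasible) next
    for (j in 1:3) {
      h <- 1e-5 * theta[j]
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      fd <- (simulateModel(fhn, tp, times = times, rtol = 1e-10,
                           atol = 1e-12)$obs[, 1] -
               simulateModel(fhn, tm, times = times, rtol = 1e-10,
                             atol = 1e-12)$obs[, 1]) / (2 * h)
      an <- s$dy_dtheta[, 1, j]
      expect_lt(max(abs(fd - an)) / max(abs(an), 1), 1e-3)
    }
  }
})

test_that("infeasible integration is flagged, not raised", {
  # explosive dynamics: dx/dt = k x^2 blows up in finite time
  m <- oscifitModel("blow", "x", "k", list(x = "k * x^2"),
                    list(fitting = list(y = "x")),
                    x0 = c(x = 1), lower = c(k = 0.1), upper = c(k = 100),
                    horizon = 10, points = 5)
  tr <- suppressWarnings(simulateModel(m, c(k = 50), times = seq(0, 10, 1)))
  expect_false(tr$feasible)
  d <- noiseless_data(decay_model())
  # the cost consumes the failure as a penalty
  m2 <- oscifitModel("blow2", "x", "k", list(x = "k * x^2"),
                     list(fitting = list(y = "x")),
                     x0 = c(x = 1), lower = c(k = 0.1), upper = c(k = 1e4),
                     horizon = 5, points = 6)
  d2 <- d; d2$variant <- "fitting"
  cost <- suppressWarnings(nlsCost(m2, c(k = 1e3), d2))
  expect_gte(cost$cost, 1e10)
})

test_that("oscillation classifier separates sustained, damped and steady", {
  h <- harmonic_model()
  r <- detectOscillations(h, c(w = 1), horizon = 100)
  expect_equal(r$classification, "sustained")
  expect_equal(r$period, 2 * pi, tolerance = 1e-2)

  d <- detectOscillations(decay_model(), c(k = 1), horizon = 50)
  expect_equal(d$classification, "steady")

  go <- caseStudy("go")
  expect_equal(detectOscillations(go, go$nominal, horizon = 1000,
                                  npoints = 3000)$classification,
               "sustained")
})

test_that("Goodwin Hill-coefficient scan splits contiguously", {
  go <- caseStudy("go")
  cls <- character(12)
  for (n in 1:12) {
    th <- go$nominal; th["n"] <- n
    cls[n] <- detectOscillations(go, th, horizon = 1000,
                                 npoints = 2500)$classification
  }
  sustained <- which(cls == "sustained")
  expect_gt(length(sustained), 0)
  # contiguous split: damped below some threshold, sustained from it up
  expect_equal(sustained, seq(min(sustained), 12))
  expect_true(all(cls[seq_len(min(sustained) - 1)] %in% c("damped", "steady")))
  expect_gte(min(sustained), 8)
})

test_that("plain-text model descriptions reproduce built-in dynamics", {
  txt <- c("name fhn_txt",
           "# FitzHugh-Nagumo in the declarative format",
           "state V' = g*(V - V^3/3 + R)",
           "state R' = -(1/g)*(V - a + b*R)",
           "init V = -1", "init R = 1",
           "param a in [1e-5, 1e5]",
           "param b in [1e-5, 1e5]",
           "param g in [1e-5, 1e5]",
           "obs y1 = V", "horizon 20", "points 6")
  m <- parseModelText(txt)
  # file-based parsing of the shipped example gives the same model
  mf <- parseModelText(file = system.file("extdata", "fhn.txt",
                                          package = "oscifit"))
  expect_equal(mf$states, m$states)
  expect_equal(mf$lower, m$lower)
  fhn <- caseStudy("fhn")
  times <- seq(0, 20, length.out = 15)
  a <- simulateModel(m, c(a = 0.2, b = 0.2, g = 3), times = times)
  b <- simulateModel(fhn, fhn$nominal, times = times)
  expect_equal(a$obs, b$obs, tolerance = 1e-9)
  expect_error(parseModelText("state x = 3"), "unrecognised|cannot parse")
  expect_error(parseModelText(c("state x' = -y*x", "param k in [0,1]",
                                "obs y1 = x")), "unknown symbol")
})
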