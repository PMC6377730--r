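# Small models and fixtures shared across the test files. Everything is
# built in code at test time; no stored fixtures.

# scalar exponential decay dx/dt = -k x, closed forms known
decay_model <- function() {
  oscifitModel("decay", states = "x", params = "k",
               rhs = list(x = "-k * x"),
               observations = list(fitting = list(y = "x")),
               x0 = c(x = 1), lower = c(k = 0.01), upper = c(k = 10),
               nominal = c(k = 1), horizon = 5, points = 6)
}

# harmonic oscillator with angular frequency w: x(t) = sin(w t) for x0=(0,w)
harmonic_model <- function() {
  oscifitModel("harmonic", states = c("x", "v"), params = "w",
               rhs = list(x = "v", v = "-w^2 * x"),
               observations = list(fitting = list(y = "x")),
               x0 = c(x = 0, v = 1), lower = c(w = 0.1), upper = c(w = 10),
               nominal = c(w = 1), horizon = 50, points = 20)
}

# model whose observation depends on two exactly interchangeable parameters
duplicated_param_model <- function() {
  oscifitModel("dup", states = "x", params = c("a", "b"),
               rhs = list(x = "-x"),
               observations = list(fitting = list(y = "x * (a + b)")),
               x0 = c(x = 1), lower = c(a = 0.01, b = 0.01),
               upper = c(a = 10, b = 10), horizon = 2, points = 5)
}

# noise-free dataset from a model at given parameters on an equidistant grid
noiseless_data <- function(model, theta = model$nominal, x0 = model$x0,
                           points = model$points, horizon = model$horizon,
                           sigma = 0.1, variant = "fitting",
                           experiment = "e1") {
  times <- seq(0, horizon, length.out = points)
  traj <- simulateModel(model, theta, x0 = x0, times = times,
                        variant = variant)
  stopifnot(traj$feasible)
  ov <- names(model$observations[[variant]])
  tab <- do.call(rbind, lapply(seq_along(ov), function(k)
    data.frame(experiment = experiment, observable = ov[k], time = times,
               value = traj$obs[, k], sigma = sigma)))
  experimentData(tab, stats::setNames(list(x0), experiment), variant)
}

# a deliberately small eSS budget for smoke runs
tiny_ess <- function(seed, max_evals = 400)
  essControl(max_evals = max_evals, local_freq = 3, local_maxit = 15,
             seed = seed)
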