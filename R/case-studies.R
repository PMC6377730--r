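#' Built-in oscillator case studies
#'
#' Returns one of four classic oscillator calibration problems, each with its
#' equations, default parameter bounds, default initial conditions and the
#' nominal (data-generating) parameter vector attached as metadata:
#'
#' \describe{
#'   \item{`fhn`}{FitzHugh-Nagumo spiking-neuron model: 2 states (V, R),
#'     3 parameters \{a, b, g\} in \[1e-5, 1e5\], observable V.}
#'   \item{`go`}{Goodwin oscillator (enzyme synthesis under feedback
#'     repression): 3 states, 8 parameters (\{k1..k6, Ki\} in \[1e-3, 1e3\],
#'     Hill coefficient n in \[1, 12\]); fitting observables (x1, x3),
#'     validation observables (x1, x2, x3).}
#'   \item{`rp`}{Repressilator synthetic gene network: 6 states,
#'     4 parameters (\{alpha0, alpha, beta\} in \[1e-3, 500\], n in \[1, 10\]);
#'     fitting observable m3, validation observables (p3, m3).}
#'   \item{`eo`}{Enzymatic (metabolic) oscillator with two coupled
#'     instability-generating mechanisms: 3 states, 7 parameters in
#'     \[1e-3, 1e3\], observables (alpha, beta).}
#' }
#'
#' The `fhn` and `eo` problems use the same observables for fitting and
#' cross-validation; requesting their `"validation"` variant warns and
#' returns the fitting variant.
#'
#' @param name one of `"fhn"`, `"go"`, `"rp"`, `"eo"`.
#' @param variant observation variant, `"fitting"` or `"validation"`. This
#'   only selects which variant downstream defaults use; both variants stay
#'   attached to the model.
#' @param rp_nominal_mapping for the Repressilator only: how to map the
#'   published nominal vector `[0.05, 298, 8.5, 0.3]` onto the parameters.
#'   `"order"` (default) uses declaration order \{alpha0, alpha, beta, n\},
#'   which places n = 0.3 outside its bound \[1, 10\] and therefore emits a
#'   prominent warning; `"swap"` maps \{alpha0, alpha, n, beta\} so that
#'   n = 8.5 and beta = 0.3.
#' @return An [oscifitModel()] with an extra element `default_variant`.
#' @export
caseStudy <- function(name = c("fhn", "go", "rp", "eo"),
                      variant = c("fitting", "validation"),
                      rp_nominal_mapping = c("order", "swap")) {
  if (!is.character(name) || !name[1] %in% c("fhn", "go", "rp", "eo"))
    stop("no such case study: ", name[1])
  name <- match.arg(name)
  variant <- match.arg(variant)
  rp_nominal_mapping <- match.arg(rp_nominal_mapping)

  model <- switch(name,
    fhn = oscifitModel(
      name = "fhn",
      states = c("V", "R"),
      params = c("a", "b", "g"),
      rhs = list(
        V = "g * (V - V^3/3 + R)",
        R = "-(1/g) * (V - a + b*R)"),
      observations = list(
        fitting = list(y1 = "V"),
        validation = list(y1 = "V")),
      x0 = c(V = -1, R = 1),
      lower = rep(1e-5, 3), upper = rep(1e5, 3),
      nominal = c(a = 0.2, b = 0.2, g = 3),
      horizon = 20, points = 6),
    go = oscifitModel(
      name = "go",
      states = c("x1", "x2", "x3"),
      params = c("k1", "k2", "k3", "k4", "k5", "k6", "Ki", "n"),
      rhs = list(
        x1 = "k1 * Ki^n / (Ki^n + x3^n) - k2 * x1",
        x2 = "k3 * x1 - k4 * x2",
        x3 = "k5 * x2 - k6 * x3"),
      observations = list(
        fitting = list(y1 = "x1", y2 = "x3"),
        validation = list(y1 = "x1", y2 = "x2", y3 = "x3")),
      x0 = c(x1 = 0.1, x2 = 0.2, x3 = 2.5),
      lower = c(rep(1e-3, 7), 1), upper = c(rep(1e3, 7), 12),
      nominal = c(k1 = 1, k2 = 0.1, k3 = 1, k4 = 0.1, k5 = 1, k6 = 0.1,
                  Ki = 1, n = 10),
      horizon = 100, points = 20),
    rp = {
      nom <- c(0.05, 298, 8.5, 0.3)
      nominal <- if (rp_nominal_mapping == "order") {
        warning("Repressilator nominal vector mapped in declaration order ",
                "{alpha0, alpha, beta, n} = {0.05, 298, 8.5, 0.3}: ",
                "n = 0.3 violates its bound [1, 10]. The published labels are ",
                "ambiguous; use rp_nominal_mapping = \"swap\" for ",
                "{alpha0, alpha, n, beta} = {0.05, 298, 8.5, 0.3}.")
        c(alpha0 = nom[1], alpha = nom[2], beta = nom[3], n = nom[4])
      } else {
        c(alpha0 = nom[1], alpha = nom[2], beta = nom[4], n = nom[3])
      }
      oscifitModel(
        name = "rp",
        states = c("p1", "p2", "p3", "m1", "m2", "m3"),
        params = c("alpha0", "alpha", "beta", "n"),
        rhs = list(
          p1 = "beta * (m1 - p1)",
          p2 = "beta * (m2 - p2)",
          p3 = "beta * (m3 - p3)",
          m1 = "alpha0 + alpha / (1 + p3^n) - m1",
          m2 = "alpha0 + alpha / (1 + p1^n) - m2",
          m3 = "alpha0 + alpha / (1 + p2^n) - m3"),
        observations = list(
          fitting = list(y1 = "m3"),
          validation = list(y1 = "p3", y2 = "m3")),
        x0 = c(p1 = 10, p2 = 0.01, p3 = 1, m1 = 1, m2 = 0.01, m3 = 10),
        lower = c(1e-3, 1e-3, 1e-3, 1), upper = c(500, 500, 500, 10),
        nominal = nominal,
        horizon = 50, points = 20)
    },
    eo = oscifitModel(
      name = "eo",
      states = c("alpha", "beta", "gamma"),
      params = c("vKm1", "L1", "sig", "L2", "d", "sig2", "ks"),
      rhs = list(
        alpha = "vKm1 - alpha*sig*(alpha + 1)*(beta + 1)^2 / (1e6*L1 + (alpha + 1)^2*(beta + 1)^2)",
        beta = "50*alpha*sig*(alpha + 1)*(beta + 1)^2 / (1e6*L1 + (alpha + 1)^2*(beta + 1)^2) - sig2*(gamma + 1)^2*(d*beta/100 + 1)*beta / (L2 + (gamma + 1)^2*(d*beta/100 + 1)^2)",
        gamma = "sig2*(gamma + 1)^2*(d*beta/100 + 1)*beta / (50*(L2 + (gamma + 1)^2*(d*beta/100 + 1)^2)) - ks*gamma"),
      observations = list(
        fitting = list(y1 = "alpha", y2 = "beta"),
        validation = list(y1 = "alpha", y2 = "beta")),
      x0 = c(alpha = 29.1999, beta = 188.8, gamma = 0.3367),
      lower = rep(1e-3, 7), upper = rep(1e3, 7),
      nominal = c(vKm1 = 0.4, L1 = 500, sig = 10, L2 = 10, d = 0.07,
                  sig2 = 7, ks = 2.5),
      horizon = 100, points = 14))

  if (variant == "validation" && name %in% c("fhn", "eo"))
    warning("the '", name, "' case study has no separate validation ",
            "observables; using the fitting variant")
  model$default_variant <- if (name %in% c("fhn", "eo")) "fitting" else variant
  model
}
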