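#' Construct a dynamic ODE model with an observation map
#'
#' A model couples a set of ordinary differential equations
#' \eqn{dx/dt = f(t, x, \theta)} with one or more named observation maps
#' \eqn{y = g(x, t, \theta)} and a box of parameter bounds
#' \eqn{\theta^{min} \le \theta \le \theta^{max}}. Right-hand sides and
#' observation expressions are given symbolically (as strings or unevaluated
#' R expressions); the constructor differentiates them once with respect to
#' states and parameters so that forward sensitivities and analytic residual
#' Jacobians are available throughout the package.
#'
#' @param name model identifier.
#' @param states character vector of state names.
#' @param params character vector of parameter names.
#' @param rhs named list (one entry per state, in order) of expressions for
#'   the time derivatives. Entries may be strings or language objects; they
#'   may reference states, parameters and `t`.
#' @param observations named list of observation variants (at least
#'   `"fitting"`); each variant is a named list of observable expressions.
#' @param x0 default initial state (named numeric, one value per state).
#' @param lower,upper named numeric parameter bounds (\eqn{\theta^{min} <
#'   \theta^{max}}; positive lower bounds are required for log10-scaled
#'   parameters).
#' @param scale per-parameter search scale, `"log10"` or `"linear"`. Default
#'   `NULL` chooses `"log10"` for parameters whose positive bounds span more
#'   than two decades and `"linear"` otherwise.
#' @param nominal optional named numeric vector of nominal (data-generating)
#'   parameter values, attached as metadata.
#' @param horizon default simulation end time \eqn{t_{end}} (with
#'   \eqn{t_0 = 0}).
#' @param points default number of data points per generated experiment.
#'
#' @return An object of class `oscifit_model`.
#' @seealso [caseStudy()], [parseModelText()], [simulateModel()]
#' @export
oscifitModel <- function(name, states, params, rhs, observations,
                         x0, lower, upper, scale = NULL,
                         nominal = NULL, horizon = 10, points = 10) {
  states <- as.character(states)
  params <- as.character(params)
  nx <- length(states)
  np <- length(params)
  if (any(duplicated(c(states, params))))
    stop("state and parameter names must be distinct")

  rhs <- lapply(rhs, as_lang)
  if (length(rhs) != nx)
    stop("rhs must have exactly one expression per state (", nx, ")")
  names(rhs) <- states

  if (is.null(names(observations)) || !"fitting" %in% names(observations))
    stop("observations must be a named list containing a 'fitting' variant")
  observations <- lapply(observations, function(variant) {
    if (length(variant) < 1L)
      stop("each observation variant must map to at least one expression")
    v <- lapply(variant, as_lang)
    if (is.null(names(v)) || any(names(v) == ""))
      stop("observables must be named")
    v
  })

  known <- c(states, params, "t", "pi")
  for (ex in c(rhs, unlist(observations)))
    check_symbols(ex, known, name)

  lower <- as_named_vec(lower, params, "lower")
  upper <- as_named_vec(upper, params, "upper")
  if (any(lower >= upper))
    stop("each lower bound must be strictly below its upper bound")

  if (is.null(scale)) {
    scale <- ifelse(lower > 0 & upper / lower > 100, "log10", "linear")
  } else {
    if (length(scale) == 1L) scale <- rep(scale, np)
    scale <- match.arg(scale, c("log10", "linear"), several.ok = TRUE)
  }
  names(scale) <- params
  if (any(scale == "log10" & lower <= 0))
    stop("log10-scaled parameters require a positive lower bound")

  x0 <- as_named_vec(x0, states, "x0")
  if (!is.null(nominal)) nominal <- as_named_vec(nominal, params, "nominal")

  model <- structure(
    list(name = name, states = states, params = params,
         rhs = rhs, observations = observations,
         x0 = x0, lower = lower, upper = upper, scale = scale,
         nominal = nominal, horizon = horizon, points = points),
    class = "oscifit_model")
  model$compiled <- compile_model(model)
  model
}

as_lang <- function(x) {
  if (is.character(x)) return(str2lang(x))
  if (is.call(x) || is.name(x) || is.numeric(x)) return(x)
  if (is.expression(x)) return(x[[1L]])
  stop("expressions must be strings or language objects")
}

check_symbols <- function(ex, known, model_name) {
  bad <- setdiff(all.vars(ex), known)
  if (length(bad))
    stop(sprintf("model '%s': unknown symbol(s) %s in expression '%s'",
                 model_name, paste(bad, collapse = ", "),
                 deparse1(ex)))
}

as_named_vec <- function(x, nms, what) {
  x <- unlist(x)
  if (length(x) == 1L && length(nms) > 1L) x <- rep(x, length(nms))
  if (length(x) != length(nms))
    stop(what, " must have length ", length(nms))
  if (!is.null(names(x)) && all(nms %in% names(x))) x <- x[nms]
  out <- as.numeric(x)
  names(out) <- nms
  out
}

# Differentiate every rhs/observation expression with respect to states and
# parameters once, and pre-assemble the calls that evaluate them in bulk.
compile_model <- function(model) {
  nx <- length(model$states)
  np <- length(model$params)

  d <- function(ex, var) {
    tryCatch(stats::D(ex, var),
             error = function(e)
               stop(sprintf("cannot differentiate '%s' with respect to '%s': %s",
                            deparse1(ex), var, conditionMessage(e)),
                  call. = FALSE))
  }

  # column-major lists of derivative expressions
  dfdx <- vector("list", nx * nx)
  dfdp <- vector("list", nx * np)
  for (j in seq_len(nx))
    for (i in seq_len(nx))
      dfdx[[(j - 1L) * nx + i]] <- d(model$rhs[[i]], model$states[j])
  for (j in seq_len(np))
    for (i in seq_len(nx))
      dfdp[[(j - 1L) * nx + i]] <- d(model$rhs[[i]], model$params[j])

  ccall <- function(exprs) as.call(c(quote(c), exprs))

  obs <- lapply(model$observations, function(variant) {
    ny <- length(variant)
    dgdx <- vector("list", ny * nx)
    dgdp <- vector("list", ny * np)
    for (j in seq_len(nx))
      for (i in seq_len(ny))
        dgdx[[(j - 1L) * ny + i]] <- d(variant[[i]], model$states[j])
    for (j in seq_len(np))
      for (i in seq_len(ny))
        dgdp[[(j - 1L) * ny + i]] <- d(variant[[i]], model$params[j])
    list(exprs = variant, names = names(variant),
         call = ccall(variant), dgdx_call = ccall(dgdx),
         dgdp_call = ccall(dgdp), ny = ny)
  })

  list(rhs_call = ccall(model$rhs),
       dfdx_call = ccall(dfdx),
       dfdp_call = ccall(dfdp),
       obs = obs)
}

#' @export
print.oscifit_model <- function(x, ...) {
  cat(sprintf("<oscifit_model> %s\n", x$name))
  cat(sprintf("  states (%d): %s\n", length(x$states),
              paste(x$states, collapse = ", ")))
  cat(sprintf("  parameters (%d): %s\n", length(x$params),
              paste(x$params, collapse = ", ")))
  for (v in names(x$observations))
    cat(sprintf("  observables [%s]: %s\n", v,
                paste(names(x$observations[[v]]), collapse = ", ")))
  b <- sprintf("%s in [%.3g, %.3g] (%s)", x$params, x$lower, x$upper, x$scale)
  cat("  bounds:", paste(b, collapse = "; "), "\n")
  if (!is.null(x$nominal))
    cat("  nominal:", paste(sprintf("%s=%.4g", x$params, x$nominal),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Parse a plain-text model description
#'
#' Reads a declarative one-statement-per-line model description. Recognised
#' forms (UTF-8, `#` starts a comment):
#' \preformatted{
#' name fhn
#' state V' = g*(V - V^3/3 + R)
#' init V = -1
#' param a in [1e-5, 1e5]
#' obs y1 = V
#' horizon 20
#' points 6
#' }
#' `state` declares one ODE per line, `init` its initial value (default 0),
#' `param` a parameter with its bounds, `obs` an observable of the
#' `"fitting"` variant. Parameter search scale follows the package default
#' (log10 when positive bounds span more than two decades).
#'
#' @param text character vector of lines, or a single string with newlines.
#' @param file path to a model description file (used when `text` is missing).
#' @return An [oscifitModel()] object.
#' @export
parseModelText <- function(text, file = NULL) {
  if (missing(text)) text <- readLines(file, encoding = "UTF-8")
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  name <- "custom"; horizon <- 10; points <- 10
  states <- character(); rhs <- list(); inits <- list()
  params <- character(); lower <- c(); upper <- c()
  obs <- list()

  for (ln in lines) {
    if (grepl("^name\\s+", ln)) {
      name <- trimws(sub("^name\\s+", "", ln))
    } else if (grepl("^horizon\\s+", ln)) {
      horizon <- as.numeric(sub("^horizon\\s+", "", ln))
    } else if (grepl("^points\\s+", ln)) {
      points <- as.integer(sub("^points\\s+", "", ln))
    } else if (grepl("^state\\s+", ln)) {
      m <- regmatches(ln, regexec("^state\\s+([A-Za-z][A-Za-z0-9_.]*)'\\s*=\\s*(.+)$", ln))[[1]]
      if (length(m) != 3) stop("cannot parse state declaration: ", ln)
      states <- c(states, m[2]); rhs[[m[2]]] <- str2lang(m[3])
    } else if (grepl("^init\\s+", ln)) {
      m <- regmatches(ln, regexec("^init\\s+([A-Za-z][A-Za-z0-9_.]*)\\s*=\\s*(.+)$", ln))[[1]]
      if (length(m) != 3) stop("cannot parse init declaration: ", ln)
      inits[[m[2]]] <- as.numeric(m[3])
    } else if (grepl("^param\\s+", ln)) {
      m <- regmatches(ln, regexec(
        "^param\\s+([A-Za-z][A-Za-z0-9_.]*)\\s+in\\s*\\[\\s*([^,]+),\\s*([^]]+)\\]\\s*$", ln))[[1]]
      if (length(m) != 4) stop("cannot parse param declaration: ", ln)
      params <- c(params, m[2])
      lower <- c(lower, as.numeric(m[3])); upper <- c(upper, as.numeric(m[4]))
    } else if (grepl("^obs\\s+", ln)) {
      m <- regmatches(ln, regexec("^obs\\s+([A-Za-z][A-Za-z0-9_.]*)\\s*=\\s*(.+)$", ln))[[1]]
      if (length(m) != 3) stop("cannot parse obs declaration: ", ln)
      obs[[m[2]]] <- str2lang(m[3])
    } else {
      stop("unrecognised model declaration: ", ln)
    }
  }
  if (!length(states)) stop("model text declares no states")
  if (!length(params)) stop("model text declares no parameters")
  if (!length(obs)) stop("model text declares no observables")
  x0 <- vapply(states, function(s) if (!is.null(inits[[s]])) inits[[s]] else 0,
               numeric(1))
  names(lower) <- names(upper) <- params
  oscifitModel(name, states, params, rhs, list(fitting = obs),
               x0 = x0, lower = lower, upper = upper,
               horizon = horizon, points = points)
}
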