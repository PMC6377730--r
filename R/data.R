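#' Bundle experimental measurements for one or more experiments
#'
#' Holds the measurement table (long format) together with the initial state
#' of every experiment and the observation variant the observable names refer
#' to. Each row of `table` is one measured point
#' \eqn{(\tilde y_{kji}, \sigma_{kji})} of observable j at time i in
#' experiment k.
#'
#' @param table data frame with columns `experiment`, `observable`, `time`,
#'   `value`, `sigma`.
#' @param x0 named list mapping each experiment id to its initial state
#'   vector, or a single numeric vector shared by all experiments.
#' @param variant observation variant the `observable` column refers to.
#' @return An object of class `oscifit_data`.
#' @export
experimentData <- function(table, x0, variant = "fitting") {
  req <- c("experiment", "observable", "time", "value", "sigma")
  if (!all(req %in% names(table)))
    stop("table must have columns ", paste(req, collapse = ", "))
  table <- as.data.frame(table)[req]
  table$experiment <- as.character(table$experiment)
  table$observable <- as.character(table$observable)
  if (nrow(table) == 0) stop("no measurements: total residual count is zero")
  if (any(!is.finite(table$value)))
    stop("non-finite measurement values rejected")
  if (any(!is.finite(table$sigma) | table$sigma <= 0))
    stop("every sigma must be a positive finite number")
  exps <- unique(table$experiment)
  if (is.numeric(x0)) x0 <- stats::setNames(rep(list(x0), length(exps)), exps)
  if (!all(exps %in% names(x0)))
    stop("x0 must provide an initial state for every experiment")
  structure(list(table = table, x0 = x0[exps], variant = variant),
            class = "oscifit_data")
}

#' @export
print.oscifit_data <- function(x, ...) {
  cat(sprintf("<oscifit_data> %d points, %d experiment(s), variant '%s'\n",
              nrow(x$table), length(x$x0), x$variant))
  cat("  observables:", paste(unique(x$table$observable), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of residuals in a dataset
#' @param data an [experimentData()] object.
#' @export
nResiduals <- function(data) nrow(data$table)

# Check that every observable named in the data exists in the model variant.
check_data_model <- function(model, data) {
  ov <- model$compiled$obs[[data$variant]]
  if (is.null(ov))
    stop("data refer to observation variant '", data$variant,
         "' which the model does not define")
  bad <- setdiff(unique(data$table$observable), ov$names)
  if (length(bad))
    stop("observable(s) not in model variant '", data$variant, "': ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Write a dataset to CSV (plus an optional JSON manifest)
#'
#' The CSV has the columns `experiment,observable,time,value,sigma` with a
#' header, UTF-8 encoding and `.` as the decimal separator. Initial
#' conditions and the observation variant, which the CSV cannot carry, go
#' into the manifest.
#'
#' @param data an [experimentData()] object.
#' @param file CSV path.
#' @param manifest optional path for a JSON manifest storing `x0`, `variant`
#'   and any `extra` entries (e.g. generator seeds).
#' @param extra named list merged into the manifest.
#' @export
writeExperimentData <- function(data, file, manifest = NULL, extra = list()) {
  utils::write.csv(data$table, file, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  if (!is.null(manifest)) {
    payload <- c(list(schema = "oscifit-dataset/1", variant = data$variant,
                      x0 = lapply(data$x0, as.list)), extra)
    jsonlite::write_json(payload, manifest, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(file)
}

#' Read a dataset from CSV
#'
#' @param file CSV path (columns `experiment,observable,time,value,sigma`).
#' @param manifest optional JSON manifest written by [writeExperimentData()];
#'   supplies `x0` and `variant` when given.
#' @param x0 initial state(s), used when no manifest is given.
#' @param variant observation variant, used when no manifest is given.
#' @return An [experimentData()] object.
#' @export
readExperimentData <- function(file, manifest = NULL, x0 = NULL,
                               variant = "fitting") {
  table <- utils::read.csv(file, fileEncoding = "UTF-8",
                           stringsAsFactors = FALSE)
  if (!is.null(manifest)) {
    m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
    x0 <- lapply(m$x0, unlist)
    variant <- m$variant
  }
  if (is.null(x0)) stop("initial conditions required (x0 or manifest)")
  experimentData(table, x0, variant)
}

# Pool a list of single-experiment datasets into one oscifit_data object,
# renaming experiments to stay unique.
poolExperimentData <- function(datasets) {
  if (inherits(datasets, "oscifit_data")) return(datasets)
  stopifnot(length(datasets) >= 1)
  tabs <- list(); x0 <- list()
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    tab <- d$table
    new_ids <- paste0("d", i, "_", tab$experiment)
    tab$experiment <- new_ids
    tabs[[i]] <- tab
    nm <- paste0("d", i, "_", names(d$x0))
    x0[nm] <- d$x0
  }
  experimentData(do.call(rbind, tabs), x0, datasets[[1]]$variant)
}
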