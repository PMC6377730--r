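#' Collinearity indices of a (weighted) sensitivity matrix
#'
#' Practical-identifiability diagnostic: for a parameter subset K the
#' collinearity index is \eqn{\gamma_K = 1/\sqrt{\lambda_{min}(\hat S_K^T
#' \hat S_K)}}, where \eqn{\hat S} is the sensitivity matrix with each
#' column scaled to unit norm. \eqn{\gamma_K \ge 1}; large values mean the
#' parameters in K can compensate one another almost exactly along the
#' measured outputs, so the subset is non-identifiable in practice. Subsets
#' are enumerated exhaustively up to size 4 and grown greedily (adding the
#' parameter that maximises \eqn{\gamma}) beyond that, which keeps large
#' custom models tractable while remaining exhaustive for the bundled case
#' studies.
#'
#' @param S numeric matrix of observable sensitivities at the measurement
#'   points (rows: residuals, columns: parameters), typically weighted by
#'   1/sigma. Needs at least as many rows as columns.
#' @param subset_max_size largest subset size to evaluate.
#' @param threshold subsets with \eqn{\gamma} above this are flagged
#'   non-identifiable (conventional default 20).
#' @return An object of class `oscifit_collinearity`: data frame `subsets`
#'   (columns `size`, `parameters`, `gamma`, `flagged`), the `threshold`,
#'   and `excluded` (zero-sensitivity parameters).
#' @export
collinearityIndices <- function(S, subset_max_size = 4, threshold = 20) {
  S <- as.matrix(S)
  if (is.null(colnames(S))) colnames(S) <- paste0("p", seq_len(ncol(S)))
  if (nrow(S) < ncol(S))
    stop("sensitivity matrix needs at least as many rows as parameters")
  norms <- sqrt(colSums(S^2))
  excluded <- colnames(S)[norms == 0]
  if (length(excluded) == ncol(S))
    stop("model output insensitive to all parameters")
  if (length(excluded))
    warning("excluding parameter(s) with zero sensitivity: ",
            paste(excluded, collapse = ", "))
  S <- S[, norms > 0, drop = FALSE]
  Sh <- sweep(S, 2L, sqrt(colSums(S^2)), "/")
  G <- crossprod(Sh)
  pn <- colnames(Sh)
  np <- ncol(Sh)

  gamma_of <- function(idx) {
    lam <- min(eigen(G[idx, idx, drop = FALSE], symmetric = TRUE,
                     only.values = TRUE)$values)
    if (lam <= 0) Inf else 1 / sqrt(lam)
  }

  rows <- list()
  kmax <- min(subset_max_size, np)
  exhaustive_to <- min(kmax, 4L)
  for (k in 2:exhaustive_to) {
    if (k > np) break
    combos <- utils::combn(np, k)
    for (c_i in seq_len(ncol(combos))) {
      idx <- combos[, c_i]
      rows[[length(rows) + 1L]] <- list(
        size = k, parameters = paste(pn[idx], collapse = "+"),
        gamma = gamma_of(idx))
    }
  }
  if (kmax > exhaustive_to) {
    # greedy growth from the worst exhaustive subset
    sizes <- vapply(rows, `[[`, numeric(1), "size")
    gammas <- vapply(rows, `[[`, numeric(1), "gamma")
    seed_row <- rows[[which.max(ifelse(sizes == exhaustive_to, gammas, -Inf))]]
    idx <- match(strsplit(seed_row$parameters, "+", fixed = TRUE)[[1]], pn)
    while (length(idx) < kmax) {
      cand <- setdiff(seq_len(np), idx)
      g <- vapply(cand, function(c_) gamma_of(c(idx, c_)), numeric(1))
      idx <- c(idx, cand[which.max(g)])
      rows[[length(rows) + 1L]] <- list(
        size = length(idx), parameters = paste(pn[idx], collapse = "+"),
        gamma = max(g))
    }
  }
  subsets <- do.call(rbind, lapply(rows, function(r)
    data.frame(size = r$size, parameters = r$parameters, gamma = r$gamma)))
  subsets$flagged <- subsets$gamma > threshold
  structure(list(subsets = subsets, threshold = threshold,
                 excluded = excluded),
            class = "oscifit_collinearity")
}

#' Collinearity diagnostic of a fitted model
#'
#' Builds the weighted observable-sensitivity matrix at the estimate over
#' the measurement points of `data` and calls [collinearityIndices()].
#'
#' @inheritParams nlsCost
#' @inheritParams collinearityIndices
#' @export
modelCollinearity <- function(model, theta, data, subset_max_size = 4,
                              threshold = 20, rtol = 1e-8, atol = 1e-10) {
  rj <- model_resid_jac(model, data, rtol, atol)
  J <- rj$jac(as_named_vec(theta, model$params, "theta"))
  if (is.null(J)) stop("simulation infeasible at the supplied estimate")
  collinearityIndices(J, subset_max_size = subset_max_size,
                      threshold = threshold)
}

#' @export
print.oscifit_collinearity <- function(x, ...) {
  n_flag <- sum(x$subsets$flagged)
  cat(sprintf("<oscifit_collinearity> %d subsets, %d flagged (gamma > %g)\n",
              nrow(x$subsets), n_flag, x$threshold))
  if (n_flag) {
    worst <- x$subsets[x$subsets$flagged, ]
    worst <- worst[order(-worst$gamma), ][seq_len(min(5, nrow(worst))), ]
    print(worst, row.names = FALSE)
  }
  invisible(x)
}
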