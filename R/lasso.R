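# L1-penalised least squares by cyclic coordinate descent.
#
# Objective (intercept unpenalised):
#   f(w, b) = sum_i (y_i - b - w'x_i)^2 + lambda * sum_j p_j |w_j|
# with per-feature penalty factors p_j (all 1 for plain Lasso; 1/|beta_j^OLS|
# for the adaptive variant). Soft-threshold update for coordinate j:
#   w_j <- S(<x_j, r_j>, lambda * p_j / 2) / <x_j, x_j>
# where r_j is the partial residual with w_j removed. The factor 1/2 comes
# from the unscaled squared-error loss.

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

.lasso_objective <- function(x, y, w, b, lambda, pf) {
  pen <- pf * abs(w)
  pen[pf == Inf & w == 0] <- 0
  sum((y - b - drop(x %*% w))^2) + lambda * sum(pen)
}

#' Fit a Lasso regression by coordinate descent
#'
#' Minimises \eqn{\sum_i (y_i - b - w^\top x_i)^2 + \lambda \sum_j p_j |w_j|}
#' with an unpenalised intercept `b` (optional). A penalty factor
#' `p_j = Inf` excludes feature `j` a priori.
#'
#' @param x Numeric design matrix (observations x features).
#' @param y Numeric response.
#' @param lambda Penalty weight, `>= 0`.
#' @param penalty_factor Optional non-negative per-feature penalty factors
#'   (default all 1); `Inf` forces a zero coefficient.
#' @param intercept Fit an unpenalised intercept? Default `TRUE`.
#' @param w_init Optional warm-start coefficients.
#' @param max_iter,tol Convergence control: stop when the largest scaled
#'   squared coefficient update of a sweep,
#'   \eqn{\langle x_j, x_j\rangle \Delta w_j^2}, falls below `tol` times the
#'   null deviance of `y` (the usual coordinate-descent criterion), or when a
#'   full sweep no longer improves the objective measurably.
#' @return A list of class `lasso_fit`: `coefficients`, `intercept`,
#'   `lambda`, `selected` (indices with `|coef| >` the zero tolerance,
#'   `1e-8`), `objective`, `objective_trace` (one value per sweep),
#'   `n_iter`, `converged`, `variant`.
#' @seealso [fit_adaptive_lasso()], [select_regions()]
#' @export
fit_lasso <- function(x, y, lambda, penalty_factor = NULL, intercept = TRUE,
                      w_init = NULL, max_iter = 100000L, tol = 1e-10) {
  x <- as.matrix(x)
  d <- ncol(x)
  m <- nrow(x)
  stopifnot(length(y) == m, lambda >= 0)
  if (is.null(penalty_factor)) penalty_factor <- rep(1, d)
  stopifnot(length(penalty_factor) == d, all(penalty_factor >= 0))
  if (anyNA(x)) stop("design matrix contains missing values")

  w0 <- if (is.null(w_init)) numeric(d) else as.numeric(w_init)
  w0[penalty_factor == Inf] <- 0
  storage.mode(x) <- "double"
  res <- .cd_lasso(x, as.numeric(y), lambda, as.numeric(penalty_factor),
                   isTRUE(intercept), w0, as.integer(max_iter), tol)
  if (!res$converged)
    stop(sprintf("coordinate descent did not converge in %d sweeps (last step gap %.3g)",
                 max_iter, res$max_delta))
  w <- setNames(res$w, colnames(x))
  trace <- res$objective_trace
  structure(list(coefficients = w, intercept = res$b, lambda = lambda,
                 penalty_factor = penalty_factor,
                 selected = which(abs(w) > 1e-8),
                 objective = trace[length(trace)],
                 objective_trace = trace, n_iter = res$n_iter,
                 converged = res$converged, variant = "lasso"),
            class = "lasso_fit")
}

#' Fit an Adaptive Lasso
#'
#' Minimises \eqn{\sum_i (y_i - b - w^\top x_i)^2 +
#' \lambda \sum_j |w_j| / |\hat\beta_j|}, where \eqn{\hat\beta} are
#' preliminary least-squares estimates. Solved by rescaling each column
#' \eqn{x_j \leftarrow x_j |\hat\beta_j|}, fitting a plain Lasso, and
#' back-transforming; a zero adaptive weight means an infinite penalty and
#' the feature is excluded a priori.
#'
#' When the design has at least as many features as observations the
#' ordinary least-squares weights are not unique; the minimum-norm
#' least-squares solution (SVD pseudoinverse) is used by default, ridge
#' estimates (`weight_method = "ridge"`, penalty 1e-3) as an alternative.
#'
#' @inheritParams fit_lasso
#' @param adaptive_weights Optional per-feature weights \eqn{\hat\beta_j};
#'   computed from the data when `NULL`.
#' @param weight_method How to compute weights when not supplied: `"ols"`
#'   (minimum-norm least squares when singular) or `"ridge"`.
#' @return A `lasso_fit` (see [fit_lasso()]) with `variant =
#'   "adaptive_lasso"` and the weights in `$adaptive_weights`.
#' @export
fit_adaptive_lasso <- function(x, y, lambda, adaptive_weights = NULL,
                               intercept = TRUE,
                               weight_method = c("ols", "ridge"),
                               max_iter = 100000L, tol = 1e-10) {
  x <- as.matrix(x)
  weight_method <- match.arg(weight_method)
  if (is.null(adaptive_weights))
    adaptive_weights <- ols_weights(x, y, intercept = intercept,
                                    method = weight_method)
  stopifnot(length(adaptive_weights) == ncol(x))
  aw <- abs(adaptive_weights)
  excluded <- aw == 0
  if (any(excluded))
    message(sprintf("adaptive lasso: %d feature(s) with zero weight excluded a priori",
                    sum(excluded)))
  xs <- sweep(x, 2, ifelse(excluded, 1, aw), `*`)
  xs[, excluded] <- 0
  fit <- fit_lasso(xs, y, lambda, intercept = intercept,
                   max_iter = max_iter, tol = tol)
  w <- fit$coefficients * ifelse(excluded, 0, aw)
  names(w) <- colnames(x)
  fit$coefficients <- w
  fit$selected <- which(abs(w) > 1e-8)
  fit$adaptive_weights <- adaptive_weights
  fit$penalty_factor <- ifelse(excluded, Inf, 1 / aw)
  fit$variant <- "adaptive_lasso"
  fit
}

#' Preliminary least-squares weights for the Adaptive Lasso
#'
#' @param x,y Design matrix and response.
#' @param intercept Include an (unreported) intercept in the preliminary fit?
#' @param method `"ols"` (minimum-norm least squares via SVD pseudoinverse
#'   when the design is singular) or `"ridge"` (penalty `ridge_lambda`).
#' @param ridge_lambda Ridge penalty used by `method = "ridge"`.
#' @return Numeric vector of per-feature weights.
#' @export
ols_weights <- function(x, y, intercept = TRUE,
                        method = c("ols", "ridge"), ridge_lambda = 1e-3) {
  x <- as.matrix(x)
  method <- match.arg(method)
  xc <- if (intercept) scale(x, center = TRUE, scale = FALSE) else x
  yc <- if (intercept) y - mean(y) else y
  d <- ncol(x)
  if (method == "ridge") {
    return(drop(solve(crossprod(xc) + diag(ridge_lambda, d), crossprod(xc, yc))))
  }
  if (nrow(xc) > d && qr(xc)$rank == d) {
    drop(qr.coef(qr(xc), yc))
  } else {
    # minimum-norm least squares via the pseudoinverse
    drop(MASS::ginv(xc) %*% yc)
  }
}

#' Smallest penalty shrinking every coefficient to zero
#'
#' For the intercept-adjusted objective, all coefficients are zero at the
#' optimum iff \eqn{\lambda \ge \max_j |2\langle x_j, y - \bar y\rangle|}.
#'
#' @param x,y Design matrix and response.
#' @param intercept Account for an unpenalised intercept (centres `y`)?
#' @return The critical penalty \eqn{\lambda_{max}}.
#' @export
lambda_max <- function(x, y, intercept = TRUE) {
  yc <- if (intercept) y - mean(y) else y
  max(abs(2 * crossprod(as.matrix(x), yc)))
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("%s fit: lambda = %.4g, %d/%d non-zero coefficients, objective %.6g (%d sweeps)\n",
              x$variant, x$lambda, length(x$selected),
              length(x$coefficients), x$objective, x$n_iter))
  invisible(x)
}
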