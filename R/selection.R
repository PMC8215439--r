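# Region selection: standardised Lasso / Adaptive Lasso over a CV-chosen
# penalty grid, applied to the regional iron feature matrix.

#' Encode diagnosis labels as a numeric regression response
#'
#' Default encoding is ordinal, following disease progression:
#' NC = 0, MCI = 1, AD = 2.
#'
#' @param labels Factor or character vector with values among `NC`, `MCI`,
#'   `AD` (any subset of at least two).
#' @return Numeric vector.
#' @export
encode_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), CLASS_LEVELS)
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  c(NC = 0, MCI = 1, AD = 2)[labels]
}

#' Select AD-predictive regions by penalised regression
#'
#' Standardises the iron features to zero mean / unit variance, encodes the
#' diagnosis labels ordinally (NC = 0, MCI = 1, AD = 2), fits a Lasso or
#' Adaptive Lasso over a logarithmic penalty grid, chooses the penalty by
#' k-fold cross-validated squared error, and returns the fit at that penalty
#' refitted on all subjects. Coefficients are reported on the original
#' feature scale; regions whose standardised coefficient exceeds the zero
#' tolerance (1e-8) in magnitude form the selected set.
#'
#' Columns that are entirely missing or constant are dropped with a warning
#' before fitting. Ties in the cross-validation error are broken toward the
#' larger (sparser) penalty. Collinear features are resolved by coordinate
#' order (ascending region ID), so the outcome among exact duplicates is
#' order-dependent.
#'
#' @param features A `region_feature_matrix` (subjects x regions) or plain
#'   numeric matrix with region IDs as column names.
#' @param labels Diagnosis labels aligned with the rows of `features`.
#' @param variant `"lasso"` or `"adaptive_lasso"`.
#' @param lambda Optional fixed penalty; skips cross-validation.
#' @param n_lambda,lambda_min_ratio Penalty grid: `n_lambda` log-spaced
#'   values from \eqn{\lambda_{max}} down to
#'   \eqn{\lambda_{max} \cdot} `lambda_min_ratio`.
#' @param n_folds Folds for the internal cross-validation.
#' @param weight_method Passed to [fit_adaptive_lasso()].
#' @return A list of class `selection_result`: `coefficients` (original
#'   scale), `coefficients_std` (standardised scale), `intercept`,
#'   `selected_regions` (column names), `selected_idx`, `lambda_used`,
#'   `lambda_grid`, `cv_error` (mean CV squared error per grid point),
#'   `variant`, `dropped_columns`.
#' @export
select_regions <- function(features, labels,
                           variant = c("lasso", "adaptive_lasso"),
                           lambda = NULL, n_lambda = 50,
                           lambda_min_ratio = 1e-3, n_folds = 5,
                           weight_method = c("ols", "ridge")) {
  variant <- match.arg(variant)
  weight_method <- match.arg(weight_method)
  x <- as.matrix(unclass(features))
  if (is.null(colnames(x))) colnames(x) <- as.character(seq_len(ncol(x)))
  y <- encode_labels(labels)
  if (length(unique(y)) < 2) stop("labels must cover at least two classes")
  stopifnot(nrow(x) == length(y))

  all_missing <- colSums(!is.na(x)) == 0
  if (any(all_missing)) {
    warning("dropping all-missing column(s): ",
            paste(colnames(x)[all_missing], collapse = ", "))
    x <- x[, !all_missing, drop = FALSE]
  }
  if (anyNA(x)) stop("features contain partially missing columns")
  sds <- apply(x, 2, sd)
  constant <- sds == 0
  if (any(constant)) {
    warning("dropping constant column(s): ",
            paste(colnames(x)[constant], collapse = ", "))
    x <- x[, !constant, drop = FALSE]
    sds <- sds[!constant]
  }
  dropped <- c(names(all_missing)[all_missing], names(constant)[constant])
  mus <- colMeans(x)
  xs <- scale(x, center = mus, scale = sds)

  fitter <- function(x, y, lambda, w_init = NULL, tol = 1e-10) {
    if (variant == "lasso")
      fit_lasso(x, y, lambda, w_init = w_init, tol = tol)
    else
      fit_adaptive_lasso(x, y, lambda, weight_method = weight_method, tol = tol)
  }

  lam_max <- lambda_max(xs, y)
  if (is.null(lambda)) {
    grid <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                    length.out = n_lambda))
    folds <- sample(rep_len(seq_len(n_folds), length(y)))
    cv_err <- matrix(NA_real_, n_folds, n_lambda)
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      w_prev <- NULL
      for (l in seq_along(grid)) {
        # looser tolerance inside CV: only the held-out error matters here
        fit <- fitter(xs[tr, , drop = FALSE], y[tr], grid[l],
                      w_init = w_prev, tol = 1e-8)
        w_prev <- fit$coefficients
        if (fit$variant == "adaptive_lasso") w_prev <- NULL
        pred <- fit$intercept + drop(xs[!tr, , drop = FALSE] %*% fit$coefficients)
        cv_err[f, l] <- mean((y[!tr] - pred)^2)
      }
    }
    mean_err <- colMeans(cv_err)
    lambda <- grid[which.min(mean_err)]  # first minimum = largest lambda
  } else {
    grid <- lambda
    mean_err <- NA_real_
  }

  fit <- fitter(xs, y, lambda)
  w_std <- fit$coefficients
  w_orig <- w_std / sds
  sel <- which(abs(w_std) > 1e-8)
  structure(list(coefficients = w_orig,
                 coefficients_std = w_std,
                 intercept = fit$intercept - sum(w_orig * mus),
                 selected_regions = colnames(x)[sel],
                 selected_idx = sel,
                 lambda_used = lambda,
                 lambda_grid = grid,
                 cv_error = mean_err,
                 variant = variant,
                 dropped_columns = dropped,
                 fit = fit),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Region selection (%s): lambda = %.4g, %d region(s) selected\n",
              x$variant, x$lambda_used, length(x$selected_regions)))
  if (length(x$selected_regions))
    cat("  ", paste(x$selected_regions, collapse = ", "), "\n")
  invisible(x)
}
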