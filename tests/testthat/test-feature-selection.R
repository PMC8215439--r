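# Lasso / Adaptive Lasso solver correctness and region selection behaviour.

test_that("single-feature fit matches the closed-form soft-threshold solution", {
  x <- matrix(c(-1.2, -0.5, 0.1, 0.7, 1.3), ncol = 1)
  y <- c(-2.0, -0.8, 0.3, 1.1, 2.2)
  for (lam in c(0, 0.5, 2, 10)) {
    fit <- fit_lasso(x, y, lam, intercept = FALSE)
    want <- soft_threshold(sum(x * y), lam / 2) / sum(x^2)
    expect_equal(unname(fit$coefficients), want, tolerance = 1e-8)
  }
})

test_that("lambda = 0 reproduces least squares; lambda >= lambda_max kills all coefficients", {
  inst <- random_instance(10, 3, seed = 21)
  fit0 <- fit_lasso(inst$x, inst$y, 0)
  ols <- lm.fit(cbind(1, inst$x), inst$y)$coefficients
  expect_equal(unname(fit0$coefficients), unname(ols[-1]), tolerance = 1e-4)
  expect_equal(fit0$intercept, unname(ols[1]), tolerance = 1e-4)

  lmax <- lambda_max(inst$x, inst$y)
  for (lam in c(lmax, lmax * 1.5)) {
    fit <- fit_lasso(inst$x, inst$y, lam)
    expect_length(fit$selected, 0)
    expect_equal(unname(fit$coefficients), rep(0, 3))
  }
  # just below lambda_max, something enters
  expect_gt(length(fit_lasso(inst$x, inst$y, lmax * 0.95)$selected), 0)
})

test_that("solver objective meets the exhaustive grid-search oracle on d <= 3", {
  cases <- list(list(m = 6, d = 1, seed = 31), list(m = 8, d = 2, seed = 32),
                list(m = 8, d = 3, seed = 33), list(m = 12, d = 3, seed = 34))
  for (cs in cases) {
    inst <- random_instance(cs$m, cs$d, cs$seed)
    for (lam in c(0.1, 1)) {
      fit <- fit_lasso(inst$x, inst$y, lam, intercept = FALSE)
      expect_lt(max(abs(fit$coefficients)), 2)  # optimum inside the grid box
      oracle <- lasso_grid_oracle(inst$x, inst$y, lam, step = 0.01)
      expect_lte(fit$objective, oracle + 1e-4)
    }
  }
})

test_that("the penalised objective is non-increasing across sweeps", {
  inst <- random_instance(15, 3, seed = 41, noise = 0.5)
  for (lam in c(0.05, 1, 5)) {
    fit <- fit_lasso(inst$x, inst$y, lam)
    expect_true(all(diff(fit$objective_trace) <= 1e-9))
  }
})

test_that("adaptive lasso reduces to plain lasso under unit weights", {
  inst <- random_instance(12, 3, seed = 51)
  for (lam in c(0.2, 1.5)) {
    a <- fit_adaptive_lasso(inst$x, inst$y, lam, adaptive_weights = rep(1, 3))
    p <- fit_lasso(inst$x, inst$y, lam)
    expect_equal(a$coefficients, p$coefficients, tolerance = 1e-7)
    expect_equal(a$intercept, p$intercept, tolerance = 1e-7)
  }
})

test_that("adaptive weights rescale the per-feature penalty as 1/|w|", {
  # orthogonal two-feature design
  x <- cbind(c(1, 1, -1, -1, 1, -1) / sqrt(6) * 2,
             c(1, -1, 1, -1, -1, 1) / sqrt(6) * 2)
  x <- scale(x, center = TRUE, scale = FALSE)
  set.seed(61)
  y <- drop(x %*% c(0.8, 0.8)) + rnorm(6, sd = 0.05)
  lam <- 1
  fit <- fit_adaptive_lasso(x, y, lam, adaptive_weights = c(10, 0.1),
                            intercept = FALSE)
  # support/objective agree with the brute-force grid under pf = 1/|w|
  oracle <- lasso_grid_oracle(x, y, lam, pf = c(1 / 10, 1 / 0.1), step = 0.01)
  pen <- sum(abs(fit$coefficients) / c(10, 0.1))
  obj <- sum((y - drop(x %*% fit$coefficients))^2) + lam * pen
  expect_lte(obj, oracle + 1e-4)
  # feature 1 (weakly penalised) survives; feature 2 is shrunk to zero
  expect_gt(abs(fit$coefficients[1]), 1e-3)
  expect_equal(unname(fit$coefficients[2]), 0)

  # lambda = 0: OLS regardless of weights
  inst <- random_instance(12, 3, seed = 62)
  a0 <- fit_adaptive_lasso(inst$x, inst$y, 0, adaptive_weights = c(9, 0.3, 2))
  ols <- lm.fit(cbind(1, inst$x), inst$y)$coefficients
  expect_equal(unname(a0$coefficients), unname(ols[-1]), tolerance = 1e-4)

  # zero adaptive weight excludes the feature a priori
  expect_message(
    az <- fit_adaptive_lasso(inst$x, inst$y, 0.1,
                             adaptive_weights = c(0, 1, 1)),
    "excluded")
  expect_equal(unname(az$coefficients[1]), 0)
})

test_that("solution agrees with an independent solver (glmnet)", {
  skip_if_not_installed("glmnet")
  inst <- random_instance(30, 5, seed = 71, noise = 0.3)
  m <- nrow(inst$x)
  for (lam in c(0.5, 3)) {
    fit <- fit_lasso(inst$x, inst$y, lam)
    # glmnet minimises RSS/(2m) + lambda ||w||_1
    g <- glmnet::glmnet(inst$x, inst$y, lambda = lam / (2 * m),
                        standardize = FALSE, thresh = 1e-14)
    expect_equal(unname(fit$coefficients),
                 as.numeric(coef(g))[-1], tolerance = 1e-4)
    expect_lt(abs(fit$intercept - as.numeric(coef(g))[1]), 1e-5)
  }
})

test_that("support shrinks monotonically with lambda on an orthonormal design", {
  set.seed(81)
  q <- qr.Q(qr(matrix(rnorm(64), 8, 8)))[, 1:5]
  y <- drop(q %*% c(2, -1.5, 1, -0.5, 0.2)) # exact, no noise
  lmax <- lambda_max(q, y, intercept = FALSE)
  grid <- lmax * c(0.01, 0.05, 0.2, 0.5, 0.9, 1)
  prev <- NULL
  for (lam in grid) {
    sel <- fit_lasso(q, y, lam, intercept = FALSE)$selected
    if (!is.null(prev)) expect_true(all(sel %in% prev))
    prev <- sel
  }
  expect_length(prev, 0)  # at lambda_max nothing survives
})

test_that("select_regions recovers known effect regions and resists duplicates", {
  spec <- cohort_spec(seed = 1)
  co <- generate_cohort(spec)
  fm <- build_feature_matrix(co$volumes, co$atlas)
  set.seed(1)
  sel <- select_regions(fm, co$labels$class, "lasso")
  expect_true(all(as.character(spec$effect_regions) %in% sel$selected_regions))
  set.seed(1)
  sel_a <- select_regions(fm, co$labels$class, "adaptive_lasso")
  expect_true(all(as.character(spec$effect_regions) %in% sel_a$selected_regions))

  # appending an exact duplicate of a selected column leaves the optimum
  # objective unchanged (collinear degeneracy; split is order-dependent)
  xs <- scale(unclass(fm))
  y <- encode_labels(co$labels$class)
  lam <- sel$lambda_used
  base <- fit_lasso(xs, y, lam)
  dup <- cbind(xs, xs[, sel$selected_idx[1]])
  dup_fit <- fit_lasso(dup, y, lam)
  expect_equal(dup_fit$objective, base$objective, tolerance = 1e-6)
})

test_that("null cohorts yield near-empty selections", {
  # no true effects anywhere: CV-chosen penalty should keep the model sparse
  sizes <- vapply(1:5, function(s) {
    co0 <- generate_cohort(cohort_spec(effect_sizes = matrix(0, 3, 3),
                                       seed = s))
    f0 <- build_feature_matrix(co0$volumes, co0$atlas)
    set.seed(s)
    length(select_regions(f0, co0$labels$class, "lasso")$selected_regions)
  }, numeric(1))
  expect_lte(median(sizes), 2)
  expect_lte(max(sizes), 8)  # never anywhere near the full 16 regions
})

test_that("select_regions validates inputs and drops degenerate columns", {
  co <- generate_cohort(small_cohort_spec(seed = 9))
  fm <- unclass(build_feature_matrix(co$volumes, co$atlas))
  expect_error(select_regions(fm, rep("NC", nrow(fm))), "two classes")
  fm_bad <- cbind(fm, bad = NA_real_)
  set.seed(2)
  expect_warning(sel <- select_regions(fm_bad, co$labels$class), "all-missing")
  expect_false("bad" %in% sel$selected_regions)
})
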