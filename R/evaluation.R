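# Repeated stratified random subsampling evaluation (62 train / 7 test by
# default, 100 repeats), with in-repeat region selection to avoid leakage.

#' Plan for a repeated train/test evaluation
#'
#' @param n_train,n_test Training and test set sizes; must sum to the cohort
#'   size at evaluation time. Defaults 62 / 7.
#' @param n_repeats Number of random splits (default 100).
#' @param selection_variant `"lasso"` or `"adaptive_lasso"` (used when
#'   `selection_mode = "within_fold"`).
#' @param classifiers Character vector of classifier kinds (see
#'   [make_classifier()]).
#' @param selection_mode `"within_fold"` (default; regions are re-selected
#'   from each repeat's training subjects, so test subjects never influence
#'   selection) or `"fixed"` (use `fixed_regions` throughout).
#' @param fixed_regions Region column names used when
#'   `selection_mode = "fixed"`.
#' @param stratified Stratify splits by class (default) so every class is
#'   represented in training.
#' @param seed Integer seed driving all splits.
#' @return An object of class `evaluation_plan`.
#' @export
evaluation_plan <- function(n_train = 62, n_test = 7, n_repeats = 100,
                            selection_variant = c("lasso", "adaptive_lasso"),
                            classifiers = .CLASSIFIER_KINDS,
                            selection_mode = c("within_fold", "fixed"),
                            fixed_regions = NULL,
                            stratified = TRUE, seed = 1) {
  selection_variant <- match.arg(selection_variant)
  selection_mode <- match.arg(selection_mode)
  classifiers <- vapply(classifiers, .canon_kind, character(1))
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  if (selection_mode == "fixed" && is.null(fixed_regions))
    stop("selection_mode = 'fixed' requires fixed_regions")
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 n_repeats = as.integer(n_repeats),
                 selection_variant = selection_variant,
                 classifiers = unname(classifiers),
                 selection_mode = selection_mode,
                 fixed_regions = fixed_regions,
                 stratified = stratified, seed = as.integer(seed)),
            class = "evaluation_plan")
}

# largest-remainder allocation of n_test across classes, >= proportional
.stratified_test_idx <- function(labels, n_test) {
  tab <- table(labels)
  tab <- tab[tab > 0]
  quota <- n_test * as.numeric(tab) / length(labels)
  take <- floor(quota)
  rem <- n_test - sum(take)
  if (rem > 0) {
    ord <- order(quota - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
  }
  # never exhaust a class's training examples
  take <- pmin(take, as.numeric(tab) - 1)
  idx <- unlist(lapply(seq_along(tab), function(k) {
    pool <- which(labels == names(tab)[k])
    sample(pool, take[k])
  }))
  sort(idx)
}

#' Run a repeated train/test classification evaluation
#'
#' For each repeat: draw a (stratified) random train/test split, select
#' regions on the training subjects only (default) or use a fixed region
#' set, standardise features with training statistics, train every
#' classifier in the plan, and score three-class accuracy on the held-out
#' subjects. Deterministic given `plan$seed`.
#'
#' If a repeat's selection is empty, all regions are used for that repeat
#' (recorded in the result). Provenance of every repeat (test subjects and
#' the subjects that drove selection) is retained so leakage can be audited.
#'
#' @param features A `region_feature_matrix` or numeric matrix
#'   (subjects x regions).
#' @param labels Diagnosis labels (`NC`/`MCI`/`AD`) aligned with rows.
#' @param plan An [evaluation_plan()].
#' @return An object of class `accuracy_table`: `per_repeat` (repeats x
#'   classifiers accuracy matrix), `mean` (per-classifier mean accuracy),
#'   `provenance` (per-repeat test/selection subject indices and the
#'   selected regions), and the `plan`.
#' @export
run_evaluation <- function(features, labels, plan) {
  stopifnot(inherits(plan, "evaluation_plan"))
  x <- as.matrix(unclass(features))
  labels <- factor(as.character(labels), levels = CLASS_LEVELS)
  labels <- droplevels(labels)
  n <- nrow(x)
  if (length(labels) != n) stop("labels must align with feature rows")
  if (plan$n_train + plan$n_test != n)
    stop(sprintf("plan sizes %d + %d do not sum to cohort size %d",
                 plan$n_train, plan$n_test, n))
  factories <- lapply(plan$classifiers, make_classifier)
  names(factories) <- plan$classifiers

  set.seed(plan$seed)
  repeat_seeds <- sample.int(.Machine$integer.max - 1L, plan$n_repeats)
  acc <- matrix(NA_real_, plan$n_repeats, length(factories),
                dimnames = list(NULL, plan$classifiers))
  prov <- vector("list", plan$n_repeats)

  for (r in seq_len(plan$n_repeats)) {
    set.seed(repeat_seeds[r])
    repeat {
      test_idx <- if (plan$stratified)
        .stratified_test_idx(labels, plan$n_test)
      else
        sort(sample(n, plan$n_test))
      if (length(unique(labels[-test_idx])) == length(levels(labels))) break
      message("redrawing split: a class was missing from training")
    }
    train_idx <- setdiff(seq_len(n), test_idx)

    if (plan$selection_mode == "within_fold") {
      sel <- select_regions(x[train_idx, , drop = FALSE], labels[train_idx],
                            variant = plan$selection_variant)
      regions <- sel$selected_regions
    } else {
      regions <- plan$fixed_regions
    }
    fallback <- length(regions) == 0
    if (fallback) regions <- colnames(x)

    xtr <- x[train_idx, regions, drop = FALSE]
    xte <- x[test_idx, regions, drop = FALSE]
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2, sd)
    sdv[sdv == 0] <- 1
    xtr <- scale(xtr, mu, sdv)
    xte <- scale(xte, mu, sdv)
    ytr <- labels[train_idx]

    for (k in seq_along(factories)) {
      fac <- factories[[k]]
      model <- fac$fit(xtr, ytr)
      pred <- fac$predict(model, xte)
      acc[r, k] <- mean(as.character(pred) == as.character(labels[test_idx]))
    }
    prov[[r]] <- list(test_idx = test_idx,
                      selection_input_idx = if (plan$selection_mode == "within_fold")
                        train_idx else integer(0),
                      regions = regions, empty_selection = fallback)
  }
  structure(list(per_repeat = acc, mean = colMeans(acc),
                 provenance = prov, plan = plan),
            class = "accuracy_table")
}

#' @export
print.accuracy_table <- function(x, ...) {
  cat(sprintf("Three-class accuracy over %d repeats (%s selection, %d/%d split):\n",
              x$plan$n_repeats, x$plan$selection_variant,
              x$plan$n_train, x$plan$n_test))
  print(round(x$mean, 4))
  invisible(x)
}
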