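# Three-class classifier factories with the study's hyperparameters:
# AdaBoost (SAMME, 100 rounds, learning rate 0.1, stump base learner),
# linear max-margin SVM (cost 1), decision tree of depth 4, and
# gradient-boosted trees of depth 5 with a softmax multiclass objective.

.CLASSIFIER_KINDS <- c("adaboost", "linear_svm", "decision_tree", "xgboost")

.canon_kind <- function(kind) {
  aliases <- c("adaboost" = "adaboost", "adaptive-boosting" = "adaboost",
               "linear_svm" = "linear_svm", "linear max-margin" = "linear_svm",
               "linearsvc" = "linear_svm", "svm" = "linear_svm",
               "decision_tree" = "decision_tree", "decision-tree" = "decision_tree",
               "randomtree" = "decision_tree",
               "xgboost" = "xgboost", "gradient-boosted-trees" = "xgboost")
  k <- aliases[tolower(kind)]
  if (is.na(k)) stop("unknown classifier kind: ", kind)
  unname(k)
}

#' Create a classifier factory
#'
#' Returns a factory honouring the study hyperparameters: boosting runs 100
#' rounds at learning rate 0.1 on decision-stump base learners; the single
#' decision tree has depth 4; the gradient-boosted trees have maximum depth 5
#' with a softmax multiclass objective (100 rounds, shrinkage 0.3); the
#' linear max-margin classifier uses cost `C = 1`.
#'
#' @param kind One of `"adaboost"` (alias `"adaptive-boosting"`),
#'   `"linear_svm"` (`"linear max-margin"`), `"decision_tree"`
#'   (`"decision-tree"`), `"xgboost"` (`"gradient-boosted-trees"`).
#' @return A list of class `classifier_factory` with elements `kind`,
#'   `config` (named hyperparameters), `fit(x, y)` returning a model, and
#'   `predict(model, x)` returning a factor with the training levels.
#' @export
make_classifier <- function(kind) {
  kind <- .canon_kind(kind)
  obj <- switch(kind,
    adaboost = list(
      config = list(n_rounds = 100L, learning_rate = 0.1, base_depth = 1L),
      fit = function(x, y) .samme_fit(x, y, n_rounds = 100L,
                                      learning_rate = 0.1, base_depth = 1L),
      predict = function(model, x) .samme_predict(model, x)),
    linear_svm = list(
      config = list(kernel = "linear", cost = 1),
      fit = function(x, y) e1071::svm(x, y, kernel = "linear", cost = 1,
                                      scale = FALSE),
      predict = function(model, x) predict(model, x)),
    decision_tree = list(
      config = list(max_depth = 4L),
      fit = function(x, y) {
        df <- data.frame(.y = y, x, check.names = FALSE)
        rpart::rpart(.y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(maxdepth = 4, cp = 0,
                                                    minsplit = 2, xval = 0))
      },
      predict = function(model, x) {
        p <- predict(model, data.frame(x, check.names = FALSE), type = "class")
        factor(as.character(p), levels = attr(model, "ylevels"))
      }),
    xgboost = list(
      config = list(max_depth = 5L, objective = "multi:softmax",
                    n_rounds = 100L, eta = 0.3),
      fit = function(x, y) {
        lev <- levels(y)
        dtrain <- xgboost::xgb.DMatrix(as.matrix(x),
                                       label = as.integer(y) - 1L)
        m <- xgboost::xgb.train(params = list(max_depth = 5,
                                              objective = "multi:softmax",
                                              num_class = length(lev),
                                              eta = 0.3, nthread = 1),
                                data = dtrain, nrounds = 100, verbose = 0)
        attr(m, "levels") <- lev
        m
      },
      predict = function(model, x) {
        p <- predict(model, as.matrix(x))
        factor(attr(model, "levels")[p + 1L], levels = attr(model, "levels"))
      })
  )
  structure(c(list(kind = kind), obj), class = "classifier_factory")
}

# SAMME multi-class AdaBoost on rpart stumps with case weights.
.samme_fit <- function(x, y, n_rounds, learning_rate, base_depth) {
  y <- droplevels(as.factor(y))
  lev <- levels(y)
  k <- length(lev)
  n <- length(y)
  d <- rep(1 / n, n)
  df <- data.frame(.y = y, x, check.names = FALSE)
  trees <- list()
  alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = base_depth, cp = -1, minsplit = 2,
                               xval = 0, maxcompete = 0, maxsurrogate = 0)
  for (t in seq_len(n_rounds)) {
    tree <- rpart::rpart(.y ~ ., data = df, weights = d, method = "class",
                         control = ctrl)
    pred <- as.character(predict(tree, df, type = "class"))
    miss <- pred != as.character(y)
    err <- sum(d[miss])
    if (err >= 1 - 1 / k) break           # worse than chance: stop
    err <- max(err, 1e-12)
    alpha <- learning_rate * (log((1 - err) / err) + log(k - 1))
    d <- d * exp(alpha * miss)
    d <- d / sum(d)
    trees[[length(trees) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    if (err < 1e-12) break                 # perfect stump: no reweighting left
  }
  list(trees = trees, alphas = alphas, levels = lev)
}

.samme_predict <- function(model, x) {
  df <- data.frame(x, check.names = FALSE)
  votes <- matrix(0, nrow(df), length(model$levels),
                  dimnames = list(NULL, model$levels))
  for (t in seq_along(model$trees)) {
    pred <- as.character(predict(model$trees[[t]], df, type = "class"))
    idx <- cbind(seq_len(nrow(df)), match(pred, model$levels))
    votes[idx] <- votes[idx] + model$alphas[t]
  }
  factor(model$levels[max.col(votes, ties.method = "first")],
         levels = model$levels)
}

#' @export
print.classifier_factory <- function(x, ...) {
  cfg <- paste(names(x$config), unlist(x$config), sep = "=", collapse = ", ")
  cat(sprintf("Classifier factory '%s' (%s)\n", x$kind, cfg))
  invisible(x)
}
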