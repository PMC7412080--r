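#' Fit an activity classifier on a windowed feature table
#'
#' The modelling heart of the package. Trains either a random forest (500
#' trees by default, Breiman's algorithm, `mtry = floor(sqrt(p))`) or a
#' support vector machine with the radial-basis-function kernel on the
#' windowed statistics, predicting the window's activity label. Undefined
#' feature entries are filled with per-feature training medians that are
#' frozen into the model (see [fill_undefined()]); for the SVM, features are
#' additionally standardized with training-set mean and standard deviation
#' only, and the default kernel width follows the
#' `gamma = 1/(p * var(X_scaled))` heuristic. Fits are deterministic given
#' `seed`.
#'
#' To make a model robust to test-time sample loss, train it on features
#' extracted from a stream corrupted with [induce_mar()] at the missing rate
#' expected in deployment — see [run_scenario()] for the packaged protocols.
#'
#' @param features A `har_features` table from [featurize()] with at least
#'   two classes present.
#' @param classifier `"random_forest"` or `"svm_rbf"`.
#' @param n_trees Number of trees for the random forest (default 500).
#' @param svm_c SVM soft-margin cost (default 1).
#' @param rbf_gamma RBF kernel width, or `"auto"` for the variance heuristic.
#' @param seed Integer seed for the (stochastic) forest fit.
#' @return An object of class `har_model` with `print`, `summary` and
#'   `predict` methods.
#' @examples
#' d <- build_simulated_dataset(n_per_class = 200)
#' ft <- featurize(d$train, window_config(1, 0.5))
#' m <- har_fit(ft)
#' m
#' predict(m, featurize(d$test, window_config(1, 0.5)))
#' @export
har_fit <- function(features, classifier = c("random_forest", "svm_rbf"),
                    n_trees = 500L, svm_c = 1, rbf_gamma = "auto",
                    seed = 1L) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(features, "har_features"))
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  filled <- fill_undefined(features)
  y <- factor(filled$labels)
  if (nlevels(y) < 2L)
    stop("training data must contain at least two classes", call. = FALSE)
  x <- filled$matrix

  center <- scale_sd <- NULL
  gamma <- NULL
  fit <- switch(classifier,
    random_forest = with_seed(seed,
      randomForest::randomForest(x = x, y = y, ntree = as.integer(n_trees))),
    svm_rbf = {
      center <- colMeans(x)
      scale_sd <- apply(x, 2L, stats::sd)
      scale_sd[scale_sd == 0 | !is.finite(scale_sd)] <- 1
      xs <- sweep(sweep(x, 2L, center), 2L, scale_sd, "/")
      gamma <- if (identical(rbf_gamma, "auto")) {
        v <- stats::var(as.vector(xs))
        1 / (ncol(xs) * if (v > 0) v else 1)
      } else rbf_gamma
      with_seed(seed,
        e1071::svm(x = xs, y = y, kernel = "radial", cost = svm_c,
                   gamma = gamma, scale = FALSE))
    })

  structure(
    list(fit = fit, classifier = classifier,
         feature_cols = attr(features, "feature_cols"),
         fill_medians = filled$medians, levels = levels(y),
         center = center, scale_sd = scale_sd,
         config = list(n_trees = as.integer(n_trees), svm_c = svm_c,
                       rbf_gamma = gamma, seed = as.integer(seed)),
         n_train = nrow(x)),
    class = "har_model"
  )
}

#' Predict activity labels for new windows
#'
#' @param object A [har_fit()] model.
#' @param newdata A `har_features` table whose feature columns match the
#'   training schema.
#' @param ... Unused.
#' @return Factor of predicted labels, one per window, with the training
#'   class levels.
#' @export
predict.har_model <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "har_features"))
  if (!all(object$feature_cols %in% attr(newdata, "feature_cols")))
    stop("feature columns of newdata do not match the training schema",
         call. = FALSE)
  filled <- fill_undefined(newdata[, c("subject_id", "window_start", "label",
                                       "n_valid", object$feature_cols)],
                           medians = object$fill_medians)
  x <- filled$matrix[, object$feature_cols, drop = FALSE]
  if (object$classifier == "svm_rbf")
    x <- sweep(sweep(x, 2L, object$center), 2L, object$scale_sd, "/")
  p <- stats::predict(object$fit, x)
  factor(as.character(p), levels = object$levels)
}

#' @export
print.har_model <- function(x, ...) {
  cat(sprintf("<har_model> %s on %d features, %d training windows\n",
              x$classifier, length(x$feature_cols), x$n_train))
  cat("  classes:", paste(x$levels, collapse = ", "), "\n")
  if (x$classifier == "random_forest")
    cat("  trees:", x$config$n_trees, "\n")
  else
    cat(sprintf("  cost %g, gamma %.4g\n", x$config$svm_c, x$config$rbf_gamma))
  invisible(x)
}

#' @export
summary.har_model <- function(object, ...) {
  print(object)
  if (object$classifier == "random_forest") {
    imp <- randomForest::importance(object$fit)
    ord <- order(imp[, 1L], decreasing = TRUE)
    cat("  top features by Gini importance:\n")
    top <- utils::head(rownames(imp)[ord], 5L)
    for (f in top) cat(sprintf("    %-10s %8.2f\n", f, imp[f, 1L]))
  }
  invisible(object)
}

#' Evaluate a fitted model on a feature table
#'
#' @param model A [har_fit()] model.
#' @param features A labeled `har_features` test table.
#' @return A `har_eval`: window-level `accuracy` (correct/total), the
#'   `confusion` matrix (rows = truth, columns = prediction) and `per_class`
#'   recall.
#' @export
evaluate_model <- function(model, features) {
  pred <- predict(model, features)
  truth <- factor(features$label, levels = union(model$levels,
                                                 unique(features$label)))
  pred <- factor(as.character(pred), levels = levels(truth))
  confusion <- table(truth = truth, predicted = pred)
  acc <- mean(as.character(pred) == as.character(truth))
  per_class <- diag(confusion) / pmax(rowSums(confusion), 1L)
  structure(list(accuracy = acc, confusion = confusion,
                 per_class = per_class, n = length(pred)),
            class = "har_eval")
}

#' @export
print.har_eval <- function(x, ...) {
  cat(sprintf("<har_eval> accuracy %.3f over %d windows\n", x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}

#' Leave-one-person-out cross-validation folds
#'
#' One fold per subject: the fold's test set is every window of that subject
#' and its training set is every other subject's windows, so no person
#' appears on both sides of any fold.
#'
#' @param features A `har_features` table with `subject_id` populated.
#' @return List of folds, each `list(train_ids, test_id)`.
#' @export
lopo_splits <- function(features) {
  ids <- unique(features$subject_id)
  if (length(ids) == 0L || anyNA(ids))
    stop("subject ids are required for leave-one-person-out folds",
         call. = FALSE)
  lapply(ids, function(id) list(train_ids = setdiff(ids, id), test_id = id))
}
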