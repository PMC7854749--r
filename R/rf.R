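#' Random forest configuration
#'
#' The printed classifier settings: 100 trees, minimum leaf population 10,
#' variables per split = floor(sqrt(n_features)), bag fraction 0.5 (drawn
#' without replacement), plus the training seed. `variables_per_split = NULL`
#' defers the square-root default until the feature count is known.
#'
#' @param n_trees Number of CART trees (default 100).
#' @param min_leaf Minimum samples in a leaf (default 10).
#' @param variables_per_split mtry; `NULL` for floor(sqrt(p)).
#' @param bag_fraction Per-tree subsample fraction (default 0.5).
#' @param seed Integer training seed.
#' @return An `rf_config` list.
#' @export
rf_config <- function(n_trees = 100L, min_leaf = 10L, variables_per_split = NULL,
                      bag_fraction = 0.5, seed = 1L) {
  stopifnot(n_trees >= 1, min_leaf >= 1, bag_fraction > 0, bag_fraction <= 1)
  structure(list(n_trees = as.integer(n_trees), min_leaf = as.integer(min_leaf),
                 variables_per_split = variables_per_split,
                 bag_fraction = bag_fraction, seed = as.integer(seed)),
            class = "rf_config")
}

#' Fit a random forest classifier
#'
#' CART trees with Gini impurity; the forest also yields Mean Decrease
#' Impurity (MDI) importances normalised to sum 1. Deterministic for a fixed
#' `cfg$seed`.
#'
#' @param X Numeric feature matrix with column names.
#' @param y Class labels (integer codes or factor); at least 2 classes.
#' @param cfg An [rf_config()].
#' @return A `crop_rf` model.
#' @export
rf_fit <- function(X, y, cfg = rf_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("training labels contain a single class")
  yi <- match(y, classes) - 1L
  mtry <- cfg$variables_per_split
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  set.seed(cfg$seed)
  fit <- rf_train_cpp(X, as.integer(yi), length(classes), cfg$n_trees,
                      cfg$min_leaf, as.integer(mtry), cfg$bag_fraction)
  structure(list(forest = fit, classes = classes,
                 features = colnames(X), cfg = cfg,
                 importance = stats::setNames(as.numeric(fit$importance),
                                              colnames(X))),
            class = "crop_rf")
}

#' Predict from a fitted random forest
#'
#' @param object A `crop_rf` model.
#' @param newdata Feature matrix; columns must match the training features by
#'   name (any order). A mismatch is an error, not a reorder-silently.
#' @param type `"class"` for labels, `"prob"` for vote fractions.
#' @param ... Unused.
#' @return Labels (same type as training `y`) or an n x K probability matrix.
#' @export
predict.crop_rf <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(object$features))
      stop("feature count mismatch with the trained model")
    colnames(newdata) <- object$features
  }
  if (!all(object$features %in% colnames(newdata)))
    stop("feature names do not match the trained model: missing ",
         paste(utils::head(setdiff(object$features, colnames(newdata)), 3L),
               collapse = ", "))
  newdata <- newdata[, object$features, drop = FALSE]
  votes <- rf_votes_cpp(object$forest, newdata)
  if (type == "prob") {
    pr <- votes / rowSums(votes)
    colnames(pr) <- as.character(object$classes)
    return(pr)
  }
  object$classes[max.col(votes, ties.method = "first")]
}
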