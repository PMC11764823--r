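#' Random-forest settings
#'
#' @param n_trees Trees per forest (default 500).
#' @param mtry Features sampled per split; \code{NULL} (default) requests
#'   cross-validated selection over the full candidate grid 1..p.
#' @param cv_folds Folds for mtry selection (default 5).
#' @param seed Integer seed governing fold assignment and forest growth.
#' @return Object of class \code{forest_settings}.
#' @export
forest_settings <- function(n_trees = 500, mtry = NULL, cv_folds = 5,
                            seed = 1) {
  stopifnot(n_trees >= 1, cv_folds >= 2)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "forest_settings")
}

# Feature matrix and food-id factor from an eating-labeled IU table.
.iu_xy <- function(iu_table) {
  feats <- iu_features(iu_table)
  if (!length(feats)) stop("iu_table has no *_slope feature columns")
  list(x = iu_table[, feats, drop = FALSE],
       y = factor(iu_table$food_id, levels = sort(unique(iu_table$food_id))))
}

# Stratified fold assignment: within each class, shuffled samples are dealt
# round-robin across folds, so every fold sees every class when possible.
.stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
  }
  folds
}

#' Select mtry by stratified k-fold cross-validation
#'
#' Searches the whole candidate grid \code{1..p} (p = number of slope
#' features), fitting one forest per fold and candidate, and returns the
#' candidate maximising the global validation accuracy — the proportion of
#' correctly predicted IUs pooled over all validation folds. Ties go to the
#' smallest mtry (the cheapest, weakest trees). Folds are stratified by food
#' class; when the rarest class has fewer IUs than \code{cv_folds}, the fold
#' count is reduced with a warning.
#'
#' @param iu_table Eating-labeled IU table (rows = training IUs) with
#'   \code{food_id} targets and \code{*_slope} features.
#' @param settings A \code{\link{forest_settings}}.
#' @return List with \code{mtry} (chosen value), \code{accuracy} (data
#'   frame of the full per-candidate accuracy curve) and \code{cv_folds}
#'   (folds actually used).
#' @export
select_mtry_cv <- function(iu_table, settings = forest_settings()) {
  d <- .iu_xy(iu_table)
  if (nlevels(d$y) < 2) {
    stop("mtry selection needs at least 2 food classes; got ",
         nlevels(d$y))
  }
  p <- ncol(d$x)
  if (p == 1) {
    return(list(mtry = 1L,
                accuracy = data.frame(mtry = 1L, accuracy = NA_real_),
                cv_folds = settings$cv_folds))
  }
  k <- settings$cv_folds
  min_class <- min(table(d$y))
  if (min_class < k) {
    k <- max(2L, min_class)
    warning("rarest food class has ", min_class,
            " IUs; reducing CV folds to ", k)
  }
  set.seed(split_seed(settings$seed, "folds"))
  folds <- .stratified_folds(d$y, k)
  correct <- integer(p)
  for (m in seq_len(p)) {
    for (f in seq_len(k)) {
      train <- folds != f
      set.seed(split_seed(settings$seed, "cv", m, f))
      rf <- randomForest::randomForest(
        x = d$x[train, , drop = FALSE], y = d$y[train],
        ntree = settings$n_trees, mtry = m
      )
      pred <- stats::predict(rf, d$x[!train, , drop = FALSE])
      correct[m] <- correct[m] + sum(pred == d$y[!train])
    }
  }
  acc <- correct / length(d$y)
  list(mtry = which.max(acc),  # which.max takes the first (smallest) tie
       accuracy = data.frame(mtry = seq_len(p), accuracy = acc),
       cv_folds = k)
}

#' Fit the food-item random-forest classifier
#'
#' The package's central model: a multiclass random forest predicting the
#' food item of eating-labeled Information Units from their window-slope
#' features. Each of the \code{n_trees} trees is grown to purity on a
#' bootstrap resample (with replacement) of the IUs, sampling \code{mtry}
#' candidate features at each split; in-bag identities are retained so
#' every IU can later be evaluated on the trees for which it was
#' out-of-bag. When \code{settings$mtry} is \code{NULL} the value is first
#' chosen by \code{\link{select_mtry_cv}}.
#'
#' @param iu_table Eating-labeled IU table with \code{food_id} targets and
#'   \code{*_slope} features (see \code{\link{build_ius}}).
#' @param settings A \code{\link{forest_settings}}.
#' @return Object of class \code{food_forest}: list with the fitted
#'   \code{forest} (a \code{randomForest} object with in-bag records),
#'   \code{mtry}, \code{cv} (the CV accuracy curve, or NULL if mtry was
#'   fixed), \code{settings}, \code{levels} (food ids) and the training
#'   data.
#' @seealso \code{\link{oob_metrics}}, \code{\link{scaled_importance}},
#'   \code{\link{predict.food_forest}}
#' @export
food_forest <- function(iu_table, settings = forest_settings()) {
  if (!nrow(iu_table)) stop("iu_table is empty")
  d <- .iu_xy(iu_table)
  p <- ncol(d$x)
  cv <- NULL
  mtry <- settings$mtry
  if (is.null(mtry)) {
    sel <- select_mtry_cv(iu_table, settings)
    mtry <- sel$mtry
    cv <- sel$accuracy
  }
  if (mtry > p) stop("mtry (", mtry, ") exceeds the number of features (",
                     p, ")")
  set.seed(split_seed(settings$seed, "final"))
  rf <- randomForest::randomForest(
    x = d$x, y = d$y, ntree = settings$n_trees, mtry = mtry,
    keep.inbag = TRUE
  )
  structure(list(forest = rf, mtry = as.integer(mtry), cv = cv,
                 settings = settings, levels = levels(d$y),
                 x = d$x, y = d$y),
            class = "food_forest")
}

#' @export
print.food_forest <- function(x, ...) {
  cat(sprintf("<food_forest> %d trees, mtry %d%s, %d IUs, %d foods, %d features\n",
              x$settings$n_trees, x$mtry,
              if (is.null(x$cv)) " (fixed)" else " (CV-selected)",
              nrow(x$x), length(x$levels), ncol(x$x)))
  invisible(x)
}

#' @export
summary.food_forest <- function(object, ...) {
  m <- oob_metrics(object)
  imp <- scaled_importance(object)
  out <- list(model = object, metrics = m, importance = imp)
  class(out) <- "summary.food_forest"
  out
}

#' @export
print.summary.food_forest <- function(x, ...) {
  print(x$model)
  cat("\nOut-of-bag one-vs-all performance:\n")
  print(x$metrics, row.names = FALSE, digits = 3)
  cat("\nVariable importance (mean Gini decrease, scaled 0-100):\n")
  print(x$importance, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Predict food items for new Information Units
#'
#' @param object A \code{\link{food_forest}}.
#' @param newdata IU table (or feature data frame) with the model's feature
#'   columns.
#' @param type \code{"class"} for food-id labels, \code{"vote"} for the
#'   per-class vote fractions.
#' @param ... Unused.
#' @return Factor of predicted food ids, or a vote matrix.
#' @export
predict.food_forest <- function(object, newdata,
                                type = c("class", "vote"), ...) {
  type <- match.arg(type)
  feats <- colnames(object$x)
  missing_cols <- setdiff(feats, names(newdata))
  if (length(missing_cols)) {
    stop("newdata lacks feature column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  stats::predict(object$forest, newdata[, feats, drop = FALSE],
                 type = if (type == "class") "response" else "vote")
}

#' Out-of-bag one-vs-all sensitivity and specificity per food
#'
#' Each IU's out-of-bag prediction is the majority vote among the trees for
#' which it was out-of-bag (ties broken toward the lowest food id). For
#' every food f the one-vs-all confusion is tallied on those predictions:
#' sensitivity = TP / (TP + FN) and specificity = TN / (TN + FP), treating f
#' as the positive class. IUs that were in-bag for every tree (possible only
#' with very few trees) are excluded and reported via a message; foods with
#' no evaluated IUs get NA sensitivity rather than being dropped.
#'
#' @param model A \code{\link{food_forest}}.
#' @return Data frame with columns \code{food_id}, \code{sensitivity},
#'   \code{specificity}, \code{support} (evaluated IUs of that food).
#' @export
oob_metrics <- function(model) {
  stopifnot(inherits(model, "food_forest"))
  pred <- oob_predictions(model)
  keep <- !is.na(pred)
  if (any(!keep)) {
    message(sum(!keep), " IU(s) were in-bag for every tree and are ",
            "excluded from OOB evaluation")
  }
  y <- model$y[keep]
  pred <- pred[keep]
  out <- data.frame(food_id = model$levels, sensitivity = NA_real_,
                    specificity = NA_real_, support = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(model$levels)) {
    f <- model$levels[i]
    pos <- y == f
    out$support[i] <- sum(pos)
    tp <- sum(pos & pred == f)
    tn <- sum(!pos & pred != f)
    if (any(pos)) out$sensitivity[i] <- tp / sum(pos)
    if (any(!pos)) out$specificity[i] <- tn / sum(!pos)
  }
  out
}

#' Out-of-bag majority-vote predictions
#'
#' @param model A \code{\link{food_forest}}.
#' @return Factor of OOB-predicted food ids (NA for IUs never out-of-bag).
#' @export
oob_predictions <- function(model) {
  stopifnot(inherits(model, "food_forest"))
  rf <- model$forest
  counts <- rf$votes * rf$oob.times  # votes are OOB fractions
  pred <- rep(NA_integer_, nrow(counts))
  evaluated <- rf$oob.times > 0
  # max.col with ties.method = "first" breaks ties toward the lowest food id
  # because vote columns are in sorted food-id order.
  pred[evaluated] <- max.col(counts[evaluated, , drop = FALSE],
                             ties.method = "first")
  factor(model$levels[pred], levels = model$levels)
}

#' Gini variable importance scaled to 0-100
#'
#' Raw importance is the mean over trees of the total decrease in node Gini
#' impurity attributed to splits on each variable; the scaled value maps
#' the least important variable to 0 and the most important to 100:
#' \code{100 * (raw - min) / (max - min)}. With a single feature, or when
#' all raw importances coincide, scaling is degenerate and every variable
#' is reported as 100 (with a warning in the tied case).
#'
#' @param model A \code{\link{food_forest}}.
#' @return Data frame with columns \code{variable},
#'   \code{raw_gini_decrease}, \code{scaled_0_100}.
#' @export
scaled_importance <- function(model) {
  stopifnot(inherits(model, "food_forest"))
  raw <- model$forest$importance[, "MeanDecreaseGini"]
  if (length(raw) == 1) {
    scaled <- 100
  } else if (diff(range(raw)) == 0) {
    warning("all variables have identical raw importance; ",
            "scaling is degenerate, reporting 100 for every variable")
    scaled <- rep(100, length(raw))
  } else {
    scaled <- 100 * (raw - min(raw)) / (max(raw) - min(raw))
  }
  data.frame(variable = names(raw), raw_gini_decrease = as.numeric(raw),
             scaled_0_100 = as.numeric(scaled), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Plot variable importance of a fitted food forest
#'
#' Horizontal bar chart of the 0-100 scaled mean Gini decrease.
#'
#' @param x A \code{\link{food_forest}}.
#' @param ... Passed to \code{\link[graphics]{barplot}}.
#' @return The importance table, invisibly.
#' @export
plot.food_forest <- function(x, ...) {
  imp <- scaled_importance(x)
  ord <- order(imp$scaled_0_100)
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(imp$scaled_0_100[ord], names.arg = imp$variable[ord],
                    horiz = TRUE, las = 1,
                    xlab = "scaled mean Gini decrease (0-100)",
                    main = "Variable importance", ...)
  invisible(imp)
}
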