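#' Area under the ROC curve
#'
#' Mann-Whitney U formulation: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, ties counted 1/2.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical (or 0/1) class labels; both classes must be present.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("auc: need at least one positive and one negative label")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

outcome_columns <- function() {
  c(cor = "pass_cor", fold = "pass_fold", pval = "pass_p")
}

## extract the feature matrix (columns in canonical order) from a
## training set / feature table, with schema checking
feature_matrix <- function(data) {
  fn <- feature_names()
  missing <- setdiff(fn, names(data))
  if (length(missing) > 0L)
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  as.data.frame(data)[, fn]
}

#' Fit the three-outcome ELISA-validation predictor
#'
#' Fits one random forest per validation outcome (array-ELISA correlation,
#' ELISA fold, ELISA p-value), each a binary classifier over the nine array
#' features. Predicted probabilities are the fraction of trees voting for
#' the positive class. The three outcomes are modelled independently: the
#' published workflow reports three separate probabilities per peptide and
#' thresholds them jointly at selection time.
#'
#' @param training A \code{\link{make_training_labels}} data frame (nine
#'   feature columns plus \code{pass_cor}, \code{pass_fold}, \code{pass_p}).
#' @param outcomes Which outcomes to fit; default all three.
#' @param n_trees Trees per forest, default 500.
#' @param mtry Features tried per split; default the square-root rule.
#' @param min_leaf Minimum terminal node size, default 1.
#' @param seed Integer seed making the fit reproducible.
#' @return An object of class \code{"validation_model"} with
#'   \code{\link{predict.validation_model}}, \code{print} and \code{summary}
#'   methods.
#' @export
validation_model <- function(training, outcomes = c("cor", "fold", "pval"),
                             n_trees = 500L, mtry = NULL, min_leaf = 1L,
                             seed = NULL) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  stopifnot(n_trees >= 1L)
  x <- feature_matrix(training)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  oc_cols <- outcome_columns()
  forests <- list()
  oob_auc <- c()
  for (i in seq_along(outcomes)) {
    oc <- outcomes[i]
    y <- training[[oc_cols[[oc]]]]
    if (is.null(y)) stop("training set lacks column ", oc_cols[[oc]])
    y <- factor(as.logical(y), levels = c(FALSE, TRUE))
    if (length(unique(y)) < 2L)
      stop("single-class training labels for outcome '", oc,
           "': cannot fit a classifier")
    if (!is.null(seed)) set.seed(seed + i)
    forests[[oc]] <- randomForest::randomForest(
      x = x, y = y, ntree = n_trees, mtry = mtry, nodesize = min_leaf)
    ## rows never out of bag (possible under extreme class imbalance) have
    ## no OOB vote; drop them from the OOB summary
    oob <- forests[[oc]]$votes[, "TRUE"]
    ok <- !is.na(oob)
    oob_auc[oc] <- if (length(unique(y[ok])) == 2L)
      auc(oob[ok], y[ok] == "TRUE") else NA_real_
  }
  structure(list(forests = forests, outcomes = outcomes,
                 feature_names = feature_names(),
                 n_trees = n_trees, mtry = mtry, min_leaf = min_leaf,
                 seed = seed, n_train = nrow(x), oob_auc = oob_auc,
                 call = match.call()),
            class = "validation_model")
}

#' Predict ELISA-validation probabilities for peptides
#'
#' @param object A \code{\link{validation_model}}.
#' @param newdata A feature table or any data frame carrying
#'   \code{peptide_id} and the nine feature columns.
#' @param ... Unused.
#' @return Data frame with \code{peptide_id}, \code{p_cor}, \code{p_fold},
#'   \code{p_pval}: per-outcome fractions of trees voting that the peptide
#'   would meet that ELISA criterion.
#' @export
predict.validation_model <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)
  out <- data.frame(peptide_id = as.data.frame(newdata)$peptide_id,
                    stringsAsFactors = FALSE)
  for (oc in object$outcomes) {
    v <- predict(object$forests[[oc]], newdata = x, type = "vote",
                 norm.votes = TRUE)
    out[[paste0("p_", oc)]] <- unname(v[, "TRUE"])
  }
  out
}

#' @export
print.validation_model <- function(x, ...) {
  cat("ELISA-validation random-forest model\n")
  cat(sprintf("  %d training peptides, %d trees/forest, mtry %d\n",
              x$n_train, x$n_trees, x$mtry))
  cat("  outcomes:", paste(x$outcomes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.validation_model <- function(object, ...) {
  out <- list(model = object, oob_auc = object$oob_auc,
              importance = lapply(object$forests, function(f)
                randomForest::importance(f)))
  class(out) <- "summary.validation_model"
  out
}

#' @export
print.summary.validation_model <- function(x, ...) {
  print(x$model)
  cat("  out-of-bag AUC:",
      paste(sprintf("%s=%.3f", names(x$oob_auc), x$oob_auc),
            collapse = ", "), "\n")
  imp <- sapply(x$importance, function(m) m[, 1])
  cat("  mean decrease in Gini by feature:\n")
  print(round(imp, 2))
  invisible(x)
}
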