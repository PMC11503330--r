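## one stratified train/test split of indices 1..n by logical y;
## resampled (up to max_tries) until the test fold holds both classes
stratified_split <- function(y, train_fraction, max_tries = 100L) {
  n <- length(y)
  for (i in seq_len(max_tries)) {
    pos <- which(y); neg <- which(!y)
    tr <- c(sample(pos, max(1L, round(train_fraction * length(pos)))),
            sample(neg, max(1L, round(train_fraction * length(neg)))))
    te <- setdiff(seq_len(n), tr)
    ytr <- y[tr]; yte <- y[te]
    if (length(te) > 0L && any(yte) && any(!yte) && any(ytr) && any(!ytr))
      return(list(train = tr, test = te))
  }
  stop("stratified_split: could not produce a two-class test fold")
}

#' Repeated 70/30 cross-validation of the validation predictor
#'
#' For each repeat and each outcome: draw a stratified split, fit a random
#' forest on the training fraction, and score held-out peptides; the report
#' carries the per-outcome mean AUC over repeats and, optionally, the AUC of
#' each feature taken alone (by refitting a single-feature forest on the
#' same splits, or by using the sign-oriented raw feature as the score).
#' Splits yielding a single-class test fold are resampled.
#'
#' @param training A \code{\link{make_training_labels}} data frame.
#' @param n_repeats Number of random splits, default 500.
#' @param train_fraction Fraction of peptides used for fitting, default 0.7.
#' @param stratified Stratify splits by outcome label, default TRUE (plain
#'   splits are still resampled until the test fold has both classes).
#' @param n_trees,mtry,min_leaf Forest hyperparameters (see
#'   \code{\link{validation_model}}).
#' @param seed Integer seed.
#' @param feature_aucs Also compute single-feature AUCs (default TRUE).
#' @param feature_auc_mode \code{"forest"}: refit a one-feature forest;
#'   \code{"raw"}: use the feature itself, oriented so larger = more likely
#'   to validate (locFDR and r-value are negated).
#' @param outcomes Outcomes to evaluate, default all three.
#' @return Object of class \code{"cv_report"}: \code{mean_auc} (named by
#'   outcome), \code{repeat_auc} (repeats x outcomes matrix),
#'   \code{feature_auc} (features x outcomes matrix or NULL), settings.
#' @export
cross_validate <- function(training, n_repeats = 500L, train_fraction = 0.7,
                           stratified = TRUE, n_trees = 500L, mtry = NULL,
                           min_leaf = 1L, seed = NULL, feature_aucs = TRUE,
                           feature_auc_mode = c("forest", "raw"),
                           outcomes = c("cor", "fold", "pval")) {
  feature_auc_mode <- match.arg(feature_auc_mode)
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  stopifnot(train_fraction > 0, train_fraction < 1)
  x <- feature_matrix(training)
  n <- nrow(x)
  if (n < 10L) stop("cross_validate: need a labeled set of >= 10 peptides")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  fn <- feature_names()
  ## orientation: larger value = stronger evidence of a validating peptide
  orientation <- c(fold = 1, fold_nn = 1, rvalue = -1, locfdr = -1,
                   locfdr_nn = -1, prop_exp = 1, prop_exp_nn = 1,
                   prop_con = 1, prop_con_nn = 1)
  oc_cols <- outcome_columns()

  if (!is.null(seed)) set.seed(seed)
  repeat_auc <- matrix(NA_real_, n_repeats, length(outcomes),
                       dimnames = list(NULL, outcomes))
  feat_auc_sum <- matrix(0, length(fn), length(outcomes),
                         dimnames = list(fn, outcomes))

  fit_score <- function(xtr, ytr, xte) {
    ## a feature block with no variation cannot be split on (and stalls the
    ## forest fitter): such a score carries no information, AUC 0.5
    if (all(vapply(xtr, function(col) length(unique(col)) == 1L, logical(1))))
      return(rep(0.5, nrow(xte)))
    f <- randomForest::randomForest(
      x = xtr, y = factor(ytr, levels = c(FALSE, TRUE)),
      ntree = n_trees, mtry = min(mtry, ncol(xtr)), nodesize = min_leaf)
    unname(predict(f, newdata = xte, type = "vote",
                   norm.votes = TRUE)[, "TRUE"])
  }

  for (r in seq_len(n_repeats)) {
    for (j in seq_along(outcomes)) {
      oc <- outcomes[j]
      y <- as.logical(training[[oc_cols[[oc]]]])
      if (length(unique(y)) < 2L)
        stop("cross_validate: single-class labels for outcome '", oc, "'")
      sp <- if (stratified) stratified_split(y, train_fraction)
            else plain_split(y, train_fraction)
      sc <- fit_score(x[sp$train, , drop = FALSE], y[sp$train],
                      x[sp$test, , drop = FALSE])
      repeat_auc[r, j] <- auc(sc, y[sp$test])
      if (feature_aucs) {
        for (f in fn) {
          if (feature_auc_mode == "forest") {
            sf <- fit_score(x[sp$train, f, drop = FALSE], y[sp$train],
                            x[sp$test, f, drop = FALSE])
          } else {
            sf <- orientation[[f]] * x[sp$test, f]
          }
          feat_auc_sum[f, j] <- feat_auc_sum[f, j] + auc(sf, y[sp$test])
        }
      }
    }
  }

  structure(list(
    mean_auc = colMeans(repeat_auc),
    repeat_auc = repeat_auc,
    feature_auc = if (feature_aucs) feat_auc_sum / n_repeats else NULL,
    n_repeats = n_repeats, train_fraction = train_fraction,
    stratified = stratified, n_trees = n_trees,
    feature_auc_mode = if (feature_aucs) feature_auc_mode else NA_character_,
    seed = seed),
    class = "cv_report")
}

plain_split <- function(y, train_fraction, max_tries = 100L) {
  n <- length(y)
  for (i in seq_len(max_tries)) {
    tr <- sample(n, max(2L, round(train_fraction * n)))
    te <- setdiff(seq_len(n), tr)
    if (length(te) > 0L && any(y[te]) && any(!y[te]) &&
        any(y[tr]) && any(!y[tr]))
      return(list(train = tr, test = te))
  }
  stop("plain_split: could not produce a two-class test fold")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "Cross-validation report: %d repeats of %.0f-%.0f%% splits%s\n",
    x$n_repeats, 100 * x$train_fraction, 100 * (1 - x$train_fraction),
    if (x$stratified) " (stratified)" else ""))
  tab <- if (is.null(x$feature_auc)) NULL else x$feature_auc
  if (!is.null(tab)) {
    tab <- rbind(tab, `all features` = x$mean_auc)
    colnames(tab) <- c(cor = "ELISA-array cor", fold = "ELISA fold",
                       pval = "ELISA p-value")[colnames(tab)]
    print(round(tab, 2))
  } else {
    print(round(x$mean_auc, 3))
  }
  invisible(x)
}

#' Write a cross-validation report as TSV
#'
#' @param report A \code{\link{cross_validate}} result.
#' @param path File path.
#' @export
write_cv_report <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  rows <- data.frame(feature = "all_features", t(report$mean_auc),
                     check.names = FALSE)
  if (!is.null(report$feature_auc))
    rows <- rbind(data.frame(feature = rownames(report$feature_auc),
                             report$feature_auc, check.names = FALSE,
                             row.names = NULL),
                  rows)
  write_tsv(rows, path,
            comments = sprintf(
              "cv: %d repeats, train fraction %.2f, %d trees, seed %s",
              report$n_repeats, report$train_fraction, report$n_trees,
              if (is.null(report$seed)) "none" else report$seed))
  invisible(path)
}
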