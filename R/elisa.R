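#' Two-sample rank-sum (Mann-Whitney / Wilcoxon) p-value
#'
#' Two-sided throughout. In \code{"auto"} mode the exact null distribution is
#' used when both samples have at most 10 observations and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used. \code{"exact"} forces the exact p-value (by the
#' classical rank-sum null distribution, or by full enumeration of group
#' reassignments when ties are present); \code{"normal"} forces the
#' approximation.
#'
#' @param a,b Numeric samples (non-empty).
#' @param mode \code{"auto"}, \code{"exact"} or \code{"normal"}.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # exact: 0.1
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("mann_whitney: both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("mann_whitney: missing values")
  n1 <- length(a); n2 <- length(b)
  ties <- anyDuplicated(c(a, b)) > 0L
  if (mode == "auto")
    mode <- if (!ties && n1 <= 10L && n2 <= 10L) "exact" else "normal"

  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (mode == "exact") {
    if (!ties) {
      p <- if (U > n1 * n2 / 2)
        2 * stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
      else
        2 * stats::pwilcox(U, n1, n2)
      return(min(p, 1))
    }
    ## ties: enumerate all group reassignments of the pooled values
    n <- n1 + n2
    if (choose(n, n1) > 2e5)
      stop("mann_whitney: exact mode with ties infeasible for n1=", n1,
           ", n2=", n2, "; use mode='normal'")
    dev_obs <- abs(U - n1 * n2 / 2)
    idx <- utils::combn(n, n1)
    devs <- apply(idx, 2L, function(i) {
      abs(sum(r[i]) - n1 * (n1 + 1) / 2 - n1 * n2 / 2)
    })
    return(mean(devs >= dev_obs - 1e-9))
  }

  ## normal approximation with tie and continuity corrections
  n <- n1 + n2
  z <- U - n1 * n2 / 2
  tab <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(tab^3 - tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(2 * stats::pnorm(-abs(z)), 1)
}

#' Spearman rank correlation
#'
#' Mid-ranks are used for ties. A constant vector has no rank ordering, so
#' the correlation is undefined: the function warns and returns NA, which
#' downstream criteria treat as a failed correlation.
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return Correlation in [-1, 1], or NA for degenerate input.
#' @export
spearman <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("spearman: unequal lengths")
  if (length(x) < 3L) stop("spearman: need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("spearman: missing values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("spearman: constant vector, correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' ELISA validation criteria
#'
#' The three empiric thresholds a peptide must meet for its array signal to
#' count as confirmed by ELISA: array-ELISA Spearman correlation strictly
#' above \code{cor_threshold}, ELISA fold change at or above
#' \code{fold_threshold}, and rank-sum p-value at or below
#' \code{p_threshold}.
#'
#' @param cor_threshold Correlation cut (strict >), default 0.6.
#' @param fold_threshold Fold cut (inclusive >=), default 5.
#' @param p_threshold P-value cut (inclusive <=), default 0.1.
#' @return An object of class \code{"criteria_config"}.
#' @export
criteria_config <- function(cor_threshold = 0.6, fold_threshold = 5,
                            p_threshold = 0.1) {
  stopifnot(cor_threshold > 0, fold_threshold > 0, p_threshold > 0)
  structure(list(cor_threshold = cor_threshold,
                 fold_threshold = fold_threshold,
                 p_threshold = p_threshold),
            class = "criteria_config")
}

#' Summarize ELISA measurements for one peptide against its array signal
#'
#' Computes the three empiric ELISA statistics: \code{e_cor}, the Spearman
#' correlation between array intensity and ELISA absorbance across all
#' contrast subjects (both arms pooled, since array-ELISA concordance is a
#' per-subject property); \code{e_fold}, the ratio of experimental to control
#' mean absorbance (denominator floored at \code{fold_floor} OD); and
#' \code{e_p}, the two-sided rank-sum p-value comparing the arms.
#'
#' @param absorbance Named numeric vector, subject id -> optical density.
#' @param design A \code{\link{group_design}}.
#' @param array_row Named numeric vector, subject id -> array intensity for
#'   the same peptide.
#' @param fold_floor Denominator floor in OD units, default 0.001.
#' @param p_mode Passed to \code{\link{mann_whitney}}.
#' @return List of class \code{"elisa_summary"} with \code{e_cor},
#'   \code{e_fold}, \code{e_p}.
#' @export
summarize_elisa <- function(absorbance, design, array_row,
                            fold_floor = 0.001, p_mode = "auto") {
  stopifnot(inherits(design, "group_design"))
  if (is.null(names(absorbance)) || is.null(names(array_row)))
    stop("summarize_elisa: absorbance and array_row must be named by subject")
  subjects <- names(absorbance)
  if (!all(subjects %in% names(array_row)))
    stop("summarize_elisa: subject mismatch between ELISA and array")
  if (any(absorbance < 0)) stop("summarize_elisa: negative absorbance")
  arms <- contrast_subjects(design, subjects)
  if (length(arms$exp) < 2L || length(arms$con) < 2L)
    stop("summarize_elisa: need >= 2 subjects per contrast arm")
  in_contrast <- c(arms$exp, arms$con)
  e_cor <- spearman(array_row[in_contrast], absorbance[in_contrast])
  e_fold <- mean(absorbance[arms$exp]) /
    max(mean(absorbance[arms$con]), fold_floor)
  e_p <- mann_whitney(absorbance[arms$exp], absorbance[arms$con],
                      mode = p_mode)
  structure(list(e_cor = unname(e_cor), e_fold = unname(e_fold),
                 e_p = unname(e_p)),
            class = "elisa_summary")
}

#' Binarize empiric ELISA statistics into validation outcomes
#'
#' @param summary An \code{\link{elisa_summary}} (or any list with
#'   \code{e_cor}, \code{e_fold}, \code{e_p}).
#' @param criteria A \code{\link{criteria_config}}.
#' @return List of class \code{"validation_labels"} with logicals
#'   \code{pass_cor}, \code{pass_fold}, \code{pass_p}. An undefined
#'   correlation (NA) fails the correlation criterion.
#' @export
evaluate_criteria <- function(summary, criteria = criteria_config()) {
  stopifnot(inherits(criteria, "criteria_config"))
  structure(list(
    pass_cor = isTRUE(summary$e_cor > criteria$cor_threshold),
    pass_fold = isTRUE(summary$e_fold >= criteria$fold_threshold),
    pass_p = isTRUE(summary$e_p <= criteria$p_threshold)
  ), class = "validation_labels")
}

#' Build the labeled training set for the validation predictor
#'
#' Joins per-peptide array features to the binarized ELISA outcomes. Each
#' ELISA-assayed peptide must have a feature row; anything unjoinable is an
#' error, since a silent drop would bias the training set.
#'
#' @param elisa Long data frame of measurements (\code{peptide_id},
#'   \code{subject_id}, \code{absorbance}).
#' @param features A \code{\link{compute_features}} table.
#' @param experiment The \code{\link{array_experiment}} supplying per-subject
#'   array intensities.
#' @param design A \code{\link{group_design}}.
#' @param criteria A \code{\link{criteria_config}}.
#' @param p_mode Passed to \code{\link{mann_whitney}}.
#' @return Data frame of class \code{"training_set"}: peptide_id, the nine
#'   features, \code{e_cor}, \code{e_fold}, \code{e_p}, and logical
#'   \code{pass_cor}, \code{pass_fold}, \code{pass_p}.
#' @export
make_training_labels <- function(elisa, features, experiment, design,
                                 criteria = criteria_config(),
                                 p_mode = "auto") {
  stopifnot(is.data.frame(elisa),
            all(c("peptide_id", "subject_id", "absorbance") %in% names(elisa)))
  ids <- unique(elisa$peptide_id)
  missing <- setdiff(ids, features$peptide_id)
  if (length(missing) > 0L)
    stop("make_training_labels: no feature row for peptide(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  missing <- setdiff(ids, rownames(experiment$intensity))
  if (length(missing) > 0L)
    stop("make_training_labels: no array row for peptide(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  rows <- lapply(ids, function(id) {
    sub <- elisa[elisa$peptide_id == id, ]
    absorb <- stats::setNames(sub$absorbance, sub$subject_id)
    arr <- experiment$intensity[id, ]
    s <- summarize_elisa(absorb, design, arr, p_mode = p_mode)
    lab <- evaluate_criteria(s, criteria)
    data.frame(peptide_id = id, e_cor = s$e_cor, e_fold = s$e_fold,
               e_p = s$e_p, pass_cor = lab$pass_cor,
               pass_fold = lab$pass_fold, pass_p = lab$pass_p,
               stringsAsFactors = FALSE)
  })
  labels <- do.call(rbind, rows)
  feat <- as.data.frame(features)[match(ids, features$peptide_id),
                                  c("peptide_id", feature_names())]
  out <- cbind(feat, labels[, -1, drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("training_set", "data.frame")
  out
}
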