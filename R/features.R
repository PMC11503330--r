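#' Whole-array intensity statistics
#'
#' Pools every cell of the intensity matrix to compute the array mean, the
#' population standard deviation, and the high-signal threshold mu + 3 sigma
#' used by the prop_exp / prop_con features. On the array that motivated this
#' package the threshold was 1047.4 raw fluorescence units; here it is always
#' recomputed from the matrix at hand.
#'
#' @param experiment An \code{\link{array_experiment}}.
#' @return List with elements \code{mu}, \code{sigma} (population formula)
#'   and \code{t_high} = mu + 3 sigma.
#' @export
global_stats <- function(experiment) {
  stopifnot(inherits(experiment, "array_experiment"))
  x <- experiment$intensity
  if (length(x) == 0L) stop("global_stats: empty intensity matrix")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  list(mu = mu, sigma = sigma, t_high = mu + 3 * sigma)
}

#' Signal fold difference between contrast arms
#'
#' Ratio of arithmetic group means on the raw intensity scale, with the
#' denominator floored to keep the ratio finite on dark control signals.
#'
#' @param exp_values,con_values Raw intensities for the experimental and
#'   control subjects.
#' @param floor Lower bound applied to the control mean (default 1 raw unit).
#' @return Positive ratio.
#' @export
fold_difference <- function(exp_values, con_values, floor = 1.0) {
  if (length(exp_values) == 0L || length(con_values) == 0L)
    stop("fold_difference: both groups must be non-empty")
  if (any(exp_values < 0) || any(con_values < 0))
    stop("fold_difference: negative intensities")
  mean(exp_values) / max(mean(con_values), floor)
}

#' Proportion of subjects at or above / strictly below a threshold
#'
#' \code{prop_above} is the prop_exp feature: the fraction of disease-group
#' subjects whose raw signal reaches the whole-array mu + 3 sigma threshold
#' (inclusive). \code{prop_below} is the prop_con feature: the fraction of
#' control subjects strictly below the threshold.
#'
#' @param values Raw intensities for one group.
#' @param threshold Intensity threshold (typically
#'   \code{global_stats(x)$t_high}).
#' @return Proportion in [0, 1].
#' @export
prop_above <- function(values, threshold) {
  if (length(values) == 0L) stop("prop_above: empty value list")
  mean(values >= threshold)
}

#' @rdname prop_above
#' @export
prop_below <- function(values, threshold) {
  if (length(values) == 0L) stop("prop_below: empty value list")
  mean(values < threshold)
}

#' Nearest-neighbor average of a per-peptide quantity
#'
#' For each peptide, averages the value over the one tiling-adjacent peptide
#' on either side (self excluded). Because adjacent 16-mers at 2-residue
#' steps share 14 residues, a real epitope elevates a run of tiles, and the
#' neighbor average separates such runs from isolated bright probes. Terminal
#' tiles take their single neighbor's value; neighbor-less peptides fall back
#' to their own value.
#'
#' @param values Named numeric vector keyed by peptide id.
#' @param neighbor_map Neighbor data frame from
#'   \code{\link{build_neighbor_map}} (or a \code{\link{peptide_library}}).
#' @return Named numeric vector over the same peptides.
#' @export
nn_average <- function(values, neighbor_map) {
  if (inherits(neighbor_map, "peptide_library"))
    neighbor_map <- neighbor_map$neighbors
  stopifnot(is.data.frame(neighbor_map),
            all(c("peptide_id", "left", "right") %in% names(neighbor_map)))
  if (is.null(names(values))) stop("nn_average: 'values' must be named")
  missing <- setdiff(neighbor_map$peptide_id, names(values))
  if (length(missing) > 0L)
    stop("nn_average: values missing for peptide(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  v <- values[neighbor_map$peptide_id]
  lv <- unname(values[neighbor_map$left])   # NA where no left neighbor
  rv <- unname(values[neighbor_map$right])
  out <- rowMeans(cbind(lv, rv), na.rm = TRUE)
  out[is.nan(out)] <- unname(v)[is.nan(out)]  # no neighbors at all
  names(out) <- neighbor_map$peptide_id
  out[names(values)]
}

#' Compute the nine per-peptide array features for a contrast
#'
#' Assembles, for every library peptide in the experiment: signal fold
#' difference, empirical-Bayes locFDR and r-value, prop_exp and prop_con
#' (threshold-crossing proportions against the whole-array mu + 3 sigma cut),
#' plus nearest-neighbor averages of fold, locFDR, prop_exp and prop_con.
#'
#' @param experiment An \code{\link{array_experiment}}.
#' @param design A \code{\link{group_design}} defining the contrast.
#' @param inference A \code{\link{peptide_inference}} fitted on the same
#'   experiment and contrast (supplies locFDR and r-values).
#' @param propcon_mode How to read the prop_con threshold: \code{"below_high"}
#'   (default) counts control subjects strictly below mu + 3 sigma, the
#'   complement criterion to prop_exp; \code{"below_low"} counts them below
#'   mu - 3 sigma.
#' @param fold_floor Denominator floor for \code{\link{fold_difference}}.
#' @return A data frame of class \code{"feature_table"}: one row per peptide,
#'   columns \code{peptide_id}, \code{fold}, \code{fold_nn}, \code{rvalue},
#'   \code{locfdr}, \code{locfdr_nn}, \code{prop_exp}, \code{prop_exp_nn},
#'   \code{prop_con}, \code{prop_con_nn}. The global statistics and contrast
#'   are attached as attributes.
#' @export
compute_features <- function(experiment, design, inference,
                             propcon_mode = c("below_high", "below_low"),
                             fold_floor = 1.0) {
  stopifnot(inherits(experiment, "array_experiment"),
            inherits(design, "group_design"),
            inherits(inference, "peptide_inference"))
  propcon_mode <- match.arg(propcon_mode)
  x <- experiment$intensity
  arms <- contrast_subjects(design, colnames(x))
  xe <- x[, arms$exp, drop = FALSE]
  xc <- x[, arms$con, drop = FALSE]
  gs <- global_stats(experiment)
  thr_con <- if (propcon_mode == "below_high") gs$t_high else gs$mu - 3 * gs$sigma

  ids <- rownames(x)
  fold <- rowMeans(xe) / pmax(rowMeans(xc), fold_floor)
  prop_exp <- rowMeans(xe >= gs$t_high)
  prop_con <- rowMeans(xc < thr_con)

  inf_ids <- inference$stats$peptide_id
  if (!setequal(inf_ids, ids))
    stop("compute_features: inference results do not cover the experiment")
  idx <- match(ids, inf_ids)
  locfdr <- inference$locfdr[idx]
  rvalue <- inference$rvalue[idx]

  nmap <- experiment$library$neighbors
  nmap <- nmap[nmap$peptide_id %in% ids, , drop = FALSE]
  nn <- function(v) unname(nn_average(stats::setNames(v, ids), nmap)[ids])

  out <- data.frame(
    peptide_id = ids,
    fold = unname(fold),
    fold_nn = nn(fold),
    rvalue = unname(rvalue),
    locfdr = unname(locfdr),
    locfdr_nn = nn(locfdr),
    prop_exp = unname(prop_exp),
    prop_exp_nn = nn(prop_exp),
    prop_con = unname(prop_con),
    prop_con_nn = nn(prop_con),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out,
            class = c("feature_table", "data.frame"),
            global_stats = gs,
            contrast = list(experimental = design$experimental,
                            control = design$control),
            propcon_mode = propcon_mode)
}

## names of the nine model features, in canonical order
feature_names <- function() {
  c("fold", "fold_nn", "rvalue", "locfdr", "locfdr_nn",
    "prop_exp", "prop_exp_nn", "prop_con", "prop_con_nn")
}

#' Write / read a feature table as TSV
#'
#' Contrast and global statistics travel as '#' comment lines ahead of the
#' header.
#'
#' @param features A \code{\link{compute_features}} result.
#' @param path File path.
#' @export
write_feature_table <- function(features, path) {
  gs <- attr(features, "global_stats")
  ct <- attr(features, "contrast")
  comments <- character()
  if (!is.null(ct))
    comments <- c(comments,
                  paste("contrast:", paste(ct$experimental, collapse = ","),
                        "vs", paste(ct$control, collapse = ",")))
  if (!is.null(gs))
    comments <- c(comments,
                  sprintf("global: mu=%.6g sigma=%.6g t_high=%.6g",
                          gs$mu, gs$sigma, gs$t_high))
  write_tsv(as.data.frame(features), path, comments = comments)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("peptide_id", feature_names())
  if (!all(need %in% names(df)))
    stop("feature table ", path, ": missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  structure(df[, need], class = c("feature_table", "data.frame"))
}
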