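#' Candidate-selection rule over predicted probabilities
#'
#' Two thresholding schemes are used in practice: \code{"all_exceed"} keeps a
#' peptide when every one of the three predicted probabilities is strictly
#' above the threshold (the 0.5 rule used for validation contrasts);
#' \code{"mean_exceeds"} keeps it when the mean of the three is strictly
#' above the threshold (the more conservative 0.75 rule used for discovery).
#'
#' @param mode \code{"all_exceed"} or \code{"mean_exceeds"}.
#' @param threshold Probability threshold in (0, 1).
#' @return An object of class \code{"selection_rule"}.
#' @export
selection_rule <- function(mode = c("all_exceed", "mean_exceeds"),
                           threshold = 0.5) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  structure(list(mode = mode, threshold = threshold),
            class = "selection_rule")
}

#' Select candidate peptides from predicted probabilities
#'
#' @param probabilities Data frame with \code{peptide_id}, \code{p_cor},
#'   \code{p_fold}, \code{p_pval} (as from
#'   \code{\link{predict.validation_model}}).
#' @param rule A \code{\link{selection_rule}}.
#' @return The selected rows, with an added \code{mean_p} column, sorted by
#'   mean probability descending.
#' @export
select_peptides <- function(probabilities,
                            rule = selection_rule("all_exceed", 0.5)) {
  stopifnot(inherits(rule, "selection_rule"))
  need <- c("peptide_id", "p_cor", "p_fold", "p_pval")
  missing <- setdiff(need, names(probabilities))
  if (length(missing) > 0L)
    stop("select_peptides: missing column(s): ",
         paste(missing, collapse = ", "))
  p <- as.data.frame(probabilities)
  if (anyNA(p[, c("p_cor", "p_fold", "p_pval")]))
    stop("select_peptides: missing probabilities")
  p$mean_p <- (p$p_cor + p$p_fold + p$p_pval) / 3
  keep <- switch(rule$mode,
    all_exceed = p$p_cor > rule$threshold & p$p_fold > rule$threshold &
      p$p_pval > rule$threshold,
    mean_exceeds = p$mean_p > rule$threshold)
  out <- p[keep, , drop = FALSE]
  out <- out[order(-out$mean_p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Modification enrichment of a peptide selection
#'
#' Reports the fraction of selected peptides whose sequence contains
#' citrulline ('B') or homocitrulline ('Z'), the same fractions over the
#' whole library, and their ratio — the sanity check that a selection driven
#' by an anti-citrullinated-protein response is in fact citrulline-enriched.
#'
#' @param selected Character vector of selected peptide ids (or a
#'   \code{\link{select_peptides}} result).
#' @param library A \code{\link{peptide_library}} containing them.
#' @return Object of class \code{"enrichment_report"} with counts, fractions
#'   (NA when the selection is empty, with \code{empty = TRUE}), and ratios.
#' @export
enrichment_report <- function(selected, library) {
  stopifnot(inherits(library, "peptide_library"))
  if (is.data.frame(selected)) selected <- selected$peptide_id
  selected <- as.character(selected)
  r <- library$records
  unknown <- setdiff(selected, r$peptide_id)
  if (length(unknown) > 0L)
    stop("enrichment_report: selected peptide(s) not in library: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  lib_cit <- grepl("B", r$sequence, fixed = TRUE)
  lib_hcit <- grepl("Z", r$sequence, fixed = TRUE)
  sel <- r$peptide_id %in% selected
  n_sel <- sum(sel)
  frac <- function(x) if (n_sel == 0L) NA_real_ else mean(x[sel])
  ratio <- function(s, l) if (is.na(s) || l == 0) NA_real_ else s / l
  out <- list(
    n_selected = n_sel,
    n_library = nrow(r),
    empty = n_sel == 0L,
    selected_citrulline = frac(lib_cit),
    library_citrulline = mean(lib_cit),
    selected_homocitrulline = frac(lib_hcit),
    library_homocitrulline = mean(lib_hcit),
    n_selected_citrulline = sum(sel & lib_cit),
    n_selected_homocitrulline = sum(sel & lib_hcit)
  )
  out$citrulline_ratio <- ratio(out$selected_citrulline,
                                out$library_citrulline)
  out$homocitrulline_ratio <- ratio(out$selected_homocitrulline,
                                    out$library_homocitrulline)
  structure(out, class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("Modification enrichment:", x$n_selected, "selected of",
      x$n_library, "library peptides\n")
  if (x$empty) {
    cat("  empty selection: fractions undefined\n")
    return(invisible(x))
  }
  cat(sprintf("  citrulline: %.1f%% of selected (%d/%d) vs %.1f%% of library\n",
              100 * x$selected_citrulline, x$n_selected_citrulline,
              x$n_selected, 100 * x$library_citrulline))
  cat(sprintf("  homocitrulline: %.1f%% of selected vs %.1f%% of library\n",
              100 * x$selected_homocitrulline,
              100 * x$library_homocitrulline))
  invisible(x)
}
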