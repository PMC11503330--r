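#' Bundled worked-example validation panels
#'
#' Three small peptide panels, shipped as plain TSV under
#' \code{inst/extdata}, each carrying published per-peptide predicted
#' probabilities (\code{p_cor}, \code{p_fold}, \code{p_pval}) and empiric
#' ELISA summaries (\code{e_cor}, \code{e_fold}, \code{e_p}): a COVID-19
#' convalescent-vs-naive panel of four SARS-CoV-2 peptides, a lupus
#' vs-all-others panel of five human peptides, and a spondyloarthropathy
#' panel of three. They are the package's worked examples for
#' \code{\link{evaluate_criteria}} and \code{\link{select_peptides}}.
#'
#' @param panel \code{"covid"}, \code{"lupus"} or \code{"spa"}.
#' @return Data frame with columns \code{peptide_id}, \code{sequence},
#'   \code{p_cor}, \code{p_fold}, \code{p_pval}, \code{e_cor},
#'   \code{e_fold}, \code{e_p}.
#' @examples
#' p <- validation_panel("covid")
#' select_peptides(p, selection_rule("all_exceed", 0.5))$peptide_id
#' @export
validation_panel <- function(panel = c("covid", "lupus", "spa")) {
  panel <- match.arg(panel)
  path <- system.file("extdata", paste0(panel, "_panel.tsv"),
                      package = "pepforest", mustWork = TRUE)
  read_tsv_checked(path)
}
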