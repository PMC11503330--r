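#' Tile a protein into overlapping peptides
#'
#' Generates fixed-length peptides along a protein at a fixed step so that
#' adjacent peptides overlap, the standard design for linear-epitope discovery
#' arrays (16-mers at 2-residue steps by default). A protein shorter than the
#' tile length yields a single record covering the whole sequence.
#'
#' @param protein_id Character scalar identifying the source protein.
#' @param sequence Amino-acid sequence (uppercase one-letter codes; 'B' =
#'   citrulline, 'Z' = homocitrulline are permitted).
#' @param tile_length Peptide length, default 16.
#' @param step Offset between consecutive tile starts, default 2.
#' @return A data frame of peptide records with columns \code{peptide_id},
#'   \code{sequence}, \code{protein_id}, \code{start} (1-based inclusive) and
#'   \code{modification} (\code{"native"}).
#' @examples
#' tile_protein("P1", paste(rep("ACDEFGHIKL", 3), collapse = ""))
#' @export
tile_protein <- function(protein_id, sequence, tile_length = 16L, step = 2L) {
  stopifnot(length(protein_id) == 1L, length(sequence) == 1L,
            is.character(sequence))
  if (is.na(sequence) || !nzchar(sequence))
    stop("tile_protein: 'sequence' must be a non-empty amino-acid string")
  tile_length <- as.integer(tile_length)
  step <- as.integer(step)
  stopifnot(tile_length >= 1L, step >= 1L)
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  if (len < tile_length) {
    starts <- 1L
    seqs <- sequence
  } else {
    starts <- seq.int(1L, len - tile_length + 1L, by = step)
    seqs <- substring(sequence, starts, starts + tile_length - 1L)
  }
  data.frame(
    peptide_id = paste0(protein_id, "-", starts),
    sequence = seqs,
    protein_id = protein_id,
    start = starts,
    modification = "native",
    stringsAsFactors = FALSE
  )
}

#' Apply citrullination or homocitrullination to peptide records
#'
#' Citrullination replaces every arginine ('R') with citrulline ('B');
#' homocitrullination replaces every lysine ('K') with homocitrulline ('Z').
#' All other positions are unchanged, the modification flag is updated, and a
#' modification suffix is appended to the peptide id so the modified series
#' remains distinct from the native one.
#'
#' @param records Data frame of native peptide records (as from
#'   \code{\link{tile_protein}}).
#' @param mode \code{"citrullinated"} or \code{"homocitrullinated"}.
#' @return The modified records.
#' @examples
#' rec <- data.frame(peptide_id = "p-1", sequence = "ARKAGRSA",
#'                   protein_id = "p", start = 1, modification = "native")
#' apply_modification(rec, "citrullinated")$sequence  # "ABKAGBSA"
#' @export
apply_modification <- function(records,
                               mode = c("citrullinated", "homocitrullinated")) {
  mode <- match.arg(mode)
  records <- as_peptide_records(records)
  if (any(records$modification != "native"))
    stop("apply_modification: records must be native (already modified input)")
  if (mode == "citrullinated") {
    records$sequence <- chartr("R", "B", records$sequence)
    suffix <- "-cit"
  } else {
    records$sequence <- chartr("K", "Z", records$sequence)
    suffix <- "-hcit"
  }
  records$modification <- mode
  records$peptide_id <- paste0(records$peptide_id, suffix)
  records
}

## coerce and validate a bare record data frame
as_peptide_records <- function(records) {
  required <- c("peptide_id", "sequence", "protein_id", "start", "modification")
  if (!is.data.frame(records) || !all(required %in% names(records)))
    stop("peptide records must be a data frame with columns: ",
         paste(required, collapse = ", "))
  records <- as.data.frame(records[, required], stringsAsFactors = FALSE)
  records$peptide_id <- as.character(records$peptide_id)
  records$sequence <- toupper(as.character(records$sequence))
  records$protein_id <- as.character(records$protein_id)
  records$start <- as.integer(records$start)
  records$modification <- as.character(records$modification)
  bad <- !records$modification %in%
    c("native", "citrullinated", "homocitrullinated")
  if (any(bad))
    stop("unknown modification value(s): ",
         paste(unique(records$modification[bad]), collapse = ", "))
  if (any(records$start < 1L)) stop("peptide start offsets must be >= 1")
  if (any(!nzchar(records$sequence))) stop("empty peptide sequence")
  cit <- records$modification == "citrullinated"
  if (any(grepl("R", records$sequence[cit], fixed = TRUE)))
    stop("citrullinated records may not contain 'R'")
  hcit <- records$modification == "homocitrullinated"
  if (any(grepl("K", records$sequence[hcit], fixed = TRUE)))
    stop("homocitrullinated records may not contain 'K'")
  records
}

#' Construct a tiled peptide library
#'
#' Bundles an ordered set of peptide records with the nearest-neighbor map
#' linking tiling-adjacent peptides (same protein, same modification series,
#' starts differing by exactly the tiling step).
#'
#' @param records Data frame of peptide records.
#' @param step Tiling step used to define adjacency, default 2.
#' @return An object of class \code{"peptide_library"}: a list with elements
#'   \code{records}, \code{neighbors} (see \code{\link{build_neighbor_map}})
#'   and \code{step}.
#' @export
peptide_library <- function(records, step = 2L) {
  records <- as_peptide_records(records)
  if (anyDuplicated(records$peptide_id))
    stop("peptide_library: duplicate peptide_id values")
  ord <- order(records$protein_id, records$modification, records$start)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  lib <- structure(
    list(records = records, neighbors = NULL, step = as.integer(step)),
    class = "peptide_library"
  )
  lib$neighbors <- build_neighbor_map(lib)
  lib
}

#' @export
print.peptide_library <- function(x, ...) {
  r <- x$records
  cat("Tiled peptide library:", nrow(r), "peptides from",
      length(unique(r$protein_id)), "proteins (step", x$step, ")\n")
  tab <- table(r$modification)
  cat("  series:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Build the nearest-neighbor map of a peptide library
#'
#' Adjacency is defined within a (protein, modification) series: peptide b is
#' the right neighbor of a when their starts differ by exactly the tiling
#' step. Terminal tiles have one neighbor; singleton peptides have none.
#'
#' @param library A \code{\link{peptide_library}}.
#' @return Data frame with columns \code{peptide_id}, \code{left},
#'   \code{right} (NA where no neighbor exists).
#' @export
build_neighbor_map <- function(library) {
  stopifnot(inherits(library, "peptide_library"))
  r <- library$records
  key <- paste(r$protein_id, r$modification, sep = "\r")
  if (anyDuplicated(paste(key, r$start)))
    stop("build_neighbor_map: duplicate (protein_id, modification, start)")
  ## records are sorted by (protein, modification, start) on construction
  n <- nrow(r)
  same_series_next <- c(key[-1] == key[-n], FALSE)
  step_ok <- c(r$start[-1] - r$start[-n] == library$step, FALSE)
  has_right <- same_series_next & step_ok
  right <- ifelse(has_right, c(r$peptide_id[-1], NA), NA_character_)
  left <- rep(NA_character_, n)
  left[which(has_right) + 1L] <- r$peptide_id[which(has_right)]
  data.frame(peptide_id = r$peptide_id, left = left, right = right,
             stringsAsFactors = FALSE)
}

#' Define the two-group contrast for an array experiment
#'
#' @param groups Named character vector mapping subject id to group label.
#' @param experimental Character vector of group labels forming the
#'   experimental (disease) arm.
#' @param control Character vector of group labels forming the control arm.
#' @return An object of class \code{"group_design"}.
#' @export
group_design <- function(groups, experimental, control) {
  stopifnot(is.character(groups), !is.null(names(groups)),
            all(nzchar(names(groups))))
  if (anyDuplicated(names(groups))) stop("group_design: duplicate subject ids")
  experimental <- as.character(experimental)
  control <- as.character(control)
  if (length(experimental) == 0L || length(control) == 0L)
    stop("group_design: experimental and control group sets must be non-empty")
  if (length(intersect(experimental, control)) > 0L)
    stop("group_design: experimental and control group sets must be disjoint")
  missing <- setdiff(c(experimental, control), unique(groups))
  if (length(missing) > 0L)
    stop("group_design: contrast group(s) absent from design: ",
         paste(missing, collapse = ", "))
  structure(list(groups = groups, experimental = experimental,
                 control = control),
            class = "group_design")
}

#' @export
print.group_design <- function(x, ...) {
  cat("Group design:", length(x$groups), "subjects\n")
  cat("  experimental:", paste(x$experimental, collapse = ", "),
      sprintf("(n=%d)", sum(x$groups %in% x$experimental)), "\n")
  cat("  control:     ", paste(x$control, collapse = ", "),
      sprintf("(n=%d)", sum(x$groups %in% x$control)), "\n")
  invisible(x)
}

## subject ids of each contrast arm, validated against a set of subjects
contrast_subjects <- function(design, subjects) {
  stopifnot(inherits(design, "group_design"))
  unlabeled <- setdiff(subjects, names(design$groups))
  if (length(unlabeled) > 0L)
    stop("subjects missing from group design: ",
         paste(unlabeled, collapse = ", "))
  g <- design$groups[subjects]
  exp_sub <- subjects[g %in% design$experimental]
  con_sub <- subjects[g %in% design$control]
  if (length(exp_sub) == 0L || length(con_sub) == 0L)
    stop("contrast arm has no subjects in this experiment")
  list(exp = exp_sub, con = con_sub)
}

#' Construct an array experiment
#'
#' Couples a peptides-by-subjects raw fluorescence matrix to the peptide
#' library it was measured on.
#'
#' @param intensity Numeric matrix, rows = peptides (rownames are peptide
#'   ids), columns = subjects (colnames are subject ids). Non-negative, no
#'   missing values.
#' @param library The \code{\link{peptide_library}} the rows refer to.
#' @return An object of class \code{"array_experiment"}.
#' @export
array_experiment <- function(intensity, library) {
  stopifnot(is.matrix(intensity), is.numeric(intensity),
            inherits(library, "peptide_library"))
  if (is.null(rownames(intensity)) || is.null(colnames(intensity)))
    stop("array_experiment: intensity matrix needs row and column names")
  if (anyNA(intensity)) stop("array_experiment: missing intensity values")
  if (any(intensity < 0)) stop("array_experiment: negative intensity values")
  unknown <- setdiff(rownames(intensity), library$records$peptide_id)
  if (length(unknown) > 0L)
    stop("array_experiment: matrix rows absent from library: ",
         paste(utils::head(unknown, 5L), collapse = ", "),
         if (length(unknown) > 5L) ", ..." else "")
  structure(list(intensity = intensity, library = library,
                 subjects = colnames(intensity)),
            class = "array_experiment")
}

#' @export
print.array_experiment <- function(x, ...) {
  cat("Array experiment:", nrow(x$intensity), "peptides x",
      ncol(x$intensity), "subjects\n")
  gs <- global_stats(x)
  cat(sprintf("  whole-array mean %.1f, sd %.1f, mu+3sigma threshold %.1f\n",
              gs$mu, gs$sigma, gs$t_high))
  invisible(x)
}
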