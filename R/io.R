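## TSV dialect used throughout: tab-separated, UTF-8, header row, '#' comments.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv <- function(df, path, comments = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments) > 0L)
    writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write a peptide library
#'
#' TSV files carry the record columns (\code{peptide_id}, \code{sequence},
#' \code{protein_id}, \code{start}, \code{modification}). FASTA files encode
#' the metadata in the header as \code{peptide_id|protein_id|start|modification}.
#' The format is chosen from the file extension (\code{.fa}/\code{.fasta} vs
#' anything else).
#'
#' @param path File path.
#' @param step Tiling step passed to \code{\link{peptide_library}}.
#' @return \code{read_peptide_library} returns a \code{\link{peptide_library}}.
#' @export
read_peptide_library <- function(path, step = 2L) {
  if (grepl("\\.(fa|fasta)$", path, ignore.case = TRUE)) {
    seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                               forceDNAtolower = FALSE)
    headers <- vapply(seqs, function(s) attr(s, "Annot"), character(1))
    headers <- sub("^>", "", headers)
    fields <- strsplit(headers, "|", fixed = TRUE)
    bad <- which(lengths(fields) != 4L)
    if (length(bad) > 0L)
      stop("malformed FASTA header (need peptide_id|protein_id|start|",
           "modification) in ", path, ", record ", bad[1])
    records <- data.frame(
      peptide_id = vapply(fields, `[`, "", 1L),
      sequence = toupper(unlist(seqs, use.names = FALSE)),
      protein_id = vapply(fields, `[`, "", 2L),
      start = as.integer(vapply(fields, `[`, "", 3L)),
      modification = vapply(fields, `[`, "", 4L),
      stringsAsFactors = FALSE
    )
  } else {
    records <- read_tsv_checked(path)
  }
  peptide_library(records, step = step)
}

#' @rdname read_peptide_library
#' @param library A \code{\link{peptide_library}}.
#' @export
write_peptide_library <- function(library, path) {
  stopifnot(inherits(library, "peptide_library"))
  if (grepl("\\.(fa|fasta)$", path, ignore.case = TRUE)) {
    write_selected_fasta(library$records, path)
  } else {
    write_tsv(library$records, path)
  }
  invisible(path)
}

#' Export peptide records as FASTA
#'
#' Headers follow the \code{peptide_id|protein_id|start|modification}
#' convention, so selections can be handed to external motif tools and read
#' back with \code{\link{read_peptide_library}}.
#'
#' @param records Peptide record data frame.
#' @param path Output file.
#' @export
write_selected_fasta <- function(records, path) {
  records <- as_peptide_records(records)
  names <- paste(records$peptide_id, records$protein_id, records$start,
                 records$modification, sep = "|")
  seqinr::write.fasta(as.list(records$sequence), names = names,
                      file.out = path, as.string = TRUE, nbchar = 80)
  invisible(path)
}

#' Read / write an intensity matrix
#'
#' TSV layout: first column \code{peptide_id}, remaining columns one per
#' subject. Rows are validated against the library and values must be
#' non-negative with no gaps.
#'
#' @param path File path.
#' @param library The \code{\link{peptide_library}} rows must belong to.
#' @return An \code{\link{array_experiment}}.
#' @export
read_intensity_matrix <- function(path, library) {
  df <- read_tsv_checked(path)
  if (names(df)[1] != "peptide_id")
    stop("intensity matrix ", path, ": first column must be 'peptide_id'")
  if (ncol(df) < 2L) stop("intensity matrix ", path, ": no subject columns")
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1] + 1L
    stop("intensity matrix ", path, ": non-numeric values in column ",
         names(df)[bad])
  }
  if (anyNA(mat)) {
    row <- which(rowSums(is.na(mat)) > 0)[1]
    stop("intensity matrix ", path, ": missing value at data line ", row)
  }
  if (any(mat < 0)) {
    row <- which(rowSums(mat < 0) > 0)[1]
    stop("intensity matrix ", path, ": negative intensity at data line ", row)
  }
  rownames(mat) <- df$peptide_id
  array_experiment(mat, library)
}

#' @rdname read_intensity_matrix
#' @param experiment An \code{\link{array_experiment}}.
#' @export
write_intensity_matrix <- function(experiment, path) {
  stopifnot(inherits(experiment, "array_experiment"))
  df <- data.frame(peptide_id = rownames(experiment$intensity),
                   experiment$intensity, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' Read / write a group design
#'
#' TSV layout: columns \code{subject_id} and \code{group}; the contrast is
#' supplied separately (it is an analysis choice, not a property of the
#' samples).
#'
#' @param path File path.
#' @param experimental,control Group labels forming each contrast arm.
#' @return A \code{\link{group_design}}.
#' @export
read_group_design <- function(path, experimental, control) {
  df <- read_tsv_checked(path)
  need <- c("subject_id", "group")
  if (!all(need %in% names(df)))
    stop("group design ", path, ": need columns subject_id, group")
  groups <- stats::setNames(as.character(df$group), df$subject_id)
  group_design(groups, experimental, control)
}

#' @rdname read_group_design
#' @param design A \code{\link{group_design}}.
#' @export
write_group_design <- function(design, path) {
  stopifnot(inherits(design, "group_design"))
  write_tsv(data.frame(subject_id = names(design$groups),
                       group = unname(design$groups),
                       stringsAsFactors = FALSE),
            path,
            comments = c(paste("experimental:",
                               paste(design$experimental, collapse = ",")),
                         paste("control:",
                               paste(design$control, collapse = ","))))
  invisible(path)
}

#' Read / write ELISA measurements
#'
#' Long TSV layout: columns \code{peptide_id}, \code{subject_id},
#' \code{absorbance} (optical density, non-negative).
#'
#' @param path File path.
#' @return A data frame of measurements.
#' @export
read_elisa_measurements <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("peptide_id", "subject_id", "absorbance")
  if (!all(need %in% names(df)))
    stop("ELISA table ", path,
         ": need columns peptide_id, subject_id, absorbance")
  if (anyNA(df$absorbance) || any(df$absorbance < 0))
    stop("ELISA table ", path, ": absorbances must be non-negative")
  df[, need]
}

#' @rdname read_elisa_measurements
#' @param elisa Data frame with columns \code{peptide_id}, \code{subject_id},
#'   \code{absorbance}.
#' @export
write_elisa_measurements <- function(elisa, path) {
  write_tsv(elisa[, c("peptide_id", "subject_id", "absorbance")], path)
  invisible(path)
}
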