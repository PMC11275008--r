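#' Read a delimited numeric matrix with row identifiers
#'
#' Canonical reader for profile, agent-library and abundance matrices:
#' TSV (comma-delimited files are sniffed) with a header row, the first
#' column holding unique row identifiers, blanks/"NA" as missing.
#' Non-numeric cells and duplicate identifiers are reported with their
#' coordinates.
#'
#' @param path file path.
#' @return Numeric matrix with row and column names.
#' @export
readMatrixTSV <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (!grepl("\t", first) && grepl(",", first)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA"), quote = "\"",
                           comment.char = "")
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate row id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- raw[, -1L, drop = FALSE]
  mat <- matrix(NA_real_, nrow(vals), ncol(vals),
                dimnames = list(ids, names(vals)))
  for (j in seq_len(ncol(vals))) {
    col <- vals[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   col[bad[1]], ids[bad[1]], names(vals)[j]))
    mat[, j] <- num
  }
  mat
}

#' Write a numeric matrix as TSV with a row-id column
#'
#' Inverse of [readMatrixTSV()]; `NA` is written as an empty cell.
#'
#' @param mat named numeric matrix.
#' @param path output path.
#' @param idColumn header of the row-id column (default `"id"`).
#' @return Invisibly, `path`.
#' @export
writeMatrixTSV <- function(mat, path, idColumn = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read an activity profile from a matrix file
#'
#' @param path matrix file (compounds in rows, cell lines in columns).
#' @param compound row to extract; defaults to the first row.
#' @return An [ActivityProfile-class].
#' @export
readActivityProfile <- function(path, compound = NULL) {
  mat <- readMatrixTSV(path)
  if (is.null(compound)) compound <- rownames(mat)[1L]
  if (!compound %in% rownames(mat))
    stop("compound '", compound, "' not found in ", path)
  ActivityProfile(compound, mat[compound, ])
}

#' Read a resistance-marker table
#'
#' TSV with columns `marker`, `assay`, then one column per cell line.
#'
#' @param path file path.
#' @return Data frame suitable for [resistanceTable()].
#' @export
readMarkerTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE,
                           na.strings = c("", "NA"))
  if (!all(c("marker", "assay") %in% names(tab)))
    stop("marker table needs 'marker' and 'assay' columns")
  tab
}

#' Read survival cohorts from a long-format CSV/TSV
#'
#' Columns `cohort`, `time`, `event`, `expression` (extra columns are
#' kept); returns the named list of per-cohort tables that
#' [survivalScreen()] consumes.
#'
#' @param path file path.
#' @return Named list of data frames.
#' @export
readCohorts <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (!grepl("\t", first) && grepl(",", first)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("cohort", "time", "event", "expression")
  if (!all(need %in% names(tab)))
    stop("cohort file needs columns: ", paste(need, collapse = ", "))
  split(tab[setdiff(names(tab), "cohort")], tab$cohort)
}
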