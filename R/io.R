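# Delimited-text readers/writers for omics matrices, PPI edge lists and
# drug-response tables.  All are plain rectangular text: header row of
# feature/drug ids, first column of cell-line ids.  Parsing is done line by
# line so errors can name the offending row/column.

sep_char <- function(delim) {
  switch(match.arg(delim, c("tab", "comma")), tab = "\t", comma = ",")
}

# Parse a rectangular id-matrix file into row ids, column ids and a
# character value matrix.  Errors name the file line at fault.
read_table_raw <- function(path, sep) {
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) < 1L)
    stop("empty file: ", path, call. = FALSE)
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1L]]
  ncol_expected <- length(header)
  col_ids <- header[-1L]
  if (length(col_ids) < 1L)
    stop("no data columns in ", path, call. = FALSE)
  n <- length(fields) - 1L
  row_ids <- character(n)
  vals <- matrix(NA_character_, nrow = n, ncol = length(col_ids))
  for (i in seq_len(n)) {
    f <- fields[[i + 1L]]
    if (length(f) != ncol_expected)
      stop(sprintf("parse error in %s line %d: expected %d fields, found %d",
                   path, i + 1L, ncol_expected, length(f)), call. = FALSE)
    row_ids[i] <- f[1L]
    vals[i, ] <- f[-1L]
  }
  list(row_ids = row_ids, col_ids = col_ids, values = vals)
}

# Convert a character matrix to numeric, with location-aware errors.
# Cells equal to a token in `missing_tokens` become NA without complaint.
to_numeric_matrix <- function(chr, row_ids, col_ids, missing_tokens,
                              what, path) {
  num <- suppressWarnings(as.numeric(chr))
  bad <- is.na(num) & !(chr %in% missing_tokens)
  if (any(bad)) {
    idx <- which(bad)[1L]
    i <- (idx - 1L) %% nrow(chr) + 1L
    j <- (idx - 1L) %/% nrow(chr) + 1L
    stop(sprintf("non-numeric %s value %s in %s at row '%s', column '%s'",
                 what, dQuote(chr[i, j]), path, row_ids[i], col_ids[j]),
         call. = FALSE)
  }
  matrix(num, nrow = nrow(chr), dimnames = list(row_ids, col_ids))
}

fmt_num <- function(x) {
  # %.17g round-trips IEEE doubles exactly, so write->read is bit-identical
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

write_table_raw <- function(row_ids, col_ids, chr_values, path, sep) {
  header <- paste(c("id", col_ids), collapse = sep)
  body <- vapply(seq_along(row_ids), function(i)
    paste(c(row_ids[i], chr_values[i, ]), collapse = sep), "")
  writeLines(c(header, body), path)
}

#' Read an omics matrix from delimited text
#'
#' Expects a header row of feature ids and a first column of cell-line ids;
#' rows are cell lines, columns features.  Every cell must be numeric and
#' finite; duplicate ids and ragged rows are reported with their location.
#'
#' @param path file path.
#' @param omics_name,embedding_kind passed to [omics_matrix()].
#' @param delim `"tab"` (default) or `"comma"`.
#' @return An `omics_matrix`, preserving the file's row/column order.
#' @export
read_omics_matrix <- function(path, omics_name, embedding_kind,
                              delim = "tab") {
  sep <- sep_char(delim)
  raw <- read_table_raw(path, sep)
  if (anyDuplicated(raw$col_ids))
    stop("duplicate feature id in header of ", path, ": ",
         raw$col_ids[duplicated(raw$col_ids)][1L], call. = FALSE)
  if (anyDuplicated(raw$row_ids))
    stop("duplicate cell-line id in ", path, ": ",
         raw$row_ids[duplicated(raw$row_ids)][1L], call. = FALSE)
  vals <- to_numeric_matrix(raw$values, raw$row_ids, raw$col_ids,
                            character(), "omics", path)
  if (!all(is.finite(vals)))
    stop("non-finite omics value in ", path, call. = FALSE)
  omics_matrix(vals, omics_name, embedding_kind)
}

#' Write an omics matrix as delimited text
#'
#' Values are written with enough digits that reading the file back
#' reproduces the doubles exactly.
#'
#' @param m an `omics_matrix`.
#' @param path output file path.
#' @param delim `"tab"` or `"comma"`.
#' @export
write_omics_matrix <- function(m, path, delim = "tab") {
  stopifnot(inherits(m, "omics_matrix"))
  sep <- sep_char(delim)
  chr <- matrix(fmt_num(m$values), nrow = nrow(m$values))
  write_table_raw(m$cell_line_ids, m$feature_ids, chr, path, sep)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' Two whitespace- or tab-separated symbols per line (HINT-style).  Edges
#' are unordered and deduplicated; self-pairs are dropped.
#'
#' @param path file path.
#' @return An `interactome_edges` object.
#' @export
read_ppi_edges <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(interactome_edges(matrix(character(), ncol = 2L)))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    i <- which(nf != 2L)[1L]
    stop(sprintf("parse error in %s line %d: expected 2 fields, found %d",
                 path, i, nf[i]), call. = FALSE)
  }
  interactome_edges(do.call(rbind, fields))
}

#' Write a protein-protein interaction edge list
#' @param edges an `interactome_edges` object.
#' @param path output file path.
#' @export
write_ppi_edges <- function(edges, path) {
  stopifnot(inherits(edges, "interactome_edges"))
  writeLines(paste(edges$edges[, 1L], edges$edges[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Read a drug-response (log IC50) table
#'
#' Rows are cell lines, columns drugs.  Cells equal to `missing_token`
#' become unobserved entries in the mask; everything else must be numeric.
#' Responses are taken as already on the log scale; set `log_transform` for
#' raw micromolar IC50 files.
#'
#' @param path file path.
#' @param missing_token string marking unobserved responses (default "NA").
#' @param delim `"tab"` or `"comma"`.
#' @param log_transform apply natural log to observed values on load.
#' @return A `drug_response_table`.
#' @export
read_drug_responses <- function(path, missing_token = "NA", delim = "tab",
                                log_transform = FALSE) {
  sep <- sep_char(delim)
  raw <- read_table_raw(path, sep)
  if (anyDuplicated(raw$col_ids))
    stop("duplicate drug id in header of ", path, ": ",
         raw$col_ids[duplicated(raw$col_ids)][1L], call. = FALSE)
  if (anyDuplicated(raw$row_ids))
    stop("duplicate cell-line id in ", path, ": ",
         raw$row_ids[duplicated(raw$row_ids)][1L], call. = FALSE)
  vals <- to_numeric_matrix(raw$values, raw$row_ids, raw$col_ids,
                            missing_token, "response", path)
  if (log_transform) vals <- log(vals)
  drug_response_table(vals)
}

#' Write a drug-response table as delimited text
#' @param r a `drug_response_table`.
#' @param path output file path.
#' @param missing_token string written for unobserved entries.
#' @param delim `"tab"` or `"comma"`.
#' @export
write_drug_responses <- function(r, path, missing_token = "NA",
                                 delim = "tab") {
  stopifnot(inherits(r, "drug_response_table"))
  sep <- sep_char(delim)
  chr <- matrix(fmt_num(r$values), nrow = nrow(r$values))
  chr[!r$observed_mask] <- missing_token
  write_table_raw(r$cell_line_ids, r$drug_ids, chr, path, sep)
  invisible(path)
}
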