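#' @keywords internal
"_PACKAGE"

OMICS_NAMES <- c("expression", "mutation", "cnv", "rppa", "metabolomics")
EMBEDDING_KINDS <- c("graph", "dense")

#' Construct an omics block
#'
#' An omics block is one measurement modality (mRNA expression, mutations,
#' copy-number variation, RPPA protein expression or metabolomics) stored as
#' a cell-line-by-feature numeric matrix, together with the embedding kind
#' its sub-network should use: `"graph"` for a first layer masked by a
#' protein-protein interaction adjacency, `"dense"` for an ordinary dense
#' first layer.
#'
#' @param values numeric matrix, rows = cell lines, columns = features.
#' @param omics_name one of `"expression"`, `"mutation"`, `"cnv"`, `"rppa"`,
#'   `"metabolomics"`.
#' @param embedding_kind `"graph"` or `"dense"`.
#' @param cell_line_ids,feature_ids character vectors; default to the
#'   dimnames of `values`.
#' @return An object of class `omics_matrix` with fields `omics_name`,
#'   `cell_line_ids`, `feature_ids`, `values`, `embedding_kind`.
#' @export
omics_matrix <- function(values, omics_name, embedding_kind,
                         cell_line_ids = rownames(values),
                         feature_ids = colnames(values)) {
  omics_name <- match.arg(omics_name, OMICS_NAMES)
  embedding_kind <- match.arg(embedding_kind, EMBEDDING_KINDS)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_line_ids) || is.null(feature_ids))
    stop("omics_matrix requires cell-line and feature ids", call. = FALSE)
  cell_line_ids <- as.character(cell_line_ids)
  feature_ids <- as.character(feature_ids)
  if (anyDuplicated(cell_line_ids))
    stop("duplicate cell-line id: ",
         cell_line_ids[duplicated(cell_line_ids)][1L], call. = FALSE)
  if (anyDuplicated(feature_ids))
    stop("duplicate feature id: ",
         feature_ids[duplicated(feature_ids)][1L], call. = FALSE)
  if (nrow(values) != length(cell_line_ids) ||
      ncol(values) != length(feature_ids))
    stop("values dimensions do not match id lists", call. = FALSE)
  if (!all(is.finite(values)))
    stop("omics matrix contains non-finite entries", call. = FALSE)
  dimnames(values) <- list(cell_line_ids, feature_ids)
  structure(list(omics_name = omics_name,
                 cell_line_ids = cell_line_ids,
                 feature_ids = feature_ids,
                 values = values,
                 embedding_kind = embedding_kind),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %s (%s embedding): %d cell lines x %d features\n",
              x$omics_name, x$embedding_kind,
              length(x$cell_line_ids), length(x$feature_ids)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Construct an interactome edge set
#'
#' Binary protein-protein interactions stored as an unordered, deduplicated
#' set of symbol pairs; `(a, b)` and `(b, a)` are the same edge.  Self-pairs
#' are dropped (the adjacency diagonal is set separately by
#' [build_adjacency()]).
#'
#' @param pairs two-column character matrix or data frame of symbols.
#' @return Object of class `interactome_edges` with fields `edges`
#'   (two-column character matrix in canonical order) and `node_symbols`.
#' @export
interactome_edges <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (length(pairs) == 0L) {
    pairs <- matrix(character(), ncol = 2L)
  }
  if (ncol(pairs) != 2L)
    stop("edge table must have exactly two columns", call. = FALSE)
  mode(pairs) <- "character"
  pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (nrow(pairs) > 0L) {
    canon <- t(apply(pairs, 1L, sort))
    canon <- canon[!duplicated(paste(canon[, 1L], canon[, 2L], sep = "\r")),
                   , drop = FALSE]
  } else {
    canon <- pairs
  }
  colnames(canon) <- c("a", "b")
  structure(list(edges = canon,
                 node_symbols = sort(unique(as.vector(canon)))),
            class = "interactome_edges")
}

#' @export
print.interactome_edges <- function(x, ...) {
  cat(sprintf("<interactome_edges> %d edges over %d symbols\n",
              nrow(x$edges), length(x$node_symbols)))
  invisible(x)
}

#' Number of edges in an interactome
#' @param edges an `interactome_edges` object.
#' @return integer edge count.
#' @export
n_edges <- function(edges) {
  stopifnot(inherits(edges, "interactome_edges"))
  nrow(edges$edges)
}

#' Construct a drug-response table
#'
#' Log IC50 drug responses as a cell-line-by-drug matrix with an observed
#' mask; unobserved entries are `NA` in `values` and `FALSE` in the mask.
#' Lower log IC50 means a more effective drug.
#'
#' @param values numeric matrix (log IC50), `NA` where unobserved.
#' @param cell_line_ids,drug_ids character vectors; default to dimnames.
#' @param observed_mask logical matrix; defaults to `!is.na(values)`.
#' @return Object of class `drug_response_table`.
#' @export
drug_response_table <- function(values,
                                cell_line_ids = rownames(values),
                                drug_ids = colnames(values),
                                observed_mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_line_ids) || is.null(drug_ids))
    stop("drug_response_table requires cell-line and drug ids", call. = FALSE)
  cell_line_ids <- as.character(cell_line_ids)
  drug_ids <- as.character(drug_ids)
  if (anyDuplicated(cell_line_ids))
    stop("duplicate cell-line id: ",
         cell_line_ids[duplicated(cell_line_ids)][1L], call. = FALSE)
  if (anyDuplicated(drug_ids))
    stop("duplicate drug id: ", drug_ids[duplicated(drug_ids)][1L],
         call. = FALSE)
  if (is.null(observed_mask)) observed_mask <- !is.na(values)
  observed_mask <- as.matrix(observed_mask)
  if (!identical(dim(observed_mask), dim(values)))
    stop("observed mask shape does not match values", call. = FALSE)
  if (nrow(values) != length(cell_line_ids) ||
      ncol(values) != length(drug_ids))
    stop("values dimensions do not match id lists", call. = FALSE)
  obs <- values[observed_mask]
  if (any(!is.finite(obs)))
    stop("observed responses must be finite", call. = FALSE)
  values[!observed_mask] <- NA_real_
  dimnames(values) <- list(cell_line_ids, drug_ids)
  dimnames(observed_mask) <- dimnames(values)
  structure(list(cell_line_ids = cell_line_ids,
                 drug_ids = drug_ids,
                 values = values,
                 observed_mask = observed_mask),
            class = "drug_response_table")
}

#' @export
print.drug_response_table <- function(x, ...) {
  cat(sprintf("<drug_response_table> %d cell lines x %d drugs (%.1f%% observed)\n",
              length(x$cell_line_ids), length(x$drug_ids),
              100 * mean(x$observed_mask)))
  invisible(x)
}

#' Construct a multi-omics dataset
#'
#' Bundles M omics blocks sharing one cell-line ordering, the drug-response
#' table on the same cell lines, and, for graph-embedded blocks, their PPI
#' adjacency masks.
#'
#' @param blocks named list of `omics_matrix` objects with identical
#'   cell-line id sequences.
#' @param responses a `drug_response_table` on the same cell lines.
#' @param adjacency named list of adjacency matrices (see
#'   [build_adjacency()]) for the graph-embedded blocks; may be `NULL`.
#' @return Object of class `multi_omics_dataset`.
#' @export
multi_omics_dataset <- function(blocks, responses, adjacency = NULL) {
  if (length(blocks) < 1L) stop("need at least one omics block", call. = FALSE)
  stopifnot(all(vapply(blocks, inherits, TRUE, "omics_matrix")),
            inherits(responses, "drug_response_table"))
  names(blocks) <- vapply(blocks, function(b) b$omics_name, "")
  if (anyDuplicated(names(blocks)))
    stop("duplicate omics block names", call. = FALSE)
  ref <- blocks[[1L]]$cell_line_ids
  for (b in blocks)
    if (!identical(b$cell_line_ids, ref))
      stop("all blocks must share one cell-line ordering", call. = FALSE)
  if (!identical(responses$cell_line_ids, ref))
    stop("responses must share the blocks' cell-line ordering", call. = FALSE)
  if (!is.null(adjacency)) {
    for (nm in names(adjacency)) {
      if (!nm %in% names(blocks))
        stop("adjacency given for unknown block: ", nm, call. = FALSE)
      if (!identical(rownames(adjacency[[nm]]), blocks[[nm]]$feature_ids))
        stop("adjacency feature order must match block ", nm, call. = FALSE)
    }
  }
  structure(list(blocks = blocks, responses = responses,
                 adjacency = adjacency),
            class = "multi_omics_dataset")
}

#' @export
print.multi_omics_dataset <- function(x, ...) {
  cat(sprintf("<multi_omics_dataset> %d cell lines, %d drugs, blocks: %s\n",
              length(x$responses$cell_line_ids), length(x$responses$drug_ids),
              paste(names(x$blocks), collapse = ", ")))
  invisible(x)
}
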