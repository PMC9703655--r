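# Preprocessing: low-information feature filtering, per-feature
# standardization (train-fold statistics), cell-line alignment across
# blocks, coverage-based drug selection, and PPI adjacency construction.

#' Drop features that are zero in more than a given fraction of cell lines
#'
#' A feature is removed when its fraction of exactly-zero values is strictly
#' greater than `zero_fraction` (the default 0.95 mirrors the "over 95% of
#' cell lines" rule applied to expression, mutation and CNV features alike).
#' Surviving features keep their original order; the operation is
#' idempotent.
#'
#' @param m an `omics_matrix`.
#' @param zero_fraction threshold in (0, 1].
#' @return Filtered `omics_matrix`.
#' @export
filter_low_information_features <- function(m, zero_fraction = 0.95) {
  stopifnot(inherits(m, "omics_matrix"),
            zero_fraction > 0, zero_fraction <= 1)
  zero_frac <- colMeans(m$values == 0)
  keep <- zero_frac <= zero_fraction
  if (!any(keep))
    stop("empty omics block: every ", m$omics_name,
         " feature is zero in more than ", 100 * zero_fraction,
         "% of cell lines", call. = FALSE)
  omics_matrix(m$values[, keep, drop = FALSE], m$omics_name,
               m$embedding_kind)
}

#' Per-feature standardization statistics
#'
#' @param feature_ids character vector.
#' @param center,scale numeric vectors of per-feature mean and scale.
#' @return Object of class `standardization_stats`.
#' @export
standardization_stats <- function(feature_ids, center, scale) {
  stopifnot(length(feature_ids) == length(center),
            length(center) == length(scale), all(scale > 0))
  structure(list(feature_ids = as.character(feature_ids),
                 center = as.numeric(center), scale = as.numeric(scale)),
            class = "standardization_stats")
}

#' Standardize an omics block
#'
#' With `stats = NULL`, computes per-feature mean and sample standard
#' deviation (denominator n-1) on the given rows and applies
#' `(x - mean) / scale`; constant features get scale 1 so they map to zero
#' rather than NaN.  With `stats` supplied (the train-fold path), applies
#' those statistics after checking that the feature ids match.
#'
#' @param m an `omics_matrix`.
#' @param stats `standardization_stats` from a training fold, or `NULL`.
#' @return list with elements `matrix` (standardized `omics_matrix`) and
#'   `stats` (the statistics used).
#' @export
standardize <- function(m, stats = NULL) {
  stopifnot(inherits(m, "omics_matrix"))
  if (is.null(stats)) {
    center <- colMeans(m$values)
    scale <- apply(m$values, 2L, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
    stats <- standardization_stats(m$feature_ids, center, scale)
  } else {
    stopifnot(inherits(stats, "standardization_stats"))
    if (!identical(stats$feature_ids, m$feature_ids))
      stop("standardization statistics do not match block feature ids",
           call. = FALSE)
  }
  std <- sweep(sweep(m$values, 2L, stats$center, "-"), 2L, stats$scale, "/")
  list(matrix = omics_matrix(std, m$omics_name, m$embedding_kind),
       stats = stats)
}

#' Align omics blocks and responses on their common cell lines
#'
#' Keeps only the cell lines present in every block and in the response
#' table, re-indexing all tables to the sorted intersection so the result
#' is deterministic and invariant to the order in which blocks are given.
#'
#' @param blocks list of `omics_matrix` objects.
#' @param responses a `drug_response_table`.
#' @param adjacency optional named list of adjacency matrices per graph
#'   block, carried into the result.
#' @return A `multi_omics_dataset`.
#' @export
align_cell_lines <- function(blocks, responses, adjacency = NULL) {
  stopifnot(length(blocks) >= 1L, inherits(responses, "drug_response_table"))
  common <- Reduce(intersect, lapply(blocks, function(b) b$cell_line_ids),
                   responses$cell_line_ids)
  if (length(common) == 0L)
    stop("no cell line is present in all omics blocks and the response table",
         call. = FALSE)
  common <- sort(common)
  blocks <- lapply(blocks, function(b)
    omics_matrix(b$values[common, , drop = FALSE], b$omics_name,
                 b$embedding_kind))
  r <- drug_response_table(responses$values[common, , drop = FALSE])
  multi_omics_dataset(blocks, r, adjacency)
}

#' Keep drugs tested on more than a given fraction of cell lines
#'
#' With `k = NULL`, keeps every drug observed in strictly more than
#' `coverage` of the cell lines (the "tested on more than 95% of the cell
#' lines" rule).  With `k` given, keeps the `k` highest-coverage drugs,
#' breaking coverage ties by drug id.  Survivors preserve input order.
#'
#' @param r a `drug_response_table`.
#' @param coverage threshold in \[0, 1\]; 0 keeps every drug with at least
#'   one observation.
#' @param k optional count of drugs to keep.
#' @return Filtered `drug_response_table`.
#' @export
select_top_drugs <- function(r, coverage = 0.95, k = NULL) {
  stopifnot(inherits(r, "drug_response_table"),
            coverage >= 0, coverage <= 1)
  frac <- colMeans(r$observed_mask)
  if (is.null(k)) {
    keep <- which(frac > coverage)
  } else {
    stopifnot(k >= 1L, k <= length(r$drug_ids))
    ord <- order(-frac, r$drug_ids)
    keep <- sort(ord[seq_len(k)])
  }
  if (length(keep) == 0L)
    stop("no drug is observed in more than ", 100 * coverage,
         "% of cell lines", call. = FALSE)
  drug_response_table(r$values[, keep, drop = FALSE])
}

#' Build a binary PPI adjacency mask for one feature list
#'
#' `A[i, j] = 1` iff features i and j interact in the edge set or `i = j`;
#' the matrix is symmetric with a unit diagonal, so a gene's own measurement
#' always reaches its hidden unit and interactome-absent features keep only
#' their self-loop.
#'
#' @param edges an `interactome_edges` object.
#' @param feature_ids ordered feature symbols of the paired omics block.
#' @return Binary symmetric matrix with `feature_ids` dimnames, class
#'   `adjacency_matrix`.
#' @export
build_adjacency <- function(edges, feature_ids) {
  stopifnot(inherits(edges, "interactome_edges"))
  feature_ids <- as.character(feature_ids)
  stopifnot(!anyDuplicated(feature_ids))
  p <- length(feature_ids)
  A <- diag(1, p)
  dimnames(A) <- list(feature_ids, feature_ids)
  e <- edges$edges
  keep <- e[, 1L] %in% feature_ids & e[, 2L] %in% feature_ids
  e <- e[keep, , drop = FALSE]
  if (nrow(e) > 0L) {
    i <- match(e[, 1L], feature_ids)
    j <- match(e[, 2L], feature_ids)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  class(A) <- c("adjacency_matrix", class(A))
  A
}
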