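# Evaluation statistics: masked MSE, per-drug-averaged R^2, Top-k drug
# accuracy, per-drug MSE ranking, and attention-score reporting.

#' Bundle predictions with truths for evaluation
#'
#' @param predictions,truths numeric matrices (cell lines x drugs).
#' @param observed_mask logical matrix; defaults to `!is.na(truths)`.
#' @param drug_ids,cell_line_ids character vectors; default to dimnames.
#' @return Object of class `prediction_set`.
#' @export
prediction_set <- function(predictions, truths, observed_mask = NULL,
                           drug_ids = colnames(truths),
                           cell_line_ids = rownames(truths)) {
  predictions <- as.matrix(predictions)
  truths <- as.matrix(truths)
  if (is.null(observed_mask)) observed_mask <- !is.na(truths)
  observed_mask <- as.matrix(observed_mask)
  stopifnot(identical(dim(predictions), dim(truths)),
            identical(dim(predictions), dim(observed_mask)))
  if (is.null(drug_ids)) drug_ids <- sprintf("D%02d", seq_len(ncol(truths)))
  if (is.null(cell_line_ids))
    cell_line_ids <- sprintf("CL%04d", seq_len(nrow(truths)))
  structure(list(predictions = predictions, truths = truths,
                 observed_mask = observed_mask,
                 drug_ids = as.character(drug_ids),
                 cell_line_ids = as.character(cell_line_ids)),
            class = "prediction_set")
}

#' Mean squared error of a prediction set
#'
#' `MSE = (1 / n_obs) sum (y - yhat)^2` over observed entries; with a fully
#' observed table this is the `1 / (n_c n_d)` double sum.
#'
#' @param ps a `prediction_set`.
#' @return scalar MSE.
#' @export
mse <- function(ps) {
  stopifnot(inherits(ps, "prediction_set"))
  masked_mse_loss(ps$predictions, ifelse(ps$observed_mask, ps$truths, 0),
                  ps$observed_mask)
}

#' Per-drug-averaged coefficient of determination
#'
#' For each drug j, `1 - SSres_j / SStot_j` with the drug's mean truth on
#' the evaluated set as baseline, averaged over drugs.  Equals 1 under
#' perfect prediction, 0 when every prediction is the per-drug mean, and
#' can be arbitrarily negative.  Drugs with fewer than two observed cells
#' or constant truths are excluded with a warning.
#'
#' @param ps a `prediction_set`.
#' @return scalar R-squared.
#' @export
r_squared <- function(ps) {
  stopifnot(inherits(ps, "prediction_set"))
  vals <- vapply(seq_along(ps$drug_ids), function(j) {
    obs <- ps$observed_mask[, j]
    y <- ps$truths[obs, j]
    if (length(y) < 2L) return(NA_real_)
    sstot <- sum((y - mean(y))^2)
    if (sstot == 0) return(NA_real_)
    1 - sum((y - ps$predictions[obs, j])^2) / sstot
  }, numeric(1L))
  if (anyNA(vals)) {
    warning("excluded ", sum(is.na(vals)),
            " drug(s) with constant or insufficient observed truths ",
            "from R^2", call. = FALSE)
    vals <- vals[!is.na(vals)]
  }
  if (length(vals) == 0L)
    stop("no drug has enough non-constant observed truths for R^2",
         call. = FALSE)
  mean(vals)
}

#' Top-k drug recommendation accuracy
#'
#' For each cell line, the truly most effective drug is the one with the
#' lowest observed true log IC50 (ties broken by drug id).  The cell line
#' counts as a hit when that drug is among the k lowest predicted values
#' over its observed drugs.  Returns `100 * hits / cells`.
#'
#' @param ps a `prediction_set`.
#' @param k number of top predicted drugs considered.
#' @return accuracy percentage.
#' @export
top_k_accuracy <- function(ps, k) {
  stopifnot(inherits(ps, "prediction_set"), k >= 1L)
  id_rank <- order(ps$drug_ids)          # lexical tie-break, deterministic
  tie <- match(seq_along(ps$drug_ids), id_rank)
  hits <- 0L; cells <- 0L; short <- 0L
  for (i in seq_len(nrow(ps$truths))) {
    obs <- which(ps$observed_mask[i, ])
    if (length(obs) < k) { short <- short + 1L; next }
    y <- ps$truths[i, obs]
    best <- obs[order(y, tie[obs])[1L]]
    p <- ps$predictions[i, obs]
    topk <- obs[order(p, tie[obs])[seq_len(k)]]
    hits <- hits + (best %in% topk)
    cells <- cells + 1L
  }
  if (short > 0L)
    warning(short, " cell line(s) with fewer than k observed drugs ",
            "skipped in Top-k accuracy", call. = FALSE)
  if (cells == 0L) stop("no cell line has k observed drugs", call. = FALSE)
  100 * hits / cells
}

#' Rank drugs by prediction accuracy (per-drug MSE)
#'
#' @param ps a `prediction_set`.
#' @return data frame with columns `drug_id` and `mse`, ascending MSE, ties
#'   broken by drug id.
#' @export
per_drug_mse_ranking <- function(ps) {
  stopifnot(inherits(ps, "prediction_set"))
  per <- vapply(seq_along(ps$drug_ids), function(j) {
    obs <- ps$observed_mask[, j]
    if (!any(obs)) return(NA_real_)
    mean((ps$truths[obs, j] - ps$predictions[obs, j])^2)
  }, numeric(1L))
  ord <- order(per, ps$drug_ids)
  data.frame(drug_id = ps$drug_ids[ord], mse = per[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write attention scores as TSV and a heatmap
#'
#' Scores are written untransformed; columns must sum to 1 over omics
#' (within 1e-6) or an error is raised.
#'
#' @param scores M x n_d matrix from [attention_scores()], rownames =
#'   omics, colnames = drugs.
#' @param tsv_path output TSV path.
#' @param heatmap_path optional PNG path for a [pheatmap::pheatmap()]
#'   heatmap.
#' @return invisibly, the TSV path.
#' @export
attention_report <- function(scores, tsv_path, heatmap_path = NULL) {
  scores <- as.matrix(scores)
  if (any(abs(colSums(scores) - 1) > 1e-6))
    stop("attention scores violate normalization: columns must sum to 1",
         call. = FALSE)
  if (is.null(rownames(scores)))
    rownames(scores) <- sprintf("omics%d", seq_len(nrow(scores)))
  if (is.null(colnames(scores)))
    colnames(scores) <- sprintf("D%02d", seq_len(ncol(scores)))
  chr <- matrix(fmt_num(scores), nrow = nrow(scores))
  write_table_raw(rownames(scores), colnames(scores), chr, tsv_path, "\t")
  if (!is.null(heatmap_path)) {
    grDevices::png(heatmap_path, width = 1200, height = 400, res = 120)
    pheatmap::pheatmap(scores, cluster_rows = FALSE, cluster_cols = FALSE,
                       breaks = seq(0, 1, length.out = 101),
                       main = "Attention scores per omics and drug")
    grDevices::dev.off()
  }
  invisible(tsv_path)
}

#' Read an attention-score TSV back
#' @param path TSV written by [attention_report()].
#' @return numeric matrix of scores.
#' @export
read_attention_scores <- function(path) {
  raw <- read_table_raw(path, "\t")
  to_numeric_matrix(raw$values, raw$row_ids, raw$col_ids, character(),
                    "attention score", path)
}

#' Ridge-regression baseline on concatenated omics features
#'
#' Independent per-drug ridge fit (closed form) on the observed training
#' responses; serves as the linear reference the network is compared
#' against on synthetic data.
#'
#' @param X_train,X_test numeric feature matrices (standardized,
#'   concatenated blocks).
#' @param Y_train numeric response matrix with `NA` for unobserved.
#' @param lambda ridge penalty (default 1, the common library default for
#'   standardized features).
#' @return predicted response matrix for `X_test`.
#' @export
ridge_baseline <- function(X_train, Y_train, X_test, lambda = 1) {
  stopifnot(nrow(X_train) == nrow(Y_train))
  p <- ncol(X_train)
  pred <- matrix(NA_real_, nrow(X_test), ncol(Y_train),
                 dimnames = list(rownames(X_test), colnames(Y_train)))
  for (j in seq_len(ncol(Y_train))) {
    obs <- !is.na(Y_train[, j])
    Xo <- X_train[obs, , drop = FALSE]
    yo <- Y_train[obs, j]
    ctr <- mean(yo)
    beta <- solve(crossprod(Xo) + lambda * diag(p), crossprod(Xo, yo - ctr))
    pred[, j] <- X_test %*% beta + ctr
  }
  pred
}
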