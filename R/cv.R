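# Cross-validation and ablation drivers.  Each fold fits preprocessing
# statistics and both training stages on the training cell lines only;
# held-out cells are evaluated with MSE, per-drug R^2 and Top-1/Top-3
# accuracy.  The ablation driver trains stage 1 once per fold and varies
# only the attention fusion over omics subsets.

#' Partition cell lines into cross-validation folds
#'
#' Uniform random partition, balanced to within one cell line,
#' reproducible from the seed.
#'
#' @param cell_ids character vector of cell-line ids.
#' @param n_folds number of folds.
#' @param seed integer RNG seed.
#' @return named integer vector of fold assignments (1..n_folds).
#' @export
make_folds <- function(cell_ids, n_folds, seed) {
  stopifnot(n_folds >= 2L, length(cell_ids) >= n_folds)
  set.seed(as.integer(seed))
  fold <- stats::setNames(rep(NA_integer_, length(cell_ids)), cell_ids)
  fold[sample(cell_ids)] <- rep(seq_len(n_folds),
                                length.out = length(cell_ids))
  fold
}

subset_dataset <- function(data, ids) {
  blocks <- lapply(data$blocks, function(b)
    omics_matrix(b$values[ids, , drop = FALSE], b$omics_name,
                 b$embedding_kind))
  multi_omics_dataset(blocks,
                      drug_response_table(data$responses$values[ids, ,
                                                                drop = FALSE]),
                      data$adjacency)
}

fold_cfg <- function(cfg, fold) {
  cfg$seed <- cfg$seed + 1000L * fold
  cfg
}

eval_on_test <- function(model, test_data) {
  pred <- stats::predict(model, test_data$blocks)
  ps <- prediction_set(pred, test_data$responses$values,
                       test_data$responses$observed_mask,
                       drug_ids = test_data$responses$drug_ids,
                       cell_line_ids = test_data$responses$cell_line_ids)
  list(ps = ps,
       mse = mse(ps),
       r2 = r_squared(ps),
       top1 = top_k_accuracy(ps, 1L),
       top3 = top_k_accuracy(ps, 3L))
}

#' Cross-validate the two-stage model
#'
#' For each fold, feature filtering, standardization and both training
#' stages are fit on the training cells only; the held-out cells are scored
#' with MSE, per-drug-averaged R^2 and Top-1/Top-3 drug accuracy.  Fully
#' deterministic for a fixed config seed.
#'
#' @param data a `multi_omics_dataset`.
#' @param cfg a [training_config()].
#' @return list with `per_fold` (data frame of fold metrics), `aggregate`
#'   (mean and sample sd per metric), `attention` (per-fold and mean
#'   M x n_d attention-score matrices) and `folds` (the assignment).
#' @export
cross_validate <- function(data, cfg) {
  stopifnot(inherits(data, "multi_omics_dataset"),
            inherits(cfg, "training_config"))
  ids <- data$responses$cell_line_ids
  folds <- make_folds(ids, cfg$n_folds, cfg$seed)
  per_fold <- NULL
  att_scores <- list()
  for (f in seq_len(cfg$n_folds)) {
    train_ids <- ids[folds != f]
    test_ids <- ids[folds == f]
    stopifnot(length(intersect(train_ids, test_ids)) == 0L)
    model <- train_model(subset_dataset(data, train_ids), fold_cfg(cfg, f))
    ev <- eval_on_test(model, subset_dataset(data, test_ids))
    per_fold <- rbind(per_fold,
                      data.frame(fold = f, mse = ev$mse, r2 = ev$r2,
                                 top1 = ev$top1, top3 = ev$top3))
    att_scores[[f]] <- attention_scores(
      attention_normalize(model$attention$W3, model$attention$k),
      omics_names = model$omics, drug_ids = model$drug_ids)
  }
  agg <- data.frame(metric = c("mse", "r2", "top1", "top3"),
                    mean = vapply(per_fold[, -1L], mean, 0),
                    sd = vapply(per_fold[, -1L], stats::sd, 0),
                    row.names = NULL)
  list(per_fold = per_fold, aggregate = agg,
       attention = list(per_fold = att_scores,
                        mean = Reduce(`+`, att_scores) / length(att_scores)),
       folds = folds)
}

omics_short <- c(expression = "exp", mutation = "mut", cnv = "cnv",
                 rppa = "rppa", metabolomics = "metabolites")

#' Label an omics combination
#' @param omics character vector of omics names.
#' @return hyphen-joined short label (e.g. `"mut-rppa"`).
#' @export
combination_label <- function(omics) {
  paste(ifelse(omics %in% names(omics_short), omics_short[omics], omics),
        collapse = "-")
}

#' Parse a combination label back to omics names
#' @param label label produced by [combination_label()].
#' @return character vector of omics names.
#' @export
parse_combination <- function(label) {
  short <- strsplit(label, "-", fixed = TRUE)[[1L]]
  long <- names(omics_short)[match(short, omics_short)]
  ifelse(is.na(long), short, long)
}

all_subsets <- function(omics) {
  n <- length(omics)
  out <- list()
  for (bits in seq_len(2^n - 1L))
    out[[bits]] <- omics[bitwAnd(bits, 2^(seq_len(n) - 1L)) > 0L]
  out
}

#' Ablation over all omics combinations
#'
#' Per fold, stage-1 sub-networks are trained once on all blocks and reused
#' across combinations; one attention stage is trained per non-empty omics
#' subset (set `retrain_subnets` to refit stage 1 per combination).  Test
#' MSE and R^2 are averaged over folds and the table is sorted by MSE
#' ascending, best combination first.
#'
#' @param data a `multi_omics_dataset` with at least two blocks.
#' @param cfg a [training_config()].
#' @param retrain_subnets refit stage 1 for every combination.
#' @return list with `table` (data frame: combination, mse, r2, sorted by
#'   mse) and `per_fold` (unsorted long data frame).
#' @export
ablation_run <- function(data, cfg, retrain_subnets = FALSE) {
  stopifnot(inherits(data, "multi_omics_dataset"),
            length(data$blocks) >= 2L)
  omics <- names(data$blocks)
  combos <- all_subsets(omics)
  ids <- data$responses$cell_line_ids
  folds <- make_folds(ids, cfg$n_folds, cfg$seed)
  per_fold <- NULL
  for (f in seq_len(cfg$n_folds)) {
    train_data <- subset_dataset(data, ids[folds != f])
    test_data <- subset_dataset(data, ids[folds == f])
    cfg_f <- fold_cfg(cfg, f)
    full <- if (retrain_subnets) NULL else train_model(train_data, cfg_f)
    for (combo in combos) {
      model <- if (retrain_subnets)
        train_model(train_data, cfg_f, omics_subset = combo)
      else
        train_model(train_data, cfg_f, omics_subset = combo,
                    subnets = full$subnets, stats = full$stats)
      ev <- eval_on_test(model, test_data)
      per_fold <- rbind(per_fold,
                        data.frame(fold = f,
                                   combination = combination_label(combo),
                                   mse = ev$mse, r2 = ev$r2))
    }
  }
  tab <- do.call(rbind, lapply(split(per_fold, per_fold$combination),
                               function(d)
    data.frame(combination = d$combination[1L], mse = mean(d$mse),
               r2 = mean(d$r2), mse_sd = stats::sd(d$mse),
               r2_sd = stats::sd(d$r2))))
  tab <- tab[order(tab$mse, tab$combination), ]
  rownames(tab) <- NULL
  list(table = tab, per_fold = per_fold)
}
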