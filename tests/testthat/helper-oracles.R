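# Independent explicit-loop oracles the vectorized implementations are
# checked against, plus tiny fixture builders.  The oracles deliberately
# use scalar loops and the textbook formulas only.

oracle_mse <- function(pred, truth, mask) {
  s <- 0; n <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred)))
    if (mask[i, j]) { s <- s + (truth[i, j] - pred[i, j])^2; n <- n + 1 }
  s / n
}

oracle_r2 <- function(pred, truth, mask) {
  vals <- c()
  for (j in seq_len(ncol(pred))) {
    y <- c(); p <- c()
    for (i in seq_len(nrow(pred)))
      if (mask[i, j]) { y <- c(y, truth[i, j]); p <- c(p, pred[i, j]) }
    if (length(y) < 2) next
    ybar <- mean(y)
    sstot <- sum((y - ybar)^2)
    if (sstot == 0) next
    vals <- c(vals, 1 - sum((y - p)^2) / sstot)
  }
  mean(vals)
}

oracle_topk <- function(pred, truth, mask, k, drug_ids) {
  hits <- 0; cells <- 0
  for (i in seq_len(nrow(pred))) {
    obs <- which(mask[i, ])
    if (length(obs) < k) next
    o <- obs[order(truth[i, obs], drug_ids[obs])]
    best <- o[1]
    ok <- obs[order(pred[i, obs], drug_ids[obs])][seq_len(k)]
    if (best %in% ok) hits <- hits + 1
    cells <- cells + 1
  }
  100 * hits / cells
}

oracle_ranking <- function(pred, truth, mask, drug_ids) {
  per <- numeric(ncol(pred))
  for (j in seq_len(ncol(pred))) {
    s <- 0; n <- 0
    for (i in seq_len(nrow(pred)))
      if (mask[i, j]) { s <- s + (truth[i, j] - pred[i, j])^2; n <- n + 1 }
    per[j] <- s / n
  }
  ord <- order(per, drug_ids)
  data.frame(drug_id = drug_ids[ord], mse = per[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

oracle_attention_normalize <- function(W3) {
  d <- dim(W3)
  W <- array(0, dim = d)
  for (dd in seq_len(d[1])) for (i in seq_len(d[3])) {
    denom <- 0
    for (m in seq_len(d[2])) denom <- denom + exp(W3[dd, m, i])
    for (m in seq_len(d[2]))
      W[dd, m, i] <- exp(W3[dd, m, i]) * as.numeric(dd == i) / denom
  }
  W
}

oracle_dense_forward <- function(x, W, b, f) {
  out <- numeric(ncol(W))
  for (j in seq_len(ncol(W))) {
    s <- b[j]
    for (i in seq_len(nrow(W))) s <- s + W[i, j] * x[i]
    out[j] <- f(s)
  }
  out
}

oracle_graph_forward <- function(x, W, A, b, f) {
  out <- numeric(ncol(W))
  for (j in seq_len(ncol(W))) {
    s <- b[j]
    for (i in seq_len(nrow(W))) s <- s + W[i, j] * A[i, j] * x[i]
    out[j] <- f(s)
  }
  out
}

relu_s <- function(x) max(x, 0)

random_prediction_set <- function(n_c, n_d, missing = 0) {
  truth <- matrix(rnorm(n_c * n_d), n_c, n_d,
                  dimnames = list(sprintf("CL%03d", seq_len(n_c)),
                                  sprintf("D%02d", seq_len(n_d))))
  pred <- truth + matrix(rnorm(n_c * n_d, sd = 0.7), n_c, n_d)
  mask <- matrix(runif(n_c * n_d) >= missing, n_c, n_d)
  # keep at least 2 observed per drug and 1 per cell so statistics exist
  mask[1:2, ] <- TRUE
  mask[, 1] <- TRUE
  vals <- truth; vals[!mask] <- NA
  prediction_set(pred, vals, mask)
}

tiny_omics <- function(values, name = "expression", kind = "dense") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("CL%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("G%03d", seq_len(ncol(values)))
  omics_matrix(values, name, kind)
}

# Small simulated dataset for training tests (fast: few features/epochs).
small_sim <- function(seed = 5, n_cells = 150, n_drugs = 6,
                      counts = c(expression = 25, mutation = 20),
                      dominant = "mutation",
                      dominance = 0.9, noise_sd = 0.3, ...) {
  simulate_dataset(simulation_config(
    n_cells = n_cells, feature_counts = counts,
    dominant_omics = dominant,
    dominance = dominance, n_drugs = n_drugs, noise_sd = noise_sd,
    seed = seed, ...))
}

fast_cfg <- function(...) {
  args <- utils::modifyList(list(epochs_graph = 60, epochs_dense = 120,
                                 epochs_attention = 60), list(...))
  do.call(training_config, args)
}
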