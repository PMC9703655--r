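# Two-stage training.  Stage 1 fits each omics sub-network alone against
# all drugs (masked MSE, Adam).  Stage 2 freezes every sub-network and
# learns only the attention weights and output bias.  Gradients are written
# out explicitly; the network is small enough that full R matrix algebra
# per minibatch is fast.

#' Training configuration
#'
#' Optimizer is Adam at learning rate 0.001 throughout.  Graph-embedded
#' sub-networks train for `epochs_graph` (they converge faster), dense ones
#' for `epochs_dense`, the attention stage for `epochs_attention`.  Dropout
#' and hidden sizes default to the per-omics settings used for the
#' cell-line panels (dropout 0.2 for expression/mutation/metabolomics, 0.4
#' for CNV/RPPA; hidden sizes 64/32/32/128/64; dense embedding width 200).
#'
#' @param learning_rate Adam step size.
#' @param epochs_graph,epochs_dense,epochs_attention epoch budgets.
#' @param batch_size minibatch size; `NULL` trains full-batch.
#' @param dropout named per-omics dropout rates in \[0, 1).
#' @param hidden_sizes named per-omics hidden-layer widths.
#' @param embed_size_dense embedding width for dense-embedded blocks.
#' @param seed integer seed controlling init, shuffling and dropout.
#' @param n_folds cross-validation fold count.
#' @param early_stopping if `TRUE` (default), pick the epoch count by the
#'   loss on a 10% validation split, then retrain on all training cells for
#'   that many epochs.  Guards the attention stage against sub-networks
#'   that memorize their training responses: a memorizing head looks best
#'   on the very data the attention weights are fit on, and fusion then
#'   locks onto the worst-generalizing block.
#' @return Object of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.001,
                            epochs_graph = 200L,
                            epochs_dense = 1000L,
                            epochs_attention = 200L,
                            batch_size = 32L,
                            dropout = c(expression = 0.2, mutation = 0.2,
                                        metabolomics = 0.2, cnv = 0.4,
                                        rppa = 0.4),
                            hidden_sizes = c(expression = 64L,
                                             metabolomics = 64L,
                                             mutation = 32L, cnv = 32L,
                                             rppa = 128L),
                            embed_size_dense = 200L,
                            seed = 1L,
                            n_folds = 3L,
                            early_stopping = TRUE) {
  stopifnot(learning_rate > 0, epochs_graph >= 0L, epochs_dense >= 0L,
            epochs_attention >= 0L,
            is.null(batch_size) || batch_size >= 1L,
            all(dropout >= 0), all(dropout < 1),
            all(hidden_sizes >= 1L), embed_size_dense >= 1L, n_folds >= 2L)
  structure(list(learning_rate = learning_rate,
                 epochs_graph = as.integer(epochs_graph),
                 epochs_dense = as.integer(epochs_dense),
                 epochs_attention = as.integer(epochs_attention),
                 batch_size = if (is.null(batch_size)) NULL
                              else as.integer(batch_size),
                 dropout = dropout, hidden_sizes = hidden_sizes,
                 embed_size_dense = as.integer(embed_size_dense),
                 seed = as.integer(seed), n_folds = as.integer(n_folds),
                 early_stopping = isTRUE(early_stopping)),
            class = "training_config")
}

# Dropout is applied after the embedding activation only.  Placing a second
# dropout after the hidden dense layer was tried and consistently degraded
# held-out error of the graph-embedded sub-networks without reducing
# overfitting beyond what embedding dropout already achieves.
cfg_dropout <- function(cfg, omics) {
  p <- if (omics %in% names(cfg$dropout)) cfg$dropout[[omics]] else 0.2
  c(embed = p, hidden = 0)
}

cfg_hidden <- function(cfg, omics) {
  if (omics %in% names(cfg$hidden_sizes)) cfg$hidden_sizes[[omics]] else 64L
}

#' Mean squared error over observed entries
#'
#' @param pred,truth numeric matrices of equal shape.
#' @param mask logical matrix; only `TRUE` entries enter the mean.
#' @return scalar loss.
#' @export
masked_mse_loss <- function(pred, truth, mask) {
  stopifnot(identical(dim(pred), dim(truth)),
            identical(dim(pred), dim(mask)))
  n <- sum(mask)
  if (n == 0L) stop("masked MSE undefined: no observed entries",
                    call. = FALSE)
  sum((pred[mask] - truth[mask])^2) / n
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / c1) / (sqrt(state$v[[k]] / c2) + eps)
  }
  list(params = params, state = state)
}

# ---- stage 1: sub-network backprop ---------------------------------------

subnet_loss_grad <- function(params, X, Y, mask, train_mode) {
  W1eff <- if (is.null(params$A)) params$W1 else params$W1 * params$A
  Z1 <- sweep(X %*% W1eff, 2L, params$b1, "+")
  H1 <- pmax(Z1, 0)
  D1 <- if (train_mode) dropout_mask(dim(H1), params$dropout[["embed"]])
  if (!is.null(D1)) H1 <- H1 * D1
  Z2 <- sweep(H1 %*% params$W2, 2L, params$b2, "+")
  H2 <- pmax(Z2, 0)
  D2 <- if (train_mode) dropout_mask(dim(H2), params$dropout[["hidden"]])
  if (!is.null(D2)) H2 <- H2 * D2
  P <- sweep(H2 %*% params$Wh, 2L, params$bh, "+")

  nobs <- sum(mask)
  R <- (P - Y) * mask
  loss <- sum(R * R) / nobs
  dP <- 2 * R / nobs
  gWh <- crossprod(H2, dP)
  gbh <- colSums(dP)
  dH2 <- dP %*% t(params$Wh)
  if (!is.null(D2)) dH2 <- dH2 * D2
  dZ2 <- dH2 * (Z2 > 0)
  gW2 <- crossprod(H1, dZ2)
  gb2 <- colSums(dZ2)
  dH1 <- dZ2 %*% t(params$W2)
  if (!is.null(D1)) dH1 <- dH1 * D1
  dZ1 <- dH1 * (Z1 > 0)
  gW1 <- crossprod(X, dZ1)
  if (!is.null(params$A)) gW1 <- gW1 * params$A
  gb1 <- colSums(dZ1)
  list(loss = loss,
       grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    Wh = gWh, bh = gbh))
}

epoch_batches <- function(n, batch_size) {
  ord <- sample.int(n)
  if (is.null(batch_size) || batch_size >= n) return(list(ord))
  split(ord, ceiling(seq_along(ord) / batch_size))
}

#' Train one omics sub-network (stage 1)
#'
#' Fits the sub-network to predict all drug responses from this block alone
#' by minimizing masked MSE with Adam.  The epoch budget is
#' `epochs_graph` when an adjacency is given (graph embedding), otherwise
#' `epochs_dense`.  Fully deterministic for a fixed seed.
#'
#' @param block `omics_matrix` (already standardized) or numeric matrix.
#' @param responses `drug_response_table` on the same cell lines.
#' @param adjacency binary PPI mask or `NULL` for dense embedding.
#' @param cfg a [training_config()].
#' @param seed RNG seed; defaults to `cfg$seed`.
#' @return list with `params` (`subnetwork_params`), `history` (per-epoch
#'   full-data inference loss) and `final_loss`.
#' @export
train_subnetwork <- function(block, responses, adjacency = NULL, cfg,
                             seed = cfg$seed) {
  stopifnot(inherits(cfg, "training_config"))
  if (inherits(block, "omics_matrix")) {
    omics <- block$omics_name
    X <- block$values
  } else {
    omics <- "expression"
    X <- as.matrix(block)
  }
  if (inherits(responses, "drug_response_table")) {
    Y <- responses$values
    mask <- responses$observed_mask
  } else {
    Y <- as.matrix(responses)
    mask <- !is.na(Y)
  }
  Y[!mask] <- 0
  stopifnot(nrow(X) == nrow(Y))
  n_d <- ncol(Y)
  set.seed(as.integer(seed))
  epochs <- if (is.null(adjacency)) cfg$epochs_dense else cfg$epochs_graph
  embed_size <- if (is.null(adjacency)) cfg$embed_size_dense else ncol(X)
  params <- init_subnetwork_params(ncol(X), embed_size,
                                   cfg_hidden(cfg, omics), n_d,
                                   adjacency = adjacency,
                                   dropout = cfg_dropout(cfg, omics),
                                   omics_name = omics)
  trained <- run_subnet_epochs(params, X, Y, mask, epochs, cfg)
  trained$params$omics_name <- omics
  trained
}

# One optimization pass: `epochs` epochs of minibatch Adam on the given
# rows, recording the full-data inference loss per epoch and, when val
# rows are supplied, the per-epoch validation loss.
subnet_opt_loop <- function(params, X, Y, mask, epochs, cfg,
                            val = NULL) {
  keys <- c("W1", "b1", "W2", "b2", "Wh", "bh")
  state <- adam_init(params[keys])
  history <- numeric(epochs)
  val_history <- numeric(epochs)
  for (e in seq_len(epochs)) {
    for (idx in epoch_batches(nrow(X), cfg$batch_size)) {
      lg <- subnet_loss_grad(params, X[idx, , drop = FALSE],
                             Y[idx, , drop = FALSE],
                             mask[idx, , drop = FALSE], train_mode = TRUE)
      if (!is.finite(lg$loss))
        stop("divergence: non-finite training loss at epoch ", e,
             call. = FALSE)
      upd <- adam_step(params[keys], lg$grads, state, cfg$learning_rate)
      params[keys] <- upd$params
      state <- upd$state
    }
    history[e] <- subnet_loss_grad(params, X, Y, mask,
                                   train_mode = FALSE)$loss
    if (!is.finite(history[e]))
      stop("divergence: non-finite training loss at epoch ", e,
           call. = FALSE)
    if (!is.null(val))
      val_history[e] <- subnet_loss_grad(params, val$X, val$Y, val$mask,
                                         train_mode = FALSE)$loss
  }
  list(params = params, history = history, val_history = val_history)
}

run_subnet_epochs <- function(params, X, Y, mask, epochs, cfg) {
  init <- params
  if (epochs > 0L && cfg$early_stopping && nrow(X) >= 10L) {
    # epoch selection on a 10% validation split, then refit on all rows
    val_rows <- sort(sample.int(nrow(X), max(1L, floor(0.1 * nrow(X)))))
    tr <- setdiff(seq_len(nrow(X)), val_rows)
    probe <- subnet_opt_loop(params,
                             X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                             mask[tr, , drop = FALSE], epochs, cfg,
                             val = list(X = X[val_rows, , drop = FALSE],
                                        Y = Y[val_rows, , drop = FALSE],
                                        mask = mask[val_rows, ,
                                                    drop = FALSE]))
    epochs <- which.min(probe$val_history)
    params <- init
  }
  fit <- subnet_opt_loop(params, X, Y, mask, epochs, cfg)
  final <- if (epochs > 0L) fit$history[epochs] else
    subnet_loss_grad(fit$params, X, Y, mask, train_mode = FALSE)$loss
  list(params = fit$params, history = fit$history, final_loss = final)
}

# ---- stage 2: attention --------------------------------------------------

softmax_rows <- function(V) {
  E <- exp(V - apply(V, 1L, max))
  E / rowSums(E)
}

#' Train the attention fusion stage (stage 2)
#'
#' Computes the frozen per-omics head outputs once, then optimizes only the
#' raw attention weights `W3` (their kill-matrix diagonal slice; all other
#' entries cannot affect the output) and the output bias with Adam on
#' masked MSE.  Sub-network parameters are asserted bit-identical before
#' and after.
#'
#' @param subnets list of trained `subnetwork_params`, one per block.
#' @param blocks list of standardized `omics_matrix` (or numeric matrices),
#'   same order as `subnets`.
#' @param responses `drug_response_table` (or numeric matrix with `NA`s).
#' @param cfg a [training_config()].
#' @param seed RNG seed; defaults to `cfg$seed + 1`.
#' @return list with `attention` (`attention_params`), `history`,
#'   `final_loss` and `heads` (the frozen head outputs).
#' @export
train_attention <- function(subnets, blocks, responses, cfg,
                            seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "training_config"),
            length(subnets) == length(blocks), length(subnets) >= 1L)
  frozen_before <- lapply(subnets, function(p)
    p[c("W1", "b1", "W2", "b2", "Wh", "bh")])
  if (inherits(responses, "drug_response_table")) {
    Y <- responses$values
    mask <- responses$observed_mask
  } else {
    Y <- as.matrix(responses)
    mask <- !is.na(Y)
  }
  Y[!mask] <- 0
  M <- length(subnets)
  n_d <- ncol(Y)
  heads <- lapply(seq_len(M), function(m) {
    X <- if (inherits(blocks[[m]], "omics_matrix")) blocks[[m]]$values
         else as.matrix(blocks[[m]])
    subnetwork_forward(X, subnets[[m]], train_mode = FALSE)
  })
  set.seed(as.integer(seed))
  V <- matrix(0, n_d, M)       # raw weights on the kill-matrix diagonal
  b <- numeric(n_d)
  pars <- list(V = V, b = b)
  state <- adam_init(pars)
  n <- nrow(Y)
  att_loss_grad <- function(pars, idx) {
    w <- softmax_rows(pars$V)                       # (n_d, M)
    pred <- matrix(0, length(idx), n_d)
    Hm <- lapply(heads, function(h) h[idx, , drop = FALSE])
    for (m in seq_len(M)) pred <- pred + sweep(Hm[[m]], 2L, w[, m], "*")
    pred <- sweep(pred, 2L, pars$b, "+")
    mk <- mask[idx, , drop = FALSE]
    nobs <- sum(mk)
    R <- (pred - Y[idx, , drop = FALSE]) * mk
    dP <- 2 * R / nobs
    gw <- vapply(seq_len(M), function(m) colSums(dP * Hm[[m]]),
                 numeric(n_d))                      # (n_d, M)
    gV <- w * sweep(gw, 1L, rowSums(gw * w), "-")
    list(loss = sum(R * R) / nobs,
         grads = list(V = gV, b = colSums(dP)))
  }
  history <- numeric(cfg$epochs_attention)
  for (e in seq_len(cfg$epochs_attention)) {
    for (idx in epoch_batches(n, cfg$batch_size)) {
      lg <- att_loss_grad(pars, idx)
      if (!is.finite(lg$loss))
        stop("divergence: non-finite attention loss at epoch ", e,
             call. = FALSE)
      upd <- adam_step(pars, lg$grads, state, cfg$learning_rate)
      pars <- upd$params
      state <- upd$state
    }
    history[e] <- att_loss_grad(pars, seq_len(n))$loss
  }
  final <- if (cfg$epochs_attention > 0L) history[cfg$epochs_attention]
           else att_loss_grad(pars, seq_len(n))$loss
  frozen_after <- lapply(subnets, function(p)
    p[c("W1", "b1", "W2", "b2", "Wh", "bh")])
  if (!identical(frozen_before, frozen_after))
    stop("stage-2 contract violated: sub-network parameters changed",
         call. = FALSE)
  W3 <- array(0, dim = c(n_d, M, n_d))
  for (m in seq_len(M)) W3[cbind(seq_len(n_d), m, seq_len(n_d))] <- pars$V[, m]
  list(attention = attention_params(W3, pars$b),
       history = history, final_loss = final, heads = heads)
}

# ---- full two-stage model ------------------------------------------------

#' Fit the full two-stage model on a multi-omics dataset
#'
#' Runs the preprocessing the model expects (low-information feature
#' filter, per-feature standardization), trains every sub-network (stage
#' 1), then the attention fusion with frozen sub-networks (stage 2).
#' Preprocessing statistics are retained so the model can be applied to new
#' cell lines.
#'
#' @param data a `multi_omics_dataset` (raw values).
#' @param cfg a [training_config()].
#' @param omics_subset optional character vector restricting fusion to a
#'   subset of blocks (used by the ablation driver).
#' @param subnets optional pre-trained stage-1 sub-networks (named list) to
#'   reuse; blocks must already match their feature lists and statistics.
#' @param stats optional named list of `standardization_stats` paired with
#'   `subnets`.
#' @return Object of class `omicsfusion_model`: sub-networks, attention,
#'   per-block standardization stats and feature lists, drug ids, config.
#' @export
train_model <- function(data, cfg, omics_subset = NULL,
                        subnets = NULL, stats = NULL) {
  stopifnot(inherits(data, "multi_omics_dataset"),
            inherits(cfg, "training_config"))
  omics <- names(data$blocks)
  if (!is.null(omics_subset)) {
    stopifnot(all(omics_subset %in% omics))
    omics <- omics[omics %in% omics_subset]
  }
  blocks_std <- list()
  out_stats <- list()
  out_subnets <- list()
  histories <- list()
  for (i in seq_along(omics)) {
    nm <- omics[i]
    if (is.null(subnets)) {
      filt <- filter_low_information_features(data$blocks[[nm]])
      std <- standardize(filt)
      out_stats[[nm]] <- std$stats
      blocks_std[[nm]] <- std$matrix
      adj <- if (std$matrix$embedding_kind == "graph" &&
                 !is.null(data$adjacency[[nm]]))
        data$adjacency[[nm]][std$matrix$feature_ids,
                             std$matrix$feature_ids, drop = FALSE]
      else NULL
      fit <- train_subnetwork(std$matrix, data$responses,
                              adjacency = adj, cfg, seed = cfg$seed + i)
      out_subnets[[nm]] <- fit$params
      histories[[nm]] <- fit$history
    } else {
      st <- stats[[nm]]
      filt <- omics_matrix(
        data$blocks[[nm]]$values[, st$feature_ids, drop = FALSE],
        nm, data$blocks[[nm]]$embedding_kind)
      blocks_std[[nm]] <- standardize(filt, st)$matrix
      out_stats[[nm]] <- st
      out_subnets[[nm]] <- subnets[[nm]]
    }
  }
  att <- train_attention(out_subnets, blocks_std, data$responses, cfg,
                         seed = cfg$seed + length(omics) + 1L)
  histories[["attention"]] <- att$history
  structure(list(omics = omics,
                 subnets = out_subnets,
                 attention = att$attention,
                 stats = out_stats,
                 drug_ids = data$responses$drug_ids,
                 stage2_final_loss = att$final_loss,
                 histories = histories,
                 cfg = cfg),
            class = "omicsfusion_model")
}

#' @export
print.omicsfusion_model <- function(x, ...) {
  cat(sprintf("<omicsfusion_model> blocks: %s; %d drugs; stage-2 loss %.4g\n",
              paste(x$omics, collapse = ", "), length(x$drug_ids),
              x$stage2_final_loss))
  invisible(x)
}

#' Predict drug responses for new cell lines
#'
#' Applies the stored feature selection and standardization statistics to
#' each raw omics block, runs the frozen sub-networks and fuses their heads
#' with the trained attention weights.
#'
#' @param object an `omicsfusion_model`.
#' @param blocks named list of raw `omics_matrix` objects covering the
#'   model's omics and feature ids, all on one cell-line ordering.
#' @param ... unused.
#' @return numeric matrix (cell lines x drugs) of predicted log IC50.
#' @export
predict.omicsfusion_model <- function(object, blocks, ...) {
  heads <- lapply(object$omics, function(nm) {
    b <- blocks[[nm]]
    stopifnot(inherits(b, "omics_matrix"))
    st <- object$stats[[nm]]
    if (!all(st$feature_ids %in% b$feature_ids))
      stop("block ", nm, " lacks features the model was trained on",
           call. = FALSE)
    sub <- omics_matrix(b$values[, st$feature_ids, drop = FALSE],
                        nm, b$embedding_kind)
    subnetwork_forward(standardize(sub, st)$matrix$values,
                       object$subnets[[nm]], train_mode = FALSE)
  })
  pred <- fuse_and_predict(heads, object$attention)
  rownames(pred) <- blocks[[object$omics[1L]]]$cell_line_ids
  colnames(pred) <- object$drug_ids
  pred
}
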