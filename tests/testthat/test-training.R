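test_that("masked MSE matches the explicit sum", {
  truth <- matrix(c(1, 3, 2, 4), 2, 2)
  pred <- matrix(c(1, 3, 3, 6), 2, 2)
  all_on <- matrix(TRUE, 2, 2)
  expect_equal(masked_mse_loss(truth, truth, all_on), 0)
  expect_equal(masked_mse_loss(pred, truth, all_on), 1.25)
  m <- all_on; m[2, 2] <- FALSE
  expect_equal(masked_mse_loss(pred, truth, m), 1 / 3)
  expect_error(masked_mse_loss(pred, truth, !all_on), "no observed")
})

test_that("a zero-epoch budget returns the initialized parameters", {
  sim <- small_sim(seed = 61, n_cells = 40, n_drugs = 3,
                   counts = c(mutation = 10), dominant = "mutation",
                   dominance = 1)
  std <- standardize(sim$dataset$blocks$mutation)$matrix
  adj <- sim$dataset$adjacency$mutation
  cfg <- fast_cfg(epochs_graph = 0, seed = 9)
  fit <- train_subnetwork(std, sim$dataset$responses, adj, cfg)
  expect_length(fit$history, 0L)
  set.seed(9)
  ref <- init_subnetwork_params(10, 10, cfg$hidden_sizes[["mutation"]], 3,
                                adjacency = adj,
                                dropout = c(embed = 0.2, hidden = 0),
                                omics_name = "mutation")
  expect_identical(fit$params$W1, ref$W1)
  expect_identical(fit$params$W2, ref$W2)
  expect_identical(fit$params$Wh, ref$Wh)
})

test_that("training is deterministic for a fixed seed", {
  sim <- small_sim(seed = 62, n_cells = 80, n_drugs = 4,
                   counts = c(mutation = 12), dominant = "mutation",
                   dominance = 1, missing_rate = 0.1)
  std <- standardize(sim$dataset$blocks$mutation)$matrix
  adj <- sim$dataset$adjacency$mutation
  cfg <- fast_cfg(seed = 4)
  a <- train_subnetwork(std, sim$dataset$responses, adj, cfg)
  b <- train_subnetwork(std, sim$dataset$responses, adj, cfg)
  expect_identical(a$params, b$params)
  expect_identical(a$history, b$history)
})

test_that("noiseless linear data is fit well within the default epochs", {
  sim <- small_sim(seed = 63, n_cells = 120, n_drugs = 5,
                   counts = c(expression = 20), dominant = "expression",
                   dominance = 1, noise_sd = 0, missing_rate = 0)
  std <- standardize(sim$dataset$blocks$expression)$matrix
  cfg <- training_config(seed = 3, dropout = c(expression = 0),
                         early_stopping = FALSE)
  fit <- train_subnetwork(std, sim$dataset$responses,
                          sim$dataset$adjacency$expression, cfg)
  expect_lt(fit$final_loss, 0.05)
})

test_that("full-batch training descends monotonically on noiseless data", {
  sim <- small_sim(seed = 64, n_cells = 80, n_drugs = 4,
                   counts = c(expression = 15), dominant = "expression",
                   dominance = 1, noise_sd = 0, missing_rate = 0)
  std <- standardize(sim$dataset$blocks$expression)$matrix
  cfg <- training_config(seed = 3, batch_size = NULL,
                         dropout = c(expression = 0),
                         early_stopping = FALSE, epochs_graph = 300,
                         learning_rate = 1e-3)
  fit <- train_subnetwork(std, sim$dataset$responses,
                          sim$dataset$adjacency$expression, cfg)
  expect_true(all(diff(fit$history) <= 1e-8))
})

test_that("stage 2 leaves sub-network parameters bit-identical", {
  sim <- small_sim(seed = 65, n_cells = 90, n_drugs = 4,
                   counts = c(expression = 15, mutation = 12))
  cfg <- fast_cfg(seed = 5)
  blocks <- lapply(sim$dataset$blocks, function(b) standardize(b)$matrix)
  subs <- lapply(names(blocks), function(nm)
    train_subnetwork(blocks[[nm]], sim$dataset$responses,
                     sim$dataset$adjacency[[nm]], cfg)$params)
  before <- serialize(subs, NULL)
  att <- train_attention(subs, blocks, sim$dataset$responses, cfg)
  expect_identical(serialize(subs, NULL), before)
  expect_s3_class(att$attention, "attention_params")
})

test_that("attention locks onto an exact head over a noise head", {
  set.seed(71)
  n <- 200; n_d <- 6
  Y <- matrix(rnorm(n * n_d), n, n_d,
              dimnames = list(sprintf("CL%03d", 1:n),
                              sprintf("D%02d", 1:n_d)))
  passthrough <- function() {
    # relu splits x into positive/negative parts which the linear head
    # recombines, so the sub-network copies its input exactly
    subnetwork_params(W1 = cbind(diag(n_d), -diag(n_d)),
                      b1 = numeric(2 * n_d),
                      W2 = diag(2 * n_d), b2 = numeric(2 * n_d),
                      Wh = rbind(diag(n_d), -diag(n_d)),
                      bh = numeric(n_d))
  }
  blocks <- list(exact = Y, noise = matrix(rnorm(n * n_d), n, n_d))
  subs <- list(passthrough(), passthrough())
  cfg <- training_config(seed = 6)
  att <- train_attention(subs, blocks, Y, cfg)
  s <- attention_scores(attention_normalize(att$attention$W3,
                                            att$attention$k))
  expect_gte(mean(s[1, ] > 0.8), 0.9)
  expect_lt(att$final_loss, 0.1)
})

test_that("single-omics fusion degenerates to the sub-network head", {
  sim <- small_sim(seed = 66, n_cells = 80, n_drugs = 4,
                   counts = c(mutation = 12), dominant = "mutation",
                   dominance = 1)
  std <- standardize(sim$dataset$blocks$mutation)$matrix
  cfg <- fast_cfg(seed = 2)
  fit <- train_subnetwork(std, sim$dataset$responses,
                          sim$dataset$adjacency$mutation, cfg)
  att <- train_attention(list(fit$params), list(std),
                         sim$dataset$responses, cfg)
  # bias-only stage: final loss cannot be worse than stage 1
  expect_lte(att$final_loss, fit$final_loss + 1e-6)
  # with a zero-epoch attention budget the fusion is the head exactly
  cfg0 <- fast_cfg(seed = 2, epochs_attention = 0)
  att0 <- train_attention(list(fit$params), list(std),
                          sim$dataset$responses, cfg0)
  head <- subnetwork_forward(std$values, fit$params)
  expect_equal(fuse_and_predict(list(head), att0$attention), head,
               tolerance = 1e-15)
})

test_that("folds partition the cell lines reproducibly", {
  ids <- sprintf("CL%03d", 1:47)
  f1 <- make_folds(ids, 3, seed = 10)
  f2 <- make_folds(ids, 3, seed = 10)
  expect_identical(f1, f2)
  expect_setequal(names(f1), ids)
  expect_true(all(f1 %in% 1:3))
  expect_true(max(table(f1)) - min(table(f1)) <= 1)
  expect_false(identical(make_folds(ids, 3, seed = 11), f1))
})

test_that("cross-validation is deterministic and leak-checked", {
  sim <- small_sim(seed = 67, n_cells = 90, n_drugs = 5,
                   counts = c(expression = 15, mutation = 12))
  cfg <- fast_cfg(seed = 8)
  cv1 <- cross_validate(sim$dataset, cfg)
  cv2 <- cross_validate(sim$dataset, cfg)
  expect_identical(cv1$per_fold, cv2$per_fold)
  expect_identical(cv1$attention$mean, cv2$attention$mean)
  expect_equal(nrow(cv1$per_fold), 3L)
  expect_true(all(c("mse", "r2", "top1", "top3") %in%
                    cv1$aggregate$metric))
  # attention columns are normalized per fold
  expect_equal(colSums(cv1$attention$mean),
               rep(1, ncol(cv1$attention$mean)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("dominant-block attention grows with the planted dominance", {
  doms <- c(0.7, 0.8, 0.9)
  means <- sapply(doms, function(dm) {
    per_seed <- sapply(1:3, function(s) {
      sim <- small_sim(seed = 100 + s, n_cells = 240, n_drugs = 5,
                       counts = c(expression = 20, mutation = 15),
                       dominance = dm, noise_sd = 0.3)
      cfg <- fast_cfg(seed = s)
      model <- train_model(sim$dataset, cfg)
      s_mat <- attention_scores(attention_normalize(model$attention$W3,
                                                    model$attention$k),
                                model$omics, model$drug_ids)
      mean(s_mat["mutation", ])
    })
    mean(per_seed)
  })
  expect_true(all(diff(means) > 0))
})

test_that("ablation enumerates subsets and ranks by MSE", {
  sim <- small_sim(seed = 68, n_cells = 90, n_drugs = 4,
                   counts = c(expression = 15, mutation = 12,
                              metabolomics = 10),
                   dominance = 0.9)
  cfg <- fast_cfg(seed = 12, epochs_dense = 80)
  ab <- ablation_run(sim$dataset, cfg)
  expect_equal(nrow(ab$table), 7L)           # 2^3 - 1
  expect_true(!is.unsorted(ab$table$mse))
  # labels parse back to valid subsets
  for (lab in ab$table$combination) {
    subset <- parse_combination(lab)
    expect_true(all(subset %in% names(sim$dataset$blocks)))
    expect_identical(combination_label(subset), lab)
  }
})
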