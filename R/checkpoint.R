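# Checkpoints: a directory of per-parameter TSV arrays plus a JSON
# manifest.  Numbers are written with 17 significant digits so a reloaded
# model reproduces the saved model's forward pass bit-identically.

# FNV-1a 32-bit hash of a string; a tiny content fingerprint used to detect
# manifest tampering (not cryptographic).
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- bitwXor(as.integer(h %% 256), b)   # xor only touches low byte
    h <- h - (h %% 256) + low
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403,
    # kept exact in doubles: only the low byte survives the 2^24 shift
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Vectorized fingerprint for larger texts (an Adler-like position-weighted
# byte sum); fed into fnv1a together with the manifest core.
content_fingerprint <- function(lines) {
  b <- as.integer(charToRaw(paste(lines, collapse = "\n")))
  n <- length(b)
  if (n == 0L) return("0:0:0")
  s1 <- sum(b) %% 65521
  s2 <- sum(b * (seq_len(n) %% 4096)) %% 2147483647
  paste(n, s1, s2, sep = ":")
}

write_array_tsv <- function(x, path) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  writeLines(c(paste(d, collapse = "\t"),
               paste(fmt_num(as.vector(x)), collapse = "\t")), path)
}

read_array_tsv <- function(path) {
  lines <- readLines(path)
  d <- as.integer(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]])
  v <- as.numeric(strsplit(lines[2L], "\t", fixed = TRUE)[[1L]])
  if (length(v) != prod(d))
    stop("corrupt parameter file: ", path, call. = FALSE)
  if (length(d) == 1L) v else array(v, dim = d)
}

subnet_param_names <- c("W1", "b1", "W2", "b2", "Wh", "bh")

#' Save a fitted model as a checkpoint directory
#'
#' Writes every parameter array (sub-network weights, adjacency masks,
#' attention weights, output bias), the per-block standardization
#' statistics, and a JSON manifest recording omics names, feature and drug
#' lists, the training config, the seed and a content checksum.
#'
#' @param model an `omicsfusion_model`.
#' @param dir checkpoint directory (created if needed).
#' @return invisibly, `dir`.
#' @export
save_checkpoint <- function(model, dir) {
  stopifnot(inherits(model, "omicsfusion_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put <- function(x, name) {
    write_array_tsv(x, file.path(dir, name))
    files <<- c(files, name)
  }
  for (nm in model$omics) {
    p <- model$subnets[[nm]]
    for (w in subnet_param_names) put(p[[w]], sprintf("%s_%s.tsv", nm, w))
    if (!is.null(p$A)) put(p$A, sprintf("%s_A.tsv", nm))
    st <- model$stats[[nm]]
    put(st$center, sprintf("%s_center.tsv", nm))
    put(st$scale, sprintf("%s_scale.tsv", nm))
  }
  put(model$attention$W3, "attention_W3.tsv")
  put(model$attention$b, "attention_b.tsv")
  cfg_json <- unclass(model$cfg)
  for (nm in c("dropout", "hidden_sizes"))
    cfg_json[[nm]] <- as.list(cfg_json[[nm]])
  manifest <- list(
    format = "omicsfusion-checkpoint-1",
    omics = model$omics,
    embedding = as.list(vapply(model$omics, function(nm)
      if (is.null(model$subnets[[nm]]$A)) "dense" else "graph", "")),
    dropout = lapply(model$subnets[model$omics], function(p)
      as.list(p$dropout)),
    feature_ids = lapply(model$stats[model$omics], function(s)
      s$feature_ids),
    drug_ids = model$drug_ids,
    config = cfg_json,
    seed = model$cfg$seed,
    files = files)
  core <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA)
  payload <- vapply(files, function(f)
    content_fingerprint(readLines(file.path(dir, f))), "")
  manifest$checksum <- fnv1a(c(as.character(core), payload))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a checkpoint directory
#'
#' Verifies the manifest checksum (tampering raises an incompatibility
#' error) and rebuilds the model; the restored forward pass is
#' bit-identical to the saved model's.
#'
#' @param dir checkpoint directory written by [save_checkpoint()].
#' @return An `omicsfusion_model`.
#' @export
load_checkpoint <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!identical(manifest$format, "omicsfusion-checkpoint-1"))
    stop("incompatible checkpoint format", call. = FALSE)
  stored <- manifest$checksum
  manifest$checksum <- NULL
  core <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA)
  payload <- vapply(manifest$files, function(f)
    content_fingerprint(readLines(file.path(dir, f))), "")
  if (!identical(fnv1a(c(as.character(core), payload)), stored))
    stop("checkpoint manifest/content mismatch: checksum failed",
         call. = FALSE)
  cfgl <- manifest$config
  if (!length(cfgl$batch_size)) cfgl["batch_size"] <- list(NULL)
  for (nm in c("dropout", "hidden_sizes"))
    cfgl[[nm]] <- unlist(cfgl[[nm]])
  cfg <- do.call(training_config, cfgl)
  subnets <- list(); stats <- list()
  for (nm in manifest$omics) {
    get <- function(w) read_array_tsv(file.path(dir,
                                                sprintf("%s_%s.tsv", nm, w)))
    A <- if (identical(manifest$embedding[[nm]], "graph")) get("A") else NULL
    dp <- unlist(manifest$dropout[[nm]])
    subnets[[nm]] <- subnetwork_params(W1 = get("W1"), b1 = get("b1"),
                                       W2 = get("W2"), b2 = get("b2"),
                                       Wh = get("Wh"), bh = get("bh"),
                                       A = A,
                                       dropout = c(embed = dp[["embed"]],
                                                   hidden = dp[["hidden"]]),
                                       omics_name = nm)
    stats[[nm]] <- standardization_stats(manifest$feature_ids[[nm]],
                                         get("center"), get("scale"))
  }
  att <- attention_params(read_array_tsv(file.path(dir, "attention_W3.tsv")),
                          read_array_tsv(file.path(dir, "attention_b.tsv")))
  structure(list(omics = manifest$omics, subnets = subnets,
                 attention = att, stats = stats,
                 drug_ids = manifest$drug_ids,
                 stage2_final_loss = NA_real_, cfg = cfg),
            class = "omicsfusion_model")
}
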