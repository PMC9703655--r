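# Forward computation of the network.  Each omics block m has its own
# sub-network: an embedding layer (dense, or graph: weights elementwise
# masked by the PPI adjacency A so hidden unit j only receives input from
# features interacting with j), a hidden dense layer, and a linear "head"
# of size n_f = n_d producing that block's per-drug predictions.  Heads are
# fused per drug by softmax attention weights under a kill matrix
# k(d, i) = [d == i], so drug d's output only attends to position d of each
# head.  All functions here are pure; training lives in train.R.

act_fun <- function(name) {
  switch(match.arg(name, c("relu", "identity")),
         relu = function(x) pmax(x, 0),
         identity = function(x) x)
}

as_input_matrix <- function(x, n_in, what) {
  if (is.matrix(x)) {
    if (ncol(x) != n_in)
      stop("dimension mismatch in ", what, ": input has ", ncol(x),
           " features, weights expect ", n_in, call. = FALSE)
    list(x = x, vector = FALSE)
  } else {
    if (length(x) != n_in)
      stop("dimension mismatch in ", what, ": input has ", length(x),
           " features, weights expect ", n_in, call. = FALSE)
    list(x = matrix(x, nrow = 1L), vector = TRUE)
  }
}

affine_forward <- function(x, W, b, f, what) {
  inp <- as_input_matrix(x, nrow(W), what)
  if (length(b) != ncol(W))
    stop("dimension mismatch in ", what, ": bias length ", length(b),
         " but ", ncol(W), " output units", call. = FALSE)
  out <- f(sweep(inp$x %*% W, 2L, b, "+"))
  if (inp$vector) as.vector(out) else out
}

#' Dense embedding layer forward pass
#'
#' Computes `f(W1' x + b1)`.
#'
#' @param x input feature vector (or matrix of row vectors).
#' @param W1 weight matrix (n_in x n_out).
#' @param b1 bias vector (n_out).
#' @param f activation function (default rectifier).
#' @return activation vector (or matrix).
#' @export
dense_embedding_forward <- function(x, W1, b1, f = act_fun("relu")) {
  affine_forward(x, W1, b1, f, "dense embedding")
}

#' Graph embedding layer forward pass
#'
#' Computes `f((W1 . A)' x + b1)` where `.` is the elementwise product with
#' the binary PPI adjacency `A`; weights at `A = 0` have no effect, so each
#' hidden unit only sees interacting features.
#'
#' @param x input feature vector (or matrix of row vectors).
#' @param W1 square weight matrix (n_m x n_m).
#' @param A binary adjacency matrix, same shape as `W1`.
#' @param b1 bias vector (n_m).
#' @param f activation function (default rectifier).
#' @return activation vector (or matrix).
#' @export
graph_embedding_forward <- function(x, W1, A, b1, f = act_fun("relu")) {
  A <- unclass(A)
  if (!identical(dim(W1), dim(A)) || nrow(W1) != ncol(W1))
    stop("dimension mismatch in graph embedding: W1 and A must be equal ",
         "square matrices", call. = FALSE)
  affine_forward(x, W1 * A, b1, f, "graph embedding")
}

#' Dense hidden layer forward pass
#'
#' Computes `f(W2' y1 + b2)`.
#'
#' @param y1 embedding-layer output vector (or matrix of row vectors).
#' @param W2 weight matrix, `b2` bias vector.
#' @param b2 bias vector.
#' @param f activation function (default rectifier).
#' @return activation vector (or matrix).
#' @export
dense_layer_forward <- function(y1, W2, b2, f = act_fun("relu")) {
  affine_forward(y1, W2, b2, f, "dense layer")
}

#' Per-omics sub-network parameters
#'
#' Bundles the embedding layer (`W1`, `b1`, optional adjacency mask `A`),
#' the hidden dense layer (`W2`, `b2`) and the linear per-drug head (`Wh`,
#' `bh`, with `n_f` columns equal to the drug count so heads line up with
#' the kill matrix).
#'
#' @param W1,b1 embedding weights/bias; `W1` must be square when `A` given.
#' @param W2,b2 hidden dense layer weights/bias.
#' @param Wh,bh linear head weights/bias (`ncol(Wh)` = n_f = n_d).
#' @param A binary adjacency mask or `NULL` for a dense embedding.
#' @param activation hidden activation name (`"relu"`).
#' @param dropout named numeric, rates after the embedding and hidden
#'   activations (`c(embed = , hidden = )`), each in \[0, 1).
#' @param omics_name optional label carried for bookkeeping.
#' @return Object of class `subnetwork_params`.
#' @export
subnetwork_params <- function(W1, b1, W2, b2, Wh, bh, A = NULL,
                              activation = "relu",
                              dropout = c(embed = 0, hidden = 0),
                              omics_name = NULL) {
  if (!is.null(A)) {
    A <- unclass(A)
    if (nrow(W1) != ncol(W1) || !identical(dim(A), dim(W1)))
      stop("graph embedding requires square W1 matching A", call. = FALSE)
    if (!all(A %in% c(0, 1)))
      stop("adjacency mask must be binary", call. = FALSE)
  }
  stopifnot(length(b1) == ncol(W1), nrow(W2) == ncol(W1),
            length(b2) == ncol(W2), nrow(Wh) == ncol(W2),
            length(bh) == ncol(Wh),
            all(dropout >= 0), all(dropout < 1))
  structure(list(W1 = W1, b1 = b1, A = A, W2 = W2, b2 = b2,
                 Wh = Wh, bh = bh, activation = activation,
                 dropout = c(embed = unname(dropout[["embed"]]),
                             hidden = unname(dropout[["hidden"]])),
                 omics_name = omics_name),
            class = "subnetwork_params")
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize sub-network parameters
#'
#' Glorot-uniform weights, zero biases, using the current RNG stream.  With
#' an adjacency the embedding is graph-masked and its size equals the input
#' size.
#'
#' @param n_in input feature count.
#' @param embed_size embedding width (ignored and forced to `n_in` when
#'   `adjacency` is given).
#' @param hidden_size hidden dense layer width.
#' @param n_f head width (must equal the drug count).
#' @param adjacency binary mask or `NULL`.
#' @param dropout named rates `c(embed = , hidden = )`.
#' @param omics_name optional label.
#' @return A `subnetwork_params` object.
#' @export
init_subnetwork_params <- function(n_in, embed_size, hidden_size, n_f,
                                   adjacency = NULL,
                                   dropout = c(embed = 0, hidden = 0),
                                   omics_name = NULL) {
  if (!is.null(adjacency)) embed_size <- n_in
  subnetwork_params(W1 = glorot(n_in, embed_size),
                    b1 = numeric(embed_size),
                    W2 = glorot(embed_size, hidden_size),
                    b2 = numeric(hidden_size),
                    Wh = glorot(hidden_size, n_f),
                    bh = numeric(n_f),
                    A = adjacency, dropout = dropout,
                    omics_name = omics_name)
}

dropout_mask <- function(n, p) {
  if (p <= 0) return(NULL)
  matrix(stats::rbinom(n[1L] * n[2L], 1L, 1 - p) / (1 - p), n[1L], n[2L])
}

#' Sub-network forward pass
#'
#' `head(dense(embed(x)))`: embedding (graph-masked when the params carry an
#' adjacency), hidden dense layer, then the linear per-drug head.  Inverted
#' dropout is applied after the two hidden activations only when
#' `train_mode` is set; inference is deterministic.
#'
#' @param x input feature vector (or matrix of row vectors).
#' @param params a `subnetwork_params` object.
#' @param train_mode apply dropout (consumes RNG draws).
#' @return head output vector of length n_f (or matrix).
#' @export
subnetwork_forward <- function(x, params, train_mode = FALSE) {
  stopifnot(inherits(params, "subnetwork_params"))
  f <- act_fun(params$activation)
  h1 <- if (is.null(params$A))
    dense_embedding_forward(x, params$W1, params$b1, f)
  else
    graph_embedding_forward(x, params$W1, params$A, params$b1, f)
  h1m <- if (is.matrix(h1)) h1 else matrix(h1, nrow = 1L)
  if (train_mode && params$dropout[["embed"]] > 0)
    h1m <- h1m * dropout_mask(dim(h1m), params$dropout[["embed"]])
  h2 <- dense_layer_forward(h1m, params$W2, params$b2, f)
  if (train_mode && params$dropout[["hidden"]] > 0)
    h2 <- h2 * dropout_mask(dim(h2), params$dropout[["hidden"]])
  out <- dense_layer_forward(h2, params$Wh, params$bh, act_fun("identity"))
  if (is.matrix(x)) out else as.vector(out)
}

#' The kill matrix
#'
#' Binary identity pattern `k(d, i) = 1` iff `d = i`, forcing drug d's
#' output neuron to attend only to position d of every omics head.
#'
#' @param n_d drug count.
#' @param n_f head width (defaults to `n_d`).
#' @return n_d x n_f binary matrix.
#' @export
kill_matrix <- function(n_d, n_f = n_d) {
  k <- matrix(0, n_d, n_f)
  idx <- seq_len(min(n_d, n_f))
  k[cbind(idx, idx)] <- 1
  k
}

#' Attention fusion parameters
#'
#' Raw attention weights `W3[d, m, i]` over drugs d, omics m and head
#' positions i, the kill matrix, and the output layer bias/activation.
#'
#' @param W3 numeric array of shape (n_d, M, n_f).
#' @param b output bias vector (n_d).
#' @param activation output activation name (`"identity"` for log IC50
#'   regression).
#' @return Object of class `attention_params`.
#' @export
attention_params <- function(W3, b, activation = "identity") {
  stopifnot(is.array(W3), length(dim(W3)) == 3L)
  n_d <- dim(W3)[1L]; n_f <- dim(W3)[3L]
  stopifnot(length(b) == n_d)
  structure(list(W3 = W3, k = kill_matrix(n_d, n_f),
                 b = b, activation = activation),
            class = "attention_params")
}

#' Initialize attention parameters
#'
#' Raw weights start at zero (uniform attention over omics) and the output
#' bias at zero.
#'
#' @param n_d drug count.
#' @param M omics count.
#' @param n_f head width (defaults to `n_d`).
#' @return An `attention_params` object.
#' @export
init_attention_params <- function(n_d, M, n_f = n_d) {
  attention_params(array(0, dim = c(n_d, M, n_f)), numeric(n_d))
}

#' Normalize attention weights under the kill matrix
#'
#' `W(d, m, i) = exp(W3[d, m, i]) k(d, i) / sum_m exp(W3[d, m, i])`, with a
#' max-subtracted softmax so arbitrarily large raw weights stay finite.  For
#' every (d, i) the normalized weights sum over omics to `k(d, i)`.
#'
#' @param W3 raw weight array (n_d, M, n_f).
#' @param k kill matrix (n_d, n_f); defaults to the identity pattern.
#' @return normalized weight array, same shape as `W3`.
#' @export
attention_normalize <- function(W3, k = NULL) {
  stopifnot(is.array(W3), length(dim(W3)) == 3L)
  d <- dim(W3)
  if (is.null(k)) k <- kill_matrix(d[1L], d[3L])
  stopifnot(identical(dim(k), d[c(1L, 3L)]))
  mx <- apply(W3, c(1L, 3L), max)                     # (n_d, n_f)
  expand <- function(m) aperm(array(m, dim = c(d[1L], d[3L], d[2L])),
                              c(1L, 3L, 2L))
  E <- exp(W3 - expand(mx))
  W <- E / expand(apply(E, c(1L, 3L), sum)) * expand(k)
  dimnames(W) <- dimnames(W3)
  W
}

# Per-drug fusion weights: wdm[d, m] = W(d, m, d)
attention_diag_weights <- function(att) {
  W <- attention_normalize(att$W3, att$k)
  n_d <- dim(W)[1L]; M <- dim(W)[2L]
  wdm <- matrix(0, n_d, M)
  for (m in seq_len(M)) wdm[, m] <- W[cbind(seq_len(n_d), m, seq_len(n_d))]
  wdm
}

#' Fuse per-omics head outputs into drug predictions
#'
#' With the kill matrix, drug d's prediction reduces to
#' `y_d = g(sum_m W(d, m, d) heads_m[d] + b_d)`: a convex combination of
#' the per-omics predictions for that drug, plus a bias.
#'
#' @param heads list of M head vectors of length n_f (or n x n_f matrices).
#' @param att an `attention_params` object.
#' @return prediction vector of length n_d (or n x n_d matrix).
#' @export
fuse_and_predict <- function(heads, att) {
  stopifnot(inherits(att, "attention_params"), length(heads) >= 1L)
  n_d <- dim(att$W3)[1L]; M <- dim(att$W3)[2L]; n_f <- dim(att$W3)[3L]
  if (n_f != n_d)
    stop("configuration error: kill-matrix fusion requires head width n_f ",
         "equal to drug count n_d", call. = FALSE)
  if (length(heads) != M)
    stop("expected ", M, " heads, got ", length(heads), call. = FALSE)
  vec_in <- !is.matrix(heads[[1L]])
  heads <- lapply(heads, function(h) if (is.matrix(h)) h else
    matrix(h, nrow = 1L))
  for (h in heads)
    if (ncol(h) != n_f) stop("head width mismatch", call. = FALSE)
  wdm <- attention_diag_weights(att)
  out <- matrix(0, nrow(heads[[1L]]), n_d)
  for (m in seq_len(M))
    out <- out + sweep(heads[[m]], 2L, wdm[, m], "*")
  out <- act_fun(att$activation)(sweep(out, 2L, att$b, "+"))
  if (vec_in) as.vector(out) else out
}

#' Per-omics attention scores
#'
#' Sums normalized weights over head positions:
#' `score(m, d) = sum_i W(d, m, i)`, which under the kill matrix equals
#' `W(d, m, d)`.  Columns sum to 1 over omics.
#'
#' @param W normalized weight array from [attention_normalize()].
#' @param omics_names,drug_ids optional dimnames for the result.
#' @return M x n_d score matrix.
#' @export
attention_scores <- function(W, omics_names = NULL, drug_ids = NULL) {
  stopifnot(is.array(W), length(dim(W)) == 3L)
  s <- apply(W, c(2L, 1L), sum)
  dimnames(s) <- list(omics_names, drug_ids)
  s
}
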