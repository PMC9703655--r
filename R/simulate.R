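# Synthetic multi-omics generator.  Emulates the structure the model
# assumes: several omics blocks over a known interactome, drug responses
# driven predominantly by one designated block through sparse drug-specific
# linear scores (optionally graph-smoothed), Gaussian noise, and missing
# responses.  The linear ground truth makes recovery checkable in closed
# form: the fitted network only has to compete with ridge regression.

GRAPH_OMICS <- c("expression", "mutation", "cnv")

#' Configuration for the synthetic multi-omics generator
#'
#' Defaults emulate a scaled-down cell-line panel: 522 cell lines, 22 drugs,
#' five omics blocks (expression/mutation/CNV graph-embedded, RPPA and
#' metabolomics dense), a sparse interactome, responses dominated by the
#' mutation block, and 5% missing responses.
#'
#' @param n_cells number of cell lines.
#' @param feature_counts named integer vector of features per omics block;
#'   names choose the blocks (subset of `r toString(OMICS_NAMES)`).
#' @param edge_prob Erdos-Renyi edge probability of the simulated
#'   interactome over the gene universe.
#' @param dominant_omics block contributing the `dominance` share of the
#'   response signal variance.
#' @param dominance fraction in \[0, 1\] of signal variance from the
#'   dominant block; the remainder is split equally over the other blocks.
#' @param n_drugs number of drugs.
#' @param noise_sd standard deviation of additive Gaussian response noise
#'   (the signal is built to unit variance per drug).
#' @param missing_rate fraction of responses masked as unobserved.
#' @param graph_signal if `TRUE`, scores of graph blocks are computed from
#'   adjacency-smoothed features, so responses depend on interactome
#'   neighbours.
#' @param coef_density fraction of features with nonzero coefficient per
#'   drug (sparse target-pathway-like signals).
#' @param mutation_rate Bernoulli rate of the binary mutation block.
#' @param seed integer RNG seed; every draw derives from it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = 522L,
                              feature_counts = c(expression = 120L,
                                                 mutation = 80L,
                                                 cnv = 80L,
                                                 rppa = 40L,
                                                 metabolomics = 45L),
                              edge_prob = 0.05,
                              dominant_omics = "mutation",
                              dominance = 0.9,
                              n_drugs = 22L,
                              noise_sd = 0.3,
                              missing_rate = 0.05,
                              graph_signal = TRUE,
                              coef_density = 0.1,
                              mutation_rate = 0.1,
                              seed = 1L) {
  stopifnot(n_cells >= 1L, n_drugs >= 1L,
            all(feature_counts >= 1L), length(feature_counts) >= 1L,
            edge_prob >= 0, edge_prob <= 1,
            noise_sd >= 0, missing_rate >= 0, missing_rate < 1,
            coef_density > 0, coef_density <= 1,
            mutation_rate > 0, mutation_rate < 1)
  omics <- names(feature_counts)
  if (is.null(omics) || !all(omics %in% OMICS_NAMES))
    stop("feature_counts must be named by omics: ",
         paste(OMICS_NAMES, collapse = ", "), call. = FALSE)
  if (!dominant_omics %in% omics)
    stop("dominant_omics must be one of the simulated blocks", call. = FALSE)
  if (dominance < 0 || dominance > 1)
    stop("dominance must lie in [0, 1]", call. = FALSE)
  M <- length(omics)
  shares <- if (M == 1L) {
    if (dominance != 1)
      stop("invalid shares: a single block must carry dominance = 1",
           call. = FALSE)
    stats::setNames(1, omics)
  } else {
    s <- stats::setNames(rep((1 - dominance) / (M - 1), M), omics)
    s[dominant_omics] <- dominance
    s
  }
  structure(list(n_cells = as.integer(n_cells),
                 feature_counts = feature_counts,
                 edge_prob = edge_prob,
                 dominant_omics = dominant_omics,
                 dominance = dominance, shares = shares,
                 n_drugs = as.integer(n_drugs),
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 graph_signal = isTRUE(graph_signal),
                 coef_density = coef_density,
                 mutation_rate = mutation_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Erdos-Renyi edge draw over given symbols using the current RNG stream.
r_interactome <- function(symbols, edge_prob) {
  n <- length(symbols)
  if (n < 2L || edge_prob <= 0)
    return(interactome_edges(matrix(character(), ncol = 2L)))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(idx)) < edge_prob
  interactome_edges(cbind(symbols[idx[keep, 1L]], symbols[idx[keep, 2L]]))
}

#' Simulate an Erdos-Renyi interactome
#'
#' Each unordered symbol pair is included independently with probability
#' `edge_prob`; the draw is reproducible for a fixed seed.
#'
#' @param n_genes number of gene symbols.
#' @param edge_prob edge probability in \[0, 1\].
#' @param seed integer RNG seed.
#' @param symbols optional symbol vector (defaults to `G0001`, ...).
#' @return An `interactome_edges` object.
#' @export
simulate_interactome <- function(n_genes, edge_prob, seed,
                                 symbols = NULL) {
  stopifnot(n_genes >= 0L, edge_prob >= 0, edge_prob <= 1)
  if (is.null(symbols)) symbols <- sprintf("G%04d", seq_len(n_genes))
  set.seed(as.integer(seed))
  r_interactome(symbols, edge_prob)
}

block_feature_ids <- function(omics, p) {
  prefix <- switch(omics, expression = "G", mutation = "G", cnv = "G",
                   rppa = "R", metabolomics = "M")
  sprintf("%s%04d", prefix, seq_len(p))
}

#' Simulate a multi-omics drug-response dataset with planted structure
#'
#' Continuous blocks are standard normal, the mutation block is a Bernoulli
#' indicator matrix, and CNV is integer copy counts centred at 2.  Per drug
#' j and block m a sparse coefficient vector defines a linear score
#' `s_m` (computed from adjacency-smoothed features when `graph_signal` is
#' set), centred and scaled to unit sample variance.  Responses are
#' `y_ij = sum_m sqrt(share_m) s_m(i, j) + eps`, `eps ~ N(0, noise_sd^2)`,
#' and entries are masked unobserved at `missing_rate`.
#'
#' @param cfg a [simulation_config()].
#' @return list with `dataset` (a `multi_omics_dataset` whose graph blocks
#'   carry adjacency masks) and `truth` (shares, per-block coefficients and
#'   score-normalization constants, realized scores, the interactome, the
#'   dominant block and the config).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  omics <- names(cfg$feature_counts)
  kinds <- ifelse(omics %in% GRAPH_OMICS, "graph", "dense")
  names(kinds) <- omics
  n <- cfg$n_cells
  cells <- sprintf("CL%04d", seq_len(n))
  drugs <- sprintf("D%02d", seq_len(cfg$n_drugs))

  n_genes <- if (any(kinds == "graph"))
    max(cfg$feature_counts[kinds == "graph"]) else 0L
  gene_universe <- sprintf("G%04d", seq_len(n_genes))
  edges <- r_interactome(gene_universe, cfg$edge_prob)

  blocks <- list(); adjacency <- list()
  for (m in omics) {
    p <- cfg$feature_counts[[m]]
    feats <- block_feature_ids(m, p)
    vals <- switch(m,
      mutation = matrix(stats::rbinom(n * p, 1L, cfg$mutation_rate), n, p),
      cnv = matrix(sample(c(0, 1, 2, 3, 4), n * p, replace = TRUE,
                          prob = c(0.05, 0.1, 0.7, 0.1, 0.05)), n, p),
      matrix(stats::rnorm(n * p), n, p))
    dimnames(vals) <- list(cells, feats)
    blocks[[m]] <- omics_matrix(vals, m, kinds[[m]])
    if (kinds[[m]] == "graph")
      adjacency[[m]] <- build_adjacency(edges, feats)
  }

  coef <- list(); scores <- list()
  for (m in omics) {
    p <- cfg$feature_counts[[m]]
    X <- scale(blocks[[m]]$values, center = TRUE, scale = FALSE)
    if (cfg$graph_signal && kinds[[m]] == "graph") {
      A <- unclass(adjacency[[m]])
      X <- X %*% sweep(A, 2L, colSums(A), "/")
    }
    nnz <- max(1L, round(cfg$coef_density * p))
    beta <- matrix(0, p, cfg$n_drugs,
                   dimnames = list(blocks[[m]]$feature_ids, drugs))
    for (j in seq_len(cfg$n_drugs)) {
      pos <- sample.int(p, nnz)
      beta[pos, j] <- stats::rnorm(nnz)
    }
    s <- X %*% beta
    ctr <- colMeans(s)
    scl <- apply(s, 2L, stats::sd)
    scl[!is.finite(scl) | scl < 1e-12] <- 1
    s <- sweep(sweep(s, 2L, ctr, "-"), 2L, scl, "/")
    coef[[m]] <- list(beta = beta, center = ctr, scale = scl)
    scores[[m]] <- s
  }

  y <- matrix(0, n, cfg$n_drugs, dimnames = list(cells, drugs))
  for (m in omics) y <- y + sqrt(cfg$shares[[m]]) * scores[[m]]
  if (cfg$noise_sd > 0)
    y <- y + matrix(stats::rnorm(n * cfg$n_drugs, sd = cfg$noise_sd),
                    n, cfg$n_drugs)
  mask <- matrix(stats::runif(n * cfg$n_drugs) >= cfg$missing_rate,
                 n, cfg$n_drugs)
  vals <- y
  vals[!mask] <- NA_real_
  responses <- drug_response_table(vals, cells, drugs)

  dataset <- multi_omics_dataset(blocks, responses,
                                 if (length(adjacency)) adjacency else NULL)
  truth <- list(shares = cfg$shares, coefficients = coef, scores = scores,
                edges = edges, dominant_omics = cfg$dominant_omics,
                config = cfg)
  list(dataset = dataset, truth = truth)
}
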