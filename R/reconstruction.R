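#' Infer a network by thresholding beta-diversity similarity
#'
#' The simplest inversion of the beta-matrix: connect every pair of species
#' whose TE-content similarity `1 - beta(i, j)` reaches the threshold, with
#' the similarity kept as edge weight. Raising the threshold can only remove
#' edges.
#'
#' @param beta a beta-matrix (Jaccard distance) from [beta_matrix()].
#' @param threshold similarity threshold in `[0, 1]`.
#' @param capacity capacity assigned to the species of the inferred network
#'   (default 100).
#' @return an [htt_network()] with `topology = "custom"`. A warning is
#'   raised when the result is edgeless or complete.
#' @examples
#' p <- rbind(c(TRUE, TRUE), c(TRUE, TRUE), c(FALSE, TRUE))
#' infer_by_threshold(beta_matrix(p), threshold = 0.9)
#' @export
infer_by_threshold <- function(beta, threshold, capacity = 100L) {
  stopifnot(is.matrix(beta), nrow(beta) == ncol(beta),
            threshold >= 0, threshold <= 1)
  n <- nrow(beta)
  sim <- 1 - beta
  keep <- which(upper.tri(sim) & sim >= threshold, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(keep) > 0) {
    g <- igraph::add_edges(g, t(keep))
    # weights carry the similarity; floored so zero-similarity edges kept by
    # a zero threshold still satisfy the positive-weight invariant
    igraph::E(g)$weight <- pmax(sim[keep], .Machine$double.eps)
  }
  m <- nrow(keep)
  if (m == 0) warning("threshold produced an edgeless network")
  if (m == n * (n - 1) / 2) warning("threshold produced a complete network")
  htt_network(g, capacities = capacity, topology = "custom")
}

#' Pairwise mutual information between species TE profiles
#'
#' Scores each species pair by the mutual information (in bits) between
#' their binary family-presence profiles, estimated by the plug-in
#' (maximum-likelihood) estimator on the empirical 2x2 joint distribution
#' over families. MI measures how redundant the TE contents of two genomes
#' are: 0 for independent profiles, up to the marginal entropy for identical
#' ones. The diagonal holds each profile's entropy.
#'
#' @param p a logical species x family matrix (see [presence_matrix()]).
#' @return a symmetric non-negative species x species matrix with attribute
#'   `"method" = "mutual_information"`.
#' @examples
#' p <- rbind(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
#' mutual_information_scores(p)[1, 2]  # independent profiles: 0 bits
#' @export
mutual_information_scores <- function(p) {
  stopifnot(is.matrix(p), ncol(p) >= 2)
  m <- matrix(as.numeric(p), nrow(p), ncol(p))
  F <- ncol(m)
  n11 <- tcrossprod(m)
  s <- rowSums(m)
  n10 <- outer(s, s, function(a, b) a) - n11
  n01 <- outer(s, s, function(a, b) b) - n11
  n00 <- F - n11 - n10 - n01
  px1 <- s / F
  plogp <- function(joint, pa, pb) {
    term <- joint / F * log2(pmax(joint, 1) / F / (pa * pb))
    ifelse(joint > 0, term, 0)
  }
  mi <- plogp(n11, px1, rep(px1, each = nrow(m))) +
        plogp(n10, px1, rep(1 - px1, each = nrow(m))) +
        plogp(n01, 1 - px1, rep(px1, each = nrow(m))) +
        plogp(n00, 1 - px1, rep(1 - px1, each = nrow(m)))
  mi[mi < 0] <- 0 # numerical noise
  ids <- if (!is.null(rownames(p))) rownames(p) else seq_len(nrow(p))
  dimnames(mi) <- list(ids, ids)
  attr(mi, "method") <- "mutual_information"
  mi
}

#' ABC-style candidate-network selection
#'
#' Simulation-based network inference in the approximate-Bayesian-
#' computation spirit: every candidate network is used to simulate
#' `n_sims_per_candidate` beta-matrices under `config`, and candidates are
#' ranked by the mean Mantel correlation of their simulated beta-matrices
#' with the observed one (ties broken by lower SD). The top-ranked candidate
#' is the network whose emergent TE composition best matches the data.
#'
#' @param beta_obs the observed (empirical or simulated) beta-matrix.
#' @param candidates a list of [htt_network()] objects over the same species
#'   set as `beta_obs`.
#' @param config a [sim_config()] describing the assumed TE dynamics.
#' @param n_sims_per_candidate simulations per candidate (default 10).
#' @param seed master seed (hierarchical per candidate / simulation).
#' @return a data frame with one row per candidate, ordered by rank:
#'   `candidate` (index into `candidates`), `mean_r`, `sd_r`, `n_ok`
#'   (simulations that produced a usable beta-matrix), `rank`. The candidate
#'   list is attached as attribute `"candidates"`.
#' @export
abc_reconstruct <- function(beta_obs, candidates, config = sim_config(),
                            n_sims_per_candidate = 10L, seed = 1L) {
  stopifnot(is.matrix(beta_obs), is.list(candidates), length(candidates) >= 1)
  n <- nrow(beta_obs)
  ok_dims <- vapply(candidates, function(cand) n_species(cand) == n, logical(1))
  if (!all(ok_dims)) stop("all candidates must share the species set of beta_obs")
  rows <- lapply(seq_along(candidates), function(ci) {
    rs <- vapply(seq_len(n_sims_per_candidate), function(j) {
      res <- run_to_htt_count(candidates[[ci]], config,
                              seed = derive_seed(seed, ci, j),
                              log_events = FALSE)
      if (res$failed) NA_real_
      else mantel_r(beta_obs, beta_matrix(presence_matrix(res)))
    }, numeric(1))
    rs_ok <- rs[!is.na(rs)]
    data.frame(candidate = ci,
               mean_r = if (length(rs_ok)) mean(rs_ok) else NA_real_,
               sd_r = if (length(rs_ok) > 1) sd(rs_ok) else NA_real_,
               n_ok = length(rs_ok),
               flagged = length(rs_ok) < n_sims_per_candidate)
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$mean_r, tab$sd_r, tab$candidate)
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "candidates") <- candidates
  tab
}
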