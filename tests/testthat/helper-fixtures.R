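# Small deterministic objects shared across tests.

# network from an explicit edge list (1-based ids)
net_from_edges <- function(el, n = max(el), capacity = 100L, modules = NULL,
                           topology = "custom") {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(el))
  igraph::E(g)$weight <- 1
  htt_network(g, capacities = capacity, topology = topology, modules = modules)
}

two_node_net <- function(capacity = 100L) {
  net_from_edges(rbind(c(1, 2)), capacity = capacity)
}

four_cycle <- function() {
  net_from_edges(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
}

edge_set <- function(net) {
  el <- igraph::as_edgelist(as_igraph(net), names = FALSE)
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "-"))
}

# numeric matrix stripped of names/attributes, for value-only comparison
bare <- function(m) matrix(as.numeric(m), nrow(m), ncol(m))

# brute-force Jaccard beta-diversity via explicit set arithmetic
beta_oracle <- function(p) {
  n <- nrow(p)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      fi <- which(p[i, ])
      fj <- which(p[j, ])
      u <- length(union(fi, fj))
      out[i, j] <- if (u == 0) 0 else 1 - length(intersect(fi, fj)) / u
    }
  }
  out
}

# independent permutation enumerator (index-tuple filter, not recursion)
all_perms_oracle <- function(n) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  keep <- apply(grid, 1, function(r) length(unique(r)) == n)
  lapply(which(keep), function(i) as.integer(grid[i, ]))
}
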