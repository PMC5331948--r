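#' HTT network objects
#'
#' An `htt_network` represents the ecological network along which
#' transposable elements can move horizontally: nodes are species acting as
#' TE reservoirs (each with a carrying capacity, the maximal number of TE
#' copies its genome holds), and weighted edges are ecological links whose
#' weight stands for the density of "TE molecular vehicles" (viruses,
#' parasites...) transiting between the two species.
#'
#' @param graph an [igraph::igraph] object; vertices must be `1..n` in order.
#' @param capacities positive integer vector (length 1 or `n`): per-species
#'   genome carrying capacity.
#' @param topology one of `"complete"`, `"random"`, `"scale_free"`,
#'   `"modular"`, `"bipartite"`, `"custom"`.
#' @param modules optional integer vector of group memberships (modular /
#'   bipartite networks).
#' @return an object of class `htt_network`: a list with elements `graph`,
#'   `capacities`, `topology`, `modules`.
#' @seealso [generate_network()], [shuffle_edges()], [degree_summary()]
#' @export
htt_network <- function(graph, capacities = 100L,
                        topology = "custom", modules = NULL) {
  stopifnot(igraph::is_igraph(graph))
  n <- igraph::vcount(graph)
  if (n < 2) stop("an HTT network needs at least 2 species")
  if (length(capacities) == 1) capacities <- rep(capacities, n)
  if (length(capacities) != n) stop("capacities must have length 1 or n_species")
  capacities <- as.integer(capacities)
  if (any(is.na(capacities)) || any(capacities < 1))
    stop("all capacities must be >= 1")
  topology <- match.arg(topology, c("complete", "random", "scale_free",
                                    "modular", "bipartite", "custom"))
  if (!is.null(modules)) {
    if (length(modules) != n) stop("modules must have length n_species")
    modules <- as.integer(modules)
  }
  if (igraph::any_loop(graph)) stop("self-loops are not allowed")
  if (igraph::any_multiple(graph)) stop("duplicate edges are not allowed")
  w <- igraph::E(graph)$weight
  if (is.null(w)) {
    igraph::E(graph)$weight <- 1.0
  } else if (any(w <= 0)) {
    stop("all edge weights must be > 0")
  }
  if (topology == "bipartite") {
    if (is.null(modules) || length(unique(modules)) != 2)
      stop("bipartite networks need a 2-group module assignment")
    el <- igraph::as_edgelist(graph, names = FALSE)
    if (any(modules[el[, 1]] == modules[el[, 2]]))
      stop("bipartite networks may not have within-set edges")
  }
  structure(list(graph = graph, capacities = capacities,
                 topology = topology, modules = modules),
            class = "htt_network")
}

#' @export
print.htt_network <- function(x, ...) {
  ds <- degree_summary(x)
  cat(sprintf("<htt_network> %s: %d species, %d links (mean degree %.2f, density %.3f)\n",
              x$topology, n_species(x), igraph::ecount(x$graph),
              ds$mean_degree, ds$density))
  cat(sprintf("  capacities: %s copies/genome\n",
              if (length(unique(x$capacities)) == 1) as.character(x$capacities[1])
              else paste0(min(x$capacities), "-", max(x$capacities))))
  if (!is.null(x$modules))
    cat("  modules:", paste(table(x$modules), collapse = "/"), "\n")
  invisible(x)
}

#' Number of species in an HTT network
#' @param net an `htt_network`.
#' @return integer.
#' @export
n_species <- function(net) as.integer(igraph::vcount(net$graph))

#' Extract the underlying igraph object
#' @param net an `htt_network`.
#' @return an [igraph::igraph].
#' @export
as_igraph <- function(net) net$graph

known_topologies <- c("complete", "random", "scale_free", "modular",
                      "bipartite", "custom")

#' Generate an HTT network of a given topology
#'
#' Builds the five classical ecological-network topologies used to contrast
#' routes of horizontal transposon transfer: `complete` (all species
#' interact equally), `random` (Erdos-Renyi; Poisson degrees, no hubs),
#' `scale_free` (preferential attachment; heavy-tailed degrees with hub
#' species such as generalist hosts), `modular` (stochastic-block: denser
#' links within than between groups, e.g. partially isolated communities),
#' and `bipartite` (two disjoint sets, e.g. macroparasites vs hosts, with
#' links only between sets).
#'
#' By default the returned network is connected: generation is retried up to
#' `max_tries` times and, failing that, components are joined by random
#' bridging edges (recorded in attribute `"bridged"`). Set `connect = FALSE`
#' to get the raw draw from the generator.
#'
#' @param topology topology label (see above).
#' @param n_species number of species (>= 2).
#' @param mean_degree target mean degree; ignored for `complete`, and for
#'   `modular` when `p_within`/`p_between` are given.
#' @param n_modules number of groups for `modular`.
#' @param p_within,p_between within/between-group edge probabilities
#'   (`modular`). When missing they are derived from `mean_degree` with
#'   `within_between_ratio`.
#' @param within_between_ratio ratio p_within / p_between used when deriving
#'   probabilities from `mean_degree` (default 20).
#' @param set_sizes integer vector of length 2, sizes of the two node sets
#'   (`bipartite`); defaults to an even split.
#' @param capacity per-species genome carrying capacity (scalar or vector).
#' @param connect require a connected network (default `TRUE`).
#' @param max_tries regeneration attempts before bridging (default 100).
#' @param seed integer RNG seed; same spec + seed gives an identical network.
#' @return an [htt_network()].
#' @examples
#' net <- generate_network("scale_free", n_species = 20, mean_degree = 4, seed = 7)
#' degree_summary(net)$mean_degree
#' @export
generate_network <- function(topology, n_species,
                             mean_degree = 4,
                             n_modules = 4,
                             p_within = NULL, p_between = NULL,
                             within_between_ratio = 20,
                             set_sizes = NULL,
                             capacity = 100L,
                             connect = TRUE, max_tries = 100L,
                             seed = NULL) {
  topology <- match.arg(topology, setdiff(known_topologies, "custom"))
  n <- as.integer(n_species)
  if (n < 2) stop("n_species must be >= 2")
  if (topology != "complete" && (mean_degree <= 0 || mean_degree >= n))
    stop("mean_degree must be in (0, n_species)")
  if (!is.null(seed)) set.seed(seed)

  modules <- NULL
  gen <- switch(topology,
    complete = function() igraph::make_full_graph(n, directed = FALSE),
    random = function() igraph::sample_gnp(n, p = mean_degree / (n - 1)),
    scale_free = function() {
      m <- max(1L, as.integer(round(mean_degree / 2)))
      igraph::sample_pa(n, m = m, directed = FALSE)
    },
    modular = function() {
      sizes <- module_sizes(n, n_modules)
      pw <- p_within; pb <- p_between
      if (is.null(pw) || is.null(pb)) {
        # E[deg] = pw*(m-1) + pb*(n-m) with pw = ratio*pb, m = mean group size
        m <- n / n_modules
        pb <- mean_degree / (within_between_ratio * (m - 1) + (n - m))
        pw <- min(1, within_between_ratio * pb)
      }
      if (pw <= pb) stop("modular networks require p_within > p_between")
      pref <- matrix(pb, n_modules, n_modules)
      diag(pref) <- pw
      igraph::sample_sbm(n, pref.matrix = pref, block.sizes = sizes)
    },
    bipartite = function() {
      if (is.null(set_sizes)) set_sizes <- c(floor(n / 2), ceiling(n / 2))
      if (sum(set_sizes) != n) stop("bipartite set sizes must sum to n_species")
      p <- min(1, mean_degree * n / (2 * prod(set_sizes)))
      igraph::sample_bipartite(set_sizes[1], set_sizes[2], p = p)
    })

  g <- gen()
  bridged <- FALSE
  if (connect && !igraph::is_connected(g)) {
    for (i in seq_len(max_tries)) {
      g <- gen()
      if (igraph::is_connected(g)) break
    }
    if (!igraph::is_connected(g)) {
      g <- bridge_components(g)
      bridged <- TRUE
    }
  }

  modules <- switch(topology,
    modular = rep(seq_len(n_modules), module_sizes(n, n_modules)),
    bipartite = {
      if (is.null(set_sizes)) set_sizes <- c(floor(n / 2), ceiling(n / 2))
      rep(1:2, set_sizes)
    },
    NULL)

  igraph::E(g)$weight <- 1.0
  net <- htt_network(g, capacities = capacity, topology = topology,
                     modules = modules)
  attr(net, "bridged") <- bridged
  net
}

module_sizes <- function(n, k) {
  if (k < 1 || k > n) stop("n_modules must be between 1 and n_species")
  base <- n %/% k
  sizes <- rep(base, k)
  extra <- n - base * k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

# Join disconnected components with random bridging edges (minimal count).
bridge_components <- function(g) {
  comp <- igraph::components(g)
  while (comp$no > 1) {
    a <- sample(which(comp$membership == 1), 1)
    other <- sample(which(comp$membership != 1), 1)
    g <- igraph::add_edges(g, c(a, other))
    comp <- igraph::components(g)
  }
  g
}

#' Perturb a network by edge shuffles
#'
#' Applies `n_shuffles` degree-preserving double-edge swaps: two edges
#' (a,b) and (c,d) are replaced by (a,d) and (c,b), rejecting self-loops and
#' duplicate edges, so node degrees, edge count and capacities are all
#' preserved while the wiring departs from the reference network. With
#' `method = "endpoint"` each shuffle instead rewires one endpoint of a
#' random edge to a random new node (degrees not preserved).
#'
#' @param net an [htt_network()].
#' @param n_shuffles non-negative number of shuffles; 0 returns a
#'   structurally identical network.
#' @param seed integer RNG seed.
#' @param method `"double_swap"` (default) or `"endpoint"`.
#' @param max_tries bound on total attempted swaps (default
#'   `100 * n_shuffles`); if fewer shuffles succeed a warning reports the
#'   effective count, also stored in attribute `"effective_shuffles"`.
#' @return a new `htt_network` with the same node set and edge count.
#' @examples
#' net <- generate_network("random", 10, mean_degree = 3, seed = 1)
#' shuf <- shuffle_edges(net, 5, seed = 2)
#' identical(sort(igraph::degree(as_igraph(net))),
#'           sort(igraph::degree(as_igraph(shuf))))
#' @export
shuffle_edges <- function(net, n_shuffles, seed = NULL,
                          method = c("double_swap", "endpoint"),
                          max_tries = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(net, "htt_network"), n_shuffles >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- n_species(net)
  el <- igraph::as_edgelist(net$graph, names = FALSE)
  w <- igraph::E(net$graph)$weight
  m <- nrow(el)
  done <- 0L
  if (n_shuffles > 0) {
    if (m < 2 && method == "double_swap")
      stop("double-edge swaps need at least 2 edges")
    if (is.null(max_tries)) max_tries <- 100L * n_shuffles
    adj <- matrix(FALSE, n, n)
    adj[el] <- TRUE
    adj[el[, 2:1, drop = FALSE]] <- TRUE
    tries <- 0L
    while (done < n_shuffles && tries < max_tries) {
      tries <- tries + 1L
      if (method == "double_swap") {
        ij <- sample.int(m, 2)
        a <- el[ij[1], 1]; b <- el[ij[1], 2]
        cc <- el[ij[2], 1]; d <- el[ij[2], 2]
        if (stats::runif(1) < 0.5) { tmp <- cc; cc <- d; d <- tmp }
        # propose (a,d) and (c,b)
        if (a == d || cc == b) next
        if (adj[a, d] || adj[cc, b]) next
        adj[a, b] <- adj[b, a] <- FALSE
        adj[cc, d] <- adj[d, cc] <- FALSE
        adj[a, d] <- adj[d, a] <- TRUE
        adj[cc, b] <- adj[b, cc] <- TRUE
        el[ij[1], ] <- c(a, d)
        el[ij[2], ] <- c(cc, b)
      } else {
        i <- sample.int(m, 1)
        keep <- el[i, sample(1:2, 1)]
        new <- sample.int(n, 1)
        if (new == keep || adj[keep, new]) next
        drop <- setdiff(el[i, ], keep)
        adj[keep, drop] <- adj[drop, keep] <- FALSE
        adj[keep, new] <- adj[new, keep] <- TRUE
        el[i, ] <- c(keep, new)
      }
      done <- done + 1L
    }
    if (done < n_shuffles)
      warning(sprintf("only %d of %d edge shuffles succeeded", done, n_shuffles))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(el))
  igraph::E(g)$weight <- w
  out <- htt_network(g, capacities = net$capacities,
                     topology = net$topology, modules = net$modules)
  attr(out, "effective_shuffles") <- done
  out
}

#' Degree summary of an HTT network
#'
#' @param net an [htt_network()].
#' @return a list with `degrees` (per-species degree sequence),
#'   `mean_degree` (`2|E|/N`) and `density`.
#' @export
degree_summary <- function(net) {
  stopifnot(inherits(net, "htt_network"))
  deg <- igraph::degree(net$graph)
  n <- length(deg)
  m <- igraph::ecount(net$graph)
  list(degrees = as.integer(deg),
       mean_degree = 2 * m / n,
       density = if (n > 1) 2 * m / (n * (n - 1)) else NA_real_)
}

#' Read/write HTT networks
#'
#' Networks are serialized either as a tab-separated edge list with columns
#' `source`, `target`, `weight` (node attributes go to a side-car
#' `<file>.nodes.tsv` with columns `species`, `capacity`, `module`) or as
#' GraphML with node attributes `capacity` and `module`. The format is
#' chosen from the file extension (`.tsv`/`.txt` vs `.graphml`).
#'
#' @param net an [htt_network()].
#' @param file path to write to / read from.
#' @return `write_network` returns `file` invisibly; `read_network` returns
#'   an `htt_network`.
#' @export
write_network <- function(net, file) {
  stopifnot(inherits(net, "htt_network"))
  if (grepl("\\.graphml$", file)) {
    g <- net$graph
    igraph::V(g)$capacity <- net$capacities
    igraph::V(g)$module <- if (is.null(net$modules)) NA_integer_ else net$modules
    igraph::V(g)$topology <- net$topology
    igraph::write_graph(g, file, format = "graphml")
  } else {
    el <- igraph::as_edgelist(net$graph, names = FALSE)
    df <- data.frame(source = el[, 1], target = el[, 2],
                     weight = igraph::E(net$graph)$weight)
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    nd <- data.frame(species = seq_len(n_species(net)),
                     capacity = net$capacities,
                     module = if (is.null(net$modules)) NA_integer_ else net$modules)
    write.table(nd, paste0(file, ".nodes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(file)
}

#' @rdname write_network
#' @export
read_network <- function(file) {
  if (grepl("\\.graphml$", file)) {
    g <- igraph::read_graph(file, format = "graphml")
    caps <- igraph::V(g)$capacity
    mods <- igraph::V(g)$module
    topo <- igraph::V(g)$topology
    topo <- if (is.null(topo)) "custom" else topo[1]
    if (all(is.na(mods))) mods <- NULL
    g2 <- igraph::make_empty_graph(igraph::vcount(g), directed = FALSE)
    g2 <- igraph::add_edges(g2, t(igraph::as_edgelist(g, names = FALSE)))
    igraph::E(g2)$weight <- if (is.null(igraph::E(g)$weight))
      rep(1, igraph::ecount(g)) else igraph::E(g)$weight
    htt_network(g2, capacities = if (is.null(caps)) 100L else as.integer(caps),
                topology = topo, modules = mods)
  } else {
    df <- read.table(file, header = TRUE, sep = "\t")
    nodes_file <- paste0(file, ".nodes.tsv")
    caps <- 100L; mods <- NULL
    n <- max(df$source, df$target)
    if (file.exists(nodes_file)) {
      nd <- read.table(nodes_file, header = TRUE, sep = "\t")
      n <- max(n, nrow(nd))
      caps <- as.integer(nd$capacity)
      if (!all(is.na(nd$module))) mods <- as.integer(nd$module)
    }
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(as.matrix(df[, c("source", "target")])))
    igraph::E(g)$weight <- if ("weight" %in% names(df)) df$weight else 1
    htt_network(g, capacities = caps, topology = "custom", modules = mods)
  }
}
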