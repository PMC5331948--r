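test_that("complete networks have all C(n,2) edges and mean degree n-1", {
  net <- generate_network("complete", 20, seed = 1)
  expect_equal(igraph::ecount(as_igraph(net)), 190)
  expect_equal(degree_summary(net)$mean_degree, 19)
})

test_that("degree_summary reports sequence, mean degree and density", {
  single <- net_from_edges(rbind(c(1, 2)), n = 2)
  expect_equal(degree_summary(single)$density, 1.0)
  star <- net_from_edges(cbind(1, 2:5), n = 5)
  expect_equal(sort(degree_summary(star)$degrees, decreasing = TRUE),
               c(4, 1, 1, 1, 1))
  expect_equal(degree_summary(star)$mean_degree, 2 * 4 / 5)
})

test_that("generation is reproducible and respects the requested label", {
  for (spec in list(list(topology = "random", n_species = 15, mean_degree = 4),
                    list(topology = "scale_free", n_species = 15, mean_degree = 4),
                    list(topology = "modular", n_species = 16, n_modules = 4,
                         mean_degree = 4),
                    list(topology = "bipartite", n_species = 14, mean_degree = 3))) {
    a <- do.call(generate_network, c(spec, list(seed = 42)))
    b <- do.call(generate_network, c(spec, list(seed = 42)))
    expect_identical(edge_set(a), edge_set(b))
    expect_identical(a$topology, spec$topology)
    expect_true(igraph::is_connected(as_igraph(a)))
    expect_false(igraph::any_loop(as_igraph(a)))
    expect_false(igraph::any_multiple(as_igraph(a)))
  }
})

test_that("infeasible specs are rejected", {
  expect_error(generate_network("random", 10, mean_degree = 10), "mean_degree")
  expect_error(generate_network("random", 1, mean_degree = 0.5), "n_species")
  expect_error(generate_network("bipartite", 10, mean_degree = 3,
                                set_sizes = c(4, 4)), "sum")
  expect_error(generate_network("modular", 12, n_modules = 3,
                                p_within = 0.1, p_between = 0.5), "p_within")
})

test_that("modular networks have more within- than between-module edges", {
  net <- generate_network("modular", 20, n_modules = 4,
                          p_within = 0.6, p_between = 0.02, seed = 7)
  el <- igraph::as_edgelist(as_igraph(net), names = FALSE)
  within <- sum(net$modules[el[, 1]] == net$modules[el[, 2]])
  expect_gt(within, nrow(el) - within)
})

test_that("scale-free networks are heavier-tailed than Erdos-Renyi", {
  sf <- generate_network("scale_free", 200, mean_degree = 4, seed = 3)
  er <- generate_network("random", 200, mean_degree = 4, seed = 3)
  expect_gt(max(degree_summary(sf)$degrees), max(degree_summary(er)$degrees))
  expect_gt(stats::var(degree_summary(sf)$degrees),
            stats::var(degree_summary(er)$degrees))
})

test_that("bipartite networks pass a two-coloring check", {
  net <- generate_network("bipartite", 15, mean_degree = 3,
                          set_sizes = c(6, 9), seed = 5)
  el <- igraph::as_edgelist(as_igraph(net), names = FALSE)
  expect_true(all(net$modules[el[, 1]] != net$modules[el[, 2]]))
  expect_true(igraph::bipartite_mapping(as_igraph(net))$res)
})

test_that("zero shuffles returns a graph-identical network", {
  net <- generate_network("scale_free", 12, mean_degree = 4, seed = 2)
  shuf <- shuffle_edges(net, 0, seed = 9)
  expect_identical(edge_set(shuf), edge_set(net))
  expect_identical(shuf$capacities, net$capacities)
})

test_that("shuffles preserve node set, edge count, degrees and capacities", {
  net <- generate_network("random", 15, mean_degree = 4, seed = 4,
                          capacity = c(rep(50L, 7), rep(200L, 8)))
  for (k in c(1, 5, 20)) {
    shuf <- shuffle_edges(net, k, seed = k)
    expect_equal(n_species(shuf), 15L)
    expect_equal(igraph::ecount(as_igraph(shuf)), igraph::ecount(as_igraph(net)))
    expect_equal(igraph::degree(as_igraph(shuf)), igraph::degree(as_igraph(net)))
    expect_identical(shuf$capacities, net$capacities)
    expect_false(igraph::any_loop(as_igraph(shuf)))
    expect_false(igraph::any_multiple(as_igraph(shuf)))
  }
})

test_that("a single swap of a 4-cycle yields one of the legal rewirings", {
  net <- four_cycle()
  # legal double-edge swaps of cycle 1-2-3-4: swapping two opposite edges
  # introduces the two chords; adjacent edges cannot be swapped legally
  legal <- list(sort(c("1-3", "2-4", "2-3", "1-4")),
                sort(c("1-3", "2-4", "1-2", "3-4")))
  for (s in 1:10) {
    shuf <- shuffle_edges(net, 1, seed = s, max_tries = 1000)
    es <- edge_set(shuf)
    expect_true(any(vapply(legal, identical, logical(1), y = es)),
                info = paste(es, collapse = ","))
  }
})

test_that("network distance to the reference grows with shuffle count", {
  net <- generate_network("scale_free", 20, mean_degree = 4, seed = 6)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  ref <- edge_set(net)
  sims <- sapply(c(1, 5, 20), function(k) {
    mean(sapply(1:10, function(r) jac(ref, edge_set(
      shuffle_edges(net, k, seed = derive_seed(100, k, r))))))
  })
  expect_true(all(diff(sims) < 0))
})

test_that("impossible swaps warn and report the effective count", {
  net <- generate_network("complete", 5, seed = 1) # complete: no legal swap
  expect_warning(shuf <- shuffle_edges(net, 3, max_tries = 50, seed = 1),
                 "0 of 3")
  expect_identical(attr(shuf, "effective_shuffles"), 0L)
})

test_that("networks round-trip through edge-list TSV and GraphML", {
  net <- generate_network("modular", 12, n_modules = 3, mean_degree = 4,
                          seed = 8, capacity = 7L)
  for (ext in c("tsv", "graphml")) {
    f <- file.path(tempdir(), paste0("net.", ext))
    write_network(net, f)
    back <- read_network(f)
    expect_identical(edge_set(back), edge_set(net))
    expect_identical(back$capacities, net$capacities)
    expect_identical(back$modules, net$modules)
  }
})

test_that("invalid networks are rejected by the constructor", {
  g <- igraph::make_full_graph(3)
  expect_error(htt_network(g, capacities = 0L), "capacities")
  expect_error(htt_network(g, capacities = c(1L, 2L)), "length")
  gl <- igraph::add_edges(igraph::make_empty_graph(3, directed = FALSE),
                          c(1, 1))
  expect_error(htt_network(gl), "self-loops")
  gb <- igraph::make_full_graph(3)
  expect_error(htt_network(gb, topology = "bipartite",
                           modules = c(1L, 1L, 2L)), "within-set")
})
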