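#' Read a simulation/pipeline configuration file
#'
#' Configurations are YAML or JSON (chosen by extension) mirroring the
#' [sim_config()] field names, optionally wrapped in a pipeline layout:
#' `seed`, `topology` (arguments of [generate_network()]), `sim` (arguments
#' of [sim_config()]), and `cluster` (`n_blocks`).
#'
#' @param file path to a `.yaml`/`.yml` or `.json` file.
#' @return a named list.
#' @export
read_sim_config <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file)
  cfg <- if (grepl("\\.json$", file)) jsonlite::read_json(file, simplifyVector = TRUE)
         else yaml::read_yaml(file)
  if (!is.list(cfg)) stop("config must parse to a named list")
  cfg
}

#' Write deterministic toy fixtures
#'
#' Materializes the small reference inputs used in examples and tests:
#' \describe{
#'   \item{`tiny-net`}{a connected 6-species network with two modules of 3
#'     (written as edge list TSV + node table).}
#'   \item{`block-beta`}{a 4x4 block-diagonal beta-matrix (two blocks;
#'     within-distance 0, between-distance 1).}
#'   \item{`toy-presence`}{a 6-species x 8-family presence table.}
#' }
#'
#' @param kind one of `"tiny-net"`, `"block-beta"`, `"toy-presence"`.
#' @param dir output directory (created if needed).
#' @param seed RNG seed (used by `toy-presence`).
#' @return the path(s) of the file(s) written, invisibly.
#' @export
make_fixtures <- function(kind = c("tiny-net", "block-beta", "toy-presence"),
                          dir = ".", seed = 1L) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (kind == "tiny-net") {
    # two triangles joined by one bridge: connected, modular
    el <- rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6), c(3, 4))
    g <- igraph::make_empty_graph(6, directed = FALSE)
    g <- igraph::add_edges(g, t(el))
    igraph::E(g)$weight <- 1
    net <- htt_network(g, capacities = 100L, topology = "modular",
                       modules = rep(1:2, each = 3))
    f <- file.path(dir, "tiny-net.tsv")
    write_network(net, f)
    invisible(c(f, paste0(f, ".nodes.tsv")))
  } else if (kind == "block-beta") {
    b <- matrix(1, 4, 4)
    b[1:2, 1:2] <- 0
    b[3:4, 3:4] <- 0
    dimnames(b) <- list(1:4, 1:4)
    f <- file.path(dir, "block-beta.tsv")
    write_matrix_tsv(b, f)
    invisible(f)
  } else {
    set.seed(seed)
    p <- matrix(stats::runif(48) < 0.5, 6, 8,
                dimnames = list(species = 1:6, family = 1:8))
    f <- file.path(dir, "toy-presence.tsv")
    write_matrix_tsv(p * 1L, f)
    invisible(f)
  }
}

pipeline_defaults <- function() {
  list(seed = 1L,
       topology = list(topology = "scale_free", n_species = 20L,
                       mean_degree = 4),
       sim = list(),
       cluster = list(n_blocks = NULL))
}

#' Run the full generate -> simulate -> beta -> cluster pipeline
#'
#' Executes the standard workflow from a single configuration: generate the
#' network, simulate the TE flow to the HTT stop criterion, derive the
#' presence and beta matrices, order species by clustering, and write every
#' artifact plus a JSON run manifest (config snapshot, derived seeds,
#' package version, md5 checksum of each output). Re-running the same
#' configuration reproduces identical checksums.
#'
#' @param config a named list (see [read_sim_config()]) or the path of a
#'   YAML/JSON config file. Recognized keys: `seed`, `topology`, `sim`,
#'   `cluster`.
#' @param out_dir output directory.
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_sim_config(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  # validate before any stage runs
  if (!cfg$topology$topology %in% setdiff(known_topologies, "custom"))
    stop("unknown topology label: ", cfg$topology$topology)
  sim_cfg <- do.call(sim_config, cfg$sim)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(network = derive_seed(cfg$seed, 1),
                simulation = derive_seed(cfg$seed, 2))

  net <- do.call(generate_network,
                 c(cfg$topology, list(seed = seeds$network)))
  write_network(net, file.path(out_dir, "network.graphml"))
  write_network(net, file.path(out_dir, "network.tsv"))

  res <- run_to_htt_count(net, sim_cfg, seed = seeds$simulation)
  write_matrix_tsv(res$copies, file.path(out_dir, "copies.tsv"))
  write.table(res$event_log, file.path(out_dir, "events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  p <- presence_matrix(res)
  write_matrix_tsv(p * 1L, file.path(out_dir, "presence.tsv"))
  beta <- beta_matrix(p)
  write_matrix_tsv(beta, file.path(out_dir, "beta.tsv"))
  write_beta_phylip(beta, file.path(out_dir, "beta.phylip"))

  cl <- cluster_order(beta, n_blocks = cfg$cluster$n_blocks)
  ord <- data.frame(position = seq_along(cl$order), species = cl$order,
                    block = cl$blocks[cl$order])
  write.table(ord, file.path(out_dir, "ordering.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  outputs <- c("network.graphml", "network.tsv", "network.tsv.nodes.tsv",
               "copies.tsv", "events.tsv", "presence.tsv", "beta.tsv",
               "beta.phylip", "ordering.tsv")
  manifest <- list(
    package_version = as.character(packageVersion("httnet")),
    config = cfg,
    seeds = seeds,
    stats = list(iterations = res$iteration, htt_count = res$htt_count,
                 transpositions = res$n_transpositions,
                 capacity_rejected = res$n_capacity_rejected,
                 truncated = res$truncated, n_blocks = cl$n_blocks),
    checksums = as.list(tools::md5sum(file.path(out_dir, outputs))))
  names(manifest$checksums) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
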