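#' Simulation configuration
#'
#' Bundles all parameters of the TE-flow model. Each iteration, every TE
#' copy (i) duplicates within its genome with probability `u_transposition`,
#' blocked when the genome is at its carrying capacity; (ii) attempts a
#' horizontal transfer with probability `u_transposition / htt_ratio`
#' towards a network neighbour drawn proportionally to edge weight; and
#' (iii) is lost with probability `loss_prob`. The simulation stops at the
#' first iteration where the cumulative number of successful transfers
#' reaches `target_htt_count` (or at `max_iterations`, flagged truncated).
#'
#' `at_capacity` controls establishment in a genome already at capacity:
#' `"replace"` (default) evicts a uniformly chosen resident copy so the
#' transfer still succeeds and the genome stays at its cap; `"reject"`
#' discards the attempt (not counted as a successful HTT). `capacity_mode`
#' selects whether the cap applies to the per-species total over families
#' (`"species"`, default) or to each species-family count (`"family"`).
#'
#' @param n_species number of species (default 20).
#' @param n_families number of TE families (default 30).
#' @param capacity genome carrying capacity, scalar or per-species vector
#'   (default 100 copies).
#' @param u_transposition per-copy duplication probability per iteration
#'   (default 0.01).
#' @param htt_ratio ratio of transposition to HTT rate (rho >= 1; default
#'   100, i.e. one horizontal transfer attempt per 100 duplications).
#' @param target_htt_count stop criterion: number of successful HTTs
#'   (default 150).
#' @param max_iterations safety cap on iterations (default 50000).
#' @param loss_prob per-copy loss probability per iteration (default 0).
#' @param capacity_mode `"species"` or `"family"` (see above).
#' @param at_capacity `"replace"` or `"reject"` (see above).
#' @param seed default RNG seed used by the run functions when no explicit
#'   seed is passed.
#' @return an object of class `sim_config`.
#' @examples
#' cfg <- sim_config()
#' cfg$target_htt_count
#' @export
sim_config <- function(n_species = 20L, n_families = 30L, capacity = 100L,
                       u_transposition = 0.01, htt_ratio = 100,
                       target_htt_count = 150L, max_iterations = 50000L,
                       loss_prob = 0,
                       capacity_mode = c("species", "family"),
                       at_capacity = c("replace", "reject"),
                       seed = NULL) {
  capacity_mode <- match.arg(capacity_mode)
  at_capacity <- match.arg(at_capacity)
  stopifnot(n_species >= 2, n_families >= 1,
            u_transposition > 0, u_transposition <= 1,
            htt_ratio >= 1, target_htt_count >= 1, max_iterations >= 1,
            loss_prob >= 0, loss_prob < 1, all(capacity >= 1))
  structure(list(n_species = as.integer(n_species),
                 n_families = as.integer(n_families),
                 capacity = as.integer(capacity),
                 u_transposition = u_transposition,
                 htt_ratio = htt_ratio,
                 target_htt_count = as.integer(target_htt_count),
                 max_iterations = as.integer(max_iterations),
                 loss_prob = loss_prob,
                 capacity_mode = capacity_mode,
                 at_capacity = at_capacity,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d species x %d families, capacity %s (%s, %s at cap)\n",
                     "  u = %g, rho = %g (HTT prob %g), loss = %g; stop at %d HTTs (max %d iter)\n"),
              x$n_species, x$n_families,
              paste(unique(x$capacity), collapse = ","),
              x$capacity_mode, x$at_capacity,
              x$u_transposition, x$htt_ratio,
              x$u_transposition / x$htt_ratio, x$loss_prob,
              x$target_htt_count, x$max_iterations))
  invisible(x)
}

cap_vector <- function(config, n) {
  if (length(config$capacity) == 1) rep(config$capacity, n)
  else if (length(config$capacity) == n) config$capacity
  else stop("capacity vector length does not match n_species")
}

#' Initialize the simulation state
#'
#' Seeds every TE family with exactly one founding copy. For multi-family
#' runs the founder species is drawn uniformly and independently per family;
#' for single-family runs (or when reproducing a specific invasion) the
#' founder can be fixed with `start_species`.
#'
#' @param config a [sim_config()].
#' @param net an [htt_network()]; its species count must match the config.
#' @param start_species optional founder species id (recycled over
#'   families).
#' @return a `sim_state`: list with `copies` (species x family integer
#'   matrix), `iteration = 0`, `htt_count = 0`.
#' @export
init_state <- function(config, net, start_species = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(net, "htt_network"))
  if (config$n_species != n_species(net))
    stop("config n_species does not match the network")
  S <- config$n_species; F <- config$n_families
  copies <- matrix(0L, S, F,
                   dimnames = list(species = seq_len(S), family = seq_len(F)))
  founders <- if (is.null(start_species)) sample.int(S, F, replace = TRUE)
              else rep_len(as.integer(start_species), F)
  if (any(founders < 1 | founders > S)) stop("start_species out of range")
  for (f in seq_len(F)) copies[founders[f], f] <- 1L
  structure(list(copies = copies, iteration = 0L, htt_count = 0L,
                 founders = founders),
            class = "sim_state")
}

# Neighbour index/weight lists consumed by the compiled core.
neighbour_lists <- function(net) {
  g <- net$graph
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  idx <- vector("list", n)
  wts <- vector("list", n)
  for (s in seq_len(n)) { idx[[s]] <- integer(0); wts[[s]] <- numeric(0) }
  for (e in seq_len(nrow(el))) {
    a <- el[e, 1]; b <- el[e, 2]
    idx[[a]] <- c(idx[[a]], b); wts[[a]] <- c(wts[[a]], w[e])
    idx[[b]] <- c(idx[[b]], a); wts[[b]] <- c(wts[[b]], w[e])
  }
  list(idx = idx, wts = wts)
}

run_core <- function(state, net, config, target, max_iter,
                     log_events, track_spread, stop_full) {
  nb <- neighbour_lists(net)
  .sim_core(state$copies, nb$idx, nb$wts,
            cap_vector(config, config$n_species),
            config$u_transposition, config$htt_ratio, config$loss_prob,
            as.integer(target), as.integer(max_iter),
            config$capacity_mode == "family",
            config$at_capacity == "replace",
            log_events, track_spread, stop_full,
            state$iteration, state$htt_count)
}

event_log_df <- function(m) {
  df <- as.data.frame(m)
  df$type <- c("transposition", "htt", "loss", "htt_blocked")[df$type]
  df
}

#' Advance the simulation by one (or more) iterations
#'
#' @param state a `sim_state` (from [init_state()] or a previous step/run).
#' @param net the [htt_network()] the simulation runs on.
#' @param config the [sim_config()].
#' @param n_iter number of iterations to advance (default 1).
#' @return an updated `sim_state`; the events of the advanced iterations are
#'   attached as attribute `"events"` (a data frame).
#' @export
sim_step <- function(state, net, config, n_iter = 1L) {
  res <- run_core(state, net, config, target = .Machine$integer.max,
                  max_iter = n_iter, log_events = TRUE,
                  track_spread = FALSE, stop_full = FALSE)
  out <- structure(list(copies = res$copies, iteration = res$iteration,
                        htt_count = res$htt_count, founders = state$founders),
                   class = "sim_state")
  dimnames(out$copies) <- dimnames(state$copies)
  attr(out, "events") <- event_log_df(res$event_log)
  out
}

#' Run the TE-flow simulation to the target HTT count
#'
#' Simulates the joint dynamics of all TE families over the network until
#' `config$target_htt_count` successful horizontal transfers accumulated
#' (the stop criterion), or `config$max_iterations` elapsed (result flagged
#' `truncated`), or all copies were lost (`failed`, possible only with
#' `loss_prob > 0` or eviction).
#'
#' @param net an [htt_network()].
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`. Identical seed + config
#'   + network give a bit-identical result including the event log.
#' @param start_species optional founder species (see [init_state()]).
#' @param log_events keep the per-event log (default `TRUE`; disable for
#'   large replicate experiments).
#' @return a `sim_result`: list with `copies`, `iteration`, `htt_count`,
#'   `event_log` (data frame), `n_transpositions`, `n_capacity_rejected`,
#'   `truncated`, `failed`, `config`, `founders`.
#' @examples
#' net <- generate_network("scale_free", 20, mean_degree = 4, seed = 1)
#' res <- run_to_htt_count(net, sim_config(), seed = 1)
#' res$htt_count
#' @export
run_to_htt_count <- function(net, config = sim_config(), seed = config$seed,
                             start_species = NULL, log_events = TRUE) {
  stopifnot(inherits(net, "htt_network"), inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  state <- init_state(config, net, start_species)
  res <- run_core(state, net, config, target = config$target_htt_count,
                  max_iter = config$max_iterations, log_events = log_events,
                  track_spread = FALSE, stop_full = FALSE)
  copies <- res$copies
  dimnames(copies) <- dimnames(state$copies)
  structure(list(copies = copies,
                 iteration = res$iteration,
                 htt_count = res$htt_count,
                 event_log = if (log_events) event_log_df(res$event_log) else NULL,
                 n_transpositions = res$n_transpositions,
                 n_capacity_rejected = res$n_capacity_rejected,
                 truncated = res$truncated,
                 failed = res$extinct,
                 founders = state$founders,
                 config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d iterations, %d successful HTTs, %.0f copies total%s%s\n",
              x$iteration, x$htt_count, sum(x$copies),
              if (isTRUE(x$truncated)) " [truncated]" else "",
              if (isTRUE(x$failed)) " [failed: all copies lost]" else ""))
  invisible(x)
}

#' Propagation of a single TE family from one founder species
#'
#' Places one TE copy in `start_species` and simulates until the family is
#' present in every species or `config$max_iterations` is reached, recording
#' for each x the first iteration at which x species carried at least one
#' copy (the first-passage profile of the invasion).
#'
#' @param net an [htt_network()].
#' @param config a [sim_config()]; `n_families` is forced to 1 and the HTT
#'   stop criterion is ignored (the run is stopped by full contamination or
#'   the iteration cap).
#' @param start_species founder species id.
#' @param seed RNG seed.
#' @return a `trajectory`: list with `first_passage` (integer vector, entry
#'   x = first iteration with x species infected, `NA` if never reached),
#'   `start_species`, `n_infected`, `iterations`, `truncated`.
#' @examples
#' net <- generate_network("complete", 5, seed = 1)
#' tr <- run_single_family(net, sim_config(n_species = 5), start_species = 2, seed = 1)
#' tr$first_passage[1]  # founder is infected at iteration 0
#' @export
run_single_family <- function(net, config = sim_config(), start_species = 1L,
                              seed = config$seed) {
  stopifnot(inherits(net, "htt_network"))
  cfg <- config
  cfg$n_families <- 1L
  if (!is.null(seed)) set.seed(seed)
  state <- init_state(cfg, net, start_species = start_species)
  res <- run_core(state, net, cfg, target = .Machine$integer.max,
                  max_iter = cfg$max_iterations, log_events = FALSE,
                  track_spread = TRUE, stop_full = TRUE)
  fp <- res$first_passage
  names(fp) <- seq_along(fp)
  structure(list(first_passage = fp,
                 start_species = as.integer(start_species),
                 n_infected = sum(!is.na(fp)),
                 iterations = res$iteration,
                 truncated = res$truncated),
            class = "trajectory")
}

#' Replay an event log onto an initial copies matrix
#'
#' Applies the logged transposition / HTT / loss events in order; blocked
#' HTT attempts are ignored. Used to verify that copy counts change only
#' through logged events.
#'
#' @param event_log event-log data frame from a `sim_result`.
#' @param copies_init the initial species x family copies matrix.
#' @return the reconstructed final copies matrix.
#' @export
replay_event_log <- function(event_log, copies_init) {
  copies <- copies_init
  for (i in seq_len(nrow(event_log))) {
    ty <- event_log$type[i]
    f <- event_log$family[i]
    if (ty == "transposition") {
      copies[event_log$source[i], f] <- copies[event_log$source[i], f] +
        event_log$count[i]
    } else if (ty == "htt") {
      copies[event_log$target[i], f] <- copies[event_log$target[i], f] + 1L
    } else if (ty == "loss") {
      copies[event_log$source[i], f] <- copies[event_log$source[i], f] -
        event_log$count[i]
    }
  }
  copies
}
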