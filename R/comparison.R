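#' Mantel correlation between two beta-matrices
#'
#' Pearson (or Spearman) correlation between the upper-triangle entries of
#' two species x species distance matrices, with significance assessed by
#' permuting the species labels of the second matrix. The one-sided
#' (upper-tail) permutation p-value uses the standard +1 correction:
#' `p = (1 + #{r_perm >= r_obs}) / (1 + n_permutations)`. With
#' `exact = TRUE` all `n!` label permutations are enumerated instead and the
#' p-value is the exact permutation tail probability (identity included).
#'
#' @param a,b beta-matrices over the same species in the same order.
#' @param n_permutations number of random permutations (default 999; set to
#'   0 to skip the test and return only r).
#' @param seed RNG seed for the permutations.
#' @param method `"pearson"` (canonical Mantel statistic) or `"spearman"`.
#' @param exact enumerate all permutations (only for small matrices, n <= 8).
#' @return a list with `r`, `p` (`NA` when not computed), `n_permutations`,
#'   and `method`.
#' @examples
#' b1 <- beta_matrix(rbind(c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE)))
#' mantel_test(b1, b1, n_permutations = 99, seed = 1)$r  # 1 when non-constant
#' @export
mantel_test <- function(a, b, n_permutations = 999L, seed = NULL,
                        method = c("pearson", "spearman"), exact = FALSE) {
  method <- match.arg(method)
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)),
            nrow(a) == ncol(a), nrow(a) >= 3)
  n <- nrow(a)
  ut <- upper.tri(a)
  x <- a[ut]
  y <- b[ut]
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance in a distance triangle; Mantel r undefined")
    return(list(r = NA_real_, p = NA_real_, n_permutations = 0L,
                method = method))
  }
  r <- cor(x, y, method = method)
  p <- NA_real_
  if (exact) {
    if (n > 8) stop("exact enumeration is limited to n <= 8 species")
    perms <- all_permutations(n)
    rp <- vapply(perms, function(pi) {
      cor(x, b[pi, pi][ut], method = method)
    }, numeric(1))
    p <- mean(rp >= r - 1e-12)
    n_permutations <- length(perms)
  } else if (n_permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (k in seq_len(n_permutations)) {
      pi <- sample.int(n)
      if (cor(x, b[pi, pi][ut], method = method) >= r - 1e-12)
        hits <- hits + 1L
    }
    p <- (1 + hits) / (1 + n_permutations)
  }
  list(r = r, p = p, n_permutations = as.integer(n_permutations),
       method = method)
}

# All permutations of 1..n as a list (n small).
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (s in sub) {
      k <- k + 1L
      rest <- seq_len(n)[-i]
      out[[k]] <- c(i, rest[s])
    }
  }
  out
}

# Mantel r only (no permutations) -- the statistic used by the experiments.
mantel_r <- function(a, b) {
  ut <- upper.tri(a)
  x <- a[ut]; y <- b[ut]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Edge-shuffle perturbation experiment
#'
#' Measures how specific the simulated beta-matrix is to the network that
#' generated it. For each of `n_networks` reference networks: simulate a
#' reference beta-matrix; then, for every perturbation level (number of
#' degree-preserving edge shuffles) and each of `n_reps` replicates, shuffle
#' the reference network, re-simulate, and record the Mantel correlation
#' between the replicate and reference beta-matrices. Level 0 replicates
#' leave the network unchanged and so measure pure simulation
#' stochasticity: the stability baseline.
#'
#' Seeding is hierarchical (master seed -> per-network -> per-replicate via
#' [derive_seed()]), so the full table is reproducible and adding levels or
#' replicates does not perturb existing ones.
#'
#' @param topology_spec a named list of [generate_network()] arguments, e.g.
#'   `list(topology = "scale_free", n_species = 20, mean_degree = 4)`.
#' @param config a [sim_config()].
#' @param shuffle_levels integer vector of perturbation levels; must include
#'   0 (default `c(0, 1, 2, 5, 10, 20)`).
#' @param n_networks number of reference networks (default 10).
#' @param n_reps replicates per network x level (default 5).
#' @param seed master seed.
#' @return a `shuffle_experiment` object: list with `table` (data frame:
#'   `network`, `level`, `rep`, `r`), `summary` (data frame: `level`,
#'   `mean_r`, `sd_r`, `n`), `n_failed`, and the call parameters.
#' @examples
#' \donttest{
#' ex <- shuffle_experiment(list(topology = "scale_free", n_species = 20,
#'                               mean_degree = 4),
#'                          sim_config(), shuffle_levels = c(0, 10),
#'                          n_networks = 2, n_reps = 2, seed = 1)
#' ex$summary
#' }
#' @export
shuffle_experiment <- function(topology_spec, config = sim_config(),
                               shuffle_levels = c(0L, 1L, 2L, 5L, 10L, 20L),
                               n_networks = 10L, n_reps = 5L, seed = 1L) {
  stopifnot(0 %in% shuffle_levels)
  rows <- vector("list", n_networks * length(shuffle_levels) * n_reps)
  k <- 0L
  for (i in seq_len(n_networks)) {
    net <- do.call(generate_network,
                   c(topology_spec, list(seed = derive_seed(seed, i, 0))))
    ref <- run_to_htt_count(net, config, seed = derive_seed(seed, i, 1),
                            log_events = FALSE)
    beta_ref <- beta_matrix(presence_matrix(ref))
    for (li in seq_along(shuffle_levels)) {
      level <- shuffle_levels[li]
      for (j in seq_len(n_reps)) {
        net_j <- if (level == 0) net
                 else shuffle_edges(net, level,
                                    seed = derive_seed(seed, i, 2, li, j))
        res <- run_to_htt_count(net_j, config,
                                seed = derive_seed(seed, i, 3, li, j),
                                log_events = FALSE)
        r <- if (res$failed) NA_real_
             else mantel_r(beta_ref, beta_matrix(presence_matrix(res)))
        k <- k + 1L
        rows[[k]] <- data.frame(network = i, level = level, rep = j, r = r)
      }
    }
  }
  table <- do.call(rbind, rows)
  ok <- !is.na(table$r)
  summary <- do.call(rbind, lapply(sort(unique(table$level)), function(l) {
    ri <- table$r[ok & table$level == l]
    data.frame(level = l, mean_r = mean(ri), sd_r = sd(ri), n = length(ri))
  }))
  structure(list(table = table, summary = summary,
                 n_failed = sum(!ok),
                 shuffle_levels = shuffle_levels, n_networks = n_networks,
                 n_reps = n_reps, seed = seed, config = config,
                 topology_spec = topology_spec),
            class = "shuffle_experiment")
}

#' @export
print.shuffle_experiment <- function(x, ...) {
  cat(sprintf("<shuffle_experiment> %d networks x %d reps, levels {%s}%s\n",
              x$n_networks, x$n_reps,
              paste(x$shuffle_levels, collapse = ", "),
              if (x$n_failed > 0) sprintf(" (%d failed runs excluded)", x$n_failed)
              else ""))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Plot an edge-shuffle experiment (mean Mantel r +/- SD per level)
#' @param x a `shuffle_experiment`.
#' @param ... further arguments passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.shuffle_experiment <- function(x, ...) {
  s <- x$summary
  plot(s$level, s$mean_r, type = "b", pch = 19,
       ylim = range(c(s$mean_r - s$sd_r, s$mean_r + s$sd_r)),
       xlab = "number of edge shuffles", ylab = "Mantel correlation r", ...)
  arrows(s$level, s$mean_r - s$sd_r, s$level, s$mean_r + s$sd_r,
         angle = 90, code = 3, length = 0.04)
  invisible(x)
}

#' Sensitivity of the shuffle experiment to the HTT stop criterion
#'
#' Repeats [shuffle_experiment()] for several values of the target number of
#' successful HTTs, keeping everything else (including the seed hierarchy)
#' identical, to quantify how the beta-matrix signal strengthens with the
#' number of transfers accumulated in the network.
#'
#' @param topology_spec,config,shuffle_levels,n_networks,n_reps,seed as in
#'   [shuffle_experiment()].
#' @param htt_targets integer vector of `target_htt_count` values
#'   (default `c(50, 100, 150)`).
#' @return a named list of `shuffle_experiment` objects, one per target,
#'   with a combined summary data frame in attribute `"summary"`.
#' @export
htt_count_sensitivity <- function(topology_spec, config = sim_config(),
                                  htt_targets = c(50L, 100L, 150L),
                                  shuffle_levels = c(0L, 1L, 2L, 5L, 10L, 20L),
                                  n_networks = 10L, n_reps = 5L, seed = 1L) {
  out <- lapply(htt_targets, function(t) {
    cfg <- config
    cfg$target_htt_count <- as.integer(t)
    shuffle_experiment(topology_spec, cfg, shuffle_levels = shuffle_levels,
                       n_networks = n_networks, n_reps = n_reps, seed = seed)
  })
  names(out) <- as.character(htt_targets)
  combined <- do.call(rbind, lapply(seq_along(out), function(i) {
    cbind(target_htt_count = htt_targets[i], out[[i]]$summary)
  }))
  attr(out, "summary") <- combined
  out
}

#' Single-family propagation experiment
#'
#' Characterizes the speed and reach of the invasion of one TE family in
#' each of several networks: from every species in turn, `n_reps_per_start`
#' independent single-copy invasions are simulated (so `n_species *
#' n_reps_per_start` trajectories per network, 400 at the defaults), and the
#' first-passage times to x infected species are aggregated.
#'
#' @param networks a named list of [htt_network()] objects sharing the same
#'   species count.
#' @param config a [sim_config()]; `max_iterations` bounds each trajectory
#'   (truncated trajectories still count in the reach denominators).
#' @param n_reps_per_start replicates per founder species (default 20).
#' @param seed master seed (hierarchical per network / start / replicate).
#' @return a `propagation_experiment` object: named list, one element per
#'   network, each with `summary` (data frame per x: quartiles `q1`,
#'   `median`, `q3` of iterations-to-x over trajectories that reached x, and
#'   `prop_reaching`) and `first_passage` (trajectories x species matrix).
#' @export
propagation_experiment <- function(networks, config = sim_config(),
                                   n_reps_per_start = 20L, seed = 1L) {
  stopifnot(is.list(networks), length(networks) >= 1)
  ns <- vapply(networks, n_species, integer(1))
  if (length(unique(ns)) != 1) stop("all networks must share n_species")
  S <- ns[1]
  if (is.null(names(networks)))
    names(networks) <- paste0("network", seq_along(networks))
  out <- lapply(seq_along(networks), function(k) {
    net <- networks[[k]]
    fp <- matrix(NA_integer_, S * n_reps_per_start, S)
    row <- 0L
    for (start in seq_len(S)) {
      for (j in seq_len(n_reps_per_start)) {
        tr <- run_single_family(net, config, start_species = start,
                                seed = derive_seed(seed, k, start, j))
        row <- row + 1L
        fp[row, ] <- tr$first_passage
      }
    }
    summary <- do.call(rbind, lapply(seq_len(S), function(x) {
      t_x <- fp[, x]
      reached <- !is.na(t_x)
      q <- if (any(reached)) quantile(t_x[reached], c(0.25, 0.5, 0.75))
           else rep(NA_real_, 3)
      data.frame(x = x, q1 = q[[1]], median = q[[2]], q3 = q[[3]],
                 prop_reaching = mean(reached), n_reaching = sum(reached))
    }))
    list(summary = summary, first_passage = fp)
  })
  names(out) <- names(networks)
  structure(out, class = "propagation_experiment",
            n_reps_per_start = n_reps_per_start, seed = seed)
}

#' @export
print.propagation_experiment <- function(x, ...) {
  cat(sprintf("<propagation_experiment> %d network(s), %d trajectories each\n",
              length(x), nrow(x[[1]]$first_passage)))
  for (nm in names(x)) {
    s <- x[[nm]]$summary
    full <- s[nrow(s), ]
    cat(sprintf("  %s: %.0f%% of trajectories infected all %d species (median %.0f iter to x=%d)\n",
                nm, 100 * full$prop_reaching, nrow(s),
                s$median[ceiling(nrow(s) / 2)], ceiling(nrow(s) / 2)))
  }
  invisible(x)
}
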