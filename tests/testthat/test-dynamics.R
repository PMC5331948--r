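test_that("init_state seeds one founding copy per family", {
  net <- generate_network("random", 20, mean_degree = 4, seed = 1)
  cfg <- sim_config()
  set.seed(1)
  st <- init_state(cfg, net)
  expect_equal(sum(st$copies), 30)
  expect_equal(sum(st$copies == 1), 30)
  expect_equal(st$iteration, 0L)
  expect_equal(st$htt_count, 0L)
  set.seed(1)
  st2 <- init_state(cfg, net)
  expect_identical(st$copies, st2$copies)
  # fixed founder
  st3 <- init_state(sim_config(n_families = 1), net, start_species = 5)
  expect_equal(st3$copies[5, 1], 1L)
  expect_equal(sum(st3$copies), 1)
  expect_error(init_state(sim_config(n_species = 10), net), "match")
})

test_that("zero rates leave the state unchanged apart from the clock", {
  net <- two_node_net()
  cfg <- sim_config(n_species = 2, n_families = 3, u_transposition = 1e-12)
  set.seed(1)
  st <- init_state(cfg, net)
  st2 <- sim_step(st, net, cfg)
  expect_identical(st2$copies, st$copies)
  expect_equal(st2$iteration, 1L)
})

test_that("an isolated species can never export or import copies", {
  net <- net_from_edges(rbind(c(1, 2)), n = 3) # species 3 isolated
  cfg <- sim_config(n_species = 3, n_families = 1, u_transposition = 0.5,
                    htt_ratio = 1, target_htt_count = 1000,
                    max_iterations = 200)
  res <- run_to_htt_count(net, cfg, start_species = 3, seed = 2)
  expect_equal(res$htt_count, 0L)
  expect_true(res$truncated)
  expect_equal(sum(res$copies[1:2, ]), 0)
})

test_that("a genome at capacity gains no intragenomic copies", {
  net <- two_node_net(capacity = 5L)
  cfg <- sim_config(n_species = 2, n_families = 1, capacity = 5L,
                    u_transposition = 1, htt_ratio = 1e9,
                    target_htt_count = 1, max_iterations = 30)
  res <- run_to_htt_count(net, cfg, start_species = 1, seed = 3)
  expect_lte(max(rowSums(res$copies)), 5)
  tr <- res$event_log[res$event_log$type == "transposition", ]
  expect_equal(sum(tr$count), sum(res$copies) - 1)
})

test_that("mean intragenomic growth of one unsaturated copy is u", {
  net <- two_node_net()
  u <- 0.3
  cfg <- sim_config(n_species = 2, n_families = 1, capacity = 10000L,
                    u_transposition = u, htt_ratio = 1e9)
  set.seed(4)
  st <- init_state(cfg, net, start_species = 1)
  gains <- replicate(2000, {
    s2 <- sim_step(st, net, cfg)
    sum(s2$copies) - 1
  })
  expect_lt(abs(mean(gains) - u), 3 * sqrt(u * (1 - u) / 2000))
})

test_that("the run stops exactly at the HTT stop criterion", {
  net <- generate_network("scale_free", 20, mean_degree = 4, seed = 1)
  res <- run_to_htt_count(net, sim_config(), seed = 1)
  expect_equal(res$htt_count, 150L)
  expect_false(res$truncated)
  expect_equal(sum(res$event_log$type == "htt"), 150)
  # target 1 on a 2-node network
  net2 <- two_node_net()
  cfg2 <- sim_config(n_species = 2, n_families = 2, target_htt_count = 1)
  res2 <- run_to_htt_count(net2, cfg2, seed = 5)
  expect_equal(sum(res2$event_log$type == "htt"), 1)
})

test_that("identical seeds give bit-identical runs", {
  net <- generate_network("modular", 12, n_modules = 3, mean_degree = 4,
                          seed = 2)
  cfg <- sim_config(n_species = 12, n_families = 8, target_htt_count = 40)
  a <- run_to_htt_count(net, cfg, seed = 99)
  b <- run_to_htt_count(net, cfg, seed = 99)
  expect_identical(a$copies, b$copies)
  expect_identical(a$event_log, b$event_log)
})

test_that("replaying the event log reproduces the final copies exactly", {
  net <- generate_network("random", 10, mean_degree = 3, seed = 3)
  cfg <- sim_config(n_species = 10, n_families = 5, capacity = 40L,
                    target_htt_count = 60, loss_prob = 0.002)
  res <- run_to_htt_count(net, cfg, seed = 7)
  set.seed(7)
  st <- init_state(cfg, net)
  expect_identical(replay_event_log(res$event_log, st$copies), res$copies)
})

test_that("per-species totals never exceed capacity", {
  net <- generate_network("random", 8, mean_degree = 3, seed = 4, capacity = 25L)
  cfg <- sim_config(n_species = 8, n_families = 6, capacity = 25L,
                    u_transposition = 0.2, target_htt_count = 200,
                    max_iterations = 400)
  res <- run_to_htt_count(net, cfg, seed = 8)
  expect_lte(max(rowSums(res$copies)), 25)
  # family mode caps each species-family count instead
  cfgf <- sim_config(n_species = 8, n_families = 6, capacity = 4L,
                     capacity_mode = "family", u_transposition = 0.2,
                     target_htt_count = 200, max_iterations = 400)
  resf <- run_to_htt_count(net, cfgf, seed = 8)
  expect_lte(max(resf$copies), 4)
})

test_that("presence is monotone when capacity never binds and loss is 0", {
  net <- generate_network("random", 6, mean_degree = 3, seed = 5)
  cfg <- sim_config(n_species = 6, n_families = 4, capacity = 100000L,
                    u_transposition = 0.05, htt_ratio = 10,
                    target_htt_count = 1e6, max_iterations = 1)
  set.seed(11)
  st <- init_state(cfg, net)
  present <- st$copies > 0
  for (i in 1:150) {
    st <- sim_step(st, net, cfg)
    now <- st$copies > 0
    expect_true(all(now[present]))
    present <- now
  }
})

test_that("strict rejection blocks transfers into full genomes", {
  net <- two_node_net(capacity = 1L)
  cfg <- sim_config(n_species = 2, n_families = 2, capacity = 1L,
                    u_transposition = 0.9, htt_ratio = 1,
                    at_capacity = "reject", target_htt_count = 5,
                    max_iterations = 50)
  set.seed(6)
  st <- init_state(cfg, net, start_species = c(1, 2)) # both genomes full
  out <- sim_step(st, net, cfg, n_iter = 50)
  expect_equal(out$htt_count, 0L)
  expect_identical(out$copies, st$copies)
  blocked <- attr(out, "events")
  expect_true(all(blocked$type == "htt_blocked"))
  expect_gt(nrow(blocked), 0)
})

test_that("replacement keeps full genomes at capacity but transfers succeed", {
  net <- two_node_net(capacity = 1L)
  cfg <- sim_config(n_species = 2, n_families = 2, capacity = 1L,
                    u_transposition = 0.9, htt_ratio = 1,
                    at_capacity = "replace", target_htt_count = 5,
                    max_iterations = 500)
  res <- run_to_htt_count(net, cfg, start_species = c(1, 2), seed = 6)
  expect_equal(res$htt_count, 5L)
  expect_true(all(rowSums(res$copies) == 1))
})

test_that("extinction with loss is flagged as a failed run", {
  net <- two_node_net()
  cfg <- sim_config(n_species = 2, n_families = 1, u_transposition = 1e-6,
                    loss_prob = 0.9, target_htt_count = 10,
                    max_iterations = 1000)
  res <- run_to_htt_count(net, cfg, seed = 9)
  expect_true(res$failed)
  expect_equal(sum(res$copies), 0)
})

test_that("single-family trajectories record first-passage times", {
  net <- net_from_edges(rbind(c(1, 2)), n = 3)
  cfg <- sim_config(n_species = 3, n_families = 1, max_iterations = 300)
  tr <- run_single_family(net, cfg, start_species = 3, seed = 10)
  expect_equal(unname(tr$first_passage[1]), 0)
  expect_true(all(is.na(tr$first_passage[2:3]))) # start isolated from 1-2
  expect_true(tr$truncated)

  # 2-node net with capacity 1: first passage to 2 species is geometric
  # with success probability u/rho per iteration (no copy growth possible)
  net2 <- two_node_net(capacity = 1L)
  cfg2 <- sim_config(n_species = 2, n_families = 1, capacity = 1L,
                     u_transposition = 0.5, htt_ratio = 5,
                     max_iterations = 1000)
  set.seed(12)
  times <- sapply(1:800, function(i)
    run_single_family(net2, cfg2, start_species = 1,
                      seed = derive_seed(12, i))$first_passage[2])
  expect_false(any(is.na(times)))
  p <- 0.5 / 5
  expect_lt(abs(mean(times) - 1 / p), 3 * (1 / p) / sqrt(800))
})

test_that("infected-species counts are non-decreasing without loss", {
  net <- generate_network("random", 10, mean_degree = 3, seed = 6)
  cfg <- sim_config(n_species = 10, n_families = 1, max_iterations = 2000)
  tr <- run_single_family(net, cfg, start_species = 1, seed = 13)
  fp <- tr$first_passage[!is.na(tr$first_passage)]
  expect_true(all(diff(fp) >= 0))
})
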