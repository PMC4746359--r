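test_that("default build yields the 704-unit architecture with disjoint contiguous id ranges", {
  net <- build_network(network_config(), seed = 1)
  expect_equal(sum(net$pops$size), 704)
  expect_equal(net$n_neuron, 512)
  expect_equal(net$n_p, 192)
  sz <- setNames(net$pops$size, net$pops$label)
  expect_equal(sz[c("P", "ES", "IS", "ILS", "EM", "IM", "ILM")],
               c(P = 192, ES = 192, IS = 44, ILS = 20, EM = 192, IM = 44,
                 ILM = 20))
  ids <- unlist(lapply(net$pops$label, population_ids, net = net))
  expect_equal(sort(ids), 1:704)
  expect_false(anyDuplicated(ids) > 0)
  # every synapse endpoint is a valid id; no autapses by default
  expect_true(all(net$syn$pre %in% 1:704))
  expect_true(all(net$syn$post %in% 1:512))
  expect_false(any(net$syn$pre == net$syn$post))
})

test_that("degenerate configs build correctly and bad probabilities are rejected", {
  cfg <- network_config()
  cfg$sizes[] <- 0L
  cfg$sizes["ES"] <- 1L
  cfg$conn$p <- 0
  net <- build_network(cfg, seed = 1)
  expect_equal(sum(net$pops$size), 1)
  expect_equal(nrow(net$syn), 0)

  bad <- network_config()
  bad$conn$p[3] <- 1.2
  expect_error(build_network(bad, seed = 1), "configuration error")
})

test_that("connectivity draw matches a replayed-RNG oracle and is deterministic", {
  cfg <- tiny_config()
  net <- build_network(cfg, seed = 42)
  net2 <- build_network(cfg, seed = 42)
  expect_identical(net$syn, net2$syn)

  # replay the seeded draws rule by rule, exactly as documented
  ids <- lapply(setNames(net$pops$label, net$pops$label),
                population_ids, net = net)
  counts <- with_seed(derive_seed(42, "construct"), {
    out <- integer(nrow(cfg$conn))
    for (k in seq_len(nrow(cfg$conn))) {
      rule <- cfg$conn[k, ]
      src <- ids[[rule$src]]
      dst <- ids[[rule$dst]]
      pre <- rep(src, times = length(dst))
      post <- rep(dst, each = length(src))
      keep <- runif(length(pre)) < rule$p
      keep <- keep & (pre != post)
      out[k] <- sum(keep)
      if (rule$init == "uniform") runif(sum(keep))
      runif(sum(keep), rule$delay_min, rule$delay_max)
    }
    out
  })
  expect_equal(nrow(net$syn), sum(counts))
})

test_that("simulation is deterministic, inert without drive, and Poisson generators hit their rate", {
  cfg <- tiny_config(bg_rate = 0)
  net <- build_network(cfg, seed = 1)
  sp <- simulate_network(net, 200, seed = 5)
  expect_equal(sum(lengths(sp$trains)), 0)

  # one ES cell driven by a 250 Hz generator for 200 ms: the generator
  # count is within 3 sigma of 250 * 0.2 = 50 and the cell fires
  pat <- stim_pattern(cells = 1, onset = 0, duration = 200, rate = 250)
  net2 <- attach_stimulators(net, pat)
  counts <- sapply(1:20, function(s) {
    sp2 <- simulate_network(net2, 200, seed = s)
    c(gen = nrow(sp2$stim_spikes), cell = length(sp2$trains[[1]]))
  })
  expect_true(all(abs(counts["gen", ] - 50) <= 3 * sqrt(50)))
  expect_true(mean(counts["cell", ]) > 0)

  sp_a <- simulate_network(net2, 200, seed = 7)
  sp_b <- simulate_network(net2, 200, seed = 7)
  expect_identical(sp_a$trains, sp_b$trains)
})

test_that("a two-cell chain respects the synaptic delay", {
  cfg <- tiny_config(bg_rate = 0)
  cfg$sizes[] <- 0L
  cfg$sizes["ES"] <- 2L
  cfg$conn <- cfg$conn[0, ]
  net <- build_network(cfg, seed = 1)
  d_ms <- 4
  net$syn <- data.frame(pre = 1L, post = 2L, receptor = "AMPA",
                        weight = 60, delay_ms = d_ms, trainable = FALSE)
  pat <- stim_pattern(1, onset = 0, duration = 300, rate = 200)
  net <- attach_stimulators(net, pat)
  sp <- simulate_network(net, 300, seed = 3)
  t1 <- sp$trains[[1]]
  t2 <- sp$trains[[2]]
  expect_gt(length(t1), 0)
  expect_gt(length(t2), 0)
  for (t in t2) {
    expect_true(any(t1 <= t - d_ms))  # caused by an earlier pre spike
  }
  expect_gte(min(t2) - min(t1), d_ms)
})

test_that("cell lesions silence the right count and silenced cells never spike", {
  net <- build_network(network_config(), seed = 1)
  expect_identical(apply_cell_lesion(net, 0, 1), net)
  les <- apply_cell_lesion(net, 0.10, seed = 9)
  expect_equal(length(les$silenced), 19)  # round(0.10 * 192)
  expect_true(all(les$silenced %in% population_ids(net, "ES")))
  les2 <- apply_cell_lesion(net, 0.10, seed = 9)
  expect_identical(les$silenced, les2$silenced)
  expect_error(apply_cell_lesion(net, 1.5), "input error")

  mini <- apply_cell_lesion(build_network(tiny_config(), seed = 1),
                            0.10, seed = 2)
  sp <- simulate_network(mini, 300, seed = 4)
  expect_equal(sum(lengths(sp$trains[mini$silenced])), 0)
})

test_that("synapse lesions remove the right count reproducibly", {
  net <- build_network(network_config(), seed = 1)
  n0 <- nrow(net$syn)
  expect_identical(apply_synapse_lesion(net, 0, 1)$syn, net$syn)
  expect_equal(nrow(apply_synapse_lesion(net, 1, 1)$syn), 0)
  les <- apply_synapse_lesion(net, 0.05, seed = 3)
  expect_equal(nrow(les$syn), n0 - round(0.05 * n0))
  les2 <- apply_synapse_lesion(net, 0.05, seed = 3)
  expect_identical(les$syn, les2$syn)
  expect_false(any(duplicated(les$syn)))
  expect_error(apply_synapse_lesion(net, -0.1), "input error")
})

test_that("stimulators follow the 10x-background-weight rule and validate targets", {
  net <- build_network(tiny_config(), seed = 1)
  pat <- stim_pattern(170 %% length(population_ids(net, "ES")) + 1,
                      100, 200, 250)
  net2 <- attach_stimulators(net, pat)
  expect_equal(net2$stim[[1]]$weight, 10 * net$config$background$weight)
  expect_identical(attach_stimulators(net, stim_pattern(integer(0),
                                                        numeric(0),
                                                        numeric(0),
                                                        numeric(0))),
                   net)
  expect_error(stim_pattern(1, 100, 200, -5), "input error")
  em <- population_ids(net, "EM")[1]
  expect_error(attach_stimulators(net, stim_pattern(em, 0, 100, 100)),
               "input error")
  les <- apply_cell_lesion(net, 0.5, seed = 1)
  expect_warning(attach_stimulators(les, stim_pattern(les$silenced[1],
                                                      0, 100, 100)),
                 "silenced")
  # rate-0 entry produces no generator spikes
  sp <- simulate_network(attach_stimulators(
    net, stim_pattern(1, 0, 100, 0)), 100, seed = 1)
  expect_equal(nrow(sp$stim_spikes), 0)
})

test_that("stimulation does not perturb pre-onset activity and raises target spiking", {
  net <- build_network(tiny_config(), seed = 1)
  les <- apply_cell_lesion(net, 0.1, seed = 2)
  cell <- setdiff(population_ids(net, "ES"), les$silenced)[1]
  pat <- stim_pattern(cell, onset = 100, duration = 150, rate = 250)
  stim_net <- attach_stimulators(les, pat)
  base <- c()
  stimmed <- c()
  for (s in 1:20) {
    a <- simulate_network(les, 250, seed = s)
    b <- simulate_network(stim_net, 250, seed = s)
    pre <- function(sp) lapply(sp$trains, function(tt) tt[tt <= 100])
    if (s <= 3) expect_identical(pre(a), pre(b))
    win <- function(sp) sum(sp$trains[[cell]] > 100 & sp$trains[[cell]] <= 250)
    base <- c(base, win(a))
    stimmed <- c(stimmed, win(b))
  }
  expect_gte(mean(stimmed), mean(base))
  expect_gt(mean(stimmed), mean(base))  # 10x background weight is strong
})

test_that("network and spike serialization round-trips", {
  net <- build_network(tiny_config(), seed = 3)
  net <- apply_cell_lesion(net, 0.1, seed = 1)
  pre <- file.path(tempdir(), "net_rt")
  write_network(net, pre)
  back <- read_network(pre)
  expect_equal(back$pops, net$pops)
  expect_equal(back$silenced, net$silenced)
  expect_equal(back$syn$weight, net$syn$weight, tolerance = 1e-12)
  sp <- simulate_network(net, 150, seed = 2)
  sp2 <- simulate_network(back, 150, seed = 2)
  expect_identical(lengths(sp$trains), lengths(sp2$trains))

  pre2 <- file.path(tempdir(), "spk_rt")
  write_spikes(sp, pre2)
  rd <- read_spikes(pre2)
  expect_equal(rd$duration, sp$duration)
  expect_equal(unname(lengths(rd$trains)), unname(lengths(sp$trains)))
  expect_equal(unlist(rd$trains), unlist(sp$trains), tolerance = 1e-9,
               ignore_attr = TRUE)
})
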