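# shared miniature lesioned setup for probing tests (built once)
probe_env <- new.env()
get_probe_setup <- function() {
  if (is.null(probe_env$setup)) {
    net <- build_network(tiny_config(), seed = 1)
    arm <- arm_params()
    tg <- reach_target("bottom", arm)
    les <- apply_cell_lesion(net, 0.10, seed = 2)
    probe_env$setup <- list(net = net, arm = arm, tg = tg, les = les)
  }
  probe_env$setup
}

test_that("single-cell probing follows the 250 Hz / 200 ms / 100 ms protocol", {
  s <- get_probe_setup()
  n_es <- length(population_ids(s$les, "ES"))
  n_sil <- length(s$les$silenced)
  probes <- generate_single_cell_probes(s$les, s$arm, s$tg, seed = 4)
  expect_equal(length(probes), n_es - n_sil)  # one per surviving cell
  for (pr in probes[c(1, length(probes))]) {
    e <- pr$pattern$entries
    expect_equal(nrow(e), 1)
    expect_equal(e$onset, 100)
    expect_equal(e$duration, 200)
    expect_equal(e$rate, 250)
    expect_false(e$cell %in% s$les$silenced)
  }
  expect_false(any(vapply(probes, function(p) p$cells, integer(1)) %in%
                     s$les$silenced))
})

test_that("multi-cell probes draw 1-10 cells and 100-500 ms durations reproducibly", {
  s <- get_probe_setup()
  pr1 <- generate_multicell_probes(s$les, s$arm, s$tg, n_probes = 12,
                                   seed = 9)
  pr2 <- generate_multicell_probes(s$les, s$arm, s$tg, n_probes = 12,
                                   seed = 9)
  for (i in seq_along(pr1)) {
    e <- pr1[[i]]$pattern$entries
    expect_gte(nrow(e), 1)
    expect_lte(nrow(e), 10)
    expect_true(all(e$duration >= 100))
    expect_true(all(e$duration <= 500))
    expect_true(all(e$onset + e$duration <= s$tg$duration))
    expect_false(any(e$cell %in% s$les$silenced))
    expect_identical(pr1[[i]]$pattern, pr2[[i]]$pattern)
    expect_identical(pr1[[i]]$trial$spikes$trains,
                     pr2[[i]]$trial$spikes$trains)
  }
})

test_that("the delay embedding follows the reach-duration subtraction", {
  arm <- arm_params()
  expect_equal(embedding_config(reach_target("left", arm))$D, 300)
  expect_equal(embedding_config(reach_target("bottom", arm))$D, 200)
})

test_that("training pairs window the response without altering spikes", {
  s <- get_probe_setup()
  probes <- generate_single_cell_probes(s$les, s$arm, s$tg,
                                        seed = 4)[1:3]
  emb <- embedding_config(s$tg, step = 1)
  pairs <- make_training_pairs(probes, emb, s$les)
  # 200 pairs per probe at 1 ms steps over [100, 300)
  expect_equal(length(pairs$inputs), 3 * 200)
  expect_equal(range(pairs$times), c(100, 299))

  em <- population_ids(s$les, "EM")
  es <- population_ids(s$les, "ES")
  # window at t contains exactly the EM spikes of [t - h(t), t + D],
  # relativized; h(100) = 100 so the first input spans [0, 100 + D]
  w0 <- pairs$inputs[[1]]
  expect_equal(w0$len, 2 * emb$D)
  tr <- subset_spikes(probes[[1]]$trial$spikes, em)
  for (u in c(1, length(em))) {
    want <- tr[[u]][tr[[u]] >= 0 & tr[[u]] <= 100 + emb$D] - (100 - emb$D)
    expect_equal(w0$spikes[[u]], want)
  }
  # no spikes later than t + D ever enter the window at step t
  k <- which(pairs$times == 250)[1]
  expect_true(all(unlist(pairs$inputs[[k]]$spikes) <= 2 * emb$D))

  # single-cell probe targets have one nonzero entry, at the probed cell
  for (k in seq(1, 600, by = 97)) {
    tgt <- pairs$targets[k, ]
    t <- pairs$times[k]
    cell <- probes[[pairs$probe[k]]]$cells
    if (t >= 100 && t < 300) {
      expect_equal(which(tgt > 0), match(cell, es))
      expect_equal(max(tgt), 250)
    }
    expect_lte(sum(tgt > 0), 1)
  }
})

test_that("the default spike-kernel parameter is 0.05 and empty pairs error", {
  expect_equal(formals(train_inverse_model)$a_lambda, 0.05)
  expect_equal(formals(kaf_model)$a_lambda, 0.05)
  emb <- embedding_config(reach_target("left", arm_params()))
  expect_error(train_inverse_model(list(inputs = list()), emb),
               "input error")
})

test_that("the inverse model recovers probe rates on a toy memoryless plant", {
  set.seed(77)
  m <- 6    # stimulation channels
  N <- 8    # response units
  G <- matrix(runif(N * m, 5, 15), N, m)
  G[cbind(seq_len(N), rep_len(seq_len(m), N))] <- 60  # distinct signatures
  dur <- 500
  toy_target <- list(label = "toy", duration = dur)
  emb <- embedding_config(toy_target, step = 5)

  gen_response <- function(ch) {
    # memoryless plant: unit n fires Poisson at 3 Hz + G[n, ch] during
    # the stimulation window [100, 300)
    lapply(seq_len(N), function(n) {
      base <- runif(rpois(1, 3 * dur / 1000), 0, dur)
      drive <- runif(rpois(1, G[n, ch] * 0.2), 100, 300)
      sort(c(base, drive))
    })
  }
  probes <- unlist(lapply(seq_len(m), function(ch) {
    lapply(1:3, function(r) list(ch = ch, trains = gen_response(ch)))
  }), recursive = FALSE)
  steps <- seq(emb$stim_start, emb$stim_end - 1, by = emb$step)
  inputs <- list()
  targets <- NULL
  for (pr in probes) {
    tr <- as_trains(pr$trains, dur)
    for (t in steps) {
      inputs[[length(inputs) + 1]] <-
        spike_window(tr, t - emb$D, t + emb$D)
      targets <- rbind(targets, 250 * (seq_len(m) == pr$ch))
    }
  }
  pairs <- list(inputs = inputs, targets = targets)
  inv_cv <- train_inverse_model(pairs, emb, seed = 5,
                                a_lambda = c(0.05, 2, 20), cv_folds = 3,
                                eta = 0.5, eps = 0, cap = 300)
  # held-out responses: fresh noise realizations per channel
  errs <- vapply(seq_len(m), function(ch) {
    tr <- as_trains(gen_response(ch), dur)
    pat <- derive_stimulation(inv_cv, tr, seq_len(m), threshold = 0,
                              step = 20)
    pred <- rowMeans(pat$rates)
    truth <- 250 * (seq_len(m) == ch)
    sqrt(mean((pred - truth)^2)) / 250
  }, numeric(1))
  expect_lt(mean(errs), 0.2)
  # support and sign constraints of the derived pattern
  tr <- as_trains(gen_response(2), dur)
  pat <- derive_stimulation(inv_cv, tr, seq_len(m), threshold = 10)
  expect_true(all(pat$rates >= 0))
  expect_equal(pat$t_start, 100)
  expect_equal(ncol(pat$rates), 200)
})
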