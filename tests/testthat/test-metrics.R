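test_that("SPIKE-distance and SPIKE-sync match brute-force oracles on 100 random pairs", {
  set.seed(31)
  for (i in 1:100) {
    Tdur <- 100
    x <- random_train(10, Tdur)
    y <- random_train(10, Tdur)
    a <- as_trains(list(x), Tdur)
    b <- as_trains(list(y), Tdur)
    d <- spike_distance(a, b)
    s <- spike_sync(a, b)
    expect_equal(d, oracle_spike_dist(x, y, Tdur), tolerance = 1e-9)
    expect_equal(s, oracle_spike_sync(x, y, Tdur), tolerance = 1e-9)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_gte(s, 0); expect_lte(s, 1)
    # symmetry
    expect_equal(d, spike_distance(b, a), tolerance = 1e-12)
    expect_equal(s, spike_sync(b, a), tolerance = 1e-12)
  }
})

test_that("identical inputs give distance 0 and sync 1; disjoint spikes give sync 0", {
  set.seed(32)
  tr <- lapply(1:5, function(i) sort(runif(6, 0, 200)))
  a <- as_trains(tr, 200)
  expect_equal(spike_distance(a, a), 0)
  expect_equal(spike_sync(a, a), 1)
  far_a <- as_trains(list(c(10, 12, 14)), 200)
  far_b <- as_trains(list(c(150, 152, 154)), 200)
  expect_equal(spike_sync(far_a, far_b), 0)
  expect_error(spike_distance(a, as_trains(tr[1:3], 200)), "unit sets")
})

test_that("both Kreuz metrics are invariant to a common time shift of the window", {
  set.seed(33)
  x <- sort(runif(8, 20, 80))
  y <- sort(runif(8, 20, 80))
  d0 <- spike_distance(as_trains(list(x), 100), as_trains(list(y), 100))
  s0 <- spike_sync(as_trains(list(x), 100), as_trains(list(y), 100))
  # shifting spikes and observation window together is the identity once
  # times are expressed relative to the window start (spike_window does
  # exactly this relativization), so the metrics cannot change
  shift <- 35
  wx <- spike_window(list(x + shift), shift, 100 + shift)$spikes[[1]]
  wy <- spike_window(list(y + shift), shift, 100 + shift)$spikes[[1]]
  expect_equal(spike_distance(as_trains(list(wx), 100),
                              as_trains(list(wy), 100)), d0,
               tolerance = 1e-12)
  expect_equal(spike_sync(as_trains(list(wx), 100),
                          as_trains(list(wy), 100)), s0,
               tolerance = 1e-12)
  # SPIKE-sync additionally tolerates shifting the spikes alone, since
  # its adaptive windows depend only on inter-spike intervals
  expect_equal(spike_sync(as_trains(list(x - 15), 100),
                          as_trains(list(y - 15), 100)), s0,
               tolerance = 1e-12)
})

test_that("PETH bins, conservation and correlation offsets behave as specified", {
  set.seed(34)
  tr <- lapply(1:4, function(i) sort(runif(40, 0, 600)))
  a <- as_trains(tr, 600)
  p <- peth(a, bin = 20, offset = 0)
  expect_equal(length(p$counts), 30)            # 600 / 20
  expect_equal(sum(p$counts), sum(lengths(tr))) # conservation
  expect_equal(sum(peth(a, 20, 7)$counts),
               sum(vapply(tr, function(t) sum(t >= 7), numeric(1))))
  z <- peth(as_trains(list(numeric(0)), 600), 20)
  expect_true(all(z$counts == 0))

  # correlation: exactly N-1 = 19 offsets averaged; equals direct oracle
  b <- as_trains(lapply(tr, function(t) sort(c(t[-1], runif(5, 0, 600)))),
                 600)
  r <- peth_correlation(a, b, bin = 20)
  oracle <- mean(vapply(0:18, function(k) {
    cor(peth(a, 20, k)$counts, peth(b, 20, k)$counts)
  }, numeric(1)))
  expect_equal(r, oracle, tolerance = 1e-12)
  expect_equal(peth_correlation(a, a, 20), 1, tolerance = 1e-12)
  expect_warning(
    peth_correlation(as_trains(list(numeric(0)), 600), a, 20),
    "zero-variance")
})

test_that("behavioral metrics follow the geometry", {
  tg <- c(10, 0)
  traj <- data.frame(t = 0:100, x = seq(0, 10, length.out = 101),
                     y = rep(0, 101))
  ref <- data.frame(t = 0:100, x = seq(0, 10, length.out = 101),
                    y = rep(2, 101))
  m <- behavioral_metrics(traj, traj, tg)
  expect_equal(unname(m), c(0, 0))
  m2 <- behavioral_metrics(traj, ref, tg)
  expect_equal(m2[["mean_pointwise"]], 2)      # parallel lines 2 cm apart
  expect_equal(m2[["final_distance"]], 0)
  expect_warning(
    behavioral_metrics(traj, ref[1:51, ], tg), "restricted")
})

test_that("bin-size sweep reduces to its trivial cases and matches recomputation", {
  set.seed(35)
  tr <- lapply(1:4, function(i) sort(runif(30, 0, 500)))
  orig <- as_trains(tr, 500)
  les <- as_trains(lapply(tr, function(t) sort(runif(25, 0, 500))), 500)
  bins <- c(10, 20, 50)
  sw_same <- bin_size_sweep(orig, les, orig, bins)
  expect_equal(sw_same$improvement, 1 - sw_same$r_lesioned,
               tolerance = 1e-12)
  sw_eq <- bin_size_sweep(orig, les, les, bins)
  expect_equal(sw_eq$improvement, rep(0, 3))
  rep_tr <- as_trains(lapply(tr, function(t) sort(runif(28, 0, 500))), 500)
  sw <- bin_size_sweep(orig, les, rep_tr, bins)
  for (i in seq_along(bins)) {
    expect_equal(sw$improvement[i],
                 suppressWarnings(
                   peth_correlation(orig, rep_tr, bins[i], rate = TRUE) -
                   peth_correlation(orig, les, bins[i], rate = TRUE)),
                 tolerance = 1e-12)
  }
})

test_that("perfectly linear synthetic metric columns give |R| = 1", {
  x <- seq(0.1, 0.9, length.out = 20)
  tab <- data.frame(spike_dist = x, spike_sync = 1 - x, peth_r = 1 - x,
                    final_distance = 10 * x, mean_pointwise = 5 * x)
  for (sm in c("spike_dist", "spike_sync", "peth_r")) {
    for (bm in c("final_distance", "mean_pointwise")) {
      expect_equal(abs(cor(tab[[sm]], tab[[bm]])), 1, tolerance = 1e-12)
    }
  }
})
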