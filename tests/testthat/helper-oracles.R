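# Independent brute-force oracles, coded directly from the published
# definitions with naive loops.  They share no code with the package's
# vectorized implementations.

# SPIKE-distance: evaluate the dissimilarity profile S(t) pointwise by
# linear search, integrate segment-by-segment with the trapezoid rule on
# the exact piecewise-linear segments (profile is linear between
# consecutive merged spike events).
oracle_spike_dist <- function(x, y, Tdur) {
  xa <- sort(unique(c(0, x, Tdur)))
  ya <- sort(unique(c(0, y, Tdur)))
  S_at <- function(t, lo, hi) {
    # previous/following spikes of each train w.r.t. segment [lo, hi]
    tPx <- max(xa[xa <= lo]); tFx <- min(xa[xa >= hi])
    tPy <- max(ya[ya <= lo]); tFy <- min(ya[ya >= hi])
    dPx <- min(abs(tPx - ya)); dFx <- min(abs(tFx - ya))
    dPy <- min(abs(tPy - xa)); dFy <- min(abs(tFy - xa))
    xx <- tFx - tPx; xy <- tFy - tPy
    Sx <- (dPx * (tFx - t) + dFx * (t - tPx)) / xx
    Sy <- (dPy * (tFy - t) + dFy * (t - tPy)) / xy
    (Sx * xy + Sy * xx) / (2 * ((xx + xy) / 2)^2)
  }
  ev <- sort(unique(c(xa, ya)))
  total <- 0
  for (i in seq_len(length(ev) - 1)) {
    lo <- ev[i]; hi <- ev[i + 1]
    if (hi <= lo) next
    total <- total + (S_at(lo, lo, hi) + S_at(hi, lo, hi)) / 2 * (hi - lo)
  }
  total / Tdur
}

# SPIKE-synchronization: naive double loop over spikes.
oracle_spike_sync <- function(x, y, Tdur) {
  nx <- length(x); ny <- length(y)
  if (nx == 0 && ny == 0) return(1)
  if (nx == 0 || ny == 0) return(0)
  nu <- function(t, i) {
    n <- length(t)
    if (n == 1) return(Tdur)
    if (i == 1) return(t[2] - t[1])
    if (i == n) return(t[n] - t[n - 1])
    min(t[i + 1] - t[i], t[i] - t[i - 1])
  }
  count <- 0
  for (i in seq_len(nx)) {
    j <- which.min(abs(x[i] - y))
    tau <- 0.5 * min(nu(x, i), nu(y, j))
    if (abs(x[i] - y[j]) < tau) count <- count + 1
  }
  for (j in seq_len(ny)) {
    i <- which.min(abs(y[j] - x))
    tau <- 0.5 * min(nu(y, j), nu(x, i))
    if (abs(y[j] - x[i]) < tau) count <- count + 1
  }
  count / (nx + ny)
}

# random toy spike train on [0, T]
random_train <- function(n_max, Tdur) {
  n <- sample(0:n_max, 1)
  sort(runif(n, 0, Tdur))
}

# wrap plain spike-time lists as the sr_trains the metrics consume
as_trains <- function(lst, duration) {
  structure(lst, duration = duration, ids = seq_along(lst),
            class = "sr_trains")
}

# tiny network configuration used across tests (fast to build/simulate)
tiny_config <- function(...) network_config(scale = 8, ...)
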