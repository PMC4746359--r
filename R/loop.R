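#' Proprioceptive population-coding configuration
#'
#' The P population is split into 4 equal groups, one per muscle group;
#' within a group the units' preferred-length subranges tile `[0, 1]`, so
#' with boxcar tuning exactly one unit per group is active at any interior
#' length.
#'
#' @param n_per_group P units per muscle group.
#' @param peak_rate firing rate of an active unit (Hz).
#' @param shape `"boxcar"` or `"gaussian"` tuning.
#' @return A list of class `sr_proprio_config`.
#' @export
proprio_config <- function(n_per_group = 48, peak_rate = 250,
                           shape = c("boxcar", "gaussian")) {
  shape <- match.arg(shape)
  stopifnot(n_per_group >= 1, peak_rate >= 0)
  structure(list(n_per_group = as.integer(n_per_group),
                 peak_rate = peak_rate, shape = shape),
            class = "sr_proprio_config")
}

#' Encode muscle lengths as P-unit firing rates
#'
#' @param lengths 4 normalized muscle lengths in `[0, 1]`.
#' @param config an [proprio_config()].
#' @return Numeric vector of rates (Hz), length `4 * n_per_group`, ordered
#'   group-by-group (unit order matches P-population ids).
#' @export
encode_proprioception <- function(lengths, config) {
  stopifnot(length(lengths) == 4, all(lengths >= 0 & lengths <= 1))
  K <- config$n_per_group
  centers <- (seq_len(K) - 0.5) / K
  rates <- numeric(4 * K)
  for (g in 1:4) {
    idx <- (g - 1) * K + seq_len(K)
    if (config$shape == "boxcar") {
      # subrange of unit k is [(k-1)/K, k/K); length 1 falls in the last
      k <- min(K, floor(lengths[g] * K) + 1)
      rates[idx[k]] <- config$peak_rate
    } else {
      sigma <- 1 / K
      rates[idx] <- config$peak_rate *
        exp(-(lengths[g] - centers)^2 / (2 * sigma^2))
    }
  }
  rates
}

#' Motor decoder configuration
#'
#' @param window sliding-window length (ms).
#' @param threshold spike-count normalization threshold per group; counts
#'   at or above it saturate the excitation at 1.
#' @return A list of class `sr_decoder_config`.
#' @export
motor_decoder_config <- function(window = 80, threshold = 12) {
  stopifnot(window > 0, threshold > 0)
  structure(list(window = window, threshold = threshold),
            class = "sr_decoder_config")
}

#' Decode muscle excitations from EM spiking
#'
#' Per muscle group, counts the spikes of the group's EM subpopulation in
#' `(t - window, t]` (truncated at trial start), divides by the threshold
#' and clamps to `[0, 1]`.
#'
#' @param em_spikes an `sr_trains` of the EM population (see
#'   [subset_spikes()]), blocked in 4 contiguous groups.
#' @param t decoding time (ms).
#' @param config an [motor_decoder_config()].
#' @return Length-4 excitation vector.
#' @export
decode_motor_excitation <- function(em_spikes, t, config) {
  stopifnot(t >= 0)
  n <- length(em_spikes)
  stopifnot(n %% 4 == 0)
  per <- n / 4
  lo <- max(0, t - config$window)
  counts <- vapply(em_spikes, function(tt) sum(tt > lo & tt <= t), numeric(1))
  grp <- rep(1:4, each = per)
  as.numeric(pmin(1, pmax(0, tapply(counts, grp, sum) / config$threshold)))
}

#' Run one closed-loop reaching trial
#'
#' Every 1 ms: the arm's muscle lengths are encoded as P rates, the
#' network advances 1 ms, the EM spike counts over the sliding window are
#' decoded into muscle excitations, and the arm advances.  Optionally a
#' stimulation pattern is attached for this trial only.
#'
#' @param net an `sr_network` (trained or untrained).
#' @param arm an [arm_params()].
#' @param target a [reach_target()].
#' @param seed trial seed.
#' @param stim optional `sr_stim_pattern` applied for this trial.
#' @param duration trial duration (ms); defaults to the target's.
#' @param proprio,decoder encoder/decoder configurations; group sizes
#'   default to the network's population sizes.
#' @param open_loop optional `4 x duration` matrix of forced excitations;
#'   when given, the arm is driven by these instead of the decoded EM
#'   output (motor babbling).
#' @param .extra_stim internal extra generator drive.
#' @return An object of class `sr_trial` with elements `spikes`
#'   (`sr_spikes`), `trajectory` (data.frame `t, x, y`), `excitations`
#'   (`4 x duration`), `lengths`, `target`, `stim`, `seed`.
#' @export
run_trial <- function(net, arm, target, seed = 1L, stim = NULL,
                      duration = NULL, proprio = NULL, decoder = NULL,
                      open_loop = NULL, .extra_stim = NULL) {
  if (is.null(duration)) duration <- target$duration
  stopifnot(duration > 0)
  n_ms <- as.integer(ceiling(duration))
  if (!is.null(stim)) net <- attach_stimulators(net, stim)
  if (is.null(proprio)) {
    proprio <- proprio_config(n_per_group = net$n_p / 4)
  }
  if (is.null(decoder)) {
    em_n <- length(population_ids(net, "EM"))
    decoder <- motor_decoder_config(threshold = default_threshold(em_n))
  }
  em_ids <- population_ids(net, "EM")
  stopifnot(length(em_ids) %% 4 == 0)
  em_grp <- rep(1:4, each = length(em_ids) / 4)
  win <- as.integer(decoder$window)

  state <- arm_state(arm)
  # per-ms EM group counts over the sliding window
  ring <- matrix(0, 4, win)
  traj <- matrix(NA_real_, n_ms + 1, 2)
  traj[1, ] <- hand_position(state, arm)
  exc_log <- matrix(0, 4, n_ms)
  len_log <- matrix(0, 4, n_ms + 1)
  len_log[, 1] <- muscle_lengths(state, arm)

  cb <- function(t_ms, counts) {
    m <- as.integer(t_ms)  # 1-ms block m (1-based) just ended
    gc4 <- c(
      sum(counts[em_ids[em_grp == 1]]), sum(counts[em_ids[em_grp == 2]]),
      sum(counts[em_ids[em_grp == 3]]), sum(counts[em_ids[em_grp == 4]]))
    ring[, (m - 1) %% win + 1] <<- gc4
    exc <- pmin(1, rowSums(ring) / decoder$threshold)
    if (!is.null(open_loop)) exc <- open_loop[, m]
    exc_log[, m] <<- exc
    state <<- arm_step(state, exc, 1, arm)
    traj[m + 1, ] <<- hand_position(state, arm)
    lens <- muscle_lengths(state, arm)
    len_log[, m + 1] <<- lens
    encode_proprioception(lens, proprio)
  }

  p0 <- matrix(0, net$n_p, n_ms)
  p0[, 1] <- encode_proprioception(muscle_lengths(state, arm), proprio)
  spikes <- simulate_network(net, n_ms, seed = seed, p_rates = p0,
                             callback = cb, .extra_stim = .extra_stim)
  # the callback is not invoked after the final block; finish the arm
  last_counts <- integer(net$n_neuron)
  for (id in em_ids) {
    last_counts[id] <- sum(spikes$trains[[id]] > n_ms - 1)
  }
  cb(n_ms, last_counts)

  structure(list(spikes = spikes,
                 trajectory = data.frame(t = 0:n_ms, x = traj[, 1],
                                         y = traj[, 2]),
                 excitations = exc_log, lengths = len_log,
                 target = target, stim = stim, seed = as.integer(seed),
                 arm = arm, decoder = decoder, proprio = proprio),
            class = "sr_trial")
}

# decoder threshold calibrated to the EM group size: saturation when the
# group fires at ~35 Hz/cell across the 80 ms window
default_threshold <- function(em_n) {
  max(2, round(em_n / 4 * 0.08 * 35))
}

#' @export
print.sr_trial <- function(x, ...) {
  fin <- unlist(tail(x$trajectory[, c("x", "y")], 1))
  cat("<sr_trial> target", x$target$label, "- final distance",
      round(sqrt(sum((fin - x$target$position)^2)), 2), "cm\n")
  invisible(x)
}

#' Final hand-to-target distance of a trial
#'
#' @param trial an `sr_trial`.
#' @return Distance (cm).
#' @export
final_distance <- function(trial) {
  fin <- unlist(tail(trial$trajectory[, c("x", "y")], 1))
  sqrt(sum((fin - trial$target$position)^2))
}

#' Reward-modulated STDP training configuration
#'
#' Two exploration modes are available.  `"bump"` (the default) runs
#' closed-loop episodes in which random muscle groups receive brief
#' extra efference drive ("bumps"), so that credit is evaluated locally
#' around the current policy's own trajectory.  `"babble"` runs
#' open-loop episodes with random piecewise-constant excitations
#' driving the arm and an efference copy delivered to the corresponding
#' EM subpopulations (global workspace coverage); `babble_every`
#' interleaves babbling with plain closed-loop episodes.
#'
#' @param lr learning rate (weight change per unit eligibility).
#' @param reward_interval reward evaluation interval (ms); also the
#'   exploration segment length.
#' @param stdp_window pre-before-post coincidence window (ms).
#' @param tau_elig eligibility-trace decay constant (ms).
#' @param tau_stdp decay of the pairing kernel within the window (ms).
#' @param explore `"bump"` or `"babble"`.
#' @param p_bump per-segment probability that a muscle group receives an
#'   exploration bump (bump mode).
#' @param babble_every babble mode: every how many episodes a babbling
#'   episode occurs (1 = always).
#' @param babble_rate efference generator rate at full drive (Hz),
#'   shared by both modes.
#' @param babble_weight efference synaptic weight, as a multiple of the
#'   background input weight.
#' @param baseline reward baseline: `"time"` subtracts a per-interval
#'   running mean across episodes (removes the reward's temporal
#'   profile, which otherwise masks late-movement credit), `"episode"`
#'   subtracts the episode mean, `"none"` uses the raw sign.
#' @param w_norm homeostatic synaptic scaling: after each episode all
#'   trainable weights are rescaled so their global mean equals
#'   `w_norm`, making plasticity competitive between motor groups.
#'   `NULL` disables scaling.
#' @param lr_half learning-rate annealing half-life (episodes):
#'   `lr_ep = lr / (1 + ep / lr_half)`; `Inf` keeps the rate constant.
#' @param reward_kind `"sign"` (the +/-1 closer/farther rule) or
#'   `"delta"` (signed distance change in cm).
#' @return A list of class `sr_rlstdp_config`.
#' @export
rlstdp_config <- function(lr = 0.05, reward_interval = 50, stdp_window = 20,
                          tau_elig = 80, tau_stdp = 10,
                          explore = c("bump", "babble"), p_bump = 0.35,
                          babble_every = 2, babble_rate = 800,
                          babble_weight = 4,
                          baseline = c("time", "episode", "none"),
                          w_norm = 1.8, lr_half = Inf,
                          reward_kind = c("sign", "delta")) {
  stopifnot(lr >= 0, reward_interval > 0, p_bump >= 0, p_bump <= 1)
  structure(list(lr = lr, reward_interval = reward_interval,
                 stdp_window = stdp_window, tau_elig = tau_elig,
                 tau_stdp = tau_stdp, explore = match.arg(explore),
                 p_bump = p_bump, babble_every = babble_every,
                 babble_rate = babble_rate, babble_weight = babble_weight,
                 baseline = match.arg(baseline), w_norm = w_norm,
                 lr_half = lr_half,
                 reward_kind = match.arg(reward_kind)),
            class = "sr_rlstdp_config")
}

# eligibility of each trainable synapse accumulated per reward interval:
# for every post spike, pre spikes in the preceding stdp_window contribute
# exp(-dt_pair / tau_stdp)
stdp_eligibility <- function(syn_idx, syn, trains, breaks, config) {
  n_int <- length(breaks) - 1
  elig <- matrix(0, length(syn_idx), n_int)
  for (r in seq_along(syn_idx)) {
    s <- syn_idx[r]
    post_t <- trains[[syn$post[s]]]
    if (length(post_t) == 0) next
    pre_t <- trains[[syn$pre[s]]]
    if (length(pre_t) == 0) next
    for (tp in post_t) {
      prev <- pre_t[pre_t < tp & pre_t >= tp - config$stdp_window]
      if (length(prev) > 0) {
        k <- findInterval(tp, breaks, rightmost.closed = TRUE)
        if (k >= 1 && k <= n_int) {
          elig[r, k] <- elig[r, k] + sum(exp(-(tp - prev) / config$tau_stdp))
        }
      }
    }
  }
  elig
}

#' Train the network to reach a target
#'
#' Reward-modulated STDP on the trainable projections (ES to EM and the
#' recurrent excitatory connections): pre-before-post coincidences build
#' eligibility traces; at the end of each reward interval the traces are
#' converted into weight changes with positive sign if the hand moved
#' closer to the target over the interval and negative sign otherwise.
#' Closed-loop episodes alternate with open-loop exploratory (babbling)
#' episodes.
#'
#' @param net an `sr_network`.
#' @param arm an [arm_params()].
#' @param target a [reach_target()].
#' @param episodes number of training episodes.
#' @param config an [rlstdp_config()].
#' @param seed training seed.
#' @param verbose print per-episode distances.
#' @return The trained network.
#' @export
train_reaching <- function(net, arm, target, episodes = 40,
                           config = rlstdp_config(), seed = 1L,
                           proprio = NULL, decoder = NULL,
                           verbose = FALSE) {
  stopifnot(episodes >= 0)
  if (episodes == 0) return(net)
  tr_idx <- which(net$syn$trainable)
  em_ids <- population_ids(net, "EM")
  em_grp <- rep(1:4, each = length(em_ids) / 4)
  dur <- target$duration
  R <- config$reward_interval
  breaks <- seq(0, dur, by = R)
  trace <- numeric(length(tr_idx))
  dec_tr <- exp(-R / config$tau_elig)
  rbar <- NULL
  segs <- ceiling(dur / R)
  seg_expand <- rep(seq_len(segs), each = R)[seq_len(dur)]
  eff_w <- config$babble_weight * net$config$background$weight

  for (ep in seq_len(episodes)) {
    babble <- config$explore == "babble" && config$babble_every > 0 &&
      (ep - 1) %% config$babble_every == 0
    ep_seed <- derive_seed(seed, paste0("episode", ep))
    if (babble) {
      exc <- with_seed(derive_seed(seed, paste0("babble", ep)), {
        on <- matrix(runif(4 * segs) < 0.5, 4, segs)
        raw <- matrix(runif(4 * segs, 0.4, 1), 4, segs) * on
        raw[, seg_expand, drop = FALSE]
      })
      eff <- list(list(cells = em_ids,
                       rates = exc[em_grp, , drop = FALSE] * config$babble_rate,
                       weight = eff_w))
      trial <- run_trial(net, arm, target, seed = ep_seed, open_loop = exc,
                         proprio = proprio, decoder = decoder,
                         .extra_stim = eff)
    } else if (config$explore == "bump") {
      bump <- with_seed(derive_seed(seed, paste0("bump", ep)), {
        on <- matrix(runif(4 * segs) < config$p_bump, 4, segs)
        (matrix(runif(4 * segs, 0.3, 0.8), 4, segs) * on)[, seg_expand,
                                                          drop = FALSE]
      })
      eff <- list(list(cells = em_ids,
                       rates = bump[em_grp, , drop = FALSE] * config$babble_rate,
                       weight = eff_w))
      trial <- run_trial(net, arm, target, seed = ep_seed,
                         proprio = proprio, decoder = decoder,
                         .extra_stim = eff)
    } else {
      trial <- run_trial(net, arm, target, seed = ep_seed,
                         proprio = proprio, decoder = decoder)
    }
    traj <- trial$trajectory
    d <- sqrt((traj$x - target$position[1])^2 +
              (traj$y - target$position[2])^2)
    d_at <- d[findInterval(breaks, traj$t)]
    reward <- d_at[-length(d_at)] - d_at[-1]  # + if moved closer (cm)
    if (!identical(config$reward_kind, "delta")) reward <- sign(reward)
    if (config$baseline == "time") {
      if (is.null(rbar)) rbar <- reward
      adj <- reward - rbar
      rbar <- 0.9 * rbar + 0.1 * reward
      reward <- adj
    } else if (config$baseline == "episode") {
      reward <- reward - mean(reward)
    }
    elig <- stdp_eligibility(tr_idx, net$syn, trial$spikes$trains, breaks,
                             config)
    lr_ep <- config$lr / (1 + ep / config$lr_half)
    dw <- numeric(length(tr_idx))
    for (k in seq_along(reward)) {
      trace <- trace * dec_tr + elig[, k]
      dw <- dw + lr_ep * reward[k] * trace
    }
    w <- pmin(net$config$w_max, pmax(0, net$syn$weight[tr_idx] + dw))
    if (!is.null(config$w_norm)) {
      # global homeostatic scaling: the mean trainable weight is pinned,
      # so plasticity redistributes drive (motor groups compete) without
      # pinning each cell's total input
      w <- pmin(net$config$w_max,
                w * config$w_norm / max(1e-12, mean(w)))
    }
    net$syn$weight[tr_idx] <- w
    if (verbose) {
      message(sprintf("episode %3d (%s): final distance %.2f cm", ep,
                      if (babble) "babble" else "closed", d[length(d)]))
    }
  }
  net
}
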