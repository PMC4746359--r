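#' Default configuration of the spiking sensorimotor network
#'
#' The network has 7 subpopulations: proprioceptive spike generators (P),
#' sensory excitatory (ES), sensory fast-spiking inhibitory (IS), sensory
#' low-threshold inhibitory (ILS), and their motor counterparts (EM, IM,
#' ILM).  At the default scale the sizes are P = 192, ES = 192, IS = 44,
#' ILS = 20, EM = 192, IM = 44, ILM = 20 (704 units in total: 512 neurons
#' plus 192 P generators).  Neurons are leaky integrate-and-fire units with
#' conductance-based AMPA, NMDA (voltage-gated) and GABA_A synapses and a
#' relative refractory period implemented as a post-spike threshold jump
#' plus decaying hyperpolarization.  Connection probabilities, weights and
#' delays depend on the pre/post population pair; they are exposed here as
#' a rule table with calibrated defaults.
#'
#' @param scale integer shrink factor: population sizes are divided by
#'   `scale` (keeping the four-group structure of P and EM).  `scale = 1`
#'   is the full network; `scale = 4` is the "mini" preset used in fast
#'   tests and campaigns.
#' @param bg_rate background Poisson input rate per neuron (Hz).
#' @param bg_weight synaptic weight of a background input event.
#' @param allow_self allow autapses when drawing connectivity.
#' @return A list with elements `sizes`, `neuron` (per-cell-kind
#'   parameters), `receptors`, `conn` (connectivity rule table),
#'   `background`, `dt`, `allow_self`, `w_max`, `scale`.
#' @export
network_config <- function(scale = 1, bg_rate = 130, bg_weight = 0.5,
                           allow_self = FALSE) {
  stopifnot(scale >= 1)
  g4 <- function(n) max(4L, 4L * as.integer(round(n / scale / 4)))
  sz <- function(n) max(2L, as.integer(round(n / scale)))
  sizes <- c(ES = g4(192), IS = sz(44), ILS = sz(20),
             EM = g4(192), IM = sz(44), ILM = sz(20), P = g4(192))

  neuron <- list(
    excitatory = list(tau_m = 20, v_rest = -65, v_thresh = -40,
                      v_reset = -65, th_jump = 12, tau_th = 10,
                      hyp_jump = 8, tau_hyp = 25),
    fast_spiking = list(tau_m = 10, v_rest = -65, v_thresh = -42,
                        v_reset = -65, th_jump = 4, tau_th = 4,
                        hyp_jump = 2, tau_hyp = 10),
    low_threshold = list(tau_m = 20, v_rest = -65, v_thresh = -47,
                         v_reset = -65, th_jump = 8, tau_th = 10,
                         hyp_jump = 5, tau_hyp = 25)
  )

  receptors <- list(labels = c("AMPA", "NMDA", "GABA_A"),
                    e_rev = c(0, 0, -80), tau_syn = c(5, 150, 10),
                    nmda_vhalf = -25, nmda_vslope = 12, g_scale = 0.05)

  conn <- rbind(
    conn_rule("P",   "ES", 0.25, 4.0, "AMPA",   1, 3),
    conn_rule("ES",  "ES", 0.05, 1.0, "AMPA",   1, 5),
    conn_rule("ES",  "ES", 0.05, 0.3, "NMDA",   1, 5),
    conn_rule("ES",  "IS", 0.20, 2.0, "AMPA",   1, 3),
    conn_rule("ES",  "ILS", 0.20, 2.0, "AMPA",  1, 3),
    conn_rule("IS",  "ES", 0.30, 2.0, "GABA_A", 1, 2),
    conn_rule("ILS", "ES", 0.30, 1.0, "GABA_A", 1, 2),
    conn_rule("IS",  "IS", 0.10, 2.0, "GABA_A", 1, 2),
    conn_rule("ES",  "EM", 0.30, 1.0, "AMPA",   1, 5, trainable = TRUE,
              init = "uniform"),
    conn_rule("EM",  "EM", 0.05, 1.0, "AMPA",   1, 5, trainable = TRUE,
              init = "uniform"),
    conn_rule("EM",  "ES", 0.05, 0.5, "AMPA",   1, 5),
    conn_rule("EM",  "IM", 0.20, 2.0, "AMPA",   1, 3),
    conn_rule("EM",  "ILM", 0.20, 2.0, "AMPA",  1, 3),
    conn_rule("IM",  "EM", 0.30, 2.0, "GABA_A", 1, 2),
    conn_rule("ILM", "EM", 0.30, 1.0, "GABA_A", 1, 2),
    conn_rule("IM",  "IM", 0.10, 2.0, "GABA_A", 1, 2)
  )

  list(sizes = sizes, neuron = neuron, receptors = receptors, conn = conn,
       background = list(rate = bg_rate, weight = bg_weight),
       dt = 0.1, allow_self = allow_self, w_max = 4, scale = scale)
}

#' Define one population-pair connectivity rule
#'
#' @param src,dst population labels.
#' @param p Bernoulli connection probability in `[0, 1]`.
#' @param weight synaptic weight (dimensionless conductance scale).
#' @param receptor one of `"AMPA"`, `"NMDA"`, `"GABA_A"`.
#' @param delay_min,delay_max conduction delay range (ms).
#' @param trainable whether the projection is plastic under
#'   reward-modulated STDP.
#' @param init `"fixed"` (all synapses get `weight`) or `"uniform"`
#'   (weights drawn uniformly on `[0, weight]`).
#' @return One-row data frame.
#' @export
conn_rule <- function(src, dst, p, weight, receptor, delay_min = 1,
                      delay_max = 3, trainable = FALSE, init = "fixed") {
  data.frame(src = src, dst = dst, p = p, weight = weight,
             receptor = receptor, delay_min = delay_min,
             delay_max = delay_max, trainable = trainable, init = init,
             stringsAsFactors = FALSE)
}

pop_kinds <- c(ES = "excitatory", IS = "fast_spiking", ILS = "low_threshold",
               EM = "excitatory", IM = "fast_spiking", ILM = "low_threshold",
               P = "spike_generator")

#' Build the spiking network
#'
#' Units get contiguous global ids in the order ES, IS, ILS, EM, IM, ILM
#' (neurons), then P (spike generators).  Connectivity is drawn per
#' ordered pair as an independent Bernoulli trial with the rule's
#' probability; the draw is fully determined by `(config, seed)`.
#'
#' @param config a [network_config()] list.
#' @param seed integer construction seed.
#' @return An object of class `sr_network`.
#' @export
build_network <- function(config = network_config(), seed = 1L) {
  p <- config$conn$p
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("configuration error: connection probabilities must lie in [0, 1]")
  }
  if (any(config$sizes < 0)) stop("configuration error: negative population size")
  order <- c("ES", "IS", "ILS", "EM", "IM", "ILM", "P")
  sizes <- config$sizes[order]
  to <- cumsum(sizes)
  from <- to - sizes + 1L
  pops <- data.frame(label = order, size = as.integer(sizes),
                     kind = unname(pop_kinds[order]),
                     from = as.integer(from), to = as.integer(to),
                     stringsAsFactors = FALSE)
  nz <- pops[pops$size > 0, ]
  all_ids <- unlist(mapply(seq.int, nz$from, nz$to, SIMPLIFY = FALSE))
  if (anyDuplicated(all_ids)) stop("internal error: overlapping id ranges")
  n_neuron <- sum(sizes[order != "P"])

  ids_of <- function(label) {
    r <- pops[pops$label == label, ]
    if (r$size == 0) integer(0) else seq.int(r$from, r$to)
  }

  syn <- with_seed(derive_seed(seed, "construct"), {
    out <- vector("list", nrow(config$conn))
    for (k in seq_len(nrow(config$conn))) {
      rule <- config$conn[k, ]
      src <- ids_of(rule$src)
      dst <- ids_of(rule$dst)
      if (length(src) == 0 || length(dst) == 0 || rule$p == 0) next
      pre <- rep(src, times = length(dst))
      post <- rep(dst, each = length(src))
      keep <- runif(length(pre)) < rule$p
      if (!config$allow_self) keep <- keep & (pre != post)
      pre <- pre[keep]
      post <- post[keep]
      if (length(pre) == 0) next
      w <- if (rule$init == "uniform") {
        rule$weight * runif(length(pre))
      } else {
        rep(rule$weight, length(pre))
      }
      d <- runif(length(pre), rule$delay_min, rule$delay_max)
      out[[k]] <- data.frame(pre = pre, post = post,
                             receptor = rule$receptor, weight = w,
                             delay_ms = d, trainable = rule$trainable,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
  })
  if (is.null(syn)) {
    syn <- data.frame(pre = integer(0), post = integer(0),
                      receptor = character(0), weight = numeric(0),
                      delay_ms = numeric(0), trainable = logical(0))
  }
  rownames(syn) <- NULL

  structure(list(config = config, seed = as.integer(seed), pops = pops,
                 n_neuron = as.integer(n_neuron),
                 n_p = as.integer(sizes[["P"]]), syn = syn,
                 silenced = integer(0), stim = NULL),
            class = "sr_network")
}

#' @export
print.sr_network <- function(x, ...) {
  cat("<sr_network> ", sum(x$pops$size), " units (",
      x$n_neuron, " neurons + ", x$n_p, " P generators), ",
      nrow(x$syn), " synapses, ", length(x$silenced), " silenced\n", sep = "")
  invisible(x)
}

#' Ids of one population
#'
#' @param net an `sr_network`.
#' @param label population label (`"P"`, `"ES"`, ...).
#' @return Integer vector of global unit ids.
#' @export
population_ids <- function(net, label) {
  r <- net$pops[net$pops$label == label, ]
  if (nrow(r) == 0 || r$size == 0) return(integer(0))
  seq.int(r$from, r$to)
}

#' Silence a random fraction of ES cells
#'
#' Cell-ablation lesion: `round(fraction * |ES|)` distinct surviving ES
#' cells are added to the silenced set.  Silencing suppresses all outgoing
#' spikes of a cell; its incoming synapses remain but are inert.
#'
#' @param net an `sr_network`.
#' @param fraction proportion of the ES population to silence, in `[0, 1]`.
#' @param seed lesion seed.
#' @return The lesioned network.
#' @export
apply_cell_lesion <- function(net, fraction, seed = 1L) {
  if (!is.finite(fraction) || fraction < 0 || fraction > 1) {
    stop("input error: lesion fraction must lie in [0, 1]")
  }
  es <- population_ids(net, "ES")
  k <- round(fraction * length(es))
  if (k == 0) return(net)
  pool <- setdiff(es, net$silenced)
  pick <- with_seed(derive_seed(seed, "cell_lesion"),
                    sample(pool, min(k, length(pool))))
  net$silenced <- sort(c(net$silenced, pick))
  net
}

#' Remove a random fraction of synapses
#'
#' @param net an `sr_network`.
#' @param fraction proportion of all synapses to remove, in `[0, 1]`.
#' @param seed lesion seed.
#' @return The lesioned network.
#' @export
apply_synapse_lesion <- function(net, fraction, seed = 1L) {
  if (!is.finite(fraction) || fraction < 0 || fraction > 1) {
    stop("input error: lesion fraction must lie in [0, 1]")
  }
  n <- nrow(net$syn)
  k <- round(fraction * n)
  if (k == 0) return(net)
  drop <- with_seed(derive_seed(seed, "synapse_lesion"), sample.int(n, k))
  net$syn <- net$syn[-drop, , drop = FALSE]
  rownames(net$syn) <- NULL
  net
}

#' Stimulation pattern targeting ES cells
#'
#' Either an entry list (one external spike generator per cell/interval)
#' or a dense rate matrix at 1 ms resolution.
#'
#' @param cells ES cell ids (one per entry).
#' @param onset,duration onset and duration of each entry (ms).
#' @param rate generator firing rate of each entry (Hz).
#' @return An object of class `sr_stim_pattern`.
#' @export
stim_pattern <- function(cells, onset, duration, rate) {
  e <- data.frame(cell = as.integer(cells), onset = as.numeric(onset),
                  duration = as.numeric(duration), rate = as.numeric(rate))
  if (any(e$rate < 0) || any(e$duration < 0)) {
    stop("input error: stimulation rates and durations must be >= 0")
  }
  structure(list(entries = e, rates = NULL, cells = NULL, t_start = NULL),
            class = "sr_stim_pattern")
}

#' Dense-matrix stimulation pattern
#'
#' @param rates numeric matrix, one row per cell in `cells`, one column per
#'   1 ms step starting at `t_start`.
#' @param cells ES cell ids (row order of `rates`).
#' @param t_start time of the first column (ms).
#' @return An object of class `sr_stim_pattern`.
#' @export
stim_pattern_matrix <- function(rates, cells, t_start = 100) {
  stopifnot(is.matrix(rates), nrow(rates) == length(cells))
  if (any(rates < 0)) stop("input error: stimulation rates must be >= 0")
  structure(list(entries = NULL, rates = rates, cells = as.integer(cells),
                 t_start = as.numeric(t_start)),
            class = "sr_stim_pattern")
}

#' Attach external stimulators to ES cells
#'
#' One Poisson spike generator is attached per entry (cell, interval,
#' rate), connected through an AMPA synapse whose weight is 10x the
#' background input weight.  Entries targeting silenced cells are dropped
#' with a warning.
#'
#' @param net an `sr_network`.
#' @param pattern an [stim_pattern()] or [stim_pattern_matrix()].
#' @return The network with stimulators attached.
#' @export
attach_stimulators <- function(net, pattern) {
  stopifnot(inherits(pattern, "sr_stim_pattern"))
  es <- population_ids(net, "ES")
  cells <- if (is.null(pattern$entries)) pattern$cells else pattern$entries$cell
  if (length(cells) == 0) return(net)
  if (!all(cells %in% es)) {
    stop("input error: stimulators may only target ES cells")
  }
  bad <- cells %in% net$silenced
  if (any(bad)) {
    warning(sum(bad), " stimulation entries target silenced cells; dropped")
    if (is.null(pattern$entries)) {
      pattern$rates <- pattern$rates[!bad, , drop = FALSE]
      pattern$cells <- pattern$cells[!bad]
    } else {
      pattern$entries <- pattern$entries[!bad, , drop = FALSE]
    }
  }
  weight <- 10 * net$config$background$weight
  net$stim <- c(net$stim, list(list(pattern = pattern, weight = weight)))
  net
}

# Expand attached stimulators (plus any internal extra drive) into the
# per-generator rate matrix the C++ core consumes.
stim_matrices <- function(net, n_ms, extra = NULL) {
  targets <- integer(0)
  weights <- numeric(0)
  rates <- NULL
  add_rows <- function(tg, wt, rm) {
    targets <<- c(targets, tg)
    weights <<- c(weights, wt)
    rates <<- rbind(rates, rm)
  }
  for (st in net$stim) {
    pat <- st$pattern
    if (!is.null(pat$entries) && nrow(pat$entries) > 0) {
      e <- pat$entries
      rm <- matrix(0, nrow(e), n_ms)
      for (i in seq_len(nrow(e))) {
        c0 <- floor(e$onset[i]) + 1
        c1 <- min(n_ms, ceiling(e$onset[i] + e$duration[i]))
        if (c1 >= c0) rm[i, c0:c1] <- e$rate[i]
      }
      add_rows(e$cell, rep(st$weight, nrow(e)), rm)
    } else if (!is.null(pat$rates) && nrow(pat$rates) > 0) {
      rm <- matrix(0, nrow(pat$rates), n_ms)
      c0 <- floor(pat$t_start) + 1
      c1 <- min(n_ms, c0 + ncol(pat$rates) - 1)
      if (c1 >= c0) rm[, c0:c1] <- pat$rates[, seq_len(c1 - c0 + 1)]
      add_rows(pat$cells, rep(st$weight, nrow(rm)), rm)
    }
  }
  for (ex in extra) {
    stopifnot(nrow(ex$rates) == length(ex$cells), ncol(ex$rates) == n_ms)
    add_rows(ex$cells, rep(ex$weight, length(ex$cells)), ex$rates)
  }
  if (length(targets) == 0) {
    list(target = integer(0), weight = numeric(0),
         rates = matrix(0, 0, n_ms))
  } else {
    list(target = targets, weight = weights, rates = rates)
  }
}

#' Simulate the network
#'
#' Clock-driven simulation at `dt = 0.1` ms.  Background Poisson drive, P
#' generator spiking and attached stimulators each draw from independent
#' seeded streams, so outputs are identical for identical
#' `(network, duration, inputs, seed)` and the pre-stimulation activity of
#' a run with and without stimulators is spike-identical.
#'
#' @param net an `sr_network`.
#' @param duration trial duration (ms).
#' @param seed simulation seed.
#' @param p_rates optional `n_P x duration` matrix of P-unit rates (Hz) at
#'   1 ms resolution (open-loop proprioceptive drive).
#' @param callback optional closed-loop callback `function(t_ms, counts)`
#'   returning the next 1 ms block's P rates; `counts` holds each neuron's
#'   spike count in the block that just ended.
#' @param .extra_stim internal: extra generator drive (used for the
#'   efference copy during motor babbling).
#' @return An `sr_spikes` object: sorted spike times (ms) per unit.
#' @export
simulate_network <- function(net, duration, seed = 1L, p_rates = NULL,
                             callback = NULL, .extra_stim = NULL) {
  stopifnot(inherits(net, "sr_network"), duration > 0)
  n_ms <- as.integer(ceiling(duration))
  n <- net$n_neuron
  if (is.null(p_rates)) {
    p_rates <- matrix(0, net$n_p, n_ms)
  }
  stopifnot(nrow(p_rates) == net$n_p, ncol(p_rates) >= n_ms)

  kind <- rep(net$pops$kind, net$pops$size)[seq_len(n)]
  par_of <- function(field) {
    vapply(kind, function(k) net$config$neuron[[k]][[field]], numeric(1),
           USE.NAMES = FALSE)
  }
  rec_idx <- match(net$syn$receptor, net$config$receptors$labels) - 1L
  if (anyNA(rec_idx)) stop("input error: unknown receptor in synapse table")
  dt <- net$config$dt
  sil <- logical(n)
  sil[net$silenced] <- TRUE

  sm <- stim_matrices(net, n_ms, extra = .extra_stim)
  if (length(sm$target) > 0 &&
      (any(sm$target < 1) || any(sm$target > n))) {
    stop("input error: stimulator references unknown cell")
  }

  carg <- list(n_neuron = n, n_p = net$n_p,
               v_rest = par_of("v_rest"), v_thresh = par_of("v_thresh"),
               v_reset = par_of("v_reset"), tau_m = par_of("tau_m"),
               th_jump = par_of("th_jump"), tau_th = par_of("tau_th"),
               hyp_jump = par_of("hyp_jump"), tau_hyp = par_of("tau_hyp"),
               e_rev = net$config$receptors$e_rev,
               tau_syn = net$config$receptors$tau_syn,
               nmda_vhalf = net$config$receptors$nmda_vhalf,
               nmda_vslope = net$config$receptors$nmda_vslope,
               g_scale = net$config$receptors$g_scale,
               bg_rate = rep(net$config$background$rate, n),
               bg_weight = net$config$background$weight,
               silenced = sil,
               syn_pre = net$syn$pre - 1L, syn_post = net$syn$post - 1L,
               syn_rec = rec_idx,
               syn_delay = pmax(1L, as.integer(round(net$syn$delay_ms / dt))),
               syn_w = net$syn$weight)

  res <- sim_core(carg, n_ms, p_rates, callback,
                  as.integer(sm$target - 1L), sm$rates, sm$weight,
                  derive_seed(seed, "background"), derive_seed(seed, "p_drive"),
                  derive_seed(seed, "stimulator"), dt)

  n_units <- n + net$n_p
  f <- factor(res$id + 1L, levels = seq_len(n_units))
  trains <- split(res$time, f)
  structure(list(duration = n_ms, n_units = n_units,
                 trains = trains, pops = net$pops,
                 seed = as.integer(seed),
                 stim_spikes = data.frame(gen = res$stim_id,
                                          time = res$stim_time)),
            class = "sr_spikes")
}

#' @export
print.sr_spikes <- function(x, ...) {
  cat("<sr_spikes> ", x$n_units, " units over ", x$duration, " ms, ",
      sum(lengths(x$trains)), " spikes\n", sep = "")
  invisible(x)
}

#' Restrict a spike set to a subset of units
#'
#' @param spikes an `sr_spikes`.
#' @param ids global unit ids to keep (order preserved).
#' @return A named list of spike-time vectors with attributes `duration`
#'   and `ids`, of class `sr_trains`.
#' @export
subset_spikes <- function(spikes, ids) {
  structure(spikes$trains[as.character(ids)],
            duration = spikes$duration, ids = as.integer(ids),
            class = "sr_trains")
}

#' Total spike count per unit
#'
#' @param spikes an `sr_spikes`.
#' @param ids optional unit subset.
#' @return Named integer vector.
#' @export
spike_counts <- function(spikes, ids = NULL) {
  tr <- if (is.null(ids)) spikes$trains else spikes$trains[as.character(ids)]
  lengths(tr)
}
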