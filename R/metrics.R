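# nearest-neighbour distance from each element of a to the set b
nn_dist <- function(a, b) {
  i <- findInterval(a, b)
  lo <- b[pmax(i, 1)]
  hi <- b[pmin(i + 1, length(b))]
  pmin(abs(a - lo), abs(a - hi))
}

# Time-averaged SPIKE-distance between two single-unit trains on [0, T].
# Exact piecewise-linear integration of the dissimilarity profile; edge
# handling adds auxiliary spikes at 0 and T to both trains.
spike_dist_pair <- function(x, y, Tdur) {
  xa <- sort(unique(c(0, x, Tdur)))
  ya <- sort(unique(c(0, y, Tdur)))
  ev <- sort(unique(c(xa, ya)))
  e0 <- ev[-length(ev)]
  e1 <- ev[-1]
  nnx <- nn_dist(xa, ya)   # dist of each x spike to nearest y spike
  nny <- nn_dist(ya, xa)
  iPx <- findInterval(e0, xa)
  iFx <- findInterval(e1 - 1e-12, xa) + 1L
  iPy <- findInterval(e0, ya)
  iFy <- findInterval(e1 - 1e-12, ya) + 1L
  tPx <- xa[iPx]; tFx <- xa[iFx]; dPx <- nnx[iPx]; dFx <- nnx[iFx]
  tPy <- ya[iPy]; tFy <- ya[iFy]; dPy <- nny[iPy]; dFy <- nny[iFy]
  isx <- tFx - tPx
  isy <- tFy - tPy
  Sx0 <- (dPx * (tFx - e0) + dFx * (e0 - tPx)) / isx
  Sx1 <- (dPx * (tFx - e1) + dFx * (e1 - tPx)) / isx
  Sy0 <- (dPy * (tFy - e0) + dFy * (e0 - tPy)) / isy
  Sy1 <- (dPy * (tFy - e1) + dFy * (e1 - tPy)) / isy
  den <- 2 * ((isx + isy) / 2)^2
  S0 <- (Sx0 * isy + Sy0 * isx) / den
  S1 <- (Sx1 * isy + Sy1 * isx) / den
  sum((S0 + S1) / 2 * (e1 - e0)) / Tdur
}

# SPIKE-synchronization between two single-unit trains on [0, T]:
# adaptive coincidence detection, tau = half the smaller of the local
# inter-spike intervals (a single-spike train gets nu = T).
spike_sync_pair <- function(x, y, Tdur) {
  nx <- length(x)
  ny <- length(y)
  if (nx == 0 && ny == 0) return(1)
  if (nx == 0 || ny == 0) return(0)
  local_isi <- function(t) {
    n <- length(t)
    if (n == 1) return(Tdur)
    d <- diff(t)
    pmin(c(d[1], d), c(d, d[n - 1]))
  }
  nux <- local_isi(x)
  nuy <- local_isi(y)
  coin <- function(a, nua, b, nub) {
    i <- findInterval(a, b)
    lo <- pmax(i, 1)
    hi <- pmin(i + 1, length(b))
    j <- ifelse(abs(a - b[lo]) <= abs(a - b[hi]), lo, hi)
    tau <- 0.5 * pmin(nua, nub[j])
    sum(abs(a - b[j]) < tau)
  }
  (coin(x, nux, y, nuy) + coin(y, nuy, x, nux)) / (nx + ny)
}

check_trains <- function(a, b) {
  stopifnot(inherits(a, "sr_trains"), inherits(b, "sr_trains"))
  if (length(a) != length(b) ||
      !identical(attr(a, "ids"), attr(b, "ids"))) {
    stop("input error: spike sets cover different unit sets")
  }
  if (abs(attr(a, "duration") - attr(b, "duration")) > 1e-9) {
    stop("input error: spike sets cover different durations")
  }
  invisible(TRUE)
}

#' SPIKE-distance between two multi-unit spike sets
#'
#' Parameter-free time-resolved spike-train dissimilarity (0 identical, up
#' to 1), computed per matched unit pair (unit k of `a` vs unit k of `b`)
#' by exact integration of the piecewise-linear dissimilarity profile, and
#' averaged over time and units.
#'
#' @param a,b `sr_trains` over the same unit set and duration (see
#'   [subset_spikes()]).
#' @param mode `"matched"` (default) compares unit k with unit k;
#'   `"all_pairs"` averages over all cross pairs (exploratory).
#' @return Scalar in `[0, 1]`.
#' @export
spike_distance <- function(a, b, mode = c("matched", "all_pairs")) {
  mode <- match.arg(mode)
  check_trains(a, b)
  Tdur <- attr(a, "duration")
  if (mode == "matched") {
    mean(vapply(seq_along(a),
                function(k) spike_dist_pair(a[[k]], b[[k]], Tdur),
                numeric(1)))
  } else {
    mean(outer(seq_along(a), seq_along(b),
               Vectorize(function(k, l) spike_dist_pair(a[[k]], b[[l]], Tdur))))
  }
}

#' SPIKE-synchronization between two multi-unit spike sets
#'
#' Fraction of spikes with an adaptive-window coincidence partner in the
#' other condition's matched unit (1 = every spike coincides), averaged
#' over units.
#'
#' @inheritParams spike_distance
#' @return Scalar in `[0, 1]`.
#' @export
spike_sync <- function(a, b, mode = c("matched", "all_pairs")) {
  mode <- match.arg(mode)
  check_trains(a, b)
  Tdur <- attr(a, "duration")
  if (mode == "matched") {
    mean(vapply(seq_along(a),
                function(k) spike_sync_pair(a[[k]], b[[k]], Tdur),
                numeric(1)))
  } else {
    mean(outer(seq_along(a), seq_along(b),
               Vectorize(function(k, l) spike_sync_pair(a[[k]], b[[l]], Tdur))))
  }
}

#' Population peri-event time histogram
#'
#' Pools the spikes of all units into bins of `bin` ms starting at
#' `offset`; a trailing partial bin is kept so that the histogram covers
#' `[offset, duration]` and conserves the spike count.
#'
#' @param trains an `sr_trains`.
#' @param bin bin size (ms).
#' @param offset start offset (ms), `0 <= offset < bin`.
#' @return Object of class `sr_peth`: `breaks`, `counts`, `rate` (spikes/s
#'   per unit), `bin`, `offset`, `n_units`.
#' @export
peth <- function(trains, bin = 20, offset = 0) {
  stopifnot(bin > 0, offset >= 0, offset < bin)
  dur <- attr(trains, "duration")
  breaks <- seq(offset, dur, by = bin)
  if (breaks[length(breaks)] < dur) breaks <- c(breaks, dur)
  tt <- unlist(trains, use.names = FALSE)
  tt <- tt[tt >= offset & tt <= dur]
  idx <- findInterval(tt, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  widths <- diff(breaks)
  structure(list(breaks = breaks, counts = counts,
                 rate = counts / (length(trains) * widths / 1000),
                 bin = bin, offset = offset, n_units = length(trains)),
            class = "sr_peth")
}

#' Shifted-PETH correlation between two spike sets
#'
#' Pearson correlation between the population PETHs of `a` and `b`,
#' averaged across `bin - 1` histograms whose start offsets increase in
#' 1 ms steps (offsets `0 ... bin - 2`), to avoid initial-phase bias.
#' Offsets where either histogram has zero variance are skipped with a
#' warning.
#'
#' @param a,b `sr_trains` over the same duration.
#' @param bin PETH bin size (ms).
#' @param rate correlate rate-based histograms (scaling leaves Pearson r
#'   unchanged except for the trailing partial bin).
#' @return Scalar in `[-1, 1]` (`NA` if every offset is degenerate).
#' @export
peth_correlation <- function(a, b, bin = 20, rate = FALSE) {
  stopifnot(abs(attr(a, "duration") - attr(b, "duration")) < 1e-9)
  offsets <- 0:(bin - 2)
  rs <- rep(NA_real_, length(offsets))
  skipped <- 0
  for (i in seq_along(offsets)) {
    pa <- peth(a, bin, offsets[i])
    pb <- peth(b, bin, offsets[i])
    va <- if (rate) pa$rate else pa$counts
    vb <- if (rate) pb$rate else pb$counts
    if (sd(va) == 0 || sd(vb) == 0) {
      skipped <- skipped + 1
      next
    }
    rs[i] <- cor(va, vb)
  }
  if (skipped > 0) {
    warning(skipped, " offsets skipped (zero-variance histogram)")
  }
  if (all(is.na(rs))) NA_real_ else mean(rs, na.rm = TRUE)
}

#' Behavioral metrics of a reach
#'
#' Final distance between the hand at trial end and the target, and the
#' mean point-wise distance between the trajectory and a reference
#' trajectory after linear resampling to a common 1 ms grid.  When the
#' durations differ, the comparison is restricted to the shorter one with
#' a warning.
#'
#' @param traj,reference data frames with columns `t`, `x`, `y` (ms, cm).
#' @param target target position (cm).
#' @return Named numeric: `final_distance`, `mean_pointwise` (cm).
#' @export
behavioral_metrics <- function(traj, reference, target) {
  fin <- c(traj$x[nrow(traj)], traj$y[nrow(traj)])
  final <- sqrt(sum((fin - target)^2))
  t_max <- min(max(traj$t), max(reference$t))
  if (abs(max(traj$t) - max(reference$t)) > 1e-9) {
    warning("durations differ; point-wise distance restricted to ",
            t_max, " ms")
  }
  g <- seq(0, t_max, by = 1)
  ax <- approx(traj$t, traj$x, g)$y
  ay <- approx(traj$t, traj$y, g)$y
  bx <- approx(reference$t, reference$x, g)$y
  by <- approx(reference$t, reference$y, g)$y
  c(final_distance = final,
    mean_pointwise = mean(sqrt((ax - bx)^2 + (ay - by)^2)))
}

#' PETH-correlation improvement across bin sizes
#'
#' For each bin size, the rate-based shifted-PETH correlation of the
#' repaired condition with the original, minus that of the lesioned
#' condition with the original.
#'
#' @param original,lesioned,repaired `sr_trains` of the motor population.
#' @param bins bin sizes to sweep (ms).
#' @return Data frame with columns `bin`, `r_lesioned`, `r_repaired`,
#'   `improvement`.
#' @export
bin_size_sweep <- function(original, lesioned, repaired,
                           bins = c(5, 10, 20, 30, 40, 50)) {
  stopifnot(all(bins > 0))
  rows <- lapply(bins, function(b) {
    rl <- suppressWarnings(peth_correlation(original, lesioned, b, rate = TRUE))
    rr <- suppressWarnings(peth_correlation(original, repaired, b, rate = TRUE))
    data.frame(bin = b, r_lesioned = rl, r_repaired = rr,
               improvement = rr - rl)
  })
  do.call(rbind, rows)
}

#' Perturbation-versus-metric correlation study
#'
#' Applies `n_perturbations` random lesions to the trained network,
#' equally distributed over targets x lesion types (cell, synapse) x
#' fractions, runs one trial per lesion, computes the three spike-train
#' metrics against the original EM activity and the two behavioral
#' metrics against the original trajectory, and reports the Pearson
#' correlation of every spike-metric / behavioral-metric pair.
#'
#' @param net trained `sr_network`.
#' @param arm an [arm_params()].
#' @param targets list of [reach_target()]s (one entry per target).
#' @param n_perturbations total lesion count, divisible by
#'   `2 * length(targets) * length(fractions)`.
#' @param seed campaign seed.
#' @param fractions lesion fractions.
#' @return List with `table` (one row per perturbation), `correlations`
#'   (3 x 2 matrix of Pearson r), `p_values`, `mean_abs_R`,
#'   `strongest_R`.
#' @export
perturbation_correlation_study <- function(net, arm, targets,
                                           n_perturbations = 80, seed = 1L,
                                           fractions = c(0.05, 0.10)) {
  combos <- expand.grid(target = seq_along(targets),
                        type = c("cell", "synapse"),
                        fraction = fractions, stringsAsFactors = FALSE)
  stopifnot(n_perturbations %% nrow(combos) == 0)
  reps <- n_perturbations / nrow(combos)
  em <- population_ids(net, "EM")
  originals <- lapply(targets, function(tg) {
    run_trial(net, arm, tg, seed = derive_seed(seed, paste0("orig", tg$label)))
  })
  rows <- list()
  idx <- 0
  for (ci in seq_len(nrow(combos))) {
    for (r in seq_len(reps)) {
      idx <- idx + 1
      cb <- combos[ci, ]
      tg <- targets[[cb$target]]
      les_seed <- derive_seed(seed, paste0("lesion", idx))
      lesioned <- if (cb$type == "cell") {
        apply_cell_lesion(net, cb$fraction, les_seed)
      } else {
        apply_synapse_lesion(net, cb$fraction, les_seed)
      }
      trial <- run_trial(lesioned, arm, tg,
                         seed = derive_seed(seed, paste0("trial", idx)))
      orig <- originals[[cb$target]]
      oa <- subset_spikes(orig$spikes, em)
      ob <- subset_spikes(trial$spikes, em)
      beh <- behavioral_metrics(trial$trajectory, orig$trajectory,
                                tg$position)
      rows[[idx]] <- data.frame(
        target = tg$label, type = cb$type, fraction = cb$fraction,
        spike_dist = spike_distance(oa, ob),
        spike_sync = spike_sync(oa, ob),
        peth_r = suppressWarnings(peth_correlation(oa, ob)),
        final_distance = beh[["final_distance"]],
        mean_pointwise = beh[["mean_pointwise"]])
    }
  }
  tab <- do.call(rbind, rows)
  sm <- c("spike_dist", "spike_sync", "peth_r")
  bm <- c("final_distance", "mean_pointwise")
  cors <- matrix(NA_real_, 3, 2, dimnames = list(sm, bm))
  pv <- cors
  for (i in sm) {
    for (j in bm) {
      ct <- stats::cor.test(tab[[i]], tab[[j]])
      cors[i, j] <- unname(ct$estimate)
      pv[i, j] <- ct$p.value
    }
  }
  list(table = tab, correlations = cors, p_values = pv,
       mean_abs_R = mean(abs(cors)), strongest_R = cors[which.max(abs(cors))])
}
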