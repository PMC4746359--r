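#' Delay-embedding configuration for the inverse model
#'
#' The stimulation window is fixed at `[100, 300]` ms.  The forward-delay
#' embedding `D` is the expected duration of the stimulation effect:
#' reach duration minus the stimulation end (600 - 300 = 300 ms for the
#' left target, 500 - 300 = 200 ms for the bottom target).  At step `t`
#' the model input is the EM response in `[t - h(t), t + D]` with history
#' `h(t) = min(t, D)` (100 ms at onset, growing to match the forward
#' window); windows are represented on a fixed relative grid of length
#' `2 D`, zero-padded where the history is shorter.
#'
#' @param target a [reach_target()] (supplies the reach duration).
#' @param stim_start,stim_end stimulation window (ms).
#' @param step pair-construction step (ms); 1 ms reproduces the full
#'   sliding-window set, larger values subsample it.
#' @return List of class `sr_embedding` with `D`, `stim_start`,
#'   `stim_end`, `step`, `duration`.
#' @export
embedding_config <- function(target, stim_start = 100, stim_end = 300,
                             step = 1) {
  D <- target$duration - stim_end
  stopifnot(D > 0, stim_end <= target$duration)
  structure(list(D = D, stim_start = stim_start, stim_end = stim_end,
                 step = step, duration = target$duration),
            class = "sr_embedding")
}

# the sliding history+forward window at step t, on the fixed relative
# grid [t - D, t + D] (spikes before trial start are simply absent)
embed_window <- function(em_trains, t, emb) {
  spike_window(em_trains, t - emb$D, t + emb$D)
}

#' Single-cell probing campaign
#'
#' One probe trial per surviving ES cell: the cell is stimulated at
#' `rate` Hz for `duration` ms starting `onset` ms after trial onset, and
#' the full lesioned-network response is recorded.
#'
#' @param lesioned lesioned `sr_network` (with the trained weights).
#' @param arm an [arm_params()].
#' @param target a [reach_target()].
#' @param seed campaign seed.
#' @param rate,duration,onset probe stimulation parameters.
#' @return List of probe records, each with `pattern` (the commanded
#'   [stim_pattern()]), `trial` (the [run_trial()] record) and `cells`.
#' @export
generate_single_cell_probes <- function(lesioned, arm, target, seed = 1L,
                                        rate = 250, duration = 200,
                                        onset = 100) {
  surviving <- setdiff(population_ids(lesioned, "ES"), lesioned$silenced)
  lapply(surviving, function(cell) {
    pat <- stim_pattern(cell, onset, duration, rate)
    trial <- run_trial(lesioned, arm, target,
                       seed = derive_seed(seed, paste0("probe_cell", cell)),
                       stim = pat)
    list(pattern = pat, trial = trial, cells = cell)
  })
}

#' Multi-cell probing campaign
#'
#' Each probe stimulates 1-10 uniformly chosen surviving ES cells from
#' `onset`, with a duration drawn uniformly on `[100, 500]` ms (truncated
#' so the stimulation fits in the trial).
#'
#' @param lesioned lesioned `sr_network`.
#' @param arm,target,seed as in [generate_single_cell_probes()].
#' @param n_probes number of probes.
#' @param rate generator rate (Hz).
#' @param onset probe onset (ms).
#' @param max_cells largest number of cells per probe.
#' @return List of probe records.
#' @export
generate_multicell_probes <- function(lesioned, arm, target, n_probes = 200,
                                      seed = 1L, rate = 250, onset = 100,
                                      max_cells = 10) {
  stopifnot(n_probes >= 0)
  surviving <- setdiff(population_ids(lesioned, "ES"), lesioned$silenced)
  dur_hi <- min(500, target$duration - onset)
  draws <- with_seed(derive_seed(seed, "multicell_probes"), {
    lapply(seq_len(n_probes), function(i) {
      k <- sample.int(min(max_cells, length(surviving)), 1)
      list(cells = sort(sample(surviving, k)),
           duration = runif(1, 100, dur_hi))
    })
  })
  lapply(seq_along(draws), function(i) {
    d <- draws[[i]]
    pat <- stim_pattern(d$cells, onset, d$duration, rate)
    trial <- run_trial(lesioned, arm, target,
                       seed = derive_seed(seed, paste0("probe_multi", i)),
                       stim = pat)
    list(pattern = pat, trial = trial, cells = d$cells)
  })
}

# commanded ES rate vector (length = ES population size) at time t
commanded_rates <- function(pattern, es_ids, t) {
  r <- numeric(length(es_ids))
  if (!is.null(pattern$entries)) {
    e <- pattern$entries
    on <- t >= e$onset & t < e$onset + e$duration
    if (any(on)) {
      r[match(e$cell[on], es_ids)] <- e$rate[on]
    }
  } else if (!is.null(pattern$rates)) {
    col <- floor(t - pattern$t_start) + 1
    if (col >= 1 && col <= ncol(pattern$rates)) {
      r[match(pattern$cells, es_ids)] <- pattern$rates[, col]
    }
  }
  r
}

#' Build (response window, stimulation rates) training pairs
#'
#' For every probe and every step `t` in `[stim_start, stim_end)`, the
#' input is the EM spike window `[t - h(t), t + D]` (history
#' `h(t) = min(t, D)`) and the target is the commanded length-`m` vector
#' of ES stimulation rates at `t` (the probe's rate on stimulated cells
#' during their stimulation interval, 0 elsewhere).
#'
#' @param probes probe records from [generate_single_cell_probes()] or
#'   [generate_multicell_probes()].
#' @param embedding an [embedding_config()].
#' @param net the probed network (supplies EM/ES ids).
#' @return List with `inputs` (spike windows), `targets` (pairs x m rate
#'   matrix), `times`, `probe` (index).
#' @export
make_training_pairs <- function(probes, embedding, net) {
  em <- population_ids(net, "EM")
  es <- population_ids(net, "ES")
  steps <- seq(embedding$stim_start, embedding$stim_end - 1,
               by = embedding$step)
  keep <- vapply(probes, function(pr) {
    ok <- pr$trial$spikes$duration >= embedding$duration
    if (!ok) warning("probe shorter than the embedding needs; skipped")
    ok
  }, logical(1))
  probes <- probes[keep]
  n_pairs <- length(probes) * length(steps)
  inputs <- vector("list", n_pairs)
  targets <- matrix(0, n_pairs, length(es))
  times <- integer(n_pairs)
  pidx <- integer(n_pairs)
  r <- 0
  for (i in seq_along(probes)) {
    pr <- probes[[i]]
    em_tr <- subset_spikes(pr$trial$spikes, em)
    for (t in steps) {
      r <- r + 1
      inputs[[r]] <- embed_window(em_tr, t, embedding)
      targets[r, ] <- commanded_rates(pr$pattern, es, t)
      times[r] <- t
      pidx[r] <- i
    }
  }
  list(inputs = inputs, targets = targets, times = times, probe = pidx)
}

#' Train the inverse model of the lesioned motor layer
#'
#' QKLMS over the shuffled training pairs, mapping EM response windows
#' (multi-unit Schoenberg kernel, `a_lambda = 0.05` by default, selectable
#' by k-fold cross-validation over a grid) to commanded ES stimulation
#' rate vectors.
#'
#' @param pairs output of [make_training_pairs()].
#' @param embedding the [embedding_config()] used to build the pairs.
#' @param seed shuffle seed.
#' @param a_lambda kernel parameter, or a numeric grid to select from by
#'   cross-validation when `cv_folds > 1`.
#' @param eta learning rate (normalized LMS step).
#' @param eps quantization size as a fraction of `sqrt(2 N)` (the
#'   kernel-metric diameter); `0` disables quantization.
#' @param cap center cap.
#' @param cv_folds folds for `a_lambda` selection (1 = no selection).
#' @param passes training passes.
#' @param dt intensity grid step for the spike kernel (ms).
#' @return Object of class `sr_inverse`: fields `model` (an [kaf_model()]),
#'   `embedding`, `a_lambda`, `error_trace`.
#' @export
train_inverse_model <- function(pairs, embedding, seed = 1L,
                                a_lambda = 0.05, eta = 0.5, eps = 0.45,
                                cap = 400, cv_folds = 1, passes = 1,
                                dt = 1) {
  if (length(pairs$inputs) == 0) stop("input error: no training pairs")
  m <- ncol(pairs$targets)
  N <- pairs$inputs[[1]]$n_units
  fit <- function(al, inputs, targets) {
    mod <- kaf_model("spike", m = m, a_lambda = al, eta = eta,
                     eps = eps * sqrt(2 * N), cap = cap,
                     normalize = TRUE, T = embedding$D, dt = dt)
    kaf_train(mod, inputs, targets, shuffle_seed = seed, passes = passes)
  }
  if (length(a_lambda) > 1 && cv_folds > 1) {
    folds <- with_seed(derive_seed(seed, "cv"),
                       sample(rep_len(seq_len(cv_folds),
                                      length(pairs$inputs))))
    score <- vapply(a_lambda, function(al) {
      mse <- 0
      for (f in seq_len(cv_folds)) {
        tr <- which(folds != f)
        te <- which(folds == f)
        mod <- fit(al, pairs$inputs[tr],
                   pairs$targets[tr, , drop = FALSE])
        pred <- t(vapply(pairs$inputs[te],
                         function(u) kaf_predict(mod, u), numeric(m)))
        mse <- mse + mean((pred - pairs$targets[te, , drop = FALSE])^2)
      }
      mse / cv_folds
    }, numeric(1))
    a_lambda <- a_lambda[which.min(score)]
  } else {
    a_lambda <- a_lambda[1]
  }
  mod <- fit(a_lambda, pairs$inputs, pairs$targets)
  structure(list(model = mod, embedding = embedding, a_lambda = a_lambda,
                 m = m, error_trace = mod$error_trace),
            class = "sr_inverse")
}

#' @export
print.sr_inverse <- function(x, ...) {
  cat("<sr_inverse> ", x$model$n_centers, " centers, m = ", x$m,
      " output channels, a_lambda = ", x$a_lambda, "\n", sep = "")
  invisible(x)
}

#' Derive a repair stimulation pattern from a desired EM response
#'
#' Slides the history+forward embedding window over the desired
#' (pre-lesion) EM spike set, predicts the ES stimulation rate vector at
#' each 1 ms step of the allowed window `[100, 300)` ms, clips negative
#' rates to zero and zeroes rates below `threshold`, and assembles the
#' dense rate-matrix pattern.
#'
#' @param inv an `sr_inverse`.
#' @param desired `sr_trains` of the pre-lesion EM population over the
#'   full trial.
#' @param es_ids ES cell ids (columns of the model output).
#' @param threshold small-rate cutoff (Hz).
#' @param step prediction step (ms); rates are held between steps.
#' @return An [stim_pattern_matrix()] over `[stim_start, stim_end)`.
#' @export
derive_stimulation <- function(inv, desired, es_ids, threshold = 10,
                               step = NULL) {
  emb <- inv$embedding
  if (attr(desired, "duration") < emb$duration) {
    stop("input error: desired response shorter than the embedding needs")
  }
  if (is.null(step)) step <- emb$step
  n_col <- emb$stim_end - emb$stim_start
  rates <- matrix(0, length(es_ids), n_col)
  ts <- seq(emb$stim_start, emb$stim_end - 1, by = step)
  for (i in seq_along(ts)) {
    t <- ts[i]
    w <- embed_window(desired, t, emb)
    r <- pmax(0, kaf_predict(inv$model, w))
    r[r < threshold] <- 0
    c0 <- t - emb$stim_start + 1
    c1 <- if (i < length(ts)) ts[i + 1] - emb$stim_start else n_col
    rates[, c0:c1] <- r
  }
  stim_pattern_matrix(rates, es_ids, t_start = emb$stim_start)
}
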