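#' Campaign configuration
#'
#' Assembles the scenario grid (targets x lesion types x fractions) and
#' all module settings.  The `"full"` preset uses the complete network
#' (704 units) and the full probing protocol; the `"mini"` preset shrinks
#' the populations by an integer factor (keeping the 4-group structure),
#' subsamples the training pairs in time and caps the inverse-model
#' centers, so that a complete train-lesion-probe-repair campaign runs in
#' minutes on one CPU.
#'
#' @param preset `"mini"` or `"full"`.
#' @param targets reach targets to train and repair.
#' @param lesion_types `"cell"`, `"synapse"` or both.
#' @param fractions lesion fractions.
#' @param ... overrides for individual fields (`scale`, `episodes`,
#'   `n_multicell`, `pair_step`, `eps`, `cap`, `eta`, `a_lambda`
#'   (fixed per preset to the value selected once by k-fold
#'   cross-validation on probe data), `kernel_dt`, `stim_threshold`,
#'   `n_perturbations`, `rlstdp`).
#' @return List of class `sr_experiment_config`.
#' @export
experiment_config <- function(preset = c("mini", "full"),
                              targets = c("left", "bottom"),
                              lesion_types = c("cell", "synapse"),
                              fractions = c(0.05, 0.10), ...) {
  preset <- match.arg(preset)
  base <- if (preset == "mini") {
    list(scale = 4, episodes = 400, n_multicell = 12, pair_step = 8,
         eps = 0.45, cap = 140, eta = 0.5, a_lambda = 10,
         kernel_dt = 2, stim_threshold = 25, n_perturbations = 40,
         rlstdp = rlstdp_config(lr = 0.1, lr_half = 100, p_bump = 0.25))
  } else {
    list(scale = 1, episodes = 800, n_multicell = 200, pair_step = 1,
         eps = 0.45, cap = 400, eta = 0.5, a_lambda = 10,
         kernel_dt = 1, stim_threshold = 25, n_perturbations = 800,
         rlstdp = rlstdp_config(lr = 0.1, lr_half = 200, p_bump = 0.25))
  }
  over <- list(...)
  stopifnot(all(names(over) %in% names(base)))
  base[names(over)] <- over
  cfg <- c(list(preset = preset, targets = targets,
                lesion_types = lesion_types, fractions = fractions),
           base)
  class(cfg) <- "sr_experiment_config"
  cfg
}

#' Read a campaign configuration from a YAML file
#'
#' @param file YAML file; top-level keys are [experiment_config()]
#'   arguments.
#' @return An `sr_experiment_config`.
#' @export
read_experiment_config <- function(file) {
  y <- yaml::read_yaml(file)
  do.call(experiment_config, y)
}

#' Build the trained baseline bundle
#'
#' Builds the network at the preset's scale, trains one copy per target
#' with reward-modulated STDP and records the original (pre-lesion)
#' trials that serve as the repair reference.
#'
#' @param preset `"mini"` or `"full"`, or an [experiment_config()].
#' @param seed campaign seed.
#' @return List of class `sr_fixture` with `config`, `arm`, `nets`
#'   (per-target trained networks), `originals` (per-target reference
#'   trials), `targets`, `seed`.
#' @export
make_fixture <- function(preset = "mini", seed = 1L) {
  cfg <- if (inherits(preset, "sr_experiment_config")) {
    preset
  } else {
    if (!preset %in% c("mini", "full")) stop("input error: unknown preset")
    experiment_config(preset)
  }
  arm <- arm_params()
  net0 <- build_network(network_config(scale = cfg$scale),
                        seed = derive_seed(seed, "construct"))
  targets <- lapply(cfg$targets, reach_target, params = arm)
  names(targets) <- cfg$targets
  nets <- list()
  originals <- list()
  rl <- if (is.null(cfg$rlstdp)) rlstdp_config() else cfg$rlstdp
  for (tg in targets) {
    trained <- train_reaching(net0, arm, tg, episodes = cfg$episodes,
                              config = rl,
                              seed = derive_seed(seed, paste0("train_", tg$label)))
    nets[[tg$label]] <- trained
    originals[[tg$label]] <-
      run_trial(trained, arm, tg,
                seed = derive_seed(seed, paste0("orig_", tg$label)))
  }
  structure(list(config = cfg, arm = arm, nets = nets,
                 originals = originals, targets = targets,
                 seed = as.integer(seed)),
            class = "sr_fixture")
}

#' Run one lesion-probe-repair scenario
#'
#' @param fixture an [make_fixture()] bundle.
#' @param target target label.
#' @param type `"cell"` or `"synapse"`.
#' @param fraction lesion fraction.
#' @param seed scenario seed.
#' @return List with the lesioned network, probe records, inverse model,
#'   repair pattern, the lesioned and repaired trials, and the metric
#'   report row.
#' @export
run_scenario <- function(fixture, target, type, fraction, seed = 1L) {
  cfg <- fixture$config
  tg <- fixture$targets[[target]]
  net <- fixture$nets[[target]]
  orig <- fixture$originals[[target]]
  em <- population_ids(net, "EM")
  es <- population_ids(net, "ES")

  lesioned <- if (type == "cell") {
    apply_cell_lesion(net, fraction, derive_seed(seed, "lesion"))
  } else {
    apply_synapse_lesion(net, fraction, derive_seed(seed, "lesion"))
  }
  les_trial <- run_trial(lesioned, arm = fixture$arm, target = tg,
                         seed = derive_seed(seed, "les_trial"))

  probes <- c(
    generate_single_cell_probes(lesioned, fixture$arm, tg,
                                seed = derive_seed(seed, "probes")),
    generate_multicell_probes(lesioned, fixture$arm, tg,
                              n_probes = cfg$n_multicell,
                              seed = derive_seed(seed, "probes")))
  emb <- embedding_config(tg, step = cfg$pair_step)
  pairs <- make_training_pairs(probes, emb, lesioned)
  inv <- train_inverse_model(pairs, emb, seed = derive_seed(seed, "fit"),
                             a_lambda = cfg$a_lambda, eta = cfg$eta,
                             eps = cfg$eps, cap = cfg$cap,
                             dt = if (is.null(cfg$kernel_dt)) 1 else cfg$kernel_dt)
  desired <- subset_spikes(orig$spikes, em)
  pattern <- derive_stimulation(inv, desired, es,
                                threshold = cfg$stim_threshold,
                                step = cfg$pair_step)
  # the repaired trial reuses the lesioned trial's seed so that, before
  # stimulation onset, the two runs are spike-identical
  rep_trial <- run_trial(lesioned, arm = fixture$arm, target = tg,
                         seed = derive_seed(seed, "les_trial"),
                         stim = pattern)

  oa <- subset_spikes(orig$spikes, em)
  report <- data.frame(
    target = target, type = type, fraction = fraction,
    spike_dist_lesioned = spike_distance(oa, subset_spikes(les_trial$spikes, em)),
    spike_dist_repaired = spike_distance(oa, subset_spikes(rep_trial$spikes, em)),
    spike_sync_lesioned = spike_sync(oa, subset_spikes(les_trial$spikes, em)),
    spike_sync_repaired = spike_sync(oa, subset_spikes(rep_trial$spikes, em)),
    peth_r_lesioned = suppressWarnings(
      peth_correlation(oa, subset_spikes(les_trial$spikes, em))),
    peth_r_repaired = suppressWarnings(
      peth_correlation(oa, subset_spikes(rep_trial$spikes, em))),
    final_dist_original = final_distance(orig),
    final_dist_lesioned = final_distance(les_trial),
    final_dist_repaired = final_distance(rep_trial),
    pointwise_lesioned = behavioral_metrics(
      les_trial$trajectory, orig$trajectory, tg$position)[["mean_pointwise"]],
    pointwise_repaired = behavioral_metrics(
      rep_trial$trajectory, orig$trajectory, tg$position)[["mean_pointwise"]])

  list(lesioned = lesioned, probes = probes, inverse = inv,
       pattern = pattern, les_trial = les_trial, rep_trial = rep_trial,
       report = report, seed = as.integer(seed))
}

#' Run the full lesion-repair campaign
#'
#' Per scenario of the grid: lesion the trained baseline, probe the
#' surviving cells, fit the inverse model, derive and apply the repair
#' stimulation, and compute the metric report.  A failing scenario is
#' recorded and the campaign continues.
#'
#' @param config an [experiment_config()].
#' @param seed campaign seed.
#' @param fixture optionally a prebuilt [make_fixture()] (must match the
#'   config).
#' @param keep_details keep per-scenario objects (networks, probes,
#'   trials); set `FALSE` to save memory.
#' @return List of class `sr_campaign`: `reports` (one row per scenario),
#'   `details`, `fixture`, `failed`, `manifest`.
#' @export
run_experiment <- function(config = experiment_config("mini"), seed = 1L,
                           fixture = NULL, keep_details = TRUE) {
  if (is.null(fixture)) fixture <- make_fixture(config, seed)
  grid <- expand.grid(target = config$targets, type = config$lesion_types,
                      fraction = config$fractions,
                      stringsAsFactors = FALSE)
  reports <- list()
  details <- list()
  failed <- character(0)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    label <- paste(g$target, g$type, g$fraction, sep = "_")
    res <- tryCatch(
      run_scenario(fixture, g$target, g$type, g$fraction,
                   seed = derive_seed(seed, paste0("scenario_", label))),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("scenario ", label, " failed: ", conditionMessage(res))
      failed <- c(failed, label)
      next
    }
    reports[[label]] <- res$report
    if (keep_details) details[[label]] <- res else details[label] <- list(NULL)
  }
  structure(list(reports = do.call(rbind, reports), details = details,
                 fixture = fixture, failed = failed,
                 manifest = list(seed = as.integer(seed), config = config,
                                 date = format(Sys.time(), "%Y-%m-%d"))),
            class = "sr_campaign")
}

#' Write campaign report files
#'
#' Writes the summary metric CSV and figure files (trajectory overlays,
#' metric bars, PETH bin-size sweep, and the perturbation scatter when
#' present) to `out_dir`.
#'
#' @param campaign an `sr_campaign` from [run_experiment()], or a bare
#'   metric-report data frame.
#' @param out_dir output directory (created if needed).
#' @param perturbation optional result of
#'   [perturbation_correlation_study()] to include as a scatter figure.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(campaign, out_dir, perturbation = NULL) {
  reports <- if (is.data.frame(campaign)) campaign else campaign$reports
  if (is.null(reports) || nrow(reports) == 0) {
    stop("input error: no reports to write")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, "summary.csv")
  write.csv(reports, paths, row.names = FALSE)

  full <- !is.data.frame(campaign) && length(campaign$details) > 0 &&
    !all(vapply(campaign$details, is.null, logical(1)))
  if (full) {
    f <- file.path(out_dir, "trajectories.pdf")
    grDevices::pdf(f, width = 8, height = 6)
    par(mfrow = c(2, 4), mar = c(3, 3, 2, 1))
    for (nm in names(campaign$details)) {
      d <- campaign$details[[nm]]
      if (is.null(d)) next
      tg <- d$les_trial$target
      orig <- campaign$fixture$originals[[tg$label]]
      xl <- range(orig$trajectory$x, d$les_trial$trajectory$x,
                  d$rep_trial$trajectory$x, tg$position[1])
      yl <- range(orig$trajectory$y, d$les_trial$trajectory$y,
                  d$rep_trial$trajectory$y, tg$position[2])
      plot(orig$trajectory$x, orig$trajectory$y, type = "l", col = "black",
           xlim = xl, ylim = yl, xlab = "x (cm)", ylab = "y (cm)",
           main = nm, cex.main = 0.8)
      lines(d$les_trial$trajectory$x, d$les_trial$trajectory$y, col = "red")
      lines(d$rep_trial$trajectory$x, d$rep_trial$trajectory$y,
            col = "forestgreen")
      points(tg$position[1], tg$position[2], pch = 1, col = "darkgreen",
             cex = 2)
    }
    grDevices::dev.off()
    paths <- c(paths, f)
  }

  f <- file.path(out_dir, "metrics.pdf")
  grDevices::pdf(f, width = 9, height = 4)
  par(mfrow = c(1, 3), mar = c(7, 4, 2, 1))
  lab <- paste(reports$target, reports$type, reports$fraction)
  for (metric in c("final_dist", "spike_sync", "peth_r")) {
    m <- rbind(reports[[paste0(metric, "_lesioned")]],
               reports[[paste0(metric, "_repaired")]])
    barplot(m, beside = TRUE, names.arg = lab, las = 2,
            col = c("red", "forestgreen"), main = metric, cex.names = 0.7)
  }
  grDevices::dev.off()
  paths <- c(paths, f)

  if (!is.null(perturbation)) {
    f <- file.path(out_dir, "perturbation_scatter.pdf")
    grDevices::pdf(f, width = 9, height = 6)
    par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
    for (bmet in c("final_distance", "mean_pointwise")) {
      for (smet in c("spike_dist", "spike_sync", "peth_r")) {
        plot(perturbation$table[[smet]], perturbation$table[[bmet]],
             xlab = smet, ylab = bmet, pch = 16, cex = 0.6,
             main = sprintf("R = %.2f",
                            perturbation$correlations[smet, bmet]))
      }
    }
    grDevices::dev.off()
    write.csv(perturbation$table,
              file.path(out_dir, "perturbations.csv"), row.names = FALSE)
    paths <- c(paths, f)
  }
  invisible(paths)
}
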