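#' Serialize a network to JSON metadata + CSV synapse table
#'
#' @param net an `sr_network`.
#' @param prefix path prefix; writes `<prefix>.json` and
#'   `<prefix>_synapses.csv`.
#' @return Invisibly, the two paths.
#' @export
write_network <- function(net, prefix) {
  meta <- list(
    pops = net$pops, seed = net$seed, silenced = net$silenced,
    config = net$config[c("sizes", "neuron", "receptors", "background",
                          "dt", "allow_self", "w_max", "scale")],
    conn = net$config$conn)
  jp <- paste0(prefix, ".json")
  cp <- paste0(prefix, "_synapses.csv")
  jsonlite::write_json(meta, jp, auto_unbox = TRUE, digits = NA)
  write.csv(net$syn, cp, row.names = FALSE)
  invisible(c(jp, cp))
}

#' Read a network written by [write_network()]
#'
#' @param prefix path prefix used when writing.
#' @return An `sr_network`.
#' @export
read_network <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  syn <- read.csv(paste0(prefix, "_synapses.csv"))
  cfg <- meta$config
  cfg$sizes <- unlist(cfg$sizes)
  cfg$conn <- meta$conn
  pops <- as.data.frame(meta$pops)
  structure(list(config = cfg, seed = as.integer(meta$seed), pops = pops,
                 n_neuron = sum(pops$size[pops$label != "P"]),
                 n_p = pops$size[pops$label == "P"], syn = syn,
                 silenced = as.integer(unlist(meta$silenced)),
                 stim = NULL),
            class = "sr_network")
}

#' Write spike trains to CSV (+ JSON sidecar)
#'
#' @param spikes an `sr_spikes`.
#' @param prefix path prefix; writes `<prefix>.csv` (columns
#'   `unit_id, time_ms`, sorted) and `<prefix>.json`.
#' @return Invisibly, the paths.
#' @export
write_spikes <- function(spikes, prefix) {
  df <- data.frame(
    unit_id = rep(seq_len(spikes$n_units), lengths(spikes$trains)),
    time_ms = unlist(spikes$trains, use.names = FALSE))
  df <- df[order(df$unit_id, df$time_ms), ]
  cp <- paste0(prefix, ".csv")
  jp <- paste0(prefix, ".json")
  write.csv(df, cp, row.names = FALSE)
  jsonlite::write_json(list(duration = spikes$duration,
                            n_units = spikes$n_units, seed = spikes$seed,
                            pops = spikes$pops),
                       jp, auto_unbox = TRUE, digits = NA)
  invisible(c(cp, jp))
}

#' Read spike trains written by [write_spikes()]
#'
#' @param prefix path prefix.
#' @return An `sr_spikes`.
#' @export
read_spikes <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  df <- read.csv(paste0(prefix, ".csv"))
  f <- factor(df$unit_id, levels = seq_len(meta$n_units))
  structure(list(duration = meta$duration, n_units = meta$n_units,
                 trains = split(df$time_ms, f),
                 pops = as.data.frame(meta$pops),
                 seed = as.integer(meta$seed),
                 stim_spikes = NULL),
            class = "sr_spikes")
}

#' Write a hand trajectory to CSV
#'
#' @param trial an `sr_trial` (or a `t, x, y` data frame).
#' @param file output CSV (`t_ms, x_cm, y_cm`).
#' @return Invisibly, `file`.
#' @export
write_trajectory <- function(trial, file) {
  df <- if (inherits(trial, "sr_trial")) trial$trajectory else trial
  names(df) <- c("t_ms", "x_cm", "y_cm")
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Write a stimulation pattern as sparse CSV triplets + JSON manifest
#'
#' @param pattern an `sr_stim_pattern`.
#' @param prefix path prefix.
#' @return Invisibly, the paths.
#' @export
write_stim_pattern <- function(pattern, prefix) {
  if (!is.null(pattern$entries)) {
    e <- pattern$entries
    tri <- do.call(rbind, lapply(seq_len(nrow(e)), function(i) {
      ts <- seq(floor(e$onset[i]), ceiling(e$onset[i] + e$duration[i]) - 1)
      data.frame(cell_id = e$cell[i], t_ms = ts, rate_hz = e$rate[i])
    }))
    kind <- "entries"
  } else {
    nz <- which(pattern$rates > 0, arr.ind = TRUE)
    tri <- data.frame(cell_id = pattern$cells[nz[, 1]],
                      t_ms = pattern$t_start + nz[, 2] - 1,
                      rate_hz = pattern$rates[nz])
    tri <- tri[order(tri$cell_id, tri$t_ms), ]
    kind <- "matrix"
  }
  cp <- paste0(prefix, ".csv")
  jp <- paste0(prefix, ".json")
  write.csv(tri, cp, row.names = FALSE)
  jsonlite::write_json(list(kind = kind, t_start = pattern$t_start,
                            cells = pattern$cells),
                       jp, auto_unbox = TRUE, digits = NA)
  invisible(c(cp, jp))
}

#' Serialize an inverse model
#'
#' Writes a JSON manifest (kernel/embedding parameters, schema version), a
#' CSV of center spike times (`center, unit, time_ms`) and a CSV of
#' coefficients (`center, channel, alpha`).
#'
#' @param inv an `sr_inverse`.
#' @param prefix path prefix.
#' @return Invisibly, the paths.
#' @export
write_inverse_model <- function(inv, prefix) {
  mod <- inv$model
  M <- mod$n_centers
  cen <- do.call(rbind, lapply(seq_len(M), function(i) {
    sp <- mod$windows[[i]]
    n <- lengths(sp)
    if (sum(n) == 0) return(NULL)
    data.frame(center = i, unit = rep(seq_along(sp), n),
               time_ms = unlist(sp, use.names = FALSE))
  }))
  if (is.null(cen)) {
    cen <- data.frame(center = integer(0), unit = integer(0),
                      time_ms = numeric(0))
  }
  co <- mod$coeff[seq_len(M), , drop = FALSE]
  codf <- data.frame(center = rep(seq_len(M), ncol(co)),
                     channel = rep(seq_len(ncol(co)), each = M),
                     alpha = as.vector(co))
  manifest <- list(schema = "sr_inverse/1", m = inv$m,
                   a_lambda = inv$a_lambda, eta = mod$eta, eps = mod$eps,
                   cap = mod$cap, n_centers = M, n_units = mod$N,
                   T = if (is.null(mod$T)) NA else mod$T, dt = mod$dt,
                   embedding = unclass(inv$embedding))
  jp <- paste0(prefix, ".json")
  jsonlite::write_json(manifest, jp, auto_unbox = TRUE, digits = NA)
  c1 <- paste0(prefix, "_centers.csv")
  c2 <- paste0(prefix, "_coeff.csv")
  write.csv(cen, c1, row.names = FALSE)
  write.csv(codf, c2, row.names = FALSE)
  invisible(c(jp, c1, c2))
}

#' Read an inverse model written by [write_inverse_model()]
#'
#' @param prefix path prefix.
#' @return An `sr_inverse` (centers' intensity representations are
#'   rebuilt from the stored spike times).
#' @export
read_inverse_model <- function(prefix) {
  man <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  if (!identical(man$schema, "sr_inverse/1")) {
    stop("input error: unknown inverse-model schema")
  }
  cen <- read.csv(paste0(prefix, "_centers.csv"))
  co <- read.csv(paste0(prefix, "_coeff.csv"))
  emb <- structure(as.list(man$embedding), class = "sr_embedding")
  mod <- kaf_model("spike", m = man$m, a_lambda = man$a_lambda,
                   eta = man$eta, eps = man$eps, cap = man$cap,
                   normalize = TRUE,
                   T = if (is.na(man$T)) NULL else man$T, dt = man$dt)
  len <- 2 * emb$D
  for (i in seq_len(man$n_centers)) {
    sp <- lapply(seq_len(man$n_units), function(u) {
      cen$time_ms[cen$center == i & cen$unit == u]
    })
    w <- structure(list(spikes = sp, len = len, n_units = man$n_units),
                   class = "sr_spike_window")
    kk <- kaf_kernels(mod, w)  # registers grid geometry
    kaf_append(mod, kk$feat, co$alpha[co$center == i])
  }
  structure(list(model = mod, embedding = emb, a_lambda = man$a_lambda,
                 m = man$m, error_trace = NULL),
            class = "sr_inverse")
}
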