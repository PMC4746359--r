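#' Estimate the intensity function of a spike train
#'
#' Smooths the spike times with a causal rectangular kernel of width `T`
#' and height `1/T`: `lambda(t) = sum_m g(t - t_m)` with
#' `g(t) = 1/T` on `[0, T)`.  Evaluated on a uniform grid.
#'
#' @param spike_times sorted spike times (ms).
#' @param grid uniform evaluation grid (ms).
#' @param T smoothing width (ms); should be much larger than the typical
#'   inter-spike interval.
#' @return An object of class `sr_intensity` with fields `grid`, `values`
#'   (1/ms), `T`, `times`, `M`.
#' @export
estimate_intensity <- function(spike_times, grid, T) {
  stopifnot(T > 0)
  if (is.unsorted(spike_times)) stop("input error: spike times must be sorted")
  if (length(grid) > 1) {
    dg <- diff(grid)
    if (max(dg) - min(dg) > 1e-9) stop("input error: grid must be uniform")
  }
  v <- (findInterval(grid, spike_times) -
          findInterval(grid - T, spike_times)) / T
  structure(list(grid = grid, values = v, T = T, times = spike_times,
                 M = length(spike_times)),
            class = "sr_intensity")
}

# trapezoid quadrature weights for a uniform grid
trap_weights <- function(grid) {
  n <- length(grid)
  if (n < 2) return(rep(0, n))
  h <- grid[2] - grid[1]
  w <- rep(h, n)
  w[c(1, n)] <- h / 2
  w
}

#' Schoenberg kernel between two intensity estimates
#'
#' `K(i, j) = exp(-a_lambda * integral (lambda_i(t) - lambda_j(t))^2 dt)`,
#' with the integral computed by the trapezoid rule on the shared grid.
#' Symmetric, bounded in `(0, 1]`, equal to 1 iff the intensities agree on
#' the grid.
#'
#' @param li,lj [estimate_intensity()] objects on the same grid.
#' @param a_lambda kernel parameter (> 0).
#' @return Scalar in `(0, 1]`.
#' @export
schoenberg_kernel <- function(li, lj, a_lambda = 0.05) {
  stopifnot(a_lambda > 0)
  if (length(li$grid) != length(lj$grid) ||
      any(abs(li$grid - lj$grid) > 1e-9)) {
    stop("input error: intensity estimates are on different grids")
  }
  w <- trap_weights(li$grid)
  exp(-a_lambda * sum(w * (li$values - lj$values)^2))
}

#' Multi-unit spike window
#'
#' Spike times of `n_units` units restricted to a window and expressed
#' relative to the window start, so that windows cut at different absolute
#' times are comparable.  Unit order is fixed and shared across windows.
#'
#' @param trains list of spike-time vectors (one per unit, absolute ms).
#' @param w_start,w_end window bounds (absolute ms).
#' @return Object of class `sr_spike_window` with fields `spikes`
#'   (relative times in `[0, len]`), `len`, `n_units`.
#' @export
spike_window <- function(trains, w_start, w_end) {
  stopifnot(w_end > w_start)
  sp <- lapply(trains, function(tt) tt[tt >= w_start & tt <= w_end] - w_start)
  structure(list(spikes = sp, len = w_end - w_start,
                 n_units = length(sp)),
            class = "sr_spike_window")
}

# window intensity matrix (grid points x units), cached on the object
window_intensity <- function(w, T, dt = 1) {
  if (!is.null(w$lam) && isTRUE(all.equal(w$lam_T, T)) &&
      isTRUE(all.equal(w$lam_dt, dt))) {
    return(w)
  }
  grid <- seq(0, w$len, by = dt)
  lam <- vapply(w$spikes,
                function(tt) estimate_intensity(tt, grid, T)$values,
                numeric(length(grid)))
  w$lam <- matrix(lam, nrow = length(grid))
  w$lam_T <- T
  w$lam_dt <- dt
  w$grid <- grid
  w
}

#' Multi-unit Schoenberg kernel
#'
#' Unweighted sum of the per-unit Schoenberg kernels:
#' `K(w_i, w_j) = sum_n K(s_i^n, s_j^n)`.  Bounded in `(0, N]` and equal
#' to `N` for identical windows.
#'
#' @param wi,wj [spike_window()]s with the same unit count and window
#'   length.
#' @param a_lambda kernel parameter.
#' @param T intensity smoothing width (ms); defaults to half the window
#'   length (the forward-response span).
#' @param dt intensity grid step (ms).
#' @return Scalar in `(0, N]`.
#' @export
multiunit_kernel <- function(wi, wj, a_lambda = 0.05, T = NULL, dt = 1) {
  if (wi$n_units != wj$n_units) {
    stop("input error: windows have different unit counts")
  }
  stopifnot(abs(wi$len - wj$len) < 1e-9)
  if (is.null(T)) T <- wi$len / 2
  wi <- window_intensity(wi, T, dt)
  wj <- window_intensity(wj, T, dt)
  tw <- trap_weights(wi$grid)
  d2 <- colSums(tw * (wi$lam - wj$lam)^2)
  sum(exp(-a_lambda * d2))
}

#' Gaussian kernel
#'
#' `K_a(u, v) = exp(-a * ||u - v||^2)`.
#'
#' @param u,v numeric vectors of equal length.
#' @param a kernel parameter (> 0).
#' @return Scalar in `(0, 1]`.
#' @export
gaussian_kernel <- function(u, v, a) {
  stopifnot(a > 0)
  if (length(u) != length(v)) stop("input error: dimension mismatch")
  exp(-a * sum((u - v)^2))
}
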