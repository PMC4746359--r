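#' Create a kernel adaptive filter (KLMS / QKLMS)
#'
#' A multi-output kernel least-mean-squares filter in representer form:
#' `f(u) = sum_i alpha_i K(u_i, u)`, with per-output-channel coefficients
#' and a shared center list.  Inputs are either numeric vectors (Gaussian
#' kernel) or multi-unit spike windows (multi-unit Schoenberg kernel).
#' Quantization merges an input into its nearest center (in the
#' kernel-induced metric `d^2 = K(u,u) + K(v,v) - 2 K(u,v)`) when that
#' distance falls below `eps`; `eps = 0` reproduces plain KLMS.
#'
#' The model uses reference semantics (an environment): [kaf_update()]
#' modifies and returns the same object.
#'
#' @param kind `"numeric"` or `"spike"`.
#' @param m output dimension.
#' @param a Gaussian kernel parameter (numeric mode).
#' @param a_lambda Schoenberg kernel parameter (spike mode).
#' @param eta learning rate.
#' @param eps quantization size (kernel-metric units).
#' @param cap maximum number of centers; at the cap every update merges
#'   into the nearest center.
#' @param normalize divide the step by `K(u, u)` (normalized LMS); the
#'   default for spike mode, where `K(u, u) = N` grows with the unit
#'   count.
#' @param T,dt intensity smoothing width and grid step for spike windows
#'   (ms); `T = NULL` defers to half the window length.
#' @return An object of class `sr_kaf`.
#' @export
kaf_model <- function(kind = c("numeric", "spike"), m = 1, a = 1,
                      a_lambda = 0.05, eta = 0.5, eps = 0, cap = Inf,
                      normalize = (kind == "spike"), T = NULL, dt = 1) {
  kind <- match.arg(kind)
  stopifnot(eta > 0, eps >= 0, a > 0, a_lambda > 0)
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$m <- as.integer(m)
  e$a <- a
  e$a_lambda <- a_lambda
  e$eta <- eta
  e$eps <- eps
  e$cap <- cap
  e$normalize <- isTRUE(normalize)
  e$T <- T
  e$dt <- dt
  e$n_centers <- 0L
  e$centers <- NULL       # numeric: d x cap_alloc; spike: (L*N) x cap_alloc
  e$coeff <- NULL         # cap_alloc x m
  e$windows <- list()     # spike mode: original windows, for serialization
  e$L <- NULL
  e$N <- NULL
  e$tw <- NULL
  class(e) <- "sr_kaf"
  e
}

#' @export
print.sr_kaf <- function(x, ...) {
  cat("<sr_kaf> ", x$kind, " kernel, ", x$n_centers, " centers, ",
      x$m, " output channels\n", sep = "")
  invisible(x)
}

# kernel vector against all stored centers, plus the self-kernel K(u, u)
kaf_kernels <- function(model, input) {
  M <- model$n_centers
  if (model$kind == "numeric") {
    u <- as.numeric(input)
    k <- if (M == 0) numeric(0) else {
      exp(-model$a * colSums((model$centers[, seq_len(M), drop = FALSE] - u)^2))
    }
    list(k = k, k_self = 1, feat = u)
  } else {
    stopifnot(inherits(input, "sr_spike_window"))
    T <- if (is.null(model$T)) input$len / 2 else model$T
    w <- window_intensity(input, T, model$dt)
    if (is.null(model$L)) {
      model$L <- nrow(w$lam)
      model$N <- ncol(w$lam)
      model$tw <- trap_weights(w$grid)
    }
    if (nrow(w$lam) != model$L || ncol(w$lam) != model$N) {
      stop("input error: window grid/unit count differs from the model's")
    }
    k <- if (M == 0) numeric(0) else {
      mu_kernel_block_cpp(model$centers[, seq_len(M)], model$L, model$N, M,
                          w$lam, model$a_lambda, model$tw)
    }
    list(k = k, k_self = model$N, feat = w)
  }
}

#' Predict with a kernel adaptive filter
#'
#' @param model an [kaf_model()].
#' @param input numeric vector or `sr_spike_window`, matching the model
#'   kind.
#' @return Numeric vector of length `m` (zeros for an empty model).
#' @export
kaf_predict <- function(model, input) {
  kk <- kaf_kernels(model, input)
  kaf_predict_k(model, kk$k)
}

kaf_predict_k <- function(model, k) {
  M <- model$n_centers
  if (M == 0) return(numeric(model$m))
  as.numeric(crossprod(model$coeff[seq_len(M), , drop = FALSE], k))
}

kaf_append <- function(model, feat, alpha) {
  M <- model$n_centers
  col <- if (model$kind == "numeric") feat else as.numeric(feat$lam)
  if (is.null(model$centers)) {
    alloc <- 256L
    model$centers <- matrix(0, length(col), alloc)
    model$coeff <- matrix(0, alloc, model$m)
  } else if (M + 1L > ncol(model$centers)) {
    model$centers <- cbind(model$centers,
                           matrix(0, nrow(model$centers), 256L))
    model$coeff <- rbind(model$coeff, matrix(0, 256L, model$m))
  }
  model$centers[, M + 1L] <- col
  model$coeff[M + 1L, ] <- alpha
  if (model$kind == "spike") {
    model$windows[[M + 1L]] <- feat$spikes
  }
  model$n_centers <- M + 1L
}

#' One stochastic-gradient (Q)KLMS update
#'
#' Computes the instantaneous error `e = target - f(u)`; if the
#' kernel-metric distance from `u` to every existing center is at least
#' `eps` (and the center cap is not reached) a new center is appended with
#' coefficients `eta_eff * e`, otherwise `eta_eff * e` is added to the
#' nearest center's coefficients.  With `normalize = TRUE`,
#' `eta_eff = eta / K(u, u)`.
#'
#' @param model an [kaf_model()] (modified in place and returned).
#' @param input input sample.
#' @param target numeric vector of length `m`.
#' @return The updated model, invisibly also carrying `last_error`.
#' @export
kaf_update <- function(model, input, target) {
  stopifnot(length(target) == model$m)
  kk <- kaf_kernels(model, input)
  e <- target - kaf_predict_k(model, kk$k)
  step <- if (model$normalize) model$eta * e / kk$k_self else model$eta * e
  M <- model$n_centers
  if (M > 0) {
    d2 <- pmax(0, 2 * (kk$k_self - kk$k))
    j <- which.min(d2)
    if (d2[j] < model$eps^2 || M >= model$cap) {
      model$coeff[j, ] <- model$coeff[j, ] + step
      model$last_error <- e
      return(invisible(model))
    }
  }
  kaf_append(model, kk$feat, step)
  model$last_error <- e
  invisible(model)
}

#' Train a kernel adaptive filter over a sample sequence
#'
#' @param model an [kaf_model()].
#' @param inputs list of input samples.
#' @param targets numeric matrix (`length(inputs)` x `m`) or vector for
#'   `m = 1`.
#' @param shuffle_seed optional seed; when given, the presentation order
#'   is shuffled reproducibly.
#' @param passes number of passes over the data.
#' @return The trained model; `model$error_trace` holds the per-update
#'   root-mean-square instantaneous error.
#' @export
kaf_train <- function(model, inputs, targets, shuffle_seed = NULL,
                      passes = 1) {
  if (is.vector(targets) && model$m == 1L) targets <- matrix(targets)
  stopifnot(nrow(targets) == length(inputs))
  ord <- seq_along(inputs)
  err <- numeric(0)
  for (p in seq_len(passes)) {
    if (!is.null(shuffle_seed)) {
      ord <- with_seed(derive_seed(shuffle_seed, paste0("pass", p)),
                       sample(length(inputs)))
    }
    for (i in ord) {
      kaf_update(model, inputs[[i]], targets[i, ])
      err <- c(err, sqrt(mean(model$last_error^2)))
    }
  }
  model$error_trace <- err
  model
}
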