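#' Derive a named sub-seed from a master seed
#'
#' Every source of randomness in the package (network construction,
#' background drive, lesions, probes, training) draws from its own stream,
#' seeded by hashing a master seed together with a stream name.  This keeps
#' campaigns reproducible while guaranteeing that, e.g., attaching a
#' stimulator does not perturb the background-noise stream.
#'
#' @param seed integer master seed.
#' @param name character stream name.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "background")
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  h <- 5381
  for (ch in utf8ToInt(name)) h <- (h * 33 + ch) %% 2147483629
  s <- abs(seed) %% 2147483629
  as.integer((s * 48271 + h) %% 2147483629) + 1L
}

# Evaluate `expr` under a temporary R RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
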