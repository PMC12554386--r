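# Internal helpers shared across modules. Nothing here is exported.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the Mersenne-Twister seed for the duration of `expr` and restores the
#' caller's `.Random.seed` afterwards, so seeded package functions never
#' perturb the user's RNG stream. With `seed = NULL` the current stream is
#' used (and advanced) as-is.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# Polynomial rolling hash over a byte/int vector, mod a prime below 2^31.
# Exact in double arithmetic: intermediate values stay below 2^31 * 256.
poly_hash <- function(ints, h = 17L) {
  h <- as.double(h)
  for (b in ints) h <- (h * 257 + as.double(b) + 1) %% 2147483629
  h
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Stage-name hashing keeps per-stage RNG substreams independent: adding one
#' stage to a pipeline never shifts another stage's randomness. Result is a
#' valid 32-bit seed.
#' @noRd
derive_seed <- function(seed, label) {
  stopifnot(length(label) == 1L)
  h <- poly_hash(utf8ToInt(as.character(label)))
  as.integer((as.double(seed) %% 2147483629 + h) %% 2147483629)
}

#' Content hash of an R object's canonical serialization (hex string)
#' @noRd
object_hash <- function(x) {
  bytes <- serialize(x, connection = NULL, version = 2, xdr = TRUE)
  # two passes with different offsets to widen the effective digest
  sprintf("%08x%08x", poly_hash(as.integer(bytes), 17L),
          poly_hash(as.integer(bytes), 101L))
}

#' @noRd
is_count_like <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(abs(x - round(x)) < tol)
}

#' @noRd
abort_arg <- function(...) stop(sprintf(...), call. = FALSE)
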