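`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not disturb the global stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Derive a per-stage seed from a base seed
#'
#' Deterministic arithmetic split of one user-facing seed into independent
#' sub-seeds, kept below 2^31 so they remain valid R integers.
#'
#' @param seed base integer seed.
#' @param k stage index (>= 1).
#' @return integer seed.
#' @export
split_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(k))
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483647)
}

#' Convert between particle velocity and displacement amplitude
#'
#' For a pure tone, velocity and displacement amplitudes obey
#' `v = 2 * pi * f * d`. Velocities are in mm/s, displacements in um
#' (1 mm/s at f Hz corresponds to `1000 / (2 pi f)` um).
#'
#' @param v_mm_s peak particle velocity, mm/s.
#' @param freq tone frequency, Hz.
#' @return displacement amplitude in um.
#' @export
velocity_to_displacement <- function(v_mm_s, freq) {
  stopifnot(freq > 0)
  v_mm_s * 1000 / (2 * pi * freq)
}

#' @rdname velocity_to_displacement
#' @param d_um displacement amplitude, um.
#' @export
displacement_to_velocity <- function(d_um, freq) {
  stopifnot(freq > 0)
  d_um * 2 * pi * freq / 1000
}

# small FNV-1a style hash of an R object's deparsed form; used to stamp
# experiment outputs with the configuration they came from
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (as.double(h) * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
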