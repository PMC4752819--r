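# Internal helpers: seed substreams, circular arithmetic, config hashing.

#' Derive a deterministic sub-seed from a master seed
#'
#' All stochastic components of the package are driven by a single integer
#' master seed; independent random sub-streams (ensemble draw, foci layout,
#' dynamics noise, imaging noise, replicate index, ...) use sub-seeds derived
#' deterministically from the master seed and a stream label, so that a run is
#' reproducible bit-for-bit while its components remain decoupled.
#'
#' @param seed integer master seed (or `NULL` to leave the RNG untouched).
#' @param stream character label of the sub-stream.
#' @param index optional integer (e.g. replicate number) folded into the
#'   sub-seed.
#' @return an integer seed in `[0, 2^31 - 1)`, or `NULL` if `seed` is `NULL`.
#' @export
substream_seed <- function(seed, stream = "default", index = 0L) {
  if (is.null(seed)) return(NULL)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  # FNV-1a over the label bytes, folded with seed and index; modulus keeps the
  # result inside R's 32-bit integer range.
  h <- 2166136261
  for (b in as.integer(charToRaw(stream))) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  as.integer((h + as.double(seed) * 2654435761 + as.double(index) * 40503) %% (2^31 - 1))
}

with_substream <- function(seed, stream, index = 0L, expr) {
  if (!is.null(seed)) set.seed(substream_seed(seed, stream, index))
  expr
}

# Wrap angles into (-pi, pi].
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

# Wrap angles into [0, 2*pi).
wrap_2pi <- function(x) x %% (2 * pi)

# Circular mean of angles (radians); NA-free input expected.
circular_mean <- function(x) Arg(mean(exp(1i * x)))

# Stable content hash (FNV-1a over ASCII serialization) used to stamp
# experiment outputs with their configuration.
config_hash <- function(x) {
  bytes <- serialize(x, connection = NULL, ascii = TRUE)
  h <- 2166136261
  # fold in chunks for speed
  v <- as.integer(bytes)
  for (i in seq_along(v)) {
    h <- ((bitwXor(as.integer(h %% 2^31), v[i]) %% 2^31) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# Euclidean distance matrix between rows of two 2-column matrices.
cross_dist <- function(a, b) {
  da <- outer(a[, 1], b[, 1], "-")
  db <- outer(a[, 2], b[, 2], "-")
  sqrt(da^2 + db^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
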