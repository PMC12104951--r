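# Internal helpers: seed derivation, scoped RNG, small numeric utilities.

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' One global seed fans out to per-stage substreams so stages can be re-run
#' independently without sharing RNG state. Uses a 32-bit FNV-1a hash of the
#' label folded into the master seed; the result is always a valid positive
#' 32-bit integer seed.
#'
#' @param seed Master integer seed.
#' @param ... Stream labels (character or integer scalars) identifying the
#'   consumer, e.g. `derive_seed(seed, "cohort", "HC", 3)`.
#' @return A positive integer below 2^31 suitable for `set.seed()`.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  parts <- vapply(list(...), function(p) paste0(as.character(p), collapse = ","),
                  character(1L))
  key <- paste(c(format(seed, scientific = FALSE), parts), collapse = "|")
  h <- 2166136261
  for (b in utf8ToInt(key)) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  as.integer(h %% 2147483646) + 1L
}

# bitwXor on doubles held in [0, 2^32)
bitwXor_dbl <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer((a %/% 65536) %% 65536), as.integer((b %/% 65536) %% 65536))
  hi * 65536 + lo
}

# Evaluate `code` under a fixed RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# FNV-1a content hash of a serialized R object, as 8 hex digits.
# Used to stamp outputs with the configuration that produced them.
config_hash <- function(x) {
  bytes <- serialize(x, connection = NULL, ascii = TRUE)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Separable Gaussian smoothing of a matrix (axial = rows, lateral = columns).
# Kernel truncated at 3 sigma; edges renormalized by smoothing a ones-matrix.
gauss_smooth2d <- function(m, sigma_row, sigma_col) {
  smooth1 <- function(mat, sigma) {
    if (sigma <= 0) return(mat)
    half <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(seq(-half, half), sd = sigma)
    k <- k / sum(k)
    n <- nrow(mat)
    # replicate edge rows so the filter is defined everywhere, then crop
    padded <- rbind(mat[rep(1L, half), , drop = FALSE], mat,
                    mat[rep(n, half), , drop = FALSE])
    out <- stats::filter(padded, k, sides = 2)
    matrix(as.numeric(out), nrow(padded), ncol(mat))[half + seq_len(n), , drop = FALSE]
  }
  m <- smooth1(m, sigma_row)
  t(smooth1(t(m), sigma_col))
}
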