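#' Derive a reproducible integer seed from a master seed and labels
#'
#' Stable string hash (FNV-style polynomial over UTF-8 bytes, modulo
#' 2^31 - 1) so that any (subject, region, cell) combination maps to the
#' same sub-seed in every session and in any evaluation order.
#'
#' @param seed master integer seed.
#' @param ... labels (coerced to character) mixed into the hash.
#' @return an integer in \[1, 2^31 - 2\].
#' @export
#' @examples
#' hash_seed(1, "sub01", "left_parahippocampal", 6, 34)
hash_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  key <- paste(c(format(seed), vapply(list(...), as.character, "")), collapse = "\r")
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- 2166136261 %% m
  for (b in utf8ToInt(key)) {
    h <- (h * 127 + b) %% m
  }
  as.integer(h + 1)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# the caller's .Random.seed is restored afterwards. A NULL seed uses
# (and advances) the current RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Wrap angles in degrees onto [0, 360). Floating %% can return exactly 360
# for tiny negative inputs; fold that back to 0 to keep the half-open range.
wrap_deg <- function(deg) {
  r <- deg %% 360
  r[r == 360] <- 0
  r
}

#' Circular mean of angles in degrees
#'
#' Angle of the mean resultant vector, reported in degrees on \[0, 360).
#'
#' @param deg numeric vector of angles in degrees.
#' @return a single angle in degrees.
#' @export
#' @examples
#' circular_mean_deg(c(10, 350))  # 0, not 180
circular_mean_deg <- function(deg) {
  stopifnot(is.numeric(deg), length(deg) >= 1)
  z <- mean(exp(1i * deg * pi / 180))
  if (Mod(z) < 1e-12) {
    abort("circular mean undefined: resultant vector has length ~0")
  }
  wrap_deg(Arg(z) * 180 / pi)
}

# Shared input coercion: accept a regional_ts or a bare numeric vector
# (then `fs` must be given). Returns list(samples, fs, subject_id, group, region).
as_signal <- function(x, fs = NULL) {
  if (inherits(x, "regional_ts")) {
    return(x)
  }
  if (is.numeric(x)) {
    if (is.null(fs)) {
      abort("`fs` must be supplied when `x` is a bare numeric vector")
    }
    return(regional_ts(x, fs = fs))
  }
  abort("`x` must be a regional_ts or a numeric vector")
}
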