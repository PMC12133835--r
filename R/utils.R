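# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stable string hash
#'
#' Polynomial rolling hash (base 31, modulus 2^31 - 1) over the UTF-8 bytes
#' of a string.  All intermediate products stay below 2^53, so the result is
#' exact in double arithmetic and identical across platforms and R sessions.
#' Used to derive per-token RNG seeds for the mock embedding backend and the
#' hash-based random scorer.
#'
#' @param x a single character string.
#' @return a non-negative number below 2^31 - 1.
#' @keywords internal
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  h
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  Mersenne-Twister + inversion are
# fixed explicitly so draws are reproducible regardless of session settings.
local_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(list = ".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483647), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  expr
}

# Clip to [0, 1]; negative cosine similarities are treated as irrelevant
# rather than anti-relevant before being used as relevance inputs.
clip01 <- function(x) pmin(pmax(x, 0), 1)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

assert_fraction <- function(x, name) {
  if (!is_number(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single number in [0, 1]", name), call. = FALSE)
  invisible(x)
}
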