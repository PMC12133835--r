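#' Embedding backends
#'
#' Relevance scoring needs sentence embeddings and cosine similarity.  Real
#' sentence encoders live behind a small contract: a backend is a list with a
#' `name`, a `dimension`, a `deterministic` flag and an `embed_token`
#' function mapping one token to a fixed vector.  The shipped mock backend
#' tokenizes the text, maps every distinct token through a seeded hash to a
#' fixed random Gaussian vector, averages and normalizes.  It is fast,
#' network-free and reproducible across platforms and sessions, which makes
#' the whole pipeline testable at desk scale; it captures lexical overlap,
#' not meaning (two paraphrases with disjoint vocabulary look unrelated).
#'
#' The default dimension matches the 384-dimensional MiniLM-class sentence
#' encoders the mock stands in for.  Dimension also sets the noise floor of
#' the mock's similarities: cosines between texts with disjoint token sets
#' fluctuate around 0 with standard deviation about `1/sqrt(dimension)`
#' (about 0.05 at 384), which keeps small relevance gradients resolvable.
#'
#' @param seed integer seed mixed into every token hash.
#' @param dimension embedding dimension (default 384).
#' @return an object of class `exrank_backend`.
#' @examples
#' be <- mock_embedding_backend(seed = 1)
#' v <- embed_text(be, "low mood and loss of interest")
#' sqrt(sum(v^2))  # 1
#' @export
mock_embedding_backend <- function(seed = 42L, dimension = 384L) {
  stopifnot(is_number(seed), is_number(dimension), dimension >= 2)
  dimension <- as.integer(dimension)
  seed <- as.integer(seed)
  cache <- new.env(parent = emptyenv())
  embed_token <- function(token) {
    hit <- cache[[token]]
    if (!is.null(hit)) return(hit)
    h <- (stable_hash(token) + 715827881 * (seed %% 2999)) %% 2147483647
    v <- local_seed(h, stats::rnorm(dimension))
    cache[[token]] <- v
    v
  }
  structure(list(name = "mock", dimension = dimension, deterministic = TRUE,
                 seed = seed, embed_token = embed_token),
            class = "exrank_backend")
}

#' Embed a text as a unit vector
#'
#' Tokenizes with the package tokenizer, embeds each distinct token via the
#' backend, averages and L2-normalizes.  Texts with identical token sets map
#' to identical vectors under the mock backend.
#'
#' @param backend an `exrank_backend`.
#' @param text a non-empty character string.
#' @return a unit-norm numeric vector of length `backend$dimension`.
#' @export
embed_text <- function(backend, text) {
  stopifnot(inherits(backend, "exrank_backend"))
  toks <- unique(tokenize(text))
  if (!length(toks)) stop("cannot embed empty text", call. = FALSE)
  m <- vapply(toks, backend$embed_token, numeric(backend$dimension))
  v <- rowMeans(as.matrix(m))
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("degenerate embedding with zero norm", call. = FALSE)
  v / nrm
}

#' Cosine similarity between two vectors
#'
#' @param u,v numeric vectors of equal length.
#' @return the cosine of the angle between `u` and `v`, in `[-1, 1]`.
#' @examples
#' cosine_similarity(c(1, 0), c(sqrt(2) / 2, sqrt(2) / 2))  # ~0.7071
#' @export
cosine_similarity <- function(u, v) {
  if (!is.numeric(u) || !is.numeric(v))
    stop("'u' and 'v' must be numeric vectors", call. = FALSE)
  if (length(u) != length(v))
    stop("dimension mismatch between 'u' and 'v'", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine similarity undefined for zero vectors", call. = FALSE)
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

# Clipped cosine between two texts; negative similarity is treated as 0
# because downstream relevance scores are probabilities.
text_similarity <- function(backend, a, b) {
  clip01(cosine_similarity(embed_text(backend, a), embed_text(backend, b)))
}
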