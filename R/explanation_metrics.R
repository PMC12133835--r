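#' Tokenization
#'
#' All lexical metrics share one tokenizer: split on Unicode whitespace,
#' strip leading/trailing punctuation from each piece, lowercase, and drop
#' empties.  Internal punctuation (as in "it's") is preserved.
#'
#' @param text a character string (possibly empty).
#' @return `tokenize()` returns the token vector in order, duplicates kept;
#'   `tokenize_text()` returns the token *set* as a list with elements
#'   `tokens` (unique tokens) and `source_length` (count before dedup).
#' @examples
#' tokenize_text("Hurt, anger!")$tokens     # "hurt" "anger"
#' tokenize_text("a a b")$source_length     # 3
#' @export
tokenize <- function(text) {
  if (is.null(text) || !length(text) || is.na(text) || !nzchar(text))
    return(character(0))
  pieces <- strsplit(text, "(*UCP)\\s+", perl = TRUE)[[1]]
  pieces <- gsub("(*UCP)^[\\p{P}\\p{S}]+|[\\p{P}\\p{S}]+$", "", pieces,
                 perl = TRUE)
  tolower(pieces[nzchar(pieces)])
}

#' @rdname tokenize
#' @export
tokenize_text <- function(text) {
  toks <- tokenize(text)
  list(tokens = unique(toks), source_length = length(toks))
}

as_text <- function(x) {
  if (is_string(x)) return(x)
  if (inherits(x, c("exrank_explanation", "exrank_gold_explanation",
                    "exrank_demonstration", "exrank_utterance")))
    return(x$text)
  if (inherits(x, "exrank_conversation"))
    return(paste(vapply(x$utterances, `[[`, character(1), "text"),
                 collapse = " | "))
  stop("cannot extract text from object of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}

#' Factuality of an explanation (lexical overlap)
#'
#' Lexical grounding of a candidate explanation against expert-written
#' references: the best achievable token-set overlap
#' `|tokens(candidate) intersect tokens(gold)| / |tokens(candidate)|`,
#' maximised over the supplied gold references.  Set (not multiset)
#' semantics: duplicated tokens in the candidate do not change the score.
#'
#' @param candidate an [explanation()] or a character string.
#' @param golds a list of [gold_explanation()]s, or a character vector.
#' @return a number in `[0, 1]`.
#' @examples
#' factuality("a b c d", "b d e")  # 0.5
#' @export
factuality <- function(candidate, golds) {
  cand <- unique(tokenize(as_text(candidate)))
  if (!length(cand))
    stop("candidate tokenizes to an empty set; overlap is undefined",
         call. = FALSE)
  if (is.character(golds)) golds <- as.list(golds)
  if (!length(golds)) stop("need at least one gold reference", call. = FALSE)
  scores <- vapply(golds, function(g) {
    gt <- unique(tokenize(as_text(g)))
    length(intersect(cand, gt)) / length(cand)
  }, numeric(1))
  max(scores)
}

#' Consistency of an explanation (greedy token-matching F1)
#'
#' BERTScore-style alignment between a candidate explanation and a reference
#' context (typically the demonstration text plus its label description, or
#' a gold explanation).  Every distinct token on each side is embedded with
#' the backend; recall is the mean over reference tokens of the maximum
#' similarity to any candidate token, precision the mean over candidate
#' tokens of the maximum similarity to any reference token, and F1 their
#' harmonic mean (0 when both vanish).  Similarities are clipped to `[0, 1]`.
#'
#' @param candidate an [explanation()] or character string.
#' @param reference reference text (string or corpus object).
#' @param backend an `exrank_backend` used to embed single tokens.
#' @return a list of class `exrank_consistency` with `precision`, `recall`,
#'   `f1` and a `matched_pairs` data frame (candidate token, best reference
#'   token, similarity).
#' @export
consistency <- function(candidate, reference, backend) {
  stopifnot(inherits(backend, "exrank_backend"))
  ct <- unique(tokenize(as_text(candidate)))
  rt <- unique(tokenize(as_text(reference)))
  if (!length(ct) || !length(rt))
    stop("both candidate and reference must tokenize non-empty", call. = FALSE)
  cm <- vapply(ct, backend$embed_token, numeric(backend$dimension))
  rm_ <- vapply(rt, backend$embed_token, numeric(backend$dimension))
  cm <- as.matrix(cm); rm_ <- as.matrix(rm_)
  # unit-normalize columns, then all pairwise cosines in one crossprod
  cm <- sweep(cm, 2, sqrt(colSums(cm^2)), "/")
  rm_ <- sweep(rm_, 2, sqrt(colSums(rm_^2)), "/")
  sim <- clip01(crossprod(cm, rm_))          # candidates x references
  precision <- mean(apply(sim, 1, max))
  recall <- mean(apply(sim, 2, max))
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  best <- apply(sim, 1, which.max)
  structure(
    list(precision = precision, recall = recall, f1 = f1,
         matched_pairs = data.frame(
           candidate_token = ct,
           reference_token = rt[best],
           similarity = sim[cbind(seq_along(ct), best)],
           stringsAsFactors = FALSE)),
    class = "exrank_consistency")
}

#' @export
print.exrank_consistency <- function(x, ...) {
  cat(sprintf("<consistency: P=%.4f R=%.4f F1=%.4f over %d tokens>\n",
              x$precision, x$recall, x$f1, nrow(x$matched_pairs)))
  invisible(x)
}
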