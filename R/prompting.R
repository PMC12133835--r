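#' Soft prompt template
#'
#' Structured scaffold for in-context classification prompts:
#' `[CLS] <query> <p1> [SEP] <p2> [EOS]`, with demonstration blocks (each
#' demonstration plus its selected explanations) serialised before the
#' query.  Prompt snippets `p1, p2, ...` stand in, as literal text, for the
#' trained soft-prompt embeddings of a full system; training them is out of
#' scope here, but the template structure is preserved so a trained backend
#' can be slotted in.  `max_length` caps the whole prompt in tokens
#' (default 3000); when exceeded, demonstration blocks are dropped from the
#' end, never the query.
#'
#' @param cls_token,sep_token,eos_token marker strings; must be distinct and
#'   non-empty.
#' @param prompt_snippets character vector of snippets; the first is placed
#'   after the query, the rest after the separator.
#' @param max_length maximum prompt length in whitespace tokens.
#' @return an object of class `exrank_soft_template`.
#' @export
soft_template <- function(cls_token = "[CLS]", sep_token = "[SEP]",
                          eos_token = "[EOS]",
                          prompt_snippets = character(0),
                          max_length = 3000L) {
  markers <- c(cls_token, sep_token, eos_token)
  if (any(!nzchar(markers)) || anyDuplicated(markers))
    stop("template markers must be distinct and non-empty", call. = FALSE)
  if (!is_number(max_length) || max_length < 1)
    stop("'max_length' must be a positive integer", call. = FALSE)
  structure(list(cls_token = cls_token, sep_token = sep_token,
                 eos_token = eos_token,
                 prompt_snippets = as.character(prompt_snippets),
                 max_length = as.integer(max_length)),
            class = "exrank_soft_template")
}

#' Verbalizer: classes and their label words
#'
#' Maps each class to the label words whose mask-fill probabilities define
#' the class score.  Word lists must be disjoint across classes.  Class
#' order matters: prediction ties resolve to the first class, so screening
#' verbalizers should list `normal` first.
#'
#' @param classes ordered character vector of class names.
#' @param label_words named list mapping each class to a character vector of
#'   at least one label word.
#' @return an object of class `exrank_verbalizer`.
#' @export
verbalizer <- function(classes, label_words) {
  stopifnot(is.character(classes), length(classes) >= 2)
  if (!all(classes %in% names(label_words)))
    stop("every class needs an entry in 'label_words'", call. = FALSE)
  label_words <- lapply(label_words[classes], function(w) tolower(as.character(w)))
  if (any(!vapply(label_words, length, integer(1))))
    stop("every class needs at least one label word", call. = FALSE)
  all_words <- unlist(label_words, use.names = FALSE)
  if (anyDuplicated(all_words))
    stop("label words must be disjoint across classes", call. = FALSE)
  structure(list(classes = classes, label_words = label_words),
            class = "exrank_verbalizer")
}

#' The shipped default verbalizer
#'
#' Two classes.  `normal`: joy, happy, elation, contentment.  `depression`:
#' hurt, anger, moody, bored, sadness, plus broken and shocking (depressive
#' content words routinely flagged in conversational screening).  Stored as
#' JSON under `inst/extdata/verbalizer_default.json` so users can supply
#' their own file with the same shape.
#'
#' @param path optional path to a verbalizer JSON file
#'   (`{"class": ["word", ...], ...}`).
#' @return an `exrank_verbalizer`.
#' @export
default_verbalizer <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "verbalizer_default.json",
                        package = "exrank", mustWork = TRUE)
  words <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  verbalizer(names(words), words)
}

serialize_demo_block <- function(demo, expls) {
  block <- sprintf("example labeled %s : %s", demo$label, demo$text)
  if (length(expls)) {
    etxt <- vapply(expls, as_text, character(1))
    block <- paste(block, paste("explanation :", etxt, collapse = " "))
  }
  block
}

token_count <- function(s) length(strsplit(trimws(s), "\\s+")[[1]])

#' Assemble a few-shot classification prompt
#'
#' Emits `cls_token + demonstration blocks + query text + p1 + sep_token +
#' p2... + eos_token`, single-space separated.  Conversation queries join
#' their utterances with `" | "`.  Each demonstration becomes one labeled
#' block, followed by its selected explanations (an `explanations` list of
#' [explanation()] objects is matched to demonstrations by `demo_id`, in the
#' order given).  If the prompt exceeds `template$max_length` tokens,
#' demonstration blocks are dropped from the end until it fits; if the query
#' alone (with markers and snippets) does not fit, assembly fails.
#'
#' @param x query: an [utterance()], [conversation()] or character string.
#' @param template a [soft_template()].
#' @param demos list of [demonstration()]s (serialised before the query).
#' @param explanations list of [explanation()]s already selected and ordered
#'   (e.g. the output of [hybrid_select()] resolved back to objects).
#' @return a single prompt string.
#' @export
assemble_template <- function(x, template = soft_template(),
                              demos = list(), explanations = list()) {
  stopifnot(inherits(template, "exrank_soft_template"))
  qtext <- as_text(x)
  snippets <- template$prompt_snippets
  p1 <- if (length(snippets) >= 1) snippets[[1]] else ""
  rest <- if (length(snippets) >= 2) snippets[-1] else character(0)

  blocks <- vapply(demos, function(d) {
    mine <- Filter(function(e) identical(e$demo_id, d$demo_id), explanations)
    serialize_demo_block(d, mine)
  }, character(1))

  build <- function(blks) {
    parts <- c(template$cls_token, blks, qtext,
               if (nzchar(p1)) p1, template$sep_token,
               rest[nzchar(rest)], template$eos_token)
    paste(parts, collapse = " ")
  }
  keep <- length(blocks)
  out <- build(blocks[seq_len(keep)])
  while (token_count(out) > template$max_length && keep > 0) {
    keep <- keep - 1
    out <- build(blocks[seq_len(keep)])
  }
  if (token_count(out) > template$max_length)
    stop(sprintf("query alone exceeds max_length (%d tokens)",
                 template$max_length), call. = FALSE)
  out
}

#' Lexicon-count mask-probability provider
#'
#' Desk-scale stand-in for a masked language model's label-word fill
#' probability: the probability of a label word given a context is its
#' occurrence count among the context tokens, divided by one plus the total
#' count of all label words (across all classes) in the context.  Values lie
#' in `[0, 1)`, are case-insensitive, and are deterministic.
#'
#' @param verbalizer an [verbalizer()] supplying the full label-word
#'   inventory (needed for the normalising total).
#' @return a function `(context, label_word) -> probability`, with attribute
#'   `name = "lexicon"`.
#' @examples
#' p <- lexicon_provider(default_verbalizer())
#' p("hurt hurt", "hurt")  # 2/3
#' @export
lexicon_provider <- function(verbalizer) {
  stopifnot(inherits(verbalizer, "exrank_verbalizer"))
  all_words <- unlist(verbalizer$label_words, use.names = FALSE)
  f <- function(context, label_word) {
    toks <- tokenize(context)
    total <- sum(toks %in% all_words)
    sum(toks == tolower(label_word)) / (1 + total)
  }
  attr(f, "name") <- "lexicon"
  f
}

#' Classify one utterance through the verbalizer
#'
#' Each class scores the sum of its label words' provider probabilities in
#' the utterance text; scores are sum-normalized into class probabilities.
#' When every score is zero the distribution is uniform and the tie resolves
#' to the first class in the verbalizer (by convention `normal`: a screening
#' tool should not default to the clinical label).
#'
#' @param x an [utterance()] or character string.
#' @param verbalizer an [verbalizer()].
#' @param provider a mask-probability provider `(context, label_word) ->
#'   [0, 1]`; defaults to [lexicon_provider()] over `verbalizer`.
#' @return a list of class `exrank_classification` with `utterance_id`,
#'   `class_probs` (named, sums to 1) and `predicted`.
#' @export
classify_utterance <- function(x, verbalizer = default_verbalizer(),
                               provider = lexicon_provider(verbalizer)) {
  stopifnot(inherits(verbalizer, "exrank_verbalizer"))
  text <- as_text(x)
  scores <- vapply(verbalizer$classes, function(cl) {
    sum(vapply(verbalizer$label_words[[cl]],
               function(v) provider(text, v), numeric(1)))
  }, numeric(1))
  s <- sum(scores)
  probs <- if (s > 0) scores / s else
    stats::setNames(rep(1 / length(scores), length(scores)),
                    verbalizer$classes)
  predicted <- verbalizer$classes[[which.max(probs)]]
  structure(list(
    utterance_id = if (inherits(x, "exrank_utterance")) x$utterance_id else NA_character_,
    class_probs = probs, predicted = predicted),
    class = "exrank_classification")
}

#' Classify every utterance of a set of conversations
#'
#' @param conversations list of [conversation()]s.
#' @inheritParams classify_utterance
#' @return a data frame with one row per utterance: `conversation_id`,
#'   `utterance_id`, `speaker_id`, `gold_label`, `predicted`, and one
#'   probability column per class.
#' @export
classify_conversations <- function(conversations,
                                   verbalizer = default_verbalizer(),
                                   provider = lexicon_provider(verbalizer)) {
  rows <- lapply(conversations, function(cv) {
    lapply(cv$utterances, function(u) {
      res <- classify_utterance(u, verbalizer, provider)
      cbind(data.frame(conversation_id = cv$conversation_id,
                       utterance_id = u$utterance_id,
                       speaker_id = u$speaker_id,
                       gold_label = u$gold_label,
                       predicted = res$predicted,
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(res$class_probs)))
    })
  })
  do.call(rbind, unlist(rows, recursive = FALSE))
}

#' @export
print.exrank_classification <- function(x, ...) {
  cat(sprintf("<classification: %s (%s)>\n", x$predicted,
              paste(sprintf("%s=%.3f", names(x$class_probs), x$class_probs),
                    collapse = ", ")))
  invisible(x)
}
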