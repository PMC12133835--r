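#' Domain records: utterances, conversations, demonstrations, explanations
#'
#' The package models depression screening over multi-party conversations
#' (MPCs).  A [conversation()] is an ordered list of [utterance()]s, each
#' attributed to a speaker and optionally carrying a gold label.
#' [demonstration()]s are labelled in-context examples retrieved for a query;
#' [explanation()]s are candidate free-text rationales attached to a
#' demonstration; [gold_explanation()]s are expert-written references used
#' for validation.  All records are plain lists with a class attribute and
#' are serialised as UTF-8 JSONL, one record per line.
#'
#' @name corpus
NULL

.label_levels <- c("normal", "depression", "unknown")

#' Construct a single utterance
#'
#' @param utterance_id unique id string.
#' @param speaker_id speaker id string.
#' @param text utterance text; must be non-empty after whitespace stripping.
#' @param position 0-based integer index within the conversation.
#' @param gold_label one of `"normal"`, `"depression"`, `"unknown"`.
#' @return an object of class `exrank_utterance`.
#' @export
utterance <- function(utterance_id, speaker_id, text, position,
                      gold_label = "unknown") {
  if (!is_string(utterance_id)) stop("'utterance_id' must be a string", call. = FALSE)
  if (!is_string(speaker_id)) stop("'speaker_id' must be a string", call. = FALSE)
  if (!is_string(text) || !nzchar(trimws(text)))
    stop("'text' must be non-empty after whitespace stripping", call. = FALSE)
  if (!is_number(position) || position < 0 || position != floor(position))
    stop("'position' must be a non-negative integer", call. = FALSE)
  gold_label <- tolower(gold_label)
  if (!is_string(gold_label) || !gold_label %in% .label_levels)
    stop("'gold_label' must be one of: ", paste(.label_levels, collapse = ", "),
         call. = FALSE)
  structure(
    list(utterance_id = utterance_id, speaker_id = speaker_id,
         text = text, position = as.integer(position), gold_label = gold_label),
    class = "exrank_utterance")
}

#' Construct a conversation
#'
#' Positions must be contiguous 0-based indices.  The session-length class
#' is `Len-5`, `Len-10` or `Len-15` when the utterance count is exactly 5,
#' 10 or 15, and `other` otherwise.
#'
#' @param conversation_id id string.
#' @param utterances list of [utterance()] objects.
#' @return an object of class `exrank_conversation`.
#' @export
conversation <- function(conversation_id, utterances) {
  if (!is_string(conversation_id)) stop("'conversation_id' must be a string", call. = FALSE)
  if (!is.list(utterances) || length(utterances) < 2L)
    stop("a conversation needs at least 2 utterances", call. = FALSE)
  ok <- vapply(utterances, inherits, logical(1), "exrank_utterance")
  if (!all(ok)) stop("'utterances' must all be utterance objects", call. = FALSE)
  pos <- vapply(utterances, `[[`, integer(1), "position")
  if (!identical(sort(pos), seq_along(pos) - 1L))
    stop("utterance positions must be contiguous 0-based indices", call. = FALSE)
  utterances <- utterances[order(pos)]
  n <- length(utterances)
  slc <- if (n %in% c(5L, 10L, 15L)) paste0("Len-", n) else "other"
  structure(
    list(conversation_id = conversation_id, utterances = utterances,
         session_length_class = slc),
    class = "exrank_conversation")
}

#' Construct a demonstration (in-context example)
#'
#' @param demo_id id string.
#' @param text example text.
#' @param label `"normal"` or `"depression"`.
#' @param source free-form provenance tag.
#' @return an object of class `exrank_demonstration`.
#' @export
demonstration <- function(demo_id, text, label, source = "") {
  if (!is_string(demo_id)) stop("'demo_id' must be a string", call. = FALSE)
  if (!is_string(text) || !nzchar(trimws(text)))
    stop("'text' must be non-empty", call. = FALSE)
  label <- tolower(label)
  if (!is_string(label) || !label %in% c("normal", "depression"))
    stop("'label' must be \"normal\" or \"depression\"", call. = FALSE)
  structure(list(demo_id = demo_id, text = text, label = label,
                 source = source),
            class = "exrank_demonstration")
}

#' Construct a candidate explanation
#'
#' @param expl_id id string.
#' @param text explanation text (non-empty).
#' @param demo_id id of the demonstration the explanation belongs to.
#' @param generator tag for the generating backend (e.g. `"synthetic"`).
#' @return an object of class `exrank_explanation`.
#' @export
explanation <- function(expl_id, text, demo_id, generator = "synthetic") {
  if (!is_string(expl_id)) stop("'expl_id' must be a string", call. = FALSE)
  if (!is_string(text) || !nzchar(trimws(text)))
    stop("'text' must be non-empty", call. = FALSE)
  if (!is_string(demo_id)) stop("'demo_id' must be a string", call. = FALSE)
  structure(list(expl_id = expl_id, text = text, demo_id = demo_id,
                 generator = generator),
            class = "exrank_explanation")
}

#' Construct a gold (expert-written) explanation
#'
#' @param gold_id id string.
#' @param text reference explanation text (non-empty).
#' @param demo_id id of the demonstration or query it refers to.
#' @return an object of class `exrank_gold_explanation`.
#' @export
gold_explanation <- function(gold_id, text, demo_id) {
  if (!is_string(gold_id)) stop("'gold_id' must be a string", call. = FALSE)
  if (!is_string(text) || !nzchar(trimws(text)))
    stop("'text' must be non-empty", call. = FALSE)
  if (!is_string(demo_id)) stop("'demo_id' must be a string", call. = FALSE)
  structure(list(gold_id = gold_id, text = text, demo_id = demo_id),
            class = "exrank_gold_explanation")
}

# --- JSONL plumbing ---------------------------------------------------------

read_jsonl <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) stop(sprintf("line %d: malformed JSON (%s)",
                                       i, conditionMessage(e)), call. = FALSE))
    attr(rec, "line") <- i
    rec
  })
}

write_jsonl <- function(records, path) {
  con <- file(path, open = "wb")  # binary mode: LF endings on every platform
  on.exit(close(con))
  for (rec in records) {
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                null = "null"),
               con = con, useBytes = TRUE)
  }
  invisible(path)
}

need_field <- function(rec, field, line) {
  if (is.null(rec[[field]]))
    stop(sprintf("line %d: missing required field \"%s\"", line, field),
         call. = FALSE)
  rec[[field]]
}

#' Read conversations from a JSONL file
#'
#' Each line holds one conversation object:
#' `{"conversation_id": "...", "utterances": [{"utterance_id": ..., "speaker_id":
#' ..., "text": ..., "position": ..., "gold_label": ...}, ...]}`.
#' A missing `gold_label` defaults to `"unknown"`.  Malformed JSON and
#' invariant violations are reported with the offending line number.
#'
#' @param path path to a JSONL file.
#' @return a list of [conversation()] objects (empty for an empty file).
#' @export
read_conversations <- function(path) {
  lapply(read_jsonl(path), function(rec) {
    ln <- attr(rec, "line")
    utts <- need_field(rec, "utterances", ln)
    parsed <- tryCatch(
      lapply(utts, function(u)
        utterance(need_field(u, "utterance_id", ln),
                  need_field(u, "speaker_id", ln),
                  need_field(u, "text", ln),
                  need_field(u, "position", ln),
                  u$gold_label %||% "unknown")),
      error = function(e) stop(sprintf("line %d: %s", ln, conditionMessage(e)),
                               call. = FALSE))
    tryCatch(conversation(need_field(rec, "conversation_id", ln), parsed),
             error = function(e) stop(sprintf("line %d: %s", ln,
                                              conditionMessage(e)),
                                      call. = FALSE))
  })
}

#' Read demonstrations from a JSONL file
#' @param path path to a JSONL file with fields `demo_id`, `text`, `label`,
#'   optional `source`.
#' @return a list of [demonstration()] objects.
#' @export
read_demonstrations <- function(path) {
  lapply(read_jsonl(path), function(rec) {
    ln <- attr(rec, "line")
    tryCatch(demonstration(need_field(rec, "demo_id", ln),
                           need_field(rec, "text", ln),
                           need_field(rec, "label", ln),
                           rec$source %||% ""),
             error = function(e) stop(sprintf("line %d: %s", ln,
                                              conditionMessage(e)),
                                      call. = FALSE))
  })
}

#' Read candidate explanations from a JSONL file
#' @param path path to a JSONL file with fields `expl_id`, `text`, `demo_id`,
#'   optional `generator`.
#' @param demos optional list of demonstrations; when given, every `demo_id`
#'   must resolve or loading fails.
#' @return a list of [explanation()] objects.
#' @export
read_explanations <- function(path, demos = NULL) {
  out <- lapply(read_jsonl(path), function(rec) {
    ln <- attr(rec, "line")
    tryCatch(explanation(need_field(rec, "expl_id", ln),
                         need_field(rec, "text", ln),
                         need_field(rec, "demo_id", ln),
                         rec$generator %||% "unknown"),
             error = function(e) stop(sprintf("line %d: %s", ln,
                                              conditionMessage(e)),
                                      call. = FALSE))
  })
  if (!is.null(demos)) {
    known <- vapply(demos, `[[`, character(1), "demo_id")
    refs <- vapply(out, `[[`, character(1), "demo_id")
    bad <- setdiff(refs, known)
    if (length(bad))
      stop(sprintf("unresolved demo_id reference(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  out
}

#' Read gold explanations from a JSONL file
#' @param path path to a JSONL file with fields `gold_id`, `text`, `demo_id`.
#' @return a list of [gold_explanation()] objects.
#' @export
read_gold_explanations <- function(path) {
  lapply(read_jsonl(path), function(rec) {
    ln <- attr(rec, "line")
    tryCatch(gold_explanation(need_field(rec, "gold_id", ln),
                              need_field(rec, "text", ln),
                              need_field(rec, "demo_id", ln)),
             error = function(e) stop(sprintf("line %d: %s", ln,
                                              conditionMessage(e)),
                                      call. = FALSE))
  })
}

#' Write conversations to a JSONL file
#' @param conversations list of [conversation()] objects.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_conversations <- function(conversations, path) {
  write_jsonl(lapply(conversations, function(cv) {
    list(conversation_id = cv$conversation_id,
         utterances = lapply(cv$utterances, unclass))
  }), path)
}

#' Write demonstrations to a JSONL file
#' @inheritParams write_conversations
#' @param demonstrations list of [demonstration()] objects.
#' @return the path, invisibly.
#' @export
write_demonstrations <- function(demonstrations, path) {
  write_jsonl(lapply(demonstrations, unclass), path)
}

#' Write explanations to a JSONL file
#' @inheritParams write_conversations
#' @param explanations list of [explanation()] objects.
#' @return the path, invisibly.
#' @export
write_explanations <- function(explanations, path) {
  write_jsonl(lapply(explanations, unclass), path)
}

#' Write gold explanations to a JSONL file
#' @inheritParams write_conversations
#' @param golds list of [gold_explanation()] objects.
#' @return the path, invisibly.
#' @export
write_gold_explanations <- function(golds, path) {
  write_jsonl(lapply(golds, unclass), path)
}

#' Write a ranked selection to a JSONL file
#'
#' One object per selected explanation with its 1-based rank, combined score
#' and score components.  Scores are serialised at full double precision so
#' that re-reading reproduces them to well under 1e-9.
#'
#' @param selection a ranked selection from [hybrid_select()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_ranked_selection <- function(selection, path) {
  stopifnot(inherits(selection, "exrank_ranked_selection"))
  sel <- selection$selected
  write_jsonl(lapply(seq_len(nrow(sel)), function(i) {
    list(rank = i, expl_id = sel$expl_id[[i]], score = sel$s_comb[[i]],
         err_term = sel$err_term[[i]], mmr_term = sel$mmr_term[[i]])
  }), path)
}

#' Read a ranked selection written by [write_ranked_selection()]
#' @param path path to the JSONL file.
#' @return an object of class `exrank_ranked_selection`.
#' @export
read_ranked_selection <- function(path) {
  recs <- read_jsonl(path)
  sel <- data.frame(
    expl_id = vapply(recs, function(r) need_field(r, "expl_id", attr(r, "line")),
                     character(1)),
    s_comb = vapply(recs, function(r) as.numeric(need_field(r, "score", attr(r, "line"))),
                    numeric(1)),
    err_term = vapply(recs, function(r) as.numeric(r$err_term %||% NA_real_), numeric(1)),
    mmr_term = vapply(recs, function(r) as.numeric(r$mmr_term %||% NA_real_), numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(selected = sel, pool_size = nrow(sel)),
            class = "exrank_ranked_selection")
}

#' Read diagnostic-criteria statements from a plain-text file
#'
#' One criterion statement per line; blank lines and lines starting with `#`
#' are ignored.  The package ships a synthetic DSM-5-style set in
#' `system.file("extdata", "criteria_depression_synthetic.txt", package = "exrank")`;
#' users screening real data should substitute their own criteria file.
#'
#' @param path path to the text file.
#' @return a character vector of criteria statements.
#' @export
read_criteria <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' @export
print.exrank_conversation <- function(x, ...) {
  cat(sprintf("<conversation %s: %d utterances, %d speakers, %s>\n",
              x$conversation_id, length(x$utterances),
              length(unique(vapply(x$utterances, `[[`, character(1),
                                   "speaker_id"))),
              x$session_length_class))
  invisible(x)
}

#' @export
print.exrank_ranked_selection <- function(x, ...) {
  cat(sprintf("<ranked selection: %d of %d candidates>\n",
              nrow(x$selected), x$pool_size))
  print(x$selected, row.names = FALSE)
  invisible(x)
}
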