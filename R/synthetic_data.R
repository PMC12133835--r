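#' Generator configuration for the synthetic corpus
#'
#' The generator emulates the *structure* of social-media depression corpora
#' at desk scale: multi-party conversations of 5/10/15 utterances in which a
#' minority of utterances carry depressive lexicon words, a minority of
#' speakers produce them, and each demonstration comes with one gold
#' explanation and several candidate explanations of controlled quality.  It
#' makes no attempt at linguistic realism; it exists so every downstream
#' stage has a deterministic, label-consistent test bed.
#'
#' `quality_levels` are token-set-overlap targets against the gold
#' explanation, one per candidate; candidate i is built by copying that
#' fraction of the gold's tokens and padding with neutral distractor tokens,
#' so its factuality hits the target within rounding.  `redundancy_rate` is
#' the probability that a candidate is instead emitted as a token-shuffled
#' copy of an earlier candidate; it defaults to 0 because a duplicate does
#' not obey its slot's overlap target — raise it deliberately to stress the
#' MMR redundancy penalty.
#'
#' @param seed integer seed; all generation is deterministic given the config.
#' @param n_conversations number of conversations.
#' @param session_length utterances per conversation (5, 10 or 15).
#' @param n_speakers speakers per conversation, `>= 2` and at most
#'   `session_length`.
#' @param depressed_utterance_fraction expected fraction of utterances seeded
#'   with depressive lexicon words.
#' @param depressed_speaker_fraction fraction of speakers designated as
#'   depressed (they receive the depressed utterances with probability 0.95).
#' @param candidates_per_demo candidate explanations per demonstration
#'   (default 3).
#' @param quality_levels overlap targets in `[0, 1]`, length
#'   `candidates_per_demo`.
#' @param redundancy_rate probability a candidate is a shuffled near-duplicate
#'   of a previous one.
#' @param label_flip_rate probability an utterance's gold label is flipped
#'   (annotation-noise knob; default 0).
#' @return an object of class `exrank_generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_conversations = 20L,
                             session_length = 5L,
                             n_speakers = 3L,
                             depressed_utterance_fraction = 0.2,
                             depressed_speaker_fraction = 0.3,
                             candidates_per_demo = 3L,
                             quality_levels = c(1.0, 0.5, 0.0),
                             redundancy_rate = 0.0,
                             label_flip_rate = 0.0) {
  stopifnot(is_number(seed), is_number(n_conversations), n_conversations >= 0,
            is_number(session_length), session_length >= 2,
            is_number(n_speakers), n_speakers >= 2)
  assert_fraction(depressed_utterance_fraction, "depressed_utterance_fraction")
  assert_fraction(depressed_speaker_fraction, "depressed_speaker_fraction")
  assert_fraction(redundancy_rate, "redundancy_rate")
  assert_fraction(label_flip_rate, "label_flip_rate")
  if (!is_number(candidates_per_demo) || candidates_per_demo < 1)
    stop("'candidates_per_demo' must be >= 1", call. = FALSE)
  for (q in quality_levels) assert_fraction(q, "quality_levels")
  if (length(quality_levels) != candidates_per_demo)
    stop("'quality_levels' must have length 'candidates_per_demo'",
         call. = FALSE)
  structure(list(seed = as.integer(seed),
                 n_conversations = as.integer(n_conversations),
                 session_length = as.integer(session_length),
                 n_speakers = as.integer(n_speakers),
                 depressed_utterance_fraction = depressed_utterance_fraction,
                 depressed_speaker_fraction = depressed_speaker_fraction,
                 candidates_per_demo = as.integer(candidates_per_demo),
                 quality_levels = as.numeric(quality_levels),
                 redundancy_rate = redundancy_rate,
                 label_flip_rate = label_flip_rate),
            class = "exrank_generator_config")
}

#' Neutral distractor vocabulary
#'
#' Fixed list of everyday, affect-neutral words shipped with the package.
#' Used to pad synthetic utterances and explanation candidates so that
#' token-overlap targets stay controllable.  Words overlapping the supplied
#' lexicons are filtered out at use.
#'
#' @return a character vector of words.
#' @export
distractor_words <- function() {
  path <- system.file("extdata", "distractor_words.txt", package = "exrank",
                      mustWork = TRUE)
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

lexicon_word_lists <- function(lexicons) {
  if (inherits(lexicons, "exrank_verbalizer")) lexicons <- lexicons$label_words
  if (is.null(lexicons$normal) || is.null(lexicons$depression) ||
      !length(lexicons$normal) || !length(lexicons$depression))
    stop("'lexicons' must supply at least one word per class", call. = FALSE)
  lapply(lexicons[c("normal", "depression")], tolower)
}

#' Generate synthetic conversations
#'
#' Each conversation has exactly `session_length` utterances from
#' `n_speakers` speakers.  An utterance is drawn depressive with probability
#' `depressed_utterance_fraction`; depressive utterances are seeded with 1-2
#' depression-lexicon words among neutral distractors and their gold label is
#' `depression`; other utterances mix neutral words with occasional
#' normal-lexicon words and are labeled `normal`.  Depressive utterances are
#' attributed to the conversation's designated depressed speakers with
#' probability 0.95, and every designated depressed speaker is guaranteed at
#' least one depressive utterance.  Output is fully determined by the config.
#'
#' @param config an [generator_config()].
#' @param lexicons an [verbalizer()] or a named list with `normal` and
#'   `depression` word vectors.
#' @return a list of [conversation()]s.
#' @export
generate_conversations <- function(config, lexicons = default_verbalizer()) {
  stopifnot(inherits(config, "exrank_generator_config"))
  lex <- lexicon_word_lists(lexicons)
  if (config$n_speakers > config$session_length)
    stop("'n_speakers' may not exceed 'session_length'", call. = FALSE)
  neutral <- setdiff(distractor_words(), unlist(lex))
  local_seed(config$seed, {
    lapply(seq_len(config$n_conversations), function(ci) {
      speakers <- sprintf("S%d", seq_len(config$n_speakers))
      dep <- stats::runif(config$session_length) < config$depressed_utterance_fraction
      n_dep <- sum(dep)
      dep_speakers <- character(0)
      if (n_dep > 0) {
        n_dep_sp <- min(n_dep,
                        max(1L, round(config$depressed_speaker_fraction *
                                        config$n_speakers)))
        dep_speakers <- sample(speakers, n_dep_sp)
      }
      speaker_of <- vapply(seq_len(config$session_length), function(i) {
        if (dep[[i]] && stats::runif(1) < 0.95) sample(dep_speakers, 1)
        else sample(speakers, 1)
      }, character(1))
      # every designated depressed speaker emits >= 1 depressive utterance
      # (n_dep_sp <= n_dep, so one slot each is always available)
      dep_idx <- which(dep)
      if (length(dep_speakers))
        speaker_of[dep_idx[seq_along(dep_speakers)]] <- dep_speakers
      utts <- lapply(seq_len(config$session_length), function(i) {
        if (dep[[i]]) {
          n_lex <- 1L + stats::rbinom(1, 1, 0.5)
          words <- c(sample(lex$depression, n_lex, replace = n_lex > length(lex$depression)),
                     sample(neutral, 4))
        } else if (stats::runif(1) < 0.5) {
          words <- c(sample(lex$normal, 1), sample(neutral, 5))
        } else {
          words <- sample(neutral, 6)
        }
        label <- if (dep[[i]]) "depression" else "normal"
        if (config$label_flip_rate > 0 &&
            stats::runif(1) < config$label_flip_rate)
          label <- setdiff(c("normal", "depression"), label)
        utterance(utterance_id = sprintf("c%04d_u%02d", ci, i - 1L),
                  speaker_id = speaker_of[[i]],
                  text = paste(sample(words), collapse = " "),
                  position = i - 1L, gold_label = label)
      })
      conversation(sprintf("c%04d", ci), utts)
    })
  })
}

#' Generate synthetic labeled demonstrations
#'
#' Half the demonstrations (rounded up) are depressive; texts follow the
#' same lexicon-seeding scheme as [generate_conversations()] but are a
#' little longer (8 tokens) since demonstrations stand for full posts.
#'
#' @param n number of demonstrations.
#' @param config an [generator_config()] (provides the seed).
#' @param lexicons as in [generate_conversations()].
#' @return a list of [demonstration()]s.
#' @export
generate_demonstrations <- function(n, config, lexicons = default_verbalizer()) {
  lex <- lexicon_word_lists(lexicons)
  neutral <- setdiff(distractor_words(), unlist(lex))
  local_seed(config$seed + 104729, {
    lapply(seq_len(n), function(i) {
      depressed <- i <= ceiling(n / 2)
      words <- if (depressed)
        c(sample(lex$depression, 2), sample(neutral, 6))
      else
        c(sample(lex$normal, 2), sample(neutral, 6))
      demonstration(sprintf("d%03d", i), paste(sample(words), collapse = " "),
                    if (depressed) "depression" else "normal",
                    source = "synthetic")
    })
  })
}

#' Generate one gold explanation per demonstration
#'
#' A gold explanation quotes all of its demonstration's content tokens, adds
#' class-appropriate lexicon words and pads with neutral scaffold words to 20
#' distinct tokens, mimicking an expert rationale that cites the evidence in
#' the example.  Tokens are kept in *salience order* — demonstration evidence
#' first, then lexicon, then scaffold — which downstream candidate generation
#' exploits: better candidates quote more of the actual evidence.
#'
#' @param demos list of [demonstration()]s.
#' @inheritParams generate_demonstrations
#' @return a list of [gold_explanation()]s, one per demonstration.
#' @export
generate_gold_explanations <- function(demos, config,
                                       lexicons = default_verbalizer()) {
  lex <- lexicon_word_lists(lexicons)
  neutral <- setdiff(distractor_words(), unlist(lex))
  local_seed(config$seed + 224737, {
    lapply(demos, function(d) {
      demo_toks <- unique(tokenize(d$text))
      lex_words <- if (d$label == "depression") lex$depression else lex$normal
      toks <- unique(c(demo_toks, sample(lex_words, min(3, length(lex_words)))))
      pad <- sample(setdiff(neutral, toks), max(0, 20 - length(toks)))
      gold_explanation(paste0(d$demo_id, "_g"),
                       paste(c(toks, pad), collapse = " "),
                       d$demo_id)
    })
  })
}

#' Generate candidate explanations for one demonstration
#'
#' Candidate i copies the *first* `round(quality_levels[i] * n)` of the gold
#' explanation's `n` distinct tokens — the gold's tokens are stored in
#' salience order (demonstration evidence, then lexicon, then scaffold), so a
#' higher-quality candidate quotes more of the demonstration's actual
#' evidence — and pads with neutral distractor tokens disjoint from the gold,
#' so its token-set overlap with the gold (its factuality) equals the target
#' up to rounding.  With probability `redundancy_rate` a candidate (after the
#' first) is instead a token-shuffle of a previously emitted candidate.
#' Deterministic given (config, demo).
#'
#' @param demo a [demonstration()].
#' @param gold its [gold_explanation()]; must have at least 5 distinct tokens.
#' @param config an [generator_config()].
#' @return a list of `config$candidates_per_demo` [explanation()]s.
#' @export
generate_explanation_candidates <- function(demo, gold, config) {
  stopifnot(inherits(config, "exrank_generator_config"))
  gold_toks <- unique(tokenize(as_text(gold)))
  n <- length(gold_toks)
  if (n < 5)
    stop("gold explanation has fewer than 5 tokens; overlap targets cannot be hit",
         call. = FALSE)
  pad_pool <- setdiff(distractor_words(), gold_toks)
  if (length(pad_pool) < n)
    stop("distractor vocabulary too small for padding", call. = FALSE)
  local_seed((config$seed * 7919 + stable_hash(demo$demo_id)) %% 2147483647, {
    texts <- character(config$candidates_per_demo)
    for (i in seq_len(config$candidates_per_demo)) {
      if (i > 1 && stats::runif(1) < config$redundancy_rate) {
        src <- sample(i - 1, 1)
        texts[[i]] <- paste(sample(tokenize(texts[[src]])), collapse = " ")
      } else {
        g <- round(config$quality_levels[[i]] * n)
        toks <- c(if (g > 0) utils::head(gold_toks, g),
                  if (g < n) sample(pad_pool, n - g))
        texts[[i]] <- paste(sample(toks), collapse = " ")
      }
    }
    lapply(seq_along(texts), function(i)
      explanation(sprintf("%s_e%d", demo$demo_id, i), texts[[i]],
                  demo$demo_id, generator = "synthetic"))
  })
}

#' Build candidate sets for utterance-level screening evaluation
#'
#' Pools utterances across the supplied conversations and draws `n_sets`
#' evaluation sets of exactly 10 candidates, exactly one of which is
#' gold-depressed — the unit on which recall-at-1-of-10 is computed.
#'
#' @param conversations list of [conversation()]s with gold labels.
#' @param n_sets number of sets to draw.
#' @param seed integer seed.
#' @return a list of `exrank_candidate_set` objects, each with `set_id`,
#'   `candidates` (10 utterances) and `positive_id`.
#' @export
generate_duc_candidate_sets <- function(conversations, n_sets, seed = 1L) {
  utts <- unlist(lapply(conversations, `[[`, "utterances"), recursive = FALSE)
  labels <- vapply(utts, `[[`, character(1), "gold_label")
  dep <- utts[labels == "depression"]
  norm <- utts[labels == "normal"]
  if (n_sets > 0 && (length(dep) < 1 || length(norm) < 9))
    stop("insufficient pool: need >= 1 depressed and >= 9 normal utterances",
         call. = FALSE)
  local_seed(seed, {
    lapply(seq_len(n_sets), function(i) {
      pos <- dep[[sample(length(dep), 1)]]
      negs <- norm[sample(length(norm), 9)]
      cands <- c(list(pos), negs)[sample(10)]
      structure(list(set_id = sprintf("set%04d", i), candidates = cands,
                     positive_id = pos$utterance_id),
                class = "exrank_candidate_set")
    })
  })
}

#' Generate a complete synthetic corpus bundle
#'
#' Conversations, demonstrations, gold explanations, candidate explanations
#' and the shipped diagnostic criteria, packaged for the downstream
#' experiment drivers and the CLI.
#'
#' @param config an [generator_config()].
#' @param n_demos number of demonstrations.
#' @param lexicons as in [generate_conversations()].
#' @return a list of class `exrank_bundle` with elements `conversations`,
#'   `demonstrations`, `gold_explanations`, `explanations`, `criteria` and
#'   the `config`.
#' @export
generate_corpus_bundle <- function(config = generator_config(), n_demos = 10L,
                                   lexicons = default_verbalizer()) {
  convs <- generate_conversations(config, lexicons)
  demos <- generate_demonstrations(n_demos, config, lexicons)
  golds <- generate_gold_explanations(demos, config, lexicons)
  cands <- unlist(lapply(seq_along(demos), function(i)
    generate_explanation_candidates(demos[[i]], golds[[i]], config)),
    recursive = FALSE)
  criteria <- read_criteria(system.file("extdata",
                                        "criteria_depression_synthetic.txt",
                                        package = "exrank", mustWork = TRUE))
  structure(list(conversations = convs, demonstrations = demos,
                 gold_explanations = golds, explanations = cands,
                 criteria = criteria, config = config),
            class = "exrank_bundle")
}
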