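#' Utterance-level screening loss (binary cross-entropy)
#'
#' Loss for a matching probability `u` against the binary ground truth `z`
#' (1 when the utterance is the depressive match, 0 otherwise):
#' `-[z * ln(u) + (1 - z) * ln(1 - u)]`.  `u` is clamped to
#' `[1e-12, 1 - 1e-12]` before the logs.
#'
#' @param u matching probability in `(0, 1)` (vectorised).
#' @param z binary ground truth, 0 or 1 (vectorised, recycled with `u`).
#' @return the loss, `>= 0`.
#' @examples
#' duc_loss(0.5, 1)  # ln 2
#' @export
duc_loss <- function(u, z) {
  if (!is.numeric(z) || !all(z %in% c(0, 1)))
    stop("'z' must be binary (0 or 1)", call. = FALSE)
  if (!is.numeric(u) || anyNA(u)) stop("'u' must be numeric", call. = FALSE)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  -(z * log(u) + (1 - z) * log(1 - u))
}

#' Speaker-identification loss over utterance pairs
#'
#' Cross-entropy over the positive (same-speaker) pairs only:
#' `-sum over pairs with same_speaker = 1 of ln(u)`, with `u` clamped as in
#' [duc_loss()].  Negative pairs contribute nothing; an input with no
#' positive pairs scores 0 (with a warning for an entirely empty input).
#'
#' @param pair_probs a data frame (or list coercible to one) with columns
#'   `u` (matching probability) and `same_speaker` (0/1).
#' @return the loss, `>= 0`.
#' @export
dsi_loss <- function(pair_probs) {
  pair_probs <- as.data.frame(pair_probs)
  if (!nrow(pair_probs)) {
    warning("empty pair list; loss is 0")
    return(0)
  }
  if (!all(c("u", "same_speaker") %in% names(pair_probs)))
    stop("'pair_probs' needs columns 'u' and 'same_speaker'", call. = FALSE)
  if (!all(pair_probs$same_speaker %in% c(0, 1)))
    stop("'same_speaker' must be binary", call. = FALSE)
  u <- pmin(pmax(pair_probs$u, 1e-12), 1 - 1e-12)
  pos <- pair_probs$same_speaker == 1
  if (!any(pos)) return(0)
  -sum(log(u[pos]))
}

#' Scorer contracts
#'
#' A scorer maps `(prompt, candidate text)` to a matching probability in
#' `[0, 1]`, deterministically.  [lexicon_scorer()] is the default mock: the
#' depression class probability of [classify_utterance()] computed on the
#' candidate text concatenated with the prompt's demonstration/explanation
#' blocks.  [random_scorer()] is a hash-based uniform scorer used for
#' calibration checks (deterministic given inputs, uniformly distributed
#' across distinct texts).
#'
#' @param verbalizer an [verbalizer()]; must contain a `depression` class.
#' @return an object of class `exrank_scorer` with fields `name` and
#'   `score(prompt, text)`.
#' @export
lexicon_scorer <- function(verbalizer = default_verbalizer()) {
  stopifnot(inherits(verbalizer, "exrank_verbalizer"))
  if (!"depression" %in% verbalizer$classes)
    stop("verbalizer must contain a 'depression' class", call. = FALSE)
  provider <- lexicon_provider(verbalizer)
  structure(list(
    name = "lexicon",
    score = function(prompt, text) {
      context <- if (nzchar(prompt)) paste(text, prompt) else text
      res <- classify_utterance(context, verbalizer, provider)
      unname(res$class_probs[["depression"]])
    }), class = "exrank_scorer")
}

#' @rdname lexicon_scorer
#' @param seed integer seed mixed into the hash.
#' @export
random_scorer <- function(seed = 1L) {
  seed <- as.integer(seed)
  structure(list(
    name = "random-hash",
    score = function(prompt, text) {
      stable_hash(paste(seed, text, prompt)) / 2147483646
    }), class = "exrank_scorer")
}

#' Recall at 1 of 10 over candidate sets
#'
#' For each 10-candidate set, all candidates are scored against the prompt
#' and ranked in descending score order (ties resolve to the lowest
#' candidate index); the set is a hit iff the top-1 candidate is the single
#' gold-depressed one.  The metric is the hit fraction over sets.
#'
#' @param sets list of candidate sets from [generate_duc_candidate_sets()].
#' @param scorer an `exrank_scorer`.
#' @param prompt the assembled prompt string (may be `""`).
#' @return an `exrank_report` with `metric = "r10_at_1"`, `value`, `n_items`
#'   and a `per_item` data frame.
#' @export
recall_at_1_of_10 <- function(sets, scorer, prompt = "") {
  stopifnot(inherits(scorer, "exrank_scorer"))
  if (!length(sets)) stop("need at least one candidate set", call. = FALSE)
  per <- lapply(sets, function(s) {
    stopifnot(inherits(s, "exrank_candidate_set"))
    u <- vapply(s$candidates, function(cand) scorer$score(prompt, cand$text),
                numeric(1))
    if (anyNA(u) || any(u < 0) || any(u > 1))
      stop("scorer contract violation: scores must lie in [0, 1]",
           call. = FALSE)
    top <- order(-u)[[1]]   # stable: ties go to the lowest index
    data.frame(set_id = s$set_id,
               top_id = s$candidates[[top]]$utterance_id,
               positive_id = s$positive_id,
               hit = s$candidates[[top]]$utterance_id == s$positive_id,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(metric = "r10_at_1", value = mean(per$hit),
                 n_items = nrow(per), per_item = per),
            class = "exrank_report")
}

#' Speaker-level F1 for depressed-speaker identification
#'
#' A speaker (within their conversation) is predicted depressed iff any of
#' their utterances scores `>= threshold`; the gold standard marks a speaker
#' depressed iff they have at least one gold-depressed utterance.  F1 is
#' computed over all (conversation, speaker) pairs, with the 0-convention
#' when precision + recall is 0.
#'
#' @param conversations list of [conversation()]s with gold labels.
#' @param scorer an `exrank_scorer`.
#' @param prompt the assembled prompt string.
#' @param threshold decision threshold on the matching probability.
#' @return an `exrank_report` with `metric = "dsi_f1"`.
#' @export
dsi_f1 <- function(conversations, scorer, prompt = "", threshold = 0.5) {
  stopifnot(inherits(scorer, "exrank_scorer"))
  assert_fraction(threshold, "threshold")
  rows <- lapply(conversations, function(cv) {
    sp <- vapply(cv$utterances, `[[`, character(1), "speaker_id")
    gold <- vapply(cv$utterances, `[[`, character(1), "gold_label")
    u <- vapply(cv$utterances, function(x) scorer$score(prompt, x$text),
                numeric(1))
    if (anyNA(u) || any(u < 0) || any(u > 1))
      stop("scorer contract violation: scores must lie in [0, 1]",
           call. = FALSE)
    data.frame(conversation_id = cv$conversation_id, speaker_id = unique(sp),
               gold_depressed = vapply(unique(sp), function(s)
                 any(gold[sp == s] == "depression"), logical(1)),
               predicted_depressed = vapply(unique(sp), function(s)
                 any(u[sp == s] >= threshold), logical(1)),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (!any(rows$gold_depressed))
    stop("no gold-depressed speakers in the corpus", call. = FALSE)
  tp <- sum(rows$gold_depressed & rows$predicted_depressed)
  fp <- sum(!rows$gold_depressed & rows$predicted_depressed)
  fn <- sum(rows$gold_depressed & !rows$predicted_depressed)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  structure(list(metric = "dsi_f1", value = f1, n_items = nrow(rows),
                 per_item = rows,
                 counts = c(tp = tp, fp = fp, fn = fn)),
            class = "exrank_report")
}

#' Experiment configuration for the downstream drivers
#'
#' @param shots number of demonstrations in the prompt (0, 2 or 5 in the
#'   reference design; any non-negative integer is accepted).
#' @param use_explanations attach explanations to each demonstration?
#' @param n_explanations explanations per demonstration (1-3).
#' @param explanation_order `"most_to_least"` (selection order) or
#'   `"least_to_most"` (reversed).
#' @param use_ranking select explanations with [hybrid_select()] (`TRUE`) or
#'   take the first `n_explanations` unranked candidates (`FALSE`, the
#'   "without hybrid ranking" ablation arm).
#' @param seed integer seed for demonstration sampling and set construction.
#' @return an object of class `exrank_experiment_config`.
#' @export
experiment_config <- function(shots = 5L, use_explanations = TRUE,
                              n_explanations = 2L,
                              explanation_order = c("most_to_least",
                                                    "least_to_most"),
                              use_ranking = TRUE, seed = 1L) {
  if (!is_number(shots) || shots < 0 || shots != floor(shots))
    stop("'shots' must be a non-negative integer", call. = FALSE)
  if (!is_number(n_explanations) || n_explanations < 1)
    stop("'n_explanations' must be >= 1", call. = FALSE)
  explanation_order <- match.arg(explanation_order)
  structure(list(shots = as.integer(shots),
                 use_explanations = isTRUE(use_explanations),
                 n_explanations = as.integer(n_explanations),
                 explanation_order = explanation_order,
                 use_ranking = isTRUE(use_ranking),
                 seed = as.integer(seed)),
            class = "exrank_experiment_config")
}

select_demo_explanations <- function(demo, bundle, exp_config, ranking_config,
                                     backend) {
  cands <- Filter(function(e) identical(e$demo_id, demo$demo_id),
                  bundle$explanations)
  if (!length(cands)) return(list())
  n <- min(exp_config$n_explanations, length(cands))
  if (exp_config$use_ranking) {
    rc <- ranking_config
    rc$k <- n
    profile <- relevance_probabilities(cands, query = demo$text,
                                       demos = list(),
                                       criteria = bundle$criteria,
                                       backend = backend, config = rc)
    sel <- hybrid_select(cands, profile, query = demo$text,
                         backend = backend, config = rc)
    picked <- cands[sel$order]
  } else {
    picked <- cands[seq_len(n)]
  }
  if (exp_config$explanation_order == "least_to_most") picked <- rev(picked)
  picked
}

#' Run one downstream experiment arm
#'
#' Builds a few-shot prompt from the bundle per the experiment config —
#' `shots` sampled demonstrations, each with its top `n_explanations`
#' explanations selected by [hybrid_select()] (or the first unranked
#' candidates in the ablation arm), ordered as configured — then evaluates
#' recall at 1 of 10 (`task = "duc"`) over freshly drawn candidate sets or
#' speaker F1 (`task = "dsi"`) over the bundle's conversations, using the
#' supplied scorer.  Fully deterministic given (bundle, configs).
#'
#' @param bundle a corpus bundle from [generate_corpus_bundle()] (or the
#'   same shape loaded from files).
#' @param exp_config an [experiment_config()].
#' @param rank_config a [ranking_config()].
#' @param verbalizer an [verbalizer()] for the default scorer.
#' @param backend an `exrank_backend`.
#' @param task `"duc"` or `"dsi"`.
#' @param n_sets number of candidate sets for the DUC task.
#' @param scorer optional `exrank_scorer`; defaults to
#'   [lexicon_scorer()] over `verbalizer`.
#' @param template a [soft_template()] for prompt assembly.
#' @param threshold DSI decision threshold.
#' @return an `exrank_report` with the metric value, per-item rows, the
#'   prompt used and an echo of the configuration.
#' @export
run_experiment <- function(bundle, exp_config = experiment_config(),
                           rank_config = ranking_config(),
                           verbalizer = default_verbalizer(),
                           backend = mock_embedding_backend(),
                           task = c("duc", "dsi"), n_sets = 50L,
                           scorer = NULL, template = soft_template(),
                           threshold = 0.5) {
  task <- match.arg(task)
  stopifnot(inherits(exp_config, "exrank_experiment_config"))
  if (exp_config$shots > length(bundle$demonstrations))
    stop("'shots' exceeds the number of available demonstrations",
         call. = FALSE)
  if (is.null(scorer)) scorer <- lexicon_scorer(verbalizer)

  # demonstrations are sampled class-balanced (the usual practice for
  # few-shot prompts): an all-one-class prompt starves the verbalizer of one
  # class's label words and degenerates the mock scorer
  demos <- if (exp_config$shots > 0) {
    labels <- vapply(bundle$demonstrations, `[[`, character(1), "label")
    local_seed(exp_config$seed, {
      picked <- integer(0)
      classes <- unique(labels)
      per_class <- floor(exp_config$shots / length(classes))
      for (cl in classes) {
        pool <- which(labels == cl)
        picked <- c(picked, pool[sample(length(pool),
                                        min(per_class, length(pool)))])
      }
      leftover <- setdiff(seq_along(labels), picked)
      extra <- exp_config$shots - length(picked)
      if (extra > 0)
        picked <- c(picked, leftover[sample(length(leftover), extra)])
      bundle$demonstrations[sample(picked)]
    })
  } else list()

  expls <- if (exp_config$use_explanations && length(demos)) {
    unlist(lapply(demos, select_demo_explanations, bundle = bundle,
                  exp_config = exp_config, ranking_config = rank_config,
                  backend = backend),
           recursive = FALSE)
  } else list()

  prompt <- if (length(demos)) {
    assemble_template("classify the following utterance", template,
                      demos = demos, explanations = expls)
  } else ""

  report <- if (task == "duc") {
    sets <- generate_duc_candidate_sets(bundle$conversations, n_sets,
                                        seed = exp_config$seed + 1L)
    recall_at_1_of_10(sets, scorer, prompt)
  } else {
    dsi_f1(bundle$conversations, scorer, prompt, threshold)
  }
  report$prompt <- prompt
  report$config <- exp_config
  report$task <- task
  report
}

#' @export
print.exrank_report <- function(x, ...) {
  cat(sprintf("<%s = %.4f over %d items>\n", x$metric, x$value, x$n_items))
  invisible(x)
}
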