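# Shared fixtures, built in code.

shipped_criteria <- function() {
  read_criteria(system.file("extdata", "criteria_depression_synthetic.txt",
                            package = "exrank", mustWork = TRUE))
}

make_conversation <- function(id = "c1", texts = c("hello there", "fine thanks"),
                              speakers = NULL, labels = NULL) {
  n <- length(texts)
  if (is.null(speakers)) speakers <- rep(c("S1", "S2"), length.out = n)
  if (is.null(labels)) labels <- rep("unknown", n)
  conversation(id, lapply(seq_len(n), function(i)
    utterance(sprintf("%s_u%d", id, i - 1), speakers[[i]], texts[[i]],
              i - 1, labels[[i]])))
}

# scorer that knows the gold labels of a pool of utterances
oracle_scorer <- function(conversations, invert = FALSE) {
  utts <- unlist(lapply(conversations, `[[`, "utterances"), recursive = FALSE)
  lut <- stats::setNames(
    vapply(utts, `[[`, character(1), "gold_label"),
    vapply(utts, `[[`, character(1), "text"))
  structure(list(
    name = if (invert) "anti-oracle" else "oracle",
    score = function(prompt, text) {
      hit <- unname(lut[text]) == "depression"
      u <- ifelse(is.na(hit), 0, as.numeric(hit))
      if (invert) 1 - u else u
    }), class = "exrank_scorer")
}

constant_scorer <- function(value = 0.5) {
  structure(list(name = "constant",
                 score = function(prompt, text) value),
            class = "exrank_scorer")
}
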