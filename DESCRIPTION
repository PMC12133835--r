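Package: exrank
Title: Hybrid ERR-MMR Ranking of Free-Text Explanations for Few-Shot
    Depression Screening Prompts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting free-text explanations to accompany
    in-context demonstrations when prompting language models for
    depression screening in multi-party conversations.  Candidate
    explanations are scored for semantic relevance against the query,
    the retrieved demonstrations and a set of diagnostic-criteria
    statements, then ranked by a greedy hybrid of expected reciprocal
    rank (ERR) and maximal marginal relevance (MMR).  The package also
    provides factuality (lexical-overlap) and consistency
    (greedy-token-matching F1) metrics for explanations, soft-template
    prompt assembly with verbalizer-based utterance classification, a
    deterministic synthetic-corpus generator, and evaluation harnesses
    for depressed-utterance classification (recall at 1 of 10) and
    depressed-speaker identification (F1).  All large-model
    dependencies sit behind pluggable contracts with deterministic mock
    backends, so the full pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
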