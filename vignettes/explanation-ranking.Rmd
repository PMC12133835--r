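---
title: "Ranking free-text explanations for few-shot depression screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking free-text explanations for few-shot depression screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exrank)
```

## The problem

Few-shot prompts for depression screening in multi-party conversations
(MPCs) consist of a query conversation, a handful of labelled
demonstrations, and — when they help — a free-text explanation attached to
each demonstration saying why it carries its label. Generative models
produce several candidate explanations per demonstration, of uneven quality
and with frequent near-duplicates. `exrank` addresses the selection
problem: among the candidates, which few explanations should enter the
prompt?

Two failure modes matter. An *irrelevant* explanation wastes prompt budget
and dilutes the signal; a *redundant* one adds nothing the prompt does not
already contain. The selection rule therefore combines a relevance cascade
with a diversity penalty.

## The selection procedure

Every candidate is embedded alongside the query, the demonstrations and a
list of diagnostic-criteria statements. Cosine similarities are clipped to
`[0, 1]` before use — relevance inputs are probabilities, and a negative
cosine carries no usable "anti-relevance" signal from a bag-of-tokens
backend. A candidate's raw relevance mixes the *average* clipped similarity
to query-plus-demonstrations with the *best* clipped similarity to any
criteria statement, weighted by `criteria_weight`; raw scores are
sum-normalised into a relevance profile `p` (uniform if all raw scores are
zero, so degenerate pools still rank deterministically).

Selection is greedy. At round `r`, each unselected candidate `e` is scored

* an **expected-reciprocal-rank contribution**: under a cascade model a
  reader inspects explanations top-down and stops at the first satisfying
  one, so placing `e` at rank `r` is worth
  `(1/r) * prod(1 - gamma * p_s) * gamma * p_e` over the already selected
  `s`. Summing these contributions along any ranking reproduces the
  classical ERR score of that ranking exactly (the package tests this
  identity to 1e-12 on a thousand random instances), so the greedy rule is
  a per-position decomposition of ERR rather than a separate heuristic; and
* a **maximal-marginal-relevance term**
  `lambda * sim(e, query) - (1 - lambda) * max_s sim(e, s)`, the standard
  trade-off between query relevance and redundancy with what is already
  chosen, with the empty-selection maximum defined as 0.

The two terms are summed unweighted and the argmax is selected, ties going
to the lowest candidate index for determinism. ERR is defined on a whole
ranking while MMR is defined per item; the per-position greedy sum is the
one reading under which "pick the argmax at each step" is well defined, and
it is adopted here as a documented design choice rather than a claim about
the only possible aggregation.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `gamma` | 0.85 | ERR decay: probability scale at which a relevant item "satisfies" the reader and discounts everything below it |
| `lam` | 0.5 | MMR trade-off: 1 = pure relevance, 0 = pure diversity |
| `k` | 2 | explanations kept per demonstration |
| `criteria_weight` | 0.5 | weight of diagnostic-criteria similarity against query/demonstration similarity |
| `max_length` | 3000 tokens | prompt budget; demonstration blocks are dropped from the end, never the query |
| `candidates_per_demo` | 3 | candidate explanations generated per demonstration |

`gamma = 0.85`, `lam = 0.5` and `k = 2` are the reference operating point
for this selection task; `criteria_weight = 0.5` is this package's choice —
the criteria are embedded into the same space as everything else, and with
no stated mixing rule an even split is the neutral default. The tie rule in
classification predicts `normal` on an exact tie: a screening tool should
not default to the clinical label.

## Mock backends and what they do (and do not) show

All model-sized components are contracts with deterministic mocks:

* **Embeddings.** Each token maps through a stable 31-polynomial string
  hash (exact in doubles, identical across platforms and sessions) to a
  seeded Gaussian vector; a text embeds as the normalised mean over its
  distinct tokens. Two texts are similar in proportion to their token
  overlap. The default dimension is 384, matching the MiniLM-class sentence
  encoders the mock stands in for; dimension also sets the mock's noise
  floor, since cosines between token-disjoint texts fluctuate around zero
  with standard deviation about `1/sqrt(dimension)` (0.05 at 384, which
  keeps the relevance gradients used by the selection rule well above
  noise; at 64 the noise floor of 0.125 drowns them).
* **Mask probabilities.** The verbalizer's label-word probability given a
  context is a lexicon count: occurrences of the word among the context
  tokens over one plus all label-word occurrences. Class scores are label-
  word sums, normalised; all-zero contexts are uniform.
* **Scorers.** The default downstream scorer is the depression class
  probability of the lexicon classifier on the candidate text concatenated
  with the prompt; a hash-based uniform scorer supports calibration checks.
  One consequence of counting over the concatenated context: when a prompt
  is attached, the absolute class probability is dominated by the prompt's
  label-word balance, so thresholded decisions (the speaker task at
  threshold 0.5) reflect demonstration sampling more than the utterance.
  *Ranking-based* metrics such as R₁₀@1 are unaffected, since the prompt
  shifts every candidate in a set equally; the speaker metric is therefore
  most interpretable on the zero-shot arm, which is what the reproduction
  script reports.

These mocks capture lexical overlap, not meaning. A paraphrase with
disjoint vocabulary looks unrelated; a contradiction sharing vocabulary
looks similar. Green tests therefore certify the *selection machinery* —
formula correctness, determinism, redundancy handling, metric plumbing —
not linguistic quality on real data. Real encoders and scorers satisfy the
same contracts and can be substituted without touching any calling code.

## The synthetic corpus

The generator emulates the *structure* of social-media depression corpora,
not their language. Conversations have exactly 5, 10 or 15 utterances from
`n_speakers` speakers; an utterance is depressive with probability
`depressed_utterance_fraction` (default 0.2, a minority rate in line with
user-level prevalence in public screening corpora) and is then seeded with
one or two depression-lexicon words among neutral distractors; its gold
label is `depression` exactly when such a word was seeded. Depressive
utterances go to a designated minority of depressed speakers with
probability 0.95, and every depressed speaker emits at least one, so
speaker-level ground truth is recoverable. An optional label-flip rate
models annotation noise and defaults to 0.

Because labels coincide with seeded lexicon words, the lexicon classifier
recovers gold labels perfectly at zero noise. This closure property is
deliberate: it makes downstream metrics interpretable end to end (a perfect
scorer must yield R₁₀@1 = 1), at the price that the mock downstream tasks
sit at or near ceiling — the five-shot-versus-zero-shot comparison verifies
that prompt assembly and explanation attachment *do no harm* and that the
machinery is wired correctly, not that explanations rescue a weak
classifier. Class-balanced demonstration sampling (the usual practice for
few-shot prompts) is part of that: an all-one-class prompt starves the
verbalizer of one class's label words and degenerates the count-based
scorer.

Gold explanations quote all content tokens of their demonstration, add
class lexicon words, and pad with neutral scaffold to 20 distinct tokens,
stored in *salience order*: demonstration evidence first, then lexicon,
then scaffold. A candidate at quality target `q` copies the first
`round(q * n)` gold tokens and pads with distractors disjoint from the
gold, so its factuality equals `q` up to rounding and — because better
candidates quote more of the demonstration's actual evidence — its semantic
relevance to the query rises with `q` by construction. That is the point of
the generator: *controlled* relevance. With uniformly sampled gold tokens
instead, a mid-quality candidate shares about half its tokens with the
top candidate and the MMR penalty cancels its query-similarity advantage in
expectation, leaving selection to noise.

`redundancy_rate` (the probability that a candidate is a token-shuffle of
an earlier one) defaults to 0, because a duplicate cannot obey its own
slot's overlap target; raise it deliberately to stress the MMR penalty,
which under set-based similarity sees a shuffled copy at similarity 1.

## Numerical choices

* Probabilities are clamped to `[1e-12, 1 - 1e-12]` before logs in both
  losses; natural log throughout.
* The utterance-level loss is binary cross-entropy; the speaker-level loss
  is cross-entropy over same-speaker positive pairs only (negative pairs
  contribute nothing, an empty input warns and scores 0).
* The speaker decision threshold defaults to 0.5 and is configurable.
* Ranking ties break to the lowest candidate index; score comparisons use a
  1e-15 slack so floating-point noise cannot flip a tie.
* JSONL is written in binary mode with full double precision, so re-reading
  scores reproduces them to well under 1e-9 and re-runs are byte-identical.

## Test and evaluation problem sizes

The test suite exercises the statistical properties at sizes chosen to make
sampling error negligible relative to the margins being tested: 100 seeded
trials for the ranking-lifts-factuality property, 50 paired runs of 20
candidate sets each on a 200-conversation corpus for the five-shot
direction property, and 1000 candidate sets for the random-scorer
calibration, where each set is scored by a freshly seeded uniform scorer so
hits are independent and the exact binomial reference applies (utterances
recur across sets, so a single scorer would correlate them).

## Known limitations

* The mocks are lexical. Nothing here validates explanation quality against
  human judgement or clinical standards; the shipped criteria file is a
  synthetic paraphrase for testing, not a clinical instrument.
* Greedy selection is not globally optimal subset selection; the regression
  oracle in the tests re-scores the greedy prefix, it does not certify
  global optimality.
* Demonstration retrieval, explanation generation, soft-prompt training and
  the internals of any real language model are out of scope; they enter
  only through the contracts.
* The generator makes no attempt at linguistic realism, dialogue coherence,
  or clinically plausible symptom expression.
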