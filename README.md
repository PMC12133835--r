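# exrank

Selecting free-text explanations for in-context demonstrations in
depression screening from multi-party conversations (MPCs).

Few-shot prompting of a frozen language model works markedly better when
each retrieved demonstration is accompanied by a good free-text explanation
of *why* it carries its label. Given several candidate explanations per
demonstration, `exrank` picks the ones worth putting in the prompt: the most
semantically relevant to the query, the demonstrations and a set of
diagnostic-criteria statements, while avoiding redundant near-duplicates.
It also evaluates explanation quality (factuality, consistency), assembles
the resulting few-shot prompts, and scores the two downstream screening
tasks — depressed-utterance classification (DUC, metric R₁₀@1) and
depressed-speaker identification (DSI, metric F1) — against gold labels.

Everything model-sized sits behind a deterministic mock contract (a hashing
sentence-embedding backend, a lexicon-count mask-probability provider, a
pluggable scorer), and a synthetic-corpus generator produces
label-consistent conversations, demonstrations, gold explanations and
candidate explanations with controlled quality. The entire pipeline
therefore runs and is tested at desk scale, with no network, GPU or
external corpus; real encoders or scorers can be slotted in behind the same
contracts.

## The selection rule

Each candidate explanation *e* gets a relevance probability by mixing its
clipped cosine similarity to the query and demonstrations (averaged) with
its best similarity to the criteria statements, sum-normalised over the
pool:

    raw(e) = (1 − w) · mean_{r ∈ {q} ∪ D} cos⁺(e, r) + w · max_{c ∈ C} cos⁺(e, c)
    p(e)   = raw(e) / Σ raw

Selection is greedy over k rounds. At each round every unselected candidate
is scored by the sum of its marginal expected-reciprocal-rank term — the
cascade-model value of placing it at the next rank,

    ERRΔ(e) = (1/k) · Π_{s ∈ selected} (1 − γ p_s) · γ p(e)

— and its maximal-marginal-relevance term, which trades query relevance
against redundancy with what is already chosen:

    MMR(e) = λ · cos⁺(e, q) − (1 − λ) · max_{s ∈ selected} cos⁺(e, s)

The argmax wins (ties to the lowest index). Defaults are γ = 0.85, λ = 0.5,
k = 2, w = 0.5. Summed over any ranking, the ERRΔ terms reproduce the
classical ERR score of that ranking exactly.

Explanation quality is measured by **factuality** — the best token-set
overlap with an expert-written gold explanation, max over golds of
|tokens(e) ∩ tokens(g)| / |tokens(e)| — and **consistency**, a greedy
token-matching F1 (BERTScore style) between explanation and reference
context. Prompts follow a `[CLS] x p1 [SEP] p2 [EOS]` soft-template scheme
with labelled demonstration blocks; classification maps label-word
probabilities (e.g. *hurt, anger, moody, bored, sadness* for depression)
through a verbalizer onto class probabilities.

## Worked example

```r
library(exrank)

vb <- default_verbalizer()
classify_utterance("Oh! I wanted to hurt myself.", vb)
#> <classification: depression (normal=0.000, depression=1.000)>
classify_utterance("Where have you been?", vb)
#> <classification: normal (normal=0.500, depression=0.500)>   # no evidence: tie -> normal

err_score(c(0.5, 0.5), gamma = 0.85)
#> [1] 0.5471875

# rank the shipped 3-candidate example against a 4-utterance conversation
backend  <- mock_embedding_backend(seed = 42)
query    <- read_conversations(system.file("extdata", "example_query.jsonl",  package = "exrank"))[[1]]
demos    <- read_demonstrations(system.file("extdata", "example_demos.jsonl", package = "exrank"))
cands    <- read_explanations(system.file("extdata", "example_candidates.jsonl", package = "exrank"))
criteria <- read_criteria(system.file("extdata", "criteria_depression_synthetic.txt", package = "exrank"))

profile <- relevance_probabilities(cands, query, demos, criteria, backend)
hybrid_select(cands, profile, query, backend, ranking_config())
#> <ranked selection: 2 of 3 candidates>
#>  expl_id     s_comb   err_term    mmr_term
#>  d001_e2  0.5432756 0.36504527  0.17823037
#>  d001_e3 -0.0170445 0.06955936 -0.08660386
```

The first pick (`d001_e2`) is the candidate most similar to the query's
depressive content; the second pick skips `d001_e1` — a near-paraphrase of
the winner — in favour of the more distinct candidate, which is exactly the
redundancy penalty doing its job.

The same operations are scriptable through the CLI:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "exrank.R", package = "exrank"))')
Rscript $CLI simulate --seed 7 --n-conversations 50 --out bundle/
Rscript $CLI rank --query q.jsonl --candidates e.jsonl --criteria dsm.txt --k 2 --out ranked.jsonl
Rscript $CLI eval-downstream --task duc --bundle bundle/ --shots 5 --n-expl 2 --seed 7 --out report.json
```

Every subcommand writes a manifest (config, seed, package version) next to
its outputs, and identical configs and seeds produce byte-identical files.

### File formats

UTF-8 JSONL, one record per line:

```
conversations.jsonl      {"conversation_id":"c0001","utterances":[{"utterance_id":"c0001_u00",
                          "speaker_id":"S1","text":"...","position":0,"gold_label":"normal"}, ...]}
demonstrations.jsonl     {"demo_id":"d001","text":"...","label":"depression","source":"synthetic"}
explanations.jsonl       {"expl_id":"d001_e1","text":"...","demo_id":"d001","generator":"synthetic"}
gold_explanations.jsonl  {"gold_id":"d001_g","text":"...","demo_id":"d001"}
```

Criteria files are plain text, one statement per line, `#` comments
ignored. The shipped `criteria_depression_synthetic.txt` is a synthetic
DSM-5-style paraphrase for testing; substitute a clinically vetted file for
real use.

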