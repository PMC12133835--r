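# Independent oracle: literal transcription of the cascade sum, kept separate
# from the package's incremental implementation.
err_oracle <- function(probs, gamma) {
  total <- 0
  for (k in seq_along(probs)) {
    stopprob <- if (k > 1) prod(1 - gamma * probs[1:(k - 1)]) else 1
    total <- total + (1 / k) * stopprob * gamma * probs[[k]]
  }
  total
}

test_that("err_score matches hand-expanded and brute-force values", {
  # hand expansion: 0.425 + (1/2)(1 - 0.425)(0.425) = 0.5471875
  expect_equal(err_score(c(0.5, 0.5), gamma = 0.85), 0.5471875,
               tolerance = 1e-12)
  expect_identical(err_score(c(1), gamma = 1), 1)
  expect_identical(err_score(c(0, 0, 0), gamma = 0.3), 0)
  expect_identical(err_score(numeric(0), 0.85), 0)
  expect_equal(err_score(c(0.9, 0.1, 0.4), 0.85), err_oracle(c(0.9, 0.1, 0.4), 0.85))
  expect_error(err_score(c(0.5, 1.2), 0.85), "\\[0, 1\\]")
  expect_error(err_score(0.5, gamma = 0), "gamma")
})

test_that("err_contribution decomposes err_score exactly over random rankings", {
  expect_identical(err_contribution(1, numeric(0), gamma = 1), 1)
  # second term of the worked two-item example
  expect_equal(err_contribution(0.5, 0.5, gamma = 0.85), 0.1221875,
               tolerance = 1e-15)
  set.seed(20240915)
  for (i in 1:1000) {
    n <- sample(1:8, 1)
    probs <- runif(n)
    gamma <- runif(1, 0.05, 1)
    contribs <- vapply(seq_len(n), function(k)
      err_contribution(probs[[k]], probs[seq_len(k - 1)], gamma), numeric(1))
    expect_equal(sum(contribs), err_score(probs, gamma), tolerance = 1e-12)
  }
})

test_that("err_score monotonicity and bounds hold on random lists", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:7, 1)
    probs <- runif(n)
    gamma <- runif(1, 0.1, 1)
    # swapping a higher-p item earlier never decreases ERR
    j <- sample(n - 1, 1)
    swapped <- probs
    if (swapped[j] < swapped[j + 1]) swapped[c(j, j + 1)] <- swapped[c(j + 1, j)]
    expect_gte(err_score(swapped, gamma) + 1e-12, err_score(probs, gamma))
    expect_lte(err_score(probs, gamma), sum(1 / seq_len(n)))
  }
  expect_equal(err_score(0.73, 0.6), 0.6 * 0.73, tolerance = 1e-12)
})

test_that("mmr_score matches its worked cases and conventions", {
  expect_equal(mmr_score(0.9, c(0.7, 0.2), lam = 0.5), 0.10, tolerance = 1e-12)
  expect_identical(mmr_score(0.8, numeric(0), lam = 0.5), 0.4)
  expect_identical(mmr_score(0.63, c(0.9, 0.1), lam = 1), 0.63)
  # lam = 0: pure diversity
  expect_identical(mmr_score(0.9, c(0.3), lam = 0), -0.3)
  expect_error(mmr_score(1.2, numeric(0), 0.5), "cand_query_sim")
  expect_error(mmr_score(0.5, c(-0.1), 0.5), "\\[0, 1\\]")
})

test_that("relevance probabilities normalize, rank by overlap, and handle edge cases", {
  be <- mock_embedding_backend(1)
  crit <- shipped_criteria()
  cfg <- ranking_config()
  one <- relevance_probabilities(list(explanation("e1", "a b", "d")),
                                 "a b c", criteria = crit, backend = be,
                                 config = cfg)
  expect_identical(one$probs, 1)

  twin <- relevance_probabilities(
    list(explanation("e1", "same words here", "d"),
         explanation("e2", "same words here", "d")),
    "query text", criteria = crit, backend = be, config = cfg)
  expect_equal(twin$probs, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sum(twin$probs), 1, tolerance = 1e-9)

  q <- "sadness mood fatigue interest pleasure"
  shares <- relevance_probabilities(
    list(explanation("A", "sadness mood fatigue pencil ladder", "d"),
         explanation("B", "pencil ladder mirror carpet engine", "d")),
    q, criteria = crit, backend = be, config = cfg)
  expect_gt(shares$probs[[1]], shares$probs[[2]])

  expect_error(relevance_probabilities(list(), q, criteria = crit,
                                       backend = be, config = cfg),
               "at least one candidate")
  expect_error(relevance_probabilities(list(explanation("e", "t x", "d")), q,
                                       criteria = character(0), backend = be,
                                       config = cfg),
               "criteria")
})

test_that("defaults match the reference operating point", {
  cfg <- ranking_config()
  expect_identical(cfg$gamma, 0.85)
  expect_identical(cfg$lam, 0.5)
  expect_identical(cfg$k, 2L)
  expect_error(ranking_config(gamma = 1.5), "gamma")
  expect_error(ranking_config(lam = -0.1), "lam")
  expect_error(ranking_config(k = 0), "k")
})

test_that("hybrid selection avoids duplicates and handles degenerate ks", {
  be <- mock_embedding_backend(42)
  q <- "speaker said they wanted to hurt themselves and feels persistent sadness"
  cands <- list(
    explanation("A", "speaker feels hurt sadness and low mood daily", "d"),
    explanation("A2", "speaker feels hurt sadness and low mood daily", "d"),
    explanation("B", "speaker reports sadness hurt and loss of interest in things", "d"))
  equal_profile <- structure(
    list(candidate_ids = c("A", "A2", "B"), probs = rep(1 / 3, 3),
         raw_scores = rep(1, 3), query_sims = rep(NA_real_, 3),
         normalization = "sum"),
    class = "exrank_relevance_profile")

  sel <- hybrid_select(cands, equal_profile, q, be, ranking_config(k = 2))
  expect_identical(sel$selected$expl_id, c("A", "B"))

  # independent check by enumerating all ordered 2-subsets: the greedy pair
  # must beat any pair containing the duplicate on summed S_comb
  emb <- lapply(cands, function(e) embed_text(be, e$text))
  qe <- embed_text(be, q)
  s <- function(u, v) min(1, max(0, cosine_similarity(u, v)))
  pair_score <- function(i, j) {
    first <- err_contribution(1 / 3, numeric(0), 0.85) + mmr_score(s(emb[[i]], qe), numeric(0), 0.5)
    second <- err_contribution(1 / 3, 1 / 3, 0.85) +
      mmr_score(s(emb[[j]], qe), s(emb[[j]], emb[[i]]), 0.5)
    first + second
  }
  expect_equal(sum(sel$selected$s_comb), pair_score(1, 3), tolerance = 1e-12)
  expect_gt(pair_score(1, 3), pair_score(1, 2))

  # k >= pool: everything returned, ids distinct, greedy order
  all3 <- hybrid_select(cands, equal_profile, q, be, ranking_config(k = 10))
  expect_identical(nrow(all3$selected), 3L)
  expect_identical(anyDuplicated(all3$selected$expl_id), 0L)

  # k = 1, lam = 1: degenerate greedy = max(gamma * p + sim to query)
  prof <- relevance_probabilities(cands, q, criteria = shipped_criteria(),
                                  backend = be)
  top1 <- hybrid_select(cands, prof, q, be, ranking_config(k = 1, lam = 1))
  simq <- vapply(emb, function(e) s(e, qe), numeric(1))
  expect_identical(top1$selected$expl_id,
                   prof$candidate_ids[[which.max(0.85 * prof$probs + simq)]])
})

test_that("greedy selection reproduces a brute-force re-scoring of its own prefix", {
  be <- mock_embedding_backend(3)
  crit <- shipped_criteria()
  vocab <- c("sadness", "mood", "sleep", "energy", "guilt", "worth", "table",
             "window", "garden", "coffee", "river", "market")
  set.seed(99)
  for (trial in 1:10) {
    n <- sample(3:6, 1)
    k <- sample(1:3, 1)
    cands <- lapply(seq_len(n), function(i)
      explanation(sprintf("e%d", i),
                  paste(sample(vocab, 5), collapse = " "), "d"))
    q <- paste(sample(vocab, 5), collapse = " ")
    prof <- relevance_probabilities(cands, q, criteria = crit, backend = be)
    cfg <- ranking_config(k = k)
    sel <- hybrid_select(cands, prof, q, be, cfg)

    emb <- lapply(cands, function(e) embed_text(be, e$text))
    qe <- embed_text(be, q)
    s <- function(u, v) min(1, max(0, cosine_similarity(u, v)))
    total <- 0
    chosen <- integer(0)
    for (idx in sel$order) {
      total <- total +
        err_contribution(prof$probs[[idx]], prof$probs[chosen], cfg$gamma) +
        mmr_score(s(emb[[idx]], qe),
                  vapply(chosen, function(cc) s(emb[[idx]], emb[[cc]]),
                         numeric(1)),
                  cfg$lam)
      chosen <- c(chosen, idx)
    }
    expect_equal(sum(sel$selected$s_comb), total, tolerance = 1e-12)
    expect_identical(length(sel$order), min(k, n))
  }
})

test_that("hybrid selection of synthetic candidates beats the unranked mean on factuality", {
  be <- mock_embedding_backend(42)
  crit <- shipped_criteria()
  helped <- logical(40)
  for (s in seq_along(helped)) {
    cfg <- generator_config(seed = s)
    d <- generate_demonstrations(1, cfg)[[1]]
    g <- generate_gold_explanations(list(d), cfg)[[1]]
    cands <- generate_explanation_candidates(d, g, cfg)
    prof <- relevance_probabilities(cands, d$text, criteria = crit,
                                    backend = be)
    sel <- hybrid_select(cands, prof, d$text, be, ranking_config())
    f <- vapply(cands, factuality, numeric(1), golds = list(g))
    helped[s] <- mean(f[sel$order]) > mean(f)
  }
  expect_gte(mean(helped), 0.95)
})
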