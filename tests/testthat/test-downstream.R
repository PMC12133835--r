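test_that("losses match closed forms and are properly shaped", {
  expect_lt(duc_loss(1 - 1e-12, 1), 1e-9)
  expect_equal(duc_loss(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(duc_loss(0.25, 0), -log(0.75), tolerance = 1e-12)
  expect_error(duc_loss(0.5, 2), "binary")

  expect_lt(dsi_loss(data.frame(u = rep(1 - 1e-12, 3), same_speaker = 1)), 1e-8)
  expect_equal(dsi_loss(data.frame(u = 0.5, same_speaker = 1)), log(2),
               tolerance = 1e-12)
  expect_identical(dsi_loss(data.frame(u = c(0.2, 0.9), same_speaker = 0)), 0)
  expect_warning(empty <- dsi_loss(data.frame(u = numeric(0),
                                              same_speaker = numeric(0))),
                 "empty")
  expect_identical(empty, 0)

  # both losses strictly decrease as u moves toward the gold label
  grid <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(duc_loss(grid, 1)) < 0))
  expect_true(all(diff(duc_loss(grid, 0)) > 0))
  expect_true(all(diff(vapply(grid, function(u)
    dsi_loss(data.frame(u = u, same_speaker = 1)), numeric(1))) < 0))
})

test_that("recall at 1 of 10 honors oracle, anti-oracle, and tie-breaking", {
  cfg <- generator_config(seed = 17, n_conversations = 40,
                          depressed_utterance_fraction = 0.3)
  convs <- generate_conversations(cfg)
  sets <- generate_duc_candidate_sets(convs, 30, seed = 2)

  expect_identical(recall_at_1_of_10(sets, oracle_scorer(convs), "")$value, 1)
  expect_identical(recall_at_1_of_10(sets, oracle_scorer(convs, invert = TRUE),
                                     "")$value, 0)

  # constant scorer: hit iff the positive sits at index 1
  const <- recall_at_1_of_10(sets, constant_scorer(0.5), "")
  frac_first <- mean(vapply(sets, function(s)
    s$candidates[[1]]$utterance_id == s$positive_id, logical(1)))
  expect_equal(const$value, frac_first, tolerance = 1e-12)

  bad <- structure(list(name = "bad", score = function(p, t) 1.5),
                   class = "exrank_scorer")
  expect_error(recall_at_1_of_10(sets, bad, ""), "contract")
})

test_that("random scorer hit rate sits near 1/10", {
  cfg <- generator_config(seed = 19, n_conversations = 60,
                          depressed_utterance_fraction = 0.3)
  sets <- generate_duc_candidate_sets(generate_conversations(cfg), 300,
                                      seed = 5)
  # a fresh scorer per set: utterances recur across sets, and the binomial
  # reference below assumes independent hits
  hits <- vapply(seq_along(sets), function(i)
    recall_at_1_of_10(sets[i], random_scorer(11 + i), "")$value, numeric(1))
  ci <- stats::qbinom(c(0.005, 0.995), 300, 0.1) / 300
  expect_gte(mean(hits), ci[[1]])
  expect_lte(mean(hits), ci[[2]])
})

test_that("speaker F1 matches hand-counted confusion cases", {
  cfg <- generator_config(seed = 23, n_conversations = 20,
                          depressed_utterance_fraction = 0.3)
  convs <- generate_conversations(cfg)
  expect_identical(dsi_f1(convs, oracle_scorer(convs), "", 0.5)$value, 1)
  # predict-nobody: F1 = 0 by the zero convention
  expect_identical(dsi_f1(convs, constant_scorer(0), "", 0.5)$value, 0)

  # one TP, one FP, one FN -> F1 = 0.5, built explicitly:
  # flags speaker A (true positive) and B (false positive), misses C (false
  # negative); D stays a true negative
  cvs <- list(
    make_conversation("x1", c("hurt sadness words", "cheerful plain words"),
                      speakers = c("A", "B"),
                      labels = c("depression", "normal")),
    make_conversation("x2", c("moody broken words", "quiet plain words"),
                      speakers = c("C", "D"),
                      labels = c("depression", "normal")))
  sc <- structure(list(name = "confusion", score = function(p, t) {
    if (grepl("hurt", t)) 1          # A: true positive
    else if (grepl("cheerful", t)) 1 # B: false positive
    else 0                           # C missed, D correctly clear
  }), class = "exrank_scorer")
  r <- dsi_f1(cvs, sc, "", 0.5)
  expect_equal(r$value, 0.5, tolerance = 1e-12)
  expect_identical(unname(r$counts), c(1L, 1L, 1L))

  none <- list(make_conversation("n", c("plain words", "other words"),
                                 labels = c("normal", "normal")))
  expect_error(dsi_f1(none, constant_scorer(1), "", 0.5), "gold-depressed")
})

test_that("experiments are deterministic and few-shot prompting does not hurt", {
  bundle <- generate_corpus_bundle(generator_config(seed = 31,
                                                    n_conversations = 60),
                                   n_demos = 10)
  cfg <- experiment_config(shots = 2, seed = 4)
  a <- run_experiment(bundle, cfg, n_sets = 10)
  b <- run_experiment(bundle, cfg, n_sets = 10)
  expect_identical(a$value, b$value)
  expect_identical(a$per_item, b$per_item)
  expect_identical(a$prompt, b$prompt)

  ok <- 0
  for (s in 1:10) {
    zs <- run_experiment(bundle, experiment_config(shots = 0,
                                                   use_explanations = FALSE,
                                                   seed = s), n_sets = 10)
    fs <- run_experiment(bundle, experiment_config(shots = 5, seed = s),
                         n_sets = 10)
    ok <- ok + (fs$value >= zs$value)
  }
  expect_gte(ok / 10, 0.9)

  expect_error(run_experiment(bundle, experiment_config(shots = 99)),
               "exceeds")

  # explanation order flips the serialized explanation blocks
  m2l <- run_experiment(bundle, experiment_config(shots = 2, seed = 4),
                        n_sets = 2)
  l2m <- run_experiment(bundle, experiment_config(
    shots = 2, seed = 4, explanation_order = "least_to_most"), n_sets = 2)
  expect_false(identical(m2l$prompt, l2m$prompt))
  expect_identical(sort(strsplit(m2l$prompt, " ")[[1]]),
                   sort(strsplit(l2m$prompt, " ")[[1]]))

  # dsi task runs end to end
  dsi <- run_experiment(bundle, experiment_config(shots = 2, seed = 4),
                        task = "dsi")
  expect_true(dsi$value >= 0 && dsi$value <= 1)
})
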