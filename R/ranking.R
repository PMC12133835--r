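#' Ranking configuration
#'
#' Defaults follow the reference operating point for explanation selection:
#' ERR decay `gamma = 0.85`, MMR relevance/diversity trade-off `lam = 0.5`,
#' and the top `k = 2` explanations retained for prompting.
#' `criteria_weight` mixes query/demonstration relevance with
#' diagnostic-criteria relevance (0 = ignore criteria, 1 = criteria only).
#'
#' @param gamma ERR decay factor, in `(0, 1]`.
#' @param lam MMR trade-off between relevance and redundancy, in `[0, 1]`.
#' @param k number of explanations to select, `>= 1`.
#' @param criteria_weight weight on diagnostic-criteria similarity, `[0, 1]`.
#' @param tie_break tie-breaking rule; only `"lowest_index"` is supported.
#' @return an object of class `exrank_ranking_config`.
#' @export
ranking_config <- function(gamma = 0.85, lam = 0.5, k = 2L,
                           criteria_weight = 0.5,
                           tie_break = "lowest_index") {
  if (!is_number(gamma) || gamma <= 0 || gamma > 1)
    stop("'gamma' must be a single number in (0, 1]", call. = FALSE)
  assert_fraction(lam, "lam")
  if (!is_number(k) || k < 1 || k != floor(k))
    stop("'k' must be an integer >= 1", call. = FALSE)
  assert_fraction(criteria_weight, "criteria_weight")
  tie_break <- match.arg(tie_break, "lowest_index")
  structure(list(gamma = gamma, lam = lam, k = as.integer(k),
                 criteria_weight = criteria_weight, tie_break = tie_break),
            class = "exrank_ranking_config")
}

#' Relevance probabilities for candidate explanations
#'
#' Scores each candidate by clipped cosine similarity to (a) the query and
#' the retrieved demonstrations (averaged) and (b) the diagnostic-criteria
#' statements (best match), mixed by `criteria_weight`, then sum-normalizes
#' the raw scores into a probability profile.  If every raw score is 0 the
#' profile falls back to uniform.
#'
#' @param candidates non-empty list of [explanation()]s (or strings).
#' @param query the query conversation, utterance or text.
#' @param demos list of [demonstration()]s (may be empty).
#' @param criteria character vector of criteria statements; required
#'   non-empty when `config$criteria_weight > 0`.
#' @param backend an `exrank_backend`.
#' @param config a [ranking_config()].
#' @return an object of class `exrank_relevance_profile` with
#'   `candidate_ids`, `probs`, `raw_scores`, `query_sims` and
#'   `normalization = "sum"`.
#' @export
relevance_probabilities <- function(candidates, query, demos = list(),
                                    criteria = character(0),
                                    backend = mock_embedding_backend(),
                                    config = ranking_config()) {
  stopifnot(inherits(config, "exrank_ranking_config"),
            inherits(backend, "exrank_backend"))
  if (!length(candidates)) stop("need at least one candidate", call. = FALSE)
  w <- config$criteria_weight
  if (w > 0 && !length(criteria))
    stop("criteria_weight > 0 requires at least one criteria statement",
         call. = FALSE)
  cand_texts <- vapply(candidates, as_text, character(1))
  cand_ids <- vapply(seq_along(candidates), function(i) {
    if (inherits(candidates[[i]], "exrank_explanation"))
      candidates[[i]]$expl_id else sprintf("cand%03d", i)
  }, character(1))
  cand_emb <- lapply(cand_texts, function(t) embed_text(backend, t))
  ref_texts <- c(as_text(query),
                 vapply(demos, as_text, character(1)))
  ref_emb <- lapply(ref_texts, function(t) embed_text(backend, t))
  crit_emb <- lapply(criteria, function(t) embed_text(backend, t))
  query_sims <- numeric(length(candidates))
  raw <- vapply(seq_along(cand_emb), function(i) {
    e <- cand_emb[[i]]
    ref_sims <- vapply(ref_emb, function(r) clip01(cosine_similarity(e, r)),
                       numeric(1))
    query_sims[i] <<- ref_sims[[1]]
    rel <- mean(ref_sims)
    crit <- if (length(crit_emb))
      max(vapply(crit_emb, function(cr) clip01(cosine_similarity(e, cr)),
                 numeric(1))) else 0
    (1 - w) * rel + w * crit
  }, numeric(1))
  s <- sum(raw)
  probs <- if (s > 0) raw / s else rep(1 / length(raw), length(raw))
  structure(list(candidate_ids = cand_ids, probs = probs, raw_scores = raw,
                 query_sims = query_sims, normalization = "sum"),
            class = "exrank_relevance_profile")
}

#' Expected reciprocal rank of an ordered relevance-probability list
#'
#' Cascade-model score of a ranking: the user inspects items top-down, stops
#' at the first satisfying one, and position k contributes `1/k` weighted by
#' the probability that items 1..k-1 did not satisfy and item k does:
#' `ERR = sum_k (1/k) * prod_{i<k} (1 - gamma * p_i) * gamma * p_k`.
#'
#' @param probs relevance probabilities in ranked order, each in `[0, 1]`.
#' @param gamma decay factor in `(0, 1]`.
#' @return the ERR score (0 for an empty list).
#' @examples
#' err_score(c(0.5, 0.5), gamma = 0.85)  # 0.5471875
#' @export
err_score <- function(probs, gamma = 0.85) {
  check_probs(probs)
  if (!is_number(gamma) || gamma <= 0 || gamma > 1)
    stop("'gamma' must be in (0, 1]", call. = FALSE)
  if (!length(probs)) return(0)
  survive <- 1
  total <- 0
  for (k in seq_along(probs)) {
    total <- total + (1 / k) * survive * gamma * probs[[k]]
    survive <- survive * (1 - gamma * probs[[k]])
  }
  total
}

check_probs <- function(probs) {
  if (length(probs) && (!is.numeric(probs) || anyNA(probs) ||
                        any(probs < 0) || any(probs > 1)))
    stop("relevance probabilities must lie in [0, 1]", call. = FALSE)
  invisible(probs)
}

#' Marginal ERR contribution of a candidate
#'
#' The term a candidate would add at position `length(selected_probs) + 1`
#' of the cascade:
#' `(1/k) * prod_i (1 - gamma * p_i) * gamma * p_cand` over the already
#' selected probabilities `p_i`.  Summing contributions along any ranking
#' reproduces [err_score()] of that ranking exactly.
#'
#' @param p_cand relevance probability of the candidate, in `[0, 1]`.
#' @param selected_probs probabilities of the already selected items, in
#'   selection order.
#' @param gamma decay factor in `(0, 1]`.
#' @return the marginal ERR term.
#' @export
err_contribution <- function(p_cand, selected_probs = numeric(0),
                             gamma = 0.85) {
  check_probs(c(p_cand, selected_probs))
  if (!is_number(gamma) || gamma <= 0 || gamma > 1)
    stop("'gamma' must be in (0, 1]", call. = FALSE)
  k <- length(selected_probs) + 1
  (1 / k) * prod(1 - gamma * selected_probs) * gamma * p_cand
}

#' Maximal marginal relevance of a candidate
#'
#' `MMR = lam * sim(candidate, query) - (1 - lam) * max_j sim(candidate,
#' selected_j)`, with the maximum over an empty selected set defined as 0.
#' Similarities are expected already clipped to `[0, 1]`.
#'
#' @param cand_query_sim similarity of the candidate to the query.
#' @param cand_selected_sims similarities of the candidate to each already
#'   selected item (possibly empty).
#' @param lam trade-off between relevance (1) and diversity (0).
#' @return the MMR score.
#' @examples
#' mmr_score(0.9, c(0.7, 0.2), lam = 0.5)  # 0.10
#' @export
mmr_score <- function(cand_query_sim, cand_selected_sims = numeric(0),
                      lam = 0.5) {
  assert_fraction(lam, "lam")
  assert_fraction(cand_query_sim, "cand_query_sim")
  if (length(cand_selected_sims)) check_sims(cand_selected_sims)
  penalty <- if (length(cand_selected_sims)) max(cand_selected_sims) else 0
  lam * cand_query_sim - (1 - lam) * penalty
}

check_sims <- function(sims) {
  if (!is.numeric(sims) || anyNA(sims) || any(sims < 0) || any(sims > 1))
    stop("similarities must lie in [0, 1] after clipping", call. = FALSE)
  invisible(sims)
}

#' Greedy hybrid ERR + MMR selection of top-k explanations
#'
#' At each of `k` rounds, every unselected candidate j is scored
#' `S_comb[j] = err_contribution(p_j, selected probs, gamma) +
#' mmr_score(sim(j, query), sims(j, selected), lam)` and the argmax is
#' selected (ties broken toward the lowest candidate index).  The ERR term
#' rewards placing high-relevance candidates early in the cascade; the MMR
#' term penalises redundancy with what is already selected.  Selection stops
#' early when the pool is exhausted.
#'
#' @param candidates list of [explanation()]s (or strings).
#' @param profile a [relevance_probabilities()] profile covering all
#'   candidates (computed from `query`/`backend` when omitted requires
#'   `criteria` via `...`); must have one probability per candidate.
#' @param query the query text or object (used for MMR similarities).
#' @param backend an `exrank_backend`.
#' @param config a [ranking_config()]; `config$k` explanations are selected.
#' @return an object of class `exrank_ranked_selection`: a data frame
#'   `selected` with columns `expl_id`, `s_comb`, `err_term`, `mmr_term` in
#'   selection order, plus `pool_size` and the selection `order` (indices
#'   into `candidates`).
#' @export
hybrid_select <- function(candidates, profile, query,
                          backend = mock_embedding_backend(),
                          config = ranking_config()) {
  stopifnot(inherits(config, "exrank_ranking_config"),
            inherits(profile, "exrank_relevance_profile"),
            inherits(backend, "exrank_backend"))
  n <- length(candidates)
  if (!n) stop("need at least one candidate", call. = FALSE)
  if (length(profile$probs) != n)
    stop("profile does not cover all candidates", call. = FALSE)
  if (config$k < 1) stop("'k' must be >= 1", call. = FALSE)

  cand_texts <- vapply(candidates, as_text, character(1))
  cand_emb <- lapply(cand_texts, function(t) embed_text(backend, t))
  q_emb <- embed_text(backend, as_text(query))
  sims_q <- vapply(cand_emb, function(e) clip01(cosine_similarity(e, q_emb)),
                   numeric(1))
  pairwise <- function(i, j) clip01(cosine_similarity(cand_emb[[i]],
                                                      cand_emb[[j]]))
  probs <- profile$probs
  selected <- integer(0)
  rows <- vector("list", min(config$k, n))
  for (r in seq_len(min(config$k, n))) {
    remaining <- setdiff(seq_len(n), selected)
    best <- NULL
    for (j in remaining) {
      errc <- err_contribution(probs[[j]], probs[selected], config$gamma)
      sel_sims <- vapply(selected, function(s) pairwise(j, s), numeric(1))
      mmr <- mmr_score(sims_q[[j]], sel_sims, config$lam)
      s <- errc + mmr
      if (is.null(best) || s > best$s + 1e-15) {
        best <- list(j = j, s = s, errc = errc, mmr = mmr)
      }
    }
    selected <- c(selected, best$j)
    rows[[r]] <- data.frame(
      expl_id = profile$candidate_ids[[best$j]],
      s_comb = best$s, err_term = best$errc, mmr_term = best$mmr,
      stringsAsFactors = FALSE)
  }
  structure(list(selected = do.call(rbind, rows), pool_size = n,
                 order = selected),
            class = "exrank_ranked_selection")
}
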