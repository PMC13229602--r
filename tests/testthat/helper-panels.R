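# shared fixtures, built in code

# 4 anchors + 1 concept; every eligible pair once, 3 repeated pairs
tiny_panel <- function(seed = 11L) {
  items <- dplyr::bind_rows(
    panel_item("a1", "Alpha", "anchor", 1L),
    panel_item("a2", "Bravo", "anchor", 2L),
    panel_item("a3", "Carol", "anchor", 3L),
    panel_item("a4", "Delta", "anchor", 4L),
    panel_item("c1", "Ghost", "concept")
  )
  panel_spec(
    panel_version = "tiny-v1",
    axis = axis_spec("hardness", "test axis", "a1", "a4"),
    items = items,
    block_counts = list(concept_anchor = 4L, concept_concept = 0L,
                        anchor_anchor = 5L, catch = 1L),
    repeat_plan = list(n_repeated_pairs = 3L, reps_per_pair = 2L),
    seed = seed
  )
}

# build a comparison-dataset row directly (bypassing the join) for unit tests
obs <- function(winner, loser, confidence = 50L, block = "anchor_anchor",
                trial_id = NULL, repeat_index = 0L) {
  tibble::tibble(
    trial_id = trial_id %||% paste0("t-", winner, "-", loser, "-",
                                    sample.int(1e6, 1)),
    block = block,
    pair_key = anchorpanel:::pair_key(winner, loser),
    repeat_index = repeat_index,
    prompt_family_id = "baseline",
    wrapper_id = "plain",
    item_a = winner,
    item_b = loser,
    choice = "A",
    winner = winner,
    loser = loser,
    confidence = as.integer(confidence)
  )
}

obs_n <- function(winner, loser, n, ...) {
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    obs(winner, loser, trial_id = paste0("t-", winner, loser, i), ...)
  }))
}

`%||%` <- rlang::`%||%`

# independent penalized-likelihood maximizer: refining dense grid search
grid_bt_oracle <- function(wins, lambda, lo = -5, hi = 5, rounds = 8L) {
  items <- sort(unique(c(wins$winner, wins$loser)))
  m <- length(items)
  wi <- match(wins$winner, items)
  li <- match(wins$loser, items)
  objective <- function(b) {
    sum(plogis(b[wi] - b[li], log.p = TRUE)) - lambda * sum(b^2)
  }
  lower <- rep(lo, m); upper <- rep(hi, m); best <- NULL
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(m), function(i) seq(lower[i], upper[i], length.out = 13))
    g <- as.matrix(expand.grid(grids))
    v <- apply(g, 1, objective)
    best <- g[which.max(v), ]
    step <- (upper - lower) / 12
    lower <- best - step; upper <- best + step
  }
  stats::setNames(best - mean(best), items)
}
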