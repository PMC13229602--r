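test_that("symmetric data gives equal strengths", {
  ds <- dplyr::bind_rows(obs("A", "B"), obs("B", "A"))
  for (lam in c(0.01, 0.1, 1)) {
    fit <- fit_bradley_terry(ds, l2_lambda = lam)
    expect_lt(abs(fit$beta[["A"]] - fit$beta[["B"]]), 1e-8)
  }
})

test_that("the Newton fit matches the dense grid-search maximizer", {
  # 3-item toy frozen from a refining grid search over beta in [-5,5]^3
  ds <- dplyr::bind_rows(obs_n("A", "B", 5), obs_n("B", "C", 5),
                         obs_n("A", "C", 5))
  fit <- fit_bradley_terry(ds, l2_lambda = 0.1)
  expect_true(fit$converged)
  frozen <- c(A = 2.365222, B = 0, C = -2.365222)
  expect_equal(fit$beta[names(frozen)], frozen, tolerance = 1e-3,
               ignore_attr = TRUE)
  m <- fit_metrics(fit, ds)
  expect_equal(m$accuracy, 1)
  expect_equal(m$log_loss, 0.06277818, tolerance = 1e-4)

  # fresh-draw oracle comparison on randomized <=4-item instances
  withr::local_seed(2024)
  for (i in 1:3) {
    items <- LETTERS[1:4]
    pairs <- t(utils::combn(items, 2))
    wins <- dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(j) {
      k <- sample(0:3, 2, replace = TRUE)
      dplyr::bind_rows(
        if (k[1] > 0) obs_n(pairs[j, 1], pairs[j, 2], k[1]),
        if (k[2] > 0) obs_n(pairs[j, 2], pairs[j, 1], k[2])
      )
    }))
    lam <- sample(c(0.05, 0.1, 0.5), 1)
    fit_i <- fit_bradley_terry(wins, l2_lambda = lam)
    oracle <- grid_bt_oracle(wins, lam)
    expect_equal(fit_i$beta[names(oracle)], oracle, tolerance = 1e-3,
                 ignore_attr = TRUE)
  }
})

test_that("an item that wins everything has the greatest strength", {
  ds <- dplyr::bind_rows(obs_n("X", "A", 3), obs_n("X", "B", 3),
                         obs_n("A", "B", 2), obs_n("B", "A", 2))
  fit <- fit_bradley_terry(ds, l2_lambda = 0.5)
  expect_identical(names(which.max(fit$beta)), "X")
})

test_that("anchored rescaling is the pinned linear map", {
  fake_fit <- function(beta) {
    structure(list(beta = beta, items = names(beta), l2_lambda = 0.1,
                   converged = TRUE, n_obs = 10L, iterations = 1L),
              class = "bt_fit")
  }
  ax <- axis_spec("hardness", "t", "low", "high")
  sc <- anchor_rescale(fake_fit(c(low = 0, mid = 2.5, high = 5)), ax)
  expect_equal(sc$score[match(c("low", "mid", "high"), sc$item_id)],
               c(0, 50, 100))
  sc2 <- anchor_rescale(fake_fit(c(low = 0, item = 6, high = 5)), ax)
  expect_equal(sc2$score[sc2$item_id == "item"], 120)
  expect_error(anchor_rescale(fake_fit(c(low = 1, high = 1)), ax),
               class = "anchorpanel_anchoring_error")

  # translation invariance: adding a constant to all strengths changes nothing
  b <- c(low = -0.3, mid = 1.1, high = 2.9)
  expect_equal(anchor_rescale(fake_fit(b), ax)$score,
               anchor_rescale(fake_fit(b + 17), ax)$score)
})

test_that("equal strengths give log loss log(2) and the 0.5 tie rule", {
  fit <- structure(list(beta = c(A = 0.7, B = 0.7), items = c("A", "B"),
                        l2_lambda = 0, converged = TRUE, n_obs = 4L,
                        iterations = 0L), class = "bt_fit")
  ds <- dplyr::bind_rows(obs_n("A", "B", 2), obs_n("B", "A", 2))
  m <- fit_metrics(fit, ds)
  expect_equal(m$log_loss, log(2))
  expect_equal(m$accuracy, 0.5)

  # widely separated strengths: accuracy 1, log loss near 0
  fit2 <- structure(list(beta = c(A = 10, B = -10), items = c("A", "B"),
                         l2_lambda = 0, converged = TRUE, n_obs = 3L,
                         iterations = 0L), class = "bt_fit")
  m2 <- fit_metrics(fit2, obs_n("A", "B", 3))
  expect_equal(m2$accuracy, 1)
  expect_lt(m2$log_loss, 1e-6)
})

test_that("fits are invariant to trial order and item labels", {
  withr::local_seed(7)
  ds <- dplyr::bind_rows(obs_n("A", "B", 4), obs_n("B", "A", 1),
                         obs_n("B", "C", 3), obs_n("C", "A", 2),
                         obs_n("A", "C", 4))
  fit <- fit_bradley_terry(ds)
  for (i in 1:5) {
    shuffled <- ds[sample.int(nrow(ds)), ]
    fit_s <- fit_bradley_terry(shuffled)
    expect_equal(fit$beta, fit_s$beta, tolerance = 1e-9)
  }
  # relabeling items permutes strengths without changing them
  relabeled <- dplyr::mutate(ds,
    winner = c(A = "Z", B = "Y", C = "X")[winner],
    loser = c(A = "Z", B = "Y", C = "X")[loser],
    pair_key = anchorpanel:::pair_key(winner, loser))
  fit_r <- fit_bradley_terry(relabeled)
  expect_equal(unname(fit_r$beta[c("Z", "Y", "X")]),
               unname(fit$beta[c("A", "B", "C")]), tolerance = 1e-9)
})

test_that("adding wins for an item never decreases its anchored score", {
  ax <- axis_spec("hardness", "t", "A", "C")
  base <- dplyr::bind_rows(obs_n("A", "B", 2), obs_n("B", "A", 2),
                           obs_n("B", "C", 2), obs_n("C", "B", 3),
                           obs_n("C", "A", 4), obs_n("A", "C", 1))
  prev <- -Inf
  for (extra in 0:4) {
    ds <- dplyr::bind_rows(base, if (extra > 0) obs_n("B", "C", extra))
    fit <- fit_bradley_terry(ds, l2_lambda = 0.1)
    s <- anchor_rescale(fit, ax)
    score_b <- s$score[s$item_id == "B"]
    expect_gte(score_b, prev - 1e-9)
    prev <- score_b
  }
})

test_that("bootstrap intervals are seeded, bounded, and pin the anchors", {
  spec <- tiny_panel()
  profile <- latent_profile(c(a1 = 0, a2 = 30, a3 = 60, a4 = 100, c1 = 45),
                            choice_temperature = 8)
  ds <- simulate_panel_run(spec, profile, seed = 4)
  fit <- fit_bradley_terry(ds)
  ci1 <- bootstrap_ci(fit, ds, spec$axis, n_reps = 60, seed = 123)
  ci2 <- bootstrap_ci(fit, ds, spec$axis, n_reps = 60, seed = 123)
  expect_identical(ci1, ci2)
  expect_false(identical(ci1, bootstrap_ci(fit, ds, spec$axis, n_reps = 60,
                                           seed = 124)))
  # pinned anchors are degenerate in every replicate
  expect_equal(ci1$ci_low[ci1$item_id == "a1"], 0)
  expect_equal(ci1$ci_high[ci1$item_id == "a1"], 0)
  expect_equal(ci1$ci_low[ci1$item_id == "a4"], 100)
  expect_equal(ci1$ci_high[ci1$item_id == "a4"], 100)
  # minimal replicate count is accepted
  expect_silent(bootstrap_ci(fit, ds, spec$axis, n_reps = 2, seed = 1))
  expect_error(bootstrap_ci(fit, ds, spec$axis, n_reps = 1, seed = 1),
               class = "anchorpanel_fit_error")
})

test_that("the assembled scale carries interval-consistent scores and metadata", {
  spec <- tiny_panel()
  profile <- latent_profile(c(a1 = 0, a2 = 30, a3 = 60, a4 = 100, c1 = 45),
                            choice_temperature = 6)
  ds <- simulate_panel_run(spec, profile, seed = 9)
  sc <- fit_anchored_scale(ds, spec, bootstrap_reps = 200, seed = 2)
  free <- !(sc$item_id %in% c("a1", "a4"))
  expect_true(all(sc$ci_low[free] <= sc$score[free] + 1e-9))
  expect_true(all(sc$ci_high[free] >= sc$score[free] - 1e-9))
  g <- glance(sc)
  expect_identical(g$n_obs, nrow(ds))
  expect_identical(g$bootstrap_reps, 200L)
  expect_s3_class(ggplot2::autoplot(sc), "ggplot")
  expect_s3_class(tidy(sc), "tbl_df")
  expect_false(inherits(tidy(sc), "anchored_scale"))

  path <- withr::local_tempfile(fileext = ".csv")
  write_scale_table(sc, path)
  expect_equal(as.data.frame(read_scale_table(path)), as.data.frame(tidy(sc)))
})

test_that("degenerate inputs raise fit errors", {
  expect_error(fit_bradley_terry(obs("A", "B")[0, ]),
               class = "anchorpanel_fit_error")
  expect_error(fit_bradley_terry(obs("A", "B"), items = "A"),
               class = "anchorpanel_fit_error")
  expect_error(fit_bradley_terry(obs("A", "B"), l2_lambda = -1),
               class = "anchorpanel_fit_error")
})
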