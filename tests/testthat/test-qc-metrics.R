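test_that("repeated-pair agreement follows the unanimity definition", {
  concordant <- function(id) dplyr::bind_rows(
    obs("a2", "a1", trial_id = paste0(id, "-1")),
    obs("a2", "a1", trial_id = paste0(id, "-2"))
  )
  discordant <- function(id) dplyr::bind_rows(
    obs("a2", "a1", trial_id = paste0(id, "-1")),
    obs("a1", "a2", trial_id = paste0(id, "-2"))
  )

  all_same <- dplyr::bind_rows(lapply(1:5, function(i) {
    dplyr::bind_rows(obs(paste0("w", i), paste0("l", i),
                         trial_id = paste0("p", i, "-1")),
                     obs(paste0("w", i), paste0("l", i),
                         trial_id = paste0("p", i, "-2")))
  }))
  out <- repeated_pair_agreement(all_same)
  expect_equal(out$agreement, 1)
  expect_identical(out$n_pairs, 5L)

  single_discord <- discordant("x")
  expect_equal(repeated_pair_agreement(single_discord)$agreement, 0)

  # 58 of 64 concordant pairs -> 90.6% to one rendered decimal
  mixed <- dplyr::bind_rows(
    lapply(1:58, function(i) dplyr::bind_rows(
      obs(paste0("w", i), paste0("l", i), trial_id = paste0("c", i, "-1")),
      obs(paste0("w", i), paste0("l", i), trial_id = paste0("c", i, "-2"))
    )),
    lapply(1:6, function(i) dplyr::bind_rows(
      obs(paste0("dw", i), paste0("dl", i), trial_id = paste0("d", i, "-1")),
      obs(paste0("dl", i), paste0("dw", i), trial_id = paste0("d", i, "-2"))
    ))
  )
  out64 <- repeated_pair_agreement(mixed)
  expect_identical(out64$n_pairs, 64L)
  expect_identical(out64$n_agree, 58L)
  expect_equal(round(100 * out64$agreement, 1), 90.6)

  # unrepeated-only data is explicitly not computed
  none <- repeated_pair_agreement(obs("a", "b"))
  expect_identical(none$status, "not_computed")

  # unanimity vs majority for triple presentations
  triple <- dplyr::bind_rows(
    obs("u", "v", trial_id = "t1"), obs("u", "v", trial_id = "t2"),
    obs("v", "u", trial_id = "t3")
  )
  expect_equal(repeated_pair_agreement(triple)$agreement, 0)
  expect_equal(repeated_pair_agreement(triple, rule = "majority")$agreement, 1)
})

test_that("agreement ignores trial order and A/B positions", {
  spec <- tiny_panel()
  profile <- latent_profile(c(a1 = 0, a2 = 30, a3 = 60, a4 = 100, c1 = 45),
                            choice_temperature = 10)
  ds <- simulate_panel_run(spec, profile, seed = 12)
  base <- repeated_pair_agreement(ds)
  shuffled <- ds[rev(seq_len(nrow(ds))), ]
  expect_equal(repeated_pair_agreement(shuffled), base)
  flipped <- dplyr::mutate(ds, tmp = item_a, item_a = item_b, item_b = tmp,
                           tmp = NULL,
                           choice = ifelse(choice == "A", "B", "A"))
  expect_equal(repeated_pair_agreement(flipped), base)
})

test_that("confidence-distance correlation matches the direct formula", {
  # frozen from the closed-form Pearson sums on this 5-point table
  ds <- dplyr::bind_rows(lapply(1:5, function(i) {
    obs(paste0("i", i), "ref", confidence = c(20, 35, 30, 60, 80)[i],
        trial_id = paste0("t", i))
  }))
  scale <- tibble::tibble(item_id = c("ref", paste0("i", 1:5)),
                          score = c(0, 10, 20, 30, 40, 50))
  out <- confidence_distance_correlation(ds, scale)
  expect_equal(out$r, 0.9359709753, tolerance = 1e-6)
  expect_identical(out$n, 5L)
  expect_true(out$ci_low <= out$r && out$r <= out$ci_high)

  # exactly affine confidence gives r = 1
  affine <- dplyr::mutate(ds, confidence = as.integer(
    10 + 1.5 * abs(scale$score[match(item_a, scale$item_id)] -
                     scale$score[match(item_b, scale$item_id)])))
  out1 <- confidence_distance_correlation(affine, scale)
  expect_equal(out1$r, 1, tolerance = 1e-12)

  # r is invariant to positive affine rescaling of the score axis
  rescaled <- dplyr::mutate(scale, score = 3.7 * score - 12)
  expect_equal(confidence_distance_correlation(ds, rescaled)$r, out$r,
               tolerance = 1e-12)

  # degenerate inputs are reported, not computed
  flat <- dplyr::mutate(ds, confidence = 50L)
  expect_identical(confidence_distance_correlation(flat, scale)$status,
                   "degenerate")
  expect_identical(confidence_distance_correlation(ds[1:2, ], scale)$status,
                   "not_computed")
})

test_that("fisher and bootstrap intervals both bracket the point estimate", {
  withr::local_seed(5)
  ds <- dplyr::bind_rows(lapply(1:40, function(i) {
    d <- sample(5:95, 1)
    obs(paste0("w", i), "ref",
        confidence = as.integer(min(100, max(0, round(d * 0.8 + rnorm(1, 0, 10))))),
        trial_id = paste0("t", i))
  }))
  scale <- tibble::tibble(item_id = c("ref", paste0("w", 1:40)),
                          score = c(0, sapply(1:40, function(i) i * 2.3)))
  fisher <- confidence_distance_correlation(ds, scale)
  boot <- confidence_distance_correlation(ds, scale, ci_method = "bootstrap",
                                          boot_reps = 500, boot_seed = 3)
  expect_equal(fisher$r, boot$r)
  for (o in list(fisher, boot)) {
    expect_true(o$ci_low <= o$r && o$r <= o$ci_high)
    expect_true(o$ci_low >= -1 && o$ci_high <= 1)
  }
})

test_that("anchor-order inversions are detected over adjacent rank pairs", {
  spec <- tiny_panel()
  mk_scale <- function(scores) {
    tibble::tibble(item_id = names(scores), score = unname(scores))
  }
  ok <- anchor_order_check(mk_scale(c(a1 = 0, a2 = 30, a3 = 70, a4 = 100,
                                      c1 = 50)), spec$items)
  expect_identical(ok$n_violations, 0L)
  expect_identical(ok$n_pairs, 3L)

  one <- anchor_order_check(mk_scale(c(a1 = 0, a2 = 75, a3 = 70, a4 = 100,
                                       c1 = 50)), spec$items)
  expect_identical(one$n_violations, 1L)
  v <- attr(one, "violations")
  expect_identical(v$lower_item, "a2")
  expect_identical(v$higher_item, "a3")

  # fully reversed 10-anchor scale: 9/9 adjacent inversions
  ten <- dplyr::bind_rows(lapply(1:10, function(i) {
    panel_item(paste0("m", i), role = "anchor", canonical_rank = i)
  }))
  rev_scale <- tibble::tibble(item_id = paste0("m", 1:10),
                              score = seq(100, 10, by = -10))
  full <- anchor_order_check(rev_scale, ten)
  expect_identical(full$n_violations, 9L)
  expect_identical(full$n_pairs, 9L)
})

test_that("a clean run compiles with no flags and a degraded run raises them", {
  spec <- default_panel()
  profiles <- make_default_profiles()

  clean <- simulate_panel_run(spec, profiles$clean, seed = 2)
  sc <- fit_anchored_scale(clean, spec, bootstrap_reps = 0)
  qc <- compile_qc_report(clean, sc, spec)
  expect_identical(qc$flags, character(0))
  expect_equal(qc$repeat_agreement$n_pairs, 64L)
  expect_identical(qc$catch$status, "ok")

  degraded <- simulate_panel_run(spec, profiles$degraded, seed = 2)
  scd <- fit_anchored_scale(degraded, spec, bootstrap_reps = 0)
  qcd <- compile_qc_report(degraded, scd, spec)
  expect_true(all(c("ANCHOR_ORDER", "LOW_REPEAT") %in% qcd$flags))
  expect_gt(qcd$anchor_order$n_violations, 0)

  # a dataset without catch trials carries a status, not a flag
  no_catch <- dplyr::filter(clean, block != "catch")
  qc2 <- compile_qc_report(no_catch, sc, spec)
  expect_identical(qc2$catch$status, "not_computed")
  expect_false("CATCH_FAIL" %in% qc2$flags)

  path <- withr::local_tempfile(fileext = ".json")
  write_qc_report(qcd, path)
  reloaded <- jsonlite::read_json(path)
  expect_true("ANCHOR_ORDER" %in% unlist(reloaded$flags))
  expect_equal(reloaded$repeat_agreement$n_pairs, 64L)
})
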