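#' Define a simulated responder profile
#'
#' The simulated responder gives every stage of the pipeline a ground truth:
#' items carry latent scores on an arbitrary axis, choices follow a logistic
#' rule on the latent difference (the Bradley-Terry generative family, so
#' fitting the pipeline on simulated data is a clean self-consistency test),
#' and reported confidence is a noisy affine function of the latent
#' distance -- generated from the *true* distance, not the fitted one, so
#' the confidence-calibration metric tests recovery of a known monotone
#' link.
#'
#' Degradation modes emulate a misbehaving responder: `anchor_inversion`
#' swaps the latent scores of listed item pairs (producing anchor-order
#' violations downstream), `repeat_noise_boost` multiplies the choice
#' temperature on repeat presentations (lowering repeated-pair agreement),
#' and `confidence_decalibration` quarters the confidence gain (weakening
#' the confidence-distance correlation).
#'
#' @param true_scores Named numeric vector: latent score per item_id.
#' @param choice_temperature Logistic noise scale tau > 0: P(choose A) =
#'   plogis((s_A - s_B) / tau).
#' @param conf_gain,conf_offset,conf_noise_sd Confidence model: reported
#'   confidence = round(clip(gain * |s_A - s_B| + offset + N(0, sd), 0, 100)).
#' @param anchor_inversion List of length-2 character vectors; each pair's
#'   latent scores are swapped.
#' @param repeat_noise_boost Multiplier (>= 1) on tau for presentations with
#'   `repeat_index > 0`.
#' @param confidence_decalibration Logical; `TRUE` multiplies `conf_gain` by
#'   0.25.
#' @return A `latent_profile`.
#' @export
latent_profile <- function(true_scores, choice_temperature = 1,
                           conf_gain = 0.9, conf_offset = 5,
                           conf_noise_sd = 14,
                           anchor_inversion = list(),
                           repeat_noise_boost = 1,
                           confidence_decalibration = FALSE) {
  if (choice_temperature <= 0) {
    stop_config("choice_temperature must be > 0")
  }
  if (is.null(names(true_scores)) || any(!nzchar(names(true_scores)))) {
    stop_config("true_scores must be a fully named vector")
  }
  structure(
    list(
      true_scores = true_scores,
      choice_temperature = choice_temperature,
      conf_gain = conf_gain,
      conf_offset = conf_offset,
      conf_noise_sd = conf_noise_sd,
      anchor_inversion = anchor_inversion,
      repeat_noise_boost = repeat_noise_boost,
      confidence_decalibration = isTRUE(confidence_decalibration)
    ),
    class = "latent_profile"
  )
}

# latent scores after applying inversion degradations
effective_scores <- function(profile) {
  s <- profile$true_scores
  for (pair in profile$anchor_inversion) {
    stopifnot(length(pair) == 2L)
    if (!all(pair %in% names(s))) {
      stop_config("anchor_inversion names unknown item(s): %s",
                  paste(setdiff(pair, names(s)), collapse = ", "))
    }
    s[pair] <- s[rev(pair)]
  }
  s
}

#' Simulate forced-choice responses for a trial plan
#'
#' Per trial: `P(choose A) = plogis((s_A - s_B) / tau)` with the profile's
#' (possibly degraded) latent scores; the choice is drawn Bernoulli and the
#' confidence from the profile's affine-plus-noise model, clipped to an
#' integer in \[0, 100\]. Bit-reproducible given (plan, profile, seed).
#'
#' @param plan Trial plan tibble.
#' @param profile A [latent_profile()].
#' @param seed Integer seed.
#' @return Response tibble with `trial_id`, `choice`, `confidence`,
#'   `repaired` (always `FALSE`), ready for [join_responses()].
#' @export
simulate_responses <- function(plan, profile, seed = 1L) {
  s <- effective_scores(profile)
  missing <- setdiff(unique(c(plan$item_a, plan$item_b)), names(s))
  if (length(missing)) {
    stop_config("no latent score for item(s): %s", paste(missing, collapse = ", "))
  }
  tau <- profile$choice_temperature *
    ifelse(plan$repeat_index > 0, profile$repeat_noise_boost, 1)
  gain <- profile$conf_gain * if (profile$confidence_decalibration) 0.25 else 1
  d <- s[plan$item_a] - s[plan$item_b]
  withr::with_seed(as.integer(seed), {
    p_a <- stats::plogis(d / tau)
    choose_a <- stats::runif(nrow(plan)) < p_a
    conf <- gain * abs(d) + profile$conf_offset +
      stats::rnorm(nrow(plan), 0, profile$conf_noise_sd)
  })
  tibble::tibble(
    trial_id = plan$trial_id,
    choice = ifelse(choose_a, "A", "B"),
    confidence = as.integer(round(clip(conf, 0, 100))),
    repaired = FALSE
  )
}

#' Write simulated responses as JSON-Lines
#'
#' Emits exactly the one-line JSON schema the ingestion parser accepts, so a
#' simulated run exercises the full file round trip.
#'
#' @param responses Response tibble.
#' @param path Output path.
#' @export
write_responses_jsonl <- function(responses, path) {
  lines <- sprintf('{"trial_id":"%s","choice":"%s","confidence":%d}',
                   responses$trial_id, responses$choice, responses$confidence)
  writeLines(lines, path)
  invisible(path)
}

#' Default clean and degraded responder profiles
#'
#' Both profiles place the default panel's 15 items at reference latent
#' positions spanning the anchored axis (anchors in canonical order from 0
#' to 100, concepts interleaved). The clean profile uses a low choice
#' temperature (tau = 0.5, small relative to the 4.8-unit minimum item
#' separation, so expected repeated-pair agreement is ~1 and fit accuracy
#' ~1) and a confidence model whose expected confidence-distance correlation
#' is ~0.84. The degraded profile emulates a weaker on-premise responder:
#' the latent scores of the polycarbonate and steel anchors are swapped
#' (guaranteeing anchor-order violations), tau = 6 with a 1.5x boost on
#' repeat presentations (expected agreement ~0.90), and decalibrated
#' confidence (expected r ~0.4).
#'
#' @return Named list with elements `clean` and `degraded`.
#' @export
make_default_profiles <- function() {
  truth <- c(
    marshmallow = 0, life = 6.04, kindness = 13.70, silence = 21.14,
    oak = 28.93, abs = 33.74, polycarbonate = 38.88, acrylic = 43.95,
    aluminum = 49.38, bone = 54.89, glass = 60.77, porcelain = 66.95,
    justice = 75.93, death = 87.15, steel = 100
  )
  list(
    clean = latent_profile(
      truth, choice_temperature = 0.5,
      conf_gain = 0.9, conf_offset = 5, conf_noise_sd = 14
    ),
    degraded = latent_profile(
      truth, choice_temperature = 6,
      conf_gain = 0.9, conf_offset = 5, conf_noise_sd = 14,
      anchor_inversion = list(c("polycarbonate", "steel")),
      repeat_noise_boost = 1.5,
      confidence_decalibration = TRUE
    )
  )
}

#' Read and write responder profiles as JSON
#'
#' @param profile A `latent_profile`.
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  out <- unclass(profile)
  out$true_scores <- as.list(out$true_scores)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  latent_profile(
    true_scores = unlist(raw$true_scores),
    choice_temperature = raw$choice_temperature,
    conf_gain = raw$conf_gain,
    conf_offset = raw$conf_offset,
    conf_noise_sd = raw$conf_noise_sd,
    anchor_inversion = purrr::map(raw$anchor_inversion, ~ unlist(.x)),
    repeat_noise_boost = raw$repeat_noise_boost,
    confidence_decalibration = raw$confidence_decalibration
  )
}

#' Simulate a complete panel run
#'
#' One call from spec to comparison dataset: build the plan, simulate
#' responses, join. Used heavily in examples and tests.
#'
#' @param spec A `panel_spec`.
#' @param profile A `latent_profile`.
#' @param seed Simulation seed.
#' @return Comparison dataset (see [join_responses()]); the plan is in
#'   `attr(, "plan")`.
#' @export
simulate_panel_run <- function(spec, profile = make_default_profiles()$clean,
                               seed = 1L) {
  plan <- build_trial_plan(spec)
  responses <- simulate_responses(plan, profile, seed = seed)
  out <- join_responses(plan, responses)
  attr(out, "plan") <- plan
  out
}
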