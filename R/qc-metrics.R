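#' Repeated-pair agreement
#'
#' A repeated unordered pair agrees when its presentations all name the same
#' winning item; agreement is the fraction of repeated pairs that agree.
#' Unanimity is the default rule (the strictest reading of "identical
#' winners"); with `rule = "majority"` a pair agrees when one item wins a
#' strict majority of its presentations. The metric depends only on
#' (pair_key, winner), so it is invariant to trial order and A/B positions.
#'
#' @param dataset Comparison dataset from [join_responses()].
#' @param rule `"unanimity"` (default) or `"majority"`.
#' @return One-row tibble with `agreement`, `n_agree`, `n_pairs`, `status`
#'   (`"not_computed"` when no pair has two or more observations).
#' @export
repeated_pair_agreement <- function(dataset, rule = c("unanimity", "majority")) {
  rule <- match.arg(rule)
  per_pair <- dplyr::summarise(
    dplyr::group_by(dataset, .data$pair_key),
    n = dplyr::n(),
    n_winners = dplyr::n_distinct(.data$winner),
    top_share = max(table(.data$winner)) / dplyr::n(),
    .groups = "drop"
  )
  rep_pairs <- dplyr::filter(per_pair, .data$n >= 2L)
  if (!nrow(rep_pairs)) {
    return(tibble::tibble(agreement = NA_real_, n_agree = NA_integer_,
                          n_pairs = 0L, status = "not_computed"))
  }
  agree <- if (rule == "unanimity") {
    rep_pairs$n_winners == 1L
  } else {
    rep_pairs$top_share > 0.5
  }
  tibble::tibble(
    agreement = mean(agree),
    n_agree = sum(agree),
    n_pairs = nrow(rep_pairs),
    status = "ok"
  )
}

#' Correlation between reported confidence and anchored pair distance
#'
#' Pearson correlation between the confidence reported on each trial and the
#' absolute difference of the two presented items' anchored scores. A
#' well-behaved responder treats confidence as a margin signal, so r should
#' be strongly positive; the 95% interval uses the Fisher z transform (a
#' bootstrap interval over trials is available as an option). Because the
#' anchored scores enter only through |score difference| and Pearson r is
#' invariant to positive affine maps, the metric does not depend on the
#' anchoring gauge. Catch trials are excluded by default: their extreme
#' distances are attention checks, not measurements.
#'
#' @param dataset Comparison dataset.
#' @param scale An `anchored_scale` (or tibble with `item_id`, `score`).
#' @param exclude_catch Drop `block == "catch"` trials first (default TRUE).
#' @param ci_method `"fisher"` (default) or `"bootstrap"`.
#' @param boot_reps,boot_seed Bootstrap controls when `ci_method =
#'   "bootstrap"`.
#' @return One-row tibble with `r`, `ci_low`, `ci_high`, `n`, `status`
#'   (`"degenerate"` when either variable has zero variance,
#'   `"not_computed"` with fewer than 3 usable trials).
#' @export
confidence_distance_correlation <- function(dataset, scale,
                                            exclude_catch = TRUE,
                                            ci_method = c("fisher", "bootstrap"),
                                            boot_reps = 2000L, boot_seed = 1L) {
  ci_method <- match.arg(ci_method)
  d <- dataset
  if (exclude_catch) d <- dplyr::filter(d, .data$block != "catch")
  score_of <- stats::setNames(scale$score, scale$item_id)
  dist <- abs(score_of[d$item_a] - score_of[d$item_b])
  keep <- is.finite(dist) & is.finite(d$confidence)
  dist <- dist[keep]
  conf <- as.numeric(d$confidence[keep])
  if (length(dist) < 3L) {
    return(tibble::tibble(r = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          n = length(dist), status = "not_computed"))
  }
  if (stats::sd(dist) == 0 || stats::sd(conf) == 0) {
    return(tibble::tibble(r = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          n = length(dist), status = "degenerate"))
  }
  r <- stats::cor(conf, dist)
  if (ci_method == "fisher") {
    # degenerate at |r| = 1 (zero residual variance): the interval collapses
    if (abs(r) >= 1 - 1e-15) {
      lo <- hi <- r
    } else {
      z <- atanh(r)
      se <- 1 / sqrt(length(dist) - 3)
      lo <- tanh(z - stats::qnorm(0.975) * se)
      hi <- tanh(z + stats::qnorm(0.975) * se)
    }
  } else {
    rs <- withr::with_seed(as.integer(boot_seed), {
      purrr::map_dbl(seq_len(boot_reps), function(i) {
        idx <- sample.int(length(dist), replace = TRUE)
        suppressWarnings(stats::cor(conf[idx], dist[idx]))
      })
    })
    qs <- stats::quantile(rs[is.finite(rs)], c(0.025, 0.975), names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  tibble::tibble(r = r, ci_low = lo, ci_high = hi, n = length(dist),
                 status = "ok")
}

#' Anchor-order sanity check
#'
#' Reference materials carry a canonical low-to-high ordering; a trustworthy
#' run must reproduce it. Anchors are sorted by canonical rank and each
#' adjacent pair is checked for a fitted-score inversion (higher-ranked
#' anchor scoring strictly below the lower-ranked one). The denominator is
#' the number of adjacent anchor pairs (9 for a 10-anchor panel); any
#' inversion is a QC flag.
#'
#' @param scale An `anchored_scale` (or tibble with `item_id`, `score`).
#' @param items Item table with `item_id`, `role`, `canonical_rank`; taken
#'   from the scale itself when it carries those columns.
#' @return One-row tibble with `n_violations`, `n_pairs`; the offending
#'   adjacent pairs are in attribute `"violations"` (tibble `lower_item`,
#'   `higher_item`, `lower_score`, `higher_score`).
#' @export
anchor_order_check <- function(scale, items = NULL) {
  if (is.null(items)) {
    stopifnot(all(c("role", "canonical_rank") %in% names(scale)))
    items <- scale
  }
  anchors <- dplyr::arrange(
    dplyr::filter(tibble::as_tibble(items[c("item_id", "role", "canonical_rank")]),
                  .data$role == "anchor", !is.na(.data$canonical_rank)),
    .data$canonical_rank
  )
  if (nrow(anchors) < 2L) {
    abort("anchor order check needs at least two ranked anchors",
          class = "anchorpanel_config_error")
  }
  score_of <- stats::setNames(scale$score, scale$item_id)
  s <- score_of[anchors$item_id]
  lo <- seq_len(nrow(anchors) - 1L)
  hi <- lo + 1L
  inverted <- s[hi] < s[lo]
  out <- tibble::tibble(n_violations = sum(inverted), n_pairs = length(lo))
  attr(out, "violations") <- tibble::tibble(
    lower_item = anchors$item_id[lo][inverted],
    higher_item = anchors$item_id[hi][inverted],
    lower_score = unname(s[lo][inverted]),
    higher_score = unname(s[hi][inverted])
  )
  out
}

#' Default QC flag thresholds
#'
#' Flags are review triggers, not verdicts. Defaults: repeated-pair
#' agreement below 0.95 raises `LOW_REPEAT`; any anchor inversion raises
#' `ANCHOR_ORDER`; confidence-distance r below 0.6 raises
#' `WEAK_CONFIDENCE_CALIBRATION`; any failed catch trial raises `CATCH_FAIL`.
#' The repeat and calibration cutoffs sit between the signatures of a clean
#' run (agreement 1.0, r above 0.8) and a visibly degraded one (agreement
#' around 0.9, r around 0.4), so either regime is classified decisively.
#'
#' @param min_repeat_agreement,min_confidence_r,min_catch_pass Numeric
#'   cutoffs.
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(min_repeat_agreement = 0.95,
                          min_confidence_r = 0.6,
                          min_catch_pass = 1.0) {
  list(min_repeat_agreement = min_repeat_agreement,
       min_confidence_r = min_confidence_r,
       min_catch_pass = min_catch_pass)
}

#' Compile the full QC report for a run
#'
#' Aggregates repeatability, confidence calibration, catch-trial pass rate
#' and the anchor-order check, and raises flags against the configured
#' thresholds. Metrics that cannot be computed (e.g. no catch block) are
#' carried with an explicit status and never flagged.
#'
#' @param dataset Comparison dataset.
#' @param scale An `anchored_scale` for the same run.
#' @param spec The `panel_spec`.
#' @param thresholds See [qc_thresholds()].
#' @param agreement_rule Passed to [repeated_pair_agreement()].
#' @return A `qc_report` list with components `repeat_agreement`,
#'   `confidence_r`, `catch`, `anchor_order`, `flags`.
#' @export
compile_qc_report <- function(dataset, scale, spec,
                              thresholds = qc_thresholds(),
                              agreement_rule = "unanimity") {
  rep_agree <- repeated_pair_agreement(dataset, rule = agreement_rule)
  conf_r <- confidence_distance_correlation(dataset, scale)
  catch <- catch_trial_pass_rate(dataset, spec)
  order_chk <- anchor_order_check(scale, spec$items)

  flags <- character()
  if (rep_agree$status == "ok" &&
      rep_agree$agreement < thresholds$min_repeat_agreement) {
    flags <- c(flags, "LOW_REPEAT")
  }
  if (order_chk$n_violations > 0) flags <- c(flags, "ANCHOR_ORDER")
  if (conf_r$status == "ok" && conf_r$r < thresholds$min_confidence_r) {
    flags <- c(flags, "WEAK_CONFIDENCE_CALIBRATION")
  }
  if (catch$status == "ok" && catch$pass_rate < thresholds$min_catch_pass) {
    flags <- c(flags, "CATCH_FAIL")
  }
  structure(
    list(
      repeat_agreement = rep_agree,
      confidence_r = conf_r,
      catch = catch,
      anchor_order = order_chk,
      anchor_violations = attr(order_chk, "violations"),
      thresholds = thresholds,
      flags = flags
    ),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  fmt_pct <- function(p) sprintf("%.1f%%", 100 * p)
  cat("Quality-control summary\n")
  ra <- x$repeat_agreement
  cat("  Repeated-pair agreement: ",
      if (ra$status == "ok") sprintf("%s (%d/%d)", fmt_pct(ra$agreement),
                                     ra$n_agree, ra$n_pairs)
      else "not computed", "\n", sep = "")
  cr <- x$confidence_r
  cat("  Confidence vs |score difference|: ",
      if (cr$status == "ok") sprintf("r = %.3f (95%% CI %.3f-%.3f)",
                                     cr$r, cr$ci_low, cr$ci_high)
      else cr$status, "\n", sep = "")
  ct <- x$catch
  cat("  Catch-trial pass rate: ",
      if (ct$status == "ok") sprintf("%s (%d/%d)", fmt_pct(ct$pass_rate),
                                     ct$n_pass, ct$n_catch)
      else "not computed", "\n", sep = "")
  ao <- x$anchor_order
  cat(sprintf("  Anchor-order violations: %d/%d\n", ao$n_violations, ao$n_pairs))
  if (nrow(x$anchor_violations)) {
    cat(sprintf("    %s > %s\n", x$anchor_violations$lower_item,
                x$anchor_violations$higher_item), sep = "")
  }
  cat("  Flags: ", if (length(x$flags)) paste(x$flags, collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param report A `qc_report`.
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  out <- list(
    repeat_agreement = as.list(report$repeat_agreement),
    confidence_r = as.list(report$confidence_r),
    catch = as.list(report$catch),
    anchor_order = c(as.list(report$anchor_order),
                     list(violations = report$anchor_violations)),
    thresholds = report$thresholds,
    flags = as.list(report$flags)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}
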