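#' Build a run signature
#'
#' The behavioral signature of one completed panel run: the anchored scale
#' with intervals, the QC summary, the analysis configuration, and a digest
#' of the instrument (prompt template bytes + run file bytes). Longitudinal
#' comparisons are meaningful only between runs of the same instrument, so
#' the digest travels with the signature and is re-verified on load.
#'
#' @param signature_id Identifier for this signature.
#' @param spec The `panel_spec`.
#' @param scale An `anchored_scale` from [fit_anchored_scale()].
#' @param qc A `qc_report` from [compile_qc_report()].
#' @param template_path Path to the archived prompt template file.
#' @param run_file_path Path to the archived run file CSV.
#' @param timestamp Run timestamp (UTC string; defaults to now).
#' @return A `run_signature` list.
#' @export
build_run_signature <- function(signature_id, spec, scale, qc,
                                template_path, run_file_path,
                                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                                   tz = "UTC")) {
  g <- glance(scale)
  structure(
    list(
      signature_id = as.character(signature_id),
      panel_version = spec$panel_version,
      axis_id = spec$axis$axis_id,
      prompt_family_id = spec$prompt_family_id,
      wrapper_id = spec$wrapper_id,
      timestamp = timestamp,
      scale = tidy(scale),
      qc = list(
        repeat_agreement = as.list(qc$repeat_agreement),
        confidence_r = as.list(qc$confidence_r),
        catch = as.list(qc$catch),
        anchor_order = as.list(qc$anchor_order),
        flags = as.character(qc$flags)
      ),
      analysis_config = list(
        l2_lambda = g$l2_lambda,
        bootstrap_reps = g$bootstrap_reps,
        bootstrap_seed = g$bootstrap_seed,
        accuracy = g$accuracy,
        log_loss = g$log_loss,
        n_obs = g$n_obs
      ),
      template_path = as.character(template_path),
      run_file_path = as.character(run_file_path),
      instrument_hash = instrument_hash(template_path, run_file_path)
    ),
    class = "run_signature"
  )
}

#' Digest of the measurement instrument
#'
#' md5 over the concatenated bytes of the prompt template file and the run
#' file. Any byte-level change to either defines a different instrument.
#'
#' @param template_path,run_file_path Paths to the archived artifacts.
#' @return Hex digest string.
#' @export
instrument_hash <- function(template_path, run_file_path) {
  paste0(md5_file(template_path), md5_file(run_file_path)) |> md5_string()
}

#' Save and load run signatures
#'
#' Signatures persist as JSON. On load the instrument hash is recomputed
#' from the referenced template and run file and compared with the stored
#' value; a mismatch means the instrument was edited after the baseline was
#' taken (or the file is corrupt) and is an error. Set `verify = FALSE` to
#' inspect a signature whose artifacts are no longer on disk.
#'
#' @param signature A `run_signature`.
#' @param path JSON path.
#' @param verify Recompute and check the instrument hash (default TRUE).
#' @return `save_signature` returns `path` invisibly; `load_signature`
#'   returns the `run_signature`.
#' @export
save_signature <- function(signature, path) {
  jsonlite::write_json(unclass(signature), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_signature
#' @export
load_signature <- function(path, verify = TRUE) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  sc <- dplyr::bind_rows(purrr::map(raw$scale, function(row) {
    tibble::tibble(
      item_id = row$item_id, label = row$label, role = row$role,
      canonical_rank = as.integer(row$canonical_rank %||% NA_integer_),
      score = as.numeric(row$score),
      ci_low = as.numeric(row$ci_low %||% NA_real_),
      ci_high = as.numeric(row$ci_high %||% NA_real_)
    )
  }))
  sig <- structure(
    list(
      signature_id = raw$signature_id,
      panel_version = raw$panel_version,
      axis_id = raw$axis_id,
      prompt_family_id = raw$prompt_family_id,
      wrapper_id = raw$wrapper_id,
      timestamp = raw$timestamp,
      scale = sc,
      qc = lapply(raw$qc, function(x) lapply(x, function(v) v %||% NA)),
      analysis_config = raw$analysis_config,
      template_path = raw$template_path,
      run_file_path = raw$run_file_path,
      instrument_hash = raw$instrument_hash
    ),
    class = "run_signature"
  )
  if (verify) {
    recomputed <- instrument_hash(sig$template_path, sig$run_file_path)
    if (!identical(recomputed, sig$instrument_hash)) {
      abort(sprintf(paste0("instrument hash mismatch for signature '%s': ",
                           "stored %s, recomputed %s -- template or run file ",
                           "changed since the baseline was taken"),
                    sig$signature_id, sig$instrument_hash, recomputed),
            class = "anchorpanel_integrity_error")
    }
  }
  sig
}

#' @export
print.run_signature <- function(x, ...) {
  cat(sprintf("<run_signature> %s (%s, axis %s, %s/%s) %s\n",
              x$signature_id, x$panel_version, x$axis_id,
              x$prompt_family_id, x$wrapper_id, x$timestamp))
  cat(sprintf("  instrument %s; flags: %s\n", substr(x$instrument_hash, 1, 8),
              if (length(x$qc$flags)) paste(unlist(x$qc$flags), collapse = ", ")
              else "none"))
  invisible(x)
}

#' Default drift action thresholds
#'
#' Review is triggered when any item's score shift exceeds the half-width of
#' its baseline interval (uncertainty-scaled, so precise items are held to a
#' tighter band), when the candidate shows an anchor-order violation the
#' baseline did not, or when repeated-pair agreement drops by more than
#' `max_repeat_drop`. Mitigation and rebaselining are deliberate human
#' escalations recorded on the report, never auto-triggered.
#'
#' @param ci_halfwidth_factor Multiple of the baseline CI half-width a score
#'   delta may reach before review (default 1).
#' @param max_repeat_drop Tolerated drop in repeated-pair agreement.
#' @return Named list of thresholds.
#' @export
drift_thresholds <- function(ci_halfwidth_factor = 1, max_repeat_drop = 0.05) {
  list(ci_halfwidth_factor = ci_halfwidth_factor,
       max_repeat_drop = max_repeat_drop)
}

#' Compare a candidate run signature against a stored baseline
#'
#' Signatures are comparable only when panel version, axis and item set
#' match; anything else is an error naming the mismatch. The report gives
#' per-item score deltas (candidate minus baseline), an interval-overlap
#' indicator, a reversal summary over pairwise winners recomputed from the
#' two score vectors, QC metric deltas, and the triggered action.
#'
#' @param baseline,candidate `run_signature`s.
#' @param thresholds See [drift_thresholds()].
#' @return A `drift_report` list with `items` (per-item tibble), `reversals`,
#'   `qc_deltas`, `triggered_actions`.
#' @export
compare_to_baseline <- function(baseline, candidate,
                                thresholds = drift_thresholds()) {
  for (field in c("panel_version", "axis_id")) {
    if (!identical(baseline[[field]], candidate[[field]])) {
      abort(sprintf("signatures are not comparable: %s differs ('%s' vs '%s')",
                    field, baseline[[field]], candidate[[field]]),
            class = "anchorpanel_compare_error")
    }
  }
  if (!setequal(baseline$scale$item_id, candidate$scale$item_id)) {
    missing <- c(setdiff(baseline$scale$item_id, candidate$scale$item_id),
                 setdiff(candidate$scale$item_id, baseline$scale$item_id))
    abort(sprintf("signatures are not comparable: item set differs (%s)",
                  paste(missing, collapse = ", ")),
          class = "anchorpanel_compare_error")
  }
  b <- dplyr::arrange(baseline$scale, .data$item_id)
  c_ <- dplyr::arrange(candidate$scale, .data$item_id)
  items <- tibble::tibble(
    item_id = b$item_id,
    baseline_score = b$score,
    candidate_score = c_$score,
    delta = c_$score - b$score,
    baseline_ci_low = b$ci_low,
    baseline_ci_high = b$ci_high,
    ci_overlap = !(c_$ci_low > b$ci_high | c_$ci_high < b$ci_low),
    exceeds_band = abs(c_$score - b$score) >
      thresholds$ci_halfwidth_factor * (b$ci_high - b$ci_low) / 2
  )

  # pairwise winners recomputed from the two score vectors
  pairs <- utils::combn(sort(b$item_id), 2)
  sb <- stats::setNames(b$score, b$item_id)
  sc <- stats::setNames(c_$score, c_$item_id)
  win_b <- ifelse(sb[pairs[1, ]] > sb[pairs[2, ]], pairs[1, ], pairs[2, ])
  win_c <- ifelse(sc[pairs[1, ]] > sc[pairs[2, ]], pairs[1, ], pairs[2, ])
  reversed <- pair_key(pairs[1, ], pairs[2, ])[win_b != win_c]

  num <- function(x) if (is.null(x) || !is.finite(suppressWarnings(as.numeric(x)))) NA_real_ else as.numeric(x)
  qc_deltas <- tibble::tibble(
    repeat_agreement_baseline = num(baseline$qc$repeat_agreement$agreement),
    repeat_agreement_candidate = num(candidate$qc$repeat_agreement$agreement),
    confidence_r_baseline = num(baseline$qc$confidence_r$r),
    confidence_r_candidate = num(candidate$qc$confidence_r$r),
    anchor_violations_baseline = num(baseline$qc$anchor_order$n_violations),
    anchor_violations_candidate = num(candidate$qc$anchor_order$n_violations)
  )

  reasons <- character()
  if (any(items$exceeds_band)) {
    reasons <- c(reasons, sprintf("score shift beyond baseline CI band (%s)",
                                  paste(items$item_id[items$exceeds_band],
                                        collapse = ", ")))
  }
  new_violation <- isTRUE(qc_deltas$anchor_violations_candidate >
                            qc_deltas$anchor_violations_baseline) ||
    (is.na(qc_deltas$anchor_violations_baseline) &&
       isTRUE(qc_deltas$anchor_violations_candidate > 0))
  if (new_violation) reasons <- c(reasons, "new anchor-order violation")
  drop <- qc_deltas$repeat_agreement_baseline -
    qc_deltas$repeat_agreement_candidate
  if (isTRUE(drop > thresholds$max_repeat_drop)) {
    reasons <- c(reasons, sprintf("repeat agreement dropped by %.3f", drop))
  }
  structure(
    list(
      baseline_id = baseline$signature_id,
      candidate_id = candidate$signature_id,
      items = items,
      reversals = reversed,
      qc_deltas = qc_deltas,
      triggered_actions = if (length(reasons)) "review" else "none",
      reasons = reasons,
      thresholds = thresholds
    ),
    class = "drift_report"
  )
}

#' @export
print.drift_report <- function(x, ...) {
  cat(sprintf("<drift_report> %s -> %s: action %s\n", x$baseline_id,
              x$candidate_id, x$triggered_actions))
  if (length(x$reasons)) cat(paste0("  - ", x$reasons, "\n"), sep = "")
  cat(sprintf("  max |score delta| %.2f; %d pairwise reversals\n",
              max(abs(x$items$delta)), length(x$reversals)))
  invisible(x)
}

#' @export
tidy.drift_report <- function(x, ...) x$items

#' Serialize a drift report to JSON
#'
#' @param report A `drift_report`.
#' @param path Output path.
#' @export
write_drift_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
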