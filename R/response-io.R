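#' Parse one forced-choice JSON response line
#'
#' The response contract is a single one-line JSON object with exactly the
#' keys `trial_id`, `choice` (`"A"` or `"B"`) and `confidence` (integer
#' 0-100). Strict mode accepts exactly that language and nothing else; any
#' surrounding prose, code fencing, extra keys, tie/abstention, or a
#' non-integer or out-of-range confidence is rejected with a distinct error
#' class. Lenient mode first strips code fences and surrounding text down to
#' the outermost `{...}` span, retries, and records that a repair occurred --
#' parse robustness is itself part of a model's behavioral signature, so
#' repairs are never silent.
#'
#' Error conditions carry classes `anchorpanel_parse_<code>` with codes
#' `empty`, `multiline`, `extra_text`, `malformed_json`, `bad_keys`,
#' `bad_choice`, `bad_confidence`.
#'
#' @param text Raw response line.
#' @param lenient Attempt repair of decorated output (default `FALSE`).
#' @return A one-row tibble with `trial_id`, `choice`, `confidence`,
#'   `repaired`.
#' @export
parse_response_line <- function(text, lenient = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  repaired <- FALSE
  line <- text
  if (!nzchar(trimws(line))) stop_parse("empty response line", "empty")
  if (grepl("[\r\n]", trimws(line, which = "both"))) {
    if (!lenient) stop_parse("response spans multiple lines", "multiline")
  }
  if (lenient) {
    cleaned <- gsub("```[a-zA-Z]*", "", line)
    cleaned <- gsub("```", "", cleaned, fixed = TRUE)
    first <- regexpr("{", cleaned, fixed = TRUE)
    last <- max(gregexpr("}", cleaned, fixed = TRUE)[[1]])
    if (first > 0 && last > first) {
      candidate <- substr(cleaned, first, last)
      repaired <- !identical(candidate, line)
      line <- candidate
    } else {
      line <- trimws(cleaned)
      repaired <- !identical(line, text)
    }
  } else {
    if (!identical(substr(line, 1, 1), "{") ||
        !identical(substr(line, nchar(line), nchar(line)), "}")) {
      stop_parse("response is not a bare one-line JSON object", "extra_text")
    }
  }
  obj <- tryCatch(
    jsonlite::fromJSON(line, simplifyVector = FALSE),
    error = function(e) stop_parse("malformed JSON: %s", "malformed_json",
                                   conditionMessage(e))
  )
  if (!is.list(obj) || is.null(names(obj)) ||
      !setequal(names(obj), c("trial_id", "choice", "confidence")) ||
      length(obj) != 3L) {
    stop_parse("object must have exactly the keys trial_id, choice, confidence",
               "bad_keys")
  }
  if (!is.character(obj$choice) || length(obj$choice) != 1L ||
      !obj$choice %in% c("A", "B")) {
    stop_parse("choice must be \"A\" or \"B\"", "bad_choice")
  }
  conf <- obj$confidence
  if (!is.numeric(conf) || length(conf) != 1L || is.na(conf) ||
      conf != trunc(conf)) {
    stop_parse("confidence must be an integer", "bad_confidence")
  }
  if (conf < 0 || conf > 100) {
    stop_parse("confidence %s outside [0, 100]", "bad_confidence",
               format(conf))
  }
  if (!is.character(obj$trial_id) || length(obj$trial_id) != 1L ||
      !nzchar(obj$trial_id)) {
    stop_parse("trial_id must be a non-empty string", "bad_keys")
  }
  tibble::tibble(
    trial_id = obj$trial_id,
    choice = obj$choice,
    confidence = as.integer(conf),
    repaired = repaired
  )
}

#' Read a response file
#'
#' Accepts JSON-Lines (one response object per line) or a CSV with a
#' `raw_response` column. Lines that fail to parse are collected, not fatal:
#' the parse-failure rate is a reportable QC signal.
#'
#' @param path Responses file (`.jsonl`/`.ndjson`/`.json` lines, or `.csv`).
#' @param lenient Passed to [parse_response_line()].
#' @return Tibble of parsed responses; failures available via
#'   [parse_failures()].
#' @export
read_responses <- function(path, lenient = FALSE) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
    if (!"raw_response" %in% names(raw)) {
      stop_parse("CSV responses file needs a raw_response column", "run_file")
    }
    lines <- raw$raw_response
  } else {
    lines <- readLines(path, warn = FALSE)
  }
  lines <- lines[nzchar(trimws(lines))]
  parsed <- purrr::map(seq_along(lines), function(i) {
    tryCatch(parse_response_line(lines[i], lenient = lenient),
             anchorpanel_parse_error = function(e) {
               tibble::tibble(line = i, error = class(e)[1],
                              message = conditionMessage(e), text = lines[i])
             })
  })
  ok <- purrr::map_lgl(parsed, ~ "trial_id" %in% names(.x))
  out <- dplyr::bind_rows(parsed[ok])
  if (!nrow(out)) {
    out <- tibble::tibble(trial_id = character(), choice = character(),
                          confidence = integer(), repaired = logical())
  }
  attr(out, "parse_failures") <- dplyr::bind_rows(parsed[!ok])
  out
}

#' Parse failures recorded while reading responses
#'
#' @param responses Result of [read_responses()].
#' @return Tibble with `line`, `error`, `message`, `text` (zero rows when all
#'   lines parsed).
#' @export
parse_failures <- function(responses) {
  attr(responses, "parse_failures") %||%
    tibble::tibble(line = integer(), error = character(),
                   message = character(), text = character())
}

#' Join responses to the trial plan
#'
#' Matches each response to its trial by `trial_id` and resolves the chosen
#' position to an item: the winner is the item presented at the chosen
#' position of that trial, so winner resolution is invariant to A/B
#' counterbalancing. Anomalies are counted, never fatal -- a partially failed
#' run must still yield a QC report. Duplicate responses for one trial keep
#' the first occurrence (deterministic and auditable); orphans (no such
#' trial) and missing trials are tallied.
#'
#' @param plan Trial plan tibble from [build_trial_plan()]/[read_run_file()].
#' @param responses Tibble from [read_responses()] (or any tibble with
#'   `trial_id`, `choice`, `confidence`).
#' @return The comparison dataset: one row per valid observation with
#'   `trial_id`, `block`, `pair_key`, `repeat_index`, condition labels,
#'   `item_a`, `item_b`, `choice`, `winner`, `loser`, `confidence`. The
#'   ingestion tally is available via [ingestion_report()].
#' @export
join_responses <- function(plan, responses) {
  n_dup <- sum(duplicated(responses$trial_id))
  resp <- dplyr::distinct(responses, .data$trial_id, .keep_all = TRUE)
  orphan <- setdiff(resp$trial_id, plan$trial_id)
  missing <- setdiff(plan$trial_id, resp$trial_id)
  joined <- dplyr::inner_join(plan, resp, by = "trial_id")
  out <- dplyr::mutate(
    joined,
    winner = ifelse(.data$choice == "A", .data$item_a, .data$item_b),
    loser = ifelse(.data$choice == "A", .data$item_b, .data$item_a)
  )
  out <- dplyr::select(
    out, "trial_id", "block", "pair_key", "repeat_index",
    "prompt_family_id", "wrapper_id", "item_a", "item_b",
    "choice", "winner", "loser", "confidence"
  )
  pf <- parse_failures(responses)
  attr(out, "ingestion") <- tibble::tibble(
    n_trials = nrow(plan),
    n_responses = nrow(responses),
    n_observations = nrow(out),
    n_missing = length(missing),
    n_orphan = length(orphan),
    n_duplicate = n_dup,
    n_parse_failed = nrow(pf),
    n_repaired = if ("repaired" %in% names(resp)) sum(resp$repaired) else 0L
  )
  attr(out, "ingestion_detail") <- list(missing_trials = missing,
                                        orphan_responses = orphan)
  out
}

#' Ingestion tally for a joined dataset
#'
#' @param dataset Result of [join_responses()].
#' @return One-row tibble of counts (trials, responses, observations,
#'   missing, orphans, duplicates, parse failures, repairs).
#' @export
ingestion_report <- function(dataset) {
  attr(dataset, "ingestion") %||%
    tibble::tibble(n_trials = NA_integer_, n_responses = NA_integer_,
                   n_observations = nrow(dataset), n_missing = NA_integer_,
                   n_orphan = NA_integer_, n_duplicate = NA_integer_,
                   n_parse_failed = NA_integer_, n_repaired = NA_integer_)
}

#' Catch-trial pass rate
#'
#' A catch trial pairs two anchors with a wide canonical rank gap, so the
#' expected winner (the higher-ranked anchor) is known in advance; choosing
#' it is the attention check. With no catch observations the metric is
#' explicitly "not computed" rather than zero.
#'
#' @param dataset Comparison dataset from [join_responses()].
#' @param spec The `panel_spec` (source of canonical anchor ranks).
#' @return One-row tibble with `pass_rate`, `n_pass`, `n_catch`, `status`;
#'   per-trial outcomes in attribute `"outcomes"`.
#' @export
catch_trial_pass_rate <- function(dataset, spec) {
  catch <- dplyr::filter(dataset, .data$block == "catch")
  if (!nrow(catch)) {
    out <- tibble::tibble(pass_rate = NA_real_, n_pass = NA_integer_,
                          n_catch = 0L, status = "not_computed")
    attr(out, "outcomes") <- tibble::tibble(trial_id = character(),
                                            winner = character(),
                                            expected = character(),
                                            pass = logical())
    return(out)
  }
  anchors <- spec$items[spec$items$role == "anchor", ]
  rank_of <- stats::setNames(anchors$canonical_rank, anchors$item_id)
  expected <- ifelse(rank_of[catch$item_a] > rank_of[catch$item_b],
                     catch$item_a, catch$item_b)
  pass <- catch$winner == expected
  out <- tibble::tibble(
    pass_rate = mean(pass),
    n_pass = sum(pass),
    n_catch = length(pass),
    status = "ok"
  )
  attr(out, "outcomes") <- tibble::tibble(
    trial_id = catch$trial_id, winner = catch$winner,
    expected = unname(expected), pass = pass
  )
  out
}
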