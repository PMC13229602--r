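#' Build the deterministic trial plan for a panel
#'
#' Expands a [panel_spec()] into presented trials. The plan is a pure
#' function of the spec (including its seed): blocks draw their unordered
#' pairs from the eligible pair sets, the repeat plan re-presents a seeded
#' subset of non-catch pairs, every presentation gets an independently
#' randomized A/B assignment, and the whole plan is returned in seeded
#' shuffled presentation order.
#'
#' Block eligibility: `concept_anchor` draws from all concept-anchor pairs,
#' `concept_concept` from all concept pairs, `catch` from anchor pairs whose
#' canonical rank gap is at least 70% of the full anchor span (so the
#' expected winner is unambiguous), and `anchor_anchor` from the remaining
#' anchor pairs. Requesting more trials than a block has eligible pairs is a
#' configuration error; within-block duplicates never occur, so repeated
#' pairs come only from the repeat plan.
#'
#' @param spec A `panel_spec`.
#' @return A tibble with columns `trial_id`, `block`, `item_a`, `item_b`,
#'   `pair_key`, `repeat_index`, `prompt_family_id`, `wrapper_id`.
#' @export
build_trial_plan <- function(spec) {
  validate_panel_spec(spec)
  items <- spec$items
  anchors <- items[items$role == "anchor", ]
  concepts <- items[items$role == "concept", ]

  all_pairs <- function(a, b = NULL) {
    if (is.null(b)) {
      if (length(a) < 2) return(tibble::tibble(x = character(), y = character()))
      m <- utils::combn(sort(a), 2)
      tibble::tibble(x = m[1, ], y = m[2, ])
    } else {
      tidyr::expand_grid(x = a, y = b)
    }
  }

  rank_of <- stats::setNames(anchors$canonical_rank, anchors$item_id)
  aa <- all_pairs(anchors$item_id)
  if (nrow(aa)) {
    gap <- abs(rank_of[aa$x] - rank_of[aa$y])
    span <- diff(range(anchors$canonical_rank))
    catch_eligible <- aa[gap >= ceiling(0.7 * span), ]
    aa_eligible <- aa[gap < ceiling(0.7 * span), ]
  } else {
    catch_eligible <- aa_eligible <- aa
  }
  eligible <- list(
    concept_anchor = all_pairs(concepts$item_id, anchors$item_id),
    concept_concept = all_pairs(concepts$item_id),
    anchor_anchor = aa_eligible,
    catch = catch_eligible
  )

  rp <- spec$repeat_plan
  withr::with_seed(spec$seed, {
    base <- purrr::imap(spec$block_counts, function(k, block) {
      k <- as.integer(k)
      if (k == 0L) return(NULL)
      pool <- eligible[[block]]
      if (k > nrow(pool)) {
        stop_config("block '%s' requests %d trials but only %d eligible pairs exist",
                    block, k, nrow(pool))
      }
      pool <- pool[sample.int(nrow(pool), k), , drop = FALSE]
      tibble::tibble(block = block, x = pool$x, y = pool$y)
    })
    base <- dplyr::bind_rows(base)
    base$pair_key <- pair_key(base$x, base$y)

    repeat_pool <- base$pair_key[base$block != "catch"]
    if (rp$n_repeated_pairs > length(repeat_pool)) {
      stop_config("repeat plan requests %d pairs but only %d non-catch pairs exist",
                  rp$n_repeated_pairs, length(repeat_pool))
    }
    rep_keys <- sample(repeat_pool, rp$n_repeated_pairs)
    extra_keys <- if (rp$extra_presentations > 0) {
      if (rp$extra_presentations > length(rep_keys)) {
        stop_config("extra_presentations (%d) exceeds repeated pairs (%d)",
                    rp$extra_presentations, length(rep_keys))
      }
      sample(rep_keys, rp$extra_presentations)
    } else character()

    reps <- dplyr::bind_rows(
      purrr::map(seq_len(rp$reps_per_pair - 1L), function(i) {
        dplyr::filter(base, .data$pair_key %in% rep_keys)
      }),
      dplyr::filter(base, .data$pair_key %in% extra_keys)
    )
    plan <- dplyr::bind_rows(base, reps)
    plan <- dplyr::group_by(plan, .data$pair_key)
    plan <- dplyr::mutate(plan, repeat_index = dplyr::row_number() - 1L)
    plan <- dplyr::ungroup(plan)

    # independent A/B assignment per presentation, then shuffled order
    flip <- stats::runif(nrow(plan)) < 0.5
    plan$item_a <- ifelse(flip, plan$y, plan$x)
    plan$item_b <- ifelse(flip, plan$x, plan$y)
    plan <- plan[sample.int(nrow(plan)), ]
  })

  frag <- version_fragment(spec$panel_version)
  width <- max(3L, nchar(nrow(plan)))
  tibble::tibble(
    trial_id = sprintf("%s-t%0*d", frag, width, seq_len(nrow(plan))),
    block = plan$block,
    item_a = plan$item_a,
    item_b = plan$item_b,
    pair_key = plan$pair_key,
    repeat_index = plan$repeat_index,
    prompt_family_id = spec$prompt_family_id,
    wrapper_id = spec$wrapper_id
  )
}

#' Default hardness prompt template
#'
#' The instrument's core forced-choice prompt with the three placeholders
#' `[TRIAL_ID]`, `[ITEM_A]`, `[ITEM_B]`. The template text is part of the
#' measurement instrument: byte-level changes to it define a new instrument
#' version.
#'
#' @return A length-1 character template.
#' @export
default_prompt_template <- function() {
  paste0(
    "Quality-assurance forced-choice trial. Compare A and B as same-sized ",
    "solid materials. Hardness means resistance to indentation and ",
    "scratching. Exclude brittleness, fragility, size, weight, emotional ",
    "valence, moral desirability, and clinical importance. ",
    "Trial_id: [TRIAL_ID]. A: [ITEM_A]. B: [ITEM_B]. ",
    "Choose the harder item. Return exactly one line of JSON and no other ",
    "text: {\"trial_id\":\"[TRIAL_ID]\",\"choice\":\"A\" or \"B\",",
    "\"confidence\":[integer 0-100]}."
  )
}

#' Render the prompt for one trial
#'
#' Substitutes `[TRIAL_ID]`, `[ITEM_A]` and `[ITEM_B]` into the template and
#' preserves every other template byte; the template is the instrument, so
#' rendering never rewrites it.
#'
#' @param trial A one-row trial tibble (or list) with `trial_id`, `item_a`,
#'   `item_b`.
#' @param template Template string containing all three placeholders.
#' @param items Optional item table mapping `item_id` to display `label`;
#'   when omitted the raw ids are inserted.
#' @return The rendered prompt string.
#' @export
render_prompt <- function(trial, template = default_prompt_template(), items = NULL) {
  for (ph in c("[TRIAL_ID]", "[ITEM_A]", "[ITEM_B]")) {
    if (!grepl(ph, template, fixed = TRUE)) {
      abort(sprintf("template is missing placeholder %s", ph),
            class = "anchorpanel_template_error")
    }
  }
  lab <- function(id) {
    if (is.null(items)) return(id)
    hit <- match(id, items$item_id)
    if (is.na(hit)) abort(sprintf("unknown item_id '%s'", id),
                          class = "anchorpanel_config_error")
    items$label[hit]
  }
  out <- gsub("[TRIAL_ID]", trial$trial_id, template, fixed = TRUE)
  out <- gsub("[ITEM_A]", lab(trial$item_a), out, fixed = TRUE)
  gsub("[ITEM_B]", lab(trial$item_b), out, fixed = TRUE)
}

#' Render prompts for a whole plan
#'
#' @param plan Trial plan tibble from [build_trial_plan()].
#' @inheritParams render_prompt
#' @return Tibble with `trial_id` and `prompt`.
#' @export
render_prompts <- function(plan, template = default_prompt_template(), items = NULL) {
  tibble::tibble(
    trial_id = plan$trial_id,
    prompt = purrr::map_chr(seq_len(nrow(plan)), function(i) {
      render_prompt(plan[i, ], template, items)
    })
  )
}

run_file_cols <- c("trial_id", "block", "item_a", "item_b", "pair_key",
                   "repeat_index", "prompt_family_id", "wrapper_id")

#' Archive and restore run files
#'
#' The run file is the archival record of a panel administration: the full
#' trial order and A/B positions, one CSV row per trial. `read_run_file()`
#' validates structure (all columns present, unique trial ids, `item_a !=
#' item_b`, pair keys consistent) and, when a spec is supplied, that every
#' item belongs to the panel. Reading a written plan restores it exactly.
#'
#' @param plan Trial plan tibble.
#' @param path CSV path.
#' @param spec Optional `panel_spec` used to check item membership.
#' @return `write_run_file` returns `path` invisibly; `read_run_file` returns
#'   the plan tibble.
#' @export
write_run_file <- function(plan, path) {
  stopifnot(all(run_file_cols %in% names(plan)))
  readr::write_csv(plan[run_file_cols], path)
  invisible(path)
}

#' @rdname write_run_file
#' @export
read_run_file <- function(path, spec = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    trial_id = readr::col_character(), block = readr::col_character(),
    item_a = readr::col_character(), item_b = readr::col_character(),
    pair_key = readr::col_character(), repeat_index = readr::col_integer(),
    prompt_family_id = readr::col_character(), wrapper_id = readr::col_character()
  ))
  missing_cols <- setdiff(run_file_cols, names(raw))
  if (length(missing_cols)) {
    stop_parse("run file '%s' lacks column(s): %s", "run_file",
               path, paste(missing_cols, collapse = ", "))
  }
  if (nrow(readr::problems(raw))) {
    p <- readr::problems(raw)
    stop_parse("malformed run file row %d: %s", "run_file", p$row[1], p$expected[1])
  }
  dup <- raw$trial_id[duplicated(raw$trial_id)]
  if (length(dup)) {
    stop_parse("duplicate trial_id '%s' (row %d)", "run_file",
               dup[1], which(raw$trial_id == dup[1])[2])
  }
  same <- which(raw$item_a == raw$item_b)
  if (length(same)) {
    stop_parse("item_a equals item_b on row %d", "run_file", same[1])
  }
  if (!is.null(spec)) {
    known <- spec$items$item_id
    bad <- which(!(raw$item_a %in% known) | !(raw$item_b %in% known))
    if (length(bad)) {
      unknown <- setdiff(c(raw$item_a[bad], raw$item_b[bad]), known)[1]
      stop_parse("unknown item '%s' on row %d", "run_file", unknown, bad[1])
    }
  }
  expected_key <- pair_key(raw$item_a, raw$item_b)
  off <- which(expected_key != raw$pair_key)
  if (length(off)) {
    stop_parse("pair_key on row %d does not match its items", "run_file", off[1])
  }
  tibble::as_tibble(as.data.frame(raw[run_file_cols]))
}
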