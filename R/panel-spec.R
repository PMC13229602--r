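#' Define a panel item
#'
#' An item is one member of the instrument: either a reference material
#' (`role = "anchor"`) with a canonical position on the axis, or an abstract
#' target (`role = "concept"`) whose position is what the panel estimates.
#'
#' @param item_id Short stable token identifying the item (e.g. `"steel"`).
#' @param label Display string inserted into prompts (e.g. `"Steel"`).
#' @param role `"anchor"` or `"concept"`.
#' @param canonical_rank For anchors, an integer giving the intended low-to-high
#'   ordering along the axis; must be `NA` for concepts.
#' @return A one-row tibble with columns `item_id`, `label`, `role`,
#'   `canonical_rank`.
#' @export
panel_item <- function(item_id, label = item_id, role = c("anchor", "concept"),
                       canonical_rank = NA_integer_) {
  role <- match.arg(role)
  if (role == "anchor" && is.na(canonical_rank)) {
    stop_config("anchor item '%s' requires a canonical_rank", item_id)
  }
  if (role == "concept" && !is.na(canonical_rank)) {
    stop_config("concept item '%s' must not carry a canonical_rank", item_id)
  }
  tibble::tibble(
    item_id = as.character(item_id),
    label = as.character(label),
    role = role,
    canonical_rank = as.integer(canonical_rank)
  )
}

#' Define the measurement axis
#'
#' @param axis_id Token naming the axis (e.g. `"hardness"`).
#' @param definition_text Wording of the axis definition inserted into the
#'   prompt; part of the instrument.
#' @param low_anchor,high_anchor Item ids of the two anchors pinned to 0 and
#'   100 on the reported scale.
#' @return A list of class `axis_spec`.
#' @export
axis_spec <- function(axis_id, definition_text, low_anchor, high_anchor) {
  if (identical(low_anchor, high_anchor)) {
    stop_config("low_anchor and high_anchor must differ")
  }
  structure(
    list(
      axis_id = as.character(axis_id),
      definition_text = as.character(definition_text),
      low_anchor = as.character(low_anchor),
      high_anchor = as.character(high_anchor)
    ),
    class = "axis_spec"
  )
}

#' Assemble a versioned panel specification
#'
#' The panel spec is the versioned instrument: its items, axis, block
#' composition, repeat plan, condition labels, and the seed that fixes the
#' trial plan. The total number of trials implied by a spec is
#' `sum(block_counts) + n_repeated_pairs * (reps_per_pair - 1) +
#' extra_presentations`.
#'
#' @param panel_version Version string; trial ids are prefixed with a hash
#'   fragment of it so plans from different versions can never collide.
#' @param axis An [axis_spec()].
#' @param items Tibble of items, typically `dplyr::bind_rows()` of
#'   [panel_item()] calls.
#' @param block_counts Named list or vector with trial counts for blocks
#'   `concept_anchor`, `concept_concept`, `anchor_anchor`, `catch`.
#' @param repeat_plan List with `n_repeated_pairs` (unordered pairs presented
#'   more than once), `reps_per_pair` (>= 2, presentations for each of those
#'   pairs), and optionally `extra_presentations` (additional third-pass
#'   presentations spread over the repeated pairs; default 0).
#' @param prompt_family_id,wrapper_id Condition labels recorded on every trial.
#' @param seed Integer seed; the trial plan is a pure function of the spec,
#'   including this seed.
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(panel_version, axis, items, block_counts, repeat_plan,
                       prompt_family_id = "baseline", wrapper_id = "plain",
                       seed = 1L) {
  spec <- structure(
    list(
      panel_version = as.character(panel_version),
      axis = axis,
      items = tibble::as_tibble(items),
      block_counts = as.list(block_counts),
      repeat_plan = utils::modifyList(
        list(n_repeated_pairs = 0L, reps_per_pair = 2L, extra_presentations = 0L),
        lapply(as.list(repeat_plan), as.integer)
      ),
      prompt_family_id = as.character(prompt_family_id),
      wrapper_id = as.character(wrapper_id),
      seed = as.integer(seed)
    ),
    class = "panel_spec"
  )
  validate_panel_spec(spec)
  spec
}

#' Validate a panel specification
#'
#' Checks item uniqueness, anchor rank integrity, axis references, block
#' names, and the repeat plan. Called by [panel_spec()]; exported so specs
#' read from files can be revalidated.
#'
#' @param spec A `panel_spec`.
#' @return `spec`, invisibly, if valid; otherwise an error.
#' @export
validate_panel_spec <- function(spec) {
  items <- spec$items
  if (anyDuplicated(items$item_id)) {
    stop_config("duplicate item_id: %s",
                paste(unique(items$item_id[duplicated(items$item_id)]), collapse = ", "))
  }
  anchors <- items[items$role == "anchor", ]
  if (any(is.na(anchors$canonical_rank))) {
    stop_config("every anchor needs a canonical_rank")
  }
  if (anyDuplicated(anchors$canonical_rank)) {
    stop_config("anchor canonical_ranks must be distinct")
  }
  if (any(items$role == "concept" & !is.na(items$canonical_rank))) {
    stop_config("concepts must not have canonical_rank")
  }
  for (a in c(spec$axis$low_anchor, spec$axis$high_anchor)) {
    if (!a %in% anchors$item_id) {
      stop_config("axis anchor '%s' is not an anchor item of the panel", a)
    }
  }
  bad <- setdiff(names(spec$block_counts),
                 c("concept_anchor", "concept_concept", "anchor_anchor", "catch"))
  if (length(bad)) stop_config("unknown block name(s): %s", paste(bad, collapse = ", "))
  rp <- spec$repeat_plan
  if (rp$n_repeated_pairs > 0 && rp$reps_per_pair < 2L) {
    stop_config("reps_per_pair must be >= 2")
  }
  if (rp$extra_presentations > rp$n_repeated_pairs * 1L && rp$extra_presentations > 0 &&
      rp$n_repeated_pairs == 0L) {
    stop_config("extra_presentations requires repeated pairs")
  }
  invisible(spec)
}

#' Total number of trials a spec generates
#'
#' `sum(block_counts) + n_repeated_pairs * (reps_per_pair - 1) +
#' extra_presentations`.
#'
#' @param spec A `panel_spec`.
#' @return Integer trial count.
#' @export
n_trials <- function(spec) {
  rp <- spec$repeat_plan
  sum(unlist(spec$block_counts)) +
    rp$n_repeated_pairs * (rp$reps_per_pair - 1L) +
    rp$extra_presentations
}

#' The default 190-trial hardness panel
#'
#' Ten reference materials spanning an intuitive hardness continuum plus five
#' abstract concept targets, with Marshmallow and Steel pinned to 0 and 100.
#' The base plan presents each of the 105 unordered pairs once (50
#' concept-anchor, 10 concept-concept, 39 anchor-anchor, 6 catch trials on
#' maximally rank-separated anchor pairs); 64 pairs are then re-presented, 21
#' of them a third time, for 190 trials in total with exactly 64 repeated
#' unordered pairs. This composition is a reconstruction: published panels of
#' this size do not break down their block structure, so any composition
#' totalling 190 with 64 repeated pairs is admissible and this one covers
#' every pair at least once.
#'
#' @param seed Seed stored in the spec (default 20260325).
#' @param prompt_family_id,wrapper_id Condition labels.
#' @return A `panel_spec`.
#' @export
default_panel <- function(seed = 20260325L, prompt_family_id = "baseline",
                          wrapper_id = "plain") {
  anchors <- c(
    marshmallow = "Marshmallow", oak = "Oak hardwood",
    abs = "ABS plastic block", polycarbonate = "Polycarbonate sheet",
    acrylic = "Acrylic sheet", aluminum = "Aluminum plate",
    bone = "Dry bone", glass = "Window glass",
    porcelain = "Porcelain", steel = "Steel"
  )
  concepts <- c(
    life = "Life", kindness = "Kindness", silence = "Silence",
    justice = "Justice", death = "Death"
  )
  items <- dplyr::bind_rows(
    unname(purrr::imap(anchors, function(lab, id) {
      panel_item(id, lab, "anchor", canonical_rank = which(names(anchors) == id))
    })),
    unname(purrr::imap(concepts, function(lab, id) panel_item(id, lab, "concept")))
  )
  panel_spec(
    panel_version = "hardness-v1",
    axis = axis_spec(
      "hardness",
      paste("Hardness means resistance to indentation and scratching.",
            "Exclude brittleness, fragility, size, weight, emotional valence,",
            "moral desirability, and clinical importance."),
      low_anchor = "marshmallow", high_anchor = "steel"
    ),
    items = items,
    block_counts = list(
      concept_anchor = 50L, concept_concept = 10L,
      anchor_anchor = 39L, catch = 6L
    ),
    repeat_plan = list(
      n_repeated_pairs = 64L, reps_per_pair = 2L, extra_presentations = 21L
    ),
    prompt_family_id = prompt_family_id,
    wrapper_id = wrapper_id,
    seed = seed
  )
}

#' Read and write panel specifications as JSON
#'
#' Serialization round-trips losslessly: `read_panel_spec(write_panel_spec(s))`
#' reproduces `s` exactly.
#'
#' @param spec A `panel_spec`.
#' @param path File path.
#' @return `write_panel_spec` returns `path` invisibly; `read_panel_spec`
#'   returns a validated `panel_spec`.
#' @export
write_panel_spec <- function(spec, path) {
  validate_panel_spec(spec)
  out <- list(
    panel_version = spec$panel_version,
    axis = unclass(spec$axis),
    items = spec$items,
    block_counts = spec$block_counts,
    repeat_plan = spec$repeat_plan,
    prompt_family_id = spec$prompt_family_id,
    wrapper_id = spec$wrapper_id,
    seed = spec$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_panel_spec
#' @export
read_panel_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  items <- dplyr::bind_rows(purrr::map(raw$items, function(it) {
    tibble::tibble(
      item_id = it$item_id, label = it$label, role = it$role,
      canonical_rank = as.integer(it$canonical_rank %||% NA_integer_)
    )
  }))
  panel_spec(
    panel_version = raw$panel_version,
    axis = axis_spec(raw$axis$axis_id, raw$axis$definition_text,
                     raw$axis$low_anchor, raw$axis$high_anchor),
    items = items,
    block_counts = raw$block_counts,
    repeat_plan = raw$repeat_plan,
    prompt_family_id = raw$prompt_family_id,
    wrapper_id = raw$wrapper_id,
    seed = raw$seed
  )
}

#' @export
print.panel_spec <- function(x, ...) {
  cat(sprintf("<panel_spec> %s  axis: %s (%s -> %s)\n",
              x$panel_version, x$axis$axis_id, x$axis$low_anchor, x$axis$high_anchor))
  cat(sprintf("  items: %d (%d anchors, %d concepts); trials: %d; seed: %d\n",
              nrow(x$items), sum(x$items$role == "anchor"),
              sum(x$items$role == "concept"), n_trials(x), x$seed))
  invisible(x)
}
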