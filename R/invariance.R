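#' Derive the pairwise winner map for one condition
#'
#' Collapses a comparison dataset (already filtered to a single wrapper or
#' prompt-family condition) to one winner per unordered pair, by majority
#' across that pair's observations; exact ties are recorded as
#' indeterminate (`NA`). Whether the condition is a wrapper or a prompt
#' family is metadata only -- the arithmetic is identical.
#'
#' @param dataset Comparison dataset for one condition.
#' @param condition_id Label stored on the map (defaults to the dataset's
#'   single wrapper/prompt-family combination when unambiguous).
#' @return A `winner_map` tibble with `pair_key`, `winner` (`NA` =
#'   indeterminate), `n_obs`.
#' @export
derive_winner_map <- function(dataset, condition_id = NULL) {
  if (!nrow(dataset)) {
    abort("cannot derive a winner map from an empty dataset",
          class = "anchorpanel_config_error")
  }
  if (is.null(condition_id)) {
    conds <- unique(paste(dataset$prompt_family_id, dataset$wrapper_id, sep = "/"))
    condition_id <- if (length(conds) == 1L) conds else "mixed"
  }
  out <- dplyr::summarise(
    dplyr::group_by(dataset, .data$pair_key),
    winner = {
      tab <- sort(table(.data$winner), decreasing = TRUE)
      if (length(tab) > 1L && tab[1] == tab[2]) NA_character_ else names(tab)[1]
    },
    n_obs = dplyr::n(),
    .groups = "drop"
  )
  structure(out, class = c("winner_map", class(out)),
            condition_id = condition_id)
}

#' Compare pairwise winners across two conditions
#'
#' The comparable set is the intersection of pairs with a determinate winner
#' in both conditions; a reversal is a comparable pair whose winner differs.
#' Agreement is `100 * (n_pairs - reversals) / n_pairs`, reported to one
#' decimal. Pairs indeterminate in either condition are excluded from the
#' denominator and listed separately.
#'
#' @param map_a,map_b `winner_map`s from [derive_winner_map()].
#' @return An `invariance_report`: one-row tibble with `condition_a`,
#'   `condition_b`, `n_pairs`, `reversals`, `agreement_pct`, plus
#'   list-columns `reversal_list` and `indeterminate`.
#' @export
compare_conditions <- function(map_a, map_b) {
  joined <- dplyr::inner_join(
    tibble::as_tibble(map_a)[c("pair_key", "winner")],
    tibble::as_tibble(map_b)[c("pair_key", "winner")],
    by = "pair_key", suffix = c("_a", "_b")
  )
  indeterminate <- joined$pair_key[is.na(joined$winner_a) | is.na(joined$winner_b)]
  comparable <- dplyr::filter(joined, !is.na(.data$winner_a),
                              !is.na(.data$winner_b))
  if (!nrow(comparable)) {
    abort("conditions share no determinate pairs",
          class = "anchorpanel_config_error")
  }
  reversed <- comparable$pair_key[comparable$winner_a != comparable$winner_b]
  n <- nrow(comparable)
  out <- tibble::tibble(
    condition_a = attr(map_a, "condition_id") %||% "A",
    condition_b = attr(map_b, "condition_id") %||% "B",
    n_pairs = n,
    reversals = length(reversed),
    agreement_pct = round(100 * (n - length(reversed)) / n, 1),
    reversal_list = list(reversed),
    indeterminate = list(indeterminate)
  )
  structure(out, class = c("invariance_report", class(out)))
}

#' @export
print.invariance_report <- function(x, ...) {
  cat(sprintf("<invariance_report> %s vs %s: %d pairs, %d reversals, %.1f%% agreement\n",
              x$condition_a, x$condition_b, x$n_pairs, x$reversals,
              x$agreement_pct))
  if (length(x$reversal_list[[1]])) {
    cat("  reversed pairs: ", paste(x$reversal_list[[1]], collapse = ", "),
        "\n", sep = "")
  }
  if (length(x$indeterminate[[1]])) {
    cat("  indeterminate (excluded): ",
        paste(x$indeterminate[[1]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.invariance_report <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("condition_a", "condition_b", "n_pairs",
                                 "reversals", "agreement_pct")])
}
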