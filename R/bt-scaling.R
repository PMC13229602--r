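# Penalized Bradley-Terry fitting.
#
# Model: P(i beats j) = exp(beta_i) / (exp(beta_i) + exp(beta_j)).
# Estimation maximizes
#   sum_obs log sigma(beta_winner - beta_loser) - lambda * sum_i beta_i^2
# (no intercept). With lambda > 0 the objective is strictly concave, so a
# damped Newton iteration converges to the unique maximizer; item counts are
# small (a panel has ~15 items) so dense linear algebra is ample.

# core solver on a fixed pair orientation: rows (ai, bi), outcome y = 1 when
# the item at position ai won. Returns the uncentered maximizer.
bt_solve <- function(ai, bi, y, m, lambda, tol = 1e-8, max_iter = 200L) {
  n <- length(ai)
  X <- matrix(0, n, m)
  X[cbind(seq_len(n), ai)] <- 1
  X[cbind(seq_len(n), bi)] <- -1
  beta <- numeric(m)
  objective <- function(b) {
    d <- b[ai] - b[bi]
    sum(y * stats::plogis(d, log.p = TRUE) +
          (1 - y) * stats::plogis(-d, log.p = TRUE)) - lambda * sum(b^2)
  }
  obj <- objective(beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    p <- stats::plogis(beta[ai] - beta[bi])
    g <- as.vector(crossprod(X, y - p)) - 2 * lambda * beta
    if (!all(is.finite(g))) {
      abort("non-finite gradient in Bradley-Terry fit",
            class = "anchorpanel_fit_error")
    }
    if (max(abs(g)) <= tol) {
      converged <- TRUE
      break
    }
    w <- p * (1 - p)
    H <- crossprod(X, X * w) + diag(2 * lambda + 1e-12, m)
    delta <- tryCatch(solve(H, g), error = function(e) g / max(diag(H)))
    step <- 1
    repeat {
      cand <- beta + step * delta
      cand_obj <- objective(cand)
      if (is.finite(cand_obj) && cand_obj >= obj - 1e-12) break
      step <- step / 2
      if (step < 1e-10) break
    }
    beta <- beta + step * delta
    obj <- objective(beta)
  }
  list(beta = beta, converged = converged, iterations = iter,
       objective = obj)
}

#' Fit an L2-regularized Bradley-Terry model
#'
#' Estimates one latent strength per item from the winner/loser observations
#' of a comparison dataset by maximizing the ridge-penalized Bradley-Terry
#' log-likelihood (damped Newton, gradient max-norm tolerance `tol`). The
#' returned strengths are mean-centered: the likelihood depends only on
#' strength differences, so the origin is arbitrary and is removed later by
#' anchoring anyway.
#'
#' The penalty weight is part of the instrument configuration; it is
#' recorded in the fit and in every run signature. `lambda = 0` is accepted
#' but with perfectly separated data the unpenalized maximizer diverges and
#' the fit will report `converged = FALSE`.
#'
#' @param dataset Tibble with `winner` and `loser` columns (one row per
#'   observation), e.g. from [join_responses()].
#' @param l2_lambda Ridge penalty weight (default 0.1).
#' @param items Optional character vector fixing the item index; defaults to
#'   the sorted items appearing in the data.
#' @param tol Gradient max-norm convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @return A `bt_fit`: list with named `beta`, `items`, `l2_lambda`,
#'   `converged`, `n_obs`, `iterations`.
#' @export
fit_bradley_terry <- function(dataset, l2_lambda = 0.1, items = NULL,
                              tol = 1e-8, max_iter = 200L) {
  if (!nrow(dataset)) {
    abort("empty comparison dataset", class = "anchorpanel_fit_error")
  }
  if (l2_lambda < 0) {
    abort("l2_lambda must be >= 0", class = "anchorpanel_fit_error")
  }
  items <- items %||% sort(unique(c(dataset$winner, dataset$loser)))
  if (length(items) < 2L) {
    abort("need at least two items to fit", class = "anchorpanel_fit_error")
  }
  ai <- match(dataset$winner, items)
  bi <- match(dataset$loser, items)
  if (anyNA(ai) || anyNA(bi)) {
    abort("dataset contains items outside the item index",
          class = "anchorpanel_fit_error")
  }
  sol <- bt_solve(ai, bi, rep(1, length(ai)), length(items), l2_lambda,
                  tol = tol, max_iter = max_iter)
  structure(
    list(
      beta = stats::setNames(sol$beta - mean(sol$beta), items),
      items = items,
      l2_lambda = l2_lambda,
      converged = sol$converged,
      n_obs = nrow(dataset),
      iterations = sol$iterations
    ),
    class = "bt_fit"
  )
}

#' @export
print.bt_fit <- function(x, ...) {
  cat(sprintf("<bt_fit> %d items, %d obs, lambda=%g, %s (%d iter)\n",
              length(x$beta), x$n_obs, x$l2_lambda,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(round(sort(x$beta), 4))
  invisible(x)
}

#' Rescale latent strengths to the anchored 0-100 axis
#'
#' `score_i = 100 * (beta_i - beta_low) / (beta_high - beta_low)`, so the low
#' anchor lands exactly at 0 and the high anchor exactly at 100. Items ranked
#' beyond the anchors legitimately fall outside \[0, 100\]. Equal anchor
#' strengths make the axis undefined; that degenerate case is raised as an
#' anchoring error and is itself a QC signal.
#'
#' @param fit A `bt_fit`.
#' @param axis An [axis_spec()] naming the pinned anchors.
#' @return Tibble with `item_id` and `score`.
#' @export
anchor_rescale <- function(fit, axis) {
  beta <- fit$beta
  for (a in c(axis$low_anchor, axis$high_anchor)) {
    if (!a %in% names(beta)) {
      abort(sprintf("anchor '%s' not in fitted items", a),
            class = "anchorpanel_anchoring_error")
    }
  }
  denom <- beta[[axis$high_anchor]] - beta[[axis$low_anchor]]
  if (!is.finite(denom) || abs(denom) < 1e-12) {
    abort("degenerate anchors: pinned anchors have equal fitted strength",
          class = "anchorpanel_anchoring_error")
  }
  tibble::tibble(
    item_id = names(beta),
    score = 100 * (unname(beta) - beta[[axis$low_anchor]]) / denom
  )
}

#' Classification accuracy and log loss of a fitted scale
#'
#' Accuracy is the fraction of observations whose observed winner has the
#' larger fitted strength (exact strength ties contribute 0.5, matching a
#' random prediction); log loss is minus the mean log-probability the fitted
#' model assigns to the observed winners.
#'
#' @param fit A `bt_fit`.
#' @param dataset The comparison dataset the fit should be scored on.
#' @return One-row tibble with `accuracy`, `log_loss`, `n_obs`.
#' @export
fit_metrics <- function(fit, dataset) {
  d <- fit$beta[dataset$winner] - fit$beta[dataset$loser]
  if (anyNA(d)) {
    abort("dataset contains items absent from the fit",
          class = "anchorpanel_fit_error")
  }
  acc <- mean(ifelse(d > 0, 1, ifelse(d == 0, 0.5, 0)))
  ll <- -mean(stats::plogis(d, log.p = TRUE))
  tibble::tibble(accuracy = acc, log_loss = ll, n_obs = nrow(dataset))
}

#' Parametric-bootstrap confidence intervals on the anchored scale
#'
#' For each replicate, every observation's winner is redrawn Bernoulli from
#' the fitted Bradley-Terry probability for its pair, the model is refit with
#' the same penalty, and the anchored rescaling is applied to that replicate;
#' the per-item 2.5/97.5 percentile bounds over replicates are the reported
#' 95% interval. The pinned anchors map to exactly 0 and 100 in every
#' replicate, so their intervals are degenerate by construction. Replicates
#' whose refit fails are dropped and counted; more than 10% drops aborts.
#'
#' @param fit A `bt_fit`.
#' @param dataset The comparison dataset that produced `fit` (fixes the pair
#'   structure that is resimulated).
#' @param axis An [axis_spec()].
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Seed for the single bootstrap generator.
#' @param level Interval level (default 0.95).
#' @return Tibble with `item_id`, `ci_low`, `ci_high`; attributes `n_reps`,
#'   `seed`, `n_dropped`.
#' @export
bootstrap_ci <- function(fit, dataset, axis, n_reps = 1000L, seed = 1L,
                         level = 0.95) {
  if (n_reps < 2L) {
    abort("n_reps must be >= 2", class = "anchorpanel_fit_error")
  }
  items <- fit$items
  ai <- match(dataset$winner, items)
  bi <- match(dataset$loser, items)
  p_win <- stats::plogis(fit$beta[ai] - fit$beta[bi])
  m <- length(items)
  low_i <- match(axis$low_anchor, items)
  high_i <- match(axis$high_anchor, items)
  scores <- matrix(NA_real_, n_reps, m)
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_reps)) {
      y <- stats::rbinom(length(ai), 1L, p_win)
      rep_fit <- tryCatch(
        bt_solve(ai, bi, y, m, fit$l2_lambda),
        error = function(e) NULL
      )
      if (is.null(rep_fit) || !all(is.finite(rep_fit$beta))) next
      denom <- rep_fit$beta[high_i] - rep_fit$beta[low_i]
      if (!is.finite(denom) || abs(denom) < 1e-12) next
      scores[r, ] <- 100 * (rep_fit$beta - rep_fit$beta[low_i]) / denom
    }
  })
  ok <- stats::complete.cases(scores)
  n_dropped <- sum(!ok)
  if (n_dropped > 0.1 * n_reps) {
    abort(sprintf("bootstrap unstable: %d of %d replicates failed",
                  n_dropped, n_reps),
          class = "anchorpanel_fit_error")
  }
  alpha <- (1 - level) / 2
  q <- apply(scores[ok, , drop = FALSE], 2, stats::quantile,
             probs = c(alpha, 1 - alpha), names = FALSE)
  out <- tibble::tibble(item_id = items, ci_low = q[1, ], ci_high = q[2, ])
  attr(out, "n_reps") <- as.integer(n_reps)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Fit the full anchored scale for a panel run
#'
#' Convenience pipeline: Bradley-Terry fit, anchored rescaling, fit metrics,
#' and (optionally) parametric-bootstrap intervals, joined with the panel's
#' item metadata. This is the table a scale report prints: one row per item
#' with its role, anchored score, and 95% interval.
#'
#' @param dataset Comparison dataset from [join_responses()].
#' @param spec The `panel_spec` for the run.
#' @param l2_lambda Ridge penalty weight.
#' @param bootstrap_reps Bootstrap replicates; `0` skips the bootstrap and
#'   leaves the interval columns `NA`.
#' @param seed Bootstrap seed.
#' @return An `anchored_scale` tibble: `item_id`, `label`, `role`,
#'   `canonical_rank`, `score`, `ci_low`, `ci_high`, sorted by score. The
#'   underlying `bt_fit` is in `attr(, "fit")`; [glance()] returns the fit
#'   summary.
#' @export
fit_anchored_scale <- function(dataset, spec, l2_lambda = 0.1,
                               bootstrap_reps = 1000L, seed = 1L) {
  fit <- fit_bradley_terry(dataset, l2_lambda = l2_lambda,
                           items = sort(spec$items$item_id))
  scores <- anchor_rescale(fit, spec$axis)
  metrics <- fit_metrics(fit, dataset)
  if (bootstrap_reps > 0) {
    ci <- bootstrap_ci(fit, dataset, spec$axis, n_reps = bootstrap_reps,
                       seed = seed)
  } else {
    ci <- tibble::tibble(item_id = fit$items, ci_low = NA_real_,
                         ci_high = NA_real_)
  }
  out <- dplyr::left_join(scores, ci, by = "item_id")
  out <- dplyr::left_join(out, spec$items, by = "item_id")
  out <- dplyr::arrange(
    dplyr::select(out, "item_id", "label", "role", "canonical_rank",
                  "score", "ci_low", "ci_high"),
    .data$score
  )
  structure(
    out,
    class = c("anchored_scale", class(out)),
    fit = fit,
    axis = spec$axis,
    metrics = metrics,
    bootstrap = list(n_reps = as.integer(bootstrap_reps),
                     seed = as.integer(seed),
                     n_dropped = if (bootstrap_reps > 0) attr(ci, "n_dropped") else NA_integer_)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.anchored_scale <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @export
glance.anchored_scale <- function(x, ...) {
  m <- attr(x, "metrics")
  b <- attr(x, "bootstrap")
  fit <- attr(x, "fit")
  tibble::tibble(
    accuracy = m$accuracy, log_loss = m$log_loss, n_obs = m$n_obs,
    l2_lambda = fit$l2_lambda, converged = fit$converged,
    bootstrap_reps = b$n_reps, bootstrap_seed = b$seed
  )
}

#' @export
print.anchored_scale <- function(x, ...) {
  m <- attr(x, "metrics")
  cat(sprintf("<anchored_scale> accuracy %.3f, log loss %.4f, %d observations\n",
              m$accuracy, m$log_loss, m$n_obs))
  print(tidy(x), n = nrow(x))
  invisible(x)
}

#' Write and read the scale table
#'
#' CSV mirror of the scale report (item, role, score, interval bounds).
#'
#' @param scale An `anchored_scale` or compatible tibble.
#' @param path CSV path.
#' @export
write_scale_table <- function(scale, path) {
  readr::write_csv(tidy(scale), path)
  invisible(path)
}

#' @rdname write_scale_table
#' @export
read_scale_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    item_id = readr::col_character(), label = readr::col_character(),
    role = readr::col_character(), canonical_rank = readr::col_integer(),
    score = readr::col_double(), ci_low = readr::col_double(),
    ci_high = readr::col_double()
  ))
}
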