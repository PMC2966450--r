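#' Precision and recall at depth
#'
#' Both metrics are computed over the top `min(N, length(ranked))` items of a
#' ranked list: precision divides by the number of items actually examined
#' (so a list shorter than `N` uses its own length as denominator), recall by
#' the total number of relevant documents. The identity
#' `R@N = P@N * min(N, |ranked|) / |relevant|` holds by construction.
#'
#' @param ranked Character vector of doc ids in rank order, or a
#'   `ranked_list` tibble from [rank_bm25()].
#' @param relevant Character vector of relevant doc ids (non-empty for
#'   recall).
#' @param n Depth `N >= 1`.
#' @return A single number in `[0, 1]`.
#' @export
precision_at <- function(ranked, relevant, n) {
  ranked <- ranked_ids(ranked)
  stopifnot(is_count(n), n >= 1)
  depth <- min(n, length(ranked))
  if (depth == 0) return(0)
  sum(ranked[seq_len(depth)] %in% relevant) / depth
}

#' @rdname precision_at
#' @export
recall_at <- function(ranked, relevant, n) {
  ranked <- ranked_ids(ranked)
  stopifnot(is_count(n), n >= 1)
  if (length(relevant) == 0) {
    abort_boolrank("recall is undefined for an empty relevant set", "boolrank_eval_error")
  }
  depth <- min(n, length(ranked))
  if (depth == 0) return(0)
  sum(ranked[seq_len(depth)] %in% relevant) / length(relevant)
}

#' Set-based precision and recall for unordered Boolean output
#'
#' @param retrieved Character vector (unordered result set).
#' @param relevant Character vector of relevant doc ids.
#' @return A single number in `[0, 1]`.
#' @export
set_precision <- function(retrieved, relevant) {
  if (length(retrieved) == 0) return(0)
  length(intersect(retrieved, relevant)) / length(retrieved)
}

#' @rdname set_precision
#' @export
set_recall <- function(retrieved, relevant) {
  if (length(relevant) == 0) {
    abort_boolrank("recall is undefined for an empty relevant set", "boolrank_eval_error")
  }
  length(intersect(retrieved, relevant)) / length(relevant)
}

#' Rank-biased precision
#'
#' RBP models a user who moves from each rank to the next with persistence
#' probability `p`: \deqn{RBP = (1 - p) \sum_{i \ge 1} r_i \, p^{\,i-1}} with
#' binary relevance `r_i`. For a finite list the sum is the lower bound of
#' the metric; the unobserved tail contributes at most `p^depth`, returned as
#' the `"residual"` attribute.
#'
#' @inheritParams precision_at
#' @param p Persistence parameter in `(0, 1)`; patient systematic reviewers
#'   are modeled with `p = 0.99`.
#' @return RBP base value with attribute `residual`.
#' @export
rbp <- function(ranked, relevant, p = 0.99) {
  ranked <- ranked_ids(ranked)
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p <= 0 || p >= 1) {
    abort_boolrank("persistence p must lie strictly between 0 and 1", "boolrank_eval_error")
  }
  r <- as.numeric(ranked %in% relevant)
  value <- if (length(r) == 0) 0 else (1 - p) * sum(r * p^(seq_along(r) - 1))
  structure(value, residual = p^length(r))
}

#' Tolerance-threshold stopping model
#'
#' Models a screener working down a ranked list who abandons it after seeing
#' more than `tau` consecutive non-relevant documents: the counter starts at
#' zero, resets on every relevant document, increments on every non-relevant
#' one, and the user stops the moment it *exceeds* `tau` (so the
#' `(tau + 1)`-th consecutive non-relevant item triggers the stop; set
#' `strict = FALSE` for the `>= tau` reading). If the list is exhausted first
#' the stop rank is the list length and no violating rank is recorded.
#'
#' @inheritParams precision_at
#' @param tau Non-negative tolerance threshold.
#' @param strict Strict exceedance (default) versus `>=` comparison.
#' @return A one-row tibble: `tau`, `stop_rank`, `recall_at_stop`,
#'   `violating_rank` (`NA` if the list was exhausted), `exhausted`.
#' @export
tolerance_run <- function(ranked, relevant, tau, strict = TRUE) {
  ranked <- ranked_ids(ranked)
  stopifnot(is_count(tau))
  if (length(relevant) == 0) {
    abort_boolrank("tolerance model needs a non-empty relevant set", "boolrank_eval_error")
  }
  counter <- 0
  stop_rank <- length(ranked)
  violating <- NA_integer_
  limit <- if (strict) tau else tau - 1
  for (i in seq_along(ranked)) {
    if (ranked[i] %in% relevant) {
      counter <- 0
    } else {
      counter <- counter + 1
      if (counter > limit) {
        stop_rank <- i
        violating <- i
        break
      }
    }
  }
  seen <- ranked[seq_len(stop_rank)]
  tibble(
    tau = tau,
    stop_rank = stop_rank,
    recall_at_stop = length(intersect(seen, relevant)) / length(relevant),
    violating_rank = violating,
    exhausted = is.na(violating)
  )
}

#' @rdname tolerance_run
#' @param tau_grid Ascending vector of thresholds.
#' @return `tolerance_curve()` returns one row per threshold; recall and
#'   violating rank are non-decreasing in `tau`.
#' @export
tolerance_curve <- function(ranked, relevant, tau_grid, strict = TRUE) {
  stopifnot(!is.unsorted(tau_grid))
  out <- dplyr::bind_rows(lapply(tau_grid, function(tau) {
    tolerance_run(ranked, relevant, tau, strict = strict)
  }))
  class(out) <- c("tolerance_curve", class(out))
  out
}

#' Random-order baseline for an unordered Boolean result set
#'
#' A Boolean system returns a set with no ranking; to evaluate it with
#' rank-based metrics the set is shuffled uniformly at random (seeded, fully
#' reproducible) and the metrics are averaged over shuffles.
#'
#' @param result_set Character vector (the unordered set).
#' @param relevant Character vector of relevant doc ids.
#' @param seed Integer seed.
#' @param repeats Number of shuffles (`>= 1`).
#' @param metrics Named list of functions `f(ranked, relevant)` returning a
#'   single number; defaults to recall at the set size and RBP(0.99).
#' @return A tibble with one row per metric: `metric`, `mean`, `sd`, and the
#'   per-shuffle values in a list column.
#' @export
random_order_baseline <- function(result_set, relevant, seed, repeats = 100,
                                  metrics = NULL) {
  stopifnot(is_count(repeats), repeats >= 1)
  metrics <- metrics %||% list(
    recall = function(ranked, relevant) {
      recall_at(ranked, relevant, max(1, length(ranked)))
    },
    rbp99 = function(ranked, relevant) as.numeric(rbp(ranked, relevant, 0.99))
  )
  set.seed(as.integer(seed))
  values <- matrix(NA_real_, nrow = repeats, ncol = length(metrics))
  colnames(values) <- names(metrics)
  for (r in seq_len(repeats)) {
    shuffled <- sample(result_set)
    for (m in names(metrics)) {
      values[r, m] <- metrics[[m]](shuffled, relevant)
    }
  }
  tibble(
    metric = names(metrics),
    mean = unname(colMeans(values)),
    sd = unname(apply(values, 2, stats::sd)),
    values = lapply(names(metrics), function(m) unname(values[, m]))
  )
}

#' Tabulate effectiveness of a run at several depths
#'
#' Produces one row per (tier, depth-pair) in the layout used for reporting
#' ranked systems: RBP at the chosen persistence plus P@N and R@N at each
#' cutoff.
#'
#' @param ranked Ranked doc ids or a `ranked_list`.
#' @param judgments A [tier_judgments()].
#' @param tier Target tier (0, 1 or 2).
#' @param cutoffs Integer vector of depths.
#' @param p RBP persistence.
#' @return A one-row tibble: `tier`, `rbp`, then `p_at_<N>` / `r_at_<N>` per
#'   cutoff.
#' @export
evaluate_run <- function(ranked, judgments, tier, cutoffs = c(1000, 10000), p = 0.99) {
  relevant <- judged_set(judgments, tier)
  if (length(relevant) == 0) {
    abort_boolrank(sprintf("tier %d has no judged documents", tier), "boolrank_eval_error")
  }
  out <- tibble(tier = tier, rbp = as.numeric(rbp(ranked, relevant, p)))
  for (n in cutoffs) {
    out[[paste0("p_at_", n)]] <- precision_at(ranked, relevant, n)
    out[[paste0("r_at_", n)]] <- recall_at(ranked, relevant, n)
  }
  out
}

ranked_ids <- function(ranked) {
  if (is.data.frame(ranked)) {
    if (!"doc_id" %in% names(ranked)) {
      abort_boolrank("ranked data frame needs a doc_id column", "boolrank_format_error")
    }
    as.character(ranked$doc_id)
  } else {
    as.character(ranked)
  }
}
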