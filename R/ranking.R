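#' Pose ranking configuration
#'
#' How to combine an external docking score with descriptor occupancies
#' into one ordering.  The published screen combined descriptor results
#' with the docking ranking without stating the rule; the default here is
#' a weighted rank sum, which is robust to the very different scales of
#' docking scores and percentages.
#'
#' @param criteria character vector of score-table column names to use.
#' @param weights nonnegative weights, recycled to `criteria`.
#' @param higher_is_better logical, recycled to `criteria`.
#' @param aggregation `"rank_sum"` (default), `"weighted_z"` or
#'   `"pareto_then_rank_sum"`.
#' @return a `ranking_config` object.
#' @export
ranking_config <- function(criteria, weights = 1, higher_is_better = TRUE,
                           aggregation = c("rank_sum", "weighted_z",
                                           "pareto_then_rank_sum")) {
  aggregation <- match.arg(aggregation)
  stopifnot(length(criteria) >= 1)
  weights <- rep_len(as.numeric(weights), length(criteria))
  higher_is_better <- rep_len(as.logical(higher_is_better), length(criteria))
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and nonnegative", call. = FALSE)
  if (all(weights == 0)) stop("at least one criterion must have weight > 0",
                              call. = FALSE)
  structure(list(criteria = criteria, weights = weights,
                 higher_is_better = higher_is_better,
                 aggregation = aggregation),
            class = "ranking_config")
}

# competition ranks (ties share the minimum rank), higher value = better
.ag_comp_rank <- function(x) {
  r <- rank(-x, ties.method = "min")
  r
}

#' Rank poses by combined criteria
#'
#' Default aggregation `rank_sum`: per criterion assign competition ranks
#' (best = 1, ties share the minimum rank), aggregate by the weighted mean
#' of ranks, order ascending by aggregate, ties broken lexicographically
#' by pose id.  `weighted_z` aggregates weighted z-scores (sign-flipped
#' for lower-is-better criteria, higher aggregate = better).
#' `pareto_then_rank_sum` orders Pareto-dominant fronts first, rank sum
#' within a front.
#'
#' @param score_table data.frame with a `pose_id` column and the criterion
#'   columns (e.g. the output of [score_poses()]).
#' @param config a [ranking_config()].
#' @return the table ordered best-first with `aggregate` and `rank`
#'   columns added.
#' @export
rank_poses <- function(score_table, config) {
  stopifnot(nrow(score_table) >= 1, "pose_id" %in% names(score_table))
  for (cr in config$criteria) {
    if (!cr %in% names(score_table))
      stop("criterion column missing from score table: ", cr, call. = FALSE)
    v <- score_table[[cr]]
    if (all(is.na(v))) stop("criterion has no values: ", cr, call. = FALSE)
    if (any(is.na(v) | is.nan(v)))
      stop(sprintf("missing/NaN value in enabled criterion '%s' for pose %s",
                   cr, score_table$pose_id[which(is.na(v) | is.nan(v))[1]]),
           call. = FALSE)
  }
  vals <- lapply(seq_along(config$criteria), function(k) {
    v <- as.numeric(score_table[[config$criteria[k]]])
    if (config$higher_is_better[k]) v else -v
  })
  w <- config$weights / sum(config$weights)
  agg <- switch(config$aggregation,
    rank_sum = {
      ranks <- vapply(vals, .ag_comp_rank, numeric(nrow(score_table)))
      as.vector(ranks %*% w)  # ascending = better
    },
    weighted_z = {
      zs <- vapply(vals, function(v) {
        s <- stats::sd(v)
        if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
      }, numeric(nrow(score_table)))
      -as.vector(zs %*% w)  # negate so ascending = better, like rank_sum
    },
    pareto_then_rank_sum = {
      n <- nrow(score_table)
      vm <- do.call(cbind, vals)
      dominated_by <- function(a, b)  # b dominates a
        all(vm[b, ] >= vm[a, ]) && any(vm[b, ] > vm[a, ])
      front <- integer(n)
      remaining <- seq_len(n)
      f <- 0L
      while (length(remaining)) {
        f <- f + 1L
        nd <- remaining[vapply(remaining, function(a)
          !any(vapply(remaining, function(b)
            b != a && dominated_by(a, b), logical(1))), logical(1))]
        front[nd] <- f
        remaining <- setdiff(remaining, nd)
      }
      ranks <- vapply(vals, .ag_comp_rank, numeric(n))
      front * n + as.vector(ranks %*% w) / (n + 1)
    })
  ord <- order(agg, score_table$pose_id)
  out <- score_table[ord, , drop = FALSE]
  out$aggregate <- agg[ord]
  out$rank <- .ag_comp_rank(-out$aggregate)
  rownames(out) <- NULL
  out
}

#' Select the top-ranked poses
#'
#' Returns the first `n` rows of a ranked table.  When ties straddle the
#' cutoff every tied row at the boundary is kept and the result is marked
#' (`attr(x, "tie_expanded")`).
#'
#' @param ranked_table output of [rank_poses()].
#' @param n number of poses requested (>= 0).
#' @return subset table; attribute `tie_expanded` is TRUE when more than
#'   `n` rows were returned because of a boundary tie.
#' @export
select_top <- function(ranked_table, n) {
  stopifnot(n >= 0)
  if (n == 0) {
    out <- ranked_table[0, , drop = FALSE]
    attr(out, "tie_expanded") <- FALSE
    return(out)
  }
  if (n >= nrow(ranked_table)) {
    attr(ranked_table, "tie_expanded") <- FALSE
    return(ranked_table)
  }
  cut_val <- ranked_table$aggregate[n]
  keep <- which(ranked_table$aggregate <= cut_val)
  out <- ranked_table[keep, , drop = FALSE]
  attr(out, "tie_expanded") <- length(keep) > n
  out
}
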