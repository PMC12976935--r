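# Recovery scoring: Jaccard overlap between groupings, and pooled R-squared
# for function predictions.

#' Jaccard comparison of two groupings
#'
#' For every ground-truth group i and predicted group j,
#' \eqn{J_{ij} = |i \cap j| / |i \cup j|} (intersection over union); each
#' truth group scores its best match \eqn{J_i = \max_j J_{ij}}, and the total
#' index is the mean over truth groups, so identical groupings score 1.
#' The alternative normalization \eqn{|i \cap j| / (|i| + |j|)} is available
#' via `denominator = "sum"` (it scores perfect recovery at 0.5).
#'
#' When the predicted grouping carries an `active` flag (gating), inactive
#' features are compared as their own class against a truth class 0
#' ("irrelevant") when one exists, and the comparison of labelled groups is
#' restricted to active features.
#'
#' @param truth Tibble with columns `feature_id` and `true_group` (or
#'   `group`); group 0 marks function-irrelevant features.
#' @param predicted Tibble with columns `feature_id` and `group`, optionally
#'   `active` (a `funclust_grouping`).
#' @param denominator `"union"` (default) or `"sum"`.
#' @return A list with `per_group` (named vector \eqn{J_i} over truth groups),
#'   `total` (their mean), and the full `matrix` \eqn{J_{ij}}.
#' @export
jaccard_index <- function(truth, predicted, denominator = c("union", "sum")) {
  denominator <- match.arg(denominator)
  t_group <- if ("true_group" %in% names(truth)) truth$true_group else truth$group
  t_ids <- as.character(truth$feature_id)
  p_ids <- as.character(predicted$feature_id)
  if (!setequal(t_ids, p_ids)) {
    abort("truth and predicted groupings cover different features",
          class = "funclust_feature_mismatch")
  }
  p_group <- predicted$group[match(t_ids, p_ids)]
  if ("active" %in% names(predicted)) {
    p_active <- predicted$active[match(t_ids, p_ids)]
    p_group[!p_active] <- 0L
  }

  t_levels <- sort(unique(t_group))
  p_levels <- sort(unique(p_group))
  J <- matrix(0, length(t_levels), length(p_levels),
              dimnames = list(t_levels, p_levels))
  for (a in seq_along(t_levels)) {
    for (b in seq_along(p_levels)) {
      ti <- t_ids[t_group == t_levels[a]]
      pj <- t_ids[p_group == p_levels[b]]
      inter <- length(intersect(ti, pj))
      denom <- if (denominator == "union") length(union(ti, pj))
               else length(ti) + length(pj)
      J[a, b] <- inter / denom
    }
  }
  per_group <- apply(J, 1, max)
  names(per_group) <- paste0("group", t_levels)
  list(per_group = per_group, total = mean(per_group), matrix = J)
}

#' Pooled R-squared
#'
#' \eqn{1 - SSE/SST} pooled over all entries of the observed block; at most 1,
#' and 0 for a constant predictor at the grand column means.
#'
#' @param observed Numeric vector or matrix of observed function values.
#' @param predicted Same shape, predicted values.
#' @return A scalar.
#' @export
r_squared <- function(observed, predicted) {
  observed <- as.matrix(observed); predicted <- as.matrix(predicted)
  stopifnot(all(dim(observed) == dim(predicted)), length(observed) >= 2)
  centered <- sweep(observed, 2, colMeans(observed))
  sst <- sum(centered^2)
  if (sst == 0) abort("zero total variance", class = "funclust_zero_variance")
  1 - sum((observed - predicted)^2) / sst
}
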