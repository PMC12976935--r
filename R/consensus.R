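# Consensus extraction: rank members by held-out R2, align group labels
# across members (clusterings are only defined up to a label permutation),
# then majority-vote per feature; gated features must be open (gamma >= 0.5)
# in a strict majority of the selected members to stay active.

#' Rank ensemble members and select the top fraction
#'
#' @param ensemble A `funclust_ensemble`.
#' @param top_fraction Fraction in (0, 1] of members to keep, ranked by
#'   held-out R2 (descending); `ceiling(top_fraction * n)` members are kept.
#' @return The selected members (list of `trained_member`), best first.
#' @export
rank_and_select <- function(ensemble, top_fraction = 0.5) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  members <- ensemble$members
  r2 <- vapply(members, function(m) m$test_r2, numeric(1))
  ord <- order(r2, decreasing = TRUE)
  members[ord[seq_len(ceiling(top_fraction * length(members)))]]
}

# Alignment key for each group of one member: average group abundance over
# the full dataset (hard assignments), or correlation of the group abundance
# with a designated function column.
alignment_keys <- function(member, X, F_mat = NULL, align_by = "abundance",
                           function_column = 1L) {
  K <- ncol(member$model$logits)
  C <- one_hot(hard_assignment(member$model), K)
  G <- X %*% C
  if (align_by == "abundance") {
    colMeans(G)
  } else {
    f <- F_mat[, function_column]
    vapply(seq_len(K), function(k) {
      if (sd(G[, k]) == 0) 0 else cor(G[, k], f)
    }, numeric(1))
  }
}

# Apply a label permutation perm (new order of old labels) to a member.
permute_member_labels <- function(member, perm) {
  member$model$logits <- member$model$logits[, perm, drop = FALSE]
  member$model$net$W[[1]] <- member$model$net$W[[1]][perm, , drop = FALSE]
  member
}

# Best label matching of a member against reference hard labels, by maximal
# assignment overlap over all K! permutations (K is small).
match_labels_to_reference <- function(labels, ref_labels, K) {
  perms <- all_permutations(K)
  overlap <- vapply(seq_len(nrow(perms)), function(i) {
    sum(perms[i, labels] == ref_labels)
  }, numeric(1))
  perms[which.max(overlap), ]
}

all_permutations <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(K - 1L)
  do.call(rbind, lapply(seq_len(K), function(pos) {
    cbind_pos <- cbind(sub + (sub >= pos), rep(pos, nrow(sub)))
    cbind_pos
  }))
}

#' Align group labels across ensemble members
#'
#' Reorders each member's group labels by descending average group abundance
#' over the full dataset (or by the correlation of each group's abundance
#' with a chosen function column), removing the arbitrary label permutation
#' between members. When alignment keys tie exactly, the member is matched to
#' the top-ranked member by maximal assignment overlap.
#'
#' @param members Selected members (see [rank_and_select()]).
#' @param ensemble The `funclust_ensemble` they came from (provides the data).
#' @param align_by `"abundance"` (default): order groups by descending
#'   average group abundance; `"function_cor"`: by the correlation of each
#'   group's abundance with a chosen function column; `"overlap"`: match each
#'   member's labels to the top-ranked member by maximal assignment overlap
#'   (the robust choice when groups have similar average abundance, as the
#'   key-based orderings then amount to a coin flip).
#' @param function_column Column of the function matrix used when
#'   `align_by = "function_cor"`.
#' @return The members with labels reordered in place.
#' @export
align_labels <- function(members, ensemble,
                         align_by = c("abundance", "function_cor", "overlap"),
                         function_column = 1L) {
  align_by <- match.arg(align_by)
  X <- ensemble$X
  K <- ensemble$config$n_clusters
  ref_labels <- NULL
  purrr::map(seq_along(members), function(i) {
    m <- members[[i]]
    keys <- if (align_by == "overlap") NULL else {
      alignment_keys(m, X, ensemble$F_mat, align_by, function_column)
    }
    if (is.null(keys) || anyDuplicated(keys)) {
      # Overlap matching against the top-ranked member (identity for the
      # first member); also the fallback for exactly tied sort keys.
      if (is.null(ref_labels)) {
        perm_of_old <- seq_len(K)
      } else {
        perm_of_old <- match_labels_to_reference(hard_assignment(m$model),
                                                 ref_labels, K)
      }
      new_order <- order(perm_of_old)
    } else {
      new_order <- order(keys, decreasing = TRUE)
    }
    m <- permute_member_labels(m, new_order)
    if (i == 1) ref_labels <<- hard_assignment(m$model)
    m
  })
}

#' Consensus grouping from aligned members
#'
#' Each feature's consensus label is the modal hard assignment (argmax of the
#' member's soft assignment row) across the selected members. With gating, a
#' feature is active iff its gate is open (\eqn{\gamma \ge 0.5}) in a strict
#' majority of members. Vote ties break toward the group with the larger mean
#' soft probability across members, then toward the lower group index.
#'
#' @param members Aligned members (see [align_labels()]).
#' @param feature_ids Character vector of feature identifiers.
#' @param gating_enabled Whether gate votes should be counted.
#' @param top_fraction_used Bookkeeping: the fraction that selected these
#'   members.
#' @return A tibble of class `funclust_grouping` with columns `feature_id`,
#'   `group`, `active`, `agreement`.
#' @export
consensus_grouping <- function(members, feature_ids = NULL,
                               gating_enabled = !is.null(members[[1]]$model$gate),
                               top_fraction_used = NA_real_) {
  stopifnot(length(members) >= 1)
  K <- ncol(members[[1]]$model$logits)
  n <- nrow(members[[1]]$model$logits)
  if (is.null(feature_ids)) feature_ids <- paste0("feature", seq_len(n))

  labels <- vapply(members, function(m) hard_assignment(m$model),
                   integer(n))
  labels <- matrix(labels, nrow = n)
  mean_P <- Reduce(`+`, lapply(members, function(m) {
    assignment_probabilities(m$model)
  })) / length(members)

  group <- integer(n); agreement <- numeric(n)
  for (i in seq_len(n)) {
    votes <- tabulate(labels[i, ], nbins = K)
    top <- which(votes == max(votes))
    if (length(top) > 1) {
      top <- top[order(-mean_P[i, top], top)][1]
    }
    group[i] <- top
    agreement[i] <- votes[top] / length(members)
  }

  active <- rep(TRUE, n)
  if (gating_enabled && !is.null(members[[1]]$model$gate)) {
    open <- vapply(members, function(m) sigmoid(m$model$gate) >= 0.5,
                   logical(n))
    open <- matrix(open, nrow = n)
    active <- rowSums(open) > length(members) / 2
  }

  out <- tibble::tibble(feature_id = feature_ids, group = group,
                        active = active, agreement = agreement)
  attr(out, "top_fraction_used") <- top_fraction_used
  class(out) <- c("funclust_grouping", class(out))
  out
}

#' One-call consensus from an ensemble
#'
#' Convenience wrapper: rank members by held-out R2, keep the top fraction,
#' align labels, and majority-vote.
#'
#' @param ensemble A `funclust_ensemble`.
#' @param top_fraction Fraction of members to keep (default 0.5).
#' @param align_by,function_column Passed to [align_labels()].
#' @return A `funclust_grouping` tibble.
#' @export
consensus <- function(ensemble, top_fraction = 0.5,
                      align_by = c("abundance", "function_cor", "overlap"),
                      function_column = 1L) {
  align_by <- match.arg(align_by)
  selected <- rank_and_select(ensemble, top_fraction)
  aligned <- align_labels(selected, ensemble, align_by, function_column)
  consensus_grouping(aligned, feature_ids = ensemble$feature_ids,
                     gating_enabled = ensemble$config$gate_strength > 0,
                     top_fraction_used = top_fraction)
}
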