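# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' Tidy an ensemble: one row per member
#'
#' @param x A `funclust_ensemble`.
#' @param ... Unused.
#' @return A tibble with `member`, `split_seed`, `test_loss`, `test_r2`,
#'   `train_loss`, `iterations_run`.
#' @export
tidy.funclust_ensemble <- function(x, ...) {
  tibble::tibble(
    member = seq_along(x$members),
    split_seed = vapply(x$members, function(m) m$split_seed %||% NA_integer_,
                        numeric(1)),
    test_loss = vapply(x$members, function(m) m$test_loss, numeric(1)),
    test_r2 = vapply(x$members, function(m) m$test_r2, numeric(1)),
    train_loss = vapply(x$members, function(m) m$train_loss, numeric(1)),
    iterations_run = vapply(x$members, function(m) m$iterations_run, integer(1))
  )
}

#' One-row ensemble summary
#'
#' @inheritParams tidy.funclust_ensemble
#' @return A one-row tibble with ensemble-level medians and the key
#'   configuration fields.
#' @export
glance.funclust_ensemble <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n_members = nrow(td),
    n_clusters = x$config$n_clusters,
    median_test_loss = median(td$test_loss),
    median_test_r2 = median(td$test_r2),
    gated = x$config$gate_strength > 0
  )
}

#' Tidy a consensus grouping (returns it as a plain tibble)
#'
#' @param x A `funclust_grouping`.
#' @param ... Unused.
#' @export
tidy.funclust_grouping <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("feature_id", "group", "active", "agreement")])
}

#' Tidy a consumer-resource fit: per-sample parameters and errors
#'
#' @param x A `crm_fit`.
#' @param ... Unused.
#' @export
tidy.crm_fit <- function(x, ...) {
  x$per_sample
}

#' One-row summary of a consumer-resource fit
#'
#' @inheritParams tidy.crm_fit
#' @export
glance.crm_fit <- function(x, ...) {
  tibble::tibble(
    gamma1 = x$gamma1, gamma2 = x$gamma2,
    n_samples = nrow(x$per_sample),
    total_objective = x$total_objective,
    median_nitrate_mse = median(x$per_sample$nitrate_mse)
  )
}

#' Plot held-out performance of an ensemble
#'
#' @param object A `funclust_ensemble`.
#' @param ... Unused.
#' @return A ggplot: per-member held-out R2, ordered.
#' @export
autoplot.funclust_ensemble <- function(object, ...) {
  td <- tidy(object) |> dplyr::arrange(dplyr::desc(.data$test_r2))
  td$rank <- seq_len(nrow(td))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$rank, y = .data$test_r2)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "member (ranked)", y = expression(R^2~"(held out)"),
                  title = "Ensemble held-out performance") +
    ggplot2::theme_minimal()
}

#' Plot a group-number scan
#'
#' @param object A `funclust_scan`.
#' @param ... Unused.
#' @return A ggplot of per-member and median held-out losses against the
#'   number of groups, with the function-variance reference as a dashed line.
#' @export
autoplot.funclust_scan <- function(object, ...) {
  ggplot2::ggplot(object$per_member,
                  ggplot2::aes(x = .data$n_clusters, y = .data$test_loss)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = object$summary,
                       ggplot2::aes(y = .data$median_test_loss),
                       color = "firebrick") +
    ggplot2::geom_hline(yintercept = object$reference_variance,
                        linetype = "dashed", color = "gray40") +
    ggplot2::labs(x = "number of groups", y = "held-out MSE",
                  title = "Loss vs number of groups") +
    ggplot2::theme_minimal()
}

#' Plot consensus group membership and agreement
#'
#' @param object A `funclust_grouping`.
#' @param ... Unused.
#' @export
autoplot.funclust_grouping <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$feature_id, y = .data$agreement,
                                   fill = factor(.data$group),
                                   alpha = .data$active)) +
    ggplot2::geom_col() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3),
                                guide = "none") +
    ggplot2::labs(x = NULL, y = "agreement", fill = "group",
                  title = "Consensus grouping") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot fitted nitrate trajectories
#'
#' @param object A `crm_fit`.
#' @param observations Optional: the observations tibble the fit used, to
#'   overlay the measured nitrate points.
#' @param ... Unused.
#' @export
autoplot.crm_fit <- function(object, observations = NULL, ...) {
  traj <- purrr::imap_dfr(object$trajectories, function(tr, id) {
    dplyr::mutate(tibble::as_tibble(tr), sample_id = id)
  })
  p <- ggplot2::ggplot(traj, ggplot2::aes(x = .data$time, y = .data$nitrate,
                                          color = .data$sample_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "nitrate (mM)",
                  title = "Fitted nitrate dynamics") +
    ggplot2::theme_minimal()
  if (!is.null(observations)) {
    parsed <- parse_crm_observations(observations)
    pts <- tibble::tibble(
      sample_id = rep(parsed$sample_id, each = length(parsed$times)),
      time = rep(parsed$times, length(parsed$sample_id)),
      nitrate = as.numeric(t(parsed$A)))
    p <- p + ggplot2::geom_point(data = pts, size = 1)
  }
  p
}
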