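# Regime-switching synthetic benchmark: a scalar community function that is
# linear in three hidden group abundances, with coefficients that switch
# between three regimes set by the medians of the first two group abundances.
# Globally the structure-function map is therefore nonlinear even though it is
# piecewise linear.

#' Default regime coefficient vectors
#'
#' Three coefficient vectors, one per environmental regime. Regime 1 applies
#' when both G1 and G2 exceed their medians, regime 2 when G1 exceeds its
#' median but G2 does not, and regime 3 whenever G1 is below its median.
#'
#' @return A list of three numeric 3-vectors `a1`, `a2`, `a3`.
#' @export
regime_coefficients <- function() {
  list(a1 = c(0.1, 1, 1), a2 = c(1, -0.5, -0.1), a3 = c(-1, 0.1, -1))
}

#' Sum abundances within ground-truth groups
#'
#' @param x Numeric abundance vector (one sample) or an N-by-n matrix.
#' @param assignment Integer vector of group indices, one per feature; 0 marks
#'   features that belong to no group (function-irrelevant).
#' @return A vector (or matrix) of group abundances, one entry per group.
#' @export
group_sums <- function(x, assignment) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == length(assignment))
  } else {
    stopifnot(length(x) == length(assignment))
    x <- matrix(x, nrow = 1)
  }
  groups <- sort(unique(assignment[assignment > 0]))
  out <- vapply(groups, function(g) {
    rowSums(x[, assignment == g, drop = FALSE])
  }, numeric(nrow(x)))
  if (nrow(x) == 1) as.numeric(out) else matrix(out, nrow = nrow(x))
}

#' Select the coefficient regime for one sample
#'
#' @param G Numeric 3-vector of group abundances for the sample.
#' @param medians Numeric 3-vector of group-abundance medians over the full
#'   generated sample set.
#' @return Integer regime index in 1:3. Ties with the median fall into the
#'   "greater than" branch (a measure-zero event under continuous abundance
#'   laws, resolved deterministically).
#' @export
select_regime <- function(G, medians) {
  if (G[1] >= medians[1]) {
    if (G[2] >= medians[2]) 1L else 2L
  } else {
    3L
  }
}

#' Generate the regime-switching benchmark dataset
#'
#' Draws per-species abundances independently from Uniform(0, 1), computes the
#' three true group abundances, and produces a scalar function
#' \eqn{f = \sum_i a_i(\mathrm{regime}) G_i} whose coefficient vector switches
#' between three regimes according to whether G1 and G2 exceed their medians.
#' Optionally appends function-irrelevant species (which never enter f) for
#' gating studies, and additive Gaussian noise on f.
#'
#' @param n_samples Number of samples (default 500).
#' @param n_species Number of function-relevant species (default 12).
#' @param n_groups Number of ground-truth groups (default 3; the regime rules
#'   are defined for 3 groups).
#' @param group_assignment Optional integer vector assigning each relevant
#'   species to a group; default is consecutive blocks of equal size.
#' @param n_irrelevant Number of extra species drawn from the same abundance
#'   law but excluded from f (default 0). They are labelled group 0 in the
#'   truth table.
#' @param coefficients Regime coefficients, as [regime_coefficients()].
#' @param noise_sd Standard deviation of additive Gaussian noise on f
#'   (default 0).
#' @param seed Integer seed; generation is exactly reproducible.
#' @return A list of class `funclust_benchmark` with elements
#'   `abundance` (tibble), `functions` (tibble with column `f`),
#'   `truth` (tibble `feature_id`, `true_group`; 0 = irrelevant),
#'   `regime` (integer vector per sample), and `medians`.
#' @export
generate_benchmark <- function(n_samples = 500,
                               n_species = 12,
                               n_groups = 3,
                               group_assignment = NULL,
                               n_irrelevant = 0,
                               coefficients = regime_coefficients(),
                               noise_sd = 0,
                               seed = 1) {
  stopifnot(n_samples >= 2, n_species >= n_groups, n_groups == 3)
  if (is.null(group_assignment)) {
    group_assignment <- rep(seq_len(n_groups), each = ceiling(n_species / n_groups),
                            length.out = n_species)
  }
  stopifnot(length(group_assignment) == n_species,
            all(sort(unique(group_assignment)) == seq_len(n_groups)))

  n_total <- n_species + n_irrelevant
  full_assignment <- c(group_assignment, rep(0L, n_irrelevant))

  out <- with_seed(seed, function() {
    X <- matrix(runif(n_samples * n_total), nrow = n_samples)
    G <- group_sums(X[, seq_len(n_species), drop = FALSE], group_assignment)
    medians <- apply(G, 2, median)
    regime <- vapply(seq_len(n_samples), function(i) select_regime(G[i, ], medians),
                     integer(1))
    A <- unname(do.call(rbind, coefficients))  # 3 x 3, row = regime
    f <- unname(rowSums(A[regime, , drop = FALSE] * G))
    if (noise_sd > 0) f <- f + rnorm(n_samples, sd = noise_sd)
    list(X = X, f = f, regime = regime, medians = medians)
  })

  feature_ids <- paste0("sp", seq_len(n_total))
  sample_ids <- paste0("sample", seq_len(n_samples))
  X <- out$X
  dimnames(X) <- list(sample_ids, feature_ids)

  structure(list(
    abundance = matrix_to_tibble(X),
    functions = tibble::tibble(sample_id = sample_ids, f = out$f),
    truth = tibble::tibble(feature_id = feature_ids,
                           true_group = as.integer(full_assignment)),
    regime = out$regime,
    medians = out$medians,
    coefficients = coefficients,
    seed = seed
  ), class = "funclust_benchmark")
}

#' @export
print.funclust_benchmark <- function(x, ...) {
  cat(sprintf(
    "<funclust_benchmark> %d samples x %d species (%d irrelevant), %d groups, seed %d\n",
    nrow(x$abundance), ncol(x$abundance) - 1L, sum(x$truth$true_group == 0),
    max(x$truth$true_group), x$seed))
  invisible(x)
}
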