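# Differentiable soft-clustering model.
#
# Parameters:
#   logits  n x K matrix; row-wise softmax gives P, the per-feature assignment
#           probabilities (each row a distribution over the K groups).
#   gate    length-n vector of gate logits l; gamma = sigmoid(l) in (0,1).
#           NULL when gating is disabled.
#   net     fully connected network mapping R^K -> R^m: lists W, b per layer,
#           smooth hidden nonlinearity, linear output.
#
# The forward pass samples an approximately one-hot clustering matrix C via
# the Gumbel-softmax relaxation, aggregates (gated) abundances into group
# abundances g = x_g C, and predicts the function with the network. Gradients
# are computed by hand-written reverse-mode differentiation; the Gumbel noise
# is held fixed within an iteration so the relaxation is differentiable.

#' Initialize a cluster model
#'
#' Assignment logits start at zero (a uniform soft clustering, i.e. no prior
#' preference for any grouping); network weights use scaled Gaussian
#' initialization; gate logits start at `gate_init` so gates begin open.
#'
#' @param n_features Number of community features (columns of the abundance
#'   matrix).
#' @param n_outputs Number of function columns.
#' @param config A [funclust_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `cluster_model`.
#' @export
init_cluster_model <- function(n_features, n_outputs, config, seed = config$seed) {
  K <- config$n_clusters
  widths <- c(K, config$hidden_layers, n_outputs)
  net <- with_seed(seed, function() {
    W <- list(); b <- list()
    for (j in seq_len(length(widths) - 1L)) {
      fan_in <- widths[j]; fan_out <- widths[j + 1L]
      W[[j]] <- matrix(rnorm(fan_in * fan_out, sd = sqrt(2 / (fan_in + fan_out))),
                       nrow = fan_in)
      b[[j]] <- numeric(fan_out)
    }
    list(W = W, b = b)
  })
  gate <- if (config$gate_strength > 0) rep(config$gate_init, n_features) else NULL
  structure(list(
    logits = matrix(0, nrow = n_features, ncol = K),
    gate = gate,
    net = net,
    activation = config$activation
  ), class = "cluster_model")
}

#' Soft assignment probabilities of a model
#'
#' @param model A `cluster_model`.
#' @return The n-by-K row-stochastic matrix P (row-wise softmax of the
#'   assignment logits).
#' @export
assignment_probabilities <- function(model) {
  row_softmax(model$logits)
}

#' Sample an approximately one-hot clustering matrix
#'
#' Draws the Gumbel-softmax relaxation
#' \eqn{C = \mathrm{softmax}\big((\Gamma + \log P)/\tau\big)} row-wise, where
#' \eqn{\Gamma} has i.i.d. standard Gumbel entries. Rows sum to exactly 1; as
#' \eqn{\tau \to 0} each row approaches a one-hot vector whose category is
#' distributed according to the corresponding row of P (the Gumbel-max
#' property).
#'
#' @param model A `cluster_model` (or a row-stochastic matrix P).
#' @param tau Positive temperature.
#' @param gumbel Optional pre-drawn n-by-K Gumbel noise matrix (used to hold
#'   the sample fixed, e.g. for gradient checks); drawn internally otherwise.
#' @param seed Optional seed for the internal draw.
#' @return The n-by-K matrix C.
#' @export
sample_clustering <- function(model, tau, gumbel = NULL, seed = NULL) {
  if (tau <= 0) abort("tau must be positive", class = "funclust_bad_input")
  log_p <- if (inherits(model, "cluster_model")) {
    row_log_softmax(model$logits)
  } else {
    log(model)
  }
  if (is.null(gumbel)) {
    draw <- function() draw_gumbel(nrow(log_p), ncol(log_p))
    gumbel <- if (is.null(seed)) draw() else with_seed(seed, draw)
  }
  row_softmax((gumbel + log_p) / tau)
}

draw_gumbel <- function(n, k) {
  u <- matrix(runif(n * k), nrow = n)
  -log(-log(u))
}

#' Apply the sparsity gate to abundances
#'
#' @param x Abundance vector or N-by-n matrix.
#' @param gate_logits Length-n vector of gate logits; the gate is
#'   `sigmoid(gate_logits)`, applied elementwise per feature.
#' @return Gated abundances of the same shape as `x`.
#' @export
apply_gate <- function(x, gate_logits) {
  gamma <- sigmoid(gate_logits)
  if (is.matrix(x)) {
    if (ncol(x) != length(gamma)) abort("gate length mismatch", class = "funclust_bad_input")
    sweep(x, 2L, gamma, `*`)
  } else {
    if (length(x) != length(gamma)) abort("gate length mismatch", class = "funclust_bad_input")
    x * gamma
  }
}

#' Aggregate abundances into group abundances
#'
#' @param x (Gated) abundance vector or N-by-n matrix.
#' @param C An n-by-K clustering matrix (hard one-hot rows or a Gumbel-softmax
#'   sample).
#' @return `x %*% C`: group abundances in \eqn{R^K} (or N-by-K).
#' @export
group_abundances <- function(x, C) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(C)) abort("dimension mismatch", class = "funclust_bad_input")
  out <- x %*% C
  if (nrow(out) == 1) as.numeric(out) else out
}

activation_fun <- function(name) {
  switch(name,
    tanh = list(f = tanh, df = function(z, a) 1 - a^2),
    softplus = list(f = function(z) log1p(exp(-abs(z))) + pmax(z, 0),
                    df = function(z, a) sigmoid(z)),
    abort("unknown activation", class = "funclust_bad_input"))
}

# Forward pass through the fully connected network; keeps intermediates for
# backprop when `keep = TRUE`.
net_forward <- function(net, G, activation, keep = FALSE) {
  act <- activation_fun(activation)
  L <- length(net$W)
  A <- G
  As <- vector("list", L + 1L); Zs <- vector("list", L)
  As[[1]] <- A
  for (j in seq_len(L)) {
    Z <- A %*% net$W[[j]]
    Z <- Z + rep(net$b[[j]], each = nrow(Z))
    A <- if (j < L) act$f(Z) else Z
    if (keep) { Zs[[j]] <- Z; As[[j + 1L]] <- A }
  }
  if (keep) list(out = A, As = As, Zs = Zs) else A
}

#' Predict function values from group abundances
#'
#' Runs the structure-function network forward: hidden layers with a smooth
#' nonlinearity, linear output layer. Deterministic given the parameters.
#'
#' @param g Group-abundance vector in \eqn{R^K} or an N-by-K matrix.
#' @param model A `cluster_model` holding the network parameters.
#' @return Predicted function values (vector for one sample, matrix otherwise).
#' @export
predict_function <- function(g, model) {
  single <- !is.matrix(g)
  if (single) g <- matrix(g, nrow = 1)
  out <- net_forward(model$net, g, model$activation)
  if (single && ncol(out) == 1) as.numeric(out)
  else if (single) as.numeric(out)
  else out
}

#' Model loss on a batch
#'
#' Mean squared error \eqn{\frac{1}{B}\sum_i \|f_i - \hat f_i\|^2} over the
#' batch, plus the gate sparsity penalty \eqn{\beta \|\gamma\|_1} when gating
#' is enabled. The clustering matrix is either supplied (`C`) or sampled at
#' temperature `tau` from the model.
#'
#' @param model A `cluster_model`.
#' @param X N-by-n abundance matrix (numeric).
#' @param F_mat N-by-m function matrix (numeric).
#' @param tau Temperature for the Gumbel-softmax sample (ignored when `C`
#'   given).
#' @param beta Gate penalty strength.
#' @param C Optional fixed clustering matrix.
#' @param gumbel Optional fixed Gumbel noise (see [sample_clustering()]).
#' @return A scalar loss.
#' @export
model_loss <- function(model, X, F_mat, tau = 0.1, beta = 0, C = NULL,
                       gumbel = NULL) {
  if (nrow(X) == 0) abort("empty batch", class = "funclust_bad_input")
  if (is.null(C)) C <- sample_clustering(model, tau, gumbel = gumbel)
  Xg <- if (!is.null(model$gate)) apply_gate(X, model$gate) else X
  G <- Xg %*% C
  pred <- net_forward(model$net, G, model$activation)
  loss <- sum((F_mat - pred)^2) / nrow(X)
  if (!is.null(model$gate) && beta > 0) {
    loss <- loss + beta * sum(sigmoid(model$gate))
  }
  loss
}

# Loss plus gradients with respect to every model parameter, for a fixed
# Gumbel noise draw. Reverse-mode differentiation written out by hand.
loss_and_grad <- function(model, X, F_mat, tau, beta, gumbel) {
  n <- ncol(X); K <- ncol(model$logits); B <- nrow(X)
  act <- activation_fun(model$activation)

  log_p <- row_log_softmax(model$logits)
  Y <- (gumbel + log_p) / tau
  C <- row_softmax(Y)

  gated <- !is.null(model$gate)
  if (gated) {
    gamma <- sigmoid(model$gate)
    Xg <- sweep(X, 2L, gamma, `*`)
  } else {
    Xg <- X
  }
  G <- Xg %*% C

  fw <- net_forward(model$net, G, model$activation, keep = TRUE)
  R <- fw$out - F_mat
  loss <- sum(R^2) / B
  if (gated && beta > 0) loss <- loss + beta * sum(gamma)

  # Backprop through the network.
  L <- length(model$net$W)
  dW <- vector("list", L); db <- vector("list", L)
  dZ <- 2 * R / B
  for (j in rev(seq_len(L))) {
    dW[[j]] <- crossprod(fw$As[[j]], dZ)
    db[[j]] <- colSums(dZ)
    dA <- dZ %*% t(model$net$W[[j]])
    if (j > 1L) {
      dZ <- dA * act$df(fw$Zs[[j - 1L]], fw$As[[j]])
    } else {
      dG <- dA
    }
  }
  # Into the clustering matrix and the gated abundances.
  dC <- crossprod(Xg, dG)                # n x K
  dXg <- dG %*% t(C)                     # B x n

  # Gumbel-softmax backprop: C = softmax(Y) rows, Y = (gumbel + logP)/tau,
  # logP = log-softmax(logits).
  dY <- (dC - rowSums(dC * C)) * C
  dlogP <- dY / tau
  P <- exp(log_p)
  dlogits <- dlogP - P * rowSums(dlogP)

  grads <- list(logits = dlogits, net = list(W = dW, b = db))
  if (gated) {
    dgamma <- colSums(dXg * X)
    if (beta > 0) dgamma <- dgamma + beta
    grads$gate <- dgamma * gamma * (1 - gamma)
  }
  list(loss = loss, grads = grads, C = C)
}

#' Hard group assignment of a model
#'
#' @param model A `cluster_model`.
#' @return Integer vector: per-feature argmax of the soft assignment
#'   probabilities (ties broken toward the lower group index).
#' @export
hard_assignment <- function(model) {
  max.col(assignment_probabilities(model), ties.method = "first")
}

# One-hot matrix from an integer assignment.
one_hot <- function(assignment, K) {
  C <- matrix(0, nrow = length(assignment), ncol = K)
  C[cbind(seq_along(assignment), assignment)] <- 1
  C
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %d features -> %d groups, net %s, %s\n",
              nrow(x$logits), ncol(x$logits),
              paste(vapply(x$net$W, ncol, integer(1)), collapse = "-"),
              if (is.null(x$gate)) "no gate" else "gated"))
  invisible(x)
}
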