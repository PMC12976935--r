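# Shared fixture builders. Everything is generated in code; no stored data.

# A hand-built trained member with prescribed soft assignments, gate logits
# and held-out R2, for consensus-machinery tests that need full control.
fake_member <- function(logits, r2, gate = NULL, n_outputs = 1) {
  K <- ncol(logits)
  model <- structure(list(
    logits = logits,
    gate = gate,
    net = list(W = list(matrix(1, nrow = K, ncol = n_outputs)),
               b = list(numeric(n_outputs))),
    activation = "tanh"
  ), class = "cluster_model")
  structure(list(model = model, test_r2 = r2, test_loss = 1 - r2,
                 train_loss = NA_real_, iterations_run = 0L, seed = 0L,
                 split_seed = 0L),
            class = "trained_member")
}

# Logits that put probability ~1 on the given hard labels.
logits_for_labels <- function(labels, K, strength = 20) {
  L <- matrix(0, length(labels), K)
  L[cbind(seq_along(labels), labels)] <- strength
  L
}

# Minimal ensemble wrapper around fake members.
fake_ensemble <- function(members, X, F_mat = NULL, gate_strength = 0) {
  cfg <- funclust_config(n_clusters = ncol(members[[1]]$model$logits),
                         n_ensemble = length(members),
                         gate_strength = gate_strength)
  structure(list(members = members, config = cfg, X = X,
                 F_mat = F_mat %||% matrix(0, nrow(X), 1),
                 feature_ids = colnames(X),
                 function_names = "f"),
            class = "funclust_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent Jaccard oracle: nested loops and explicit set operations,
# deliberately naive.
jaccard_oracle <- function(truth_labels, pred_labels, ids) {
  t_lv <- sort(unique(truth_labels))
  p_lv <- sort(unique(pred_labels))
  per <- numeric(length(t_lv))
  for (a in seq_along(t_lv)) {
    best <- 0
    set_t <- ids[truth_labels == t_lv[a]]
    for (b in seq_along(p_lv)) {
      set_p <- ids[pred_labels == p_lv[b]]
      inter <- 0
      for (id in set_t) if (id %in% set_p) inter <- inter + 1
      uni <- length(unique(c(set_t, set_p)))
      if (inter / uni > best) best <- inter / uni
    }
    per[a] <- best
  }
  mean(per)
}
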