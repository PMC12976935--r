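# Internal helpers shared across modules.

# Convert a samples-as-rows tibble (first column = sample_id) to a numeric
# matrix with sample_id as rownames. Accepts a matrix unchanged.
as_sample_matrix <- function(x, what = "table") {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
    storage.mode(x) <- "double"
    return(x)
  }
  if (!is.data.frame(x)) {
    abort(sprintf("%s must be a data frame or matrix", what),
          class = "funclust_bad_input")
  }
  df <- as.data.frame(x)
  if (ncol(df) < 2) {
    abort(sprintf("%s needs a sample_id column plus at least one value column", what),
          class = "funclust_bad_input")
  }
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

matrix_to_tibble <- function(m, id_col = "sample_id") {
  df <- data.frame(rownames(m), as.data.frame(m), check.names = FALSE)
  names(df)[1] <- id_col
  tibble::as_tibble(df)
}

check_no_duplicates <- function(ids, what) {
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate %s identifiers", what), class = "funclust_duplicate_ids")
  }
  invisible(ids)
}

row_max <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
}

# Row-wise softmax of a matrix, numerically stable.
row_softmax <- function(m) {
  m <- m - row_max(m)
  e <- exp(m)
  e / rowSums(e)
}

# Row-wise log-softmax.
row_log_softmax <- function(m) {
  m <- m - row_max(m)
  m - log(rowSums(exp(m)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Derive a stream of distinct child seeds from one master seed, all < 2^31.
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate fn() under a local, seeded RNG without disturbing the caller's stream.
with_seed <- function(seed, fn) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  fn()
}
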