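#' Read an abundance table
#'
#' Reads a samples-by-features abundance table from delimited text. The first
#' column holds sample identifiers and the header row holds feature
#' identifiers (species, ASVs, genera, or gene modules). The delimiter is
#' auto-detected from the file extension: `.csv` is comma-separated,
#' everything else is read as tab-separated.
#'
#' @param path Path to a TSV/CSV file.
#' @return A tibble with a `sample_id` column followed by one numeric column
#'   per feature.
#' @details Entries must be non-negative and finite; duplicate sample or
#'   feature identifiers are rejected. These checks guard the downstream
#'   aggregation step, which sums abundances within groups.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sample_id\tspA\tspB", "s1\t0.2\t0.8", "s2\t0.6\t0.4"), tf)
#' read_abundance_table(tf)
read_abundance_table <- function(path) {
  tab <- read_sample_table(path, what = "abundance")
  vals <- as_sample_matrix(tab, "abundance table")
  if (any(!is.finite(vals))) {
    abort("non-finite abundance entry", class = "funclust_nonfinite_abundance")
  }
  if (any(vals < 0)) {
    abort("negative abundance", class = "funclust_negative_abundance")
  }
  tab
}

#' Read a function table
#'
#' Reads a samples-by-functions table of community-level functional
#' measurements (e.g. metabolite concentrations, or a nitrate time series with
#' one column per time point). Missing values (`NA`, `NaN`, or empty cells)
#' are allowed here; samples carrying them are dropped later by
#' [pair_samples()].
#'
#' @inheritParams read_abundance_table
#' @return A tibble with a `sample_id` column followed by one numeric column
#'   per functional measurement.
#' @export
read_function_table <- function(path) {
  read_sample_table(path, what = "function")
}

read_sample_table <- function(path, what) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "funclust_missing_file")
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           na = c("", "NA", "NaN"), progress = FALSE)
  if (ncol(tab) < 2 || nrow(tab) < 1) {
    abort(sprintf("%s table must have a sample_id column and data", what),
          class = "funclust_bad_input")
  }
  names(tab)[1] <- "sample_id"
  tab$sample_id <- as.character(tab$sample_id)
  check_no_duplicates(tab$sample_id, "sample")
  check_no_duplicates(names(tab)[-1], "feature")
  for (j in seq(2L, ncol(tab))) {
    if (!is.numeric(tab[[j]])) {
      abort(sprintf("non-numeric entries in column '%s'", names(tab)[j]),
            class = "funclust_bad_input")
    }
  }
  tab
}

#' Write a samples-by-variables table
#'
#' Companion writer to [read_abundance_table()] / [read_function_table()];
#' the delimiter follows the file extension so a written table reads back
#' identically.
#'
#' @param tab A tibble whose first column is `sample_id`.
#' @param path Output path (`.csv` for comma-separated, otherwise TSV).
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(tab, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(tab, path, delim = delim)
  invisible(path)
}

#' Pair abundance and function tables by sample
#'
#' Restricts both tables to their shared samples, in a common order, and drops
#' samples whose function row contains a missing value (mirroring the standard
#' treatment of incomplete environmental measurements in survey datasets).
#'
#' @param abundance Abundance tibble (see [read_abundance_table()]).
#' @param functions Function tibble (see [read_function_table()]).
#' @return A list with elements `abundance` and `functions`, row-aligned.
#' @export
pair_samples <- function(abundance, functions) {
  a_ids <- as.character(abundance[[1]])
  f_ids <- as.character(functions[[1]])
  keep_f <- complete.cases(functions)
  shared <- intersect(a_ids, f_ids[keep_f])
  if (length(shared) < 2) {
    abort("fewer than 2 shared samples with complete function rows",
          class = "funclust_empty_intersection")
  }
  list(
    abundance = abundance[match(shared, a_ids), , drop = FALSE],
    functions = functions[match(shared, f_ids), , drop = FALSE]
  )
}

#' Write a consensus grouping to a TSV file
#'
#' @param grouping A grouping tibble with columns `feature_id`, `group`,
#'   `active`, `agreement` (as returned by [consensus_grouping()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grouping <- function(grouping, path) {
  stopifnot(all(c("feature_id", "group", "active", "agreement") %in% names(grouping)))
  readr::write_tsv(grouping[, c("feature_id", "group", "active", "agreement")], path)
  invisible(path)
}

#' Read a consensus grouping written by [write_grouping()]
#'
#' @param path Path to the grouping TSV.
#' @return A grouping tibble.
#' @export
read_grouping <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "funclust_missing_file")
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tab$feature_id <- as.character(tab$feature_id)
  tab$group <- as.integer(tab$group)
  tab$active <- as.logical(tab$active)
  tibble::as_tibble(tab)
}
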