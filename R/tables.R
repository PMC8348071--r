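#' Paired per-patient scores for two sequences
#'
#' Long-format container for the paired ordinal design in which every
#' patient is scored once under the reference segmented sequence and once
#' under the real-time sequence.
#'
#' @param score_ref,score_rt Ordinal scores per patient.
#' @param patient_id Optional identifiers (default 1..n).
#' @return A tibble of class `paired_scores`.
#' @export
paired_scores <- function(score_ref, score_rt, patient_id = seq_along(score_ref)) {
  if (length(score_ref) != length(score_rt) || length(score_ref) < 1) {
    stop_cscine("score_ref and score_rt must be matched and non-empty",
                "cscine_invalid_spec")
  }
  out <- tibble(patient_id = patient_id, score_ref = score_ref, score_rt = score_rt)
  class(out) <- c("paired_scores", class(out))
  out
}

#' Read a paired cross-tabulation fixture
#'
#' Fixture format (JSON): `labels` (ordinal categories, worst-to-best or
#' best-to-worst), `values` (numeric ordinal value per label), `counts`
#' (matrix, reference sequence in rows, real-time in columns),
#' `higher_is_better` (direction of the scale) and optionally `printed`
#' (the values quoted alongside the published table, for comparison).
#'
#' @param path Path to a cross-tab JSON file.
#' @return A list of class `crosstab` with a validated counts matrix.
#' @export
read_crosstab <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  counts <- as.matrix(x$counts)
  if (nrow(counts) != length(x$labels) || ncol(counts) != length(x$labels)) {
    stop_cscine("counts must be square on the label set", "cscine_fixture_error")
  }
  if (any(counts < 0) || sum(counts) < 1) {
    stop_cscine("counts must be non-negative with a positive total", "cscine_fixture_error")
  }
  dimnames(counts) <- list(ref = x$labels, rt = x$labels)
  x$counts <- counts
  x$values <- as.numeric(x$values)
  class(x) <- "crosstab"
  x
}

#' @describeIn read_crosstab Expand a cross-tabulation into per-patient
#'   paired scores (on the fixture's ordinal values).
#' @param ct A `crosstab`.
#' @export
crosstab_to_pairs <- function(ct) {
  idx <- which(ct$counts > 0, arr.ind = TRUE)
  rows <- rep(idx[, 1], ct$counts[idx])
  cols <- rep(idx[, 2], ct$counts[idx])
  ord <- order(rows, cols)
  paired_scores(ct$values[rows[ord]], ct$values[cols[ord]])
}

#' @describeIn read_crosstab Collapse paired scores back to a
#'   cross-tabulation on a stated ordinal value set.
#' @param pairs A [paired_scores()] tibble.
#' @param values Ordinal values defining the categories.
#' @param labels Optional labels (default the values).
#' @param higher_is_better Direction of the scale.
#' @export
pairs_to_crosstab <- function(pairs, values, labels = as.character(values),
                              higher_is_better = TRUE) {
  f <- function(s) factor(s, levels = values)
  counts <- unclass(table(ref = f(pairs$score_ref), rt = f(pairs$score_rt)))
  structure(
    list(labels = labels, values = as.numeric(values),
         counts = matrix(counts, length(values), length(values),
                         dimnames = list(ref = labels, rt = labels)),
         higher_is_better = higher_is_better),
    class = "crosstab"
  )
}

#' Fraction of patients scoring equal or better on the real-time sequence
#'
#' @param ct A `crosstab` (or [paired_scores()] with a `higher_is_better`
#'   attribute supplied via `higher_is_better`).
#' @param higher_is_better Overrides the fixture's direction if given.
#' @return A list with `n`, `n_equal_or_better`, `percent`.
#' @export
equal_or_better <- function(ct, higher_is_better = NULL) {
  if (inherits(ct, "crosstab")) {
    pairs <- crosstab_to_pairs(ct)
    if (is.null(higher_is_better)) higher_is_better <- isTRUE(ct$higher_is_better)
  } else {
    pairs <- ct
    if (is.null(higher_is_better)) higher_is_better <- TRUE
  }
  ok <- if (higher_is_better) pairs$score_rt >= pairs$score_ref
        else pairs$score_rt <= pairs$score_ref
  list(n = nrow(pairs), n_equal_or_better = sum(ok),
       percent = 100 * mean(ok))
}

#' Reproduce the summary statistics of a published paired cross-tabulation
#'
#' From a cross-tab fixture, recomputes the per-sequence median (range),
#' the proportion of patients for whom the real-time sequence scored equal
#' or better, and the two-sided Wilcoxon signed-rank p-value, and sets them
#' beside any values quoted with the printed table. Pure function of the
#' fixture: re-running is bit-identical.
#'
#' @param fixture A `crosstab` or a path to a cross-tab JSON fixture.
#' @return A list of class `crosstab_report`: `summary` (one-row tibble of
#'   the recomputed quantities), `printed` (as shipped, possibly `NULL`)
#'   and `wilcoxon` (the full `stat_result`).
#' @export
reproduce_printed_tables <- function(fixture) {
  ct <- if (inherits(fixture, "crosstab")) fixture else read_crosstab(fixture)
  pairs <- crosstab_to_pairs(ct)
  eob <- equal_or_better(ct)
  wx <- wilcoxon_signed_rank(pairs)
  mr_ref <- median_range(pairs$score_ref)
  mr_rt <- median_range(pairs$score_rt)
  summary <- tibble(
    n = eob$n,
    median_ref = mr_ref$median, min_ref = mr_ref$min, max_ref = mr_ref$max,
    median_rt = mr_rt$median, min_rt = mr_rt$min, max_rt = mr_rt$max,
    n_equal_or_better = eob$n_equal_or_better,
    pct_equal_or_better = eob$percent,
    wilcoxon_p = wx$p_value
  )
  structure(list(summary = summary, printed = ct$printed, wilcoxon = wx),
            class = "crosstab_report")
}

#' @export
print.crosstab_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<crosstab_report> n = %d | median ref %.1f (%g-%g), rt %.1f (%g-%g) | rt equal-or-better %d/%d (%.1f%%) | Wilcoxon p = %.3g\n",
    s$n, s$median_ref, s$min_ref, s$max_ref, s$median_rt, s$min_rt, s$max_rt,
    s$n_equal_or_better, s$n, s$pct_equal_or_better, s$wilcoxon_p))
  invisible(x)
}

#' Read/write long paired-score CSV
#'
#' Columns: `patient_id`, `score_ref`, `score_rt`.
#'
#' @param pairs A [paired_scores()] tibble.
#' @param path File path.
#' @export
write_paired_csv <- function(pairs, path) {
  readr::write_csv(pairs, path)
  invisible(path)
}

#' @rdname write_paired_csv
#' @export
read_paired_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("patient_id", "score_ref", "score_rt") %in% names(x))) {
    stop_cscine("expected columns patient_id, score_ref, score_rt",
                "cscine_invalid_spec")
  }
  paired_scores(x$score_ref, x$score_rt, x$patient_id)
}

#' Path to a shipped cross-tabulation fixture
#'
#' @param name Fixture file name, e.g. `"table_quality_subjective.json"`.
#' @export
cscine_fixture <- function(name) {
  p <- system.file("extdata", name, package = "cscine", mustWork = FALSE)
  if (!nzchar(p)) stop_cscine(paste("fixture not found:", name), "cscine_fixture_error")
  p
}
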