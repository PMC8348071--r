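ARTIFACT_ITEMS <- c("wrap_around", "respiratory_ghost", "cardiac_ghost",
                    "blurring_ara", "metallic", "shimming")

#' Per-slice artifact annotations
#'
#' Builds the tidy annotation table consumed by [euro_cmr_score()] and
#' [ara_rate()]: one row per short-axis slice with six logical artifact
#' flags, plus stack-level left-ventricular coverage and coil status
#' carried as constant columns.
#'
#' @param n_slices Number of slices (all flags default to `FALSE`).
#' @param coverage LV coverage of the stack: `"full"`, `"no_apex"`,
#'   `"base_or_slice_missing"` or `"both"` (apex *and* base missing).
#' @param coil_active Was the anterior coil element active?
#' @param ... Named logical vectors (length 1 or `n_slices`) overriding any
#'   of `wrap_around`, `respiratory_ghost`, `cardiac_ghost`,
#'   `blurring_ara`, `metallic`, `shimming`.
#' @return A tibble of class `slice_annotations`.
#' @examples
#' ann <- slice_annotations(8, blurring_ara = c(rep(TRUE, 6), rep(FALSE, 2)))
#' ara_rate(ann) # 75
#' @export
slice_annotations <- function(n_slices, coverage = "full", coil_active = TRUE, ...) {
  coverage <- match.arg(coverage, c("full", "no_apex", "base_or_slice_missing", "both"))
  if (n_slices < 1) stop_cscine("need at least one slice", "cscine_insufficient_data")
  flags <- stats::setNames(rep(list(FALSE), length(ARTIFACT_ITEMS)), ARTIFACT_ITEMS)
  dots <- list(...)
  bad <- setdiff(names(dots), ARTIFACT_ITEMS)
  if (length(bad)) stop_cscine(paste("unknown artifact item:", bad[1]), "cscine_invalid_spec")
  flags[names(dots)] <- dots
  out <- tibble(slice_index = seq_len(n_slices))
  for (nm in ARTIFACT_ITEMS) out[[nm]] <- rep_len(as.logical(flags[[nm]]), n_slices)
  out$coverage <- coverage
  out$coil_active <- coil_active
  class(out) <- c("slice_annotations", class(out))
  out
}

#' Modified EuroCMR artifact score
#'
#' Item-wise objective artifact score adapted from the European CMR
#' registry "LV-Function cine SSFP" rubric, restricted to its first eight
#' items so the maximum is 10 (higher = worse):
#' \itemize{
#'   \item Item 1, LV coverage: full = 0, no apex = 2, base or a slice
#'     missing = 3, both = 5.
#'   \item Items 2-7 (wrap-around, respiratory ghost, cardiac ghost,
#'     blurring/ARA, metallic, shimming): each scores 0/1/2/3 for
#'     0/1/2/>= 3 affected slices; the block contributes `min(sum, 3)` to
#'     the modified total (set `cap_items_2_7 = FALSE` for an uncapped
#'     per-item sum, which can exceed the nominal maximum).
#'   \item Item 8, coil activation: inactive = 2.
#' }
#'
#' @param annotations A [slice_annotations()] tibble (or any data frame with
#'   the same columns).
#' @param cap_items_2_7 Cap the items-2-7 block at 3 (default), the reading
#'   under which the itemised maxima sum to the stated modified maximum of
#'   10 (5 + 3 + 2).
#' @return A list of class `euro_cmr_score` with `item_scores` (named
#'   vector, items 1-8) and `modified_total`.
#' @export
euro_cmr_score <- function(annotations, cap_items_2_7 = TRUE) {
  if (!is.data.frame(annotations) || nrow(annotations) < 1) {
    stop_cscine("annotations must contain at least one slice", "cscine_insufficient_data")
  }
  coverage <- unique(annotations$coverage)
  coil <- unique(annotations$coil_active)
  if (length(coverage) != 1 || length(coil) != 1) {
    stop_cscine("coverage and coil_active must be constant within a stack",
                "cscine_invalid_spec")
  }
  item1 <- c(full = 0, no_apex = 2, base_or_slice_missing = 3, both = 5)[[coverage]]
  per_item <- vapply(ARTIFACT_ITEMS, function(nm) {
    n_aff <- sum(annotations[[nm]])
    min(n_aff, 3L)
  }, integer(1))
  block <- if (cap_items_2_7) min(sum(per_item), 3L) else sum(per_item)
  item8 <- if (isTRUE(coil)) 0L else 2L
  items <- c(coverage = item1, per_item, signal_loss = item8)
  structure(
    list(item_scores = items, modified_total = item1 + block + item8,
         capped = cap_items_2_7),
    class = "euro_cmr_score"
  )
}

#' @export
print.euro_cmr_score <- function(x, ...) {
  cat(sprintf("<euro_cmr_score> modified total: %d / 10\n", x$modified_total))
  invisible(x)
}

#' @export
tidy.euro_cmr_score <- function(x, ...) {
  tibble(item = names(x$item_scores),
         score = as.integer(x$item_scores)) |>
    dplyr::bind_rows(tibble(item = "modified_total",
                            score = as.integer(x$modified_total)))
}

#' Arrhythmia-related-artifact rate of a slice stack
#'
#' Percentage of slices in a stack flagged with blurring/ARA.
#'
#' @inheritParams euro_cmr_score
#' @return Percent of affected slices.
#' @export
ara_rate <- function(annotations) {
  if (!is.data.frame(annotations) || nrow(annotations) < 1) {
    stop_cscine("annotations must contain at least one slice", "cscine_insufficient_data")
  }
  100 * mean(annotations$blurring_ara)
}

#' Automatic blurring/ARA flag from edge sharpness
#'
#' Automates the reader's blur judgement for simulated data: a
#' reconstruction is flagged as ARA-impaired when its end-systolic
#' mid-septal edge sharpness falls below `epsilon_ratio_threshold` times
#' the matching ground-truth sharpness.
#'
#' @param recon,truth [cine_stack()]s on the same phase grid.
#' @param spec The generating [phantom_spec()] (locates the septal line).
#' @param epsilon_ratio_threshold Flag when
#'   `epsilon(recon) < threshold * epsilon(truth)` (default 0.75).
#' @return A one-row tibble: `epsilon_recon`, `epsilon_truth`, `ratio`,
#'   `blurring_ara`.
#' @export
auto_flag_ara <- function(recon, truth, spec, epsilon_ratio_threshold = 0.75) {
  k <- which.min(abs(truth$phases - spec$systole_fraction))
  ph <- truth$phases[k]
  e_truth <- septal_sharpness(truth$frames[, , k], spec, ph)$epsilon
  e_recon <- septal_sharpness(recon$frames[, , k], spec, ph)$epsilon
  tibble(
    epsilon_recon = e_recon,
    epsilon_truth = e_truth,
    ratio = e_recon / e_truth,
    blurring_ara = e_recon < epsilon_ratio_threshold * e_truth
  )
}

#' Read/write slice annotations as CSV
#'
#' The schema is one row per slice: `patient_id`, `slice_index`, `sequence`
#' (`"ref"` or `"rt"`), `coverage`, the six artifact flags, `coil_active`.
#'
#' @param annotations A data frame in the annotation schema.
#' @param path File path.
#' @export
write_annotations_csv <- function(annotations, path) {
  readr::write_csv(annotations, path)
  invisible(path)
}

#' @rdname write_annotations_csv
#' @export
read_annotations_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("slice_index", ARTIFACT_ITEMS, "coverage", "coil_active")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop_cscine(paste("annotation CSV lacks columns:",
                      paste(missing_cols, collapse = ", ")), "cscine_invalid_spec")
  }
  class(x) <- c("slice_annotations", class(x))
  x
}
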