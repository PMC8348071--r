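#' Plot a cine stack as a faceted frame mosaic
#'
#' @param object A [cine_stack()].
#' @param frames Which frames to show (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cine_stack <- function(object, frames = seq_len(dim(object$frames)[3]), ...) {
  df <- purrr::map_dfr(frames, function(k) {
    m <- object$frames[, , k]
    tibble(
      frame = sprintf("phase %.2f", object$phases[k]),
      x = rep(seq_len(ncol(m)), each = nrow(m)),
      y = rep(seq_len(nrow(m)), ncol(m)),
      intensity = as.vector(m)
    )
  })
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$intensity)) +
    geom_raster() +
    scale_y_reverse() +
    scale_fill_gradient(low = "black", high = "white") +
    facet_wrap(~frame) +
    coord_fixed() +
    labs(title = paste("cine stack:", object$provenance), x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot an edge profile with its 20%/80% crossings
#'
#' @param object A `sharpness_result` from [edge_sharpness()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sharpness_result <- function(object, ...) {
  prof <- object$profile
  lv <- object$i_min + c(0.2, 0.8) * (object$i_max - object$i_min)
  ggplot(prof, aes(x = .data$position, y = .data$intensity)) +
    geom_line(colour = "steelblue") +
    geom_hline(yintercept = c(object$i_min, object$i_max), linetype = "dotted") +
    geom_vline(xintercept = c(object$x20, object$x80), linetype = "dashed",
               colour = "firebrick") +
    annotate("point", x = c(object$x20, object$x80), y = lv,
             colour = "firebrick", shape = 8, size = 3) +
    labs(title = sprintf("edge spread: d = %.2f px, epsilon = %.4f px^-1",
                         object$d, object$epsilon),
         x = "position along profile (px)", y = "intensity") +
    theme_minimal()
}

#' Paired edge-sharpness plot for a cohort report
#'
#' One segment per patient joining the segmented-arm and real-time-arm
#' end-systolic edge sharpness.
#'
#' @param report A `study_report` from [run_cohort()].
#' @param phase `"end_systole"` (default) or `"end_diastole"`.
#' @return A ggplot object.
#' @export
plot_epsilon_pairs <- function(report, phase = c("end_systole", "end_diastole")) {
  phase <- match.arg(phase)
  cols <- if (phase == "end_systole") c("eps_es_ref", "eps_es_rt") else c("eps_ed_ref", "eps_ed_rt")
  df <- report$patients |>
    dplyr::select(patient_id = "patient_id",
                  segmented = dplyr::all_of(cols[1]),
                  realtime = dplyr::all_of(cols[2])) |>
    tidyr::pivot_longer(c("segmented", "realtime"),
                        names_to = "arm", values_to = "epsilon")
  ggplot(df, aes(x = .data$arm, y = .data$epsilon, group = .data$patient_id)) +
    geom_line(alpha = 0.4) +
    geom_point(aes(colour = .data$arm), size = 2) +
    labs(title = sprintf("edge sharpness at %s", gsub("_", "-", phase)),
         x = NULL, y = "epsilon (px^-1)") +
    theme_minimal() +
    theme(legend.position = "none")
}
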