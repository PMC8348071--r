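#' Write a cine stack to NIfTI (frames on the third axis)
#'
#' A JSON sidecar (`<path>.json`) stores the cardiac phase per frame, the
#' provenance tag and the pixel spacing, which NIfTI itself cannot carry.
#'
#' @param stack A [cine_stack()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_cine_nifti <- function(stack, path) {
  RNifti::writeNifti(RNifti::asNifti(stack$frames), path)
  jsonlite::write_json(
    list(phases = stack$phases, provenance = stack$provenance,
         pixel_spacing = stack$pixel_spacing),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cine_nifti
#' @export
read_cine_nifti <- function(path) {
  frames <- array(as.numeric(RNifti::readNifti(path)),
                  dim = dim(RNifti::readNifti(path)))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cine_stack(frames, side$phases, provenance = side$provenance,
             pixel_spacing = side$pixel_spacing)
}

#' Write cine frames as PNG files for inspection
#'
#' Intensities are min-max scaled over the whole stack so frames remain
#' comparable.
#'
#' @param stack A [cine_stack()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return The written paths, invisibly.
#' @export
write_cine_png <- function(stack, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rng <- range(stack$frames)
  paths <- vapply(seq_len(n_frames(stack)), function(k) {
    img <- (stack$frames[, , k] - rng[1]) / max(rng[2] - rng[1], 1e-12)
    p <- file.path(dir, sprintf("%s_%03d.png", prefix, k))
    png::writePNG(img, p)
    p
  }, character(1))
  invisible(paths)
}

#' Serialise a segmented k-space plan to JSON
#'
#' @param plan A plan from [plan_segmented()].
#' @param path Output path.
#' @export
write_plan_json <- function(plan, path) {
  jsonlite::write_json(
    list(tr_eff = attr(plan, "tr_eff"),
         n_heartbeats = attr(plan, "n_heartbeats"),
         n_lines = attr(plan, "n_lines"),
         entries = lapply(seq_len(nrow(plan)), function(j)
           list(frame = plan$frame[j], heartbeat = plan$heartbeat[j],
                true_phase = plan$true_phase[j], lines = plan$lines[[j]]))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
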