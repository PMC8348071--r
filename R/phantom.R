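#' Dynamic left-ventricular phantom specification
#'
#' Describes a 2D short-axis-like phantom: a bright circular blood pool
#' inside a darker myocardial annulus on a near-black background, contracting
#' and relaxing over the cardiac cycle. Contrast mimics bSSFP cine (blood >
#' myocardium > background). The endocardial radius follows a
#' cosine-smoothed contraction from end-diastole (phase 0) to end-systole
#' (phase `systole_fraction`) and back; the epicardial radius follows under
#' conservation of the annulus (myocardial) area, so the wall thickens in
#' systole as real myocardium does.
#'
#' @param grid Image size in pixels (square). Default 168, the short axis of
#'   a typical real-time acquisition matrix.
#' @param endo_radius_d,epi_radius_d End-diastolic endocardial / epicardial
#'   radii in pixels. Defaults scale with `grid`.
#' @param contraction_fraction Fractional endocardial radius reduction at
#'   end-systole (0 to < 1). Default 0.35.
#' @param systole_fraction Fraction of the cycle spent contracting (0 to 1,
#'   exclusive). Default 0.35.
#' @param intensities Named list/vector with `blood`, `myocardium`,
#'   `background` signal levels (arbitrary units, blood > myocardium >=
#'   background >= 0).
#' @param edge_softness Gaussian blur sigma in pixels applied after
#'   rasterisation, so ground-truth edges have a finite, measurable
#'   sharpness. Default 0.8.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = 168,
                         endo_radius_d = 0.18 * grid,
                         epi_radius_d = 0.27 * grid,
                         contraction_fraction = 0.35,
                         systole_fraction = 0.35,
                         intensities = c(blood = 1, myocardium = 0.35, background = 0.05),
                         edge_softness = 0.8) {
  intensities <- unlist(intensities)
  ok <- grid >= 16 &&
    endo_radius_d > 0 && endo_radius_d < epi_radius_d && epi_radius_d < grid / 2 &&
    contraction_fraction >= 0 && contraction_fraction < 1 &&
    systole_fraction > 0 && systole_fraction < 1 &&
    all(c("blood", "myocardium", "background") %in% names(intensities)) &&
    intensities["blood"] > intensities["myocardium"] &&
    intensities["myocardium"] >= intensities["background"] &&
    intensities["background"] >= 0 &&
    edge_softness >= 0
  if (!isTRUE(ok)) stop_cscine("invalid phantom specification", "cscine_invalid_spec")
  structure(
    list(grid = as.integer(grid), endo_radius_d = endo_radius_d,
         epi_radius_d = epi_radius_d, contraction_fraction = contraction_fraction,
         systole_fraction = systole_fraction, intensities = intensities,
         edge_softness = edge_softness),
    class = "phantom_spec"
  )
}

# Cosine-smoothed contraction envelope: 0 at phase 0, 1 at systole_fraction,
# back to 0 as phase -> 1. Smooth in phase so the motion itself introduces
# no velocity discontinuity (k-space ringing must come from arrhythmia, not
# from the motion model).
contraction_envelope <- function(phase, systole_fraction) {
  ifelse(phase <= systole_fraction,
         (1 - cos(pi * phase / systole_fraction)) / 2,
         (1 + cos(pi * (phase - systole_fraction) / (1 - systole_fraction))) / 2)
}

#' Endocardial/epicardial radii at a cardiac phase
#'
#' @param spec A [phantom_spec()].
#' @param phase Cardiac phase in `[0, 1)`.
#' @return Named numeric vector `c(endo = , epi = )` in pixels.
#' @export
phantom_radii <- function(spec, phase) {
  s <- contraction_envelope(phase, spec$systole_fraction)
  endo <- spec$endo_radius_d * (1 - spec$contraction_fraction * s)
  # annulus area conserved: epi^2 - endo^2 constant over the cycle
  epi <- sqrt(endo^2 + spec$epi_radius_d^2 - spec$endo_radius_d^2)
  c(endo = endo, epi = epi)
}

#' Render the phantom at one cardiac phase
#'
#' Rasterises the concentric-annulus heart at the radius dictated by the
#' contraction law, with anti-aliased edges, then applies a Gaussian blur of
#' `edge_softness` pixels. Deterministic: repeated calls are identical.
#'
#' @inheritParams phantom_radii
#' @return A `grid` x `grid` numeric matrix of signal intensities.
#' @export
render_phase <- function(spec, phase) {
  if (!is.numeric(phase) || length(phase) != 1 || is.na(phase) || phase < 0 || phase >= 1) {
    stop_cscine("phase must lie in [0, 1)", "cscine_domain_error")
  }
  r <- phantom_radii(spec, phase)
  g <- spec$grid
  cx <- (g - 1) / 2
  xs <- seq_len(g) - 1
  dist <- sqrt(outer((xs - cx)^2, (xs - cx)^2, `+`))
  cover <- function(radius) pmin(pmax(radius - dist + 0.5, 0), 1)
  ints <- spec$intensities
  img <- ints[["background"]] +
    (ints[["myocardium"]] - ints[["background"]]) * cover(r[["epi"]]) +
    (ints[["blood"]] - ints[["myocardium"]]) * cover(r[["endo"]])
  if (spec$edge_softness > 0) {
    img <- as.matrix(EBImage::gblur(img, sigma = spec$edge_softness))
  }
  img
}

#' Cine stack container
#'
#' Ordered cardiac-phase frames of one slice: a 3D array (`ny` x `nx` x
#' `n_frames`) plus the cardiac phase of each frame and a provenance tag
#' saying which pathway produced it (ground truth, segmented reconstruction
#' or real-time reconstruction).
#'
#' @param frames 3D numeric array, frames along the third axis (a single
#'   matrix is accepted for one frame).
#' @param phases Numeric vector in `[0, 1)`, one per frame, strictly
#'   increasing.
#' @param provenance `"truth"`, `"segmented"` or `"realtime"`.
#' @param pixel_spacing Pixel size, arbitrary units (default 1).
#' @return An object of class `cine_stack`.
#' @export
cine_stack <- function(frames, phases, provenance = c("truth", "segmented", "realtime"),
                       pixel_spacing = 1) {
  provenance <- match.arg(provenance)
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (length(dim(frames)) != 3 || dim(frames)[3] != length(phases)) {
    stop_cscine("frames must be ny x nx x n_frames with one phase per frame",
                "cscine_invalid_spec")
  }
  if (length(phases) < 1 || any(phases < 0 | phases >= 1) ||
      (length(phases) > 1 && any(diff(phases) <= 0))) {
    stop_cscine("phases must be strictly increasing within [0, 1)", "cscine_invalid_spec")
  }
  structure(
    list(frames = frames, phases = as.numeric(phases), provenance = provenance,
         pixel_spacing = pixel_spacing),
    class = "cine_stack"
  )
}

#' @export
print.cine_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cine_stack> %d x %d, %d frame(s), provenance: %s\n",
              d[1], d[2], d[3], x$provenance))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[3]

#' Ground-truth cine stack
#'
#' Renders the phantom at `n_phases` uniformly spaced phases `k / n_phases`,
#' the noiseless, artifact-free reference against which reconstructions are
#' compared.
#'
#' @inheritParams phantom_radii
#' @param n_phases Number of frames per cycle (default 20, the conventional
#'   cine frame rate).
#' @return A [cine_stack()] with `provenance = "truth"`.
#' @export
truth_stack <- function(spec, n_phases = 20) {
  if (n_phases < 1) stop_cscine("n_phases must be >= 1", "cscine_invalid_spec")
  phases <- (seq_len(n_phases) - 1) / n_phases
  frames <- vapply(phases, function(p) render_phase(spec, p),
                   matrix(0, spec$grid, spec$grid))
  cine_stack(array(frames, dim = c(spec$grid, spec$grid, n_phases)),
             phases, provenance = "truth")
}

#' Root-mean-square error between two cine stacks
#'
#' Frame-wise RMSE between stacks on the same phase grid, a scalar per frame
#' or its mean.
#'
#' @param a,b [cine_stack()] objects of identical dimensions.
#' @param per_frame If `TRUE` return one RMSE per frame, else the mean.
#' @export
stack_rmse <- function(a, b, per_frame = FALSE) {
  if (!identical(dim(a$frames), dim(b$frames))) {
    stop_cscine("stacks must have identical dimensions", "cscine_invalid_spec")
  }
  rmse <- sqrt(apply((a$frames - b$frames)^2, 3, mean))
  if (per_frame) rmse else mean(rmse)
}
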