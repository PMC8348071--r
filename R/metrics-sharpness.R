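#' Sample an intensity profile along a line
#'
#' Bilinear interpolation of image intensity at uniformly spaced positions
#' along the segment from `p0` to `p1`, the first step of the
#' edge-spread-function sharpness measurement. Coordinates are 0-based
#' pixel-centre `(x, y)` pairs, `x` along columns and `y` along rows;
#' positions are measured in pixels from `p0`.
#'
#' @param image Numeric matrix.
#' @param p0,p1 Numeric `c(x, y)` endpoints, inside the image bounds.
#' @param step Sample spacing along the line in pixels (default 0.1).
#' @return A tibble of class `edge_profile` with columns `position` and
#'   `intensity`; endpoints kept as attributes.
#' @export
profile_line <- function(image, p0, p1, step = 0.1) {
  nx <- ncol(image); ny <- nrow(image)
  inb <- function(p) p[1] >= 0 && p[1] <= nx - 1 && p[2] >= 0 && p[2] <= ny - 1
  if (!inb(p0) || !inb(p1)) {
    stop_cscine("profile endpoints must lie inside the image", "cscine_domain_error")
  }
  if (all(p0 == p1)) stop_cscine("endpoints must be distinct", "cscine_domain_error")
  len <- sqrt(sum((p1 - p0)^2))
  pos <- seq(0, len, by = step)
  if (pos[length(pos)] < len - 1e-9) pos <- c(pos, len)
  ux <- (p1[1] - p0[1]) / len
  uy <- (p1[2] - p0[2]) / len
  xs <- p0[1] + pos * ux
  ys <- p0[2] + pos * uy
  x0 <- pmin(pmax(floor(xs), 0), nx - 2); y0 <- pmin(pmax(floor(ys), 0), ny - 2)
  fx <- xs - x0; fy <- ys - y0
  # row index = y + 1, col index = x + 1
  v00 <- image[cbind(y0 + 1, x0 + 1)]; v01 <- image[cbind(y0 + 1, x0 + 2)]
  v10 <- image[cbind(y0 + 2, x0 + 1)]; v11 <- image[cbind(y0 + 2, x0 + 2)]
  val <- (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
  out <- tibble(position = pos, intensity = val)
  class(out) <- c("edge_profile", class(out))
  attr(out, "p0") <- p0
  attr(out, "p1") <- p1
  out
}

#' Edge sharpness from an intensity profile
#'
#' Implements the edge-spread-function sharpness metric: epsilon is the
#' reciprocal of the distance `d` (in pixels) between the positions where
#' the profile crosses 20% and 80% of the difference between the *local*
#' minimum and maximum intensities flanking the steepest edge. Local — not
#' global — extrema matter because artifact-laden profiles carry extra
#' peaks (e.g. a doubled septal border) that would corrupt global extrema.
#'
#' The steepest-gradient position is located first (within `window` if
#' given); the flanking plateaus are the regions, on each side, beyond the
#' point where the gradient magnitude falls below 5% of its peak (and
#' before it rises above 5% again); the plateau level is a robust extreme
#' (median of the 5 most extreme samples) of that region. Crossings are
#' located by linear interpolation between adjacent samples, giving
#' sub-pixel resolution.
#'
#' @param profile An [edge_profile()] from [profile_line()], or a data frame
#'   with `position` and `intensity` columns.
#' @param window Optional `c(min, max)` position range restricting the edge
#'   search, mimicking a reader's manual placement when several edges are
#'   present.
#' @return A list of class `sharpness_result` with elements `i_min`,
#'   `i_max`, `x20`, `x80`, `d`, `epsilon` and the analysed `profile`.
#' @examples
#' prof <- tibble::tibble(position = seq(0, 10, 0.1),
#'                        intensity = 10 * seq(0, 10, 0.1))
#' edge_sharpness(prof)$epsilon # 1/6
#' @export
edge_sharpness <- function(profile, window = NULL) {
  pos <- profile$position
  val <- profile$intensity
  if (length(pos) < 10) stop_cscine("need at least 10 samples", "cscine_insufficient_data")
  keep <- rep(TRUE, length(pos))
  if (!is.null(window)) keep <- pos >= window[1] & pos <= window[2]
  idx <- which(keep)
  if (length(idx) < 10) stop_cscine("window leaves too few samples", "cscine_domain_error")
  grad <- c(NA, diff(val) / diff(pos))
  grad[1] <- grad[2]
  g_in <- abs(grad[idx])
  g_peak <- max(g_in)
  rng <- diff(range(val))
  if (g_peak <= 1e-12 || rng <= 1e-12 * max(abs(val), 1)) {
    stop_cscine("profile contains no edge", "cscine_no_edge")
  }
  at_peak <- which(g_in >= g_peak * (1 - 1e-9))
  if (max(at_peak) - min(at_peak) + 1 > length(at_peak) && is.null(window)) {
    stop_cscine("multiple equally steep edges; supply a window", "cscine_ambiguous_edge")
  }
  i_edge <- idx[at_peak[ceiling(length(at_peak) / 2)]]
  rising <- grad[i_edge] > 0

  lo_set <- idx[idx <= i_edge]
  hi_set <- idx[idx >= i_edge]
  plateau <- function(side_idx, outward) {
    below <- abs(grad[side_idx]) < 0.05 * g_peak
    ord <- if (outward == "left") rev(seq_along(side_idx)) else seq_along(side_idx)
    # walk outward from the edge; plateau runs from the first sub-5% sample
    # until the gradient exceeds 5% again (a further edge) or the data end
    first <- which(below[ord])[1]
    if (is.na(first)) {
      # gradient never settles (pure ramp): use the outermost sample
      return(val[side_idx[ord[length(ord)]]])
    }
    run <- ord[first:length(ord)]
    stop_at <- which(!below[run])[1]
    if (!is.na(stop_at) && stop_at > 1) run <- run[seq_len(stop_at - 1)]
    vals <- val[side_idx[run]]
    k <- min(5L, length(vals))
    low_side <- (outward == "left") == rising
    sorted <- sort(vals, decreasing = !low_side)
    median(sorted[seq_len(k)])
  }
  v_left <- plateau(lo_set, "left")
  v_right <- plateau(hi_set, "right")
  i_min <- min(v_left, v_right)
  i_max <- max(v_left, v_right)
  if (i_max - i_min <= 1e-12 * max(abs(val), 1)) {
    stop_cscine("profile contains no edge", "cscine_no_edge")
  }
  l20 <- i_min + 0.2 * (i_max - i_min)
  l80 <- i_min + 0.8 * (i_max - i_min)

  cross_near <- function(level) {
    # nearest crossing of `level` to the steepest-gradient position
    s <- sign(val - level)
    ch <- which(s[-1] * s[-length(s)] <= 0 & (s[-1] != 0 | s[-length(s)] != 0))
    ch <- ch[ch >= min(idx) & ch + 1 <= max(idx)]
    if (length(ch) == 0) stop_cscine("threshold crossing not found", "cscine_no_edge")
    j <- ch[which.min(abs(ch - i_edge))]
    w <- (level - val[j]) / (val[j + 1] - val[j])
    pos[j] + w * (pos[j + 1] - pos[j])
  }
  x20 <- cross_near(l20)
  x80 <- cross_near(l80)
  d <- abs(x80 - x20)
  if (!is.finite(d) || d <= 0) stop_cscine("degenerate edge", "cscine_no_edge")
  structure(
    list(i_min = i_min, i_max = i_max, x20 = x20, x80 = x80,
         d = d, epsilon = 1 / d, profile = profile),
    class = "sharpness_result"
  )
}

#' @export
print.sharpness_result <- function(x, ...) {
  cat(sprintf("<sharpness_result> d = %.3f px, epsilon = %.4f px^-1\n", x$d, x$epsilon))
  invisible(x)
}

#' @export
tidy.sharpness_result <- function(x, ...) {
  tibble(i_min = x$i_min, i_max = x$i_max, x20 = x$x20, x80 = x$x80,
         d = x$d, epsilon = x$epsilon)
}

#' Serialise a sharpness result, including its profile, to JSON
#'
#' @param x A `sharpness_result`.
#' @param path Output path.
#' @export
write_sharpness_json <- function(x, path) {
  jsonlite::write_json(
    list(i_min = x$i_min, i_max = x$i_max, x20 = x$x20, x80 = x$x80,
         d = x$d, epsilon = x$epsilon,
         profile = list(position = x$profile$position,
                        intensity = x$profile$intensity)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Standard mid-septal edge-sharpness measurement on a phantom frame
#'
#' Draws the conventional profile line perpendicular to the
#' myocardium/blood-pool boundary — horizontally through the cavity centre,
#' crossing the endocardial border on the left — and returns the sharpness
#' of that edge. The line spans `reach` pixels either side of the
#' end-diastolic or current-phase endocardial radius.
#'
#' @param image Frame matrix.
#' @param spec The [phantom_spec()] that generated the geometry.
#' @param phase Cardiac phase of the frame (locates the edge).
#' @param reach Half-length of the profile line in pixels (default 6).
#' @inheritParams edge_sharpness
#' @return A `sharpness_result`.
#' @export
septal_sharpness <- function(image, spec, phase, reach = 6, window = NULL) {
  r <- phantom_radii(spec, phase)[["endo"]]
  c0 <- (spec$grid - 1) / 2
  p0 <- c(max(0, c0 - r - reach), c0)
  p1 <- c(min(spec$grid - 1, c0 - r + reach), c0)
  edge_sharpness(profile_line(image, p0, p1), window = window)
}
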