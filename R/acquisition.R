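#' Acquisition and reconstruction parameters
#'
#' Parameter bundle shared by the two simulated acquisition schemes. The
#' segmented reference arm splits each frame's k-space across many
#' heartbeats at 41.2 ms temporal resolution with 13 phase-encode views per
#' frame per heartbeat; the single-shot real-time arm acquires every frame
#' within one heartbeat at 49 ms resolution, 11-fold random undersampling
#' with 12 always-sampled central lines, and 40 cycles of iterative
#' soft-thresholding reconstruction. [ref_params()] and [rt_params()] give
#' those defaults directly.
#'
#' @param n_phases Frames per cycle for the segmented arm (default 20).
#' @param temporal_resolution Frame duration in ms.
#' @param views_per_frame Phase-encode lines acquired per frame per
#'   heartbeat (segmented arm).
#' @param acceleration Undersampling factor (>= 1).
#' @param center_lines Fully sampled central phase-encode lines (real-time
#'   arm).
#' @param n_iterations Iterative-reconstruction cycle count (>= 0).
#' @param threshold_weight Sparsity soft-threshold as a fraction of the
#'   maximum temporal-Fourier coefficient magnitude of the zero-filled
#'   reconstruction.
#' @param trigger_mode `"prospective_fixed_window"` (segmented: fixed
#'   acquisition window clamped to the shortest RR) or
#'   `"adaptive_to_next_R"` (real-time: frames until the next R peak).
#' @param noise_sd Standard deviation of optional complex Gaussian k-space
#'   noise, relative to the peak k-space magnitude (0 disables noise).
#' @param seed Integer seed driving the random undersampling masks (and
#'   noise, if any).
#' @return A list of class `acq_params`.
#' @export
acq_params <- function(n_phases = 20, temporal_resolution = 41.2,
                       views_per_frame = 13, acceleration = 2,
                       center_lines = 12, n_iterations = 40,
                       threshold_weight = 0.02,
                       trigger_mode = c("prospective_fixed_window", "adaptive_to_next_R"),
                       noise_sd = 0, seed = 1L) {
  trigger_mode <- match.arg(trigger_mode)
  if (n_phases < 1 || acceleration < 1 || center_lines < 1 ||
      n_iterations < 0 || views_per_frame < 1 || temporal_resolution <= 0 ||
      threshold_weight < 0 || noise_sd < 0) {
    stop_cscine("invalid acquisition parameters", "cscine_invalid_spec")
  }
  structure(
    list(n_phases = as.integer(n_phases), temporal_resolution = temporal_resolution,
         views_per_frame = as.integer(views_per_frame), acceleration = acceleration,
         center_lines = as.integer(center_lines), n_iterations = as.integer(n_iterations),
         threshold_weight = threshold_weight, trigger_mode = trigger_mode,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "acq_params"
  )
}

#' @rdname acq_params
#' @param ... Overrides passed on to [acq_params()].
#' @export
ref_params <- function(...) {
  args <- utils::modifyList(
    list(n_phases = 20, temporal_resolution = 41.2, views_per_frame = 13,
         acceleration = 2, trigger_mode = "prospective_fixed_window"),
    list(...))
  do.call(acq_params, args)
}

#' @rdname acq_params
#' @export
rt_params <- function(...) {
  args <- utils::modifyList(
    list(temporal_resolution = 49, acceleration = 11, center_lines = 12,
         n_iterations = 40, trigger_mode = "adaptive_to_next_R"),
    list(...))
  do.call(acq_params, args)
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Segmented acquisition plan
#'
#' Lays out which phase-encode lines each heartbeat contributes to each
#' frame of a prospectively triggered segmented acquisition, and — crucially
#' — the true cardiac phase of the heart when those lines are acquired. The
#' acquisition window is `n_phases * temporal_resolution`, clamped to the
#' shortest RR interval; a fixed time after the R peak then maps to a
#' different cardiac phase in each heartbeat whenever RR varies, which is
#' the entire arrhythmia-artifact mechanism.
#'
#' Heartbeat `h` contributes the line block `[(h-1)*v + 1, h*v]` (sequential
#' ordering) to every frame; `ceiling(n_lines / v)` heartbeats are needed.
#' If the RR series is shorter than that, it is recycled cyclically.
#'
#' @param params An [acq_params()].
#' @param rr An [rr_series()] or numeric vector of RR durations (ms).
#' @param n_lines Number of phase-encode lines in the matrix.
#' @return A tibble of class `kspace_plan` with columns `frame`,
#'   `heartbeat`, `true_phase` and list-column `lines`, plus attributes
#'   `tr_eff` (clamped per-frame duration, ms) and `n_heartbeats`.
#' @export
plan_segmented <- function(params, rr, n_lines) {
  d <- rr_durations(rr)
  if (length(d) < 1 || any(d <= 0)) {
    stop_cscine("rr must contain positive durations", "cscine_invalid_spec")
  }
  v <- params$views_per_frame
  H <- as.integer(ceiling(n_lines / v))
  d <- rep_len(d, H)
  W <- params$n_phases * params$temporal_resolution
  tr_eff <- min(W, min(d)) / params$n_phases
  if (!is.finite(tr_eff) || tr_eff <= 0) {
    stop_cscine("acquisition window cannot fit within the shortest RR interval",
                "cscine_infeasible_window")
  }
  grid_fh <- tidyr::expand_grid(frame = seq_len(params$n_phases), heartbeat = seq_len(H))
  plan <- dplyr::mutate(
    grid_fh,
    true_phase = (.data$frame - 1) * tr_eff / d[.data$heartbeat],
    lines = purrr::map(.data$heartbeat,
                       ~ seq.int((.x - 1L) * v + 1L, min(.x * v, n_lines)))
  )
  attr(plan, "tr_eff") <- tr_eff
  attr(plan, "n_heartbeats") <- H
  attr(plan, "n_lines") <- as.integer(n_lines)
  class(plan) <- c("kspace_plan", class(plan))
  plan
}

# complex Gaussian k-space noise, sd relative to peak magnitude
add_kspace_noise <- function(K, noise_sd) {
  if (noise_sd <= 0) return(K)
  s <- noise_sd * max(Mod(K))
  K + complex(real = rnorm(length(K), sd = s), imaginary = rnorm(length(K), sd = s))
}

#' Simulate a prospectively triggered segmented acquisition
#'
#' For each frame, every heartbeat's line block is taken from the 2D
#' discrete Fourier transform of the phantom rendered at that heartbeat's
#' *recorded* true phase for the frame; the merged k-space is then
#' inverse-transformed. With a perfectly regular rhythm all contributions
#' are coherent and the output equals the ground truth; under RR
#' variability, data from inconsistent cardiac phases are merged and
#' ghosting/blurring emerges mechanistically.
#'
#' @param spec A [phantom_spec()].
#' @inheritParams plan_segmented
#' @return A [cine_stack()] with `provenance = "segmented"` and nominal
#'   frame phases `k / n_phases`.
#' @export
simulate_segmented <- function(spec, params, rr) {
  g <- spec$grid
  plan <- plan_segmented(params, rr, n_lines = g)
  # cache k-space per distinct rendered phase (rounded to break fp noise)
  keys <- sprintf("%.12f", plan$true_phase)
  uniq <- !duplicated(keys)
  kcache <- stats::setNames(
    lapply(plan$true_phase[uniq], function(p) fft2(render_phase(spec, p))),
    keys[uniq])
  frames <- withr::with_seed(params$seed, {
    vapply(seq_len(params$n_phases), function(f) {
      rows <- plan[plan$frame == f, ]
      K <- matrix(0 + 0i, g, g)
      for (j in seq_len(nrow(rows))) {
        L <- rows$lines[[j]]
        K[L, ] <- kcache[[sprintf("%.12f", rows$true_phase[j])]][L, , drop = FALSE]
      }
      K <- add_kspace_noise(K, params$noise_sd)
      Re(ifft2(K))
    }, matrix(0, g, g))
  })
  cine_stack(array(frames, dim = c(g, g, params$n_phases)),
             (seq_len(params$n_phases) - 1) / params$n_phases,
             provenance = "segmented")
}

# signed frequency index of each k-space row in R's unshifted FFT layout
kline_freq <- function(n) {
  k <- seq_len(n) - 1L
  ifelse(k > n / 2, k - n, k)
}

#' Variable-density random undersampling mask for one frame
#'
#' Selects `round(n_lines / acceleration)` phase-encode lines: the
#' `center_lines` lines nearest k-space centre are always sampled, the
#' remainder drawn without replacement with Gaussian density (sigma =
#' `n_lines / 6`) favouring low spatial frequencies. Consumes the current
#' RNG stream; callers seed it.
#'
#' @param n_lines Number of phase-encode lines.
#' @param acceleration Undersampling factor.
#' @param center_lines Always-sampled central lines.
#' @return Logical vector of length `n_lines` (TRUE = sampled), in R's
#'   unshifted FFT row order.
#' @export
sampling_mask <- function(n_lines, acceleration, center_lines = 12) {
  freq <- kline_freq(n_lines)
  n_sample <- max(center_lines, round(n_lines / acceleration))
  mask <- rank(abs(freq), ties.method = "first") <= center_lines
  extra <- n_sample - sum(mask)
  if (extra > 0) {
    pool <- which(!mask)
    w <- exp(-freq[pool]^2 / (2 * (n_lines / 6)^2))
    mask[sample(pool, extra, prob = w)] <- TRUE
  }
  mask
}

#' Number of real-time frames acquired in one heartbeat
#'
#' With adaptive triggering the single-shot acquisition runs until the next
#' R peak, so a cycle of length `rr_ms` yields `floor(rr_ms /
#' temporal_resolution)` frames — fewer frames per cycle at faster heart
#' rates (below 16 frames at 49 ms resolution once the cycle is shorter
#' than 784 ms).
#'
#' @param rr_ms Cycle length in milliseconds.
#' @param temporal_resolution Frame duration in milliseconds (default 49).
#' @return Integer frame count.
#' @export
realtime_frame_count <- function(rr_ms, temporal_resolution = 49) {
  as.integer(floor(rr_ms / temporal_resolution))
}

#' Simulate a single-shot real-time compressed-sensing acquisition
#'
#' Frames tile one heartbeat at `temporal_resolution` spacing; each frame's
#' k-space is sampled on a fresh seeded variable-density random mask at the
#' stated acceleration (central lines always kept) from the phantom at the
#' frame's true phase, then reconstructed jointly with [cs_reconstruct()].
#' Because all data in every frame come from a single heartbeat, no
#' cross-beat phase mixing can occur regardless of rhythm irregularity.
#'
#' @inheritParams simulate_segmented
#' @param heartbeat Index of the heartbeat in `rr` to acquire.
#' @return A [cine_stack()] with `provenance = "realtime"`; frame phases
#'   `(f - 1) * temporal_resolution / rr`.
#' @export
simulate_realtime <- function(spec, params, rr, heartbeat = 1) {
  d <- rr_durations(rr)
  if (heartbeat < 1 || heartbeat > length(d)) {
    stop_cscine("heartbeat index out of range", "cscine_invalid_spec")
  }
  rr_ms <- d[heartbeat]
  nt <- realtime_frame_count(rr_ms, params$temporal_resolution)
  if (nt < 1) {
    stop_cscine("RR interval shorter than one temporal resolution",
                "cscine_degenerate_cycle")
  }
  g <- spec$grid
  phases <- (seq_len(nt) - 1) * params$temporal_resolution / rr_ms
  out <- withr::with_seed(params$seed + heartbeat, {
    masks <- vapply(seq_len(nt), function(t)
      sampling_mask(g, params$acceleration, params$center_lines), logical(g))
    ks <- array(0 + 0i, dim = c(g, g, nt))
    for (t in seq_len(nt)) {
      K <- add_kspace_noise(fft2(render_phase(spec, phases[t])), params$noise_sd)
      K[!masks[, t], ] <- 0 + 0i
      ks[, , t] <- K
    }
    cs_reconstruct(ks, masks, params)
  })
  stack <- cine_stack(out$frames, phases, provenance = "realtime")
  attr(stack, "residuals") <- out$residuals
  stack
}

#' Iterative soft-thresholding compressed-sensing reconstruction
#'
#' Reconstructs a randomly undersampled dynamic frame series by alternating
#' a sparsity step — soft-thresholding the coefficients of the temporal
#' Fourier transform along the frame axis by `lambda = threshold_weight *
#' max |coefficient|` of the zero-filled reconstruction — with a
#' data-consistency step that restores the measured k-space entries. Runs
#' `n_iterations` cycles (0 returns the zero-filled reconstruction);
#' deterministic given its inputs.
#'
#' @param kspace Complex array `ny x nx x n_frames` of measured k-space,
#'   zeros at unsampled locations.
#' @param masks Logical matrix `ny x n_frames`: which phase-encode rows were
#'   sampled in each frame.
#' @param params An [acq_params()] (uses `n_iterations`, `threshold_weight`).
#' @return List with `frames` (real array of reconstructed images) and
#'   `residuals` (data-consistency residual before each consistency step).
#' @export
cs_reconstruct <- function(kspace, masks, params) {
  dm <- dim(kspace)
  if (is.null(dm) || length(dm) != 3 || dm[3] < 1) {
    stop_cscine("kspace must be a ny x nx x n_frames array", "cscine_empty_input")
  }
  if (!identical(dim(masks), dm[c(1, 3)])) {
    stop_cscine("masks must be ny x n_frames and match kspace", "cscine_invalid_spec")
  }
  ny <- dm[1]; nx <- dm[2]; nt <- dm[3]
  x <- array(0 + 0i, dim = dm)
  for (t in seq_len(nt)) x[, , t] <- ifft2(kspace[, , t])

  tfft <- function(arr, inverse = FALSE) {
    mat <- matrix(arr, ny * nx, nt)            # pixels x time
    co <- t(stats::mvfft(t(mat), inverse = inverse))
    if (inverse) co <- co / nt
    array(co, dim = dm)
  }
  lambda <- params$threshold_weight * max(Mod(tfft(x)))
  residuals <- numeric(0)
  n_it <- params$n_iterations
  if (n_it > 0) {
    for (it in seq_len(n_it)) {
      if (lambda > 0) {
        co <- tfft(x)
        m <- Mod(co)
        shrink <- ifelse(m > 0, pmax(0, 1 - lambda / m), 0)
        x <- tfft(co * shrink, inverse = TRUE)
      }
      res2 <- 0
      for (t in seq_len(nt)) {
        K <- fft2(x[, , t])
        Kt <- kspace[, , t]
        smp <- masks[, t]
        res2 <- res2 + sum(Mod(K[smp, , drop = FALSE] - Kt[smp, , drop = FALSE])^2)
        K[smp, ] <- Kt[smp, , drop = FALSE]
        x[, , t] <- ifft2(K)
      }
      residuals[it] <- sqrt(res2)
    }
  }
  list(frames = array(Re(x), dim = dm), residuals = residuals)
}

#' Interpolate a cine stack onto a fixed phase grid
#'
#' Linear interpolation in cardiac phase onto `n_out` uniformly spaced
#' phases `k / n_out`, treating the cycle as periodic. This is the
#' standardisation step applied to real-time stacks so that every slice
#' presents the same number of frames to downstream analysis.
#'
#' @param stack A [cine_stack()] with at least 2 frames.
#' @param n_out Number of output phases (default 20).
#' @return A [cine_stack()] with `n_out` frames at phases `k / n_out`.
#' @export
temporal_interpolate <- function(stack, n_out = 20) {
  nt <- n_frames(stack)
  if (nt < 2) stop_cscine("at least 2 frames are required", "cscine_insufficient_frames")
  p <- stack$phases
  # periodic extension: the first frame recurs one cycle later
  p_ext <- c(p, p[1] + 1)
  f_idx <- c(seq_len(nt), 1L)
  q <- (seq_len(n_out) - 1) / n_out
  dm <- dim(stack$frames)
  out <- array(0, dim = c(dm[1], dm[2], n_out))
  for (k in seq_len(n_out)) {
    i <- findInterval(q[k], p_ext, rightmost.closed = TRUE)
    i <- max(1L, min(i, length(p_ext) - 1L))
    w <- (q[k] - p_ext[i]) / (p_ext[i + 1] - p_ext[i])
    out[, , k] <- (1 - w) * stack$frames[, , f_idx[i]] +
      w * stack$frames[, , f_idx[i + 1]]
  }
  cine_stack(out, q, provenance = stack$provenance,
             pixel_spacing = stack$pixel_spacing)
}
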