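# shared fixtures, built in code at test time

quick_spec <- function(grid = 64, ...) phantom_spec(grid = grid, ...)

# real-time parameters scaled to the small test grids
quick_rt <- function(...) rt_params(center_lines = 8, ...)

# error-function edge profile: step of unit height blurred by a Gaussian of
# width sigma; closed-form 20-80 rise distance is 1.6832 * sigma
gauss_profile <- function(sigma, extent = 8, step = 0.1) {
  pos <- seq(-extent * sigma, extent * sigma, by = step)
  tibble::tibble(position = pos, intensity = stats::pnorm(pos / sigma))
}

# independent signed-rank oracle: exhaustive enumeration over all 2^n sign
# assignments of the midranked absolute differences
brute_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  centre <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  mean(abs(ws - centre) >= abs(w_obs - centre) - 1e-9)
}

# ground-truth frames rendered at a stack's own acquired phases
truth_at_phases <- function(spec, phases) {
  vapply(phases, function(p) render_phase(spec, p),
         matrix(0, spec$grid, spec$grid))
}
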