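test_that("the segmented plan maps a fixed time after the R peak to per-beat phases", {
  # constant rhythm: no phase mixing anywhere
  p <- plan_segmented(acq_params(), rep(900, 4), 64)
  spread <- tapply(p$true_phase, p$frame, function(x) diff(range(x)))
  expect_true(all(spread == 0))
  # two-beat example: frame 11 at 40 ms resolution is 400 ms after the R peak
  p2 <- plan_segmented(acq_params(n_phases = 20, temporal_resolution = 40,
                                  views_per_frame = 48),
                       c(800, 1000), 96)
  expect_setequal(round(p2$true_phase[p2$frame == 11], 10), c(0.5, 0.4))
  # heartbeat bookkeeping: 168 lines at 13 views per frame need 13 beats
  p3 <- plan_segmented(acq_params(views_per_frame = 13), 900, 168)
  expect_equal(attr(p3, "n_heartbeats"), 13)
  expect_equal(sort(unique(unlist(p3$lines))), 1:168)
  # clamping: the window never exceeds the shortest RR
  p4 <- plan_segmented(acq_params(n_phases = 20, temporal_resolution = 50), c(600, 900), 64)
  expect_equal(attr(p4, "tr_eff"), 600 / 20)
  expect_true(all(p4$true_phase >= 0 & p4$true_phase < 1))
})

test_that("coherent merging reproduces the ground truth at zero RR variability", {
  spec <- quick_spec()
  truth <- truth_stack(spec, 20)
  seg <- simulate_segmented(spec, ref_params(seed = 1), rep(800, 8))
  rng <- diff(range(truth$frames))
  expect_lt(stack_rmse(seg, truth), 1e-6 * rng)
})

test_that("RR variability creates artifacts and degrades end-systolic sharpness", {
  spec <- quick_spec()
  truth <- truth_stack(spec, 20)
  seg0 <- simulate_segmented(spec, ref_params(seed = 1), rep(800, 8))
  rr25 <- generate_rr(arrhythmia_spec(800, "afib", 25, 32, seed = 2))
  seg25 <- simulate_segmented(spec, ref_params(seed = 1), rr25)
  expect_gt(stack_rmse(seg25, truth), stack_rmse(seg0, truth))
  k <- which.min(abs(truth$phases - spec$systole_fraction))
  eps_truth <- septal_sharpness(truth$frames[, , k], spec, truth$phases[k])$epsilon
  eps_seg <- septal_sharpness(seg25$frames[, , k], spec, truth$phases[k])$epsilon
  expect_lt(eps_seg, eps_truth)
})

test_that("real-time frame counts follow the cycle length", {
  expect_equal(realtime_frame_count(833, 49), 17L)
  expect_equal(realtime_frame_count(800, 49), 16L)   # 75 bpm
  expect_equal(realtime_frame_count(784, 49), 16L)
  expect_lt(realtime_frame_count(783, 49), 16L)
  expect_error(simulate_realtime(quick_spec(), rt_params(), 40),
               class = "cscine_degenerate_cycle")
})

test_that("fully sampled single-shot acquisition is exact without iterations", {
  spec <- quick_spec()
  rt <- simulate_realtime(spec, quick_rt(acceleration = 1, n_iterations = 0, seed = 1), 833)
  expect_equal(length(rt$phases), 17)
  tf <- truth_at_phases(spec, rt$phases)
  expect_lt(max(abs(rt$frames - array(tf, dim(rt$frames)))), 1e-10)
})

test_that("iterative reconstruction beats zero-filling on undersampled data", {
  spec0 <- quick_spec(contraction_fraction = 0)  # static: maximally sparse in time
  cs <- simulate_realtime(spec0, quick_rt(seed = 2), 800)
  zf <- simulate_realtime(spec0, quick_rt(seed = 2, n_iterations = 0), 800)
  tf <- array(truth_at_phases(spec0, cs$phases), dim(cs$frames))
  expect_lt(sqrt(mean((cs$frames - tf)^2)), sqrt(mean((zf$frames - tf)^2)))
  # the iteration converges to a fixed point: residual steps shrink and the
  # final relative change is negligible
  res <- attr(cs, "residuals")
  expect_equal(length(res), 40)
  d <- diff(res)
  expect_lt(max(abs(d[20:39])), max(abs(d[1:5])))
  expect_lt(abs(d[39]) / res[1], 1e-5)
})

test_that("a zero threshold leaves the zero-filled reconstruction fixed", {
  spec <- quick_spec()
  a <- simulate_realtime(spec, quick_rt(threshold_weight = 0, n_iterations = 7, seed = 3), 800)
  b <- simulate_realtime(spec, quick_rt(threshold_weight = 0, n_iterations = 0, seed = 3), 800)
  expect_equal(a$frames, b$frames, tolerance = 1e-12)
})

test_that("full-mask reconstruction is the unitary inverse of its k-space", {
  set.seed(9)
  g <- 16; nt <- 4
  imgs <- array(rnorm(g * g * nt), c(g, g, nt))
  ks <- array(0 + 0i, c(g, g, nt))
  for (t in 1:nt) ks[, , t] <- stats::fft(imgs[, , t])
  masks <- matrix(TRUE, g, nt)
  out <- cs_reconstruct(ks, masks, acq_params(n_iterations = 5, threshold_weight = 0))
  expect_lt(max(abs(out$frames - imgs)), 1e-10)
  # with thresholding on, the data-consistency step still restores full data
  out2 <- cs_reconstruct(ks, masks, acq_params(n_iterations = 5, threshold_weight = 0.05))
  expect_lt(max(abs(out2$frames - imgs)), 1e-10)
  expect_error(cs_reconstruct(array(0 + 0i, c(4, 4, 0)), matrix(TRUE, 4, 0), acq_params()),
               class = "cscine_empty_input")
})

test_that("sampling masks honour acceleration and the fully sampled centre", {
  set.seed(4)
  for (acc in c(2, 8, 11)) {
    m <- sampling_mask(96, acc, center_lines = 12)
    expect_equal(sum(m), max(12, round(96 / acc)))
    freq <- ifelse(0:95 > 48, 0:95 - 96, 0:95)
    expect_true(all(m[rank(abs(freq), ties.method = "first") <= 12]))
  }
})

test_that("temporal interpolation standardises the phase grid", {
  spec <- quick_spec()
  st <- truth_stack(spec, 20)
  expect_equal(temporal_interpolate(st, 20)$frames, st$frames, tolerance = 1e-12)
  # constant frames stay constant
  const <- cine_stack(array(3, c(8, 8, 2)), c(0, 0.5))
  it <- temporal_interpolate(const, 20)
  expect_equal(max(abs(it$frames - 3)), 0, tolerance = 1e-12)
  expect_equal(it$phases, (0:19) / 20)
  # 17 acquired frames are standardised to 20
  rt <- simulate_realtime(spec, quick_rt(n_iterations = 0, seed = 1), 833)
  expect_equal(dim(temporal_interpolate(rt, 20)$frames)[3], 20)
  expect_error(temporal_interpolate(cine_stack(matrix(0, 4, 4), 0)),
               class = "cscine_insufficient_frames")
})
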