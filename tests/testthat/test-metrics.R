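test_that("profile sampling interpolates bilinearly along the segment", {
  img <- matrix(5, 20, 20)
  p <- profile_line(img, c(2, 10), c(18, 10))
  expect_true(all(p$intensity == 5))
  # vertical split image: two plateaus reproduced
  img2 <- matrix(rep(c(rep(0, 10), rep(1, 10)), each = 20), 20, 20)
  p2 <- profile_line(img2, c(1, 10), c(18, 10))
  expect_true(all(p2$intensity[p2$position < 7] == 0))
  expect_true(all(p2$intensity[p2$position > 11] == 1))
  # diagonal line of length 10 at step 0.1 gives 101 samples
  p3 <- profile_line(img, c(2, 2), c(2 + 10 / sqrt(2), 2 + 10 / sqrt(2)), step = 0.1)
  expect_equal(nrow(p3), 101)
  expect_error(profile_line(img, c(-1, 5), c(5, 5)), class = "cscine_domain_error")
  expect_error(profile_line(img, c(5, 5), c(5, 5)), class = "cscine_domain_error")
})

test_that("a linear ramp gives the exact 20-80 rise distance", {
  pos <- seq(0, 10, by = 0.1)
  r <- edge_sharpness(tibble::tibble(position = pos, intensity = 10 * pos))
  expect_equal(r$x20, 2)
  expect_equal(r$x80, 8)
  expect_equal(r$d, 6)
  expect_equal(r$epsilon, 1 / 6)
  expect_equal(r$epsilon, 1 / r$d)  # definitional identity
})

test_that("a Gaussian-blurred step matches the closed form", {
  for (s in c(2, 4, 8, 12)) {
    r <- edge_sharpness(gauss_profile(s))
    expect_lt(abs(r$d - 1.6832 * s) / (1.6832 * s), 0.01)
    expect_lt(abs(r$epsilon - 1 / (1.6832 * s)) / (1 / (1.6832 * s)), 0.01)
  }
  # falling edges measure identically to rising ones
  gp <- gauss_profile(4)
  gp$intensity <- 1 - gp$intensity
  expect_equal(edge_sharpness(gp)$d, edge_sharpness(gauss_profile(4))$d, tolerance = 1e-9)
})

test_that("sharpness is invariant under affine intensity maps", {
  gp <- gauss_profile(3)
  r1 <- edge_sharpness(gp)
  gp2 <- gp
  gp2$intensity <- 7.3 * gp$intensity + 11
  r2 <- edge_sharpness(gp2)
  expect_equal(r1$epsilon, r2$epsilon, tolerance = 1e-14)
  expect_equal(r1$x20, r2$x20, tolerance = 1e-12)
})

test_that("sharpness decreases monotonically with blur", {
  eps <- vapply(c(1, 2, 3, 5, 8, 12), function(s) edge_sharpness(gauss_profile(s))$epsilon,
                numeric(1))
  expect_true(all(diff(eps) < 0))
})

test_that("flat and degenerate profiles are rejected", {
  pos <- seq(0, 20, 0.1)
  expect_error(edge_sharpness(tibble::tibble(position = pos, intensity = rep(4, length(pos)))),
               class = "cscine_no_edge")
  expect_error(edge_sharpness(tibble::tibble(position = 1:5, intensity = 1:5)),
               class = "cscine_insufficient_data")
  expect_error(edge_sharpness(gauss_profile(2), window = c(0, 0.5)),
               class = "cscine_domain_error")
})

test_that("the window disambiguates profiles with several edges", {
  # two identical opposing edges: a symmetric box
  pos <- seq(0, 40, 0.1)
  box <- stats::pnorm((pos - 10) / 1.5) - stats::pnorm((pos - 30) / 1.5)
  prof <- tibble::tibble(position = pos, intensity = box)
  r <- edge_sharpness(prof, window = c(0, 20))
  expect_equal(r$d, 1.6832 * 1.5, tolerance = 0.02)
})

test_that("EuroCMR scoring follows the itemised rubric", {
  clean <- slice_annotations(8)
  expect_equal(euro_cmr_score(clean)$modified_total, 0)
  # blurring on >= 3 slices and nothing else scores exactly 3
  ara3 <- slice_annotations(8, blurring_ara = c(rep(TRUE, 3), rep(FALSE, 5)))
  sc <- euro_cmr_score(ara3)
  expect_equal(unname(sc$item_scores[["blurring_ara"]]), 3)
  expect_equal(sc$modified_total, 3)
  # coverage 'both' (5) + ghosts on two slices (2) + inactive coil (2) = 9
  mix <- slice_annotations(8, coverage = "both", coil_active = FALSE,
                           cardiac_ghost = c(TRUE, TRUE, rep(FALSE, 6)))
  expect_equal(euro_cmr_score(mix)$modified_total, 9)
  # the items 2-7 block saturates at 3 by default but not when uncapped
  many <- slice_annotations(8, wrap_around = TRUE, cardiac_ghost = TRUE,
                            blurring_ara = TRUE)
  expect_equal(euro_cmr_score(many)$modified_total, 3)
  expect_equal(euro_cmr_score(many, cap_items_2_7 = FALSE)$modified_total, 9)
  expect_lte(euro_cmr_score(many)$modified_total, 10)
  expect_error(euro_cmr_score(clean[0, ]), class = "cscine_insufficient_data")
})

test_that("adding an artifact flag never decreases the modified total", {
  set.seed(21)
  items <- c("wrap_around", "respiratory_ghost", "cardiac_ghost",
             "blurring_ara", "metallic", "shimming")
  for (i in 1:25) {
    flags <- stats::setNames(lapply(items, function(x) runif(6) < 0.3), items)
    ann <- do.call(slice_annotations, c(list(n_slices = 6), flags))
    base <- euro_cmr_score(ann)$modified_total
    # flip one clean flag on
    clean_cells <- which(!as.matrix(ann[items]), arr.ind = TRUE)
    if (nrow(clean_cells) == 0) next
    pick <- clean_cells[sample(nrow(clean_cells), 1), ]
    ann2 <- ann
    ann2[[items[pick[2]]]][pick[1]] <- TRUE
    expect_gte(euro_cmr_score(ann2)$modified_total, base)
  }
})

test_that("ARA rate is a simple slice proportion, invariant to slice order", {
  f <- c(rep(TRUE, 6), rep(FALSE, 2))
  expect_equal(ara_rate(slice_annotations(8, blurring_ara = f)), 75)
  expect_equal(ara_rate(slice_annotations(8, blurring_ara = FALSE)), 0)
  expect_equal(ara_rate(slice_annotations(8, blurring_ara = TRUE)), 100)
  set.seed(5)
  ann <- slice_annotations(8, blurring_ara = f)
  perm <- ann[sample(8), ]
  expect_equal(ara_rate(perm), ara_rate(ann))
})

test_that("the automatic blur flag compares reconstruction to truth", {
  spec <- quick_spec()
  truth <- truth_stack(spec, 20)
  same <- auto_flag_ara(truth, truth, spec)
  expect_false(same$blurring_ara)
  expect_equal(same$ratio, 1)
  blurred <- truth
  for (k in 1:20) blurred$frames[, , k] <- as.matrix(EBImage::gblur(truth$frames[, , k], 3))
  hit <- auto_flag_ara(blurred, truth, spec)
  expect_true(hit$blurring_ara)
  expect_lt(hit$ratio, 0.75)
  expect_false(auto_flag_ara(blurred, truth, spec, epsilon_ratio_threshold = 0)$blurring_ara)
})

test_that("annotations round-trip through the CSV schema", {
  ann <- slice_annotations(4, blurring_ara = c(TRUE, FALSE, TRUE, FALSE))
  ann$patient_id <- 7L
  ann$sequence <- "ref"
  f <- withr::local_tempfile(fileext = ".csv")
  write_annotations_csv(ann, f)
  back <- read_annotations_csv(f)
  expect_equal(back$blurring_ara, ann$blurring_ara)
  expect_equal(euro_cmr_score(back)$modified_total, euro_cmr_score(ann)$modified_total)
})
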