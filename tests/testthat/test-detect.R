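test_that("maximum-intensity projection equals the per-pixel max oracle", {
  one <- patch_movie(matrix(runif(120), 10, 12))
  expect_equal(max_intensity_projection(one), one$pixels[, , 1])
  const <- patch_movie(array(rep(c(0, 5), each = 50), c(5, 10, 2)))
  expect_equal(max_intensity_projection(const), matrix(5, 5, 10))
  mv <- simulate_movie(sim_config(n_frames = 10, seed = 31))
  mip <- max_intensity_projection(mv)
  oracle <- mv$pixels[, , 1]
  for (f in 2:10) oracle <- pmax(oracle, mv$pixels[, , f])
  expect_identical(mip, oracle)
  expect_true(all(mip >= mv$pixels[, , 3]))
})

test_that("cell segmentation recovers a painted rod and its area", {
  px <- 0.064
  rod <- paint_rod(30, 60, 3.0 / px, 0.9 / px, value = 300,
                   background = 100)
  set.seed(32)
  noisy <- rod + matrix(rnorm(length(rod), 0, 10), nrow(rod))
  m <- segment_cell(noisy, px)
  true_area <- sum(rod == 300) * px^2
  expect_equal(m$area_um2, true_area, tolerance = 0.05)
  expect_equal(m$area_um2, sum(m$mask) * px^2)  # area definition
  expect_error(segment_cell(matrix(7, 20, 20), px), "variance")
})

test_that("cell dimension measurement is accurate and rotation-invariant", {
  px <- 0.064
  rod <- paint_rod(40, 70, 3.0 / px, 0.9 / px)
  d0 <- measure_cell_dimensions(rod > 0, px)
  expect_equal(d0$length_um, 3.0, tolerance = 0.05)
  expect_equal(d0$width_um, 0.9, tolerance = 0.10)
  # rotation consistency is limited by rasterization: the painted pixel
  # union of a rotated rod is genuinely wider by up to ~1 px
  rot <- paint_rod(50, 70, 3.0 / px, 0.9 / px, angle = pi / 6)
  d30 <- measure_cell_dimensions(rot > 0, px)
  expect_equal(d30$length_um, 3.0, tolerance = 0.05)
  expect_equal(d30$width_um, 0.9, tolerance = 0.10)
  expect_lt(abs(d30$length_um - d0$length_um), 0.05 * d0$length_um)
  expect_lt(abs(d30$width_um - d0$width_um), 1.5 * px)
  sq <- matrix(FALSE, 30, 30); sq[8:23, 8:23] <- TRUE
  ds <- measure_cell_dimensions(sq, px)
  expect_equal(ds$length_um, ds$width_um, tolerance = 1e-6)
})

test_that("difference-of-Gaussians enhancement behaves as a band-pass", {
  # constant in, ~zero out
  flat <- enhance_frame(matrix(100, 20, 20))
  expect_lt(max(abs(flat)), 1e-9 * 100)
  # impulse response equals an independently constructed DoG kernel
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  resp <- enhance_frame(imp)
  kern <- function(sigma) {
    r <- 2 * ceiling(3 * sigma) + 1
    half <- (r - 1) / 2
    k1 <- exp(-(-half:half)^2 / (2 * sigma^2))
    k <- outer(k1, k1)
    k / sum(k)
  }
  oracle <- matrix(0, 41, 41)
  for (s in c(1, 4)) {
    k <- kern(s); half <- (nrow(k) - 1) / 2
    sgn <- if (s == 1) 1 else -1
    rows <- (21 - half):(21 + half)
    oracle[rows, rows] <- oracle[rows, rows] + sgn * k
  }
  expect_gt(resp[21, 21], 0)
  expect_equal(resp, oracle, tolerance = 1e-7)
  # Gaussian spot on flat background: global max at the spot centre
  sp <- render_single_spot(11, 13, 50, H = 28, W = 28, sigma_px = 2,
                           background = 100)
  enh <- enhance_frame(sp)
  pk <- which(enh == max(enh), arr.ind = TRUE)
  expect_lte(abs(pk[1, 2] - 1 - 11), 0.5)
  expect_lte(abs(pk[1, 1] - 1 - 13), 0.5)
})

test_that("watershed detection finds, splits and localizes spots", {
  # one spot at SNR ~ 8: exactly one detection, sub-pixel accurate
  set.seed(33)
  img <- render_single_spot(11.4, 12.7, 145, noise = TRUE, seed = 33)
  det <- detect_patches_frame(enhance_frame(img))
  expect_equal(nrow(det), 1L)
  expect_lt(sqrt((det$x_px - 11.4)^2 + (det$y_px - 12.7)^2), 0.5)
  # two spots 10 px apart resolve; 2 px apart merge into one
  two_far <- render_single_spot(8, 12, 145, W = 30) +
    render_single_spot(18, 12, 145, W = 30) - 100
  expect_equal(nrow(detect_patches_frame(enhance_frame(two_far))), 2L)
  two_close <- render_single_spot(11, 12, 145, W = 30) +
    render_single_spot(13, 12, 145, W = 30) - 100
  expect_equal(nrow(detect_patches_frame(enhance_frame(two_close))), 1L)
  # false positives on pure noise stay below 0.1 per frame
  set.seed(34)
  fp <- vapply(seq_len(1000), function(i) {
    fr <- matrix(rpois(32 * 48, 100) + rnorm(32 * 48, 0, 2), 32, 48)
    nrow(detect_patches_frame(enhance_frame(fr)))
  }, numeric(1))
  expect_lte(mean(fp), 0.1)
})

test_that("detection is invariant to offsets and density to rescaling", {
  mv <- simulate_movie(sim_config(n_frames = 12, seed = 35))
  mask <- segment_cell(max_intensity_projection(mv), mv$pixel_size_um)
  det <- detect_movie(mv, mask)
  # constant offset: removed by the DoG, detections unchanged
  mv_off <- mv; mv_off$pixels <- mv$pixels + 500
  det_off <- detect_movie(mv_off, mask)
  expect_equal(nrow(det_off), nrow(det))
  expect_equal(det_off$x_px, det$x_px, tolerance = 1e-9)
  # uniform intensity rescaling: relative threshold, density unchanged
  mv_sc <- mv; mv_sc$pixels <- mv$pixels * 3.7
  mask_sc <- segment_cell(max_intensity_projection(mv_sc),
                          mv$pixel_size_um)
  det_sc <- detect_movie(mv_sc, mask_sc)
  rho <- patch_stats(det, mask, 12)$density_um2
  rho_sc <- patch_stats(det_sc, mask_sc, 12)$density_um2
  expect_equal(rho_sc, rho, tolerance = 1e-9)
})

test_that("patch density is the mean count over the cell area", {
  det <- det_df(rep(0:29, each = 8), runif(240, 0, 20), runif(240, 0, 20))
  ps <- patch_stats(det, 4.0, 30)
  expect_equal(ps$mean_count, 8)
  expect_equal(ps$density_um2, 2.0)
  expect_equal(patch_stats(det_df(integer(0), numeric(0), numeric(0)),
                           4.0, 30)$density_um2, 0)
  expect_error(patch_stats(det, 0, 30), "area")
})

test_that("kymographs map motion along the line to ridge slope", {
  # static spot: vertical ridge at a constant position
  frames <- array(0, c(20, 40, 8))
  for (f in 1:8) frames[, , f] <-
    render_single_spot(15, 10, 100, H = 20, W = 40, background = 0)
  mv <- patch_movie(frames)
  k <- kymograph(mv, c(5, 10), c(35, 10))
  expect_equal(dim(k), c(31, 8))
  expect_equal(unique(apply(k, 2, which.max)), 11)  # 15 - 5 + 1
  # moving 1 px/frame: ridge advances one row per column
  for (f in 1:8) frames[, , f] <-
    render_single_spot(10 + (f - 1), 10, 100, H = 20, W = 40,
                       background = 0)
  mv2 <- patch_movie(frames)
  k2 <- kymograph(mv2, c(5, 10), c(35, 10))
  expect_equal(apply(k2, 2, which.max), 6:13)
  expect_error(kymograph(mv, c(5, 10), c(5, 10)), "degenerate")
})
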