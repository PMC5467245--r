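test_that("MSD equals the brute-force all-pairs oracle", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    xy <- cbind(cumsum(rnorm(n, 0, 0.05)), cumsum(rnorm(n, 0, 0.05)))
    tr <- data.frame(x_um = xy[, 1], y_um = xy[, 2])
    m <- compute_msd(tr, frame_interval_s = 1)
    expect_equal(m$msd_um2, msd_oracle(xy), tolerance = 1e-12)
    expect_equal(nrow(m), floor(7 / 8 * (n - 1)))
    expect_equal(m$n_pairs, n - seq_len(nrow(m)))
  }
})

test_that("MSD honours closed forms and the 7/8 lag rule", {
  # stationary track: all zero
  still <- data.frame(x_um = rep(1, 10), y_um = rep(2, 10))
  expect_true(all(compute_msd(still)$msd_um2 == 0))
  # constant velocity 0.055 um/s: msd(4 s) = (0.055 * 4)^2 exactly
  tr <- linear_track(0.055, n = 20)
  m <- compute_msd(tr)
  expect_equal(m$msd_um2[m$lag_s == 4], (0.055 * 4)^2, tolerance = 1e-12)
  # 17-point track (16 s duration): lags 1..14 only
  m17 <- compute_msd(linear_track(0.05, n = 17))
  expect_equal(m17$lag_s, 1:14)
  expect_error(compute_msd(data.frame(x_um = 1, y_um = 1)), "2 points")
})

test_that("model fits are exact on noiseless profiles", {
  tt <- 1:10
  msd_dir <- structure(data.frame(lag_s = tt, msd_um2 = (0.055 * tt)^2,
                                  n_pairs = 11 - tt),
                       class = c("msd_profile", "data.frame"))
  fd <- fit_directed(msd_dir)
  expect_equal(fd$nu_um_s, 0.055, tolerance = 1e-10)
  expect_equal(fd$r2, 1, tolerance = 1e-10)
  msd_rnd <- msd_dir; msd_rnd$msd_um2 <- 4 * 0.002 * tt
  fr <- fit_random(msd_rnd)
  expect_equal(fr$d_um2_s, 0.002, tolerance = 1e-10)
  expect_equal(fr$r2, 1, tolerance = 1e-10)
  # cross-fits: the wrong model explains less variance
  expect_lt(fit_directed(msd_rnd)$r2, fit_random(msd_rnd)$r2)
  expect_lt(fit_random(msd_dir)$r2, fit_directed(msd_dir)$r2)
  # all-zero profile: zero estimates
  msd_0 <- msd_dir; msd_0$msd_um2 <- 0
  expect_equal(fit_directed(msd_0)$nu_um_s, 0)
  expect_equal(fit_random(msd_0)$d_um2_s, 0)
})

test_that("the classification rule follows the R2 and plateau criteria", {
  mk <- function(r2d, r2r, maxmsd)
    list(r2_directed = r2d, r2_random = r2r, max_msd_um2 = maxmsd)
  expect_equal(classify_track(mk(0.99, 0.7, 0.3)), "directed")
  expect_equal(classify_track(mk(0.7, 0.95, 0.3)), "random")
  expect_equal(classify_track(mk(0.5, 0.5, 0.01)), "constrained")
  expect_equal(classify_track(mk(0.5, 0.5, 0.2)), "unclassified")
  # directed wins ties at the threshold
  expect_equal(classify_track(mk(0.9, 0.9, 0.3)), "directed")
  expect_equal(classify_track(mk(0.79, 0.79, 0.049)), "constrained")
})

test_that("simulated populations classify to their generating mode", {
  set.seed(52)
  n_per <- 300
  cls_dir <- replicate(n_per, {
    tr <- linear_track(0.055, n = 16, heading = runif(1, 0, 2 * pi),
                       sigma_loc = 0.02)
    classify_track(fit_motion(tr))
  })
  expect_gte(mean(cls_dir == "directed"), 0.9)
  cls_bro <- replicate(n_per, {
    tr <- simulate_brownian_track(0.002, n = 26)
    tr$x_um <- tr$x_um + rnorm(26, 0, 0.02)
    tr$y_um <- tr$y_um + rnorm(26, 0, 0.02)
    classify_track(fit_motion(tr))
  })
  expect_lte(mean(cls_bro == "directed"), 0.15)
  cls_con <- replicate(n_per, {
    tr <- simulate_confined_track(0.15, 0.002, n = 120)
    tr$x_um <- tr$x_um + rnorm(120, 0, 0.02)
    tr$y_um <- tr$y_um + rnorm(120, 0, 0.02)
    classify_track(fit_motion(tr))
  })
  expect_gte(mean(cls_con == "constrained"), 0.8)
})

test_that("classification scales consistently with coordinate units", {
  set.seed(53)
  tr <- linear_track(0.055, n = 15, sigma_loc = 0.01)
  f1 <- fit_motion(tr)
  c_scale <- 3
  tr2 <- tr; tr2$x_um <- tr$x_um * c_scale; tr2$y_um <- tr$y_um * c_scale
  f2 <- fit_motion(tr2)
  expect_equal(f2$nu_um_s, c_scale * f1$nu_um_s, tolerance = 1e-10)
  expect_equal(f2$d_um2_s, c_scale^2 * f1$d_um2_s, tolerance = 1e-10)
  expect_equal(f2$r2_directed, f1$r2_directed, tolerance = 1e-10)
  expect_equal(f2$r2_random, f1$r2_random, tolerance = 1e-10)
})

test_that("CDF-based diffusion estimation matches closed form and truth", {
  # closed form: D = mean(r^2) / (4 dt)
  tr <- data.frame(x_um = cumsum(c(0, rep(sqrt(0.008 / 2), 60))),
                   y_um = cumsum(c(0, rep(sqrt(0.008 / 2), 60))))
  est <- estimate_D_cdf(tr, frame_interval_s = 1)
  expect_equal(est$d_mle_um2_s, 0.002, tolerance = 1e-12)
  # simulated population: within 15%, MLE and CDF fit agree
  set.seed(54)
  trs <- lapply(1:60, function(i) simulate_brownian_track(0.002, n = 26))
  est2 <- estimate_D_cdf(trs)
  expect_equal(est2$d_mle_um2_s, 0.002, tolerance = 0.15)
  expect_equal(est2$d_cdf_um2_s, est2$d_mle_um2_s, tolerance = 0.2)
  # degenerate: all-zero displacements
  zz <- data.frame(x_um = rep(0, 100), y_um = rep(0, 100))
  expect_equal(estimate_D_cdf(zz)$d_mle_um2_s, 0)
  expect_error(estimate_D_cdf(data.frame(x_um = 1:5 * 0.1, y_um = 0)),
               "samples")
})

test_that("per-cell summaries aggregate instantaneous fractions", {
  # 10 synchronous equal-length tracks: 4 directed, 3 random,
  # 2 constrained, 1 unclassified
  n <- 10
  linked <- do.call(rbind, lapply(1:10, function(id)
    data.frame(track_id = id, frame = 0:(n - 1),
               x_px = id * 5, y_px = id * 5,
               x_um = id * 0.32, y_um = id * 0.32, amplitude = 1)))
  classes <- data.frame(
    track_id = as.character(1:10), n_points = n,
    motion_class = rep(c("directed", "random", "constrained",
                         "unclassified"), c(4, 3, 2, 1)),
    nu_um_s = 0.05, d_um2_s = 0.002, r2_directed = 0.9, r2_random = 0.5,
    max_msd_um2 = 0.1)
  s <- summarize_cell(linked, classes, mask = 4.0, n_frames = n)
  expect_equal(s$theta_d, 0.4)
  expect_equal(s$theta_r, 0.3)
  expect_equal(s$theta_c, 0.2)
  expect_equal(s$theta_u, 0.1)
  expect_equal(s$theta_d + s$theta_r + s$theta_c + s$theta_u, 1,
               tolerance = 1e-9)
  expect_equal(s$rho_um2, 10 / 4.0)
  expect_equal(s$rho_d_um2, 0.4 * 10 / 4.0)
  expect_lte(s$rho_d_um2, s$rho_um2)
  # short tracks count as unclassified in the fractions
  classes$n_points[1] <- 4
  classes$motion_class[1] <- "unclassified"
  s2 <- summarize_cell(linked, classes, mask = 4.0, n_frames = n)
  expect_equal(s2$theta_d, 0.3)
  expect_equal(s2$theta_u, 0.2)
})

test_that("bootstrap standard errors are calibrated and scale as 1/sqrt(n)", {
  # constant statistic: zero SE
  trs <- lapply(1:20, function(i) data.frame(v = rnorm(5)))
  expect_equal(bootstrap_se(trs, function(x) 42, B = 50, seed = 1), 0)
  # SE of a mean of iid values ~ SD/sqrt(n)
  set.seed(55)
  vals <- rnorm(80, 10, 2)
  tracks <- as.list(vals)
  stat <- function(x) mean(unlist(x))
  se <- bootstrap_se(tracks, stat, B = 1000, seed = 2)
  expect_equal(se, sd(vals) / sqrt(80), tolerance = 0.1)
  # doubling n shrinks the SE by ~sqrt(2)
  set.seed(56)
  vals2 <- rnorm(160, 10, 2)
  se2 <- bootstrap_se(as.list(vals2), stat, B = 1000, seed = 3)
  expect_equal(se / se2, sqrt(2), tolerance = 0.15)
  expect_error(bootstrap_se(list(1), stat), "at least 2")
  # seeded: reproducible
  expect_identical(bootstrap_se(tracks, stat, B = 200, seed = 9),
                   bootstrap_se(tracks, stat, B = 200, seed = 9))
})
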