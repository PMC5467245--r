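test_that("directed tracks obey the circumferential projection law", {
  geom <- default_geom()
  # at the cell bottom (phi = 0) the projected speed equals the surface
  # speed; estimate instantaneously with a fine time step
  tr <- simulate_directed_track(geom, 0.055, start_angle = 0, n = 2,
                                dt = 1e-4)
  v0 <- (tr$y_um[2] - tr$y_um[1]) / 1e-4
  expect_equal(v0, 0.055, tolerance = 1e-4)
  # frame-wise apparent speed follows nu * cos(phi) along the whole arc
  tr <- simulate_directed_track(geom, 0.055, start_angle = -1, n = 30,
                                dt = 0.2)
  phi <- -1 + 2 * 0.055 * tr$t / geom$diameter_um
  v_app <- diff(tr$y_um) / 0.2
  v_pred <- 0.055 * cos((phi[-1] + phi[-30]) / 2)
  expect_equal(v_app, v_pred, tolerance = 1e-3)
  # zero speed: stationary
  tr0 <- simulate_directed_track(geom, 0, start_angle = 0.3, n = 10)
  expect_equal(length(unique(tr0$y_um)), 1L)
  expect_error(simulate_directed_track(geom, 0.05, n = 5, dt = 0))
})

test_that("visible fraction matches the closed form and numeric sampling", {
  expect_equal(visible_fraction(0.89, 0.2), acos(1 - 2 * 0.2 / 0.89) / pi)
  expect_lt(abs(visible_fraction(0.89, 0.2) - 0.314), 1e-3)
  # numeric cross-check: sample the circumference uniformly and count
  # points whose height is within the penetration depth
  for (d in c(0.6, 0.89, 1.2)) for (h in c(0.1, 0.2, 0.4)) {
    phi <- seq(-pi, pi, length.out = 2e5)
    z <- (d / 2) * (1 - cos(phi))
    expect_equal(mean(z <= h), visible_fraction(d, h), tolerance = 1e-3)
  }
  expect_equal(visible_fraction(0.89, 1.0), 1)  # h >= D: all visible
  # directed-track visibility agrees with the fraction
  geom <- default_geom()
  tr <- simulate_directed_track(geom, 0.055, start_angle = 0, n = 2000,
                                dt = 1)  # many full revolutions
  expect_equal(mean(tr$visible), visible_fraction(geom), tolerance = 0.01)
})

test_that("Brownian tracks have the exact increment statistics", {
  expect_equal(simulate_brownian_track(0, n = 10, seed = 1)$x_um,
               rep(0, 10))
  # ensemble mean squared 1-frame displacement = 4 D dt
  set.seed(11)
  d_true <- 0.002
  disp2 <- replicate(200, {
    tr <- simulate_brownian_track(d_true, n = 51, dt = 1)
    sum(diff(tr$x_um)^2 + diff(tr$y_um)^2) / 50
  })
  mc_se <- sd(disp2) / sqrt(length(disp2))
  expect_lt(abs(mean(disp2) - 4 * d_true), 3 * mc_se)
  # reproducibility
  expect_identical(simulate_brownian_track(0.002, 20, seed = 7),
                   simulate_brownian_track(0.002, 20, seed = 7))
  expect_error(simulate_brownian_track(-1, 10))
})

test_that("confined tracks plateau at the reflecting-disk closed form", {
  # stationary-uniform oracle: E|r1 - r2|^2 for two independent uniform
  # points in a disk of radius R equals R^2
  set.seed(21)
  R <- 0.15
  pts <- matrix(ncol = 2, nrow = 4e4)
  k <- 0
  while (k < nrow(pts)) {
    p <- runif(2, -R, R)
    if (sum(p^2) <= R^2) { k <- k + 1; pts[k, ] <- p }
  }
  i <- sample(nrow(pts)); j <- sample(nrow(pts))
  oracle <- mean(rowSums((pts[i, ] - pts[j, ])^2))
  expect_equal(oracle, R^2, tolerance = 0.03)
  # simulated long-lag MSD approaches the plateau
  set.seed(22)
  long_msd <- replicate(300, {
    tr <- simulate_confined_track(R, 0.002, n = 120, dt = 1, seed = NULL)
    m <- compute_msd(tr)
    mean(m$msd_um2[m$lag_s >= 60])
  })
  expect_equal(mean(long_msd), R^2, tolerance = 0.1)
  # max time-averaged MSD below the constrained plateau bound
  set.seed(23)
  max_msd <- replicate(200, {
    tr <- simulate_confined_track(R, 0.002, n = 120)
    max(compute_msd(tr)$msd_um2)
  })
  expect_gte(mean(max_msd < 0.05), 0.95)
  # large-R limit reproduces free diffusion at short lags
  set.seed(24)
  tr_free <- simulate_confined_track(100, 0.002, n = 2000)
  m1 <- mean(diff(tr_free$x_um)^2 + diff(tr_free$y_um)^2)
  expect_equal(m1, 4 * 0.002, tolerance = 0.15)
  expect_error(simulate_confined_track(0, 0.002, 10))
})

test_that("compose_population respects fractions, density and ground truth", {
  geom <- default_geom()
  cfg <- sim_config(theta_d = 1, theta_r = 0, theta_c = 0,
                    n_frames = 40, seed = 3)
  truth <- compose_population(cfg, geom)
  expect_true(all(truth$mode == "directed"))
  expect_true(all(c("track_id", "frame", "mode", "x_um", "y_um",
                    "visible") %in% names(truth)))
  # visible patches per frame track the configured density
  cfg2 <- sim_config(n_frames = 60, seed = 4)
  truth2 <- compose_population(cfg2, geom)
  per_frame <- table(factor(truth2$frame[truth2$visible], levels = 0:59))
  target <- cfg2$patch_density_um2 * visible_area(geom)
  expect_equal(mean(per_frame), target, tolerance = 0.25)
  # equal fractions: instantaneous mode shares near thirds (pooled seeds)
  shares <- sapply(5:10, function(s) {
    tr <- compose_population(sim_config(n_frames = 80, seed = s), geom)
    tv <- tr[tr$visible, ]
    mean(tv$mode == "directed")
  })
  expect_equal(mean(shares), 1 / 3, tolerance = 0.3)
  # determinism: identical config implies identical output
  expect_identical(compose_population(cfg2, geom),
                   compose_population(cfg2, geom))
})

test_that("rendered movies have the configured noise and PSF properties", {
  geom <- default_geom()
  # empty movie: frame mean ~ background, variance ~ shot + read
  cfg <- sim_config(n_frames = 20, background = 100, read_noise_sd = 2,
                    cell_background = 0, seed = 6)
  empty <- truth_skeleton <- compose_population(
    sim_config(theta_d = 0, theta_r = 0, theta_c = 0, n_frames = 20,
               patch_density_um2 = 1e-9, seed = 6), geom)
  mv <- render_movie(empty[0, ], geom, cfg, cell_body = FALSE)
  px <- as.numeric(mv$pixels)
  expect_equal(mean(px), 100, tolerance = 0.01 * 100)
  expect_equal(var(px), 100 + 4, tolerance = 0.1 * 104)
  expect_true(all(px >= 0))
  # single static spot, no noise: peak at the spot, centroid error small
  tr1 <- data.frame(track_id = 1, frame = 0, mode = "constrained",
                    x_um = 1.5, y_um = 0, z_um = 0, visible = TRUE,
                    true_speed_um_s = NA, true_D_um2_s = NA)
  cfg1 <- sim_config(n_frames = 1, seed = 7)
  mv1 <- render_movie(tr1, geom, cfg1, noise = FALSE, cell_body = FALSE)
  fr <- mv1$pixels[, , 1] - cfg1$background
  pk <- which(fr == max(fr), arr.ind = TRUE)
  tru <- attr(mv1, "truth")
  expect_equal(unname(pk[1, 2]) - 1, round(tru$x_px))
  expect_equal(unname(pk[1, 1]) - 1, round(tru$y_px))
  cx <- sum(t(fr) * (seq_len(ncol(fr)) - 1)) / sum(fr)
  expect_lt(abs(cx - tru$x_px), 0.05)
  # spot at surface height z = h is attenuated by exactly 1/e
  tr_h <- tr1; tr_h$z_um <- geom$penetration_depth_um
  mv_h <- render_movie(tr_h, geom, cfg1, noise = FALSE, cell_body = FALSE)
  expect_equal(max(mv_h$pixels[, , 1] - cfg1$background),
               max(fr) * exp(-1), tolerance = 1e-6)
  # byte-identical re-render under the same config
  cfg_n <- sim_config(n_frames = 5, seed = 8)
  t5 <- compose_population(cfg_n, geom)
  expect_identical(render_movie(t5, geom, cfg_n)$pixels,
                   render_movie(t5, geom, cfg_n)$pixels)
})

test_that("movies round-trip through 16-bit TIFF with sidecar metadata", {
  geom <- default_geom()
  cfg <- sim_config(n_frames = 3, seed = 9)
  mv <- simulate_movie(cfg, geom)
  path <- file.path(tempdir(), "mv.tif")
  write_movie_tiff(mv, path)
  expect_true(file.exists(paste0(path, ".json")))
  expect_true(file.exists(file.path(tempdir(), "mv_truth.csv")))
  back <- read_movie_tiff(path)
  expect_equal(back$pixel_size_um, mv$pixel_size_um)
  expect_equal(back$frame_interval_s, mv$frame_interval_s)
  # 16-bit quantization: within one count
  expect_lt(max(abs(back$pixels - round(mv$pixels))), 1.01)
})
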