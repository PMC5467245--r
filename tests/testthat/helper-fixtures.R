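# shared fixtures and independent oracles

default_geom <- function() cell_geometry(3, 0.89, 0.2)

# brute-force all-pairs time-averaged MSD (independent of compute_msd)
msd_oracle <- function(xy, dt = 1) {
  n <- nrow(xy)
  max_lag <- floor(7 / 8 * (n - 1))
  vapply(seq_len(max_lag), function(k) {
    acc <- 0
    for (i in 1:(n - k))
      acc <- acc + sum((xy[i + k, ] - xy[i, ])^2)
    acc / (n - k)
  }, numeric(1))
}

# ideal 2D directed track: straight line at constant speed (the
# MSD(t) = (nu t)^2 motion model), with optional localization noise
linear_track <- function(nu, n, dt = 1, heading = 0, sigma_loc = 0) {
  tt <- (seq_len(n) - 1) * dt
  data.frame(x_um = cos(heading) * nu * tt + rnorm(n, 0, sigma_loc),
             y_um = sin(heading) * nu * tt + rnorm(n, 0, sigma_loc))
}

# paint a filled rotated rectangle (rod) into a matrix
paint_rod <- function(nrow_px, ncol_px, length_px, width_px,
                      angle = 0, value = 200, background = 0) {
  img <- matrix(background, nrow_px, ncol_px)
  cy <- (nrow_px + 1) / 2
  cx <- (ncol_px + 1) / 2
  for (r in seq_len(nrow_px)) for (c in seq_len(ncol_px)) {
    u <- (c - cx) * cos(angle) + (r - cy) * sin(angle)
    v <- -(c - cx) * sin(angle) + (r - cy) * cos(angle)
    if (abs(u) <= length_px / 2 && abs(v) <= width_px / 2)
      img[r, c] <- value
  }
  img
}

# render a single Gaussian spot on a flat background (no cell body)
render_single_spot <- function(x_px, y_px, amplitude, H = 24, W = 24,
                               sigma_px = 1.25, background = 100,
                               noise = FALSE, read_noise = 2,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  img <- outer(seq_len(H) - 1, seq_len(W) - 1, function(r, c)
    amplitude * exp(-((r - y_px)^2 + (c - x_px)^2) / (2 * sigma_px^2))) +
    background
  if (noise) img <- matrix(rpois(H * W, img), H, W) +
      matrix(rnorm(H * W, 0, read_noise), H, W)
  img
}

# detections data frame helper
det_df <- function(frame, x, y) {
  data.frame(frame = frame, x_px = x, y_px = y,
             x_um = x * 0.064, y_um = y * 0.064,
             amplitude = rep(1, length(frame)))
}
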