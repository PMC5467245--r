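#' Simulation configuration
#'
#' Collects the ground-truth parameters of the synthetic patch population
#' and the imaging model. Defaults correspond to the steady-state TIRFM
#' conditions the analysis is designed for: 64 nm pixels, 1 s frame
#' intervals over 2-min movies, ~2 patches per um^2 split roughly in thirds
#' between directed (55 nm/s circumferential), Brownian
#' (0.002 um^2/s) and confined (reflecting disk, R = 0.15 um) motion.
#'
#' @param theta_d,theta_r,theta_c Fractions of directed, randomly diffusing
#'   and confined patches; the remainder (1 - sum) is simulated as
#'   mixed-mode ("unclassifiable") tracks.
#' @param directed_speed_um_s Circumferential speed nu of directed patches
#'   (um/s).
#' @param diffusion_um2_s Diffusion coefficient D of Brownian patches
#'   (um^2/s).
#' @param confinement_radius_um Reflecting-disk radius R of confined
#'   patches (um).
#' @param patch_density_um2 Target visible patch density rho (patches per
#'   um^2 of visible projected area).
#' @param n_frames Number of frames.
#' @param frame_interval_s Frame interval (s).
#' @param pixel_size_um Pixel size (um).
#' @param psf_sigma_um Gaussian PSF sigma (um); ~0.08 um gives the
#'   ~300 nm apparent patch width of a diffraction-limited spot.
#' @param amplitude Peak photon count of a patch at the coverslip (counts).
#' @param background Uniform background level (counts).
#' @param cell_background Additional fluorescence inside the cell footprint
#'   at the coverslip, decaying with surface height as exp(-z/h) (counts).
#' @param read_noise_sd Additive Gaussian camera read noise sd (counts).
#' @param loc_noise_um Localization noise sd applied to track-level
#'   fixtures (um); not used when rendering movies.
#' @param mean_lifetime_frames Mean patch lifetime (frames) before
#'   dissociation; lifetimes are geometric.
#' @param margin_um Dark margin around the cell footprint in rendered
#'   movies (um).
#' @param seed Integer seed; identical configurations produce identical
#'   output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(theta_d = 1 / 3, theta_r = 1 / 3, theta_c = 1 / 3,
                       directed_speed_um_s = 0.055,
                       diffusion_um2_s = 0.002,
                       confinement_radius_um = 0.15,
                       patch_density_um2 = 2,
                       n_frames = 120, frame_interval_s = 1,
                       pixel_size_um = 0.064, psf_sigma_um = 0.08,
                       amplitude = 145, background = 100,
                       cell_background = 30,
                       read_noise_sd = 2, loc_noise_um = 0.02,
                       mean_lifetime_frames = 20,
                       margin_um = 0.35, seed = 1L) {
  cfg <- list(theta_d = theta_d, theta_r = theta_r, theta_c = theta_c,
              directed_speed_um_s = directed_speed_um_s,
              diffusion_um2_s = diffusion_um2_s,
              confinement_radius_um = confinement_radius_um,
              patch_density_um2 = patch_density_um2,
              n_frames = as.integer(n_frames),
              frame_interval_s = frame_interval_s,
              pixel_size_um = pixel_size_um, psf_sigma_um = psf_sigma_um,
              amplitude = amplitude, background = background,
              cell_background = cell_background,
              read_noise_sd = read_noise_sd, loc_noise_um = loc_noise_um,
              mean_lifetime_frames = mean_lifetime_frames,
              margin_um = margin_um, seed = as.integer(seed))
  th <- c(theta_d, theta_r, theta_c)
  if (any(th < 0) || any(th > 1) || sum(th) > 1 + 1e-12)
    stop("fractions must lie in [0,1] and sum to at most 1")
  pos <- c("directed_speed_um_s", "diffusion_um2_s",
           "confinement_radius_um", "patch_density_um2", "n_frames",
           "frame_interval_s", "pixel_size_um", "psf_sigma_um")
  for (f in pos) if (!(cfg[[f]] >= 0) || (f != "directed_speed_um_s" &&
                                          f != "diffusion_um2_s" && cfg[[f]] <= 0))
    stop("field ", f, " must be positive")
  structure(cfg, class = "sim_config")
}

#' Simulate a directed (circumferential) patch trajectory
#'
#' The patch moves at constant surface speed `speed_um_s` around the
#' circumference of the cylinder, at fixed axial position. The surface
#' angle advances by 2 v dt / D per frame; the projected lateral
#' coordinate is y(t) = (D/2) sin(phi(t)) and the axial coordinate is
#' constant. Frames whose surface height (D/2)(1 - cos phi) exceeds the
#' evanescent penetration depth are flagged invisible.
#'
#' @param geom A [cell_geometry()].
#' @param speed_um_s Circumferential speed nu (um/s), >= 0.
#' @param start_angle Initial azimuthal angle (rad; 0 = cell bottom).
#' @param axial_pos_um Axial position along the cylinder (um).
#' @param n Number of frames.
#' @param dt Frame interval (s), > 0.
#' @param loc_noise_um Gaussian localization noise sd added to the
#'   projected coordinates (um).
#' @param seed Optional integer seed (only used when `loc_noise_um > 0`).
#' @return A data frame with columns `t`, `x_um`, `y_um`, `z_um`,
#'   `visible`.
#' @export
simulate_directed_track <- function(geom, speed_um_s, start_angle = 0,
                                    axial_pos_um = NULL, n = 20, dt = 1,
                                    loc_noise_um = 0, seed = NULL) {
  stopifnot(inherits(geom, "cell_geometry"))
  if (!(dt > 0)) stop("dt must be positive")
  if (speed_um_s < 0) stop("speed must be non-negative")
  r <- geom$diameter_um / 2
  if (is.null(axial_pos_um)) axial_pos_um <- geom$length_um / 2
  tt <- (seq_len(n) - 1) * dt
  phi <- start_angle + 2 * speed_um_s * tt / geom$diameter_um
  x <- rep(axial_pos_um, n)
  y <- r * sin(phi)
  z <- r * (1 - cos(phi))
  if (loc_noise_um > 0) {
    if (!is.null(seed)) set.seed(seed)
    x <- x + rnorm(n, 0, loc_noise_um)
    y <- y + rnorm(n, 0, loc_noise_um)
  }
  data.frame(t = tt, x_um = x, y_um = y, z_um = z,
             visible = z <= geom$penetration_depth_um)
}

#' Simulate a Brownian patch trajectory
#'
#' Independent Gaussian increments with per-axis variance 2 D dt.
#'
#' @param d_um2_s Diffusion coefficient D (um^2/s), >= 0.
#' @param n Number of points.
#' @param dt Frame interval (s).
#' @param origin Starting position, length-2 numeric (um).
#' @param seed Optional integer seed.
#' @return A data frame with columns `t`, `x_um`, `y_um`.
#' @export
simulate_brownian_track <- function(d_um2_s, n = 25, dt = 1,
                                    origin = c(0, 0), seed = NULL) {
  if (d_um2_s < 0) stop("diffusion coefficient must be non-negative")
  if (!(dt > 0)) stop("dt must be positive")
  if (!is.null(seed)) set.seed(seed)
  s <- sqrt(2 * d_um2_s * dt)
  x <- origin[1] + cumsum(c(0, rnorm(n - 1, 0, s)))
  y <- origin[2] + cumsum(c(0, rnorm(n - 1, 0, s)))
  data.frame(t = (seq_len(n) - 1) * dt, x_um = x, y_um = y)
}

reflect_disk <- function(p, center, radius) {
  # radial mirror at the disk boundary; repeated for (rare) large steps
  for (i in 1:8) {
    d <- sqrt(sum((p - center)^2))
    if (d <= radius) break
    p <- center + (p - center) * (2 * radius - d) / d
    if (2 * radius - d < 0) p <- center  # pathological step: recenter
  }
  p
}

#' Simulate a confined patch trajectory (reflecting disk)
#'
#' Brownian steps reflected at a disk boundary of radius `radius_um`. The
#' long-lag time-averaged MSD plateaus at approximately R^2 (the mean
#' squared distance between two independent uniform points in a disk).
#'
#' @param radius_um Confinement radius R (um), > 0.
#' @param d_um2_s Diffusion coefficient inside the disk (um^2/s).
#' @param n Number of points.
#' @param dt Frame interval (s).
#' @param center Disk center (um).
#' @param seed Optional integer seed.
#' @return A data frame with columns `t`, `x_um`, `y_um`.
#' @export
simulate_confined_track <- function(radius_um, d_um2_s = 0.002, n = 120,
                                    dt = 1, center = c(0, 0), seed = NULL) {
  if (!(radius_um > 0)) stop("confinement radius must be positive")
  if (d_um2_s < 0) stop("diffusion coefficient must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  s <- sqrt(2 * d_um2_s * dt)
  p <- center
  out <- matrix(NA_real_, n, 2)
  out[1, ] <- p
  if (n > 1) for (i in 2:n) {
    p <- reflect_disk(p + rnorm(2, 0, s), center, radius_um)
    out[i, ] <- p
  }
  data.frame(t = (seq_len(n) - 1) * dt, x_um = out[, 1], y_um = out[, 2])
}

## --- population composition -------------------------------------------------

# one new track starting at frame f0 (1-based), mode in
# {"directed","random","constrained","mixed"}; returns per-frame rows.
new_track_rows <- function(id, mode, f0, geom, cfg) {
  dt <- cfg$frame_interval_s
  n_max <- cfg$n_frames - f0 + 1
  life <- 1 + stats::rgeom(1, 1 / cfg$mean_lifetime_frames)
  n <- min(life, n_max)
  r <- geom$diameter_um / 2
  w <- visible_width(geom)
  phi_max <- acos(1 - 2 * geom$penetration_depth_um / geom$diameter_um)
  ax_lo <- geom$diameter_um / 2
  ax_hi <- geom$length_um - geom$diameter_um / 2
  speed <- NA_real_
  dcoef <- NA_real_
  if (mode == "directed") {
    # processive rotors enter the evanescent field at one edge of the
    # visible arc and traverse it; their visible segment is a full
    # crossing of the illuminated strip (cell-width-spanning traces)
    speed <- cfg$directed_speed_um_s
    phi0 <- -phi_max + runif(1, 0, 1e-6)
    tr <- simulate_directed_track(geom, speed, start_angle = phi0,
                                  axial_pos_um = runif(1, ax_lo, ax_hi),
                                  n = n, dt = dt)
    if (runif(1) < 0.5) tr$y_um <- -tr$y_um  # opposite handedness
    # track ends when the patch leaves the evanescent field
    vis <- cumprod(tr$visible) > 0
    tr <- tr[vis, , drop = FALSE]
    n <- nrow(tr)
  } else if (mode == "random") {
    dcoef <- cfg$diffusion_um2_s
    tr <- simulate_brownian_track(dcoef, n = n, dt = dt,
                                  origin = c(runif(1, ax_lo, ax_hi),
                                             runif(1, -w / 2, w / 2)))
    inside <- abs(tr$y_um) <= w / 2 & tr$x_um >= ax_lo & tr$x_um <= ax_hi
    keep <- cumprod(inside) > 0  # dies on leaving the visible strip
    tr <- tr[keep, , drop = FALSE]
    n <- nrow(tr)
    tr$z_um <- approx_height(tr$y_um, r)
    tr$visible <- TRUE
  } else if (mode == "constrained") {
    dcoef <- cfg$diffusion_um2_s
    rr <- cfg$confinement_radius_um
    ylim <- max(w / 2 - rr, 0)
    ctr <- c(runif(1, ax_lo, ax_hi), runif(1, -ylim, ylim))
    tr <- simulate_confined_track(rr, dcoef, n = n, dt = dt, center = ctr)
    tr$z_um <- approx_height(tr$y_um, r)
    tr$visible <- TRUE
  } else { # mixed: directed then Brownian; ambiguous by construction
    n1 <- max(2, floor(n / 2))
    phi0 <- runif(1, -phi_max / 2, phi_max / 2)
    tr1 <- simulate_directed_track(geom, cfg$directed_speed_um_s,
                                   start_angle = phi0,
                                   axial_pos_um = runif(1, ax_lo, ax_hi),
                                   n = n1, dt = dt)
    tr1 <- tr1[cumprod(tr1$visible) > 0, , drop = FALSE]
    tr2 <- simulate_brownian_track(cfg$diffusion_um2_s,
                                   n = max(n - nrow(tr1) + 1, 2),
                                   dt = dt,
                                   origin = c(tr1$x_um[nrow(tr1)],
                                              tr1$y_um[nrow(tr1)]))
    tr <- data.frame(t = (seq_len(nrow(tr1) + nrow(tr2) - 1) - 1) * dt,
                     x_um = c(tr1$x_um, tr2$x_um[-1]),
                     y_um = c(tr1$y_um, tr2$y_um[-1]))
    n <- nrow(tr)
    tr$z_um <- approx_height(tr$y_um, r)
    tr$visible <- TRUE
  }
  if (n == 0) return(NULL)
  if (mode == "directed") {
    tr$z_um <- tr$z_um
  }
  data.frame(track_id = id, frame = f0 - 1 + seq_len(n) - 1, mode = mode,
             x_um = tr$x_um, y_um = tr$y_um, z_um = tr$z_um,
             visible = tr$visible,
             true_speed_um_s = speed, true_D_um2_s = dcoef)
}

# surface height above the coverslip for a membrane patch at projected
# lateral offset y (bottom half of the cylinder)
approx_height <- function(y, r) {
  y <- pmin(pmax(y, -r), r)
  r - sqrt(pmax(r^2 - y^2, 0))
}

#' Compose a synthetic patch population with ground truth
#'
#' Maintains a fixed number of patch "slots" so that the expected number of
#' visible patches per frame equals `patch_density_um2 x` [visible_area()].
#' Each slot holds a track whose motion mode is drawn from the configured
#' fractions; when a track ends (dissociation, or a directed patch rotating
#' out of the evanescent field, or a Brownian patch leaving the visible
#' strip) a new track is born in the next frame. Any remainder
#' 1 - (theta_d + theta_r + theta_c) is simulated as mixed-mode tracks.
#'
#' @param config A [sim_config()].
#' @param geom A [cell_geometry()].
#' @return A ground-truth data frame with one row per track per frame:
#'   `track_id`, `frame` (0-based), `mode`, `x_um`, `y_um`, `z_um`,
#'   `visible`, `true_speed_um_s`, `true_D_um2_s`.
#' @export
compose_population <- function(config, geom) {
  stopifnot(inherits(config, "sim_config"), inherits(geom, "cell_geometry"))
  set.seed(config$seed)
  a_vis <- visible_area(geom)
  n_slots <- max(1L, round(config$patch_density_um2 * a_vis))
  spacing <- sqrt(a_vis / n_slots)
  if (spacing < 2 * config$psf_sigma_um)
    warning("patch density so high that spots will merge in detection")
  modes <- c("directed", "random", "constrained", "mixed")
  theta <- c(config$theta_d, config$theta_r, config$theta_c)
  theta <- c(theta, max(0, 1 - sum(theta)))
  # The configured fractions are *instantaneous* (patch-frame-weighted)
  # fractions, as measured by the analysis. Modes differ in how long a
  # track stays visible (directed patches rotate out of the evanescent
  # field), so birth probabilities are weighted by the inverse expected
  # visible lifetime: p_birth(m) proportional to theta_m / E[frames_m].
  mean_vis <- vapply(modes, function(m) {
    if (theta[match(m, modes)] == 0) return(1)
    cfg2 <- config
    cfg2$n_frames <- as.integer(max(20 * config$mean_lifetime_frames, 200))
    set.seed(config$seed + 1000L + match(m, modes))
    mean(vapply(1:150, function(i) {
      tr <- new_track_rows(0L, m, 1L, geom, cfg2)
      if (is.null(tr)) 0 else sum(tr$visible)
    }, numeric(1)))
  }, numeric(1))
  probs <- theta / pmax(mean_vis, 0.5)
  probs <- probs / sum(probs)
  set.seed(config$seed)
  rows <- list()
  next_id <- 1L
  # per slot: chain of tracks until the movie ends
  for (s in seq_len(n_slots)) {
    f0 <- 1L
    while (f0 <= config$n_frames) {
      mode <- sample(modes, 1, prob = probs)
      tr <- new_track_rows(next_id, mode, f0, geom, config)
      next_id <- next_id + 1L
      if (is.null(tr)) { f0 <- f0 + 1L; next }
      rows[[length(rows) + 1L]] <- tr
      f0 <- max(tr$frame) + 2L  # reborn the frame after death
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$track_id, out$frame), ]
}

## --- rendering --------------------------------------------------------------

#' Render a synthetic TIRFM movie from ground-truth tracks
#'
#' Each visible patch is rendered as a symmetric 2D Gaussian of sigma
#' `psf_sigma_um`, with amplitude attenuated by the evanescent field as
#' exp(-z/h) where z is the surface height of the patch. A cell-footprint
#' background (the TIRF-illuminated strip of the cylindrical sidewall,
#' with the same exp(-z/h) lateral decay) and a uniform offset are added;
#' shot noise is Poisson on the total signal and camera read noise is
#' additive Gaussian. Output pixels are non-negative.
#'
#' Image coordinates: `x` (columns) runs along the cell axis, `y` (rows)
#' across it; the cell axis is centered in the image with a dark margin of
#' `margin_um` on all sides. Pixel centers sit at integer (0-based)
#' coordinates: `x_px = (x_um + margin - 0) / pixel_size`, etc.
#'
#' @param truth Ground-truth data frame from [compose_population()] (may be
#'   empty for a noise-only movie).
#' @param geom A [cell_geometry()].
#' @param config A [sim_config()].
#' @param noise Logical; set `FALSE` for a noiseless rendering.
#' @param cell_body Logical; render the cell-footprint background.
#' @return A [patch_movie()] whose `truth` attribute carries the input
#'   table augmented with pixel coordinates `x_px`, `y_px`.
#' @export
render_movie <- function(truth, geom, config, noise = TRUE,
                         cell_body = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 777L)
  px <- config$pixel_size_um
  m <- config$margin_um
  h <- geom$penetration_depth_um
  W <- as.integer(ceiling((geom$length_um + 2 * m) / px))
  H <- as.integer(ceiling((geom$diameter_um + 2 * m) / px))
  x0_um <- -m                      # um coordinate of pixel column 0
  y0_um <- -(geom$diameter_um / 2 + m)  # um coordinate of pixel row 0
  to_px_x <- function(x) (x - x0_um) / px
  to_px_y <- function(y) (y - y0_um) / px
  # static cell-footprint signal (photons)
  body <- matrix(0, H, W)
  if (cell_body) {
    # smooth capsule: evanescent decay exp(-z/h) of the membrane height
    # z(x, y) over cylinder plus hemispherical poles (no sharp edges)
    yy <- (seq_len(H) - 1) * px + y0_um
    xx <- (seq_len(W) - 1) * px + x0_um
    r <- geom$diameter_um / 2
    dx <- pmax(pmax(r - xx, xx - (geom$length_um - r)), 0)
    rad2 <- outer(yy^2, dx^2, "+")  # squared distance from the axis
    zz <- ifelse(rad2 < r^2, r - sqrt(pmax(r^2 - rad2, 0)), Inf)
    body <- config$cell_background * exp(-zz / h)
  }
  sig_px <- config$psf_sigma_um / px
  frames <- array(0, dim = c(H, W, config$n_frames))
  if (nrow(truth) > 0) {
    truth$x_px <- to_px_x(truth$x_um)
    truth$y_px <- to_px_y(truth$y_um)
    vis <- truth[truth$visible, , drop = FALSE]
    half <- ceiling(5 * sig_px)
    for (i in seq_len(nrow(vis))) {
      f <- vis$frame[i] + 1L
      cx <- vis$x_px[i]; cy <- vis$y_px[i]
      amp <- config$amplitude * exp(-vis$z_um[i] / h)
      cols <- max(1, floor(cx + 1 - half)):min(W, ceiling(cx + 1 + half))
      rws <- max(1, floor(cy + 1 - half)):min(H, ceiling(cy + 1 + half))
      if (!length(cols) || !length(rws)) next
      gx <- exp(-((cols - 1 - cx)^2) / (2 * sig_px^2))
      gy <- exp(-((rws - 1 - cy)^2) / (2 * sig_px^2))
      frames[rws, cols, f] <- frames[rws, cols, f] + amp * outer(gy, gx)
    }
  } else {
    truth$x_px <- numeric(0)
    truth$y_px <- numeric(0)
  }
  for (f in seq_len(config$n_frames)) {
    signal <- frames[, , f] + body + config$background
    if (noise) {
      img <- rpois(length(signal), signal) +
        rnorm(length(signal), 0, config$read_noise_sd)
      img <- pmax(matrix(img, H, W), 0)
    } else img <- signal
    frames[, , f] <- img
  }
  mv <- patch_movie(frames, pixel_size_um = px,
                    frame_interval_s = config$frame_interval_s)
  attr(mv, "truth") <- truth
  attr(mv, "geom") <- geom
  attr(mv, "config") <- config
  mv
}

#' Simulate a complete annotated movie
#'
#' Convenience wrapper: [compose_population()] then [render_movie()].
#'
#' @inheritParams render_movie
#' @param config A [sim_config()].
#' @param geom A [cell_geometry()].
#' @return A [patch_movie()] with a `truth` attribute.
#' @export
simulate_movie <- function(config = sim_config(), geom = cell_geometry(),
                           noise = TRUE) {
  truth <- compose_population(config, geom)
  render_movie(truth, geom, config, noise = noise)
}
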