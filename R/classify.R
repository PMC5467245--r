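#' Time-averaged mean squared displacement of a track
#'
#' MSD(n dt) = mean over i of |r(i+n) - r(i)|^2, using all overlapping
#' ordered same-lag pairs, for lags n = 1 ... floor(7/8 x (n_points - 1)):
#' lag times no longer than 7/8 of the track duration.
#'
#' @param track Data frame with `x_um`, `y_um` (ordered, gap-free), or a
#'   two-column matrix of coordinates.
#' @param frame_interval_s Frame interval (s).
#' @return Data frame of class `msd_profile`: `lag_s`, `msd_um2`,
#'   `n_pairs`. Zero rows for 2-point tracks (no admissible lag).
#' @export
compute_msd <- function(track, frame_interval_s = 1) {
  xy <- as.matrix(if (is.data.frame(track)) track[, c("x_um", "y_um")]
                  else track)
  n <- nrow(xy)
  if (n < 2) stop("track must have at least 2 points")
  max_lag <- floor(7 / 8 * (n - 1))
  lags <- seq_len(max_lag)
  msd <- vapply(lags, function(k) {
    d <- xy[(k + 1):n, , drop = FALSE] - xy[1:(n - k), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  structure(data.frame(lag_s = lags * frame_interval_s, msd_um2 = msd,
                       n_pairs = n - lags),
            class = c("msd_profile", "data.frame"))
}

# R^2 about the (weighted) mean for a no-intercept fit; constant profiles
# have no variance to explain and get R^2 = 0 by convention (documented).
.r2 <- function(obs, fitted, w = NULL) {
  if (is.null(w)) w <- rep(1, length(obs))
  mu <- sum(w * obs) / sum(w)
  ss_tot <- sum(w * (obs - mu)^2)
  ss_res <- sum(w * (obs - fitted)^2)
  if (ss_tot == 0) return(0)
  1 - ss_res / ss_tot
}

#' Fit the directed-motion model MSD(t) = (nu t)^2
#'
#' Least squares of MSD on t^2 through the origin; nu is the square root
#' of the fitted slope (0 if the slope is negative). R^2 is computed about
#' the mean MSD and may be negative for poor no-intercept fits.
#'
#' @param msd An [compute_msd()] profile (>= 3 lags).
#' @param weight_by_n_pairs Weight each lag by its number of displacement
#'   pairs (the default; long lags of a time-averaged MSD average few,
#'   highly correlated pairs and are far noisier than short lags). Set
#'   FALSE for equally weighted lags.
#' @return List with `nu_um_s` and `r2`.
#' @export
fit_directed <- function(msd, weight_by_n_pairs = TRUE) {
  stopifnot(nrow(msd) >= 3)
  w <- if (weight_by_n_pairs) msd$n_pairs else rep(1, nrow(msd))
  t2 <- msd$lag_s^2
  slope <- sum(w * msd$msd_um2 * t2) / sum(w * t2^2)
  list(nu_um_s = sqrt(max(slope, 0)),
       r2 = .r2(msd$msd_um2, slope * t2, w))
}

#' Fit the random-diffusion model MSD(t) = 4 D t
#'
#' Least squares of MSD on t through the origin; D is slope / 4 (0 if the
#' slope is negative).
#'
#' @param msd An [compute_msd()] profile (>= 3 lags).
#' @inheritParams fit_directed
#' @return List with `d_um2_s` and `r2`.
#' @export
fit_random <- function(msd, weight_by_n_pairs = TRUE) {
  stopifnot(nrow(msd) >= 3)
  w <- if (weight_by_n_pairs) msd$n_pairs else rep(1, nrow(msd))
  tt <- msd$lag_s
  slope <- sum(w * msd$msd_um2 * tt) / sum(w * tt^2)
  list(d_um2_s = max(slope, 0) / 4,
       r2 = .r2(msd$msd_um2, slope * tt, w))
}

#' Fit both motion models to a track
#'
#' @param track Track data frame (`x_um`, `y_um`).
#' @param frame_interval_s Frame interval (s).
#' @inheritParams fit_directed
#' @return An object of class `motion_fit`: `nu_um_s`, `r2_directed`,
#'   `d_um2_s`, `r2_random`, `max_msd_um2`, `n_lags`.
#' @export
fit_motion <- function(track, frame_interval_s = 1,
                       weight_by_n_pairs = TRUE) {
  msd <- compute_msd(track, frame_interval_s)
  if (nrow(msd) < 3)
    return(structure(list(nu_um_s = NA_real_, r2_directed = -Inf,
                          d_um2_s = NA_real_, r2_random = -Inf,
                          max_msd_um2 = if (nrow(msd)) max(msd$msd_um2)
                          else 0,
                          n_lags = nrow(msd)),
                     class = "motion_fit"))
  fd <- fit_directed(msd, weight_by_n_pairs)
  fr <- fit_random(msd, weight_by_n_pairs)
  structure(list(nu_um_s = fd$nu_um_s, r2_directed = fd$r2,
                 d_um2_s = fr$d_um2_s, r2_random = fr$r2,
                 max_msd_um2 = max(msd$msd_um2), n_lags = nrow(msd)),
            class = "motion_fit")
}

#' Assign a motion class from the two model fits
#'
#' Directed if the directed fit reaches the R^2 threshold and dominates
#' the random fit; random if the random fit reaches the threshold and
#' dominates; constrained if both R^2 fall below the threshold and the
#' maximum MSD stays below the plateau bound (0.05 um^2); unclassified
#' otherwise.
#'
#' @param fit A [fit_motion()] result (or compatible list).
#' @param r2_threshold R^2 threshold (default 0.8).
#' @param plateau_um2 Constrained-diffusion plateau bound (um^2).
#' @return One of `"directed"`, `"random"`, `"constrained"`,
#'   `"unclassified"`.
#' @export
classify_track <- function(fit, r2_threshold = 0.8, plateau_um2 = 0.05) {
  r2d <- fit$r2_directed
  r2r <- fit$r2_random
  # tracks too short to fit both models stay unclassified
  if (!is.finite(r2d) && !is.finite(r2r)) return("unclassified")
  if (r2d >= r2_threshold && r2d >= r2r) return("directed")
  if (r2r >= r2_threshold && r2r > r2d) return("random")
  if (r2d < r2_threshold && r2r < r2_threshold &&
      fit$max_msd_um2 < plateau_um2) return("constrained")
  "unclassified"
}

#' Classify every track of a movie
#'
#' Tracks shorter than `min_points` are labelled `"unclassified"` without
#' fitting (they still count for density).
#'
#' @param tracks List of per-track data frames ([split_tracks()]).
#' @param frame_interval_s Frame interval (s).
#' @param min_points Minimum points for classification.
#' @param r2_threshold,plateau_um2 Passed to [classify_track()].
#' @inheritParams fit_directed
#' @return Data frame with one row per track: `track_id`, `n_points`,
#'   `motion_class`, `nu_um_s`, `d_um2_s`, `r2_directed`, `r2_random`,
#'   `max_msd_um2`.
#' @export
classify_tracks <- function(tracks, frame_interval_s = 1, min_points = 5,
                            r2_threshold = 0.8, plateau_um2 = 0.05,
                            weight_by_n_pairs = TRUE) {
  rows <- lapply(names(tracks), function(id) {
    tr <- tracks[[id]]
    if (nrow(tr) < min_points)
      return(data.frame(track_id = id, n_points = nrow(tr),
                        motion_class = "unclassified", nu_um_s = NA_real_,
                        d_um2_s = NA_real_, r2_directed = NA_real_,
                        r2_random = NA_real_, max_msd_um2 = NA_real_))
    fit <- fit_motion(tr, frame_interval_s, weight_by_n_pairs)
    data.frame(track_id = id, n_points = nrow(tr),
               motion_class = classify_track(fit, r2_threshold,
                                             plateau_um2),
               nu_um_s = fit$nu_um_s, d_um2_s = fit$d_um2_s,
               r2_directed = fit$r2_directed, r2_random = fit$r2_random,
               max_msd_um2 = fit$max_msd_um2)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Diffusion coefficient from the cumulative distribution of squared
#' displacements
#'
#' Pools squared displacements at a fixed lag over tracks. Under 2D
#' diffusion P(r^2 <= u) = 1 - exp(-u / (4 D dt)); the maximum-likelihood
#' estimate is D = mean(r^2) / (4 dt). A least-squares fit of the
#' empirical CDF to the exponential model is returned as a cross-check.
#'
#' @param tracks List of track data frames (`x_um`, `y_um`).
#' @param frame_interval_s Frame interval (s).
#' @param lag Lag in frames (default 1).
#' @param min_samples Minimum pooled displacements required.
#' @return List with `d_mle_um2_s`, `d_cdf_um2_s`, `n_samples`.
#' @export
estimate_D_cdf <- function(tracks, frame_interval_s = 1, lag = 1,
                           min_samples = 50) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  r2 <- unlist(lapply(tracks, function(tr) {
    n <- nrow(tr)
    if (n <= lag) return(numeric(0))
    dx <- tr$x_um[(lag + 1):n] - tr$x_um[1:(n - lag)]
    dy <- tr$y_um[(lag + 1):n] - tr$y_um[1:(n - lag)]
    dx^2 + dy^2
  }))
  if (length(r2) < min_samples)
    stop("need at least ", min_samples, " displacement samples, got ",
         length(r2))
  dt <- lag * frame_interval_s
  d_mle <- mean(r2) / (4 * dt)
  if (d_mle == 0) return(list(d_mle_um2_s = 0, d_cdf_um2_s = 0,
                              n_samples = length(r2)))
  u <- sort(r2)
  p <- (seq_along(u) - 0.5) / length(u)
  obj <- function(d) sum((p - (1 - exp(-u / (4 * d * dt))))^2)
  d_cdf <- optimize(obj, c(d_mle / 50, d_mle * 50))$minimum
  list(d_mle_um2_s = d_mle, d_cdf_um2_s = d_cdf, n_samples = length(r2))
}

#' Per-cell summary of patch dynamics
#'
#' Every detection inherits its track's motion class (tracks below the
#' classification length count as unclassified). Class fractions are
#' computed per frame over that frame's detections and averaged over
#' frames with at least one detection, giving the instantaneous fractions
#' theta_d, theta_r, theta_c, theta_u. Density rho comes from
#' [patch_stats()]; the directed density is rho_d = theta_d x rho; the
#' mean speed nu averages the fitted speeds of speed-eligible directed
#' tracks; D is estimated from random-classified tracks by MSD fit and by
#' the cumulative-distribution method.
#'
#' @param linked Linked detections ([link_detections()]).
#' @param classes Classification table ([classify_tracks()]).
#' @param mask A [segment_cell()] result or numeric area (um^2).
#' @param n_frames Number of frames in the movie.
#' @param frame_interval_s Frame interval (s).
#' @param min_steps_speed Minimum steps for the speed average.
#' @param cell_id Identifier copied to the output.
#' @return A one-row data frame of class `cell_summary`: `cell_id`,
#'   `rho_um2`, `theta_d`, `theta_r`, `theta_c`, `theta_u`, `rho_d_um2`,
#'   `nu_um_s`, `d_msd_um2_s`, `d_cdf_um2_s`, `n_tracks`, `mean_count`,
#'   `area_um2`, `length_um`, `width_um`.
#' @export
summarize_cell <- function(linked, classes, mask, n_frames,
                           frame_interval_s = 1, min_steps_speed = 4,
                           cell_id = "cell") {
  if (n_frames < 1) stop("no frames")
  cls <- setNames(classes$motion_class, classes$track_id)
  det_class <- cls[as.character(linked$track_id)]
  det_class[is.na(det_class)] <- "unclassified"
  lv <- c("directed", "random", "constrained", "unclassified")
  if (nrow(linked) > 0) {
    tab <- table(factor(linked$frame, levels = sort(unique(linked$frame))),
                 factor(det_class, levels = lv))
    frac <- tab / rowSums(tab)
    theta <- colMeans(frac)
  } else theta <- setNames(c(0, 0, 0, 0), lv)
  ps <- patch_stats(linked, mask, n_frames)
  eligible <- classes$motion_class == "directed" &
    classes$n_points - 1 >= min_steps_speed
  nu <- if (any(eligible)) mean(classes$nu_um_s[eligible]) else NA_real_
  rnd <- classes$motion_class == "random"
  d_msd <- if (any(rnd)) mean(classes$d_um2_s[rnd]) else NA_real_
  d_cdf <- NA_real_
  if (any(rnd)) {
    rnd_ids <- classes$track_id[rnd]
    rnd_tracks <- split_tracks(linked[linked$track_id %in% rnd_ids, ,
                                      drop = FALSE])
    d_cdf <- tryCatch(
      estimate_D_cdf(rnd_tracks, frame_interval_s)$d_mle_um2_s,
      error = function(e) NA_real_)
  }
  area <- if (inherits(mask, "cell_mask")) mask$area_um2 else mask
  structure(data.frame(
    cell_id = cell_id, rho_um2 = ps$density_um2,
    theta_d = unname(theta["directed"]), theta_r = unname(theta["random"]),
    theta_c = unname(theta["constrained"]),
    theta_u = unname(theta["unclassified"]),
    rho_d_um2 = unname(theta["directed"]) * ps$density_um2,
    nu_um_s = nu, d_msd_um2_s = d_msd, d_cdf_um2_s = d_cdf,
    n_tracks = length(unique(linked$track_id)),
    mean_count = ps$mean_count, area_um2 = area,
    length_um = if (inherits(mask, "cell_mask")) mask$length_um
    else NA_real_,
    width_um = if (inherits(mask, "cell_mask")) mask$width_um
    else NA_real_), class = c("cell_summary", "data.frame"))
}

#' Bootstrap standard error of a track-level statistic
#'
#' Resamples tracks with replacement `B` times and returns the standard
#' deviation of the statistic over resamples.
#'
#' @param tracks List of tracks (any objects the statistic accepts).
#' @param statistic Function: list of tracks -> single number.
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return Standard error (numeric scalar).
#' @export
bootstrap_se <- function(tracks, statistic, B = 1000, seed = 1) {
  n <- length(tracks)
  if (n < 2) stop("need at least 2 tracks to bootstrap")
  set.seed(seed)
  vals <- vapply(seq_len(B), function(b)
    statistic(tracks[sample.int(n, n, replace = TRUE)]), numeric(1))
  sd(vals)
}
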