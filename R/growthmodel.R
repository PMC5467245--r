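#' Full turns covered by directed patches over one generation
#'
#' Over a doubling time tau, N_d directed patches moving at circumferential
#' speed nu cover a distance N_d nu tau; divided by the cell perimeter
#' pi D this gives the number of full turns FT = N_d nu tau / (pi D).
#'
#' @param n_d Number of directed patches per cell.
#' @param nu_um_s Directed patch speed (um/s).
#' @param tau_s Generation (doubling) time (s).
#' @param d_cell_um Cell diameter (um).
#' @return FT, dimensionless.
#' @export
full_turns <- function(n_d, nu_um_s, tau_s, d_cell_um) {
  if (!(d_cell_um > 0)) stop("cell diameter must be positive")
  stopifnot(n_d >= 0, nu_um_s >= 0, tau_s > 0)
  n_d * nu_um_s * tau_s / (pi * d_cell_um)
}

#' Width of the inserted peptidoglycan band per full turn (simple form)
#'
#' The cylindrical sidewall elongates by L - D per generation; spread over
#' FT full turns, each turn inserts a band of width
#' omega = (L - D) / FT.
#'
#' @param length_um Cell length L (um).
#' @param d_cell_um Cell diameter D (um); must be below `length_um`.
#' @param ft Full turns per generation ([full_turns()]).
#' @return omega (um).
#' @export
band_width_simple <- function(length_um, d_cell_um, ft) {
  if (!(ft > 0)) stop("FT must be positive")
  if (!(length_um > d_cell_um)) stop("length must exceed diameter")
  (length_um - d_cell_um) / ft
}

#' Width of the inserted band, refined (cell-cycle-integrated) form
#'
#' Integrating synthesis over an exponential cell cycle gives
#' omega = ln(2) / (tau nu rho_d), with tau the generation time, nu the
#' directed speed and rho_d the directed patch density.
#'
#' @param tau_s Generation time (s).
#' @param nu_um_s Directed speed (um/s).
#' @param rho_d_um2 Directed patch density (um^-2).
#' @return omega (um).
#' @export
band_width_refined <- function(tau_s, nu_um_s, rho_d_um2) {
  if (!(tau_s > 0 && nu_um_s > 0 && rho_d_um2 > 0))
    stop("tau, nu and rho_d must all be positive")
  log(2) / (tau_s * nu_um_s * rho_d_um2)
}

#' Regression of sidewall length on full turns across cells
#'
#' Ordinary least squares of L - D on FT over a population of cells; the
#' slope (um per turn) is itself an estimate of the inserted band width
#' omega, and a linear relationship indicates constant expansion per
#' patch turn.
#'
#' @param l_minus_d Numeric vector, sidewall lengths L - D (um).
#' @param ft Numeric vector, full turns per generation.
#' @return List with `slope_um`, `intercept_um`, `r2`.
#' @export
sidewall_vs_turns_regression <- function(l_minus_d, ft) {
  stopifnot(length(l_minus_d) == length(ft))
  if (length(ft) < 3) stop("need at least 3 cells")
  if (var(ft) == 0) stop("degenerate input: FT has no variance")
  fit <- lm(l_minus_d ~ ft)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((l_minus_d - mean(l_minus_d))^2)
  list(slope_um = unname(coef(fit)[2]),
       intercept_um = unname(coef(fit)[1]),
       r2 = 1 - ss_res / ss_tot)
}

#' Extrapolate the whole-cell patch count from the TIRF-visible count
#'
#' Only the fraction f = arccos(1 - 2h/D)/pi of the circumference lies
#' within the evanescent field; assuming uniform patch placement around
#' the circumference, the total per-cell count is observed / f.
#'
#' @param observed_mean_count Mean visible patch count per frame.
#' @param d_cell_um Cell diameter (um).
#' @param penetration_depth_um Evanescent penetration depth (um).
#' @return Estimated total patches per cell.
#' @export
extrapolate_total_patches <- function(observed_mean_count, d_cell_um,
                                      penetration_depth_um = 0.2) {
  stopifnot(observed_mean_count >= 0)
  f <- visible_fraction(d_cell_um, penetration_depth_um)
  observed_mean_count / f
}

#' Aggregate per-cell summaries over an upshift time course
#'
#' Groups cell summaries by their time label and reports mean and standard
#' deviation per time point for each requested statistic. With
#' `normalize = TRUE` each mean series is divided by its pre-shift
#' (time < 0) mean.
#'
#' @param summaries Data frame with a `time_min` column and the statistic
#'   columns.
#' @param stats Character vector of column names to aggregate.
#' @param normalize Normalize each series to its pre-shift mean.
#' @return Data frame: `time_min`, then `<stat>_mean`, `<stat>_sd` and
#'   `<stat>_n` per statistic.
#' @export
upshift_timecourse <- function(summaries,
                               stats = c("rho_um2", "nu_um_s", "theta_d"),
                               normalize = FALSE) {
  stopifnot("time_min" %in% names(summaries))
  times <- sort(unique(summaries$time_min))
  out <- data.frame(time_min = times)
  for (s in stats) {
    v <- summaries[[s]]
    m <- vapply(times, function(t) mean(v[summaries$time_min == t],
                                        na.rm = TRUE), numeric(1))
    sdv <- vapply(times, function(t) {
      x <- v[summaries$time_min == t]
      if (sum(!is.na(x)) < 2) 0 else sd(x, na.rm = TRUE)
    }, numeric(1))
    n <- vapply(times, function(t)
      sum(summaries$time_min == t & !is.na(v)), numeric(1))
    if (normalize) {
      pre <- mean(v[summaries$time_min < 0], na.rm = TRUE)
      m <- m / pre
      sdv <- sdv / pre
    }
    out[[paste0(s, "_mean")]] <- m
    out[[paste0(s, "_sd")]] <- sdv
    out[[paste0(s, "_n")]] <- n
  }
  out
}

#' Instantaneous growth rate from an area time series
#'
#' Slope of ln(area) against time over a centered sliding window.
#'
#' @param time Time points (any consistent unit).
#' @param area Areas (> 0), same length.
#' @param window Window size in points (odd, >= 3).
#' @return Numeric vector of rates (per time unit), `NA` at the edges
#'   where the window does not fit.
#' @export
growth_rate_from_area <- function(time, area, window = 3) {
  stopifnot(length(time) == length(area), window >= 3)
  if (length(time) < 3) stop("need at least 3 time points")
  if (any(area <= 0)) stop("areas must be positive")
  la <- log(area)
  n <- length(time)
  half <- floor(window / 2)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- i - half; hi <- i + half
    if (lo < 1 || hi > n) next
    out[i] <- unname(coef(lm(la[lo:hi] ~ time[lo:hi]))[2])
  }
  out
}

#' Directed patch count per cell from density and geometry
#'
#' N_d = rho_d x visible area / f converts the TIRF-measured directed
#' density into a whole-cell count, where f is the visible fraction of the
#' circumference ([visible_fraction()]). With `correct_visibility =
#' FALSE` the raw projected count rho_d x visible area is returned.
#'
#' @param rho_d_um2 Directed patch density (um^-2 of visible area).
#' @param geom A [cell_geometry()].
#' @param correct_visibility Apply the 1/f whole-cell correction.
#' @return Directed patches per cell.
#' @export
directed_count <- function(rho_d_um2, geom, correct_visibility = TRUE) {
  stopifnot(inherits(geom, "cell_geometry"), rho_d_um2 >= 0)
  n_vis <- rho_d_um2 * visible_area(geom)
  if (!correct_visibility) return(n_vis)
  n_vis / visible_fraction(geom)
}
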