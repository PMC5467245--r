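#' Segment the cell from a maximum-intensity projection
#'
#' Thresholds the MIP with Otsu's method, keeps the largest connected
#' component, fills holes and measures the cell area as the number of mask
#' pixels times the pixel area.
#'
#' @param mip Matrix, the maximum-intensity projection.
#' @param pixel_size_um Pixel size (um).
#' @param closing_px Diameter (px) of the disk used to morphologically
#'   close the Otsu foreground before keeping the largest component;
#'   bridges gaps between fluorescent streaks within one cell. Set 0 to
#'   disable.
#' @return An object of class `cell_mask`: list with `mask` (logical
#'   matrix), `area_um2`, `centroid_px` (`c(x, y)`, 0-based),
#'   `length_um`, `width_um`, `pixel_size_um`.
#' @export
segment_cell <- function(mip, pixel_size_um, closing_px = 5) {
  stopifnot(is.matrix(mip), pixel_size_um > 0)
  rng <- range(mip)
  if (diff(rng) == 0 || stats::var(as.numeric(mip)) == 0)
    stop("no cell found: image has zero intensity variance")
  scaled <- (mip - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1),
                       levels = 256)
  bw <- scaled > thr
  if (!any(bw)) stop("no cell found: empty Otsu foreground")
  if (closing_px > 0) {
    brush <- EBImage::makeBrush(2 * floor(closing_px / 2) + 1,
                                shape = "disc")
    bw <- EBImage::imageData(EBImage::closing(EBImage::Image(bw * 1),
                                              brush)) > 0
    dim(bw) <- dim(scaled)
  }
  lab <- EBImage::bwlabel(EBImage::Image(bw))
  lab <- EBImage::imageData(lab)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  mask <- lab == keep
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask))) > 0
  if (any(mask[1, ]) && any(mask[nrow(mask), ]) && any(mask[, 1]) &&
      any(mask[, ncol(mask)]))
    warning("cell mask touches all four image borders; crop may be too tight")
  dims <- measure_cell_dimensions(mask, pixel_size_um)
  idx <- which(mask, arr.ind = TRUE)
  structure(list(mask = mask,
                 area_um2 = sum(mask) * pixel_size_um^2,
                 centroid_px = c(x = mean(idx[, 2]) - 1,
                                 y = mean(idx[, 1]) - 1),
                 length_um = dims$length_um, width_um = dims$width_um,
                 pixel_size_um = pixel_size_um),
            class = "cell_mask")
}

#' Measure cell length and width from a binary mask
#'
#' Length is the extent of the mask along its principal axis (largest
#' eigenvector of the pixel-coordinate covariance); width is the extent
#' along the perpendicular axis. Both include one pixel for the pixel
#' footprint itself.
#'
#' @param mask Logical matrix (single connected component assumed).
#' @param pixel_size_um Pixel size (um).
#' @return List with `length_um` and `width_um` (`length_um >= width_um`).
#' @export
measure_cell_dimensions <- function(mask, pixel_size_um) {
  stopifnot(is.matrix(mask))
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  xy <- cbind(idx[, 2], idx[, 1])  # x = col, y = row
  if (nrow(xy) < 2) return(list(length_um = pixel_size_um,
                                width_um = pixel_size_um))
  # rotating-calipers breadth over pixel-square corners: the width is the
  # minimal breadth over directions and the length the breadth
  # perpendicular to it (robust to rasterization, unlike a PCA-axis
  # extent whose small angular error leaks length into width)
  corners <- rbind(xy + rep(c(-0.5, -0.5), each = nrow(xy)),
                   xy + rep(c(-0.5, 0.5), each = nrow(xy)),
                   xy + rep(c(0.5, -0.5), each = nrow(xy)),
                   xy + rep(c(0.5, 0.5), each = nrow(xy)))
  thetas <- seq(0, pi, length.out = 181)[-181]
  breadth <- vapply(thetas, function(th) {
    p <- corners %*% c(cos(th), sin(th))
    diff(range(p))
  }, numeric(1))
  i_min <- which.min(breadth)
  th_perp <- thetas[i_min] + pi / 2
  len_px <- diff(range(corners %*% c(cos(th_perp), sin(th_perp))))
  wid <- breadth[i_min] * pixel_size_um
  len <- len_px * pixel_size_um
  if (wid / pixel_size_um < 3)
    warning("mask thinner than 3 px: width estimate unreliable")
  list(length_um = max(len, wid), width_um = min(len, wid))
}

#' Band-pass enhance a frame by difference of Gaussians
#'
#' `Gaussian(sigma1) - Gaussian(sigma2)` applied to the frame; removes
#' high-frequency noise and the smooth cell background, so flat regions
#' map to ~0 and diffraction-limited spots to positive peaks.
#'
#' @param frame Numeric matrix.
#' @param sigma1,sigma2 Gaussian sigmas in pixels (defaults 1 and 4).
#' @return Matrix of the same size.
#' @export
enhance_frame <- function(frame, sigma1 = 1, sigma2 = 4) {
  stopifnot(is.matrix(frame))
  # replicate-pad by the larger kernel half-width so edges see their own
  # values, not a circular wrap
  pad <- ceiling(3 * max(sigma1, sigma2)) + 1
  ri <- c(rep(1, pad), seq_len(nrow(frame)), rep(nrow(frame), pad))
  ci <- c(rep(1, pad), seq_len(ncol(frame)), rep(ncol(frame), pad))
  img <- EBImage::Image(frame[ri, ci])
  g1 <- EBImage::gblur(img, sigma = sigma1)
  g2 <- EBImage::gblur(img, sigma = sigma2)
  out <- EBImage::imageData(g1 - g2)
  out <- out[pad + seq_len(nrow(frame)), pad + seq_len(ncol(frame))]
  dim(out) <- dim(frame)
  out
}

#' Detect patches in one enhanced frame
#'
#' Thresholds the enhanced image at `min_threshold_sd` standard deviations
#' of its intensity, then splits touching maxima with an intensity
#' watershed whose merge tolerance is `step_sd` standard deviations (the
#' descending-threshold step). One detection is produced per catchment
#' with at least `min_area_px` pixels; its sub-pixel position is the
#' intensity-weighted centroid of the catchment in the enhanced image.
#'
#' @param enhanced Matrix from [enhance_frame()].
#' @param min_threshold_sd Detection threshold in intensity s.d. units.
#' @param step_sd Watershed step size in s.d. units.
#' @param robust_sd Use a robust s.d. (1.4826 x MAD) instead of the plain
#'   standard deviation.
#' @param min_area_px Minimum catchment area in pixels; single-pixel
#'   catchments carry no sub-pixel information and are the dominant noise
#'   failure mode, so the default is 2.
#' @param pixel_size_um Pixel size used to add micrometer coordinates.
#' @return Data frame: `x_px`, `y_px` (0-based, sub-pixel), `x_um`,
#'   `y_um`, `amplitude`, `area_px`. Zero rows when nothing is detected.
#' @export
detect_patches_frame <- function(enhanced, min_threshold_sd = 4,
                                 step_sd = 1, robust_sd = TRUE,
                                 min_area_px = 2, pixel_size_um = 0.064) {
  stopifnot(is.matrix(enhanced))
  v <- as.numeric(enhanced)
  s0 <- if (robust_sd) mad(v) else sd(v)
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      x_um = numeric(0), y_um = numeric(0),
                      amplitude = numeric(0), area_px = integer(0))
  if (s0 == 0) return(empty)
  thr <- min_threshold_sd * s0
  above <- enhanced > thr
  if (!any(above)) return(empty)
  relief <- enhanced
  relief[!above] <- 0
  lab <- EBImage::imageData(EBImage::watershed(EBImage::Image(relief),
                                               tolerance = step_sd * s0,
                                               ext = 1))
  dim(lab) <- dim(enhanced)
  labs <- sort(unique(lab[lab > 0]))
  out <- lapply(labs, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < min_area_px) return(NULL)
    wts <- enhanced[idx]
    cx <- sum((idx[, 2] - 1) * wts) / sum(wts)
    cy <- sum((idx[, 1] - 1) * wts) / sum(wts)
    data.frame(x_px = cx, y_px = cy, x_um = cx * pixel_size_um,
               y_um = cy * pixel_size_um, amplitude = max(wts),
               area_px = nrow(idx))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Detect patches in every frame of a movie
#'
#' Runs [enhance_frame()] and [detect_patches_frame()] per frame and
#' optionally discards detections outside the (1 px dilated) cell mask.
#'
#' @param movie A [patch_movie()].
#' @param mask Optional [segment_cell()] result for masking.
#' @param ... Passed to [detect_patches_frame()].
#' @param sigma1,sigma2 Difference-of-Gaussians sigmas (px).
#' @return Data frame with a 0-based `frame` column plus the
#'   [detect_patches_frame()] columns.
#' @export
detect_movie <- function(movie, mask = NULL, sigma1 = 1, sigma2 = 4, ...) {
  stopifnot(inherits(movie, "patch_movie"))
  dil <- NULL
  if (!is.null(mask)) {
    kern <- EBImage::makeBrush(3, shape = "box")
    dil <- EBImage::imageData(
      EBImage::dilate(EBImage::Image(mask$mask * 1), kern)) > 0
    dim(dil) <- dim(mask$mask)
  }
  res <- lapply(seq_len(n_frames(movie)), function(f) {
    enh <- enhance_frame(movie$pixels[, , f], sigma1, sigma2)
    det <- detect_patches_frame(enh, pixel_size_um = movie$pixel_size_um,
                                ...)
    if (nrow(det) == 0) return(cbind(frame = integer(0), det))
    if (!is.null(dil)) {
      rr <- pmin(pmax(round(det$y_px) + 1, 1), nrow(dil))
      cc <- pmin(pmax(round(det$x_px) + 1, 1), ncol(dil))
      det <- det[dil[cbind(rr, cc)], , drop = FALSE]
    }
    cbind(frame = rep(f - 1L, nrow(det)), det)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Mean patch count and patch density
#'
#' The mean count is the average number of detections per frame (frames
#' with no detections count as zero); the density is the mean count
#' divided by the cell area.
#'
#' @param detections Data frame from [detect_movie()] (already masked).
#' @param mask A [segment_cell()] result (supplies the area), or a
#'   numeric area in um^2.
#' @param n_frames Number of frames analysed.
#' @return List with `mean_count` and `density_um2`.
#' @export
patch_stats <- function(detections, mask, n_frames) {
  area <- if (inherits(mask, "cell_mask")) mask$area_um2 else mask
  if (!(area > 0)) stop("cell area must be positive")
  stopifnot(n_frames >= 1)
  mean_count <- nrow(detections) / n_frames
  list(mean_count = mean_count, density_um2 = mean_count / area)
}
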