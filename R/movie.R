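#' Calibrated time-lapse movie
#'
#' A light container for a fluorescence time-lapse: a numeric array of
#' dimensions rows x cols x frames together with the pixel size and frame
#' interval. Rows index the image `y` axis, columns the `x` axis; pixel
#' centers sit at integer 0-based coordinates and micrometer coordinates
#' are `px * pixel_size_um`.
#'
#' @param pixels Numeric array `rows x cols x frames` (a matrix is treated
#'   as a single frame).
#' @param pixel_size_um Pixel size (um), > 0.
#' @param frame_interval_s Frame interval (s), > 0.
#' @return An object of class `patch_movie`.
#' @export
patch_movie <- function(pixels, pixel_size_um = 0.064,
                        frame_interval_s = 1) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1))
  stopifnot(is.array(pixels), length(dim(pixels)) == 3,
            dim(pixels)[3] >= 1, pixel_size_um > 0, frame_interval_s > 0)
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "patch_movie")
}

#' @export
print.patch_movie <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("patch_movie: %d frames of %d x %d px (%.0f nm px, %g s)\n",
              d[3], d[1], d[2], x$pixel_size_um * 1000,
              x$frame_interval_s))
  invisible(x)
}

n_frames <- function(movie) dim(movie$pixels)[3]

#' Write a movie as a 16-bit multi-frame TIFF with JSON sidecar metadata
#'
#' Pixel values are stored as unsigned 16-bit after clamping to
#' `[0, 65535]`; calibration (pixel size, frame interval) and, when
#' present, the simulation seed go to `<path>.json`. Ground truth, if
#' attached, is written as a CSV next to the TIFF.
#'
#' @param movie A [patch_movie()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "patch_movie"))
  d <- dim(movie$pixels)
  frames <- lapply(seq_len(d[3]), function(f)
    pmin(pmax(movie$pixels[, , f], 0), 65535) / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  meta <- list(pixel_size_um = movie$pixel_size_um,
               frame_interval_s = movie$frame_interval_s)
  cfg <- attr(movie, "config")
  if (!is.null(cfg)) {
    meta$seed <- cfg$seed
    meta$config <- unclass(cfg)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  truth <- attr(movie, "truth")
  if (!is.null(truth) && nrow(truth) > 0)
    write.csv(truth, sub("\\.tiff?$", "_truth.csv", path),
              row.names = FALSE)
  invisible(path)
}

#' Read a multi-frame TIFF movie (with optional JSON sidecar)
#'
#' @param path TIFF path; `<path>.json` supplies `pixel_size_um` and
#'   `frame_interval_s` if present.
#' @param pixel_size_um,frame_interval_s Calibration used when no sidecar
#'   is found.
#' @return A [patch_movie()]. 16-bit data are rescaled back to counts.
#' @export
read_movie_tiff <- function(path, pixel_size_um = 0.064,
                            frame_interval_s = 1) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  arr <- array(0, dim = c(dim(frames[[1]])[1:2], length(frames)))
  for (f in seq_along(frames)) arr[, , f] <- frames[[f]][, , drop = TRUE] * 65535
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$pixel_size_um)) pixel_size_um <- meta$pixel_size_um
    if (!is.null(meta$frame_interval_s))
      frame_interval_s <- meta$frame_interval_s
  }
  patch_movie(arr, pixel_size_um, frame_interval_s)
}

#' Maximum-intensity projection over frames
#'
#' @param movie A [patch_movie()].
#' @return A matrix; each pixel is the maximum over frames at that pixel.
#' @export
max_intensity_projection <- function(movie) {
  stopifnot(inherits(movie, "patch_movie"))
  apply(movie$pixels, c(1, 2), max)
}

#' Kymograph along a line
#'
#' Samples the movie along the segment `p0 -> p1` (0-based pixel
#' coordinates `c(x, y)`) at one-pixel steps, averaging over `width_px`
#' parallel lines offset perpendicular to the segment; each frame
#' contributes one column. A spot moving at constant speed along the line
#' appears as a ridge of constant slope.
#'
#' @param movie A [patch_movie()].
#' @param p0,p1 Segment endpoints, `c(x_px, y_px)` (0-based).
#' @param width_px Odd integer; number of parallel lines averaged.
#' @return Matrix of dimension `n_positions x n_frames`.
#' @export
kymograph <- function(movie, p0, p1, width_px = 3) {
  stopifnot(inherits(movie, "patch_movie"), length(p0) == 2,
            length(p1) == 2)
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop("degenerate (zero-length) line")
  n_pos <- floor(len) + 1
  u <- (p1 - p0) / len                    # along-line unit vector
  v <- c(-u[2], u[1])                     # perpendicular
  offs <- seq_len(width_px) - (width_px + 1) / 2
  tpos <- seq(0, len, length.out = n_pos)
  d <- dim(movie$pixels)
  out <- matrix(0, n_pos, d[3])
  for (f in seq_len(d[3])) {
    img <- movie$pixels[, , f]
    acc <- numeric(n_pos)
    for (o in offs) {
      xs <- p0[1] + tpos * u[1] + o * v[1]
      ys <- p0[2] + tpos * u[2] + o * v[2]
      acc <- acc + bilinear_sample(img, xs, ys)
    }
    out[, f] <- acc / width_px
  }
  out
}

# bilinear interpolation at 0-based (x, y); out-of-range clamped to edge
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2); x1 <- x0 + 1
  y0 <- pmin(floor(y), nr - 2); y1 <- y0 + 1
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x1 + 1)
  i10 <- cbind(y1 + 1, x0 + 1); i11 <- cbind(y1 + 1, x1 + 1)
  img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
}
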