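#' Pipeline configuration
#'
#' All tunables of the detection/tracking/classification pipeline, with
#' defaults at the standard analysis values: difference-of-Gaussians
#' sigma1 = 1 px / sigma2 = 4 px, watershed threshold 4 s.d. with 1 s.d.
#' step, 3 px search radius with no gap closing, at least 5 points to
#' classify and 4 steps for speed, R^2 threshold 0.8, constrained plateau
#' 0.05 um^2, 7/8 maximum-lag rule (fixed in [compute_msd()]), 64 nm
#' pixels, 1 s frame interval, 200 nm penetration depth.
#'
#' @param ... Overrides for any default field; unknown names are an error.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    dog_sigma1_px = 1, dog_sigma2_px = 4,
    threshold_sd = 4, step_sd = 1, robust_sd = TRUE, min_area_px = 2,
    gate_px = 3,
    min_points_classify = 5, min_steps_speed = 4,
    r2_threshold = 0.8, plateau_um2 = 0.05, msd_weight_by_n_pairs = TRUE,
    pixel_size_um = 0.064, frame_interval_s = 1,
    penetration_depth_um = 0.2,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  cfg <- defaults
  errs <- character(0)
  num_pos <- c("dog_sigma1_px", "dog_sigma2_px", "threshold_sd", "step_sd",
               "gate_px", "r2_threshold", "plateau_um2", "pixel_size_um",
               "frame_interval_s", "penetration_depth_um")
  for (f in num_pos)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      errs <- c(errs, paste0("field '", f, "' must be a positive number"))
  for (f in c("min_points_classify", "min_steps_speed", "min_area_px"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1)
      errs <- c(errs, paste0("field '", f, "' must be >= 1"))
  if (cfg$r2_threshold > 1)
    errs <- c(errs, "field 'r2_threshold' must be <= 1")
  if (length(errs)) stop(paste(errs, collapse = "\n"))
  structure(cfg, class = "pipeline_config")
}

#' Validate (or load) a pipeline configuration
#'
#' Accepts a `pipeline_config`, a plain list of overrides, or a path to a
#' JSON file of overrides; fills defaults, rejects unknown keys and
#' enumerates range violations. An empty file or list yields the full
#' default configuration. The result round-trips through JSON unchanged.
#'
#' @param x Configuration source (list, path, or NULL for defaults).
#' @return A validated `pipeline_config`.
#' @export
validate_config <- function(x = NULL) {
  if (inherits(x, "pipeline_config")) x <- unclass(x)
  if (is.character(x)) {
    txt <- paste(readLines(x, warn = FALSE), collapse = "\n")
    x <- if (nzchar(trimws(txt)))
      jsonlite::fromJSON(txt, simplifyVector = TRUE) else list()
  }
  if (is.null(x)) x <- list()
  do.call(pipeline_config, x)
}

#' Write a configuration to JSON
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the full patch-dynamics pipeline on one movie
#'
#' Steps: maximum-intensity projection, Otsu cell segmentation, per-frame
#' difference-of-Gaussians enhancement and watershed detection (masked to
#' the cell), gated frame-to-frame linking, MSD motion classification, and
#' the per-cell summary. When the movie carries simulation ground truth,
#' an evaluation table (detection recall, localization error,
#' classification confusion matrix) is attached.
#'
#' @param movie A [patch_movie()] (e.g. from [simulate_movie()] or
#'   [read_movie_tiff()]), or a [sim_config()] (the movie is simulated
#'   first with the default [cell_geometry()]).
#' @param config A [pipeline_config()].
#' @param geom Cell geometry used when `movie` is a `sim_config`.
#' @param cell_id Identifier for the summary row.
#' @param outdir Optional directory; when given, detections.csv,
#'   tracks.csv, classified.csv, cell_summary.csv and (if ground truth is
#'   present) evaluation.json are written there.
#' @return List of class `pipeline_result`: `mip`, `mask`, `detections`,
#'   `tracks` (linked detections), `classes`, `summary`, `evaluation`
#'   (NULL without ground truth), `config`.
#' @export
run_pipeline <- function(movie, config = pipeline_config(),
                         geom = cell_geometry(), cell_id = "cell",
                         outdir = NULL) {
  config <- validate_config(config)
  if (inherits(movie, "sim_config")) movie <- simulate_movie(movie, geom)
  stopifnot(inherits(movie, "patch_movie"))
  mip <- max_intensity_projection(movie)
  mask <- segment_cell(mip, movie$pixel_size_um)
  detections <- detect_movie(movie, mask,
                             sigma1 = config$dog_sigma1_px,
                             sigma2 = config$dog_sigma2_px,
                             min_threshold_sd = config$threshold_sd,
                             step_sd = config$step_sd,
                             robust_sd = config$robust_sd,
                             min_area_px = config$min_area_px)
  linked <- link_detections(detections, config$gate_px)
  tracks <- split_tracks(linked)
  classes <- classify_tracks(tracks, movie$frame_interval_s,
                             min_points = config$min_points_classify,
                             r2_threshold = config$r2_threshold,
                             plateau_um2 = config$plateau_um2,
                             weight_by_n_pairs =
                               config$msd_weight_by_n_pairs)
  summ <- summarize_cell(linked, classes, mask, n_frames(movie),
                         movie$frame_interval_s,
                         min_steps_speed = config$min_steps_speed,
                         cell_id = cell_id)
  evaluation <- NULL
  truth <- attr(movie, "truth")
  if (!is.null(truth) && nrow(truth) > 0)
    evaluation <- evaluate_against_truth(linked, classes, truth,
                                         movie$pixel_size_um)
  res <- structure(list(mip = mip, mask = mask, detections = detections,
                        tracks = linked, classes = classes,
                        summary = summ, evaluation = evaluation,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.csv(detections, file.path(outdir, "detections.csv"),
              row.names = FALSE)
    write.csv(linked, file.path(outdir, "tracks.csv"), row.names = FALSE)
    write.csv(classes, file.path(outdir, "classified.csv"),
              row.names = FALSE)
    write.csv(summ, file.path(outdir, "cell_summary.csv"),
              row.names = FALSE)
    if (!is.null(evaluation))
      jsonlite::write_json(evaluation, file.path(outdir, "evaluation.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  res
}

#' Compare pipeline output against simulation ground truth
#'
#' Matches each visible ground-truth spot to the nearest same-frame
#' detection within `match_radius_px` to measure recall and localization
#' error; assigns each recovered track the majority true mode of its
#' matched ground-truth points to build a classification confusion
#' matrix.
#'
#' @param linked Linked detections ([link_detections()]).
#' @param classes Classification table ([classify_tracks()]).
#' @param truth Ground-truth table (from the simulator, with `x_px`,
#'   `y_px`).
#' @param pixel_size_um Pixel size (um).
#' @param match_radius_px Matching radius (px).
#' @param isolation_px Minimum distance to the nearest other visible spot
#'   in the same frame for a spot to count as "isolated"; spots closer
#'   than ~2 PSF widths merge into one detection by construction.
#' @return List with `recall` (all visible spots), `recall_isolated`
#'   (visible spots at least `isolation_px` from any neighbour),
#'   `median_loc_error_px`, `n_true_visible`, `n_detections` and
#'   `confusion` (true mode x assigned class counts).
#' @export
evaluate_against_truth <- function(linked, classes, truth, pixel_size_um,
                                   match_radius_px = 2, isolation_px = 5) {
  vis <- truth[truth$visible, , drop = FALSE]
  matched_det <- rep(NA_integer_, nrow(vis))
  err <- rep(NA_real_, nrow(vis))
  isolated <- rep(TRUE, nrow(vis))
  for (f in unique(vis$frame)) {
    ti <- which(vis$frame == f)
    if (length(ti) > 1) {
      dnn <- as.matrix(stats::dist(cbind(vis$x_px[ti], vis$y_px[ti])))
      diag(dnn) <- Inf
      isolated[ti] <- apply(dnn, 1, min) >= isolation_px
    }
    di <- which(linked$frame == f)
    if (!length(di)) next
    d2 <- outer(vis$x_px[ti], linked$x_px[di], "-")^2 +
      outer(vis$y_px[ti], linked$y_px[di], "-")^2
    # greedy nearest-first matching, adequate at these densities
    repeat {
      if (!length(d2) || min(d2) > match_radius_px^2) break
      k <- arrayInd(which.min(d2), dim(d2))
      matched_det[ti[k[1]]] <- di[k[2]]
      err[ti[k[1]]] <- sqrt(d2[k[1], k[2]])
      d2[k[1], ] <- Inf
      d2[, k[2]] <- Inf
    }
  }
  recall <- mean(!is.na(matched_det))
  recall_isolated <- if (any(isolated)) mean(!is.na(matched_det[isolated]))
  else NA_real_
  # per recovered track: majority true mode among matched truth rows
  cls <- setNames(classes$motion_class, classes$track_id)
  tid <- linked$track_id[matched_det[!is.na(matched_det)]]
  tmode <- vis$mode[!is.na(matched_det)]
  conf <- NULL
  if (length(tid)) {
    per_track_mode <- tapply(tmode, tid, function(m)
      names(sort(table(m), decreasing = TRUE))[1])
    assigned <- cls[names(per_track_mode)]
    assigned[is.na(assigned)] <- "unclassified"
    conf <- table(true_mode = unname(per_track_mode),
                  assigned = unname(assigned))
  }
  list(recall = recall, recall_isolated = recall_isolated,
       median_loc_error_px = stats::median(err, na.rm = TRUE),
       n_true_visible = nrow(vis), n_detections = nrow(linked),
       confusion = conf)
}
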