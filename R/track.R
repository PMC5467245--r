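#' Link per-frame detections into tracks
#'
#' Frame-to-frame gated assignment: for every consecutive frame pair, a
#' one-to-one assignment between tracks alive in the previous frame and
#' detections in the current frame is chosen to minimize the total squared
#' displacement among pairs within the gate (`max_radius_px`), with
#' non-assignment costing the squared gate radius. No gap closing and no
#' merging or splitting: an unmatched track terminates and an unmatched
#' detection starts a new track. Ties are broken towards the lowest
#' (previous-track id, detection index) pair, so linking is deterministic
#' and invariant to detection order within a frame.
#'
#' The optimal assignment is solved as a maximum-weight bipartite matching
#' (weight = gate^2 - distance^2 over in-gate pairs), which is equivalent
#' to the stated minimization.
#'
#' @param detections Data frame with columns `frame` (0-based), `x_px`,
#'   `y_px` (and optionally `x_um`, `y_um`, `amplitude`).
#' @param max_radius_px Search (gate) radius in pixels.
#' @return The input rows with a `track_id` column; every detection
#'   belongs to exactly one track (possibly of length 1), ordered by
#'   `track_id` then `frame`.
#' @export
link_detections <- function(detections, max_radius_px = 3) {
  stopifnot(is.data.frame(detections), max_radius_px > 0)
  if (nrow(detections) == 0)
    return(cbind(track_id = integer(0), detections))
  det <- detections[order(detections$frame), , drop = FALSE]
  det$track_id <- NA_integer_
  next_id <- 1L
  frames <- sort(unique(det$frame))
  prev_rows <- integer(0)  # row indices of track heads in previous frame
  prev_frame <- NA_integer_
  gate2 <- max_radius_px^2
  for (f in frames) {
    cur <- which(det$frame == f)
    if (length(prev_rows) && !is.na(prev_frame) && f == prev_frame + 1) {
      m <- gated_assignment(det$x_px[prev_rows], det$y_px[prev_rows],
                            det$track_id[prev_rows],
                            det$x_px[cur], det$y_px[cur], gate2)
      for (k in seq_along(m)) {
        if (m[k] > 0) det$track_id[cur[m[k]]] <- det$track_id[prev_rows[k]]
      }
    }
    new <- cur[is.na(det$track_id[cur])]
    if (length(new)) {
      det$track_id[new] <- seq.int(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
    prev_rows <- cur
    prev_frame <- f
  }
  det <- det[order(det$track_id, det$frame), , drop = FALSE]
  rownames(det) <- NULL
  det[, c("track_id", setdiff(names(det), "track_id"))]
}

# optimal one-to-one gated assignment previous -> current.
# Returns, for each previous index, the matched current index or 0.
gated_assignment <- function(px, py, pid, cx, cy, gate2) {
  np <- length(px); nc <- length(cx)
  res <- integer(np)
  if (np == 0 || nc == 0) return(res)
  d2 <- outer(px, cx, "-")^2 + outer(py, cy, "-")^2
  ok <- which(d2 <= gate2, arr.ind = TRUE)
  if (nrow(ok) == 0) return(res)
  # tie-break bonus: prefer lower previous-track id, then lower detection
  # index; epsilons are far below any meaningful cost difference
  rk_p <- rank(pid, ties.method = "first")
  w <- gate2 - d2[ok] +
    1e-9 * (np - rk_p[ok[, 1]]) + 1e-12 * (nc - ok[, 2])
  edges <- rbind(ok[, 1], np + ok[, 2])
  g <- igraph::make_bipartite_graph(c(rep(FALSE, np), rep(TRUE, nc)),
                                    edges = as.integer(edges))
  igraph::E(g)$weight <- w
  mm <- igraph::max_bipartite_match(g)$matching
  for (i in seq_len(np)) {
    j <- mm[i]
    if (!is.na(j)) res[i] <- j - np
  }
  res
}

#' Split linked detections into per-track tables
#'
#' @param linked Output of [link_detections()].
#' @return Named list of data frames, one per track, ordered by frame.
#' @export
split_tracks <- function(linked) {
  if (nrow(linked) == 0) return(list())
  out <- split(linked, linked$track_id)
  lapply(out, function(d) d[order(d$frame), , drop = FALSE])
}

#' Partition tracks by length eligibility
#'
#' Tracks need at least `min_points_classify` points to be classified by
#' MSD analysis, and directed tracks need at least `min_steps_speed` steps
#' to contribute to the speed estimate. Shorter tracks stay in the
#' detection pool (they count for density) but are labelled
#' unclassifiable.
#'
#' @param tracks List of per-track data frames ([split_tracks()]).
#' @param min_points_classify Minimum points for MSD classification.
#' @param min_steps_speed Minimum steps (points - 1) for speed estimates.
#' @return List with `classifiable` and `speed_eligible`: character
#'   vectors of track names.
#' @export
filter_tracks <- function(tracks, min_points_classify = 5,
                          min_steps_speed = 4) {
  nm <- names(tracks)
  if (is.null(nm)) nm <- character(length(tracks))
  n_pts <- vapply(tracks, nrow, integer(1))
  list(classifiable = nm[n_pts >= min_points_classify],
       speed_eligible = nm[n_pts - 1 >= min_steps_speed])
}
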