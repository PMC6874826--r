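# Lifetime filtering and the end-to-end counting pipeline. Short-lived
# trackers are assumed to be detector noise; the stand count is the number of
# trackers whose lifetime strictly exceeds a quarter of the video frame rate.

#' Lifetime threshold from the video frame rate
#'
#' A quarter of the frame rate, rounded down: 7 for 30 FPS, 15 for 60 FPS.
#'
#' @param fps video frame rate (frames/s), > 0.
#' @return Integer threshold (frames).
#' @export
lifetime_threshold <- function(fps) {
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("fps must be a single positive number")
  as.integer(floor(fps / 4))
}

#' Count valid trackers
#'
#' A tracker is valid when its lifetime is strictly greater than the
#' threshold.
#'
#' @param trackers a \code{tracker_set}, its table, or a vector of lifetimes.
#' @param threshold lifetime threshold in frames (>= 0).
#' @return Integer count.
#' @export
count_valid_trackers <- function(trackers, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  lifetimes <- tracker_lifetimes(trackers)
  sum(lifetimes > threshold)
}

tracker_lifetimes <- function(trackers) {
  if (inherits(trackers, "tracker_set")) return(trackers$table$lifetime)
  if (is.data.frame(trackers)) return(trackers$lifetime)
  as.numeric(trackers)
}

#' Counting pipeline configuration
#'
#' @param fps video frame rate (frames/s).
#' @param lifetime_threshold integer override, or \code{"auto"} to use
#'   [lifetime_threshold()] of \code{fps}.
#' @param target_class class label to track and count; all other detections
#'   are dropped before tracking.
#' @param confidence_floor minimum detection confidence fed to the tracker.
#' @return List of class \code{count_config}.
#' @export
count_config <- function(fps = 30, lifetime_threshold = "auto",
                         target_class = "seedling", confidence_floor = 0.5) {
  stopifnot(is.numeric(fps), fps > 0)
  if (!identical(lifetime_threshold, "auto"))
    stopifnot(is.numeric(lifetime_threshold), lifetime_threshold >= 0)
  structure(list(fps = fps, lifetime_threshold = lifetime_threshold,
                 target_class = target_class,
                 confidence_floor = confidence_floor),
            class = "count_config")
}

#' Count seedlings in a detection stream
#'
#' The full pipeline on an already-detected video: gate detections by class
#' and confidence, run the Kalman tracker over all frames, and count trackers
#' whose lifetime strictly exceeds the lifetime threshold (a quarter of the
#' frame rate unless overridden). All trackers ever created — terminated or
#' still active at the end of the video — enter the count.
#'
#' @param dets detection stream (see [detections()]) or a path to a MOT-style
#'   detection CSV (see [read_detections_mot()]).
#' @param config [count_config()].
#' @param params [filter_params()].
#' @param video_id identifier copied into the result.
#' @return Object of class \code{count_result}: list with \code{video_id},
#'   \code{seedling_count}, \code{tracker_lifetimes}, \code{threshold_used}
#'   and the full \code{tracker_set}.
#' @examples
#' scn <- simulate_scene(scene_config(n_seedlings = 3, seed = 1))
#' count_seedlings(scn$clean_detections, count_config(fps = 30))
#' @export
count_seedlings <- function(dets, config = count_config(),
                            params = filter_params(), video_id = "video") {
  if (is.character(dets) && length(dets) == 1L) dets <- read_detections_mot(dets)
  dets <- validate_detections(dets)
  dets <- dets[dets$class == config$target_class &
                 dets$conf >= config$confidence_floor, , drop = FALSE]
  ts <- track_video(dets, params)
  thr <- if (identical(config$lifetime_threshold, "auto"))
    lifetime_threshold(config$fps) else as.integer(config$lifetime_threshold)
  structure(list(
    video_id = video_id,
    seedling_count = count_valid_trackers(ts, thr),
    tracker_lifetimes = ts$table$lifetime,
    threshold_used = thr,
    tracker_set = ts
  ), class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat("count_result for", x$video_id, "\n")
  cat("  seedling count:", x$seedling_count,
      " (", length(x$tracker_lifetimes), "trackers, lifetime threshold",
      x$threshold_used, "frames)\n")
  invisible(x)
}

#' Write a count result to JSON
#'
#' @param result [count_seedlings()] output.
#' @param path output file.
#' @export
write_count_result <- function(result, path) {
  jsonlite::write_json(
    list(video_id = result$video_id,
         seedling_count = result$seedling_count,
         threshold_used = result$threshold_used,
         tracker_lifetimes = result$tracker_lifetimes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
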