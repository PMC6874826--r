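# Multi-object tracker lifecycle. Each frame: predict every active tracker,
# associate the frame's detections against the predicted boxes, update matched
# trackers, start a new tracker for every unmatched detection, and remove
# (terminate) every unmatched tracker. A tracker's lifetime is the number of
# frames in which it existed: 1 at creation plus one per associated frame.

#' Initialize a tracker from a detection
#'
#' The state is the detection's \code{[u, v, s, r]} with all three derivatives
#' zero; the covariance is \code{P0}.
#'
#' @param det one-row detection data frame (see [detections()]).
#' @param params [filter_params()].
#' @param frame frame index at creation.
#' @param id unique integer tracker id.
#' @return A tracker: list with id, state, P, frame_created, frame_last,
#'   lifetime, status and per-frame box history.
#' @export
init_tracker <- function(det, params, frame, id) {
  b <- c(det$x_min, det$y_min, det$x_max, det$y_max)
  names(b) <- BOX_FIELDS
  validate_box(b)
  list(
    id = as.integer(id),
    state = c(box_to_state(b), u_dot = 0, v_dot = 0, s_dot = 0),
    P = params$P0,
    frame_created = as.integer(frame),
    frame_last = as.integer(frame),
    lifetime = 1L,
    status = "active",
    history = list(list(frame = as.integer(frame), box = b))
  )
}

#' Advance the tracker set by one frame
#'
#' Order of operations: predict every active tracker, associate this frame's
#' detections against the predicted boxes, update matched trackers (lifetime
#' + 1), initialize one new tracker per unmatched detection, and terminate
#' every unmatched tracker.
#'
#' @param active list of active trackers.
#' @param frame_dets detections of this frame (all rows must carry
#'   \code{frame}).
#' @param params [filter_params()].
#' @param frame current frame index.
#' @param next_id next unused tracker id.
#' @return List with \code{active}, \code{terminated} (disjoint tracker
#'   lists) and \code{next_id}.
#' @export
track_step <- function(active, frame_dets, params, frame, next_id = 1L) {
  frame_dets <- validate_detections(frame_dets)
  if (nrow(frame_dets) > 0L && any(frame_dets$frame != frame))
    stop("frame_dets mixes frame indices; all rows must belong to frame ", frame)

  nt <- length(active)
  pred_boxes <- matrix(NA_real_, nt, 4L, dimnames = list(NULL, BOX_FIELDS))
  for (k in seq_len(nt)) {
    pr <- kf_predict(active[[k]]$state, active[[k]]$P, params)
    active[[k]]$state <- pr$state
    active[[k]]$P <- pr$P
    pb <- state_to_box_safe(pr$state)
    if (!is.null(pb)) pred_boxes[k, ] <- pb
  }

  assoc <- associate(frame_dets, pred_boxes, params$min_iou)

  for (i in seq_len(nrow(assoc$matches))) {
    j <- assoc$matches[i, 1L]
    k <- assoc$matches[i, 2L]
    b <- c(frame_dets$x_min[j], frame_dets$y_min[j],
           frame_dets$x_max[j], frame_dets$y_max[j])
    names(b) <- BOX_FIELDS
    up <- kf_update(active[[k]]$state, active[[k]]$P, box_to_state(b), params)
    active[[k]]$state <- up$state
    active[[k]]$P <- up$P
    active[[k]]$lifetime <- active[[k]]$lifetime + 1L
    active[[k]]$frame_last <- as.integer(frame)
    post_box <- state_to_box_safe(up$state)
    if (is.null(post_box)) post_box <- b
    active[[k]]$history <- c(active[[k]]$history,
                             list(list(frame = as.integer(frame), box = post_box)))
  }

  new_trackers <- vector("list", length(assoc$unmatched_detections))
  for (i in seq_along(assoc$unmatched_detections)) {
    j <- assoc$unmatched_detections[i]
    new_trackers[[i]] <- init_tracker(frame_dets[j, , drop = FALSE],
                                      params, frame, next_id)
    next_id <- next_id + 1L
  }

  terminated <- active[assoc$unmatched_trackers]
  terminated <- lapply(terminated, function(t) { t$status <- "terminated"; t })
  keep <- setdiff(seq_len(nt), assoc$unmatched_trackers)
  list(active = c(active[keep], new_trackers),
       terminated = terminated,
       next_id = next_id)
}

#' Track a full detection stream
#'
#' Runs [track_step()] over every frame from the first to the last frame index
#' in the stream (frames with no detections terminate all active trackers),
#' starting from an empty tracker set. Deterministic: identical input yields an
#' identical tracker table.
#'
#' @param dets detection stream (see [detections()]); class/confidence gating
#'   is expected upstream (see [count_seedlings()]).
#' @param params [filter_params()].
#' @return Object of class \code{tracker_set}: list with \code{trackers}
#'   (all trackers ever created, active and terminated), \code{table}
#'   (data frame: tracker_id, frame_created, frame_last, lifetime, status)
#'   and \code{history} (data frame: tracker_id, frame, x_min..y_max).
#' @export
track_video <- function(dets, params = filter_params()) {
  dets <- validate_detections(dets)
  active <- list(); finished <- list(); next_id <- 1L
  if (nrow(dets) > 0L) {
    by_frame <- split(seq_len(nrow(dets)), dets$frame)
    for (frame in seq.int(min(dets$frame), max(dets$frame))) {
      idx <- by_frame[[as.character(frame)]]
      fd <- if (is.null(idx)) empty_detections() else dets[idx, , drop = FALSE]
      st <- track_step(active, fd, params, frame, next_id)
      active <- st$active
      finished <- c(finished, st$terminated)
      next_id <- st$next_id
    }
  }
  trackers <- c(finished, active)
  trackers <- trackers[order(vapply(trackers, `[[`, integer(1L), "id"))]
  structure(list(
    trackers = trackers,
    table = tracker_table(trackers),
    history = tracker_history(trackers)
  ), class = "tracker_set")
}

tracker_table <- function(trackers) {
  data.frame(
    tracker_id = vapply(trackers, `[[`, integer(1L), "id"),
    frame_created = vapply(trackers, `[[`, integer(1L), "frame_created"),
    frame_last = vapply(trackers, `[[`, integer(1L), "frame_last"),
    lifetime = vapply(trackers, `[[`, integer(1L), "lifetime"),
    status = vapply(trackers, `[[`, character(1L), "status")
  )
}

tracker_history <- function(trackers) {
  rows <- lapply(trackers, function(t) {
    boxes <- do.call(rbind, lapply(t$history, `[[`, "box"))
    data.frame(tracker_id = t$id,
               frame = vapply(t$history, `[[`, integer(1L), "frame"),
               boxes)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tracker_id = integer(), frame = integer(),
                      x_min = numeric(), y_min = numeric(),
                      x_max = numeric(), y_max = numeric())
  rownames(out) <- NULL
  out
}

#' @export
print.tracker_set <- function(x, ...) {
  cat("tracker_set:", nrow(x$table), "trackers,",
      sum(x$table$status == "active"), "active at end of stream\n")
  print(head(x$table, 10L))
  invisible(x)
}
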