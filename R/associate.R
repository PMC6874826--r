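# Detection-to-tracker association: minimum total negative-IOU cost over
# one-to-one assignments (Hungarian algorithm), subject to the floor that a
# matched pair must overlap with IOU strictly greater than min_iou.

#' Associate detections with predicted tracker boxes
#'
#' Solves the one-to-one assignment between detection boxes and the trackers'
#' predicted boxes that minimizes total negative IOU, then demotes any matched
#' pair whose IOU does not strictly exceed \code{min_iou} to unmatched. On
#' instances where the floor is feasible this equals the constrained optimum;
#' surplus detections or trackers are reported unmatched.
#'
#' @param det_boxes detections' boxes: matrix/data frame with columns
#'   x_min, y_min, x_max, y_max (one row per detection), or NULL/empty.
#' @param trk_boxes predicted tracker boxes in the same layout. Rows that are
#'   all NA (a tracker whose prediction degenerated) never match.
#' @param min_iou association floor; default 0.1.
#' @return List of class \code{association}:
#'   \code{matches} — integer matrix with columns \code{detection}, \code{tracker}
#'   (row indices into the inputs); \code{unmatched_detections} and
#'   \code{unmatched_trackers} — integer index vectors.
#' @export
associate <- function(det_boxes, trk_boxes, min_iou = 0.1) {
  stopifnot(min_iou >= 0, min_iou < 1)
  d <- if (is.null(det_boxes)) matrix(numeric(), 0L, 4L) else as_box_matrix(det_boxes)
  t <- if (is.null(trk_boxes)) matrix(numeric(), 0L, 4L) else as_box_matrix(trk_boxes)
  nd <- nrow(d); nt <- nrow(t)
  empty <- function() structure(list(
    matches = matrix(integer(), 0L, 2L,
                     dimnames = list(NULL, c("detection", "tracker"))),
    unmatched_detections = seq_len(nd),
    unmatched_trackers = seq_len(nt)
  ), class = "association")
  if (nd == 0L || nt == 0L) return(empty())

  valid_trk <- apply(t, 1L, function(row) all(is.finite(row)))
  ious <- matrix(0, nd, nt)
  if (any(valid_trk))
    ious[, valid_trk] <- iou_matrix(d, t[valid_trk, , drop = FALSE])

  # solve_LSAP needs nonnegative costs and nrow <= ncol; 1 - IOU has the same
  # optimum as -IOU. Pairs at or below the floor can never be matched, so
  # their IOU is zeroed in the cost: this makes the solved assignment (after
  # demoting sub-floor pairs) equal to the optimum of the constrained problem,
  # which would not hold if sub-floor overlaps were left to tilt the solution.
  cost <- 1 - ious * (ious > min_iou)
  if (nd <= nt) {
    sol <- clue::solve_LSAP(cost)
    pairs <- cbind(detection = seq_len(nd), tracker = as.integer(sol))
  } else {
    sol <- clue::solve_LSAP(t(cost))
    pairs <- cbind(detection = as.integer(sol), tracker = seq_len(nt))
  }
  keep <- ious[pairs] > min_iou
  matches <- pairs[keep, , drop = FALSE]
  structure(list(
    matches = matches,
    unmatched_detections = setdiff(seq_len(nd), matches[, 1L]),
    unmatched_trackers = setdiff(seq_len(nt), matches[, 2L])
  ), class = "association")
}
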