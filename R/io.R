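# File formats: MOT-style detection CSV, COCO-style annotation/result JSON,
# tracker tables.
#
# MOT-style CSV columns: frame, id, x, y, w, h, conf, class — x, y is the box
# top-left corner, id is -1 for raw detections.

#' Read a MOT-style detection CSV
#'
#' @param path CSV with columns frame, id, x, y, w, h, conf, class.
#' @return Detection stream data frame (see [detections()]).
#' @export
read_detections_mot <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "x", "y", "w", "h")
  if (!all(need %in% names(d)))
    stop("MOT detection CSV needs columns: frame, id, x, y, w, h, conf, class")
  detections(frame = d$frame,
             x_min = d$x, y_min = d$y,
             x_max = d$x + d$w, y_max = d$y + d$h,
             class = if (is.null(d$class)) "seedling" else d$class,
             conf = if (is.null(d$conf)) 1 else d$conf)
}

#' Write a detection stream as MOT-style CSV
#'
#' @param dets detection stream (see [detections()]).
#' @param path output CSV path.
#' @export
write_detections_mot <- function(dets, path) {
  dets <- validate_detections(dets)
  out <- data.frame(frame = dets$frame, id = -1L,
                    x = dets$x_min, y = dets$y_min,
                    w = dets$x_max - dets$x_min,
                    h = dets$y_max - dets$y_min,
                    conf = dets$conf, class = dets$class)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read COCO-style detection results
#'
#' Accepts the result-list JSON convention: an array of objects with
#' \code{image_id}, \code{category_id}, \code{bbox = [x, y, w, h]} and
#' \code{score}.
#'
#' @param path result JSON file.
#' @param categories optional data frame (id, name) mapping category ids to
#'   class labels; unmapped ids keep the id as label.
#' @return Detection stream data frame; \code{frame} carries the image id.
#' @export
read_detections_coco <- function(path, categories = NULL) {
  res <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (length(res) == 0L || nrow(res) == 0L) return(empty_detections())
  bb <- do.call(rbind, res$bbox)
  cls <- as.character(res$category_id)
  if (!is.null(categories))
    cls <- categories$name[match(res$category_id, categories$id)]
  detections(frame = res$image_id,
             x_min = bb[, 1L], y_min = bb[, 2L],
             x_max = bb[, 1L] + bb[, 3L], y_max = bb[, 2L] + bb[, 4L],
             class = cls, conf = res$score)
}

#' Read a COCO-style annotation file
#'
#' @param path annotation JSON with \code{images}, \code{annotations}
#'   (\code{image_id}, \code{category_id}, \code{bbox}) and \code{categories}.
#' @return List with \code{gts} (data frame: image_id, x_min..y_max, class),
#'   \code{categories} (data frame: id, name) and \code{image_ids}.
#' @export
read_annotations_coco <- function(path) {
  a <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(a$annotations) || is.null(a$categories))
    stop("not a COCO-style annotation file: ", path)
  bb <- do.call(rbind, a$annotations$bbox)
  cats <- data.frame(id = a$categories$id, name = a$categories$name,
                     stringsAsFactors = FALSE)
  gts <- data.frame(
    image_id = a$annotations$image_id,
    x_min = bb[, 1L], y_min = bb[, 2L],
    x_max = bb[, 1L] + bb[, 3L], y_max = bb[, 2L] + bb[, 4L],
    class = cats$name[match(a$annotations$category_id, cats$id)],
    stringsAsFactors = FALSE)
  list(gts = gts, categories = cats,
       image_ids = if (is.null(a$images)) unique(gts$image_id) else a$images$id)
}

#' Write a tracker table and per-frame box history
#'
#' Writes \code{path} with tracker_id, frame_created, frame_last, lifetime,
#' status, and (optionally) a sidecar CSV of per-frame boxes as
#' tracker_id, frame, x, y, w, h.
#'
#' @param ts a \code{tracker_set} from [track_video()].
#' @param path output CSV for the tracker table.
#' @param history_path optional output CSV for the per-frame boxes.
#' @export
write_tracker_table <- function(ts, path, history_path = NULL) {
  stopifnot(inherits(ts, "tracker_set"))
  write.csv(ts$table, path, row.names = FALSE, quote = FALSE)
  if (!is.null(history_path)) {
    h <- ts$history
    out <- data.frame(tracker_id = h$tracker_id, frame = h$frame,
                      x = h$x_min, y = h$y_min,
                      w = h$x_max - h$x_min, h = h$y_max - h$y_min)
    write.csv(out, history_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
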