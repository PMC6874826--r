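# Detection stream contract: a data frame with one row per detected box.
# Columns: frame (integer, 0-based), x_min, y_min, x_max, y_max (px corners),
# class (label, e.g. "seedling"), conf (detector confidence in [0, 1]).

DET_COLS <- c("frame", "x_min", "y_min", "x_max", "y_max", "class", "conf")

#' Build a detection stream data frame
#'
#' @param frame integer frame indices (0-based; the first video frame is 0).
#' @param x_min,y_min,x_max,y_max box corners (px).
#' @param class class labels; default "seedling".
#' @param conf detector confidences in \[0, 1\]; default 1.
#' @return data.frame with the detection-stream columns.
#' @export
detections <- function(frame, x_min, y_min, x_max, y_max,
                       class = "seedling", conf = 1) {
  d <- data.frame(frame = as.integer(frame),
                  x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
                  class = class, conf = conf, stringsAsFactors = FALSE)
  validate_detections(d)
}

empty_detections <- function() {
  detections(integer(), numeric(), numeric(), numeric(), numeric(),
             character(), numeric())
}

validate_detections <- function(d) {
  if (!is.data.frame(d) || !all(DET_COLS %in% names(d)))
    stop("detections must be a data frame with columns: ",
         paste(DET_COLS, collapse = ", "))
  if (nrow(d) == 0L) return(d[, DET_COLS])
  if (any(!is.finite(d$frame)) || any(d$frame != round(d$frame)))
    stop("frame indices must be integers")
  if (any(d$x_max <= d$x_min) || any(d$y_max <= d$y_min))
    stop("detections contain degenerate boxes")
  if (any(d$conf < 0 | d$conf > 1))
    stop("confidences must lie in [0, 1]")
  d[, DET_COLS]
}
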