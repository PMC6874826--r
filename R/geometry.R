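# Bounding-box geometry: IOU and the conversion between corner boxes and the
# tracker measurement parameterization [u, v, s, r].
#
# Coordinate convention: image origin top-left, x rightward, y downward,
# continuous (sub-pixel) coordinates. A box is a named numeric vector
# c(x_min, y_min, x_max, y_max) with x_max > x_min and y_max > y_min.

BOX_FIELDS <- c("x_min", "y_min", "x_max", "y_max")

#' Construct a bounding box
#'
#' @param x_min,y_min,x_max,y_max corner pixel coordinates (origin top-left,
#'   y downward). Coordinates are continuous; no rounding is applied.
#' @return Named numeric vector of length 4.
#' @examples
#' box(0, 0, 2, 2)
#' @export
box <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max)
  validate_box(b)
  b
}

validate_box <- function(b) {
  if (length(b) != 4L || !is.numeric(b) || any(!is.finite(b)))
    stop("a box must be 4 finite numeric coordinates (x_min, y_min, x_max, y_max)")
  if (b[[3L]] <= b[[1L]] || b[[4L]] <= b[[2L]])
    stop("degenerate box: x_max must exceed x_min and y_max must exceed y_min")
  invisible(b)
}

#' Intersection over union of two boxes
#'
#' @param a,b boxes as returned by [box()].
#' @return Overlap ratio in \[0, 1\]; 0 for disjoint boxes, 1 for identical
#'   boxes. Symmetric in its arguments.
#' @examples
#' iou(box(0, 0, 2, 2), box(1, 1, 3, 3)) # 1/7
#' @export
iou <- function(a, b) {
  validate_box(a)
  validate_box(b)
  iw <- min(a[[3L]], b[[3L]]) - max(a[[1L]], b[[1L]])
  ih <- min(a[[4L]], b[[4L]]) - max(a[[2L]], b[[2L]])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[[3L]] - a[[1L]]) * (a[[4L]] - a[[2L]]) +
    (b[[3L]] - b[[1L]]) * (b[[4L]] - b[[2L]]) - inter
  inter / union
}

#' Pairwise IOU between two sets of boxes
#'
#' @param a,b numeric matrices with columns x_min, y_min, x_max, y_max
#'   (one box per row).
#' @return \code{nrow(a)} by \code{nrow(b)} matrix of IOU values.
#' @export
iou_matrix <- function(a, b) {
  a <- as_box_matrix(a)
  b <- as_box_matrix(b)
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  if (n == 0L || m == 0L) return(out)
  area_a <- (a[, 3L] - a[, 1L]) * (a[, 4L] - a[, 2L])
  area_b <- (b[, 3L] - b[, 1L]) * (b[, 4L] - b[, 2L])
  for (j in seq_len(m)) {
    iw <- pmin(a[, 3L], b[j, 3L]) - pmax(a[, 1L], b[j, 1L])
    ih <- pmin(a[, 4L], b[j, 4L]) - pmax(a[, 2L], b[j, 2L])
    inter <- pmax(iw, 0) * pmax(ih, 0)
    out[, j] <- inter / (area_a + area_b[j] - inter)
  }
  out
}

as_box_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, BOX_FIELDS, drop = FALSE])
  if (is.null(dim(x))) x <- matrix(x, ncol = 4L)
  colnames(x) <- BOX_FIELDS
  x
}

#' Convert a corner box to the tracker measurement state
#'
#' The measurement state is \code{[u, v, s, r]}: horizontal and vertical box
#' center (px), box area (px^2), and aspect ratio width/height
#' (dimensionless).
#'
#' @param b box as returned by [box()].
#' @return Named numeric vector \code{c(u, v, s, r)}.
#' @examples
#' box_to_state(box(10, 20, 30, 60)) # u = 20, v = 40, s = 800, r = 0.5
#' @export
box_to_state <- function(b) {
  validate_box(b)
  w <- b[[3L]] - b[[1L]]
  h <- b[[4L]] - b[[2L]]
  c(u = b[[1L]] + w / 2, v = b[[2L]] + h / 2, s = w * h, r = w / h)
}

#' Convert a measurement state back to a corner box
#'
#' Inverse of [box_to_state()]: width = sqrt(s * r), height = sqrt(s / r),
#' centered at (u, v).
#'
#' @param m numeric vector \code{c(u, v, s, r)} with s > 0 and r > 0.
#' @return Box as returned by [box()].
#' @export
state_to_box <- function(m) {
  if (length(m) < 4L || any(!is.finite(m[1:4])))
    stop("measurement state must hold 4 finite values (u, v, s, r)")
  if (m[[3L]] <= 0 || m[[4L]] <= 0)
    stop("measurement state requires positive area s and aspect ratio r")
  w <- sqrt(m[[3L]] * m[[4L]])
  h <- sqrt(m[[3L]] / m[[4L]])
  box(m[[1L]] - w / 2, m[[2L]] - h / 2, m[[1L]] + w / 2, m[[2L]] + h / 2)
}

# Like state_to_box() but returns NULL instead of erroring; used when
# converting a predicted tracker state whose area/ratio may have been carried
# negative by the velocity terms (such trackers simply fail to associate).
state_to_box_safe <- function(m) {
  if (any(!is.finite(m[1:4])) || m[[3L]] <= 0 || m[[4L]] <= 0) return(NULL)
  state_to_box(m)
}
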