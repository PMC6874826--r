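# Frame preprocessing: contrast-limited adaptive histogram equalization
# (CLAHE) applied to the value channel in HSV space — normalizes illumination
# across frames while leaving hue and saturation untouched — and rate-based
# frame extraction from image sequences.

#' CLAHE on the HSV value channel
#'
#' Converts an RGB frame to HSV, applies contrast-limited adaptive histogram
#' equalization to the value channel only, and converts back. Hue and
#' saturation are unchanged; image dimensions are preserved; the operation is
#' deterministic.
#'
#' @param img RGB image as an h x w x 3 numeric array with values in \[0, 1\]
#'   (as returned by [png::readPNG()]) or an 8-bit integer array in
#'   \[0, 255\] (rescaled internally and on output).
#' @param clip CLAHE clip limit (contrast amplification cap); default 2.
#' @param tiles tile grid as c(nx, ny); default 8 x 8.
#' @return Enhanced image in the same layout and scale as the input.
#' @export
clahe_value_channel <- function(img, clip = 2, tiles = c(8, 8)) {
  if (length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stop("expected an RGB image array with 3 channels")
  eight_bit <- max(img) > 1
  x <- if (eight_bit) img / 255 else img
  h <- dim(x)[1L]; w <- dim(x)[2L]
  rgb_flat <- rbind(as.vector(x[, , 1L]), as.vector(x[, , 2L]),
                    as.vector(x[, , 3L]))
  hsv <- grDevices::rgb2hsv(rgb_flat, maxColorValue = 1)
  v <- matrix(hsv[3L, ], h, w)
  # EBImage images are indexed (x, y); transpose in and out
  v_eq <- t(EBImage::clahe(t(v), nx = tiles[1L], ny = tiles[2L], limit = clip))
  v_eq <- pmin(pmax(as.vector(v_eq), 0), 1)
  rgb_eq <- hsv_to_rgb(hsv[1L, ], hsv[2L, ], v_eq)
  out <- array(0, dim(x))
  out[, , 1L] <- matrix(rgb_eq[1L, ], h, w)
  out[, , 2L] <- matrix(rgb_eq[2L, ], h, w)
  out[, , 3L] <- matrix(rgb_eq[3L, ], h, w)
  if (eight_bit) round(out * 255) else out
}

# Vectorized numeric HSV -> RGB (h in [0, 1] turns, s and v in [0, 1]).
# grDevices::hsv() goes through 8-bit hex strings, which would quantize the
# untouched hue/saturation channels; this keeps them at full precision.
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  i <- as.integer(i %% 6)
  r <- ifelse(i == 0L, v, ifelse(i == 1L, q, ifelse(i == 2L, p,
       ifelse(i == 3L, p, ifelse(i == 4L, t, v)))))
  g <- ifelse(i == 0L, t, ifelse(i == 1L, v, ifelse(i == 2L, v,
       ifelse(i == 3L, q, ifelse(i == 4L, p, p)))))
  b <- ifelse(i == 0L, p, ifelse(i == 1L, p, ifelse(i == 2L, t,
       ifelse(i == 3L, v, ifelse(i == 4L, v, q)))))
  rbind(r, g, b)
}

#' Extract frames from an image sequence at a target rate
#'
#' Uniformly decimates a frame sequence from its native frame rate to a
#' requested rate (\code{rate = "native"} keeps every frame). A 30 FPS, 10 s
#' sequence extracted at 6 FPS yields 60 frames. Rates above the native rate
#' are an error (frames cannot be invented).
#'
#' @param frames either a directory of image files (PNG/JPEG, sorted by file
#'   name), a character vector of image paths, or a list of image arrays.
#' @param rate target frames/s, or \code{"native"}.
#' @param native_fps the sequence's native frame rate (frames/s).
#' @param read whether to read pixel data (for path input). With
#'   \code{read = FALSE} only paths and indices are returned.
#' @return List of frames, each a list with \code{frame_index} (0-based index
#'   in the native sequence), \code{source} (path or NA) and \code{pixels}
#'   (array, or NULL when \code{read = FALSE}).
#' @export
extract_frames <- function(frames, rate = "native", native_fps = 30,
                           read = TRUE) {
  stopifnot(native_fps > 0)
  if (is.character(frames) && length(frames) == 1L && dir.exists(frames))
    frames <- sort(list.files(frames, pattern = "\\.(png|jpe?g)$",
                              ignore.case = TRUE, full.names = TRUE))
  n <- length(frames)
  if (n == 0L) stop("no frames found")
  if (is.character(frames) && !all(file.exists(frames)))
    stop("no frames found: missing file(s) ",
         paste(head(frames[!file.exists(frames)], 3), collapse = ", "))
  if (identical(rate, "native")) {
    keep <- seq_len(n)
  } else {
    stopifnot(is.numeric(rate), rate > 0)
    if (rate > native_fps)
      stop("requested rate ", rate, " exceeds the native rate ", native_fps)
    # keep frame i (0-based) when it crosses a new sample instant
    i <- seq_len(n) - 1L
    keep <- which(floor((i + 1L) * rate / native_fps) -
                    floor(i * rate / native_fps) >= 1L)
  }
  lapply(keep, function(k) {
    if (is.list(frames)) {
      list(frame_index = k - 1L, source = NA_character_, pixels = frames[[k]])
    } else {
      px <- NULL
      if (read) {
        px <- if (grepl("\\.png$", frames[k], ignore.case = TRUE))
          png::readPNG(frames[k]) else as.array(EBImage::readImage(frames[k]))
      }
      list(frame_index = k - 1L, source = frames[k], pixels = px)
    }
  })
}

#' Write frames as PNG files
#'
#' @param frames output of [extract_frames()] (with pixel data) or a list of
#'   image arrays.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Paths written, invisibly.
#' @export
write_frames_png <- function(frames, dir, prefix = "frame") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    px <- if (is.list(f) && !is.null(f$pixels)) f$pixels else f
    idx <- if (is.list(f) && !is.null(f$frame_index)) f$frame_index else i - 1L
    if (max(px) > 1) px <- px / 255
    paths[i] <- file.path(dir, sprintf("%s_%06d.png", prefix, idx))
    png::writePNG(px, paths[i])
  }
  invisible(paths)
}
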