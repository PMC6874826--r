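# Synthetic moving-camera row scene: a camera window of the frame size
# translates horizontally at constant speed along a crop row of seedlings with
# jittered spacing and sizes. Every seedling emits a ground-truth box in each
# frame in which its box intersects the window (clipped to the frame), giving
# exact tracks, a clean detection stream, and a known true count. A noise
# model corrupts the clean stream with center/size jitter, per-frame misses,
# and false positives, mimicking the failure modes of a real detector.

maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

#' Scene configuration for the synthetic row generator
#'
#' Defaults emulate a handheld 1080p row scan at 30 FPS: 1920 x 1080 frames,
#' camera advancing 24 px/frame (so a seedling stays in view for roughly 85
#' frames), seedlings roughly 110 x 130 px at a mean spacing of 300 px.
#'
#' @param n_seedlings number of seedlings in the row.
#' @param spacing_mean,spacing_jitter mean and s.d. of the gap between
#'   consecutive seedling centers (px).
#' @param width_mean,width_sd,height_mean,height_sd seedling box size
#'   distribution (px).
#' @param camera_speed_px_per_frame horizontal camera speed (px/frame).
#' @param frame_width,frame_height frame size (px).
#' @param fps video frame rate (frames/s).
#' @param row_length_px camera traversal length; default (NULL) long enough
#'   for every seedling to transit the full frame. A row longer than the
#'   traversal is an error in [simulate_scene()].
#' @param min_visible_px minimum visible (clipped) box width for a seedling to
#'   emit a ground-truth box while entering or leaving the frame. Detectors do
#'   not fire on a few-pixel strip of a plant — the source field datasets do
#'   not even annotate objects under 30 px — so emission starts once at least
#'   this much of the box (or half the box, if narrower) is in view.
#' @param seed RNG seed for reproducible scenes (NULL uses the session RNG).
#' @return List of class \code{scene_config}.
#' @export
scene_config <- function(n_seedlings = 20,
                         spacing_mean = 300, spacing_jitter = 60,
                         width_mean = 110, width_sd = 15,
                         height_mean = 130, height_sd = 15,
                         camera_speed_px_per_frame = 24,
                         frame_width = 1920, frame_height = 1080,
                         fps = 30, row_length_px = NULL,
                         min_visible_px = 30, seed = NULL) {
  stopifnot(n_seedlings >= 1, spacing_mean > 0, spacing_jitter >= 0,
            width_mean > 0, height_mean > 0,
            camera_speed_px_per_frame > 0,
            frame_width > 0, frame_height > 0, fps > 0)
  structure(as.list(environment()), class = "scene_config")
}

#' Detection noise configuration
#'
#' @param center_jitter_sd s.d. of the Gaussian jitter added to each box
#'   center (px).
#' @param size_jitter_sd s.d. of the jitter added to box width and height (px).
#' @param miss_prob probability that a true detection is dropped, per
#'   detection per frame.
#' @param false_positive_rate expected spurious detections per frame
#'   (Poisson).
#' @param conf_mean,conf_sd confidence model for emitted detections
#'   (Gaussian, clamped to \[0.05, 1\]).
#' @param seed RNG seed for reproducible corruption.
#' @return List of class \code{noise_config}.
#' @export
noise_config <- function(center_jitter_sd = 0, size_jitter_sd = 0,
                         miss_prob = 0, false_positive_rate = 0,
                         conf_mean = 0.9, conf_sd = 0.05, seed = NULL) {
  stopifnot(center_jitter_sd >= 0, size_jitter_sd >= 0,
            miss_prob >= 0, miss_prob <= 1, false_positive_rate >= 0,
            conf_mean > 0, conf_mean <= 1, conf_sd >= 0)
  structure(as.list(environment()), class = "noise_config")
}

#' Simulate a clean moving-camera row scene
#'
#' @param cfg [scene_config()].
#' @return Object of class \code{seedling_scene}: list with
#'   \code{gt_tracks} (data frame: seedling_id, frame, x_min..y_max, in frame
#'   coordinates, clipped to the frame), \code{clean_detections} (the same
#'   boxes as a confidence-1 detection stream), \code{true_count},
#'   \code{n_frames} and \code{config}. Deterministic under
#'   \code{cfg$seed}.
#' @export
simulate_scene <- function(cfg = scene_config()) {
  stopifnot(inherits(cfg, "scene_config"))
  maybe_with_seed(cfg$seed, {
    n <- cfg$n_seedlings
    gaps <- pmax(cfg$spacing_mean + rnorm(n, 0, cfg$spacing_jitter),
                 cfg$spacing_mean * 0.2)
    # the row starts beyond the initial camera window so that every seedling
    # makes a full transit across the frame
    x_center <- cfg$frame_width + cumsum(gaps)
    w <- pmax(cfg$width_mean + rnorm(n, 0, cfg$width_sd), 8)
    h <- pmax(cfg$height_mean + rnorm(n, 0, cfg$height_sd), 8)
    v_jit <- rnorm(n, 0, cfg$frame_height / 12)
    y_center <- pmin(pmax(cfg$frame_height / 2 + v_jit, h / 2 + 1),
                     cfg$frame_height - h / 2 - 1)

    row_len <- cfg$row_length_px
    if (is.null(row_len)) row_len <- max(x_center + w / 2) + cfg$spacing_mean
    n_frames <- as.integer(ceiling(row_len / cfg$camera_speed_px_per_frame)) + 1L
    traversal_end <- (n_frames - 1L) * cfg$camera_speed_px_per_frame +
      cfg$frame_width
    if (any(x_center - w / 2 >= traversal_end))
      stop("row longer than the camera traversal: some seedlings are never reached")

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      gx1 <- x_center[i] - w[i] / 2; gx2 <- x_center[i] + w[i] / 2
      # visible while the box overlaps the window [off, off + frame_width]
      f_lo <- max(0L, as.integer(floor((gx1 - cfg$frame_width) /
                                         cfg$camera_speed_px_per_frame)) )
      f_hi <- min(n_frames - 1L,
                  as.integer(ceiling(gx2 / cfg$camera_speed_px_per_frame)))
      fr <- seq.int(f_lo, f_hi)
      off <- fr * cfg$camera_speed_px_per_frame
      x1 <- pmax(gx1 - off, 0); x2 <- pmin(gx2 - off, cfg$frame_width)
      vis <- x2 - x1 >= min(cfg$min_visible_px, w[i] / 2)
      if (!any(vis)) next
      rows[[i]] <- data.frame(seedling_id = i, frame = fr[vis],
                              x_min = x1[vis], y_min = y_center[i] - h[i] / 2,
                              x_max = x2[vis], y_max = y_center[i] + h[i] / 2)
    }
    gt <- do.call(rbind, rows)
    gt <- gt[order(gt$frame, gt$seedling_id), ]
    rownames(gt) <- NULL
    clean <- detections(frame = gt$frame,
                        x_min = gt$x_min, y_min = gt$y_min,
                        x_max = gt$x_max, y_max = gt$y_max,
                        class = "seedling", conf = 1)
    structure(list(gt_tracks = gt, clean_detections = clean,
                   true_count = n, n_frames = n_frames, config = cfg),
              class = "seedling_scene")
  })
}

#' Corrupt a clean scene into a noisy detection stream
#'
#' Each ground-truth box is independently dropped with \code{miss_prob},
#' jittered in center and size, and assigned a confidence from the noise
#' config's model; spurious false-positive boxes are added per frame at the
#' configured Poisson rate. With identity noise (all zeros) the output boxes
#' equal the clean stream. Deterministic under \code{noise$seed}.
#'
#' @param scene [simulate_scene()] output.
#' @param noise [noise_config()].
#' @return Detection stream data frame.
#' @export
corrupt_detections <- function(scene, noise = noise_config()) {
  stopifnot(inherits(scene, "seedling_scene"), inherits(noise, "noise_config"))
  cfg <- scene$config
  maybe_with_seed(noise$seed, {
    d <- scene$clean_detections
    keep <- runif(nrow(d)) >= noise$miss_prob
    d <- d[keep, , drop = FALSE]
    m <- nrow(d)
    if (m > 0L) {
      cx <- (d$x_min + d$x_max) / 2 + rnorm(m, 0, noise$center_jitter_sd)
      cy <- (d$y_min + d$y_max) / 2 + rnorm(m, 0, noise$center_jitter_sd)
      w <- pmax(d$x_max - d$x_min + rnorm(m, 0, noise$size_jitter_sd), 4)
      h <- pmax(d$y_max - d$y_min + rnorm(m, 0, noise$size_jitter_sd), 4)
      d$x_min <- cx - w / 2; d$x_max <- cx + w / 2
      d$y_min <- cy - h / 2; d$y_max <- cy + h / 2
      d$conf <- pmin(pmax(rnorm(m, noise$conf_mean, noise$conf_sd), 0.05), 1)
    }
    if (noise$false_positive_rate > 0) {
      n_fp <- rpois(scene$n_frames, noise$false_positive_rate)
      tot <- sum(n_fp)
      if (tot > 0L) {
        fw <- pmax(cfg$width_mean + rnorm(tot, 0, cfg$width_sd * 2), 8)
        fh <- pmax(cfg$height_mean + rnorm(tot, 0, cfg$height_sd * 2), 8)
        fx <- runif(tot, fw / 2, cfg$frame_width - fw / 2)
        fy <- runif(tot, fh / 2, cfg$frame_height - fh / 2)
        fp <- detections(
          frame = rep.int(seq_len(scene$n_frames) - 1L, n_fp),
          x_min = fx - fw / 2, y_min = fy - fh / 2,
          x_max = fx + fw / 2, y_max = fy + fh / 2,
          class = "seedling",
          conf = pmin(pmax(rnorm(tot, noise$conf_mean, noise$conf_sd), 0.05), 1))
        d <- rbind(d, fp)
      }
    }
    d <- d[order(d$frame), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
}

#' Write a scene to disk
#'
#' Writes the (clean or corrupted) detection stream as a MOT-style CSV and the
#' ground-truth tracks as a CSV (seedling_id, frame, x, y, w, h).
#'
#' @param scene [simulate_scene()] output.
#' @param dir output directory (created if missing).
#' @param dets optional detection stream to write instead of the clean one
#'   (e.g. [corrupt_detections()] output).
#' @return The directory, invisibly.
#' @export
write_scene <- function(scene, dir, dets = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(dets)) dets <- scene$clean_detections
  write_detections_mot(dets, file.path(dir, "detections.csv"))
  gt <- scene$gt_tracks
  write.csv(data.frame(seedling_id = gt$seedling_id, frame = gt$frame,
                       x = gt$x_min, y = gt$y_min,
                       w = gt$x_max - gt$x_min, h = gt$y_max - gt$y_min),
            file.path(dir, "gt_tracks.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Render a scene frame as a simple raster image
#'
#' Draws each visible seedling as a pair of green discs (a stylized cotyledon
#' pair) on a speckled soil-colored background, so the preprocessing module
#' can be exercised end-to-end. Rendering fidelity is not a goal.
#'
#' @param scene [simulate_scene()] output.
#' @param frame frame index to render.
#' @param scale downscale factor for the output raster (default 0.25 keeps
#'   test images small).
#' @return RGB array (h x w x 3, values in \[0, 1\]).
#' @export
render_scene_frame <- function(scene, frame, scale = 0.25) {
  cfg <- scene$config
  w <- max(8L, as.integer(round(cfg$frame_width * scale)))
  h <- max(8L, as.integer(round(cfg$frame_height * scale)))
  maybe_with_seed(if (is.null(cfg$seed)) NULL else cfg$seed + frame, {
    soil <- array(0, c(h, w, 3L))
    speck <- matrix(runif(h * w, -0.05, 0.05), h, w)
    soil[, , 1L] <- pmin(pmax(0.45 + speck, 0), 1)
    soil[, , 2L] <- pmin(pmax(0.33 + speck, 0), 1)
    soil[, , 3L] <- pmin(pmax(0.22 + speck, 0), 1)
    g <- scene$gt_tracks[scene$gt_tracks$frame == frame, , drop = FALSE]
    if (nrow(g) > 0L) {
      xs <- matrix(rep(seq_len(w), each = h), h, w)
      ys <- matrix(rep(seq_len(h), times = w), h, w)
      for (i in seq_len(nrow(g))) {
        cx <- (g$x_min[i] + g$x_max[i]) / 2 * scale
        cy <- (g$y_min[i] + g$y_max[i]) / 2 * scale
        rad <- (g$x_max[i] - g$x_min[i]) * scale / 4
        for (dxs in c(-rad, rad)) {
          disc <- (xs - (cx + dxs))^2 + (ys - cy)^2 <= rad^2
          soil[, , 1L][disc] <- 0.15
          soil[, , 2L][disc] <- 0.55
          soil[, , 3L][disc] <- 0.12
        }
      }
    }
    soil
  })
}
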