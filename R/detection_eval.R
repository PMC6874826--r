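# Detection metrics following the COCO evaluation protocol: greedy
# confidence-ordered matching at an IOU threshold, 101-point interpolated
# average precision, average recall over the top-100 detections per image, and
# F1 computed from the (AP, AR100) pair. Metrics are reported at IOU 0.5 and
# averaged over the strict regime IOU 0.5:0.05:0.95 ("IOU_all").

IOU_ALL <- seq(0.5, 0.95, by = 0.05)

# Ground truth: data.frame(image_id, x_min..y_max, class).
# Detections:  data.frame(image_id, x_min..y_max, class, conf).
# A detection stream with a `frame` column (see detections()) is accepted:
# the frame index is used as the image id.
norm_eval_df <- function(d) {
  if (!"image_id" %in% names(d) && "frame" %in% names(d)) d$image_id <- d$frame
  if (!"image_id" %in% names(d))
    stop("expected an image_id (or frame) column")
  d
}

#' Match detections to ground truth at one IOU threshold
#'
#' Per image and class, detections are processed in descending confidence
#' (optionally capped at \code{max_dets} per image and class); each is matched
#' to the not-yet-matched same-class ground-truth box with the highest
#' IOU >= \code{threshold}, else flagged false positive. Each ground truth is
#' matched at most once.
#'
#' @param gts ground-truth data frame (image_id, x_min..y_max, class).
#' @param dets detection data frame (image_id, x_min..y_max, class, conf).
#' @param threshold IOU threshold in (0, 1\].
#' @param max_dets cap on detections per image and class (COCO uses 100).
#' @return List: \code{det} — the (possibly capped) detections with a logical
#'   \code{tp} column; \code{n_gt} — number of ground-truth boxes considered;
#'   \code{fn} — ground truths left unmatched.
#' @export
match_at_iou <- function(gts, dets, threshold, max_dets = 100L) {
  stopifnot(threshold > 0, threshold <= 1)
  gts <- norm_eval_df(gts)
  dets <- norm_eval_df(dets)
  keep <- logical(0)
  tp <- logical(0)
  kept_idx <- integer(0)
  if (nrow(dets) > 0L) {
    parts <- split(seq_len(nrow(dets)), list(dets$image_id, dets$class),
                   drop = TRUE)
    for (idx in parts) {
      idx <- idx[order(-dets$conf[idx])]
      idx <- idx[seq_len(min(length(idx), max_dets))]
      img <- dets$image_id[idx[1L]]
      cls <- dets$class[idx[1L]]
      g <- which(gts$image_id == img & gts$class == cls)
      g_used <- rep(FALSE, length(g))
      flags <- logical(length(idx))
      if (length(g) > 0L) {
        ious <- iou_matrix(dets[idx, , drop = FALSE], gts[g, , drop = FALSE])
        for (i in seq_along(idx)) {
          cand <- which(!g_used & ious[i, ] >= threshold)
          if (length(cand) > 0L) {
            best <- cand[which.max(ious[i, cand])]
            g_used[best] <- TRUE
            flags[i] <- TRUE
          }
        }
      }
      kept_idx <- c(kept_idx, idx)
      tp <- c(tp, flags)
    }
  }
  det <- dets[kept_idx, , drop = FALSE]
  det$tp <- tp
  rownames(det) <- NULL
  list(det = det, n_gt = nrow(gts), fn = nrow(gts) - sum(tp))
}

#' 101-point interpolated average precision
#'
#' Detections (their TP/FP flags) are ordered by descending confidence;
#' precision is interpolated as the maximum precision at any recall at or
#' above each of the 101 evenly spaced recall points 0, 0.01, ..., 1, and
#' averaged.
#'
#' @param tp logical TP flags per detection.
#' @param conf matching confidences.
#' @param n_gt number of ground-truth boxes for the class (> 0; 0 gives NA).
#' @return AP in \[0, 1\], or NA if \code{n_gt} is 0.
#' @export
average_precision <- function(tp, conf, n_gt) {
  if (n_gt == 0L) return(NA_real_)
  mean(pr_interpolated(tp, conf, n_gt)$precision)
}

pr_interpolated <- function(tp, conf, n_gt) {
  rec_pts <- seq(0, 1, by = 0.01)
  if (length(tp) == 0L)
    return(data.frame(recall = rec_pts, precision = 0))
  o <- order(-conf)
  tp <- tp[o]
  ctp <- cumsum(tp)
  precision <- ctp / seq_along(tp)
  recall <- ctp / n_gt
  p_int <- vapply(rec_pts, function(q) {
    ok <- recall >= q
    if (any(ok)) max(precision[ok]) else 0
  }, numeric(1L))
  data.frame(recall = rec_pts, precision = p_int)
}

#' Average recall with at most 100 detections per image
#'
#' Recall using at most the \code{max_dets} highest-confidence detections per
#' image and class, averaged over the requested IOU thresholds.
#'
#' @param gts,dets as in [match_at_iou()].
#' @param iou_thresholds IOU thresholds to average over (a single value for
#'   the IOU 0.5 regime; \code{seq(0.5, 0.95, 0.05)} for IOU_all).
#' @param max_dets detection cap per image and class.
#' @return AR in \[0, 1\], or NA when there is no ground truth.
#' @export
average_recall_100 <- function(gts, dets, iou_thresholds = IOU_ALL,
                               max_dets = 100L) {
  if (nrow(gts) == 0L) return(NA_real_)
  recalls <- vapply(iou_thresholds, function(t) {
    m <- match_at_iou(gts, dets, t, max_dets)
    sum(m$det$tp) / m$n_gt
  }, numeric(1L))
  mean(recalls)
}

f1_score <- function(p, r) {
  if (is.na(p) || is.na(r) || p + r == 0) return(NA_real_)
  2 * p * r / (p + r)
}

#' Summarize detection performance
#'
#' Computes, per category, AP / AR100 / F1 at IOU 0.5, and overall mAP /
#' mAR100 / F1 at IOU 0.5 and averaged over IOU 0.5:0.05:0.95 (IOU_all),
#' together with per-category 101-point PR curves at IOU 0.5. Categories with
#' no ground truth get NA and are excluded from the means.
#'
#' @param gts ground-truth data frame (image_id, x_min..y_max, class).
#' @param dets detection data frame (image_id, x_min..y_max, class, conf).
#' @param categories category labels to evaluate; default: classes present in
#'   the ground truth.
#' @return Object of class \code{metrics_summary}: list with
#'   \code{per_category} (data frame: class, n_gt, AP_50, AR100_50, F1_50,
#'   AP_all, AR100_all), \code{overall} (data frame: regime, mAP, mAR100, F1)
#'   and \code{pr_curves} (named list of recall/precision data frames).
#' @export
evaluate_detections <- function(gts, dets, categories = NULL) {
  if (nrow(gts) == 0L) stop("empty ground truth: nothing to evaluate")
  gts <- norm_eval_df(gts)
  dets <- norm_eval_df(dets)
  if (is.null(categories)) categories <- sort(unique(gts$class))
  per <- lapply(categories, function(cl) {
    g <- gts[gts$class == cl, , drop = FALSE]
    d <- dets[dets$class == cl, , drop = FALSE]
    if (nrow(g) == 0L)
      return(list(row = data.frame(class = cl, n_gt = 0L, AP_50 = NA,
                                   AR100_50 = NA, F1_50 = NA, AP_all = NA,
                                   AR100_all = NA),
                  pr = NULL))
    ap_t <- vapply(IOU_ALL, function(t) {
      m <- match_at_iou(g, d, t)
      average_precision(m$det$tp, m$det$conf, m$n_gt)
    }, numeric(1L))
    ap50 <- ap_t[1L]
    ar50 <- average_recall_100(g, d, 0.5)
    m50 <- match_at_iou(g, d, 0.5)
    list(row = data.frame(class = cl, n_gt = nrow(g),
                          AP_50 = ap50, AR100_50 = ar50,
                          F1_50 = f1_score(ap50, ar50),
                          AP_all = mean(ap_t),
                          AR100_all = average_recall_100(g, d, IOU_ALL)),
         pr = pr_interpolated(m50$det$tp, m50$det$conf, m50$n_gt))
  })
  per_category <- do.call(rbind, lapply(per, `[[`, "row"))
  valid <- per_category$n_gt > 0L
  map50 <- mean(per_category$AP_50[valid])
  mar50 <- mean(per_category$AR100_50[valid])
  map_all <- mean(per_category$AP_all[valid])
  mar_all <- mean(per_category$AR100_all[valid])
  overall <- data.frame(
    regime = c("IOU_0.5", "IOU_all"),
    mAP = c(map50, map_all),
    mAR100 = c(mar50, mar_all),
    F1 = c(f1_score(map50, mar50), f1_score(map_all, mar_all)))
  pr_curves <- setNames(lapply(per, `[[`, "pr"), categories)
  structure(list(per_category = per_category, overall = overall,
                 pr_curves = pr_curves[!vapply(pr_curves, is.null, logical(1L))]),
            class = "metrics_summary")
}

#' @export
print.metrics_summary <- function(x, ...) {
  cat("Detection metrics\n\nPer category (IOU 0.5):\n")
  print(x$per_category, row.names = FALSE, digits = 4)
  cat("\nOverall:\n")
  print(x$overall, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a metrics summary and PR curves to disk
#'
#' @param summary [evaluate_detections()] output.
#' @param json_path output JSON (per-category and overall tables).
#' @param pr_dir optional directory for per-category PR-curve CSVs.
#' @export
write_metrics <- function(summary, json_path, pr_dir = NULL) {
  jsonlite::write_json(list(per_category = summary$per_category,
                            overall = summary$overall),
                       json_path, dataframe = "rows", digits = NA, na = "null")
  if (!is.null(pr_dir)) {
    if (!dir.exists(pr_dir)) dir.create(pr_dir, recursive = TRUE)
    for (cl in names(summary$pr_curves))
      write.csv(summary$pr_curves[[cl]],
                file.path(pr_dir, paste0("pr_", cl, ".csv")),
                row.names = FALSE)
  }
  invisible(json_path)
}
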