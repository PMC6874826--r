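# Counting-accuracy evaluation: least-squares regression of algorithm counts
# on field-assessed counts (with or without intercept), plus error metrics
# (RMSE, MAE, MRE) and an absolute-error histogram.

#' Regress predicted counts on observed counts
#'
#' Ordinary least squares of predicted on observed, with an intercept or
#' through the origin. Reports the slope, intercept (if any), adjusted
#' R-squared and RMSE of the fit, plus MAE and MRE of the raw count errors.
#' Both fit variants are meaningful for count calibration: a through-origin
#' slope answers "what fraction of the true stand is counted", while the
#' intercept fit exposes additive bias.
#'
#' @param predicted,observed paired per-video counts (length >= 3);
#'   \code{observed} must have positive variance and, for MRE, be positive.
#' @param through_origin fit without intercept.
#' @return List of class \code{regression_report}: slope, intercept (NA for
#'   through-origin), adj_r_squared, rmse, mae, mre_pct, n.
#' @examples
#' count_regression(c(10, 19, 32, 41, 48), c(10, 20, 30, 40, 50))
#' @export
count_regression <- function(predicted, observed, through_origin = FALSE) {
  check_pairs(predicted, observed)
  if (sd(observed) == 0)
    stop("observed counts have zero variance; regression is undefined")
  fit <- if (through_origin) lm(predicted ~ 0 + observed)
         else lm(predicted ~ observed)
  cf <- coef(fit)
  res <- as.numeric(residuals(fit))
  structure(list(
    slope = unname(cf[["observed"]]),
    intercept = if (through_origin) NA_real_ else unname(cf[["(Intercept)"]]),
    # a perfect fit is a legitimate input here (predicted == observed);
    # summary.lm warns about it
    adj_r_squared = suppressWarnings(summary(fit)$adj.r.squared),
    rmse = sqrt(mean(res^2)),
    mae = mean(abs(predicted - observed)),
    mre_pct = 100 * mean(abs(predicted - observed) / observed),
    n = length(predicted),
    through_origin = through_origin
  ), class = "regression_report")
}

#' Count error metrics and absolute-error histogram
#'
#' MAE = mean |predicted - observed|; MRE = 100 * mean(|predicted - observed|
#' / observed). The histogram of absolute errors summarizes how many videos
#' fall within each error band.
#'
#' @param predicted,observed paired counts; \code{observed} must be > 0.
#' @param breaks histogram breaks for the absolute errors (passed to
#'   [graphics::hist()], not plotted).
#' @return List: mae, mre_pct, histogram (counts per bin), breaks.
#' @export
count_errors <- function(predicted, observed, breaks = "Sturges") {
  check_pairs(predicted, observed, min_n = 1L)
  if (any(observed <= 0)) stop("observed counts must be positive for MRE")
  abs_err <- abs(predicted - observed)
  hs <- graphics::hist(abs_err, breaks = breaks, plot = FALSE)
  list(mae = mean(abs_err),
       mre_pct = 100 * mean(abs_err / observed),
       histogram = hs$counts,
       breaks = hs$breaks)
}

check_pairs <- function(predicted, observed, min_n = 3L) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  if (length(predicted) < min_n)
    stop("need at least ", min_n, " paired counts")
  if (any(!is.finite(predicted)) || any(!is.finite(observed)))
    stop("counts must be finite")
  invisible(TRUE)
}

#' Read a counts CSV
#'
#' @param path CSV with columns video_id, predicted, observed.
#' @return data.frame with those columns.
#' @export
read_count_pairs <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("video_id", "predicted", "observed") %in% names(d)))
    stop("counts CSV needs columns: video_id, predicted, observed")
  d
}

#' @export
print.regression_report <- function(x, ...) {
  eq <- if (x$through_origin)
    sprintf("predicted = %.3f * observed", x$slope)
  else
    sprintf("predicted = %.3f * observed %+.3f", x$slope, x$intercept)
  cat("Counting accuracy (n =", x$n, "videos)\n  fit:", eq, "\n")
  cat(sprintf("  adj. R^2 = %.4f, RMSE = %.3f, MAE = %.3f, MRE = %.2f%%\n",
              x$adj_r_squared, x$rmse, x$mae, x$mre_pct))
  invisible(x)
}

#' Write a counting-accuracy report
#'
#' @param report [count_regression()] output (or a list of them).
#' @param json_path output JSON path.
#' @param csv_path optional CSV path (one row per report).
#' @export
write_regression_report <- function(report, json_path, csv_path = NULL) {
  reports <- if (inherits(report, "regression_report")) list(report) else report
  rows <- do.call(rbind, lapply(reports, function(r)
    data.frame(slope = r$slope, intercept = r$intercept,
               adj_r_squared = r$adj_r_squared, rmse = r$rmse,
               mae = r$mae, mre_pct = r$mre_pct, n = r$n,
               through_origin = r$through_origin)))
  jsonlite::write_json(rows, json_path, dataframe = "rows",
                       digits = NA, na = "null")
  if (!is.null(csv_path)) write.csv(rows, csv_path, row.names = FALSE)
  invisible(json_path)
}
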