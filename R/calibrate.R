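#' Confusion matrix at a logFC sensitivity threshold
#'
#' A line is predicted sensitive when its logFC is strictly below the
#' threshold `t` (a value exactly equal to `t` is predicted resistant).
#' Positives are the biomarker-positive lines, so `tp` counts
#' biomarker-positive lines predicted sensitive.
#'
#' @param values Numeric logFC per line.
#' @param labels Binary biomarker labels per line (1/TRUE = positive),
#'   aligned with `values`. Both classes must be present.
#' @param t Threshold on the logFC scale.
#' @return Named list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_threshold <- function(values, labels, t) {
  if (length(values) != length(labels)) {
    abort("`values` and `labels` must be aligned.")
  }
  labels <- as.logical(labels)
  if (anyNA(values) || anyNA(labels)) abort("missing values/labels not allowed.")
  if (all(labels) || !any(labels)) {
    abort("both classes required: sensitivity or specificity is undefined.")
  }
  pred <- values < t
  list(
    tp = sum(pred & labels),
    fp = sum(pred & !labels),
    tn = sum(!pred & !labels),
    fn = sum(!pred & labels)
  )
}

#' Scan thresholds and pick the sensitivity cutoff by Youden's index
#'
#' For every candidate threshold the sensitivity (`tp / (tp + fn)`),
#' specificity (`tn / (tn + fp)`) and Youden's J (`sensitivity +
#' specificity - 1`) are computed against biomarker ground truth, and the
#' threshold maximizing J is chosen. Ties are broken toward the threshold of
#' smallest absolute value (the most conservative call rate).
#'
#' @param data Data frame with the per-line values and labels (the shape
#'   [generate_calibration_set()] emits), or a plain numeric vector of logFC
#'   values (in which case `labels` must be the label vector).
#' @param values,labels Column names (tidy evaluation) when `data` is a data
#'   frame; when `data` is a numeric vector, `labels` is the aligned binary
#'   label vector.
#' @param grid Numeric vector of candidate thresholds. Default: the sorted
#'   unique observed values plus -1 (the conventional screen cutoff).
#' @return A `calibration_curve` tibble with columns `threshold`, `tp`, `fp`,
#'   `tn`, `fn`, `sensitivity`, `specificity`, `youden`, and attribute
#'   `chosen_threshold`. See [glance.calibration_curve()].
#' @export
youden_scan <- function(data, values = logfc, labels = biomarker,
                        grid = NULL) {
  if (is.data.frame(data)) {
    v <- dplyr::pull(data, {{ values }})
    l <- dplyr::pull(data, {{ labels }})
  } else {
    v <- data
    l <- labels
    if (!is.numeric(v) || length(l) != length(v)) {
      abort("pass a data frame, or aligned `data` and `labels` vectors.")
    }
  }
  if (is.null(grid)) grid <- sort(unique(c(v, -1)))
  if (length(grid) == 0) abort("`grid` must be non-empty.")

  rows <- lapply(grid, function(t) {
    cm <- confusion_at_threshold(v, l, t)
    sens <- cm$tp / (cm$tp + cm$fn)
    spec <- cm$tn / (cm$tn + cm$fp)
    tibble::tibble(
      threshold = t, tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
      sensitivity = sens, specificity = spec, youden = sens + spec - 1
    )
  })
  curve <- dplyr::bind_rows(rows)
  best <- which(curve$youden == max(curve$youden))
  chosen <- curve$threshold[best][which.min(abs(curve$threshold[best]))]
  structure(curve,
    chosen_threshold = chosen,
    class = c("calibration_curve", class(curve))
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(
    "<calibration_curve> chosen threshold:",
    attr(x, "chosen_threshold"), "\n"
  )
  NextMethod()
}

#' Summarize a calibration curve at its chosen threshold
#'
#' @param x A `calibration_curve` from [youden_scan()].
#' @param ... Unused.
#' @return One-row tibble: `chosen_threshold`, `sensitivity`, `specificity`,
#'   `youden`.
#' @export
glance.calibration_curve <- function(x, ...) {
  t0 <- attr(x, "chosen_threshold")
  row <- x[x$threshold == t0, ]
  tibble::tibble(
    chosen_threshold = t0,
    sensitivity = row$sensitivity[1],
    specificity = row$specificity[1],
    youden = row$youden[1]
  )
}

#' @export
tidy.calibration_curve <- function(x, ...) {
  out <- x
  attr(out, "chosen_threshold") <- NULL
  class(out) <- class(tibble::tibble())
  out
}
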