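#' @name evaluate
#' @title Beat-level evaluation: sensitivity and positive predictivity
#'
#' @description
#' Detected peaks are matched one-to-one to reference peaks within a time
#' tolerance (default 100 ms - the tolerance is the main comparability caveat
#' between studies, so it is an explicit argument everywhere). Matched pairs
#' are true positives; unmatched detections false positives; unmatched
#' references false negatives. `Se = 100 * TP / (TP + FN)`,
#' `PP = 100 * TP / (TP + FP)`. Multi-record summaries report both the
#' unweighted per-record mean (the headline figure) and the pooled
#' micro-average.
NULL

#' Match detected peaks against reference peaks
#'
#' Both series sorted ascending; detections are processed in time order and
#' each is matched to the earliest unmatched reference within the tolerance.
#' For sorted series this greedy scheme attains the maximum possible number of
#' matches (it is equivalent to maximum-cardinality bipartite matching on the
#' tolerance graph), and the match count is symmetric in the two inputs.
#'
#' @param detected integer sample indices, sorted ascending
#' @param reference integer sample indices, sorted ascending
#' @param tolerance matching tolerance in seconds
#' @param fs sampling frequency in Hz
#' @return list with `tp`, `fp`, `fn` and `pairs` (matrix of matched
#'   detected/reference indices)
#' @export
match_peaks <- function(detected, reference, tolerance = 0.100, fs) {
  stopifnot(!is.unsorted(detected), !is.unsorted(reference),
            tolerance >= 0, fs > 0)
  tol <- tolerance * fs
  nd <- length(detected)
  nr <- length(reference)
  used <- rep(FALSE, nr)
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("detected", "reference")))
  j <- 1L
  for (k in seq_len(nd)) {
    while (j <= nr && (used[j] || reference[j] < detected[k] - tol)) j <- j + 1L
    if (j <= nr && abs(reference[j] - detected[k]) <= tol) {
      used[j] <- TRUE
      pairs <- rbind(pairs, c(detected[k], reference[j]))
      j <- j + 1L
    }
  }
  tp <- sum(used)
  list(tp = tp, fp = nd - tp, fn = nr - tp, pairs = pairs)
}

#' Summarize matches into Se/PP, per record and pooled
#'
#' @param per_record named list; each element a list with `tp`, `fp`, `fn`
#'   (e.g. the output of [match_peaks()]), one per record
#' @param tolerance the tolerance the counts were computed with (metadata)
#' @return an `eval_result`: per-record table, the unweighted mean of the
#'   per-record Se/PP (records where a metric is undefined are excluded from
#'   that mean - e.g. an all-AFIB record with no reference P and no
#'   detections), and the pooled micro-average
#' @export
score_detections <- function(per_record, tolerance = 0.100) {
  stopifnot(length(per_record) >= 1)
  ids <- names(per_record) %||% as.character(seq_along(per_record))
  tab <- do.call(rbind, lapply(seq_along(per_record), function(k) {
    m <- per_record[[k]]
    se <- if (m$tp + m$fn > 0) 100 * m$tp / (m$tp + m$fn) else NA_real_
    pp <- if (m$tp + m$fp > 0) 100 * m$tp / (m$tp + m$fp) else NA_real_
    data.frame(record_id = ids[k], tp = m$tp, fp = m$fp, fn = m$fn,
               se = se, pp = pp, stringsAsFactors = FALSE)
  }))
  tp <- sum(tab$tp); fp <- sum(tab$fp); fn <- sum(tab$fn)
  structure(list(
    per_record = tab,
    mean_se = mean(tab$se, na.rm = TRUE),
    mean_pp = mean(tab$pp, na.rm = TRUE),
    pooled_se = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    pooled_pp = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    tp = tp, fp = fp, fn = fn,
    tolerance = tolerance
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %d records, tolerance %g s\n",
              nrow(x$per_record), x$tolerance))
  cat(sprintf("  mean   Se %.2f%%  PP %.2f%%\n", x$mean_se, x$mean_pp))
  cat(sprintf("  pooled Se %.2f%%  PP %.2f%%  (TP %d, FP %d, FN %d)\n",
              x$pooled_se, x$pooled_pp, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Evaluate detected against reference P peaks for one record
#'
#' Convenience wrapper: [match_peaks()] on the `p_peaks` of two
#' [wave_annotations()] objects.
#'
#' @param detected,reference [wave_annotations()]
#' @param tolerance matching tolerance in seconds
#' @param fs sampling frequency in Hz
#' @return list with `tp`, `fp`, `fn`, `se`, `pp`
#' @export
evaluate_p <- function(detected, reference, tolerance = 0.100, fs) {
  m <- match_peaks(detected$p_peaks, reference$p_peaks, tolerance, fs)
  m$se <- if (m$tp + m$fn > 0) 100 * m$tp / (m$tp + m$fn) else NA_real_
  m$pp <- if (m$tp + m$fp > 0) 100 * m$tp / (m$tp + m$fp) else NA_real_
  m
}
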