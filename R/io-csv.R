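#' Read an ECG from CSV
#'
#' Two dialects: a single `value` column (then `fs` must be supplied), or two
#' columns `time, value` (any time column is ignored for indexing - sample
#' `i` is always `(i-1)/fs` seconds - but is used to infer `fs` when not
#' given).
#'
#' @param path CSV file path
#' @param fs sampling frequency in Hz; required for one-column files
#' @param lead,record_id labels for the returned record
#' @return an [ecg_record()]
#' @export
read_ecg_csv <- function(path, fs = NULL, lead = "I", record_id = NULL) {
  df <- read.csv(path)
  record_id <- record_id %||% sub("\\.[^.]*$", "", basename(path))
  if (ncol(df) == 1) {
    if (is.null(fs)) stop("fs is required for a one-column CSV")
    return(ecg_record(df[[1]], fs, lead, record_id))
  }
  if (is.null(fs)) {
    dt <- diff(df[[1]])
    if (any(dt <= 0)) stop("time column must be strictly increasing")
    fs <- 1 / median(dt)
  }
  ecg_record(df[[2]], fs, lead, record_id)
}

#' Write detected annotations as CSV
#'
#' One row per annotated peak: `record_id`, `sample_index` (1-based) and
#' `code` (`p`, `t` or `N` for R peaks).
#'
#' @param ann a [wave_annotations()]
#' @param path output CSV path
#' @param record_id record identifier written to every row
#' @return `path`, invisibly
#' @export
write_annotations_csv <- function(ann, path, record_id = "record") {
  stopifnot(inherits(ann, "wave_annotations"))
  df <- rbind(
    data.frame(sample_index = ann$p_peaks, code = rep("p", length(ann$p_peaks))),
    data.frame(sample_index = ann$t_peaks, code = rep("t", length(ann$t_peaks))),
    data.frame(sample_index = ann$r_peaks, code = rep("N", length(ann$r_peaks)))
  )
  df <- df[order(df$sample_index), , drop = FALSE]
  df <- cbind(record_id = rep(record_id, nrow(df)), df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read annotations from CSV written by [write_annotations_csv()]
#'
#' @param path CSV path
#' @param source label for the returned annotations
#' @return a [wave_annotations()]
#' @export
read_annotations_csv <- function(path, source = "detected") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  pick <- function(code) sort(unique(df$sample_index[df$code == code]))
  wave_annotations(p_peaks = pick("p"), t_peaks = pick("t"),
                   r_peaks = pick("N"), source = source)
}
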