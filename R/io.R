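# Readers and writers for the plain-text artifact formats: CSV traces and
# feature tables, JSON weights/truth/assignments, BED-like interval text.
# Floats are serialized with full precision (17 significant digits).

#' Read a gaze trace from CSV
#'
#' Expects a header `time_ms,x_deg,y_deg` with monotone time at a fixed
#' step; the sampling rate is inferred from the time column.
#'
#' @param path CSV file path.
#' @param expected_rate_hz Optional rate to enforce; a mismatch errors.
#' @return A [gaze_trace()].
#' @export
read_trace <- function(path, expected_rate_hz = NULL) {
  df <- utils::read.csv(path)
  need <- c("time_ms", "x_deg", "y_deg")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("malformed trace CSV '", path, "': missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) < 2L) stop("trace CSV '", path, "' has fewer than 2 samples")
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad))
    stop("trace CSV '", path, "': non-finite values at line ", bad[1L] + 1L)
  dt <- diff(df$time_ms)
  if (any(dt <= 0))
    stop("trace CSV '", path, "': non-monotone time at line ",
         which(dt <= 0)[1L] + 2L)
  step <- stats::median(dt)
  if (any(abs(dt - step) > 0.01 * step))
    stop("trace CSV '", path, "': non-uniform sampling at line ",
         which(abs(dt - step) > 0.01 * step)[1L] + 2L)
  rate <- 1000 / step
  if (!is.null(expected_rate_hz) && abs(rate - expected_rate_hz) > 1e-6 * expected_rate_hz)
    stop("trace CSV '", path, "': sampling rate ", rate,
         " Hz does not match expected ", expected_rate_hz, " Hz")
  gaze_trace(df$x_deg, df$y_deg, rate_hz = rate)
}

#' Write a gaze trace to CSV
#'
#' @param trace A [gaze_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  trace <- as_trace_like(trace)
  t_ms <- (seq_along(trace$x) - 1L) * 1000 / trace$rate_hz
  df <- data.frame(time_ms = t_ms,
                   x_deg = format(trace$x, digits = 17, trim = TRUE),
                   y_deg = format(trace$y, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write intervals as BED-like text
#'
#' Three tab-separated columns: trace id, start, end (0-based, half-open).
#' @param intervals Interval matrix.
#' @param path Output path.
#' @param trace_id Identifier written in the first column.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path, trace_id = "trace") {
  df <- data.frame(trace_id = trace_id,
                   start = intervals[, 1L], end = intervals[, 2L])
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read BED-like intervals
#' @param path Input path.
#' @return Interval matrix (0-based half-open) for all rows in the file.
#' @export
read_intervals <- function(path) {
  df <- utils::read.table(path, sep = "\t",
                          col.names = c("trace_id", "start", "end"))
  if (nrow(df) == 0L) return(empty_intervals())
  intervals_matrix(df$start, df$end)
}

#' Write a weight vector as JSON
#'
#' Layout: `singles` (13 values), `cross` (78 values, i<j lexicographic).
#' @param w Weight vector of length 91.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(w, path) {
  check_weights(w)
  jsonlite::write_json(
    list(singles = w[seq_len(N_FEATURES)],
         cross = w[(N_FEATURES + 1L):N_WEIGHTS],
         layout = "i<j lexicographic"),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a weight vector from JSON
#' @param path Input path.
#' @return Weight vector of length 91.
#' @export
read_weights <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_weights(c(obj$singles, obj$cross))
}

#' Write ground-truth intervals as a JSON sidecar
#' @param intervals Interval matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(intervals, path) {
  iv <- lapply(seq_len(nrow(intervals)), function(r)
    c(intervals[r, 1L], intervals[r, 2L]))
  jsonlite::write_json(list(intervals = iv), path, digits = I(17))
  invisible(path)
}

#' Read a ground-truth JSON sidecar
#' @param path Input path.
#' @return Interval matrix.
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  iv <- obj$intervals
  if (length(iv) == 0L) return(empty_intervals())
  if (!is.matrix(iv)) iv <- do.call(rbind, iv)
  intervals_matrix(iv[, 1L], iv[, 2L])
}

#' Write a per-event feature table as CSV
#'
#' One row per microsaccade: `person_id`, `fixation_id`, `event_index`,
#' then the 13 features.
#'
#' @param fcohort Named list of persons, each a list of feature matrices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(fcohort, path) {
  rows <- list()
  pid <- names(fcohort) %||% paste0("P", seq_along(fcohort))
  for (p in seq_along(fcohort)) for (s in seq_along(fcohort[[p]])) {
    m <- fcohort[[p]][[s]]
    colnames(m) <- feature_names()
    rows[[length(rows) + 1L]] <-
      data.frame(person_id = pid[p], fixation_id = paste0("F", s),
                 event_index = seq_len(nrow(m)), m, check.names = FALSE)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table CSV back into a feature cohort
#' @param path Input path.
#' @return Named list of persons, each a list of feature matrices.
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  out <- list()
  for (p in unique(df$person_id)) {
    dp <- df[df$person_id == p, , drop = FALSE]
    out[[p]] <- lapply(unique(dp$fixation_id), function(f) {
      m <- as.matrix(dp[dp$fixation_id == f, feature_names(), drop = FALSE])
      rownames(m) <- NULL
      m
    })
  }
  out
}
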