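#' Region-level BOLD time-series container
#'
#' The working currency of the pipeline: a T x N matrix of region-mean BOLD
#' values together with its repetition time, the half-open volume-index
#' intervals of the acquisition runs, and region labels.
#'
#' @param values numeric T x N matrix (volumes x regions), no missing values.
#' @param tr_seconds repetition time in seconds.
#' @param run_boundaries list of half-open intervals `c(start, end)` in
#'   0-based volume indices; the intervals must partition `[0, T)`.
#' @param region_ids character vector of N region labels.
#' @param subject_id subject label.
#' @return An object of class `roi_series`.
#' @export
roi_series <- function(values, tr_seconds, run_boundaries = NULL,
                       region_ids = NULL, subject_id = "sub-01") {
  values <- as.matrix(values)
  if (anyNA(values)) stop_woiconn("roi_series values must have no missing entries")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop_woiconn("tr_seconds must be a positive duration")
  n_vol <- nrow(values)
  if (is.null(run_boundaries)) run_boundaries <- list(c(0L, n_vol))
  run_boundaries <- lapply(run_boundaries, function(b) as.integer(b))
  starts <- vapply(run_boundaries, `[`, integer(1), 1L)
  ends <- vapply(run_boundaries, `[`, integer(1), 2L)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  run_boundaries <- run_boundaries[o]
  if (starts[1] != 0L || ends[length(ends)] != n_vol ||
      (length(starts) > 1 && any(starts[-1] != ends[-length(ends)])))
    stop_woiconn("run_boundaries must partition [0, T)")
  if (is.null(region_ids)) {
    region_ids <- colnames(values)
    if (is.null(region_ids)) region_ids <- sprintf("region%02d", seq_len(ncol(values)))
  }
  if (length(region_ids) != ncol(values))
    stop_woiconn("region_ids length must equal the number of series columns")
  colnames(values) <- region_ids
  structure(
    list(values = values, tr_seconds = tr_seconds,
         run_boundaries = run_boundaries, region_ids = region_ids,
         subject_id = subject_id),
    class = "roi_series")
}

#' @export
print.roi_series <- function(x, ...) {
  cat(sprintf("<roi_series> %s: %d volumes x %d regions, TR %.3g s, %d run(s)\n",
              x$subject_id, nrow(x$values), ncol(x$values), x$tr_seconds,
              length(x$run_boundaries)))
  invisible(x)
}

#' @export
dim.roi_series <- function(x) dim(x$values)

# Which run does 0-based volume index v fall in? NA if out of range.
run_of_volume <- function(series, v) {
  for (i in seq_along(series$run_boundaries)) {
    b <- series$run_boundaries[[i]]
    if (v >= b[1] && v < b[2]) return(i)
  }
  NA_integer_
}

#' Event table constructor
#'
#' Holds discharge onsets as both seconds and 0-based volume indices
#' (`floor(onset / TR)`: an event at time t is attributed to the volume being
#' acquired), with durations, labels, and the run each event falls in.
#'
#' @param onset_sec event onsets in seconds from the start of the session.
#' @param duration_sec event durations in seconds.
#' @param trial_type event labels.
#' @param tr_seconds repetition time used for the volume-index conversion.
#' @param run_boundaries optional list of half-open run intervals in volume
#'   indices, used to assign `run_id` and validate onsets.
#' @return A data frame of class `event_table` with columns `onset_sec`,
#'   `duration_sec`, `trial_type`, `onset_vol`, `run_id`, carrying the TR and
#'   an eligibility report (event count, minimum inter-event gap) as
#'   attributes.
#' @export
event_table <- function(onset_sec, duration_sec = 0, trial_type = "event",
                        tr_seconds = 2, run_boundaries = NULL) {
  if (any(onset_sec < 0)) stop_woiconn("event onsets must be non-negative")
  n <- length(onset_sec)
  duration_sec <- rep_len(duration_sec, n)
  trial_type <- rep_len(trial_type, n)
  onset_vol <- as.integer(floor(onset_sec / tr_seconds))
  run_id <- rep(NA_integer_, n)
  if (!is.null(run_boundaries)) {
    t_max <- max(vapply(run_boundaries, function(b) as.numeric(b[2]), numeric(1)))
    if (any(onset_vol >= t_max))
      stop_woiconn("event onset beyond the end of the last run")
    for (i in seq_len(n)) {
      for (r in seq_along(run_boundaries)) {
        b <- run_boundaries[[r]]
        if (onset_vol[i] >= b[1] && onset_vol[i] < b[2]) { run_id[i] <- r; break }
      }
    }
  }
  df <- data.frame(onset_sec = as.numeric(onset_sec),
                   duration_sec = as.numeric(duration_sec),
                   trial_type = as.character(trial_type),
                   onset_vol = onset_vol, run_id = run_id,
                   stringsAsFactors = FALSE)
  o <- order(df$run_id, df$onset_sec, na.last = TRUE)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  # onsets must be strictly increasing within a run
  for (r in unique(df$run_id[!is.na(df$run_id)])) {
    ons <- df$onset_vol[df$run_id %in% r]
    if (anyDuplicated(ons)) stop_woiconn("event onsets must be strictly increasing within a run")
  }
  gaps <- if (n > 1) diff(sort(df$onset_sec)) else numeric(0)
  attr(df, "tr_seconds") <- tr_seconds
  attr(df, "eligibility") <- list(
    n_events = n,
    min_gap_sec = if (length(gaps)) min(gaps) else Inf,
    enough_events = n >= 10,
    enough_spacing = if (length(gaps)) min(gaps) >= 80 else TRUE)
  class(df) <- c("event_table", "data.frame")
  df
}

#' Eligibility report of an event table
#'
#' Event trains enter the analysis only if they carry at least 10 events with
#' at least 80 s between consecutive events; this reports both checks.
#'
#' @param events an `event_table`.
#' @return list with `n_events`, `min_gap_sec`, `enough_events`,
#'   `enough_spacing`.
#' @export
event_eligibility <- function(events) attr(events, "eligibility")
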