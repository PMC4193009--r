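#' Tapered window weights
#'
#' Builds the window taper by convolving a length-L rectangle with a unit-area
#' Gaussian kernel sampled on integer offsets over +/- 4 sigma, keeping the L
#' central samples and normalizing them to sum to one. `sigma = 0` gives the
#' uniform window `1/L`.
#'
#' @param L window length in TRs (>= 2).
#' @param sigma Gaussian standard deviation in TRs (default 2).
#' @return Object of class `taper`: list with `length`, `sigma` and the
#'   normalized `weights`.
#' @export
make_taper <- function(L, sigma = 2) {
  if (L < 2) stop_woiconn("taper length L must be >= 2")
  L <- as.integer(L)
  if (sigma <= 0) {
    w <- rep(1 / L, L)
  } else {
    K <- ceiling(4 * sigma)
    off <- -K:K
    g <- exp(-off^2 / (2 * sigma^2))
    g <- g / sum(g)
    rect <- rep(1, L)
    # central L samples of the full convolution
    w <- vapply(seq_len(L) - 1L, function(i) {
      idx <- i - off          # rectangle sample indices hit by the kernel
      sum(g[idx >= 0 & idx < L])
    }, numeric(1))
    w <- w / sum(w)
  }
  structure(list(length = L, sigma = sigma, weights = w), class = "taper")
}

# The four window-of-interest intervals as offsets from the event volume t:
# before [t-L, t), during [t, t+L), after [t+2L, t+3L), baseline [t+4L, t+5L).
woi_offsets <- function(L) {
  list(before = c(-L, 0), during = c(0, L),
       after = c(2 * L, 3 * L), baseline = c(4 * L, 5 * L))
}

#' Assign windows of interest to events
#'
#' Each event at volume t gets four half-open intervals: before `[t-L, t)`,
#' during `[t, t+L)`, after `[t+2L, t+3L)` and baseline `[t+4L, t+5L)`. An
#' event is valid iff all four intervals lie inside the event's run and no
#' other event onset in the same run lies within 7L TRs of t (the span of the
#' four windows plus the 2L guard after the baseline window, applied
#' symmetrically so that a before window can never overlap a preceding
#' event's windows or trailing guard). Invalid events are flagged with a
#' reason, never dropped silently.
#'
#' @param events an [event_table()] with run ids assigned.
#' @param L window length in TRs.
#' @param run_boundaries list of half-open run intervals in volume indices.
#' @return Data frame of class `woi_set`, one row per event x condition, with
#'   columns `event_index`, `condition`, `start`, `end`, `valid`, `reason`.
#' @export
assign_wois <- function(events, L, run_boundaries) {
  offs <- woi_offsets(L)
  rows <- list()
  for (i in seq_len(nrow(events))) {
    t0 <- events$onset_vol[i]
    r <- events$run_id[i]
    valid <- TRUE
    reason <- ""
    if (is.na(r)) {
      valid <- FALSE; reason <- "out-of-run"
      b <- c(NA_integer_, NA_integer_)
    } else {
      b <- run_boundaries[[r]]
      in_run <- vapply(offs, function(o)
        t0 + o[1] >= b[1] && t0 + o[2] <= b[2], logical(1))
      if (!all(in_run)) { valid <- FALSE; reason <- "out-of-run" }
      others <- events$onset_vol[events$run_id %in% r]
      others <- others[others != t0]
      if (valid && any(abs(others - t0) < 7 * L)) {
        valid <- FALSE; reason <- "neighboring event"
      }
    }
    for (cond in woi_conditions()) {
      iv <- t0 + offs[[cond]]
      rows[[length(rows) + 1]] <- data.frame(
        event_index = i, condition = cond, start = iv[1], end = iv[2],
        valid = valid, reason = reason, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("woi_set", "data.frame")
  out
}

#' Tapered windowed covariance
#'
#' Weighted covariance of the window's rows:
#' `S[j,k] = sum_i w_i (x[i,j] - xbar_j)(x[i,k] - xbar_k)` with weighted means
#' and weights summing to one. With a uniform taper this is the
#' population-normalized sample covariance of the window.
#'
#' @param series an [roi_series()].
#' @param interval half-open volume-index interval `c(start, end)` of length
#'   equal to the taper, lying inside a single run.
#' @param taper a [make_taper()] object.
#' @return Symmetric positive-semidefinite N x N matrix.
#' @export
windowed_covariance <- function(series, interval, taper) {
  L <- interval[2] - interval[1]
  if (L != taper$length)
    stop_woiconn("interval length must equal the taper length")
  r1 <- run_of_volume(series, interval[1])
  r2 <- run_of_volume(series, interval[2] - 1)
  if (is.na(r1) || is.na(r2) || r1 != r2)
    stop_woiconn("window interval must lie inside a single run")
  x <- series$values[(interval[1] + 1):interval[2], , drop = FALSE]
  w <- taper$weights
  xbar <- colSums(x * w)
  xc <- sweep(x, 2, xbar)
  S <- crossprod(xc * sqrt(w), xc * sqrt(w))
  unname(0.5 * (S + t(S)))
}

#' Export a window-of-interest set as TSV
#' @param wois a `woi_set` from [assign_wois()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_wois_tsv <- function(wois, path) {
  write.table(as.data.frame(wois), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
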