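#' The built-in 14-region default mode network table
#'
#' Seven regions per hemisphere with their MNI peak coordinates (mm):
#' precuneus/posterior cingulate cortex (PCC), inferior parietal lobule (IPL),
#' middle temporal gyrus (MTG), parahippocampal gyrus (PHG), temporal pole
#' (TP), middle frontal gyrus (MFG) and dorsal medial prefrontal cortex
#' (dMPFC).
#'
#' @return Data frame with columns `label`, `hemisphere`, `x`, `y`, `z`.
#' @export
dmn_region_table <- function() {
  tab <- rbind(
    c("PCC",   "R",   8, -53,  15), c("PCC",   "L",  -8, -55,  18),
    c("IPL",   "R",  48, -64,  31), c("IPL",   "L", -45, -69,  32),
    c("MTG",   "R",  56,  -2, -25), c("MTG",   "L", -57,  -6, -22),
    c("PHG",   "R",  27, -21, -23), c("PHG",   "L", -26, -26, -20),
    c("TP",    "R",  40,  21, -37), c("TP",    "L", -41,  19, -37),
    c("MFG",   "R",   6,  54,  -9), c("MFG",   "L",  -7,  51, -11),
    c("dMPFC", "R",  20,  39,  46), c("dMPFC", "L", -21,  32,  47))
  df <- data.frame(label = tab[, 1], hemisphere = tab[, 2],
                   x = as.numeric(tab[, 3]), y = as.numeric(tab[, 4]),
                   z = as.numeric(tab[, 5]), stringsAsFactors = FALSE)
  df
}

#' Load and validate a region table
#'
#' @param path TSV file with columns `label`, `hemisphere`, `x`, `y`, `z`;
#'   `NULL` (default) returns the built-in 14-region DMN table.
#' @return Validated region table data frame.
#' @export
load_region_table <- function(path = NULL) {
  df <- if (is.null(path)) dmn_region_table()
        else read.delim(path, stringsAsFactors = FALSE)
  required <- c("label", "hemisphere", "x", "y", "z")
  if (!setequal(names(df), required))
    stop_woiconn("region table must have exactly the columns ",
                 paste(required, collapse = ", "))
  df <- df[, required]
  if (anyDuplicated(df[, c("label", "hemisphere")]))
    stop_woiconn("duplicate (label, hemisphere) rows in region table")
  if (!all(df$hemisphere %in% c("L", "R")))
    stop_woiconn("hemisphere must be 'L' or 'R'")
  df
}

# region id used for series columns: e.g. "PCC_R"
region_ids_of <- function(region_table)
  paste(region_table$label, region_table$hemisphere, sep = "_")

#' Extract region-mean time courses from a 4D volume
#'
#' For each region, the `k` mask voxels nearest (Euclidean distance in mm) to
#' the region's peak coordinate are selected, ties broken by ascending
#' (x, y, z) voxel index, and their unweighted mean time course is returned.
#'
#' @param bold_4d 4D array of BOLD data (x, y, z, t), or an `RNifti` image.
#' @param region_table region table with MNI peak coordinates in mm.
#' @param component_mask 3D array (same grid as `bold_4d`), nonzero where
#'   voxels are eligible.
#' @param k voxels per region (default 30); if fewer eligible voxels exist a
#'   warning is issued and all available are used.
#' @param affine 4 x 4 voxel-to-world matrix (0-based voxel indices). If
#'   `bold_4d` is a NIfTI image its own transform is used.
#' @param tr_seconds repetition time of the output series.
#' @param run_boundaries optional run intervals for the output series.
#' @return An [roi_series()] with one column per region-table row.
#' @export
extract_roi_series <- function(bold_4d, region_table, component_mask, k = 30,
                               affine = NULL, tr_seconds = 2,
                               run_boundaries = NULL) {
  if (is.null(affine)) {
    if (requireNamespace("RNifti", quietly = TRUE) &&
        inherits(bold_4d, "niftiImage")) {
      affine <- structure(RNifti::xform(bold_4d), class = NULL)
    } else stop_woiconn("an affine matrix is required for plain arrays")
  }
  bold <- as.array(bold_4d)
  mask <- as.array(component_mask)
  dims <- dim(bold)
  if (length(dims) != 4) stop_woiconn("bold_4d must be 4-dimensional")
  if (!all(dim(mask) == dims[1:3]))
    stop_woiconn("mask and BOLD grids must share a shape")

  vox <- which(mask != 0, arr.ind = TRUE)   # 1-based indices
  if (nrow(vox) == 0) stop_woiconn("component mask is empty")
  # world coordinates of mask voxels (0-based voxel indices)
  v0 <- cbind(vox - 1L, 1)
  world <- v0 %*% t(affine)

  n_reg <- nrow(region_table)
  out <- matrix(NA_real_, dims[4], n_reg)
  for (i in seq_len(n_reg)) {
    peak <- c(region_table$x[i], region_table$y[i], region_table$z[i], 1)
    # peak must map to a voxel inside the grid
    pv <- solve(affine, peak)[1:3]
    if (any(pv < -0.5) || any(pv > dims[1:3] - 0.5))
      stop_woiconn(sprintf("peak of region %s_%s lies outside the volume",
                           region_table$label[i], region_table$hemisphere[i]))
    d2 <- rowSums(sweep(world[, 1:3, drop = FALSE], 2, peak[1:3])^2)
    ord <- order(d2, vox[, 1], vox[, 2], vox[, 3])
    kk <- k
    if (nrow(vox) < k) {
      warning(sprintf("region %s_%s: only %d eligible voxels (%d requested)",
                      region_table$label[i], region_table$hemisphere[i],
                      nrow(vox), k), call. = FALSE)
      kk <- nrow(vox)
    }
    sel <- vox[ord[seq_len(kk)], , drop = FALSE]
    ts <- matrix(0, dims[4], kk)
    for (j in seq_len(kk))
      ts[, j] <- bold[sel[j, 1], sel[j, 2], sel[j, 3], ]
    out[, i] <- rowMeans(ts)
  }
  roi_series(out, tr_seconds = tr_seconds, run_boundaries = run_boundaries,
             region_ids = region_ids_of(region_table))
}

#' Drop the initial volumes of each run
#'
#' Removes the first `n` volumes of every run (T1 equilibration), re-indexing
#' run boundaries. Event onsets must be shifted accordingly by the caller.
#'
#' @param series an [roi_series()].
#' @param n volumes to drop per run (default 3).
#' @return A shorter [roi_series()].
#' @export
drop_initial_volumes <- function(series, n = 3) {
  if (n == 0) return(series)
  keep <- integer(0)
  new_bounds <- list()
  cursor <- 0L
  for (b in series$run_boundaries) {
    len <- b[2] - b[1]
    if (len <= n) stop_woiconn("run shorter than the number of volumes to drop")
    keep <- c(keep, (b[1] + n + 1L):b[2])
    new_bounds[[length(new_bounds) + 1]] <- c(cursor, cursor + len - n)
    cursor <- cursor + len - as.integer(n)
  }
  roi_series(series$values[keep, , drop = FALSE], series$tr_seconds,
             new_bounds, series$region_ids, series$subject_id)
}

#' Principal-component nuisance signals from a noise region
#'
#' Top principal-component scores of the column-standardized noise-voxel
#' matrix (constant voxels are dropped before standardization). Scores are
#' scaled so each column has population variance 1, i.e. `crossprod(PC)` is
#' `T` times the identity.
#'
#' @param noise_roi_series T x V matrix of noise-region voxel series.
#' @param n_components number of components (default 5).
#' @return T x `n_components` matrix of component scores.
#' @export
compcor_components <- function(noise_roi_series, n_components = 5) {
  x <- as.matrix(noise_roi_series)
  sds <- apply(x, 2, sd)
  x <- x[, sds > 0, drop = FALSE]
  if (ncol(x) < n_components)
    stop_woiconn("fewer non-constant noise voxels than requested components")
  if (nrow(x) < n_components)
    stop_woiconn("fewer time points than requested components")
  x <- scale(x)
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  n <- nrow(scores)
  # population-variance-1 scaling
  scale_fac <- sqrt(colSums(scores^2) / n)
  sweep(scores, 2, scale_fac, "/")
}

# least-squares residual of y (matrix) on design X, rank-deficiency tolerated
ls_residual <- function(y, X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    warning("rank-deficient nuisance design; least-norm solution used",
            call. = FALSE)
  y - qr.fitted(qrX, y)
}

#' Two-stage nuisance regression
#'
#' Stage 1 regresses out, per run, an intercept, linear and quadratic trends
#' and (if supplied) six motion parameters; stage 2 regresses out component
#' nuisance signals computed per run from the noise-region voxel series via
#' [compcor_components()]. Either stage can be skipped. Residuals are exactly
#' orthogonal to all regressors.
#'
#' @param series an [roi_series()].
#' @param motion optional T x 6 motion-parameter matrix aligned with the
#'   series rows.
#' @param noise_roi_series optional T x V noise-voxel matrix aligned with the
#'   series rows.
#' @param n_components CompCor components for stage 2 (default 5).
#' @param trend_order polynomial trend order for stage 1 (default 2).
#' @param detrend run stage 1 (default TRUE).
#' @return The residual [roi_series()].
#' @export
two_stage_nuisance_regression <- function(series, motion = NULL,
                                          noise_roi_series = NULL,
                                          n_components = 5, trend_order = 2,
                                          detrend = TRUE) {
  n_vol <- nrow(series$values)
  if (!is.null(motion) && nrow(motion) != n_vol)
    stop_woiconn("motion rows must align with the series volumes")
  if (!is.null(noise_roi_series) && nrow(noise_roi_series) != n_vol)
    stop_woiconn("noise-region rows must align with the series volumes")
  vals <- series$values
  for (b in series$run_boundaries) {
    rows <- (b[1] + 1):b[2]
    y <- vals[rows, , drop = FALSE]
    X1 <- NULL
    if (detrend) {
      tt <- seq_along(rows)
      X1 <- cbind(1, outer(tt, seq_len(trend_order), `^`))
      if (!is.null(motion)) X1 <- cbind(X1, motion[rows, , drop = FALSE])
      y <- ls_residual(y, X1)
    }
    if (!is.null(noise_roi_series)) {
      comps <- compcor_components(noise_roi_series[rows, , drop = FALSE],
                                  n_components)
      # orthogonalize against the stage-1 design so the final residuals stay
      # orthogonal to every regressor of both stages
      if (!is.null(X1)) comps <- ls_residual(comps, X1)
      y <- ls_residual(y, cbind(1, comps))
    }
    vals[rows, ] <- y
  }
  roi_series(vals, series$tr_seconds, series$run_boundaries,
             series$region_ids, series$subject_id)
}

#' Zero-phase low-pass filter
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth low-pass
#' filter per run and per region. DC gain is 1.
#'
#' @param series an [roi_series()].
#' @param cutoff_hz cutoff frequency (default 0.1 Hz); must be below the
#'   Nyquist frequency `1 / (2 TR)`.
#' @return The filtered [roi_series()].
#' @export
lowpass_filter <- function(series, cutoff_hz = 0.1) {
  nyquist <- 1 / (2 * series$tr_seconds)
  if (cutoff_hz >= nyquist)
    stop_woiconn("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(4, cutoff_hz / nyquist, type = "low")
  vals <- series$values
  for (b in series$run_boundaries) {
    rows <- (b[1] + 1):b[2]
    for (j in seq_len(ncol(vals))) {
      m <- mean(vals[rows, j])   # filter around the run mean: exact DC gain
      vals[rows, j] <- signal::filtfilt(bf, vals[rows, j] - m) + m
    }
  }
  roi_series(vals, series$tr_seconds, series$run_boundaries,
             series$region_ids, series$subject_id)
}

#' Read a BIDS-style events table
#'
#' Reads a tab-separated events file with columns `onset` (s), `duration` (s)
#' and `trial_type`, converts onsets to volume indices (`floor(onset / TR)`)
#' and computes the eligibility report (event count, minimum inter-event
#' gap).
#'
#' @param path events.tsv file.
#' @param tr_seconds repetition time used for the conversion.
#' @param run_boundaries optional run intervals in volume indices.
#' @return An [event_table()].
#' @export
read_events <- function(path, tr_seconds, run_boundaries = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("onset", "duration", "trial_type")
  if (!all(required %in% names(df)))
    stop_woiconn("events file must have columns onset, duration, trial_type")
  event_table(onset_sec = df$onset, duration_sec = df$duration,
              trial_type = df$trial_type, tr_seconds = tr_seconds,
              run_boundaries = run_boundaries)
}
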