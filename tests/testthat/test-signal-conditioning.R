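test_that("the built-in region table has 7 regions per hemisphere with the right peaks", {
  rt <- load_region_table()
  expect_equal(nrow(rt), 14)
  expect_equal(sum(rt$hemisphere == "L"), 7)
  expect_equal(sum(rt$hemisphere == "R"), 7)
  pcc_r <- rt[rt$label == "PCC" & rt$hemisphere == "R", ]
  expect_equal(c(pcc_r$x, pcc_r$y, pcc_r$z), c(8, -53, 15))
})

test_that("malformed region tables are rejected", {
  f <- tempfile(fileext = ".tsv")
  bad <- dmn_region_table()[, c("label", "x", "y", "z")]
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_region_table(f), "columns")
  dup <- dmn_region_table()
  dup$hemisphere[2] <- "R"  # duplicates (PCC, R)
  f2 <- tempfile(fileext = ".tsv")
  write.table(dup, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_region_table(f2), "duplicate")
})

test_that("ROI extraction averages the k nearest mask voxels", {
  dims <- c(10, 10, 10, 5)
  affine <- diag(4)  # voxel index = mm
  set.seed(4)
  bold <- array(rnorm(prod(dims)), dims)
  rt <- data.frame(label = "PCC", hemisphere = "R", x = 5, y = 5, z = 5)

  # single eligible voxel with k = 1: the series is that voxel's series
  mask1 <- array(0, dims[1:3]); mask1[6, 6, 6] <- 1  # voxel (5,5,5) 0-based
  s1 <- extract_roi_series(bold, rt, mask1, k = 1, affine = affine)
  expect_equal(as.numeric(s1$values), bold[6, 6, 6, ])

  # dense mask, k = 4: mean of the peak voxel and its 3 nearest neighbours
  mask <- array(1, dims[1:3])
  s4 <- extract_roi_series(bold, rt, mask, k = 4, affine = affine)
  # peak voxel plus ties at distance 1 broken by ascending voxel index
  picked <- rbind(c(6, 6, 6), c(5, 6, 6), c(6, 5, 6), c(6, 6, 5))
  manual <- rowMeans(apply(picked, 1, function(v) bold[v[1], v[2], v[3], ]))
  expect_equal(as.numeric(s4$values), manual)

  # fewer eligible voxels than requested: warning, use all
  expect_warning(extract_roi_series(bold, rt, mask1, k = 30, affine = affine),
                 "eligible")

  # peak far outside the grid is an error
  rt_far <- data.frame(label = "PCC", hemisphere = "R",
                       x = 1000, y = 1000, z = 1000)
  expect_error(extract_roi_series(bold, rt_far, mask, k = 1, affine = affine),
               "outside")
})

test_that("ROI extraction is invariant to region-table row order", {
  dims <- c(8, 8, 8, 6)
  set.seed(14)
  bold <- array(rnorm(prod(dims)), dims)
  mask <- array(1, dims[1:3])
  rt <- data.frame(label = c("A", "B"), hemisphere = c("L", "R"),
                   x = c(2, 5), y = c(2, 5), z = c(2, 5))
  s12 <- extract_roi_series(bold, rt, mask, k = 3, affine = diag(4))
  s21 <- extract_roi_series(bold, rt[2:1, ], mask, k = 3, affine = diag(4))
  expect_equal(unname(s12$values), unname(s21$values[, 2:1]))
})

test_that("initial volumes are dropped per run with re-indexed boundaries", {
  x <- roi_series(matrix(rnorm(600 * 2), 600), tr_seconds = 2,
                  run_boundaries = list(c(0, 300), c(300, 600)))
  d <- drop_initial_volumes(x, 3)
  expect_equal(nrow(d$values), 594)
  expect_equal(d$run_boundaries, list(c(0L, 297L), c(297L, 594L)))
  expect_equal(d$values[1, ], x$values[4, ])
  expect_identical(drop_initial_volumes(x, 0), x)
  tiny <- roi_series(matrix(rnorm(4), 2), tr_seconds = 2)
  expect_error(drop_initial_volumes(tiny, 3), "shorter")
})

test_that("nuisance regression leaves residuals orthogonal to the design and is idempotent", {
  set.seed(7)
  n <- 200
  motion <- matrix(rnorm(n * 6), n)
  noise_vox <- matrix(rnorm(n * 20), n)
  x <- roi_series(matrix(rnorm(n * 3), n), tr_seconds = 2)
  r <- two_stage_nuisance_regression(x, motion, noise_vox)
  tt <- seq_len(n)
  design <- cbind(1, tt, tt^2, motion, compcor_components(noise_vox, 5))
  cors <- abs(crossprod(design, r$values))
  expect_lt(max(cors / n), 1e-8)

  r2 <- two_stage_nuisance_regression(r, motion, noise_vox)
  expect_equal(r2$values, r$values, tolerance = 1e-8)

  # a pure quadratic trend is removed exactly
  q <- roi_series(matrix(3 + 0.5 * tt - 0.01 * tt^2, n), tr_seconds = 2)
  rq <- two_stage_nuisance_regression(q)
  expect_lt(max(abs(rq$values)), 1e-8)

  # a sinusoid orthogonal to the confounds passes through nearly unchanged
  s <- sin(2 * pi * 25 * tt / n)
  xs <- roi_series(matrix(s, n), tr_seconds = 2)
  rs <- two_stage_nuisance_regression(xs)
  expect_gt(cor(s, rs$values[, 1]), 0.99)

  expect_error(two_stage_nuisance_regression(x, motion[-1, , drop = FALSE]),
               "align")
})

test_that("conditioning acts per run: permuting runs permutes outputs", {
  set.seed(9)
  a <- matrix(rnorm(100 * 2), 100)
  b <- matrix(rnorm(120 * 2), 120)
  x <- roi_series(rbind(a, b), 2, list(c(0, 100), c(100, 220)))
  y <- roi_series(rbind(b, a), 2, list(c(0, 120), c(120, 220)))
  rx <- lowpass_filter(two_stage_nuisance_regression(x))
  ry <- lowpass_filter(two_stage_nuisance_regression(y))
  expect_equal(unname(rx$values[1:100, ]), unname(ry$values[121:220, ]),
               tolerance = 1e-10)
  expect_equal(unname(rx$values[101:220, ]), unname(ry$values[1:120, ]),
               tolerance = 1e-10)
})

test_that("CompCor components capture shared noise and are orthonormal", {
  set.seed(3)
  n <- 80
  sig <- sin(2 * pi * (1:n) / 16)
  vox <- outer(sig, runif(50, 0.5, 2)) + matrix(rnorm(n * 50, sd = 0.01), n)
  pc <- compcor_components(vox, 5)
  expect_gt(abs(cor(pc[, 1], sig)), 0.99)
  expect_lt(max(abs(crossprod(pc) - n * diag(5))), 1e-8)
  expect_error(compcor_components(matrix(rnorm(30), 10, 3), 5), "fewer")
  # constant voxels are dropped before standardization
  vox_const <- cbind(vox, 1)
  expect_equal(compcor_components(vox_const, 5), pc)
})

test_that("the low-pass filter has unit DC gain and the specified rolloff", {
  n <- 400
  const <- roi_series(matrix(5, n, 1), tr_seconds = 2)
  expect_lt(max(abs(lowpass_filter(const)$values - 5)), 1e-8)
  tt <- (0:(n - 1)) * 2
  hi <- roi_series(matrix(sin(2 * pi * 0.2 * tt), ncol = 1), tr_seconds = 2)
  expect_lt(max(abs(lowpass_filter(hi)$values[50:350, ])), 0.1)
  lo <- roi_series(matrix(sin(2 * pi * 0.01 * tt), ncol = 1), tr_seconds = 2)
  expect_gt(max(abs(lowpass_filter(lo)$values[50:350, ])), 0.95)
  expect_error(lowpass_filter(const, cutoff_hz = 0.25), "Nyquist")
})

test_that("events files are parsed with the floor rule and eligibility checks", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(onset = c(20, 140.5), duration = c(1, 1),
                         trial_type = "IED"),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- read_events(f, tr_seconds = 2, run_boundaries = list(c(0, 300)))
  expect_equal(ev$onset_vol, c(10L, 70L))
  elig <- event_eligibility(ev)
  expect_false(elig$enough_events)    # 2 < 10
  expect_true(elig$enough_spacing)    # 120.5 s >= 80 s

  # 10 events spaced 79 s: enough events, too close
  f2 <- tempfile(fileext = ".tsv")
  write.table(data.frame(onset = 79 * (0:9), duration = 1, trial_type = "IED"),
              f2, sep = "\t", quote = FALSE, row.names = FALSE)
  ev2 <- read_events(f2, tr_seconds = 2, run_boundaries = list(c(0, 400)))
  elig2 <- event_eligibility(ev2)
  expect_true(elig2$enough_events)
  expect_false(elig2$enough_spacing)

  f3 <- tempfile(fileext = ".tsv")
  write.table(data.frame(onset = -1, duration = 1, trial_type = "IED"),
              f3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_events(f3, 2), "non-negative")

  f4 <- tempfile(fileext = ".tsv")
  write.table(data.frame(onset = 1000, duration = 1, trial_type = "IED"),
              f4, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_events(f4, 2, run_boundaries = list(c(0, 300))), "beyond")
})
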