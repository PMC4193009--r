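test_that("event trains are deterministic and respect the minimum gap", {
  spec <- simulation_spec(min_gap = 40, n_volumes_per_run = 300,
                          n_events = 10, seed = 5)
  ev1 <- simulate_event_train(spec)
  ev2 <- simulate_event_train(spec)
  expect_identical(ev1$onset_vol, ev2$onset_vol)
  for (r in unique(ev1$run_id)) {
    ons <- ev1$onset_vol[ev1$run_id == r]
    if (length(ons) > 1) expect_true(all(diff(ons) >= 40))
  }
  expect_true(all(ev1$onset_vol >= 0 & ev1$onset_vol < 6 * 300))
})

test_that("infeasible event geometry is an explicit error", {
  spec <- simulation_spec(n_events = 20, min_gap = 40,
                          n_volumes_per_run = 300, n_runs = 1)
  expect_error(simulate_event_train(spec), "infeasible")
})

test_that("condition covariances reproduce the base when unscaled and repair broken ones", {
  base <- random_pd(5, seed = 1)
  effects <- list(before = {
    m <- matrix(0.2, 5, 5); diag(m) <- 0; m
  })
  cc0 <- make_condition_covariances(base, effects, scale = 0)
  for (cond in c("before", "during", "after", "baseline"))
    expect_equal(cc0[[cond]], base)

  # 2x2 closed form: adding r = 0.5 to the identity gives integration
  # -log(1 - 0.25) / 2 = 0.1438
  cc <- make_condition_covariances(diag(2),
                                   list(before = matrix(c(0, .5, .5, 0), 2)))
  expect_equal(integration(cc$before), -0.5 * log(1 - 0.25), tolerance = 1e-6)
  expect_equal(integration(cc$baseline), 0)

  # an effect driving the smallest eigenvalue to -0.1 is repaired to >= 1e-6
  eff <- matrix(c(0, -1.1, -1.1, 0), 2)
  expect_warning(ccr <- make_condition_covariances(diag(2), list(before = eff)),
                 "floored")
  expect_gte(min(eigen(ccr$before)$values), 1e-6)

  expect_error(make_condition_covariances(matrix(1:4, 2)), "symmetric")
  expect_error(
    make_condition_covariances(diag(2), list(before = matrix(1:4, 2))),
    "symmetric")
})

test_that("simulated BOLD carries the planted covariance", {
  # independent regions: off-diagonal correlation near zero
  spec <- simulation_spec(n_regions = 4, n_runs = 1,
                          n_volumes_per_run = 10000, n_events = 1,
                          min_gap = 1, base_covariance = diag(4),
                          condition_effects = list(), ar_coefficient = 0,
                          drift_amplitude = 0, seed = 21)
  covs <- make_condition_covariances(diag(4), list())
  x <- simulate_roi_bold(spec, simulate_event_train(spec), covs)
  cc <- cor(x$values)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.03)

  # planted correlation 0.6 between two regions, recovered from the series
  S <- matrix(c(1, .6, .6, 1), 2)
  spec2 <- simulation_spec(n_regions = 2, n_runs = 1,
                           n_volumes_per_run = 20000, n_events = 1,
                           min_gap = 1, base_covariance = S,
                           condition_effects = list(), ar_coefficient = 0,
                           drift_amplitude = 0, seed = 22)
  covs2 <- make_condition_covariances(S, list())
  x2 <- simulate_roi_bold(spec2, simulate_event_train(spec2), covs2)
  expect_equal(cor(x2$values)[1, 2], 0.6, tolerance = 0.03)

  # determinism
  x3 <- simulate_roi_bold(spec2, simulate_event_train(spec2), covs2)
  expect_identical(x2$values, x3$values)

  # missing condition in the map is an error
  expect_error(
    simulate_roi_bold(spec2, simulate_event_train(spec2), covs2[1:3]),
    "missing")
})

test_that("averaged window covariances converge to the planted condition matrix", {
  # many events in one long run; the mean "before"-window covariance must
  # approach the planted "before" matrix elementwise
  n <- 3
  base <- equicorrelation_matrix(n, 0.2)
  eff <- matrix(0.3, n, n); diag(eff) <- 0
  spec <- simulation_spec(n_regions = n, n_runs = 1,
                          n_volumes_per_run = 40000, n_events = 600,
                          min_gap = 64, base_covariance = base,
                          condition_effects = list(before = eff),
                          ar_coefficient = 0, drift_amplitude = 0, seed = 33)
  events <- simulate_event_train(spec)
  covs <- make_condition_covariances(base, list(before = eff))
  series <- simulate_roi_bold(spec, events, covs)
  wois <- assign_wois(events, 8, series$run_boundaries)
  taper <- make_taper(8, 2)
  rows <- wois[wois$valid & wois$condition == "before", ]
  Ss <- lapply(seq_len(nrow(rows)), function(i)
    windowed_covariance(series, c(rows$start[i], rows$end[i]), taper))
  expect_gt(length(Ss), 300)
  S_bar <- Reduce(`+`, Ss) / length(Ss)
  # scale-corrected for the window-mean subtraction (factor 1 - sum(w^2))
  shrink <- 1 - sum(taper$weights^2)
  expect_lt(max(abs(S_bar - shrink * covs$before)), 0.05)
  expect_lt(max(abs(cov2cor(S_bar) - cov2cor(covs$before))), 0.03)
})

test_that("cohorts have one subject per spec with unique ids", {
  specs <- cohort_specs(6, seed = 3, n_runs = 1, n_events = 3,
                        n_volumes_per_run = 300, min_gap = 60)
  coh <- simulate_cohort(specs)
  expect_length(coh, 6)
  expect_false(identical(coh[[1]]$series$values, coh[[2]]$series$values))
  expect_error(simulate_cohort(list()), "at least one")
  specs_dup <- specs
  specs_dup[[2]]$subject_id <- specs_dup[[1]]$subject_id
  expect_error(simulate_cohort(specs_dup), "duplicate")
})

test_that("series and events round-trip through their TSV writers", {
  sub <- small_subject(seed = 8)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_roi_series_tsv(sub$series, f1)
  write_events_tsv(sub$events, f2)
  vals <- as.matrix(read.delim(f1))
  expect_equal(unname(vals), unname(sub$series$values), tolerance = 1e-8)
  ev <- read_events(f2, tr_seconds = 2,
                    run_boundaries = sub$series$run_boundaries)
  expect_equal(ev$onset_vol, sub$events$onset_vol)
})
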