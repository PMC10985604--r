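# Gait-event detection and gap interpolation.

test_that("clean trials yield events within one frame of the schedule", {
  prof <- test_profile()
  for (task in c("normal_walking", "overstepping", "balancing")) {
    tr <- simulate_trial(prof, task)
    errs <- event_errors_frames(tr)
    expect_lt(max(abs(errs)), 1, label = sprintf("%s event error", task))
  }
})

test_that("per foot, event kinds alternate and counts differ by at most one", {
  prof <- test_profile()
  set.seed(21)
  for (s in 1:4) {
    tr <- simulate_trial(prof, sample(gait_tasks(), 1), noise_sd = 0.002)
    ev <- detect_events(tr)
    for (f in c("L", "R")) {
      kinds <- ev$kind[ev$foot == f]
      expect_true(all(kinds[-1] != kinds[-length(kinds)]),
                  label = "kinds alternate")
      expect_lte(abs(sum(kinds == "strike") - sum(kinds == "off")), 1)
    }
    expect_true(!is.unsorted(ev$time))
  }
})

test_that("detection is invariant to rigid translation of the whole trial", {
  prof <- test_profile()
  set.seed(22)
  tr <- simulate_trial(prof, "normal_walking", noise_sd = 0.001)
  ev1 <- detect_events(tr)
  ev2 <- detect_events(translate_trial(tr, dx = 3.2, dy = -1.5, dz = 0.4))
  expect_equal(ev1$time, ev2$time, tolerance = 1e-9)
  expect_identical(ev1$kind, ev2$kind)
})

test_that("a standing record is flagged degenerate with a single strike per foot", {
  tr <- standing_trial()
  # one degenerate warning per foot
  expect_warning(expect_warning(ev <- detect_events(tr), "degenerate"),
                 "degenerate")
  expect_true(attr(ev, "degenerate"))
  for (f in c("L", "R")) {
    expect_identical(ev$kind[ev$foot == f], "strike")
    expect_equal(ev$time[ev$foot == f], 0)
  }
})

test_that("too-short trials are rejected", {
  tr <- standing_trial(n = 5)
  expect_error(detect_events(tr), "too short")
})

test_that("cubic interpolation is exact for polynomial trajectories", {
  tr <- standing_trial(n = 60)
  t <- seq_len(60)
  cubic <- 0.3 + 0.01 * t - 2e-4 * t^2 + 1e-6 * t^3
  tr$markers$L_TOE[, 1] <- cubic
  tr$markers$L_TOE[20:22, ] <- NA  # 3-frame gap
  out <- interpolate_gaps(tr, max_gap = 5)
  expect_equal(out$markers$L_TOE[20:22, 1], cubic[20:22], tolerance = 1e-9)
  rep <- attr(out, "gap_report")
  expect_true(all(rep$filled))
})

test_that("gaps beyond the limit stay missing and are reported", {
  tr <- standing_trial(n = 60)
  tr$markers$R_HEEL[10:40, ] <- NA
  out <- interpolate_gaps(tr, max_gap = 10)
  expect_true(all(is.na(out$markers$R_HEEL[10:40, 1])))
  rep <- attr(out, "gap_report")
  expect_identical(rep$filled, FALSE)
  expect_equal(rep$length, 31L)
  # and detection refuses to work across them
  expect_error(suppressWarnings(detect_events(tr)), "unresolvable")
})

test_that("interpolation of a gap-free trial is the identity", {
  prof <- test_profile()
  tr <- simulate_trial(prof, "normal_walking")
  out <- interpolate_gaps(tr, max_gap = 10)
  expect_identical(out$markers, tr$markers)
  expect_equal(nrow(attr(out, "gap_report")), 0L)
})

test_that("dropout gaps are interpolated and frame counts are preserved", {
  prof <- test_profile()
  set.seed(23)
  tr <- simulate_trial(prof, "normal_walking", noise_sd = 0.001,
                       dropout_probability = 0.01)
  n0 <- nrow(tr$markers$L_TOE)
  out <- interpolate_gaps(tr, max_gap = 10)
  expect_equal(nrow(out$markers$L_TOE), n0)
  errs <- event_errors_frames(out)
  expect_lt(mean(abs(errs) <= 2), 1 + 1e-9)  # all matched, sanity
  expect_gte(mean(abs(errs) <= 2), 0.9)
})
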