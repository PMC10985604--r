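# Synthetic trajectory generator: ground-truth overrides, feasibility,
# counting, determinism.

test_that("a prescribed leading-foot apex is recovered exactly from clean trajectories", {
  prof <- test_profile()
  tr <- simulate_trial(prof, "overstepping",
                       overrides = list(max_step_height_L = 0.30))
  tp <- task_parameters(tr, geometry = test_geometry())
  expect_equal(unname(tp$values["max_step_height_L"]), 30.0, tolerance = 1e-5)
  expect_equal(unname(tr$ground_truth$params["max_step_height_L"]), 30.0)
})

test_that("foot strikes are placed exactly one step length apart", {
  prof <- test_profile(step_length = 0.60)
  tr <- simulate_trial(prof, "normal_walking")
  tp <- task_parameters(tr)
  expect_equal(unname(tp$values["step_length"]), 60.0, tolerance = 1e-6)
})

test_that("a 45 cm spanning step over the 50 cm gap is flagged as failure", {
  prof <- test_profile()
  tr <- simulate_trial(prof, "crossing",
                       overrides = list(step_length_over_gap = 0.45))
  expect_true(tr$ground_truth$failure)
  tp <- task_parameters(tr, geometry = test_geometry())
  expect_equal(unname(tp$values["step_length"]), 45.0, tolerance = 1e-4)
  expect_true(tp$failure)
})

test_that("unknown or task-foreign overrides are rejected", {
  prof <- test_profile()
  expect_error(simulate_trial(prof, "normal_walking",
                              overrides = list(max_step_height_L = 0.3)),
               "not defined for task")
  expect_error(simulate_trial(prof, "balancing",
                              overrides = list(banana = 1)), "not defined")
})

test_that("an unachievable gap raises an infeasibility error", {
  prof <- test_profile()
  expect_error(simulate_trial(prof, "crossing",
                              overrides = list(step_length_over_gap = 0.10)),
               "not achievable")
  expect_error(simulate_trial(prof, "circumventing",
                              overrides = list(min_shoulder_obstacle_distance = 0.35)),
               "not achievable")
})

test_that("a minimal study contains one trial per cell", {
  cfg <- synthetic_config(n_participants = 1, trials_per_task = 1, rng_seed = 5)
  ds <- simulate_study(cfg)
  expect_length(ds$trials, 1 * 2 * 5 * 1)  # participant x condition x task x trial
})

test_that("zero effects and zero noise give exactly zero condition differences", {
  cfg <- synthetic_config(n_participants = 2, trials_per_task = 1,
                          rng_seed = 7, noise_sd = 0, effects = list(),
                          profile_sd = c(step_length = 0, step_width = 0,
                                         gait_speed = 0,
                                         double_stance_fraction = 0,
                                         swing_apex_height = 0,
                                         shoulder_width = 0, shoulder_height = 0,
                                         foot_length = 0))
  ds <- simulate_study(cfg, tasks = c("normal_walking", "overstepping"))
  res <- suppressWarnings(run_pipeline(ds, k = 1))
  expect_true(all(abs(res$differences$difference) < 1e-9))
})

test_that("the same seed regenerates an identical dataset", {
  cfg <- synthetic_config(n_participants = 2, trials_per_task = 2,
                          rng_seed = 42, noise_sd = 0.002,
                          dropout_probability = 0.005)
  d1 <- simulate_study(cfg, tasks = c("overstepping", "circumventing"))
  d2 <- simulate_study(cfg, tasks = c("overstepping", "circumventing"))
  expect_length(d1$trials, length(d2$trials))
  for (i in seq_along(d1$trials)) {
    expect_identical(d1$trials[[i]]$markers, d2$trials[[i]]$markers)
    expect_identical(d1$trials[[i]]$ground_truth$params,
                     d2$trials[[i]]$ground_truth$params)
  }
  expect_identical(d1$participants, d2$participants)
})

test_that("invalid-trial injection perturbs the requested fraction and is detected", {
  cfg <- synthetic_config(n_participants = 2, trials_per_task = 8, rng_seed = 43)
  ds <- simulate_study(cfg, tasks = "overstepping")
  set.seed(1)
  out <- inject_invalid_trials(ds, 0.25)
  expect_equal(nrow(out$injected), floor(0.25 * length(ds$trials)))
  res <- run_pipeline(out$dataset)
  flagged <- res$validity[!res$validity$valid, ]
  expect_gte(nrow(flagged), nrow(out$injected) - 1L)
  expect_true(all(flagged$reasons != ""))

  set.seed(1)
  out0 <- inject_invalid_trials(ds, 0)
  expect_equal(nrow(out0$injected), 0L)
  expect_identical(out0$dataset$trials[[1]]$markers, ds$trials[[1]]$markers)
})

test_that("wrong-foot injection leaves six analysable trials out of eight", {
  cfg <- synthetic_config(n_participants = 1, trials_per_task = 8,
                          rng_seed = 44, noise_sd = 0)
  ds <- simulate_study(cfg, tasks = "overstepping")
  # invalidate trials 3 and 5 of the physical condition by swapping feet
  idx <- which(vapply(ds$trials, function(tr)
    tr$condition == "physical" && tr$trial_index %in% c(3, 5), logical(1)))
  for (i in idx) ds$trials[[i]] <- obstaclegait:::invalidate_trial(
    ds$trials[[i]], "wrong_leading_foot", 45L)
  res <- run_pipeline(ds)
  used <- res$trial_parameters[res$trial_parameters$condition == "physical", ]
  expect_setequal(unique(used$trial_index), c(1, 2, 4, 6, 7, 8))
})
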