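# Task-parameter extraction: conventions, symmetries, failure rules.

test_that("mirroring the trial leaves widths unchanged and flips the leading foot", {
  prof <- test_profile()
  tr <- simulate_trial(prof, "normal_walking")
  tp1 <- task_parameters(tr)
  tp2 <- task_parameters(mirror_trial(tr))
  expect_equal(tp2$values["step_width"], tp1$values["step_width"], tolerance = 1e-9)
  expect_equal(tp2$values["step_length"], tp1$values["step_length"], tolerance = 1e-9)

  to <- simulate_trial(prof, "overstepping", leading_foot = "left")
  g <- test_geometry()
  expect_identical(task_parameters(to, geometry = g)$leading_foot, "left")
  expect_identical(task_parameters(mirror_trial(to), geometry = g)$leading_foot,
                   "right")
})

test_that("clearance over the bar never exceeds the swing apex", {
  prof <- test_profile()
  set.seed(31)
  for (s in 1:5) {
    hL <- runif(1, 0.18, 0.35); hT <- runif(1, 0.18, 0.35)
    tr <- simulate_trial(prof, "overstepping",
                         overrides = list(max_step_height_L = hL,
                                          max_step_height_T = hT),
                         noise_sd = 0.001)
    tp <- task_parameters(tr, geometry = test_geometry())
    expect_lte(tp$values[["step_height_over_obstacle_L"]],
               tp$values[["max_step_height_L"]] + 1e-6)
    expect_lte(tp$values[["step_height_over_obstacle_T"]],
               tp$values[["max_step_height_T"]] + 1e-6)
  }
})

test_that("pre-obstacle distance is negative when the toe is past the near edge", {
  prof <- test_profile()
  tr <- simulate_trial(prof, "crossing",
                       overrides = list(preobstacle_distance_T = -0.02))
  tp <- task_parameters(tr, geometry = test_geometry())
  expect_equal(unname(tp$values["preobstacle_distance_T"]), -2.0, tolerance = 1e-4)
})

test_that("a trailing apex at 15 cm trips the 16 cm failure rule", {
  prof <- test_profile()
  tr <- simulate_trial(prof, "overstepping",
                       overrides = list(max_step_height_T = 0.15))
  tp <- task_parameters(tr, geometry = test_geometry())
  expect_true(tp$failure)
  expect_match(tp$failure_reasons, "max_step_height_T")
  expect_true(tr$ground_truth$failure)
})

test_that("a 20 cm beam step fails while transition steps outside the zone are ignored", {
  prof <- test_profile(step_width = 0.22)  # wide gait off the beam
  tr <- simulate_trial(prof, "balancing", overrides = list(step_width = 0.20))
  tp <- task_parameters(tr, geometry = test_geometry())
  expect_equal(unname(tp$values["step_width"]), 20, tolerance = 0.5)
  expect_true(tp$failure)

  tr2 <- simulate_trial(prof, "balancing", overrides = list(step_width = 0.05))
  tp2 <- task_parameters(tr2, geometry = test_geometry())
  # off-beam steps are 22 cm wide; the in-zone estimate must not see them
  expect_equal(unname(tp2$values["step_width"]), 5, tolerance = 0.5)
  expect_false(tp2$failure)
})

test_that("the optimized shoulder clearance equals an exhaustive frame-by-pole scan", {
  prof <- test_profile()
  g <- test_geometry()
  set.seed(32)
  tr <- simulate_trial(prof, "circumventing", noise_sd = 0.002)
  fast <- min_shoulder_clearance(tr, g)
  zone <- c(min(g$pole_positions[, 1]) - g$task_zone_margin,
            max(g$pole_positions[, 1]) + g$task_zone_margin)
  sh <- (tr$markers$L_SHO + tr$markers$R_SHO) / 2
  brute <- Inf
  for (i in which(sh[, 1] >= zone[1] & sh[, 1] <= zone[2])) {
    for (p in seq_len(nrow(g$pole_positions))) {
      for (nm in c("L_SHO", "R_SHO")) {
        m <- tr$markers[[nm]]
        brute <- min(brute, sqrt((m[i, 1] - g$pole_positions[p, 1])^2 +
                                   (m[i, 2] - g$pole_positions[p, 2])^2))
      }
    }
  }
  expect_identical(fast, brute - g$pole_radius)
})

test_that("a path touching a pole scores zero clearance and a failure", {
  prof <- test_profile()
  tr <- simulate_trial(prof, "circumventing",
                       overrides = list(min_shoulder_obstacle_distance = 0.0001))
  tp <- task_parameters(tr, geometry = test_geometry())
  expect_lt(abs(tp$values[["min_shoulder_obstacle_distance"]]), 0.1)
  expect_true(tp$failure)
})

test_that("failure totals count trials and distinct children", {
  toy <- tibble::tibble(
    participant_id = c("A", "A", "A", "A", "B", "B", "B", "B"),
    condition = "vr", task = "overstepping", trial_index = rep(1:4, 2),
    parameter = "max_step_height_L",
    value = c(14, 15, 22, 25, 13, 20, 21, 22))
  out <- count_failures(toy)
  row <- out[out$parameter == "max_step_height_L", ]
  expect_equal(row$failures, 3L)
  expect_equal(row$children, 2L)

  none <- toy; none$value <- 30
  out0 <- count_failures(none)
  expect_equal(out0$failures[out0$parameter == "max_step_height_L"], 0L)
  expect_equal(out0$children[out0$parameter == "max_step_height_L"], 0L)

  vac <- failure_rules(); vac$threshold <- -Inf
  expect_equal(sum(count_failures(toy, vac)$failures), 0L)

  mixed <- toy; mixed$task[1] <- "crossing"
  expect_error(count_failures(mixed), "single task")
})
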