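# Pipeline orchestration and report rendering.

test_that("a null-effect study is noninferior on every primary outcome", {
  cfg <- synthetic_config(n_participants = 4, trials_per_task = 6,
                          rng_seed = 81, noise_sd = 0.001, effects = list())
  ds <- simulate_study(cfg, tasks = c("overstepping", "crossing",
                                      "balancing", "circumventing"))
  res <- run_pipeline(ds)
  expect_equal(nrow(res$decisions), 5)
  expect_true(all(res$decisions$decision == "noninferior"))
})

test_that("reanalysing the same dataset reproduces identical tables", {
  cfg <- synthetic_config(n_participants = 2, trials_per_task = 3,
                          rng_seed = 82, noise_sd = 0.002)
  ds <- simulate_study(cfg, tasks = c("normal_walking", "balancing"))
  r1 <- suppressWarnings(run_pipeline(ds, k = 3))
  ds_again <- simulate_study(cfg, tasks = c("normal_walking", "balancing"))
  r2 <- suppressWarnings(run_pipeline(ds_again, k = 3))
  expect_identical(r1$stats, r2$stats)
  expect_identical(r1$summaries, r2$summaries)
  expect_identical(r1$failures, r2$failures)
})

test_that("an empty dataset is a clean error", {
  empty <- structure(list(trials = list(), participants = tibble::tibble(),
                          config = NULL, tasks = character(0)),
                     class = "study_dataset")
  expect_error(run_pipeline(empty), "empty dataset")
})

test_that("the rendered table has one block per task with failure rows", {
  cfg <- synthetic_config(n_participants = 2, trials_per_task = 2,
                          rng_seed = 83, noise_sd = 0.001)
  ds <- simulate_study(cfg, tasks = c("normal_walking", "crossing"))
  res <- suppressWarnings(run_pipeline(ds, k = 2))
  lines <- render_summary_table(res)
  expect_true(any(grepl("-- normal_walking --", lines)))
  expect_true(any(grepl("-- crossing --", lines)))
  expect_true(any(grepl("failures step_length", lines)))
  expect_true(any(grepl("\\d+\\.\\d{2} \\(\\d+\\.\\d{2}\\)", lines)))

  single <- render_summary_table(res, tasks = "crossing")
  expect_false(any(grepl("normal_walking", single)))
})

test_that("the reference summary reproduces the published analysis end to end", {
  out <- analyze_reference()
  dec <- out[!is.na(out$decision), ]
  ref <- reference_decisions()
  m <- merge(dec, ref, by = c("task", "parameter"),
             suffixes = c("_got", "_ref"))
  expect_equal(nrow(m), 5)
  expect_identical(m$decision_got, m$decision_ref)
})
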