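# TRC dialect reading/writing.

test_that("positions are converted from millimetres and blanks become missing", {
  path <- withr::local_tempfile(fileext = ".trc")
  writeLines(c(
    "PathFileType\t4\t(X/Y/Z)\ttoy.trc",
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames",
    "100\t100\t2\t1\tmm\t100\t1\t2",
    "Frame#\tTime\tM1\t\t",
    "\t\tX1\tY1\tZ1",
    "",
    "1\t0.00\t1000\t0\t20",
    "2\t0.01\t\t\t"
  ), path)
  tr <- read_trc(path, expected_markers = NULL)
  expect_equal(tr$markers$M1[1, ], c(X = 1, Y = 0, Z = 0.02))
  expect_true(all(is.na(tr$markers$M1[2, ])))
  expect_equal(tr$sampling_rate, 100)
})

test_that("unsupported units and malformed headers are rejected with line context", {
  path <- withr::local_tempfile(fileext = ".trc")
  writeLines(c(
    "PathFileType\t4\t(X/Y/Z)\ttoy.trc",
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames",
    "100\t100\t1\t1\tcm\t100\t1\t1",
    "Frame#\tTime\tM1\t\t",
    "\t\tX1\tY1\tZ1",
    "",
    "1\t0.00\t1\t2\t3"
  ), path)
  expect_error(read_trc(path), "Units 'cm'")

  path2 <- withr::local_tempfile(fileext = ".trc")
  writeLines(c("no header", "at", "all", "x", "y"), path2)
  expect_error(read_trc(path2), "DataRate")
})

test_that("frame-count and column-count inconsistencies are errors", {
  prof <- test_profile()
  tr <- simulate_trial(prof, "normal_walking")
  path <- withr::local_tempfile(fileext = ".trc")
  write_trc(tr, path)
  lines <- readLines(path)
  writeLines(lines[-length(lines)], path)   # drop one data row
  expect_error(read_trc(path), "frames")

  path3 <- withr::local_tempfile(fileext = ".trc")
  writeLines(c(lines[1:6], paste(lines[7], "999", sep = "\t"), lines[-(1:7)]), path3)
  expect_error(read_trc(path3), "column count")
})

test_that("write followed by read reproduces positions within a micrometre", {
  prof <- test_profile()
  set.seed(9)
  tr <- simulate_trial(prof, "overstepping", noise_sd = 0.002,
                       dropout_probability = 0.01)
  path <- withr::local_tempfile(fileext = ".trc")
  write_trc(tr, path)
  tr2 <- read_trc(path)
  expect_identical(names(tr2$markers), names(tr$markers))
  for (nm in names(tr$markers)) {
    a <- tr$markers[[nm]]; b <- tr2$markers[[nm]]
    expect_identical(is.na(a), is.na(b))
    expect_lt(max(abs(a - b), na.rm = TRUE), 1e-6)
  }
})

test_that("writing requires markers and lists all nine names in the header", {
  tr <- standing_trial()
  path <- withr::local_tempfile(fileext = ".trc")
  write_trc(tr, path)
  hdr <- readLines(path, n = 4)[4]
  for (nm in names(tr$markers)) expect_match(hdr, nm, fixed = TRUE)
  tr$markers <- list()
  expect_error(write_trc(tr, path), "no markers")
})

test_that("a study round-trips through TRC files and a manifest", {
  cfg <- synthetic_config(n_participants = 1, trials_per_task = 2,
                          rng_seed = 31, noise_sd = 0)
  ds <- simulate_study(cfg, tasks = c("normal_walking", "crossing"))
  dir <- withr::local_tempdir()
  mp <- write_study(ds, dir)
  ds2 <- load_study(mp)
  expect_length(ds2$trials, length(ds$trials))
  key <- function(tr) paste(tr$participant_id, tr$condition, tr$task, tr$trial_index)
  expect_setequal(vapply(ds2$trials, key, ""), vapply(ds$trials, key, ""))
  # ground truth survives the sidecar
  gt2 <- ds2$trials[[1]]$ground_truth
  gt1 <- ds$trials[[which(vapply(ds$trials, key, "") == key(ds2$trials[[1]]))[1]]]$ground_truth
  expect_equal(gt2$params, gt1$params, tolerance = 1e-8)
})

test_that("manifest problems are reported by row", {
  cfg <- synthetic_config(n_participants = 1, trials_per_task = 1, rng_seed = 32)
  ds <- simulate_study(cfg, tasks = "normal_walking")
  dir <- withr::local_tempdir()
  mp <- write_study(ds, dir)
  man <- read.delim(mp)
  man$file[1] <- "does_not_exist.trc"
  write.table(man, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_study(mp), "does not exist")

  man2 <- read.delim(file.path(dir, "manifest.tsv"))
  man2 <- rbind(man2, man2[1, ])  # duplicate key
  write.table(man2, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_study(mp), "duplicate")

  write.table(man2[0, ], mp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(ds0 <- load_study(mp), "empty")
  expect_length(ds0$trials, 0)
})
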