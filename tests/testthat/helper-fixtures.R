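# Shared fixtures: everything is generated in code at test time.

test_profile <- function(...) gait_profile(...)

test_geometry <- function(...) course_geometry(...)

# Per-event detection errors (in frames) against the generator's schedule,
# matched per foot/kind/rank.
event_errors_frames <- function(trial, events = NULL,
                                params = detection_params()) {
  if (is.null(events)) events <- detect_events(trial, params)
  gt <- as.data.frame(trial$ground_truth$events)
  det <- as.data.frame(events)[, c("foot", "kind", "time")]
  gt$i <- stats::ave(gt$time, gt$foot, gt$kind, FUN = seq_along)
  det$i <- stats::ave(det$time, det$foot, det$kind, FUN = seq_along)
  m <- merge(gt, det, by = c("foot", "kind", "i"),
             suffixes = c("_gt", "_det"))
  stopifnot(nrow(m) == nrow(gt))
  (m$time_det - m$time_gt) * trial$sampling_rate
}

# A motionless "standing" trial: all markers constant.
standing_trial <- function(n = 200, fs = 100) {
  pos <- list(
    L_TOE = c(0.45, 0.05, 0.02), L_HEEL = c(0.30, 0.05, 0.02),
    L_ANK = c(0.36, 0.05, 0.08),
    R_TOE = c(0.45, -0.05, 0.02), R_HEEL = c(0.30, -0.05, 0.02),
    R_ANK = c(0.36, -0.05, 0.08),
    L_SHO = c(0.35, 0.165, 1.2), R_SHO = c(0.35, -0.165, 1.2),
    C7 = c(0.30, 0, 1.23)
  )
  markers <- lapply(pos, function(p) {
    m <- matrix(rep(p, each = n), n, 3)
    dimnames(m) <- list(NULL, c("X", "Y", "Z"))
    m
  })
  structure(list(participant_id = "S1", condition = "physical",
                 task = "normal_walking", trial_index = 1L,
                 sampling_rate = fs, markers = markers,
                 leading_foot = "unknown", instruction_violation = FALSE,
                 ground_truth = NULL),
            class = "trial_recording")
}

# Mirror a trial across the walkway midline (y -> -y), swapping left/right
# marker labels.
mirror_trial <- function(trial) {
  swap <- c(L_TOE = "R_TOE", L_HEEL = "R_HEEL", L_ANK = "R_ANK",
            R_TOE = "L_TOE", R_HEEL = "L_HEEL", R_ANK = "L_ANK",
            L_SHO = "R_SHO", R_SHO = "L_SHO", C7 = "C7")
  mk <- trial$markers
  out <- trial
  for (nm in names(swap)) {
    m <- mk[[swap[[nm]]]]
    m[, 2] <- -m[, 2]
    out$markers[[nm]] <- m
  }
  out$leading_foot <- switch(trial$leading_foot, left = "right",
                             right = "left", trial$leading_foot)
  out
}

# Rigid translation of every marker.
translate_trial <- function(trial, dx = 0, dy = 0, dz = 0) {
  trial$markers <- lapply(trial$markers, function(m) {
    m[, 1] <- m[, 1] + dx; m[, 2] <- m[, 2] + dy; m[, 3] <- m[, 3] + dz
    m
  })
  trial
}
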