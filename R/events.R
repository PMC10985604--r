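# Kinematic detection of foot strike and foot off from foot-marker
# trajectories.  The study this pipeline re-implements labelled gait events
# visually; here the step is algorithmic: stance is found where the filtered
# toe and heel marker speeds stay below a threshold (default 0.2 m/s for at
# least 50 ms, with hysteresis), and each stance boundary is then refined to
# sub-frame precision by extrapolating the nearly linear vertical approach /
# departure of the heel marker to the stance level.

#' Default event-detection parameters
#'
#' @param stance_speed_threshold Foot-marker speed below which a frame counts
#'   as stance (m/s).  The 0.2 m/s default suits the slow, cautious gait of
#'   children with gait disorders.
#' @param min_stance_sec Minimum stance duration (s); shorter low-speed
#'   dips are ignored.
#' @param merge_gap_frames Hysteresis: below-threshold runs separated by at
#'   most this many frames are merged.
#' @param filter_cutoff_hz Low-pass cutoff of the zero-lag 2nd-order
#'   Butterworth filter applied to marker positions before differentiation.
#' @param gate_z Vertical gate (m) around the stance level used when refining
#'   event times.
#' @param max_gap Longest marker gap (frames) filled by cubic interpolation
#'   before detection.
#' @param refine Logical: refine event times to sub-frame precision.
#' @return A list of detection parameters.
#' @export
detection_params <- function(stance_speed_threshold = 0.2,
                             min_stance_sec = 0.05,
                             merge_gap_frames = 3L,
                             filter_cutoff_hz = 10,
                             gate_z = 0.010,
                             max_gap = 10L,
                             refine = TRUE) {
  list(stance_speed_threshold = stance_speed_threshold,
       min_stance_sec = min_stance_sec,
       merge_gap_frames = as.integer(merge_gap_frames),
       filter_cutoff_hz = filter_cutoff_hz,
       gate_z = gate_z, max_gap = as.integer(max_gap), refine = refine)
}

#' Fill short marker gaps by cubic interpolation
#'
#' Missing stretches of at most `max_gap` frames (with observed frames on
#' both sides) are filled per coordinate with a cubic spline, which is exact
#' for polynomial trajectories up to degree three.  Longer or boundary gaps
#' are left missing and listed in the attached gap report.
#'
#' @param trial A `trial_recording`.
#' @param max_gap Longest gap (frames) to fill.
#' @return The trial with gaps filled; attribute `gap_report` is a tibble
#'   (marker, start, end, length, filled).
#' @export
interpolate_gaps <- function(trial, max_gap = 10L) {
  if (max_gap < 0) stopf("max_gap must be >= 0")
  rep_rows <- list()
  for (nm in names(trial$markers)) {
    m <- trial$markers[[nm]]
    if (!anyNA(m)) next
    miss <- rowSums(is.na(m)) > 0
    runs <- true_runs(miss)
    n <- nrow(m)
    for (r in seq_len(nrow(runs))) {
      a <- runs$start[r]; b <- runs$end[r]
      len <- b - a + 1L
      fillable <- len <= max_gap && a > 1L && b < n
      if (fillable) {
        known <- which(!miss)
        for (j in 1:3) {
          m[a:b, j] <- stats::spline(known, m[known, j], xout = a:b,
                                     method = "fmm")$y
        }
      }
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(marker = nm, start = a, end = b, length = len,
                   filled = fillable)
    }
    trial$markers[[nm]] <- m
  }
  report <- if (length(rep_rows)) tibble::as_tibble(do.call(rbind, rep_rows))
    else tibble::tibble(marker = character(0), start = integer(0),
                        end = integer(0), length = integer(0),
                        filled = logical(0))
  attr(trial, "gap_report") <- report
  trial
}

# Zero-lag low-pass Butterworth of an n x 3 coordinate matrix, applied in
# the frequency domain: multiplying by |H|^2 of a 2nd-order Butterworth
# reproduces the magnitude response of forward-backward (filtfilt)
# filtering without per-call overhead.  The linear trend between the
# endpoints is removed first and zero padding added so the circular
# convolution has no wrap-around transients (trials start and end in quiet
# stance).
#' @noRd
lowpass <- function(m, fs, cutoff) {
  if (cutoff >= fs / 2) return(m)
  n <- nrow(m)
  pad <- min(64L, n)
  nfft <- stats::nextn(n + 2L * pad, c(2, 3, 5))
  freq <- (0:(nfft - 1)) / nfft * fs
  freq <- pmin(freq, fs - freq)
  H <- 1 / (1 + (freq / cutoff)^4)
  ramp <- seq_len(n) - 1L
  apply(m, 2, function(x) {
    trend <- x[1] + (x[n] - x[1]) * ramp / (n - 1)
    y <- c(x - trend, numeric(nfft - n))
    z <- Re(stats::fft(stats::fft(y) * H, inverse = TRUE)) / nfft
    z[seq_len(n)] + trend
  })
}

# Central-difference speed (m/s) of an n x 3 position matrix.
#' @noRd
marker_speed <- function(m, fs) {
  n <- nrow(m)
  d <- m[c(2:n, n), ] - m[c(1, 1:(n - 1)), ]
  dt <- c(1, rep(2, n - 2), 1) / fs
  sqrt(rowSums(d^2)) / dt
}

# Refine a stance-onset time around the coarse (speed-threshold) boundary.
# The heel height is flat at the stance level after touchdown and descends
# almost linearly just before it (the swing's vertical profile ends with
# constant velocity), so touchdown is estimated as the change point of a
# local flat-plus-ramp model, by least squares over a sub-frame grid of
# candidate times.  This is robust to marker jitter (it pools the whole
# local window) and exact for clean piecewise-linear approaches.  `z` must
# be oriented so that stance FOLLOWS the approach; pass reversed vectors to
# refine a departure (foot off).
#' @noRd
refine_onset <- function(z, t, c_idx, ref_z, gate, fs) {
  n <- length(z)
  a <- c_idx
  # pull the coarse boundary back across quiet frames (handles trials that
  # begin in stance and coarse boundaries a few frames late)
  while (a > 1L && abs(z[a - 1L] - ref_z) <= gate) a <- a - 1L
  if (a == 1L) return(t[1])
  w0 <- max(1L, a - 8L); w1 <- min(n, a + 8L)
  idx <- (w0:w1)[z[w0:w1] - ref_z < 0.06]  # drop high-flight frames
  if (length(idx) < 4L) return(t[a])
  zz <- z[idx] - ref_z
  tt <- t[idx]
  # with quiet data a quadratic correction absorbs the mild curvature of the
  # approach; under visible jitter the extra term only adds variance
  sigma_z <- stats::mad(zz[tt >= t[a]])
  quad <- is.finite(sigma_z) && sigma_z < 0.0015
  zz2 <- sum(zz^2)
  rss_grid <- function(taus) {
    R <- outer(taus, tt, "-")
    R[R < 0] <- 0
    R2 <- R * R
    a11 <- rowSums(R2)
    b1 <- as.vector(R %*% zz)
    s <- b1 / pmax(a11, 1e-12)
    s[s < 0 | !is.finite(s)] <- 0
    rss <- zz2 - 2 * s * b1 + s * s * a11
    if (quad) {
      a12 <- rowSums(R2 * R); a22 <- rowSums(R2 * R2)
      b2 <- as.vector(R2 %*% zz)
      det <- a11 * a22 - a12 * a12
      ok <- det > 1e-20
      beta1 <- (b1 * a22 - b2 * a12) / ifelse(ok, det, 1)
      beta2 <- (b2 * a11 - b1 * a12) / ifelse(ok, det, 1)
      rq <- zz2 - beta1 * b1 - beta2 * b2
      rss[ok] <- rq[ok]
    }
    rss[a11 <= 0] <- zz2
    rss
  }
  lo_t <- t[max(w0, a - 6L)]; hi_t <- t[min(w1, a + 6L)]
  coarse <- seq(lo_t, hi_t, by = 0.4 / fs)
  tau0 <- coarse[which.min(rss_grid(coarse))]
  fine <- seq(max(lo_t, tau0 - 0.4 / fs), min(hi_t, tau0 + 0.4 / fs), by = 0.1 / fs)
  fine[which.min(rss_grid(fine))]
}

#' Detect foot strike and foot off events
#'
#' Finds, per foot, the alternating sequence of foot strikes and foot offs
#' from the toe and heel marker kinematics.  Short marker gaps are first
#' filled by [interpolate_gaps()]; positions are low-pass filtered before
#' differentiation; stance is declared where both the toe and heel speeds
#' stay below the stance threshold for the minimum stance duration (merged
#' with hysteresis); and each boundary is refined to sub-frame precision from
#' the heel's vertical approach.
#'
#' @param trial A `trial_recording`.
#' @param params A [detection_params()] list.
#' @return A tibble (foot, kind, time, frame) in global time order, with
#'   attribute `degenerate` set when a foot never leaves stance (for example
#'   a standing record).
#' @export
detect_events <- function(trial, params = detection_params()) {
  fs <- trial$sampling_rate
  trial <- interpolate_gaps(trial, params$max_gap)
  out <- list()
  degenerate <- FALSE
  for (f in c("L", "R")) {
    toe <- trial$markers[[paste0(f, "_TOE")]]
    heel <- trial$markers[[paste0(f, "_HEEL")]]
    if (is.null(toe) || is.null(heel)) stopf("missing toe/heel markers for foot %s", f)
    if (anyNA(toe) || anyNA(heel)) {
      stopf("unresolvable marker gaps on foot %s exceed max_gap = %d frames",
            f, params$max_gap)
    }
    n <- nrow(heel)
    if (n < ceiling(params$min_stance_sec * fs) + 4L) {
      stopf("trial too short to contain one full stance")
    }
    t <- (seq_len(n) - 1L) / fs
    spd <- pmax(marker_speed(lowpass(toe, fs, params$filter_cutoff_hz), fs),
                marker_speed(lowpass(heel, fs, params$filter_cutoff_hz), fs))
    below <- spd < params$stance_speed_threshold
    runs <- true_runs(below)
    if (nrow(runs) == 0) stopf("no stance found for foot %s", f)
    # hysteresis: merge runs separated by short supra-threshold blips
    if (nrow(runs) > 1) {
      keep <- runs[1, , drop = FALSE]
      for (r in 2:nrow(runs)) {
        if (runs$start[r] - keep$end[nrow(keep)] - 1L <= params$merge_gap_frames) {
          keep$end[nrow(keep)] <- runs$end[r]
        } else keep <- rbind(keep, runs[r, ])
      }
      runs <- keep
    }
    runs <- runs[runs$end - runs$start + 1L >= params$min_stance_sec * fs, , drop = FALSE]
    if (nrow(runs) == 0) stopf("no stance of at least %g s found for foot %s",
                               params$min_stance_sec, f)
    ev_kind <- character(0); ev_time <- numeric(0)
    # foot height = mean of heel and toe marker height: both ride the same
    # rigid foot, and averaging halves the jitter variance for refinement
    z <- (heel[, 3] + toe[, 3]) / 2
    zrev <- rev(z); trev <- rev(-t)
    for (r in seq_len(nrow(runs))) {
      a <- runs$start[r]; b <- runs$end[r]
      ref_z <- stats::median(z[a:b])
      if (a == 1L) {
        ts <- 0
      } else if (params$refine) {
        ts <- refine_onset(z, t, a, ref_z, params$gate_z, fs)
      } else ts <- t[a]
      ev_kind <- c(ev_kind, "strike"); ev_time <- c(ev_time, ts)
      if (b < n) {
        if (params$refine) {
          # refine in reversed time, where the departure looks like an onset
          to <- -refine_onset(zrev, trev, n - b + 1L, ref_z, params$gate_z, fs)
        } else to <- t[b]
        if (to < ts) { # collision: earlier sample wins
          warnf("foot %s: strike/off collision at %.3f s; keeping strike", f, ts)
          to <- ts
        }
        ev_kind <- c(ev_kind, "off"); ev_time <- c(ev_time, to)
      }
    }
    if (nrow(runs) == 1L && runs$start[1] == 1L && runs$end[1] == n) {
      degenerate <- TRUE
      warnf("foot %s never leaves stance; trial flagged degenerate", f)
    }
    out[[f]] <- data.frame(foot = f, kind = ev_kind, time = ev_time)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$time, res$foot), ]
  res$frame <- pmin(pmax(as.integer(round(res$time * fs)), 0L),
                    nrow(trial$markers[[1]]) - 1L) + 1L
  rownames(res) <- NULL
  res <- tibble::as_tibble(res)
  attr(res, "degenerate") <- degenerate
  res
}
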