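#' Round half away from zero
#'
#' Display rounding used for reported centimetre values: exact halves move away
#' from zero (so 6.2639 -> 6.26, -4.915 -> -4.92), unlike [base::round()]'s
#' round-half-to-even.  Internal comparisons always use unrounded values.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2, the reporting precision).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Maximal runs of TRUE in a logical vector; returns data.frame(start, end)
# (inclusive indices), possibly zero rows.
#' @noRd
true_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Draw from a normal truncated by clamping to [lo, hi].  Clamping (rather than
# rejection) keeps the draw count deterministic under a fixed seed.
#' @noRd
rnorm_clamped <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' @noRd
is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Tasks of the obstacle course
#'
#' The five walking tasks analysed by the pipeline: unobstructed walking plus
#' the four obstacle negotiations.
#'
#' @return Character vector of task identifiers.
#' @export
gait_tasks <- function() {
  c("normal_walking", "overstepping", "crossing", "balancing", "circumventing")
}

#' @noRd
check_task <- function(task) {
  if (!is.character(task) || length(task) != 1L || !task %in% gait_tasks()) {
    stopf("unknown task '%s'; must be one of: %s",
          paste(task, collapse = ","), paste(gait_tasks(), collapse = ", "))
  }
  task
}

# The nine-marker set: toe/heel/ankle per foot, two acromia and a C7 proxy.
#' @noRd
marker_names <- function() {
  c("L_TOE", "L_HEEL", "L_ANK", "R_TOE", "R_HEEL", "R_ANK",
    "L_SHO", "R_SHO", "C7")
}
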