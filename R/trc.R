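# TRC marker-trajectory file reading and writing.
#
# The dialect is the standard tab-delimited motion-capture interchange
# format: a PathFileType line, a DataRate/NumFrames/Units header pair, a
# Frame#/Time row naming the markers (three columns each), an X/Y/Z subrow,
# then one row per frame.  Units must be mm or m; positions are stored
# internally in metres; blank cells are missing samples.

#' Read a TRC trajectory file
#'
#' @param path File path.
#' @param expected_markers Character vector of canonical marker names the
#'   file's names are matched against case-insensitively (default the
#'   nine-marker set used by this pipeline); set `NULL` to accept any names.
#' @param aliases Named character vector mapping file marker names (upper
#'   case) to canonical names, e.g. `c(LTOE = "L_TOE")`.
#' @return A `trial_recording` with unknown study metadata (supply it via
#'   the manifest, see [load_study()]).
#' @export
read_trc <- function(path, expected_markers = marker_names(), aliases = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5) stopf("%s: truncated TRC file (%d lines)", path, length(lines))
  hdr_i <- grep("^DataRate", lines)[1]
  if (is.na(hdr_i) || hdr_i + 1 > length(lines)) {
    stopf("%s: malformed header: no DataRate line", path)
  }
  hdr_names <- strsplit(lines[hdr_i], "\t")[[1]]
  hdr_vals <- strsplit(lines[hdr_i + 1], "\t")[[1]]
  get_hdr <- function(key) {
    j <- match(key, hdr_names)
    if (is.na(j) || j > length(hdr_vals)) stopf("%s: malformed header: missing %s (line %d)",
                                               path, key, hdr_i + 1)
    hdr_vals[j]
  }
  rate <- as.numeric(get_hdr("DataRate"))
  n_frames <- as.integer(get_hdr("NumFrames"))
  n_markers <- as.integer(get_hdr("NumMarkers"))
  units <- get_hdr("Units")
  if (!units %in% c("mm", "m")) {
    stopf("%s: unsupported Units '%s' (line %d); expected mm or m",
          path, units, hdr_i + 1)
  }
  if (!is.finite(rate) || rate <= 0) stopf("%s: invalid DataRate (line %d)", path, hdr_i + 1)

  name_i <- hdr_i + 2
  name_tok <- strsplit(lines[name_i], "\t")[[1]]
  if (length(name_tok) < 3 || !grepl("^Frame", name_tok[1])) {
    stopf("%s: malformed marker-name row (line %d)", path, name_i)
  }
  mk <- name_tok[-(1:2)]
  mk <- mk[mk != ""]
  if (length(mk) != n_markers) {
    stopf("%s: header announces %d markers but %d are named (line %d)",
          path, n_markers, length(mk), name_i)
  }
  canon <- toupper(mk)
  if (!is.null(aliases)) {
    hit <- match(canon, toupper(names(aliases)))
    canon[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  }
  if (!is.null(expected_markers)) {
    hit <- match(canon, toupper(expected_markers))
    canon[!is.na(hit)] <- expected_markers[hit[!is.na(hit)]]
  }

  data_i <- name_i + 2            # skip the X/Y/Z subrow
  rows <- lines[data_i:length(lines)]
  rows <- rows[trimws(rows) != ""]
  if (length(rows) != n_frames) {
    stopf("%s: header announces %d frames but %d data rows found",
          path, n_frames, length(rows))
  }
  ncol_expect <- 2 + 3 * n_markers
  mats <- matrix(NA_real_, length(rows), 3 * n_markers)
  for (i in seq_along(rows)) {
    tok <- strsplit(rows[i], "\t")[[1]]
    if (length(tok) > ncol_expect) {
      stopf("%s: inconsistent column count on data row %d (line %d): %d > %d",
            path, i, data_i + i - 1, length(tok), ncol_expect)
    }
    tok <- c(tok, rep("", ncol_expect - length(tok)))
    v <- suppressWarnings(as.numeric(tok[-(1:2)]))
    mats[i, ] <- v
  }
  scale <- if (units == "mm") 1e-3 else 1
  markers <- list()
  for (j in seq_len(n_markers)) {
    m <- mats[, (3 * j - 2):(3 * j), drop = FALSE] * scale
    dimnames(m) <- list(NULL, c("X", "Y", "Z"))
    markers[[canon[j]]] <- m
  }
  structure(list(
    participant_id = NA_character_, condition = NA_character_,
    task = NA_character_, trial_index = NA_integer_,
    sampling_rate = rate, markers = markers,
    leading_foot = "unknown", instruction_violation = FALSE,
    ground_truth = NULL
  ), class = "trial_recording")
}

#' Write a trial to a TRC file
#'
#' @param trial A `trial_recording`.
#' @param path Output path.
#' @param units `"mm"` (default) or `"m"`.
#' @return The path, invisibly.
#' @export
write_trc <- function(trial, path, units = c("mm", "m")) {
  units <- match.arg(units)
  mk <- trial$markers
  if (!length(mk)) stopf("trial has no markers")
  n <- nrow(mk[[1]])
  if (any(vapply(mk, nrow, integer(1)) != n)) stopf("marker series differ in frame count")
  fs <- trial$sampling_rate
  scale <- if (units == "mm") 1e3 else 1
  nm <- names(mk)
  l1 <- sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path))
  l2 <- "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames"
  l3 <- sprintf("%g\t%g\t%d\t%d\t%s\t%g\t1\t%d", fs, fs, n, length(nm), units, fs, n)
  l4 <- paste(c("Frame#", "Time", unlist(lapply(nm, function(x) c(x, "", "")))),
              collapse = "\t")
  l5 <- paste(c("", "", unlist(lapply(seq_along(nm), function(j)
    paste0(c("X", "Y", "Z"), j)))), collapse = "\t")
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.5f", v))
  body <- vapply(seq_len(n), function(i) {
    cells <- unlist(lapply(mk, function(m) fmt(m[i, ] * scale)))
    paste(c(sprintf("%d", i), sprintf("%.5f", (i - 1) / fs), cells), collapse = "\t")
  }, character(1))
  writeLines(c(l1, l2, l3, l4, l5, "", body), path)
  invisible(path)
}
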