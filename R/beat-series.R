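#' Beat-annotated RR-interval series
#'
#' A `beat_series` is a tibble with one row per annotated beat and columns
#' `time_s` (seconds from recording start, strictly increasing), `rr_ms`
#' (the RR interval ending at that beat, milliseconds) and `label`
#' (`"N"` normal sinus, `"V"` ventricular ectopic, `"S"` supraventricular
#' ectopic, `"X"` artifact).  The recording's clock start (seconds from
#' midnight) and the patient id travel as attributes so that beats can be
#' placed on the wall clock: clock time = `clock_start + time_s`, modulo
#' 24 h for recordings that cross midnight.
#'
#' @param time_s Numeric vector of beat times, seconds from recording start.
#' @param rr_ms Numeric vector of RR intervals in milliseconds, one per beat.
#' @param label Character vector of beat labels in `N`, `V`, `S`, `X`.
#' @param patient_id Patient identifier.
#' @param clock_start Recording start as `"HH:MM:SS"` or seconds from
#'   midnight.
#'
#' @return A validated `beat_series` tibble.
#' @export
#' @examples
#' beat_series(time_s = cumsum(rep(0.8, 5)), rr_ms = rep(800, 5),
#'             label = c("N", "N", "V", "N", "N"), patient_id = "P1")
beat_series <- function(time_s, rr_ms, label,
                        patient_id = "unknown", clock_start = 0) {
  x <- tibble::tibble(
    time_s = as.numeric(time_s),
    rr_ms = as.numeric(rr_ms),
    label = as.character(label)
  )
  x <- new_beat_series(x, patient_id = patient_id,
                       clock_start_s = parse_clock(clock_start))
  validate_beat_series(x)
}

new_beat_series <- function(df, patient_id, clock_start_s) {
  tibble::new_tibble(df,
    patient_id = as.character(patient_id),
    clock_start_s = as.numeric(clock_start_s),
    class = "beat_series"
  )
}

#' @export
`[.beat_series` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    out <- new_beat_series(out, patient_id(x), clock_start(x))
    for (a in c("coverage", "analyzable", "window")) {
      attr(out, a) <- attr(x, a)
    }
  }
  out
}

#' @rdname beat_series
#' @param x A `beat_series`.
#' @export
patient_id <- function(x) attr(x, "patient_id") %||% "unknown"

#' @rdname beat_series
#' @export
clock_start <- function(x) attr(x, "clock_start_s") %||% 0

#' Wall-clock time of each beat
#'
#' @param x A `beat_series`.
#' @return Seconds from midnight of each beat's end, in `[0, 86400)`.
#' @export
clock_time <- function(x) (clock_start(x) + x$time_s) %% 86400

#' Validate a beat series
#'
#' Checks the structural invariants of a [beat_series()]: required columns,
#' strictly increasing beat times, positive RR intervals, known labels, and
#' internal consistency of RR against elapsed time (an RR interval may not
#' exceed the time elapsed since the previous beat by more than 1 ms; the
#' elapsed time may exceed the RR when beats were removed, which is recorded
#' as a discontinuity, not an error).
#'
#' @param x A `beat_series`.
#' @return `x`, invisibly, with a `label_counts` attribute.
#' @export
validate_beat_series <- function(x) {
  need <- c("time_s", "rr_ms", "label")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(paste0("beat series is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) abort("no beats")
  bad <- which(!(x$rr_ms > 0))
  if (length(bad)) {
    abort(paste0("non-positive RR interval at row ", bad[1],
                 " (rr_ms = ", x$rr_ms[bad[1]], ")"))
  }
  if (nrow(x) > 1) {
    dt <- diff(x$time_s)
    bad <- which(dt <= 0)
    if (length(bad)) {
      abort(paste0("beat times not strictly increasing at row ", bad[1] + 1))
    }
    over <- which(x$rr_ms[-1] > dt * 1000 + 1)
    if (length(over)) {
      abort(paste0("RR interval exceeds elapsed time at row ", over[1] + 1,
                   " (rr_ms = ", x$rr_ms[over[1] + 1], ", elapsed = ",
                   round(dt[over[1]] * 1000, 1), " ms)"))
    }
  }
  bad_lab <- which(!x$label %in% c("N", "V", "S", "X"))
  if (length(bad_lab)) {
    abort(paste0("unknown beat label '", x$label[bad_lab[1]],
                 "' at row ", bad_lab[1]))
  }
  attr(x, "label_counts") <- table(factor(x$label, c("N", "V", "S", "X")))
  invisible(x)
}

#' Read a beat-annotated RR series from delimited text
#'
#' The expected dialect is comma-separated with columns `time_s`, `rr_ms`,
#' `label`, preceded by comment header lines of the form
#' `# clock_start=HH:MM:SS` and optionally `# patient_id=...`.  Artifact
#' beats (`X`) are retained but flagged through the label column.
#'
#' @param path Path to the file.
#' @param dialect Input dialect; only `"csv"` is built in (WFDB-style
#'   annotation import is an adapter point).
#' @return A validated [beat_series()].  The per-label beat counts are
#'   available as `attr(x, "label_counts")`.
#' @export
read_beat_series <- function(path, dialect = "csv") {
  if (!identical(dialect, "csv")) {
    abort(paste0("unsupported dialect '", dialect, "'"))
  }
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) abort("no beats")

  get_field <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, "\\s*="), hdr, value = TRUE)
    if (!length(m)) return(default)
    trimws(sub(paste0("^#\\s*", key, "\\s*="), "", m[1]))
  }
  clock <- get_field("clock_start", "00:00:00")
  pid <- get_field("patient_id",
                   sub("\\.[^.]*$", "", basename(path)))

  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  need <- c("time_s", "rr_ms", "label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0("missing column(s) in ", path, ": ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- new_beat_series(
    tibble::as_tibble(df[need]),
    patient_id = pid, clock_start_s = parse_clock(clock)
  )
  validate_beat_series(x)
  x
}

#' Write a beat series in the same dialect [read_beat_series()] reads
#'
#' @param x A `beat_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beat_series <- function(x, path) {
  validate_beat_series(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# clock_start=", format_clock(clock_start(x))),
    paste0("# patient_id=", patient_id(x)),
    "time_s,rr_ms,label"
  ), con)
  writeLines(paste(format(x$time_s, trim = TRUE, scientific = FALSE),
                   format(x$rr_ms, trim = TRUE, scientific = FALSE),
                   x$label, sep = ","), con)
  invisible(path)
}

#' Nocturnal analysis window
#'
#' The scoring window on the wall clock, by default 00:00 to 06:00
#' (half-open, `[start, end)`), with the minimum fraction of the window
#' that must be covered by analyzable beats for the patient to be scored.
#'
#' @param start_s,end_s Window bounds in seconds from midnight,
#'   `0 <= start_s < end_s <= 86400`.
#' @param min_coverage Minimum analyzable-time fraction of the window, in
#'   `[0, 1]`.
#' @return A `nocturnal_window` list.
#' @export
nocturnal_window <- function(start_s = 0, end_s = 21600, min_coverage = 0.8) {
  start_s <- parse_clock(start_s)
  end_s <- parse_clock(end_s)
  stopifnot(start_s >= 0, start_s < end_s, end_s <= 86400,
            min_coverage >= 0, min_coverage <= 1)
  structure(list(start_s = start_s, end_s = end_s,
                 min_coverage = min_coverage),
            class = "nocturnal_window")
}

#' Restrict a beat series to the nocturnal window
#'
#' Keeps beats whose wall-clock end time falls in `[start, end)` of the
#' window; recordings crossing midnight are handled by modular clock
#' arithmetic.  The coverage fraction (analyzable time inside the window
#' divided by window length) is attached, and the series is flagged
#' non-analyzable — distinct from a flat tachogram — when coverage is below
#' the window's minimum.
#'
#' @param series A validated [beat_series()].
#' @param window A [nocturnal_window()].
#' @return A `beat_series` restricted to the window, with attributes
#'   `coverage` (fraction in `[0, 1]`), `analyzable` (logical) and `window`.
#' @export
extract_nocturnal_segment <- function(series, window = nocturnal_window()) {
  validate_beat_series(series)
  clock <- clock_time(series)
  keep <- clock >= window$start_s & clock < window$end_s
  out <- series[keep, ]
  # Analyzable time: each retained beat contributes its RR, truncated so
  # that an interval reaching back across the window start is not
  # over-counted.
  if (nrow(out)) {
    rr_s <- out$rr_ms / 1000
    into <- (clock[keep] - window$start_s)
    cover_s <- sum(pmin(rr_s, into))
  } else {
    cover_s <- 0
  }
  coverage <- min(1, cover_s / (window$end_s - window$start_s))
  attr(out, "coverage") <- coverage
  attr(out, "analyzable") <- coverage >= window$min_coverage && nrow(out) >= 2
  attr(out, "window") <- window
  out
}

#' Keep only normal-to-normal (NN) intervals
#'
#' An interval is NN when both bounding beats are labeled `N`; intervals
#' into or out of an ectopic or artifact beat are dropped, as is the first
#' beat of the recording (no preceding bounding beat).  Gaps left by
#' dropped beats remain as discontinuities in `time_s` (no interpolation);
#' downstream consumers detect them as elapsed time exceeding `rr_ms`.
#'
#' @param series A validated [beat_series()].
#' @return A `beat_series` whose rows are the NN intervals (one row per
#'   interval, timed at its ending beat).  Warns and returns an empty
#'   series when fewer than two `N` beats exist.
#' @export
nn_filter <- function(series) {
  validate_beat_series(series)
  n <- nrow(series)
  if (sum(series$label == "N") < 2) {
    warn(paste0("fewer than 2 N beats for patient ", patient_id(series),
                "; no NN intervals"))
    return(series[integer(0), ])
  }
  keep <- series$label == "N" & dplyr::lag(series$label, default = "X") == "N"
  series[keep, ]
}
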