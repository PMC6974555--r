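#' Instantaneous heart-rate tachogram
#'
#' Builds the instantaneous-HR tachogram from an NN-filtered beat series:
#' `hr_bpm = 60000 / rr_ms` at each NN interval's ending beat.  Alongside
#' the beat-level channels, an evenly resampled grid (default 2 Hz) is kept
#' as an attribute; the trend-filtered channel (`hr_smooth_bpm`, running
#' median, default 5 s) and the respiratory-sinus-arrhythmia amplitude
#' channel (`rsa_amplitude_bpm`, high-frequency band 0.15–0.40 Hz modulation
#' amplitude) are computed on that grid and interpolated back to beat times.
#'
#' The 5-s median default suppresses beat-level noise and single ectopy-
#' adjacent outliers while preserving the >= 10 s arousals that CVHR scoring
#' must detect.
#'
#' @param nn An NN-filtered [beat_series()] with at least 2 intervals.
#' @param smooth_window_s Running-median window for the smoothed channel,
#'   seconds.
#' @param grid_hz Resampling rate for the internal even grid, Hz.
#' @param rsa_band Frequency band of respiratory sinus arrhythmia, Hz.
#' @return A `cvhr_tachogram` tibble with columns `time_s`, `rr_ms`,
#'   `hr_bpm`, `hr_smooth_bpm`, `rsa_amplitude_bpm`; attributes `grid`
#'   (the even-grid tibble), `rsa_amplitude_bpm` (scalar summary, median of
#'   the amplitude envelope), `grid_hz`, `patient_id`, `clock_start_s`.
#' @export
build_tachogram <- function(nn, smooth_window_s = 5, grid_hz = 2,
                            rsa_band = c(0.15, 0.40)) {
  validate_beat_series(nn)
  if (nrow(nn) < 2) abort("need at least 2 NN intervals to build a tachogram")
  hr <- 60000 / nn$rr_ms
  t0 <- nn$time_s[1]
  t1 <- nn$time_s[nrow(nn)]
  grid_t <- seq(t0, t1, by = 1 / grid_hz)
  hr_grid <- approx(nn$time_s, hr, xout = grid_t, rule = 2)$y

  grid <- tibble::tibble(time_s = grid_t, hr_bpm = hr_grid)
  out <- tibble::new_tibble(
    tibble::tibble(time_s = nn$time_s, rr_ms = nn$rr_ms, hr_bpm = hr),
    grid = grid, grid_hz = grid_hz,
    patient_id = patient_id(nn), clock_start_s = clock_start(nn),
    class = "cvhr_tachogram"
  )
  out <- smooth_hr(out, window_s = smooth_window_s)
  add_rsa_channel(out, rsa_band = rsa_band)
}

#' @export
`[.cvhr_tachogram` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    for (a in c("grid", "grid_hz", "rsa_amplitude_bpm", "smooth_window_s",
                "patient_id", "clock_start_s")) {
      attr(out, a) <- attr(x, a)
    }
    class(out) <- class(x)
  }
  out
}

tachogram_grid <- function(tach) attr(tach, "grid")

#' Re-smooth the tachogram's trend channel
#'
#' Replaces `hr_smooth_bpm` with a running median of the given window,
#' computed on the even grid; window ends shrink at the recording edges.
#'
#' @param tach A `cvhr_tachogram`.
#' @param window_s Median window in seconds (> 0).
#' @return The tachogram with an updated smoothed channel.
#' @export
smooth_hr <- function(tach, window_s = 5) {
  stopifnot(window_s > 0)
  grid <- tachogram_grid(tach)
  grid_hz <- attr(tach, "grid_hz")
  k <- max(1L, as.integer(round(window_s * grid_hz)))
  if (k %% 2 == 0) k <- k + 1L
  k <- min(k, nrow(grid) - (1 - nrow(grid) %% 2))
  grid$hr_smooth_bpm <- if (k >= 3 && nrow(grid) >= k) {
    as.numeric(runmed(grid$hr_bpm, k, endrule = "median"))
  } else {
    grid$hr_bpm
  }
  tach$hr_smooth_bpm <- approx(grid$time_s, grid$hr_smooth_bpm,
                               xout = tach$time_s, rule = 2)$y
  attr(tach, "grid") <- grid
  attr(tach, "smooth_window_s") <- window_s
  tach
}

# High-frequency modulation amplitude: band-pass the (unsmoothed) resampled
# instantaneous HR in the RSA band, then estimate the local sinusoidal
# amplitude as sqrt(2) * rolling RMS (30 s window).
add_rsa_channel <- function(tach, rsa_band = c(0.15, 0.40),
                            envelope_window_s = 30) {
  grid <- tachogram_grid(tach)
  grid_hz <- attr(tach, "grid_hz")
  n <- nrow(grid)
  if (n >= 24 && rsa_band[2] < grid_hz / 2) {
    bf <- signal::butter(2, rsa_band / (grid_hz / 2), type = "pass")
    x <- grid$hr_bpm - mean(grid$hr_bpm)
    hf <- as.numeric(signal::filtfilt(bf, x))
    k <- max(3L, as.integer(round(envelope_window_s * grid_hz)))
    k <- min(k, n)
    env <- sqrt(2 * pmax(zoo::rollmean(hf^2, k, fill = "extend"), 0))
    grid$rsa_bpm <- env
  } else {
    grid$rsa_bpm <- rep(0, n)
  }
  tach$rsa_amplitude_bpm <- approx(grid$time_s, grid$rsa_bpm,
                                   xout = tach$time_s, rule = 2)$y
  attr(tach, "grid") <- grid
  attr(tach, "rsa_amplitude_bpm") <- median(grid$rsa_bpm)
  tach
}

#' Classify a flat nocturnal tachogram
#'
#' A nocturnal tachogram is flat when (1) the instantaneous heart rate shows
#' no excursions of 5 bpm or more and (2) no respiratory sinus arrhythmia is
#' present.  The excursion is measured robustly on the smoothed channel as
#' the 99.5th minus the 0.5th percentile, so a single artifact cannot defeat
#' flatness; RSA presence is quantified as a high-frequency modulation
#' amplitude of at least `rsa_min_bpm` (default 1 bpm).  Flat tachograms
#' cannot be scored for CVHR and are routed to the `indeterminate_flat`
#' sleep-disordered-breathing status.
#'
#' @param tach A `cvhr_tachogram` over the nocturnal window.
#' @param excursion_limit_bpm Flatness bound on the HR excursion, bpm.
#' @param rsa_min_bpm Minimum modulation amplitude that counts as visible
#'   RSA, bpm.
#' @param percentiles Robust range used for the excursion.
#' @return A one-row tibble: `is_flat`, `max_excursion_bpm`,
#'   `rsa_amplitude_bpm`, `rsa_present`, `rule_version`.
#' @export
classify_flat <- function(tach, excursion_limit_bpm = 5, rsa_min_bpm = 1,
                          percentiles = c(0.005, 0.995)) {
  grid <- tachogram_grid(tach)
  q <- quantile(grid$hr_smooth_bpm, percentiles, names = FALSE)
  excursion <- q[2] - q[1]
  rsa_amp <- attr(tach, "rsa_amplitude_bpm")
  rsa_present <- rsa_amp >= rsa_min_bpm
  tibble::tibble(
    is_flat = excursion < excursion_limit_bpm && !rsa_present,
    max_excursion_bpm = excursion,
    rsa_amplitude_bpm = rsa_amp,
    rsa_present = rsa_present,
    rule_version = "robust-percentile-1"
  )
}
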