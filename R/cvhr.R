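#' Detect heart-rate arousals
#'
#' An arousal is a maximal contiguous span where the smoothed instantaneous
#' HR exceeds the local baseline by at least `min_delta_bpm` (default 6 bpm)
#' for at least `min_duration_s` (default 10 s).  The baseline is the
#' running lower quartile of the smoothed HR over a `baseline_window_s`
#' (default 120 s) centered window: the lower quartile tracks the
#' inter-arousal trough of the cyclic bradycardia/tachycardia pattern
#' without being dragged upward by the surges themselves.
#'
#' @param tach A `cvhr_tachogram` over the nocturnal window.
#' @param min_delta_bpm Minimum HR rise above baseline, bpm.
#' @param min_duration_s Minimum arousal duration, seconds.
#' @param baseline_window_s Window of the running lower-quartile baseline,
#'   seconds.
#' @param flat Optional pre-computed [classify_flat()] result; computed
#'   when `NULL`.  A flat tachogram cannot be scored for arousals and is an
#'   error here — callers should route flat patients to the
#'   `indeterminate_flat` status instead.
#' @return A tibble of disjoint, time-ordered arousals: `start_s`, `end_s`,
#'   `duration_s`, `delta_bpm` (peak rise above baseline).
#' @export
detect_arousals <- function(tach, min_delta_bpm = 6, min_duration_s = 10,
                            baseline_window_s = 120, flat = NULL) {
  if (is.null(flat)) flat <- classify_flat(tach)
  if (isTRUE(flat$is_flat)) {
    abort(paste0("flat tachogram for patient ", attr(tach, "patient_id"),
                 ": CVHR cannot be scored; classify as indeterminate_flat"))
  }
  grid <- tachogram_grid(tach)
  dt <- 1 / attr(tach, "grid_hz")
  bl <- rolling_lower_quartile(grid$time_s, grid$hr_smooth_bpm,
                               window_s = baseline_window_s)
  above <- grid$hr_smooth_bpm >= bl + min_delta_bpm
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths * dt >= min_duration_s
  if (!any(keep)) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric(),
                          duration_s = numeric(), delta_bpm = numeric()))
  }
  i0 <- starts[keep]
  i1 <- ends[keep]
  tibble::tibble(
    start_s = grid$time_s[i0],
    end_s = grid$time_s[i0] + (i1 - i0 + 1) * dt,
    duration_s = (i1 - i0 + 1) * dt,
    delta_bpm = purrr::map2_dbl(i0, i1, function(a, b) {
      max(grid$hr_smooth_bpm[a:b] - bl[a:b])
    })
  )
}

# Running lower quartile over a centered time window, evaluated on a 1-s
# decimated grid and interpolated back (the quartile of a 2 Hz series over
# two minutes is insensitive to 1-s decimation).
rolling_lower_quartile <- function(time_s, x, window_s = 120) {
  step <- max(1L, as.integer(round(1 / median(diff(time_s)))))
  idx <- seq(1L, length(x), by = step)
  w <- as.integer(round(window_s / (time_s[idx[2]] - time_s[idx[1]]))) + 1L
  w <- min(w, length(idx))
  sub <- zoo::rollapply(x[idx], width = w,
                        FUN = quantile, probs = 0.25, names = FALSE,
                        partial = TRUE, align = "center")
  approx(time_s[idx], sub, xout = time_s, rule = 2)$y
}

#' Assemble arousals into CVHR episodes
#'
#' Cyclic variation of heart rate requires at least `min_arousals`
#' successive arousals (default 3) with no more than `max_gap_s` (default
#' 120 s) between the end of one arousal and the start of the next.
#' Arousals are greedily chained under the gap rule; chains shorter than
#' the minimum are discarded.  An episode spans from the onset of its first
#' arousal to the end of its last, so the bradycardic apnea phases between
#' arousals count as CVHR time.
#'
#' @param arousals Time-ordered arousal tibble from [detect_arousals()].
#' @param max_gap_s Maximum gap between successive arousals, seconds.
#' @param min_arousals Minimum number of chained arousals per episode.
#' @return A tibble of episodes: `start_s`, `end_s`, `n_arousals`,
#'   `duration_min`.
#' @export
assemble_episodes <- function(arousals, max_gap_s = 120, min_arousals = 3) {
  empty <- tibble::tibble(start_s = numeric(), end_s = numeric(),
                          n_arousals = integer(), duration_min = numeric())
  if (is.null(arousals) || nrow(arousals) == 0) return(empty)
  if (is.unsorted(arousals$start_s)) abort("arousals must be time-ordered")
  gap <- arousals$start_s - dplyr::lag(arousals$end_s)
  chain <- cumsum(dplyr::coalesce(gap > max_gap_s, TRUE))
  arousals |>
    dplyr::mutate(.chain = chain) |>
    dplyr::summarise(
      start_s = min(.data$start_s),
      end_s = max(.data$end_s),
      n_arousals = dplyr::n(),
      .by = ".chain"
    ) |>
    dplyr::filter(.data$n_arousals >= min_arousals) |>
    dplyr::mutate(duration_min = (.data$end_s - .data$start_s) / 60) |>
    dplyr::select(-".chain")
}

#' Total CVHR duration
#'
#' @param episodes Episode tibble from [assemble_episodes()]; must be
#'   disjoint.
#' @return Total minutes with CVHR (0 for no episodes).
#' @export
quantify_cvhr <- function(episodes) {
  if (is.null(episodes) || nrow(episodes) == 0) return(0)
  ord <- order(episodes$start_s)
  s <- episodes$start_s[ord]
  e <- episodes$end_s[ord]
  if (any(s[-1] < e[-length(e)])) abort("overlapping CVHR episodes")
  sum(episodes$duration_min)
}

#' Classify sleep-disordered breathing from CVHR duration
#'
#' SDB is assumed when CVHR is present during at least `sdb_fraction`
#' (default 20%) of the scored segment — 72 min of the nocturnal 6-h
#' segment.  In a patient with a flat tachogram no information on SDB can
#' be obtained from the ECG, so the status is `indeterminate_flat`
#' regardless of any CVHR value.
#'
#' @param cvhr_minutes Minutes with CVHR.
#' @param is_flat Logical; flat nocturnal tachogram.
#' @param segment_min Scored segment length in minutes (default 360).
#' @param sdb_fraction Fraction of the segment that must show CVHR.
#' @return One of `"present"`, `"absent"`, `"indeterminate_flat"`
#'   (vectorized over the first two arguments).
#' @export
classify_sdb <- function(cvhr_minutes, is_flat, segment_min = 360,
                         sdb_fraction = 0.20) {
  stopifnot(segment_min > 0)
  if (any(!is.na(cvhr_minutes) & cvhr_minutes > segment_min)) {
    abort("cvhr_minutes exceeds segment length")
  }
  cutoff <- sdb_fraction * segment_min
  dplyr::case_when(
    is_flat ~ "indeterminate_flat",
    cvhr_minutes >= cutoff ~ "present",
    .default = "absent"
  )
}

#' Score a nocturnal tachogram for CVHR
#'
#' Convenience wrapper running flat classification and, when the tachogram
#' is not flat, the arousal/episode/minutes chain and the SDB call.
#'
#' @param tach A `cvhr_tachogram` over the nocturnal window.
#' @param min_delta_bpm,min_duration_s,baseline_window_s Passed to
#'   [detect_arousals()].
#' @param max_gap_s,min_arousals Passed to [assemble_episodes()].
#' @param segment_min,sdb_fraction Passed to [classify_sdb()].
#' @param excursion_limit_bpm,rsa_min_bpm Passed to [classify_flat()].
#' @return A list with elements `flat` (one-row tibble), `arousals`,
#'   `episodes`, `cvhr_minutes`, `sdb_status`.
#' @export
score_cvhr <- function(tach, min_delta_bpm = 6, min_duration_s = 10,
                       baseline_window_s = 120, max_gap_s = 120,
                       min_arousals = 3, segment_min = 360,
                       sdb_fraction = 0.20, excursion_limit_bpm = 5,
                       rsa_min_bpm = 1) {
  flat <- classify_flat(tach, excursion_limit_bpm = excursion_limit_bpm,
                        rsa_min_bpm = rsa_min_bpm)
  if (flat$is_flat) {
    return(list(flat = flat, arousals = NULL, episodes = NULL,
                cvhr_minutes = NA_real_,
                sdb_status = "indeterminate_flat"))
  }
  arousals <- detect_arousals(tach, min_delta_bpm = min_delta_bpm,
                              min_duration_s = min_duration_s,
                              baseline_window_s = baseline_window_s,
                              flat = flat)
  episodes <- assemble_episodes(arousals, max_gap_s = max_gap_s,
                                min_arousals = min_arousals)
  minutes <- quantify_cvhr(episodes)
  list(flat = flat, arousals = arousals, episodes = episodes,
       cvhr_minutes = minutes,
       sdb_status = classify_sdb(minutes, FALSE, segment_min = segment_min,
                                 sdb_fraction = sdb_fraction))
}
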