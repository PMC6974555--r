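#' Time-domain heart-rate variability
#'
#' Classical time-domain HRV over the NN intervals of a recording:
#' * `sdnn_ms` — sample SD of all NN intervals;
#' * `sdann_ms` — sample SD of the mean NN per 5-min segment (undefined
#'   with fewer than two usable segments);
#' * `rmssd_ms` — root mean square of successive NN differences (taken
#'   within contiguous NN runs only, never across a gap);
#' * `hrv_ti` — HRV triangular index, total NN count divided by the height
#'   of the modal bin of the NN histogram at 1/128 s bin width.
#'
#' Insufficient data yields `NA` for the affected metric, never a silent
#' zero.
#'
#' @param nn An NN-filtered [beat_series()].
#' @param segment_s SDANN segment length, seconds.
#' @param min_segment_coverage Minimum fraction of a segment that must be
#'   covered by NN time for that segment to enter SDANN.
#' @param ti_bin_s Triangular-index histogram bin width, seconds (Task
#'   Force convention 1/128 s).
#' @return A one-row tibble: `sdnn_ms`, `sdann_ms`, `rmssd_ms`, `hrv_ti`,
#'   `n_nn`.
#' @export
hrv_time_domain <- function(nn, segment_s = 300, min_segment_coverage = 0.5,
                            ti_bin_s = 1 / 128) {
  rr <- nn$rr_ms
  n <- length(rr)
  sdnn <- if (n >= 2) sd(rr) else NA_real_

  rmssd <- NA_real_
  if (n >= 2) {
    d <- successive_nn_diffs(nn)
    if (length(d)) rmssd <- sqrt(mean(d^2))
  }

  sdann <- NA_real_
  if (n >= 2) {
    seg <- floor((nn$time_s - nn$time_s[1]) / segment_s)
    seg_stats <- tibble::tibble(seg = seg, rr = rr) |>
      dplyr::summarise(mean_rr = mean(.data$rr),
                       nn_time = sum(.data$rr) / 1000, .by = "seg") |>
      dplyr::filter(.data$nn_time >= min_segment_coverage * segment_s)
    if (nrow(seg_stats) >= 2) sdann <- sd(seg_stats$mean_rr)
  }

  ti <- NA_real_
  if (n >= 1) {
    bin <- floor(rr / (ti_bin_s * 1000))
    ti <- n / max(table(bin))
  }

  tibble::tibble(sdnn_ms = sdnn, sdann_ms = sdann, rmssd_ms = rmssd,
                 hrv_ti = ti, n_nn = n)
}

# Differences between adjacent NN intervals, within contiguous runs only
# (a gap is elapsed time exceeding the RR by > 1 ms).
successive_nn_diffs <- function(nn, gap_tol_ms = 1) {
  if (nrow(nn) < 2) return(numeric())
  dt_ms <- diff(nn$time_s) * 1000
  contiguous <- dt_ms <= nn$rr_ms[-1] + gap_tol_ms
  diff(nn$rr_ms)[contiguous]
}

# Split an NN series into contiguous stretches, breaking at gaps larger
# than max_gap_s between successive beats.
nn_stretches <- function(nn, max_gap_s = 20) {
  if (nrow(nn) == 0) return(list())
  brk <- c(FALSE, diff(nn$time_s) > max_gap_s)
  ids <- cumsum(brk)
  unname(split(seq_len(nrow(nn)), ids))
}

#' Frequency-domain heart-rate variability
#'
#' Spectral band powers of the NN-interval series.  The NN tachogram is
#' split into contiguous stretches (gaps over `max_gap_s` excluded), each
#' stretch is evenly resampled at `resample_hz` by cubic interpolation,
#' high-pass detrended (a running-mean trend of ~1/0.003 Hz is removed),
#' and the power spectral density estimated by Welch's method (averaged
#' Hann-windowed periodograms, 50% overlap).  Band powers are integrated
#' over VLF 0.0033–0.04 Hz, LF 0.04–0.15 Hz and HF 0.15–0.40 Hz; total
#' power is their sum (0.0033–0.40 Hz).  Stretch band powers are averaged
#' weighted by stretch duration.
#'
#' @param nn An NN-filtered [beat_series()] with at least `min_stretch_s`
#'   of contiguous data.
#' @param resample_hz Even-resampling rate, Hz.
#' @param max_gap_s Gap threshold splitting the series into stretches,
#'   seconds.
#' @param min_stretch_s Minimum analyzable stretch, seconds.
#' @param seg_len_s Welch segment length, seconds (sets the frequency
#'   resolution, 1/300 s ~ 0.0033 Hz).
#' @param bands Named list of band edges in Hz.
#' @return A one-row tibble: `tp_ms2`, `vlf_ms2`, `lf_ms2`, `hf_ms2`,
#'   `n_stretches`, `analyzed_s` (all-`NA` band powers when no stretch is
#'   long enough).
#' @export
hrv_frequency_domain <- function(nn, resample_hz = 4, max_gap_s = 20,
                                 min_stretch_s = 300, seg_len_s = 300,
                                 bands = list(vlf = c(0.0033, 0.04),
                                              lf = c(0.04, 0.15),
                                              hf = c(0.15, 0.40))) {
  stretches <- nn_stretches(nn, max_gap_s = max_gap_s)
  powers <- list()
  weights <- numeric()
  for (idx in stretches) {
    t <- nn$time_s[idx]
    if (length(idx) < 8) next
    span <- t[length(t)] - t[1]
    if (span < min_stretch_s) next
    grid_t <- seq(t[1], t[length(t)], by = 1 / resample_hz)
    rr <- spline(t, nn$rr_ms[idx], xout = grid_t)$y
    rr <- detrend_highpass(rr, fs = resample_hz, cutoff_hz = 0.003)
    psd <- welch_psd(rr, fs = resample_hz, seg_len_s = seg_len_s)
    bp <- vapply(bands, function(b) {
      sum(psd$psd[psd$freq >= b[1] & psd$freq < b[2]]) * psd$df
    }, numeric(1))
    powers[[length(powers) + 1]] <- bp
    weights <- c(weights, span)
  }
  if (!length(powers)) {
    return(tibble::tibble(tp_ms2 = NA_real_, vlf_ms2 = NA_real_,
                          lf_ms2 = NA_real_, hf_ms2 = NA_real_,
                          n_stretches = 0L, analyzed_s = 0))
  }
  m <- do.call(rbind, powers)
  bp <- colSums(m * weights / sum(weights))
  tibble::tibble(tp_ms2 = sum(bp), vlf_ms2 = bp[["vlf"]],
                 lf_ms2 = bp[["lf"]], hf_ms2 = bp[["hf"]],
                 n_stretches = length(weights), analyzed_s = sum(weights))
}

# Remove the slow trend: subtract a centered running mean of width
# 1/cutoff_hz (shrinking at the ends), i.e. a crude high-pass at cutoff_hz.
detrend_highpass <- function(x, fs, cutoff_hz = 0.003) {
  w <- as.integer(round(fs / cutoff_hz))
  if (w %% 2 == 0) w <- w + 1L
  if (w >= length(x)) return(x - mean(x))
  x - zoo::rollmean(x, w, fill = "extend")
}

# Welch power spectral density: averaged Hann-windowed periodograms with
# 50% overlap, one-sided, scaled so that sum(psd) * df equals the variance
# of the (windowed) signal.
welch_psd <- function(x, fs, seg_len_s = 300, overlap = 0.5) {
  n <- length(x)
  nper <- min(n, as.integer(round(seg_len_s * fs)))
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nper - 1) / (nper - 1)))
  u <- mean(w^2)
  step <- max(1L, as.integer(floor(nper * (1 - overlap))))
  starts <- seq(1L, n - nper + 1L, by = step)
  acc <- numeric(nper)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- seg - mean(seg)
    acc <- acc + Mod(fft(seg * w))^2 / (fs * nper * u)
  }
  p2 <- acc / length(starts)
  half <- nper %/% 2
  p1 <- p2[seq_len(half + 1)]
  # fold negative frequencies (DC and, for even nper, Nyquist are unique)
  if (nper %% 2 == 0) {
    if (half >= 2) p1[2:half] <- 2 * p1[2:half]
  } else {
    p1[2:(half + 1)] <- 2 * p1[2:(half + 1)]
  }
  df <- fs / nper
  list(freq = (0:half) * df, psd = p1, df = df)
}

#' Full HRV metric panel
#'
#' Binds [hrv_time_domain()] and [hrv_frequency_domain()] into the one-row
#' panel used by the risk table.
#'
#' @param nn An NN-filtered [beat_series()].
#' @param ... Passed to the two component functions where names match.
#' @return A one-row tibble with the eight HRV metrics.
#' @export
hrv_metrics <- function(nn, ...) {
  args <- list(...)
  td_args <- args[names(args) %in% names(formals(hrv_time_domain))]
  fd_args <- args[names(args) %in% names(formals(hrv_frequency_domain))]
  dplyr::bind_cols(
    do.call(hrv_time_domain, c(list(nn), td_args)),
    do.call(hrv_frequency_domain, c(list(nn), fd_args)) |>
      dplyr::select(-"n_stretches", -"analyzed_s")
  )
}
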