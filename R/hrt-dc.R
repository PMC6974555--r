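#' Heart rate turbulence
#'
#' Turbulence onset (TO) and slope (TS) of the sinus response to
#' ventricular premature complexes (VPCs), per the standard definitions:
#' a valid VPC has a coupling interval shorter than `coupling_max` (default
#' 80%) of the local reference NN, a compensatory pause longer than
#' `pause_min` (default 120%) of it, at least two NN intervals before the
#' coupling interval, 15 NN intervals after the pause, and all context NN
#' within the physiologic `nn_range`.  TO is the percentage change of the
#' two NN intervals after versus before the VPC, averaged over valid VPCs;
#' TS is the steepest least-squares slope over any 5 consecutive intervals
#' of the post-pause NN sequence, taken on the VPC-averaged tachogram.
#' Abnormal HRT is TS <= 2.5 ms/RR together with TO >= 0%.
#'
#' @param series A labeled [beat_series()] (full recording, ectopics
#'   included).
#' @param coupling_max,pause_min VPC validity bounds relative to the
#'   reference NN.
#' @param nn_range Physiologic NN range in ms.
#' @param ref_beats Number of preceding NN intervals averaged into the
#'   reference.
#' @param min_vpc Minimum number of valid VPCs for a defined result.
#' @param to_abnormal,ts_abnormal Abnormality thresholds for TO (%) and TS
#'   (ms/RR).
#' @return One-row tibble: `turbulence_onset_pct`,
#'   `turbulence_slope_ms_per_rr`, `n_valid_vpc`, `hrt_abnormal`.  With no
#'   valid VPC the metrics and `hrt_abnormal` are `NA` (the patient leaves
#'   the SAF denominator rather than defaulting).
#' @export
compute_hrt <- function(series, coupling_max = 0.8, pause_min = 1.2,
                        nn_range = c(300, 2000), ref_beats = 5,
                        min_vpc = 1, to_abnormal = 0, ts_abnormal = 2.5) {
  validate_beat_series(series)
  lab <- series$label
  rr <- series$rr_ms
  n <- length(rr)
  undefined <- tibble::tibble(turbulence_onset_pct = NA_real_,
                              turbulence_slope_ms_per_rr = NA_real_,
                              n_valid_vpc = 0L, hrt_abnormal = NA)
  v_idx <- which(lab == "V")
  v_idx <- v_idx[v_idx >= 4 & v_idx <= n - 16]
  if (!length(v_idx)) return(undefined)

  to_list <- numeric()
  post_list <- list()
  for (i in v_idx) {
    # pre context: RR-1, RR-2 must be NN (beats i-3..i-1 all N)
    if (!all(lab[(i - 3):(i - 1)] == "N")) next
    # post context: pause ends at i+1; RR+1..RR+15 need beats i+1..i+16 N
    if (!all(lab[(i + 1):(i + 16)] == "N")) next
    pre_nn <- rr[(i - 2):(i - 1)]
    post_nn <- rr[(i + 2):(i + 16)]
    if (any(c(pre_nn, post_nn) < nn_range[1]) ||
        any(c(pre_nn, post_nn) > nn_range[2])) next
    # reference: mean of up to ref_beats NN intervals before the VPC
    ref_lo <- max(2, i - ref_beats)
    ref_ok <- (ref_lo:(i - 1))[lab[ref_lo:(i - 1)] == "N" &
                               lab[ref_lo:(i - 1) - 1] == "N"]
    if (length(ref_ok) < 2) next
    ref <- mean(rr[ref_ok])
    if (!(rr[i] < coupling_max * ref && rr[i + 1] > pause_min * ref)) next
    to_list <- c(to_list,
                 100 * (sum(post_nn[1:2]) - sum(pre_nn)) / sum(pre_nn))
    post_list[[length(post_list) + 1]] <- post_nn
  }
  if (length(to_list) < min_vpc) return(undefined)

  to <- mean(to_list)
  avg_tach <- colMeans(do.call(rbind, post_list))
  slopes <- vapply(1:11, function(k) {
    y <- avg_tach[k:(k + 4)]
    unname(coef(lm(y ~ seq_along(y)))[2])
  }, numeric(1))
  ts <- max(slopes)
  tibble::tibble(
    turbulence_onset_pct = to,
    turbulence_slope_ms_per_rr = ts,
    n_valid_vpc = length(to_list),
    hrt_abnormal = ts <= ts_abnormal && to >= to_abnormal
  )
}

#' Deceleration capacity by phase-rectified signal averaging
#'
#' Anchors are NN intervals longer than their predecessor by less than
#' `prolongation_limit` (default 5%); windows of `half_width` beats around
#' each anchor are aligned and averaged into `X(k)`, and
#' `DC = (X(0) + X(1) - X(-1) - X(-2)) / 4`.  Anchors are taken only within
#' contiguous NN runs with the full window available.  Low DC (<= 4.5 ms)
#' indicates impaired vagal modulation.  `direction = "acceleration"`
#' computes the mirrored acceleration-sided quantity (anchors shorter than
#' their predecessor), used as a symmetry check, not as a risk output.
#'
#' @param nn An NN-filtered [beat_series()].
#' @param prolongation_limit Maximum relative prolongation (shortening) at
#'   an anchor.
#' @param half_width Beats averaged on each side of the anchor.
#' @param min_anchors Minimum anchors for a defined result.
#' @param dc_abnormal Abnormality threshold, ms.
#' @param direction `"deceleration"` (default) or `"acceleration"`.
#' @return One-row tibble: `dc_ms`, `n_anchors`, `dc_abnormal` (all `NA`
#'   when fewer than `min_anchors` anchors exist, e.g. a constant series).
#' @export
compute_dc <- function(nn, prolongation_limit = 0.05, half_width = 20,
                       min_anchors = 100, dc_abnormal = 4.5,
                       direction = c("deceleration", "acceleration")) {
  direction <- match.arg(direction)
  validate_beat_series(nn)
  undefined <- tibble::tibble(dc_ms = NA_real_, n_anchors = 0L,
                              dc_abnormal = NA)
  runs <- nn_contiguous_runs(nn)
  segs <- list()
  for (idx in runs) {
    rr <- nn$rr_ms[idx]
    m <- length(rr)
    if (m < 2 * half_width + 1) next
    i <- seq(2L, m)
    anchors <- if (direction == "deceleration") {
      i[rr[i] > rr[i - 1] & rr[i] < (1 + prolongation_limit) * rr[i - 1]]
    } else {
      i[rr[i] < rr[i - 1] & rr[i] > rr[i - 1] / (1 + prolongation_limit)]
    }
    anchors <- anchors[anchors - half_width >= 1 &
                       anchors + half_width - 1 <= m]
    for (a in anchors) {
      segs[[length(segs) + 1]] <- rr[(a - half_width):(a + half_width - 1)]
    }
  }
  if (length(segs) < min_anchors) return(undefined)
  x <- colMeans(do.call(rbind, segs))
  k0 <- half_width + 1L  # index of X(0)
  dc <- (x[k0] + x[k0 + 1] - x[k0 - 1] - x[k0 - 2]) / 4
  tibble::tibble(dc_ms = dc, n_anchors = length(segs),
                 dc_abnormal = if (direction == "deceleration")
                   dc <= dc_abnormal else NA)
}

# Beat-contiguous runs: a break is elapsed time exceeding the RR interval,
# i.e. at least one beat was removed between the two rows.
nn_contiguous_runs <- function(nn, gap_tol_ms = 1) {
  if (nrow(nn) == 0) return(list())
  dt_ms <- c(0, diff(nn$time_s) * 1000)
  brk <- c(FALSE, dt_ms[-1] > nn$rr_ms[-1] + gap_tol_ms)
  unname(split(seq_len(nrow(nn)), cumsum(brk)))
}

#' Severe autonomic failure
#'
#' SAF is the conjunction of abnormal heart rate turbulence (TS <= 2.5
#' ms/RR and TO >= 0%) and abnormal deceleration capacity (DC <= 4.5 ms).
#' If either component is undefined, SAF is undefined.
#'
#' @param hrt One-row tibble from [compute_hrt()].
#' @param dc One-row tibble from [compute_dc()].
#' @return One-row tibble: `saf`, `hrt_abnormal`, `dc_abnormal`.
#' @export
classify_saf <- function(hrt, dc) {
  h <- hrt$hrt_abnormal[1]
  d <- dc$dc_abnormal[1]
  tibble::tibble(
    saf = if (is.na(h) || is.na(d)) NA else h && d,
    hrt_abnormal = h,
    dc_abnormal = d
  )
}
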