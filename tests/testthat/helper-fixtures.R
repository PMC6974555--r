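# Build a beat series from an RR sequence (ms); times are the cumulative
# sums, so the RR/time consistency invariant holds by construction.
series_from_rr <- function(rr_ms, labels = NULL, clock_start = 0,
                           patient_id = "fixture") {
  labels <- labels %||% rep("N", length(rr_ms))
  beat_series(time_s = cumsum(rr_ms) / 1000, rr_ms = rr_ms, label = labels,
              patient_id = patient_id, clock_start = clock_start)
}

# Build a beat series whose instantaneous HR follows hr_fun(t) (bpm);
# beats are laid down sequentially as in the generator.
series_from_hr <- function(hr_fun, duration_s, clock_start = 0,
                           patient_id = "fixture") {
  times <- numeric(0)
  rrs <- numeric(0)
  t <- 0
  repeat {
    rr_s <- 60 / hr_fun(t)
    t <- t + rr_s
    if (t > duration_s) break
    times <- c(times, t)
    rrs <- c(rrs, rr_s * 1000)
  }
  beat_series(time_s = times, rr_ms = rrs, label = rep("N", length(times)),
              patient_id = patient_id, clock_start = clock_start)
}

# HR profile with plateaus: list of c(start, end, level); base elsewhere.
hr_plateaus <- function(base, plateaus) {
  function(t) {
    for (p in plateaus) {
      if (t >= p[1] && t < p[2]) return(p[3])
    }
    base
  }
}

# A ventricular premature complex embedded in sinus rhythm: n_pre sinus
# beats at ref ms, the VPC (coupling), the compensatory pause, then the
# post sequence (ms).
series_with_vpc <- function(ref = 800, n_pre = 6, coupling = 500,
                            pause = 1100, post = rep(780, 16)) {
  rr <- c(rep(ref, n_pre), coupling, pause, post)
  labels <- c(rep("N", n_pre), "V", rep("N", 1 + length(post)))
  series_from_rr(rr, labels)
}

`%||%` <- rlang::`%||%`
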