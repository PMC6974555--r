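#' Specification of a synthetic nocturnal tachogram
#'
#' Describes the generative model of a synthetic nocturnal RR series:
#' instantaneous HR is a base rate plus a slow drift, a respiratory-sinus-
#' arrhythmia sinusoid (~0.25 Hz), planted apnea-arousal episode waveforms,
#' and Gaussian beat-level noise; RR = 60000 / HR.  Each episode cycle dips
#' by half the surge amplitude during the "apnea" phase and then surges
#' above baseline for the arousal.  Planted episodes satisfy the CVHR
#' scoring rules by construction (at least 3 cycles, surge >= 6 bpm for
#' >= 10 s, inter-surge gaps <= 120 s).  `flat_mode` forces zero RSA, no
#' episodes, and total drift under 5 bpm, so the result meets the flat-
#' tachogram definition by construction.
#'
#' @param duration_s Recording length, seconds (default the 6-h nocturnal
#'   window).
#' @param base_hr_bpm Baseline heart rate, bpm.
#' @param rsa_amplitude_bpm RSA sinusoid amplitude, bpm.
#' @param rsa_freq_hz RSA frequency, Hz.
#' @param noise_sd_bpm Beat-level Gaussian HR noise SD, bpm.
#' @param drift_bpm Peak-to-trough slow drift (1-h period sinusoid), bpm.
#' @param flat_mode Logical; construct a flat tachogram.
#' @param episodes Episode table with columns `start_s`, `n_cycles`,
#'   `cycle_period_s`, `surge_bpm`, `surge_dur_s` (see [plant_episodes()]).
#' @param vpc_rate Per-beat probability of replacing a sinus beat by a
#'   ventricular premature complex (short coupling, long pause); used to
#'   exercise the turbulence stage.
#' @param clock_start Recording clock start (seconds from midnight or
#'   `"HH:MM:SS"`); the default places the recording exactly on the
#'   nocturnal window.
#' @param patient_id Identifier for the generated series.
#' @return A `tachogram_spec` list.
#' @export
tachogram_spec <- function(duration_s = 21600, base_hr_bpm = 60,
                           rsa_amplitude_bpm = 2, rsa_freq_hz = 0.25,
                           noise_sd_bpm = 0.5, drift_bpm = 2,
                           flat_mode = FALSE, episodes = NULL,
                           vpc_rate = 0, clock_start = 0,
                           patient_id = "synthetic") {
  if (flat_mode) {
    rsa_amplitude_bpm <- 0
    episodes <- NULL
    drift_bpm <- min(drift_bpm, 3)
  }
  if (!is.null(episodes) && nrow(episodes)) {
    episodes <- tibble::as_tibble(episodes)
    need <- c("start_s", "n_cycles", "cycle_period_s", "surge_bpm",
              "surge_dur_s")
    stopifnot(all(need %in% names(episodes)))
    with(episodes, {
      stopifnot(all(n_cycles >= 3), all(surge_bpm >= 6),
                all(surge_dur_s >= 10),
                all(cycle_period_s - surge_dur_s <= 120),
                all(cycle_period_s > surge_dur_s))
    })
    span <- episodes$start_s + episodes$n_cycles * episodes$cycle_period_s
    if (any(span > duration_s)) abort("episode extends past the recording")
    ord <- order(episodes$start_s)
    if (any(episodes$start_s[ord][-1] < span[ord][-length(span)])) {
      abort("episodes overlap")
    }
  }
  stopifnot(duration_s > 0, base_hr_bpm > 20, noise_sd_bpm >= 0)
  structure(list(duration_s = duration_s, base_hr_bpm = base_hr_bpm,
                 rsa_amplitude_bpm = rsa_amplitude_bpm,
                 rsa_freq_hz = rsa_freq_hz, noise_sd_bpm = noise_sd_bpm,
                 drift_bpm = drift_bpm, flat_mode = flat_mode,
                 episodes = episodes, vpc_rate = vpc_rate,
                 clock_start_s = parse_clock(clock_start),
                 patient_id = patient_id),
            class = "tachogram_spec")
}

#' Evenly spaced episode table for [tachogram_spec()]
#'
#' @param n_episodes Number of episodes.
#' @param duration_s Recording length the episodes must fit in.
#' @param n_cycles Apnea-arousal cycles per episode.
#' @param cycle_period_s Cycle period, seconds (~45 s is typical of
#'   obstructive apnea).
#' @param surge_bpm Arousal surge amplitude above baseline, bpm.
#' @param surge_dur_s Arousal surge duration, seconds.
#' @param margin_s Episode-free margin at both ends of the recording.
#' @return Episode tibble; deterministic (no randomness).
#' @export
plant_episodes <- function(n_episodes, duration_s = 21600, n_cycles = 8,
                           cycle_period_s = 45, surge_bpm = 8,
                           surge_dur_s = 15, margin_s = 300) {
  if (n_episodes == 0) return(NULL)
  span <- n_cycles * cycle_period_s
  usable <- duration_s - 2 * margin_s - span
  if (usable < 0) abort("episodes do not fit in the recording")
  starts <- if (n_episodes == 1) {
    margin_s + usable / 2
  } else {
    gap_needed <- (usable - (n_episodes - 1) * span) / (n_episodes - 1)
    if (gap_needed <= 125) {
      abort("too many episodes: inter-episode gap would merge them")
    }
    margin_s + (0:(n_episodes - 1)) * (span + gap_needed)
  }
  tibble::tibble(start_s = starts, n_cycles = n_cycles,
                 cycle_period_s = cycle_period_s, surge_bpm = surge_bpm,
                 surge_dur_s = surge_dur_s)
}

# Episode waveform at times t (vector), in bpm relative to base HR.
# One cycle: apnea dip of -surge/2, cosine-free linear ramps of ramp_s,
# surge plateau, ramp back down at the cycle end.
episode_waveform <- function(t, episodes, ramp_s = 3) {
  out <- numeric(length(t))
  if (is.null(episodes) || !nrow(episodes)) return(out)
  for (j in seq_len(nrow(episodes))) {
    ep <- episodes[j, ]
    period <- ep$cycle_period_s
    a <- period - ep$surge_dur_s  # apnea phase length
    s <- ep$surge_bpm
    span <- ep$n_cycles * period
    sel <- t >= ep$start_s & t < ep$start_s + span
    if (!any(sel)) next
    pos <- (t[sel] - ep$start_s) %% period
    kx <- c(0, a - ramp_s, a, period - ramp_s, period)
    ky <- c(-s / 2, -s / 2, s, s, -s / 2)
    out[sel] <- out[sel] + approx(kx, ky, xout = pos, rule = 2)$y
  }
  out
}

# Ground-truth arousal surge intervals of one planted episode table.
episode_truth <- function(episodes) {
  if (is.null(episodes) || !nrow(episodes)) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric(),
                          n_arousals = integer(), duration_min = numeric()))
  }
  a <- episodes$cycle_period_s - episodes$surge_dur_s
  start <- episodes$start_s + a
  end <- episodes$start_s + episodes$n_cycles * episodes$cycle_period_s
  tibble::tibble(start_s = start, end_s = end,
                 n_arousals = as.integer(episodes$n_cycles),
                 duration_min = (end - start) / 60)
}

#' Simulate a beat-annotated RR series from a tachogram specification
#'
#' Beats are generated sequentially: at each beat time the clean HR (base +
#' drift + RSA + episode waveform) is perturbed by Gaussian noise, the RR
#' is `60000 / HR`, and the next beat falls one RR later — so the series
#' satisfies the RR/time consistency invariant by construction.  With
#' `vpc_rate > 0`, occasional beats become ventricular premature complexes
#' with a 65% coupling interval and a 135% compensatory pause.
#'
#' @param spec A [tachogram_spec()].
#' @param seed Integer seed; the caller's RNG state is restored.
#' @return A [beat_series()] with attribute `truth`: a list with `flat`
#'   (logical) and `episodes` (ground-truth episode spans, first surge
#'   onset to last surge end).
#' @export
simulate_tachogram <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "tachogram_spec"))
  with_seed(seed, {
    dt <- 0.5
    grid_t <- seq(0, spec$duration_s, by = dt)
    phase_rsa <- runif(1, 0, 2 * pi)
    phase_drift <- runif(1, 0, 2 * pi)
    drift_period <- min(3600, spec$duration_s)  # full swing realized
    hr_clean <- spec$base_hr_bpm +
      (spec$drift_bpm / 2) * sin(2 * pi * grid_t / drift_period +
                                 phase_drift) +
      spec$rsa_amplitude_bpm * sin(2 * pi * spec$rsa_freq_hz * grid_t +
                                   phase_rsa) +
      episode_waveform(grid_t, spec$episodes)

    n_max <- as.integer(spec$duration_s / 0.25)
    times <- numeric(n_max)
    rrs <- numeric(n_max)
    labs <- character(n_max)
    t <- 0
    k <- 0L
    pend_pause <- FALSE
    while (TRUE) {
      hr <- hr_clean[min(length(hr_clean), floor(t / dt) + 1L)] +
        rnorm(1, 0, spec$noise_sd_bpm)
      hr <- max(hr, 25)
      rr_s <- 60 / hr
      lab <- "N"
      if (pend_pause) {
        rr_s <- rr_s * 1.35
        pend_pause <- FALSE
      } else if (spec$vpc_rate > 0 && runif(1) < spec$vpc_rate) {
        rr_s <- rr_s * 0.65
        lab <- "V"
        pend_pause <- TRUE
      }
      t <- t + rr_s
      if (t > spec$duration_s) break
      k <- k + 1L
      times[k] <- t
      rrs[k] <- rr_s * 1000
      labs[k] <- lab
    }
    series <- new_beat_series(
      tibble::tibble(time_s = times[seq_len(k)], rr_ms = rrs[seq_len(k)],
                     label = labs[seq_len(k)]),
      patient_id = spec$patient_id, clock_start_s = spec$clock_start_s
    )
    attr(series, "truth") <- list(flat = spec$flat_mode,
                                  episodes = episode_truth(spec$episodes))
    series
  })
}

#' Ground truth of a simulated series
#'
#' @param series Output of [simulate_tachogram()].
#' @return The `truth` list (`flat`, `episodes`).
#' @export
simulation_truth <- function(series) attr(series, "truth")

#' Specification of a synthetic post-MI cohort
#'
#' Parameterizes the statistical twin of a post-myocardial-infarction
#' Holter cohort: covariate distributions (medians/IQRs of age, LVEF and
#' GRACE score; prevalences of female sex and diabetes; nocturnal
#' respiratory rate), the flat-tachogram prevalence with its positive age
#' association, a two-component CVHR-minutes mixture populating both sides
#' of the 72-min cutpoint and the low (<= 19 min) tail, and a
#' proportional-hazards outcome model (exponential baseline, administrative
#' censoring at 5 years) whose covariate hazard ratios default to the
#' multivariable estimates the generator is meant to emulate.
#'
#' @param n Cohort size.
#' @param flat_prevalence Marginal probability of a flat tachogram.
#' @param hazard_ratios Named vector of per-covariate hazard ratios:
#'   `flat`, `age` (per year), `female`, `lvef` (per %), `grace` (per
#'   point), `diabetes`.
#' @param event_frac_5y Marginal 5-year event fraction the baseline hazard
#'   is calibrated to.
#' @param age_median,age_iqr,age_range Age distribution (years), normal
#'   from median/IQR, truncated to `age_range`.
#' @param female_p,diabetes_p Prevalences.
#' @param lvef_median,lvef_iqr,lvef_range LVEF distribution (%).
#' @param grace_median,grace_iqr,grace_range GRACE score distribution
#'   (points).
#' @param nrr_median,nrr_sdlog Nocturnal respiratory rate, lognormal
#'   (breaths/min).
#' @param sdb_p Probability that a non-flat patient's CVHR minutes come
#'   from the high (>= 72 min) mixture component.
#' @param cvhr_high_mean,cvhr_high_sd High component: normal, truncated to
#'   `[72, 360]` minutes.
#' @param cvhr_low_shape,cvhr_low_scale Low component: gamma, truncated to
#'   `[0, 72)` minutes.
#' @param flat_age_slope Log-odds of flat per year of age.
#' @param censor_years Administrative censoring horizon.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n = 1590, flat_prevalence = 0.048,
                        hazard_ratios = c(flat = 1.73, age = 1.06,
                                          female = 0.98, lvef = 0.95,
                                          grace = 1.004, diabetes = 1.66),
                        event_frac_5y = 0.1035,
                        age_median = 59.2, age_iqr = c(51.6, 66.8),
                        age_range = c(30, 80),
                        female_p = 0.206, diabetes_p = 0.17,
                        lvef_median = 55, lvef_iqr = c(45, 63),
                        lvef_range = c(15, 80),
                        grace_median = 96, grace_iqr = c(80, 113),
                        grace_range = c(40, 200),
                        nrr_median = 16.5, nrr_sdlog = 0.15,
                        sdb_p = 0.386,
                        cvhr_high_mean = 115, cvhr_high_sd = 30,
                        cvhr_low_shape = 1.5, cvhr_low_scale = 18,
                        flat_age_slope = 0.065, censor_years = 5) {
  stopifnot(n >= 2, flat_prevalence >= 0, flat_prevalence <= 1,
            event_frac_5y > 0, event_frac_5y < 1,
            female_p >= 0, female_p <= 1, diabetes_p >= 0, diabetes_p <= 1,
            sdb_p >= 0, sdb_p <= 1)
  need <- c("flat", "age", "female", "lvef", "grace", "diabetes")
  stopifnot(all(need %in% names(hazard_ratios)), all(hazard_ratios > 0))
  structure(as.list(environment()), class = "cohort_spec")
}

# sd implied by an IQR under normality
iqr_to_sd <- function(iqr) diff(iqr) / (2 * qnorm(0.75))

rnorm_trunc <- function(n, mean, sd, range) {
  p <- pnorm(range, mean, sd)
  qnorm(runif(n, p[1], p[2]), mean, sd)
}

#' Simulate a synthetic post-MI cohort
#'
#' Draws covariates per the [cohort_spec()], links flat-tachogram status to
#' age through a logistic model whose intercept is calibrated so the
#' marginal flat prevalence matches the spec, draws CVHR minutes for
#' non-flat patients from the two-component mixture, and generates 5-year
#' survival from an exponential proportional-hazards model whose baseline
#' rate is calibrated so the marginal event fraction matches the spec.
#' Covariates enter the linear predictor centered at their spec medians
#' (centering shifts only the baseline, not the hazard ratios).
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; same seed, same cohort.
#' @return A tibble with one row per patient: `id`, `age`, `female`,
#'   `lvef`, `grace`, `diabetes`, `nrr`, `flat`, `cvhr_minutes` (`NA` for
#'   flat patients), `sdb_status`, `time_years`, `event`.
#' @export
simulate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    n <- spec$n
    age <- rnorm_trunc(n, spec$age_median, iqr_to_sd(spec$age_iqr),
                       spec$age_range)
    female <- runif(n) < spec$female_p
    diabetes <- runif(n) < spec$diabetes_p
    lvef <- rnorm_trunc(n, spec$lvef_median, iqr_to_sd(spec$lvef_iqr),
                        spec$lvef_range)
    grace <- rnorm_trunc(n, spec$grace_median, iqr_to_sd(spec$grace_iqr),
                         spec$grace_range)
    nrr <- rlnorm(n, log(spec$nrr_median), spec$nrr_sdlog)

    # flat ~ age: logistic link, intercept calibrated to the marginal
    # prevalence over the drawn ages
    flat <- if (spec$flat_prevalence > 0) {
      ac <- age - spec$age_median
      a0 <- uniroot(function(a) {
        mean(plogis(a + spec$flat_age_slope * ac)) - spec$flat_prevalence
      }, c(-30, 10))$root
      runif(n) < plogis(a0 + spec$flat_age_slope * ac)
    } else {
      rep(FALSE, n)
    }

    cvhr_minutes <- rep(NA_real_, n)
    nf <- which(!flat)
    hi <- runif(length(nf)) < spec$sdb_p
    p_hi <- pnorm(c(72, 360), spec$cvhr_high_mean, spec$cvhr_high_sd)
    cvhr_minutes[nf[hi]] <- qnorm(
      runif(sum(hi), p_hi[1], p_hi[2]),
      spec$cvhr_high_mean, spec$cvhr_high_sd
    )
    p_lo <- pgamma(72, spec$cvhr_low_shape, scale = spec$cvhr_low_scale)
    cvhr_minutes[nf[!hi]] <- qgamma(
      runif(sum(!hi)) * p_lo,
      spec$cvhr_low_shape, scale = spec$cvhr_low_scale
    )

    b <- log(spec$hazard_ratios)
    lp <- b[["flat"]] * flat +
      b[["age"]] * (age - spec$age_median) +
      b[["female"]] * female +
      b[["lvef"]] * (lvef - spec$lvef_median) +
      b[["grace"]] * (grace - spec$grace_median) +
      b[["diabetes"]] * diabetes

    h <- spec$censor_years
    f <- function(l0) mean(1 - exp(-h * l0 * exp(lp))) - spec$event_frac_5y
    if (f(1e-9) > 0 || f(50) < 0) abort("infeasible event fraction")
    l0 <- uniroot(f, c(1e-9, 50), tol = 1e-12)$root

    tt <- rexp(n, rate = l0 * exp(lp))
    event <- tt <= h
    tibble::tibble(
      id = sprintf("S%04d", seq_len(n)),
      age = age, female = female, lvef = lvef, grace = grace,
      diabetes = diabetes, nrr = nrr, flat = flat,
      cvhr_minutes = cvhr_minutes,
      sdb_status = classify_sdb(cvhr_minutes, flat),
      time_years = pmin(tt, h), event = event
    )
  })
}

#' Simulate one survival group with a fixed 5-year event probability
#'
#' Event indicators are Bernoulli with the given probability; event times
#' are uniform on (0, 5] years and survivors are administratively censored
#' at 5 years.  Used to emulate a known group-level mortality rate.
#'
#' @param n Group size.
#' @param event_prob_5y Probability of death within the horizon.
#' @param censor_years Administrative censoring horizon.
#' @param seed Integer seed.
#' @return A tibble: `time_years`, `event`.
#' @export
simulate_survival_group <- function(n, event_prob_5y, censor_years = 5,
                                    seed = NULL) {
  stopifnot(n >= 1, event_prob_5y >= 0, event_prob_5y <= 1)
  with_seed(seed, {
    event <- runif(n) < event_prob_5y
    time <- ifelse(event, runif(n, 0, censor_years), censor_years)
    time <- pmax(time, 1e-6)
    tibble::tibble(time_years = time, event = event)
  })
}

#' Tachogram specification consistent with a cohort row
#'
#' Builds a [tachogram_spec()] matching a simulated patient's flat flag and
#' (approximately) their drawn CVHR minutes, by planting episodes of 8
#' cycles (5.5 min each) plus one remainder episode of at least 3 cycles.
#'
#' @param flat Logical; flat tachogram.
#' @param cvhr_minutes Target minutes with CVHR (ignored when flat).
#' @param duration_s Recording length, seconds.
#' @param patient_id Identifier.
#' @param ... Passed to [tachogram_spec()].
#' @return A `tachogram_spec`.
#' @export
patient_tachogram_spec <- function(flat, cvhr_minutes, duration_s = 21600,
                                   patient_id = "synthetic", ...) {
  if (isTRUE(flat)) {
    return(tachogram_spec(duration_s = duration_s, flat_mode = TRUE,
                          noise_sd_bpm = 0.3, patient_id = patient_id, ...))
  }
  cvhr_minutes <- if (is.na(cvhr_minutes)) 0 else cvhr_minutes
  period <- 45
  ep_min <- (7 * period + 15) / 60  # 8-cycle episode duration, minutes
  n_full <- floor(cvhr_minutes / ep_min)
  rem <- cvhr_minutes - n_full * ep_min
  cycles <- rep(8, n_full)
  if (rem >= 1.75) {
    cycles <- c(cycles, max(3, round((rem * 60 - 15) / period + 1)))
  }
  # cap to what fits in the night
  while (length(cycles) &&
         sum(cycles) * period + (length(cycles) + 1) * 150 > duration_s) {
    cycles <- cycles[-length(cycles)]
  }
  eps <- NULL
  if (length(cycles)) {
    span <- cycles * period
    gap <- (duration_s - sum(span)) / (length(cycles) + 1)
    starts <- cumsum(c(gap, head(span + gap, -1)))
    eps <- tibble::tibble(start_s = starts, n_cycles = cycles,
                          cycle_period_s = period, surge_bpm = 8,
                          surge_dur_s = 15)
  }
  tachogram_spec(duration_s = duration_s, episodes = eps,
                 patient_id = patient_id, ...)
}
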