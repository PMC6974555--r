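test_that("turbulence onset matches the two-before/two-after formula", {
  s <- series_with_vpc(ref = 800, coupling = 500, pause = 1100,
                       post = rep(780, 16))
  hrt <- compute_hrt(s)
  expect_equal(hrt$n_valid_vpc, 1L)
  # TO = 100 * ((780 + 780) - (800 + 800)) / (800 + 800) = -2.5 %
  expect_equal(hrt$turbulence_onset_pct, -2.5, tolerance = 1e-9)
})

test_that("turbulence slope on a linear post-pause ramp equals its step", {
  post <- 780 + 10 * (0:15)
  s <- series_with_vpc(post = post)
  hrt <- compute_hrt(s)
  expect_equal(hrt$turbulence_slope_ms_per_rr, 10, tolerance = 1e-9)
})

test_that("abnormal HRT is slope <= 2.5 with onset >= 0", {
  # flat post-pause sequence above the pre level: TO > 0, TS = 0
  s <- series_with_vpc(ref = 800, post = rep(810, 16))
  hrt <- compute_hrt(s)
  expect_gt(hrt$turbulence_onset_pct, 0)
  expect_lte(hrt$turbulence_slope_ms_per_rr, 2.5)
  expect_true(hrt$hrt_abnormal)

  # decelerating ramp: TS = 10 > 2.5, not abnormal despite TO sign
  s2 <- series_with_vpc(post = 780 + 10 * (0:15))
  expect_false(compute_hrt(s2)$hrt_abnormal)
})

test_that("series without a valid VPC give an undefined HRT result", {
  expect_equal(compute_hrt(series_from_rr(rep(800, 100)))$n_valid_vpc, 0L)
  # V beat with a too-long coupling interval is not a valid VPC
  rr <- c(rep(800, 6), 700, 900, rep(800, 16))
  labels <- c(rep("N", 6), "V", rep("N", 17))
  s <- series_from_rr(rr, labels)
  hrt <- compute_hrt(s)
  expect_equal(hrt$n_valid_vpc, 0L)
  expect_true(is.na(hrt$hrt_abnormal))
})

test_that("injected TO/TS are recovered from noisy averaged responses", {
  # 25 VPCs with the same deterministic response + RR noise (sd 10 ms)
  make_long <- function(noise_sd, seed) {
    set.seed(seed)
    rr <- numeric(0)
    labels <- character(0)
    post_shape <- 760 + 8 * (0:15)   # injected TS = 8, TO < 0
    for (k in 1:25) {
      blk_pre <- rep(800, 10) + rnorm(10, 0, noise_sd)
      blk_post <- post_shape + rnorm(16, 0, noise_sd)
      rr <- c(rr, blk_pre, 500, 1100, blk_post)
      labels <- c(labels, rep("N", 10), "V", rep("N", 17))
    }
    series_from_rr(rr, labels)
  }
  clean <- compute_hrt(make_long(0, 1))
  to_true <- 100 * ((760 + 768) - 1600) / 1600
  expect_equal(clean$turbulence_onset_pct, to_true, tolerance = 1e-6)
  expect_equal(clean$turbulence_slope_ms_per_rr, 8, tolerance = 1e-6)

  noisy <- compute_hrt(make_long(10, 2))
  expect_equal(noisy$turbulence_onset_pct, to_true, tolerance = 0.5)
  expect_equal(noisy$turbulence_slope_ms_per_rr, 8, tolerance = 0.5)
})

test_that("HRT is invariant under time translation", {
  s <- series_with_vpc(post = 780 + 5 * (0:15))
  s2 <- beat_series(s$time_s + 3600, s$rr_ms, s$label, clock_start = 0)
  expect_equal(compute_hrt(s2)$turbulence_onset_pct,
               compute_hrt(s)$turbulence_onset_pct)
  expect_equal(compute_hrt(s2)$turbulence_slope_ms_per_rr,
               compute_hrt(s)$turbulence_slope_ms_per_rr)
})

test_that("deceleration capacity recovers canonical PRSA values", {
  # monotone ramp with step d: every interior beat is an anchor, DC = d
  ramp <- series_from_rr(600 + 2 * (0:299))
  dc <- compute_dc(nn_filter(ramp), half_width = 5, min_anchors = 10)
  expect_equal(dc$dc_ms, 2, tolerance = 1e-9)

  # alternating 800/810: DC = (810 + 800 - 800 - 810)/4 = 0
  alt <- series_from_rr(rep(c(800, 810), 200))
  dc2 <- compute_dc(nn_filter(alt), half_width = 5, min_anchors = 10)
  expect_equal(dc2$dc_ms, 0, tolerance = 1e-9)

  # constant series has no anchors: undefined
  const <- compute_dc(nn_filter(series_from_rr(rep(800, 300))),
                      half_width = 5, min_anchors = 10)
  expect_true(is.na(const$dc_ms))
  expect_equal(const$n_anchors, 0L)
})

test_that("DC scales linearly with the NN deviation amplitude", {
  base <- 900
  make <- function(scale) {
    rr <- base + scale * 30 * sin(2 * pi * (1:600) / 9)
    compute_dc(nn_filter(series_from_rr(rr)), half_width = 5,
               min_anchors = 10)$dc_ms
  }
  expect_equal(make(2), 2 * make(1), tolerance = 1e-6)
  expect_equal(make(0.5), 0.5 * make(1), tolerance = 1e-6)
})

test_that("DC of the time-reversed series mirrors acceleration capacity", {
  set.seed(13)
  rr <- 850 + 25 * sin(2 * pi * (1:800) / 7) + rnorm(800, 0, 8)
  # prepend a dummy beat so the NN vector after filtering is exactly rr
  ac <- compute_dc(nn_filter(series_from_rr(c(1000, rr))),
                   half_width = 5, min_anchors = 10,
                   direction = "acceleration")$dc_ms
  dc_rev <- compute_dc(nn_filter(series_from_rr(c(1000, rev(rr)))),
                       half_width = 5, min_anchors = 10)$dc_ms
  expect_equal(dc_rev, -ac, tolerance = 1e-9)
  expect_lt(ac, 0)
})

test_that("SAF is the conjunction of abnormal HRT and abnormal DC", {
  hrt_ab <- tibble::tibble(hrt_abnormal = TRUE)
  hrt_ok <- tibble::tibble(hrt_abnormal = FALSE)
  hrt_na <- tibble::tibble(hrt_abnormal = NA)
  dc_ab <- tibble::tibble(dc_abnormal = TRUE)
  dc_ok <- tibble::tibble(dc_abnormal = FALSE)
  expect_true(classify_saf(hrt_ab, dc_ab)$saf)
  expect_false(classify_saf(hrt_ok, dc_ab)$saf)
  expect_false(classify_saf(hrt_ab, dc_ok)$saf)
  expect_true(is.na(classify_saf(hrt_na, dc_ab)$saf))
})

test_that("threshold conjunction matches the stated examples", {
  # TO 1 %, TS 2.0, DC 4.0 -> SAF
  mk_hrt <- function(to, ts) tibble::tibble(
    turbulence_onset_pct = to, turbulence_slope_ms_per_rr = ts,
    n_valid_vpc = 5L, hrt_abnormal = ts <= 2.5 && to >= 0)
  mk_dc <- function(d) tibble::tibble(dc_ms = d, n_anchors = 200L,
                                      dc_abnormal = d <= 4.5)
  expect_true(classify_saf(mk_hrt(1, 2.0), mk_dc(4.0))$saf)
  expect_false(classify_saf(mk_hrt(-1, 2.0), mk_dc(4.0))$saf)
  expect_false(classify_saf(mk_hrt(1, 2.0), mk_dc(5.0))$saf)
})
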