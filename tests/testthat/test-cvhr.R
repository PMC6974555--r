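# Arousal fixtures are built from HR plateau profiles over a 60 bpm base;
# the 120 s lower-quartile baseline sits at 60 in all of them.

test_that("arousal detection applies the 6 bpm / 10 s rules", {
  # 68 bpm plateau for 15 s: one arousal (delta 8, duration ~15)
  t1 <- build_tachogram(nn_filter(series_from_hr(
    hr_plateaus(60, list(c(400, 415, 68))), 900)))
  a1 <- detect_arousals(t1)
  expect_equal(nrow(a1), 1)
  expect_gte(a1$delta_bpm, 6)
  expect_equal(a1$duration_s, 15, tolerance = 4)
  expect_equal(a1$start_s, 400, tolerance = 4)

  # same plateau lasting 8 s: too short
  t2 <- build_tachogram(nn_filter(series_from_hr(
    hr_plateaus(60, list(c(400, 408, 68))), 900)))
  expect_equal(nrow(detect_arousals(t2)), 0)

  # 65 bpm for 30 s: rise 5 < 6
  t3 <- build_tachogram(nn_filter(series_from_hr(
    hr_plateaus(60, list(c(400, 430, 65))), 900)))
  expect_equal(nrow(detect_arousals(t3)), 0)

  # two 15 s surges 60 s apart: two arousals
  t4 <- build_tachogram(nn_filter(series_from_hr(
    hr_plateaus(60, list(c(300, 315, 70), c(375, 390, 70))), 900)))
  a4 <- detect_arousals(t4)
  expect_equal(nrow(a4), 2)
  expect_true(all(a4$delta_bpm >= 6))
  expect_true(all(a4$duration_s >= 10))
})

test_that("every reported arousal satisfies its stored thresholds", {
  spec <- tachogram_spec(duration_s = 3600,
                         episodes = plant_episodes(3, 3600, n_cycles = 4),
                         noise_sd_bpm = 1)
  for (seed in 1:5) {
    s <- simulate_tachogram(spec, seed = seed)
    a <- detect_arousals(build_tachogram(nn_filter(s)))
    expect_true(all(a$delta_bpm >= 6))
    expect_true(all(a$end_s - a$start_s >= 10))
    expect_true(all(diff(a$start_s) > 0))
    expect_true(all(a$start_s[-1] >= head(a$end_s, -1)))  # disjoint
  }
})

test_that("episode assembly chains arousals per the gap and count rules", {
  ar <- function(starts, dur = 15) {
    tibble::tibble(start_s = starts, end_s = starts + dur,
                   duration_s = dur, delta_bpm = 8)
  }
  # 3 arousals at 0, 60, 120 s: one episode spanning 0-135 s = 2.25 min
  e1 <- assemble_episodes(ar(c(0, 60, 120)))
  expect_equal(nrow(e1), 1)
  expect_equal(e1$start_s, 0)
  expect_equal(e1$end_s, 135)
  expect_equal(e1$duration_min, 2.25)
  expect_equal(e1$n_arousals, 3L)

  # 2 arousals 30 s apart: below the minimum count
  expect_equal(nrow(assemble_episodes(ar(c(0, 45)))), 0)

  # 4 arousals split by a > 2 min gap into two chains of 2: no episode
  expect_equal(nrow(assemble_episodes(ar(c(0, 60, 300, 360)))), 0)

  # 6 arousals, all gaps 90 s (inclusive <= 120 s): one episode of 6
  e4 <- assemble_episodes(ar(c(0, 105, 210, 315, 420, 525)))
  expect_equal(nrow(e4), 1)
  expect_equal(e4$n_arousals, 6L)

  # boundary: gap exactly 120 s chains, 121 s does not
  expect_equal(nrow(assemble_episodes(ar(c(0, 135, 270)))), 1)
  expect_equal(nrow(assemble_episodes(ar(c(0, 136, 272)))), 0)
})

test_that("episode assembly matches brute-force chaining on random inputs", {
  # brute force: all maximal runs of consecutive arousals whose successive
  # gaps are <= 120 s, kept if their length is >= 3
  brute_chains <- function(a, max_gap = 120, min_k = 3) {
    n <- nrow(a)
    if (n == 0) return(NULL)
    link <- if (n > 1) (a$start_s[-1] - a$end_s[-n]) <= max_gap else logical(0)
    id <- cumsum(c(TRUE, !link))
    keep <- as.vector(table(id)) >= min_k
    split(seq_len(n), id)[keep]
  }
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(0:50, 1)
    starts <- sort(runif(n, 0, 7200))
    dur <- runif(n, 10, 30)
    starts <- starts[c(TRUE, diff(starts) > 35)]  # enforce disjointness
    a <- tibble::tibble(start_s = starts,
                        end_s = starts + pmin(30, c(diff(starts), Inf) - 1),
                        delta_bpm = 8)
    a$duration_s <- a$end_s - a$start_s
    got <- assemble_episodes(a)
    want <- brute_chains(a)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$n_arousals, unname(vapply(want, length, integer(1))))
      expect_equal(
        got$start_s,
        unname(vapply(want, function(i) a$start_s[i[1]], numeric(1))))
    }
  }
})

test_that("CVHR minutes sum episode spans", {
  expect_equal(quantify_cvhr(NULL), 0)
  expect_equal(quantify_cvhr(tibble::tibble(start_s = numeric(),
                                            end_s = numeric(),
                                            duration_min = numeric())), 0)
  one <- tibble::tibble(start_s = 100, end_s = 400, duration_min = 5)
  expect_equal(quantify_cvhr(one), 5)
  two <- tibble::tibble(start_s = c(0, 500), end_s = c(135, 770),
                        duration_min = c(2.25, 4.5))
  expect_equal(quantify_cvhr(two), 6.75)
  overlap <- tibble::tibble(start_s = c(0, 100), end_s = c(135, 400),
                            duration_min = c(2.25, 5))
  expect_error(quantify_cvhr(overlap), "overlap")
})

test_that("SDB classification uses the 20% cutpoint (72 min of 6 h)", {
  expect_equal(classify_sdb(72, FALSE, 360), "present")
  expect_equal(classify_sdb(71.9, FALSE, 360), "absent")
  expect_equal(classify_sdb(200, TRUE, 360), "indeterminate_flat")
  expect_equal(classify_sdb(0, FALSE, 360), "absent")
  expect_error(classify_sdb(400, FALSE, 360), "exceeds")
  # the cutoff scales with the segment: 20% of 4 h = 48 min
  expect_equal(classify_sdb(50, FALSE, 240), "present")
  expect_equal(classify_sdb(47, FALSE, 240), "absent")
})

test_that("scoring is invariant under time translation", {
  spec <- tachogram_spec(duration_s = 3600,
                         episodes = plant_episodes(2, 3600, n_cycles = 5))
  s <- simulate_tachogram(spec, seed = 11)
  shifted <- beat_series(s$time_s, s$rr_ms, s$label,
                         clock_start = clock_start(s))
  res <- score_cvhr(build_tachogram(nn_filter(s)))
  # same beats, clock moved by 2 h: identical minutes
  s2 <- beat_series(s$time_s, s$rr_ms, s$label, clock_start = 7200)
  res2 <- score_cvhr(build_tachogram(nn_filter(s2)))
  expect_equal(res2$cvhr_minutes, res$cvhr_minutes)
  expect_lte(res$cvhr_minutes, 60)  # never exceeds the segment length
})

test_that("a flat tachogram cannot enter arousal detection", {
  s <- simulate_tachogram(tachogram_spec(duration_s = 1800,
                                         flat_mode = TRUE,
                                         noise_sd_bpm = 0.3), seed = 3)
  tach <- build_tachogram(nn_filter(s))
  expect_error(detect_arousals(tach), "indeterminate_flat")
  expect_equal(score_cvhr(tach)$sdb_status, "indeterminate_flat")
})
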