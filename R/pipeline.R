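#' Pipeline configuration
#'
#' All tunable thresholds of the per-patient and cohort stages, with the
#' documented defaults.  The object is a plain nested list, fully
#' serializable to JSON and echoed into result bundles.
#'
#' @param window A [nocturnal_window()].
#' @param smooth_window_s Tachogram running-median window, seconds.
#' @param grid_hz Tachogram resampling rate, Hz.
#' @param flat Flat-classifier thresholds: `excursion_limit_bpm`,
#'   `rsa_min_bpm`.
#' @param cvhr CVHR-scoring thresholds: `arousal_min_delta_bpm`,
#'   `arousal_min_dur_s`, `baseline_window_s`, `max_gap_s`, `min_arousals`,
#'   `sdb_fraction`.
#' @param hrv HRV options: `segment` (`"full"` or `"nocturnal"` recording).
#' @param hrt_dc HRT/DC thresholds: `coupling_max`, `pause_min`,
#'   `nn_range`, `to_abnormal`, `ts_abnormal`, `prolongation_limit`,
#'   `half_width`, `min_anchors`, `dc_abnormal`.
#' @param survival Cohort-stage options: `min_subgroup`, `conf_level`,
#'   `horizon_years`.
#' @param seed Seed recorded into output bundles.
#' @return A `cvhr_config` list.
#' @export
pipeline_config <- function(window = nocturnal_window(),
                            smooth_window_s = 5, grid_hz = 2,
                            flat = list(excursion_limit_bpm = 5,
                                        rsa_min_bpm = 1),
                            cvhr = list(arousal_min_delta_bpm = 6,
                                        arousal_min_dur_s = 10,
                                        baseline_window_s = 120,
                                        max_gap_s = 120,
                                        min_arousals = 3,
                                        sdb_fraction = 0.20),
                            hrv = list(segment = "full"),
                            hrt_dc = list(coupling_max = 0.8,
                                          pause_min = 1.2,
                                          nn_range = c(300, 2000),
                                          to_abnormal = 0,
                                          ts_abnormal = 2.5,
                                          prolongation_limit = 0.05,
                                          half_width = 20,
                                          min_anchors = 100,
                                          dc_abnormal = 4.5),
                            survival = list(min_subgroup = 20,
                                            conf_level = 0.95,
                                            horizon_years = 5),
                            seed = NULL) {
  structure(list(window = window, smooth_window_s = smooth_window_s,
                 grid_hz = grid_hz, flat = flat, cvhr = cvhr, hrv = hrv,
                 hrt_dc = hrt_dc, survival = survival, seed = seed),
            class = "cvhr_config")
}

config_json <- function(config) {
  strip <- function(x) if (is.list(x)) lapply(x, strip) else x
  jsonlite::toJSON(strip(unclass(config)), auto_unbox = TRUE,
                   null = "null", digits = NA)
}

#' Score one patient
#'
#' Runs the per-patient pipeline in order: nocturnal extraction (with
#' coverage check), NN filtering, tachogram construction, flat
#' classification, then — for non-flat patients — CVHR scoring, and in all
#' analyzable patients the HRV panel, heart rate turbulence, deceleration
#' capacity, and the severe-autonomic-failure composite.  Flat patients get
#' `sdb_status = "indeterminate_flat"` and no CVHR fields; patients with
#' insufficient nocturnal coverage are reported with status
#' `"non_analyzable"` (distinct from flat) and excluded downstream.
#'
#' @param series A validated [beat_series()] (full recording).
#' @param config A [pipeline_config()].
#' @return A one-row tibble with identification, status, coverage, flat
#'   metrics, CVHR summary, the HRV panel, HRT/DC/SAF, and label counts.
#' @export
run_patient <- function(series, config = pipeline_config()) {
  validate_beat_series(series)
  base <- tibble::tibble(patient_id = patient_id(series),
                         n_beats = nrow(series))
  noct <- extract_nocturnal_segment(series, config$window)
  base$coverage <- attr(noct, "coverage")
  if (!attr(noct, "analyzable")) {
    return(dplyr::mutate(base, status = "non_analyzable",
                         is_flat = NA, cvhr_minutes = NA_real_,
                         sdb_status = NA_character_))
  }

  nn_noct <- nn_filter(noct)
  tach <- build_tachogram(nn_noct, smooth_window_s = config$smooth_window_s,
                          grid_hz = config$grid_hz)
  cv <- config$cvhr
  sc <- score_cvhr(tach,
                   min_delta_bpm = cv$arousal_min_delta_bpm,
                   min_duration_s = cv$arousal_min_dur_s,
                   baseline_window_s = cv$baseline_window_s,
                   max_gap_s = cv$max_gap_s,
                   min_arousals = cv$min_arousals,
                   segment_min = (config$window$end_s -
                                    config$window$start_s) / 60,
                   sdb_fraction = cv$sdb_fraction,
                   excursion_limit_bpm = config$flat$excursion_limit_bpm,
                   rsa_min_bpm = config$flat$rsa_min_bpm)

  hrv_src <- if (identical(config$hrv$segment, "nocturnal")) nn_noct else
    nn_filter(series)
  hrv <- hrv_metrics(hrv_src)

  hd <- config$hrt_dc
  hrt <- compute_hrt(series, coupling_max = hd$coupling_max,
                     pause_min = hd$pause_min, nn_range = hd$nn_range,
                     to_abnormal = hd$to_abnormal,
                     ts_abnormal = hd$ts_abnormal)
  dc <- compute_dc(nn_filter(series),
                   prolongation_limit = hd$prolongation_limit,
                   half_width = hd$half_width,
                   min_anchors = hd$min_anchors,
                   dc_abnormal = hd$dc_abnormal)
  saf <- classify_saf(hrt, dc)

  out <- dplyr::bind_cols(
    dplyr::mutate(base, status = "ok",
                  is_flat = sc$flat$is_flat,
                  max_excursion_bpm = sc$flat$max_excursion_bpm,
                  rsa_amplitude_bpm = sc$flat$rsa_amplitude_bpm,
                  n_arousals = if (is.null(sc$arousals)) NA_integer_ else
                    nrow(sc$arousals),
                  n_episodes = if (is.null(sc$episodes)) NA_integer_ else
                    nrow(sc$episodes),
                  cvhr_minutes = sc$cvhr_minutes,
                  sdb_status = sc$sdb_status),
    hrv, hrt, dc["dc_ms"], dc["n_anchors"], saf[c("saf", "dc_abnormal")]
  )
  attr(out, "arousals") <- sc$arousals
  attr(out, "episodes") <- sc$episodes
  out
}

#' Per-patient JSON report
#'
#' @param patient_row One-row tibble from [run_patient()].
#' @param path Optional path to write the JSON to.
#' @return The JSON string, invisibly when written to a file.
#' @export
patient_report_json <- function(patient_row, path = NULL) {
  rep <- as.list(patient_row)
  rep$arousals <- attr(patient_row, "arousals")
  rep$episodes <- attr(patient_row, "episodes")
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, null = "null",
                         na = "null", digits = NA, dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Run the cohort analysis
#'
#' Scores every patient ([run_patient()]), joins the covariate/outcome
#' table, and reproduces the cohort-level statistics: group sizes (flat /
#' SDB present / SDB absent / non-analyzable), Kaplan-Meier curves and
#' log-rank tests for the flat-vs-non-flat and SDB groupings, the
#' CVHR-threshold mortality scan over non-flat patients, the multivariable
#' Cox model (flat + age + sex + LVEF + GRACE + diabetes), the
#' SAF / flat-tachogram cross-tabulation, and the CVHR-vs-nocturnal-
#' respiratory-rate correlation.  Per-patient failures quarantine the
#' patient and continue; cohort-level failures abort.
#'
#' @param series_list A list of [beat_series()] objects, or a directory
#'   path containing files readable by [read_beat_series()].
#' @param outcomes A data frame keyed by `patient_id` (or `id`) with
#'   `time_years` and `event`, plus any of `age`, `female`, `lvef`,
#'   `grace`, `diabetes`, `nrr` for the Cox model.
#' @param config A [pipeline_config()].
#' @return A `cvhr_cohort_results` list: `patients` (the per-patient
#'   table joined to outcomes), `group_sizes`, `km` (list of `km_curve`),
#'   `logrank`, `scan`, `cox`, `saf_table`, `cvhr_nrr_r`, `failures`,
#'   `config`.
#' @export
run_cohort <- function(series_list, outcomes, config = pipeline_config()) {
  if (is.character(series_list) && length(series_list) == 1 &&
      dir.exists(series_list)) {
    paths <- list.files(series_list, full.names = TRUE)
    series_list <- lapply(paths, read_beat_series)
  }
  if (!length(series_list) || nrow(outcomes) < 2) {
    abort("need at least 2 patients with outcomes")
  }
  if ("id" %in% names(outcomes) && !"patient_id" %in% names(outcomes)) {
    outcomes <- dplyr::rename(outcomes, patient_id = "id")
  }
  if (!all(c("patient_id", "time_years", "event") %in% names(outcomes))) {
    abort("outcomes must have columns patient_id (or id), time_years, event")
  }

  failures <- list()
  rows <- list()
  for (s in series_list) {
    res <- tryCatch(run_patient(s, config), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        tibble::tibble(patient_id = patient_id(s),
                       message = conditionMessage(res))
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  patients <- dplyr::bind_rows(rows)
  if (!nrow(patients)) abort("no patient could be scored")
  patients <- dplyr::inner_join(patients, outcomes, by = "patient_id",
                                suffix = c("", ".outcome"))

  ok <- dplyr::filter(patients, .data$status == "ok")
  group_sizes <- tibble::tibble(
    group = c("flat", "sdb_present", "sdb_absent", "non_analyzable"),
    n = c(sum(ok$is_flat), sum(ok$sdb_status == "present", na.rm = TRUE),
          sum(ok$sdb_status == "absent", na.rm = TRUE),
          sum(patients$status == "non_analyzable"))
  )

  km <- list()
  logrank <- list()
  if (sum(ok$is_flat) >= 1 && sum(!ok$is_flat) >= 1) {
    km$flat <- km_estimate(dplyr::filter(ok, .data$is_flat),
                           time_years, event)
    km$non_flat <- km_estimate(dplyr::filter(ok, !.data$is_flat),
                               time_years, event)
    if (sum(ok$event) > 0) {
      logrank$flat_vs_nonflat <-
        logrank_test(ok, time_years, event, is_flat)
    }
  }
  nf <- dplyr::filter(ok, !.data$is_flat)
  if (length(unique(nf$sdb_status)) >= 2) {
    km$sdb_present <- km_estimate(
      dplyr::filter(nf, .data$sdb_status == "present"), time_years, event)
    km$sdb_absent <- km_estimate(
      dplyr::filter(nf, .data$sdb_status == "absent"), time_years, event)
    if (sum(nf$event) > 0) {
      logrank$sdb <- logrank_test(nf, time_years, event, sdb_status)
    }
  }

  scan <- if (nrow(nf) >= config$survival$min_subgroup) {
    threshold_mortality_scan(nf, cvhr_minutes, time_years, event,
                             min_n = config$survival$min_subgroup,
                             horizon_years = config$survival$horizon_years)
  }

  cox_covs <- intersect(c("is_flat", "age", "female", "lvef", "grace",
                          "diabetes"), names(ok))
  cox <- NULL
  if (sum(ok$event) >= length(cox_covs) + 1) {
    cox <- tryCatch(
      cox_fit(ok, time_years, event, covariates = cox_covs,
              conf_level = config$survival$conf_level),
      error = function(e) {
        failures[[length(failures) + 1]] <<-
          tibble::tibble(patient_id = "<cohort>",
                         message = paste("cox:", conditionMessage(e)))
        NULL
      })
  } else {
    failures[[length(failures) + 1]] <-
      tibble::tibble(patient_id = "<cohort>",
                     message = "cox skipped: too few events")
  }

  saf_table <- if ("saf" %in% names(ok)) {
    dplyr::count(ok, .data$is_flat, .data$saf)
  }

  cvhr_nrr_r <- if ("nrr" %in% names(nf) &&
                    sum(!is.na(nf$cvhr_minutes) & !is.na(nf$nrr)) >= 3) {
    pearson_r(nf$cvhr_minutes, nf$nrr)
  } else {
    NA_real_
  }

  structure(list(patients = patients, group_sizes = group_sizes, km = km,
                 logrank = logrank, scan = scan, cox = cox,
                 saf_table = saf_table, cvhr_nrr_r = cvhr_nrr_r,
                 failures = dplyr::bind_rows(failures), config = config),
            class = "cvhr_cohort_results")
}

#' @export
print.cvhr_cohort_results <- function(x, ...) {
  cat("<cvhr cohort results>\n")
  cat("patients scored:", nrow(x$patients), "\n")
  print(x$group_sizes)
  if (!is.null(x$cox)) {
    cat("\nmultivariable Cox model:\n")
    print(tidy(x$cox))
  }
  if (!is.null(x$logrank$flat_vs_nonflat)) {
    cat("\nlog-rank flat vs non-flat: p =",
        format(x$logrank$flat_vs_nonflat$p_value, digits = 3), "\n")
  }
  invisible(x)
}

#' @method glance cvhr_cohort_results
#' @export
glance.cvhr_cohort_results <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$patients),
    n_flat = x$group_sizes$n[x$group_sizes$group == "flat"],
    n_sdb_present = x$group_sizes$n[x$group_sizes$group == "sdb_present"],
    n_sdb_absent = x$group_sizes$n[x$group_sizes$group == "sdb_absent"],
    n_non_analyzable =
      x$group_sizes$n[x$group_sizes$group == "non_analyzable"],
    events = sum(x$patients$event),
    cvhr_nrr_r = x$cvhr_nrr_r
  )
}
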