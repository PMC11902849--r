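#' Pipeline run configuration
#'
#' Exactly one input source must be supplied: either a [synthetic_config()]
#' (the cohort is generated) or `recordings` + `scores` (pre-loaded data).
#'
#' @param synthetic Optional [synthetic_config()].
#' @param recordings Optional list of [imu_recording()]s.
#' @param scores Optional tibble in the [load_scores()] layout.
#' @param mss An [mss_config()].
#' @param accel_mode Passed to [calibrated_acceleration()].
#' @param calibration_window_s Stationary window used by
#'   [estimate_calibration()] (default 1 s).
#' @param rate_hz Uniform resampling rate before kinematics (default 25).
#' @param score Clinical score for the correlation grid (default `"arat"`).
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(synthetic = NULL, recordings = NULL, scores = NULL,
                            mss = mss_config(),
                            accel_mode = c("static_removed", "raw"),
                            calibration_window_s = 1, rate_hz = 25,
                            score = "arat") {
  accel_mode <- match.arg(accel_mode)
  has_synth <- !is.null(synthetic)
  has_real <- !is.null(recordings) && !is.null(scores)
  if (has_synth == has_real) {
    stop("supply exactly one of `synthetic` or `recordings`+`scores`",
         call. = FALSE)
  }
  structure(list(synthetic = synthetic, recordings = recordings,
                 scores = scores, mss = mss, accel_mode = accel_mode,
                 calibration_window_s = calibration_window_s,
                 rate_hz = rate_hz, score = score),
            class = "run_config")
}

# one recording -> per-signal MSS rows (with metadata and segment sizes)
process_recording <- function(rec, cfg) {
  rec <- resample_uniform(rec, cfg$rate_hz)
  cal <- estimate_calibration(rec, window_s = cfg$calibration_window_s)
  orient <- integrate_orientation(rec, cal)
  accel <- calibrated_acceleration(rec, cal, mode = cfg$accel_mode)
  res <- compute_mss(orient, accel, cfg$mss, keep_segments = TRUE)
  dplyr::bind_cols(
    imu_meta(rec)[rep(1, nrow(res)),
                  c("subject_id", "session", "domain", "wrist_side", "affected")],
    res
  )
}

# pool the four domain rows of each subject/session/signal into whole-test rows
pool_whole_test <- function(mss_rows) {
  mss_rows |>
    dplyr::group_by(.data$subject_id, .data$session, .data$wrist_side,
                    .data$affected, .data$signal, .data$threshold) |>
    dplyr::summarise(
      domain = "whole",
      n_segments = sum(.data$n_segments),
      n_above_threshold = sum(.data$n_above_threshold),
      pooled = list(unlist(.data$sizes)),
      performance_time_s = sum(.data$performance_time_s),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      average_mss = purrr::map2_dbl(.data$pooled, .data$threshold, average_mss),
      sizes = .data$pooled
    ) |>
    dplyr::select(-"pooled")
}

#' Run the full analysis pipeline
#'
#' Ingest (or generate) the cohort, reconstruct kinematics, compute the MSS
#' table per task domain plus pooled whole-test rows, and produce the
#' correlation grid against the clinical score, pre/post change summaries
#' (when both sessions are present), and the demographics block. The run is
#' deterministic given the configuration and seed.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of class `mss_report`: `mss_table`, `correlations`,
#'   `changes` (or `NULL`), `demographics`, `log` (character vector of stage
#'   messages), `config`.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(synthetic = synthetic_config(n_subjects = 6, seed = 7))
#' rep <- run_pipeline(cfg)
#' rep$correlations
#' }
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  if (!is.null(cfg$synthetic)) {
    cohort <- generate_cohort(cfg$synthetic)
    recordings <- cohort$recordings
    scores <- cohort$scores
    note("generated synthetic cohort: %d subjects, %d recordings, seed %d",
         cfg$synthetic$n_subjects, length(recordings), cfg$synthetic$seed)
  } else {
    recordings <- cfg$recordings
    scores <- cfg$scores
    note("using %d supplied recordings", length(recordings))
  }
  rows <- purrr::map(recordings, function(rec) {
    m <- imu_meta(rec)
    tryCatch(process_recording(rec, cfg),
             error = function(e) {
               stop(sprintf("MSS stage failed for subject %s domain %s: %s",
                            m$subject_id, m$domain, conditionMessage(e)),
                    call. = FALSE)
             })
  })
  per_domain <- dplyr::bind_rows(rows)
  mss_table <- dplyr::bind_rows(per_domain,
                                pool_whole_test(per_domain)[names(per_domain)])
  note("MSS table: %d rows; %d of %d segments above threshold",
       nrow(mss_table), sum(mss_table$n_above_threshold),
       sum(mss_table$n_segments))
  correlations <- correlation_table(mss_table, scores, score = cfg$score)
  note("correlation grid: %d cells, %d significant at 0.05",
       nrow(correlations), sum(correlations$p_value < 0.05, na.rm = TRUE))
  changes <- NULL
  if (all(c("baseline", "followup") %in% scores$session)) {
    ang <- mss_table |>
      dplyr::filter(.data$affected, .data$domain == "4",
                    .data$signal %in% c("roll", "pitch", "yaw")) |>
      dplyr::select("subject_id", "session", parameter = "signal",
                    value = "average_mss")
    completers <- scores$subject_id[scores$session == "followup"]
    changes <- suppressWarnings(
      pre_post_changes(dplyr::filter(ang, .data$subject_id %in% completers)))
    note("pre/post changes over %d completers", length(unique(completers)))
  }
  demographics <- summarize_demographics(scores)
  out <- list(mss_table = dplyr::select(mss_table, -"sizes"),
              correlations = correlations, changes = changes,
              demographics = demographics, log = log, config = cfg)
  class(out) <- "mss_report"
  out
}

#' @export
print.mss_report <- function(x, ...) {
  cat("<mss_report>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  cat(sprintf("  demographics: n = %d, mean age %.1f +/- %.1f, median onset %g d\n",
              x$demographics$n, x$demographics$mean_age, x$demographics$sd_age,
              x$demographics$median_days_since_onset))
  print(x$correlations)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mss_report <- function(x, ...) {
  x$mss_table
}

#' @exportS3Method generics::glance
glance.mss_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_recordings = sum(x$mss_table$domain != "whole") / 6),
    glance(x$correlations)
  )
}

fixture_checks <- function() {
  tibble::tribble(
    ~check, ~expected, ~tol,
    "n_records_total", 13, 0,
    "n_baseline", 9, 0,
    "n_followup", 4, 0,
    "spearman_arat_fmue", 0.938, 5e-4,
    "spearman_arat_mbi", 0.812, 5e-4,
    "mean_age", 61.3, 0.05,
    "sd_age", 14.5, 0.05,
    "median_days_since_onset", 28, 0,
    "d4_roll_mean_change", 11.5, 0.05,
    "d4_roll_sd_change", 14.2, 0.05,
    "d4_pitch_mean_change", 9.1, 0.05,
    "d4_pitch_sd_change", 1.5, 0.05,
    "d4_yaw_mean_change", 24.1, 0.05,
    "d4_yaw_sd_change", 27.9, 0.05
  )
}

#' Recompute the published summary statistics from the bundled fixtures
#'
#' Recomputes, from the score and change fixtures shipped with the package,
#' every summary statistic the study prints from its clinical tables --
#' record counts, Spearman ARAT--FMUE/MBI over the 13 pooled sessions,
#' demographics, and the domain-4 angular MSS change summaries over the four
#' completers -- and compares each against the published value.
#'
#' @param scores_path,changes_path Fixture paths; defaults to the bundled
#'   files.
#' @return Tibble: `check`, `computed`, `expected`, `tol`, `pass`. Missing
#'   files yield explicit failure rows rather than errors.
#' @export
verify_fixtures <- function(scores_path = wristmss_example("table1_scores.csv"),
                            changes_path = wristmss_example("table3_domain4_changes.csv")) {
  exp <- fixture_checks()
  computed <- stats::setNames(rep(NA_real_, nrow(exp)), exp$check)
  if (file.exists(scores_path)) {
    scores <- load_scores(scores_path)
    demo <- summarize_demographics(scores)
    computed["n_records_total"] <- nrow(scores)
    computed["n_baseline"] <- sum(scores$session == "baseline")
    computed["n_followup"] <- sum(scores$session == "followup")
    computed["spearman_arat_fmue"] <- spearman_cor(scores$arat, scores$fmue)$rs
    computed["spearman_arat_mbi"] <- spearman_cor(scores$arat, scores$mbi)$rs
    computed["mean_age"] <- demo$mean_age
    computed["sd_age"] <- demo$sd_age
    computed["median_days_since_onset"] <- demo$median_days_since_onset
  }
  if (file.exists(changes_path)) {
    ch <- table3_changes(changes_path)
    for (p in c("roll", "pitch", "yaw")) {
      computed[paste0("d4_", p, "_mean_change")] <- ch$mean_change[ch$parameter == p]
      computed[paste0("d4_", p, "_sd_change")] <- ch$sd_change[ch$parameter == p]
    }
  }
  out <- dplyr::mutate(exp, computed = unname(computed[exp$check]),
                       # epsilon so reported values exactly tol away still pass
                       pass = !is.na(.data$computed) &
                         abs(.data$computed - .data$expected) <= .data$tol + 1e-9)
  dplyr::select(out, "check", "computed", "expected", "tol", "pass")
}

#' Domain-4 angular MSS changes from the completer fixture
#'
#' @param path Fixture CSV of pre/post domain-4 average MSS values per
#'   completer (defaults to the bundled table).
#' @return [pre_post_changes()] summary over roll, pitch and yaw.
#' @export
table3_changes <- function(path = wristmss_example("table3_domain4_changes.csv")) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(subject_id = readr::col_character()))
  long <- df |>
    dplyr::select("subject_id", dplyr::matches("^(roll|pitch|yaw)_(pre|post)$")) |>
    tidyr::pivot_longer(-"subject_id",
                        names_to = c("parameter", "session"), names_sep = "_") |>
    dplyr::mutate(session = dplyr::recode(.data$session,
                                          pre = "baseline", post = "followup"))
  pre_post_changes(long)
}
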