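score_ranges <- list(arat = c(0, 57), mbi = c(0, 100), fmue = c(0, 66))

#' Load and validate clinical score records
#'
#' Reads a table of per-session clinical records (one row per subject and
#' session) and validates scale ranges: ARAT 0--57, MBI 0--100, FMUE 0--66.
#' The package ships the study cohort as a fixture; see
#' `wristmss_example("table1_scores.csv")`.
#'
#' @param path CSV file with columns `subject_id`, `age`, `sex`, `diagnosis`,
#'   `days_since_onset`, `hemiplegic_side`, `session` (`baseline` or
#'   `followup`), `arat`, `mbi`, `fmue`.
#' @return A tibble of validated records.
#' @export
#' @examples
#' scores <- load_scores(wristmss_example("table1_scores.csv"))
#' dplyr::count(scores, session)
load_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(subject_id = readr::col_character()))
  if (nrow(df) == 0) {
    warning("score table is empty: ", path, call. = FALSE)
    return(df)
  }
  req <- c("subject_id", "session", "arat", "mbi", "fmue")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_session <- setdiff(unique(df$session), c("baseline", "followup"))
  if (length(bad_session)) {
    stop("unknown session label(s): ", paste(bad_session, collapse = ", "),
         call. = FALSE)
  }
  for (scale in names(score_ranges)) {
    rng <- score_ranges[[scale]]
    bad <- which(df[[scale]] < rng[1] | df[[scale]] > rng[2])
    if (length(bad)) {
      stop(sprintf("%s out of range [%d, %d] for subject %s (%s session)",
                   toupper(scale), rng[1], rng[2],
                   df$subject_id[bad[1]], df$session[bad[1]]),
           call. = FALSE)
    }
  }
  df
}

#' Path to a bundled example/fixture file
#'
#' @param file File name under the package's `extdata`; with no argument,
#'   lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
wristmss_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "wristmss")))
  }
  path <- system.file("extdata", file, package = "wristmss", mustWork = FALSE)
  if (!nzchar(path)) stop("no bundled file called ", file, call. = FALSE)
  path
}

#' Summarize cohort demographics
#'
#' Baseline-session summary: mean and (n-1) standard deviation of age, median
#' days since stroke onset (midpoint convention for even n), and sex counts.
#'
#' @param records Tibble from [load_scores()].
#' @return One-row tibble: `n`, `mean_age`, `sd_age`, `median_days_since_onset`,
#'   `n_male`, `n_female`. `sd_age` is `NA` for a single record.
#' @export
summarize_demographics <- function(records) {
  base <- dplyr::filter(records, .data$session == "baseline")
  if (nrow(base) < 1) stop("no baseline records", call. = FALSE)
  tibble::tibble(
    n = nrow(base),
    mean_age = mean(base$age),
    sd_age = if (nrow(base) > 1) stats::sd(base$age) else NA_real_,
    median_days_since_onset = stats::median(base$days_since_onset),
    n_male = sum(base$sex == "M"),
    n_female = sum(base$sex == "F")
  )
}
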