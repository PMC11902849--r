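#' Spearman rank correlation with midranks and t-approximation p-value
#'
#' Ties receive midranks and the coefficient is the Pearson correlation of
#' the rank vectors. The two-sided p-value uses the t approximation with
#' n - 2 degrees of freedom (the convention of mainstream statistical
#' packages for this analysis), or, behind a flag, exact enumeration of all
#' rank permutations for small samples.
#'
#' @param x,y Paired numeric vectors; pairs with a missing value in either
#'   are dropped.
#' @param p_method `"t"` (default) or `"exact"` (full permutation null of
#'   `|rs|`, available for n <= 8).
#' @return One-row tibble: `rs`, `p_value`, `n`. `rs` is `NA` when either
#'   rank vector has zero variance (all-tied input); `p_value` is the
#'   probability of an |rs| at least as large under the null.
#' @export
#' @examples
#' spearman_cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
spearman_cor <- function(x, y, p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs, have ", n, call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(tibble::tibble(rs = NA_real_, p_value = NA_real_, n = n))
  }
  rs <- stats::cor(rx, ry)
  p <- if (p_method == "t") {
    if (abs(rs) >= 1) 0 else {
      tstat <- rs * sqrt((n - 2) / (1 - rs^2))
      2 * stats::pt(-abs(tstat), df = n - 2)
    }
  } else {
    if (n > 8) stop("exact permutation p-value supported for n <= 8", call. = FALSE)
    perms <- all_permutations(n)
    obs <- abs(rs)
    null_rs <- apply(perms, 1, function(p_) stats::cor(rx, ry[p_]))
    mean(abs(null_rs) >= obs - 1e-12)
  }
  tibble::tibble(rs = rs, p_value = p, n = n)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

mss_parameters <- function() {
  c("accel_x", "accel_y", "accel_z", "roll", "pitch", "yaw", "performance_time")
}

#' Correlation grid of sensor parameters against a clinical score
#'
#' Builds the domain-by-parameter grid of Spearman correlations between the
#' affected-wrist sensor parameters (average MSS of the three acceleration
#' channels and three angles, plus performance time) and a clinical score,
#' pooling baseline and follow-up sessions as independent observations.
#' Undefined MSS cells (no above-threshold segment) are dropped pairwise, not
#' listwise.
#'
#' @param mss_rows Tibble with columns `subject_id`, `session`, `affected`,
#'   `domain` (`"1"`..`"4"`, `"whole"`), `signal`, `average_mss`,
#'   `performance_time_s` (as produced by [run_pipeline()]'s MSS stage).
#' @param scores Tibble from [load_scores()].
#' @param score Clinical score column to correlate against (default `"arat"`).
#' @return A tibble of class `mss_correlation`: one row per (domain,
#'   parameter) with `rs`, `p_value`, `n`, and a significance marker (`*` at
#'   0.05, `**` at 0.01).
#' @export
correlation_table <- function(mss_rows, scores, score = "arat") {
  stopifnot(score %in% names(scores))
  sens <- dplyr::filter(mss_rows, .data$affected)
  long <- dplyr::bind_rows(
    dplyr::select(sens, "subject_id", "session", "domain",
                  parameter = "signal", value = "average_mss"),
    sens |>
      dplyr::distinct(.data$subject_id, .data$session, .data$domain,
                      .data$performance_time_s) |>
      dplyr::mutate(parameter = "performance_time") |>
      dplyr::rename(value = "performance_time_s")
  )
  joined <- dplyr::inner_join(
    long,
    dplyr::select(scores, "subject_id", "session", score = dplyr::all_of(score)),
    by = c("subject_id", "session")
  )
  unmatched <- dplyr::anti_join(
    dplyr::distinct(long, .data$subject_id, .data$session),
    dplyr::distinct(scores, .data$subject_id, .data$session),
    by = c("subject_id", "session")
  )
  if (nrow(unmatched)) {
    stop("sensor rows without matching scores: ",
         paste(paste(unmatched$subject_id, unmatched$session, sep = "/"),
               collapse = ", "), call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    domain = intersect(c("1", "2", "3", "4", "whole"), unique(long$domain)),
    parameter = mss_parameters()
  )
  out <- purrr::pmap(grid, function(domain, parameter) {
    cell <- joined[joined$domain == domain & joined$parameter == parameter, ]
    ok <- !is.na(cell$value) & !is.na(cell$score)
    # cells with too few complete pairs stay in the grid as undefined
    res <- if (sum(ok) < 3) {
      list(rs = NA_real_, p_value = NA_real_, n = sum(ok))
    } else {
      spearman_cor(cell$value, cell$score)
    }
    tibble::tibble(domain = domain, parameter = parameter,
                   rs = res$rs, p_value = res$p_value, n = res$n)
  })
  out <- dplyr::bind_rows(out)
  out$sig <- dplyr::case_when(
    is.na(out$p_value) ~ "",
    out$p_value < 0.01 ~ "**",
    out$p_value < 0.05 ~ "*",
    .default = ""
  )
  class(out) <- c("mss_correlation", class(out))
  out
}

#' @export
print.mss_correlation <- function(x, ...) {
  cat("Spearman correlation of sensor parameters vs clinical score\n")
  wide <- x |>
    dplyr::mutate(cell = ifelse(is.na(.data$rs), "--",
                                sprintf("%.3f%s (%.3f)", .data$rs, .data$sig,
                                        .data$p_value))) |>
    dplyr::select("domain", "parameter", "cell") |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "cell")
  print(as.data.frame(wide), row.names = FALSE)
  cat("* significant at 0.05; ** significant at 0.01\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mss_correlation <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method generics::glance
glance.mss_correlation <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_defined = sum(!is.na(x$rs)),
    n_significant_05 = sum(x$p_value < 0.05, na.rm = TRUE),
    n_significant_01 = sum(x$p_value < 0.01, na.rm = TRUE),
    max_abs_rs = max(abs(x$rs), na.rm = TRUE)
  )
}

#' Plot a correlation grid
#'
#' @param object An `mss_correlation` from [correlation_table()].
#' @param ... Unused.
#' @return A ggplot tile map of rs by domain and parameter, starred for
#'   significance.
#' @method autoplot mss_correlation
#' @export
autoplot.mss_correlation <- function(object, ...) {
  df <- dplyr::mutate(object,
                      domain = factor(.data$domain,
                                      levels = c("1", "2", "3", "4", "whole")),
                      parameter = factor(.data$parameter, levels = mss_parameters()))
  ggplot2::ggplot(df, ggplot2::aes(.data$parameter, .data$domain, fill = .data$rs)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$rs), "", sprintf("%.2f%s", .data$rs, .data$sig)))) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182b", na.value = "grey90") +
    ggplot2::labs(x = NULL, y = "ARAT domain", fill = "rs") +
    ggplot2::theme_minimal()
}

#' Pre/post change summaries for protocol completers
#'
#' For each parameter, computes the per-subject follow-up minus baseline
#' change and its mean and (n-1) standard deviation over the subjects that
#' have both sessions; subjects missing a session are excluded with a
#' warning.
#'
#' @param data Long tibble with columns `subject_id`, `session`
#'   (`baseline`/`followup`), `parameter`, `value`.
#' @param parameters Optional character vector restricting/ordering the
#'   parameters summarized.
#' @return Tibble: `parameter`, `n`, `mean_change`, `sd_change`, plus a
#'   list-column `deltas` of the per-subject changes (named by subject).
#' @export
pre_post_changes <- function(data, parameters = NULL) {
  if (!is.null(parameters)) {
    data <- dplyr::filter(data, .data$parameter %in% parameters)
  }
  wide <- tidyr::pivot_wider(data, names_from = "session", values_from = "value")
  if (!all(c("baseline", "followup") %in% names(wide))) {
    stop("need both baseline and followup sessions", call. = FALSE)
  }
  incomplete <- wide$subject_id[is.na(wide$baseline) | is.na(wide$followup)]
  if (length(incomplete)) {
    warning("excluding subject(s) missing a session: ",
            paste(unique(incomplete), collapse = ", "), call. = FALSE)
    wide <- wide[!wide$subject_id %in% incomplete, ]
  }
  wide |>
    dplyr::mutate(delta = .data$followup - .data$baseline) |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_change = mean(.data$delta),
      sd_change = if (dplyr::n() > 1) stats::sd(.data$delta) else NA_real_,
      deltas = list(stats::setNames(.data$delta, .data$subject_id)),
      .groups = "drop"
    )
}
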