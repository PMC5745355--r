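#' Impute missing bounds of self-report entries
#'
#' Entries missing one bound get an 8-minute (default) window on the
#' reported side: a missing start becomes `end - window_s`, a missing
#' end becomes `start + window_s`. Complete entries are unchanged.
#'
#' @param log Self-report tibble with `start`, `end` columns (epoch
#'   seconds, `NA` allowed for at most one of the two per row).
#' @param window_s Imputation window in seconds.
#' @return `log` with both bounds filled in.
#' @export
#' @examples
#' impute_bounds(tibble::tibble(start = c(1000, NA), end = c(NA, 1480)))
impute_bounds <- function(log, window_s = 480) {
  if (window_s <= 0) abort("window_s must be positive")
  if (any(is.na(log$start) & is.na(log$end))) {
    abort("entries must have at least one bound")
  }
  dplyr::mutate(
    as_tibble(log),
    start = dplyr::coalesce(.data$start, .data$end - window_s),
    end = dplyr::coalesce(.data$end, .data$start + window_s)
  )
}

#' Match detected sessions against a self-report log
#'
#' Greedy one-to-one overlap matching: reports are walked in time order,
#' and each consumes the earliest not-yet-consumed detection that
#' overlaps it in time (any nonzero overlap counts; self-report windows
#' are already generous). Matched detections are true positives,
#' unmatched detections false positives, unmatched reports false
#' negatives. Detections and reports must share a time origin.
#'
#' @param detected Session tibble (`start_s`, `end_s`), e.g. from
#'   [detect_sessions()].
#' @param reported Self-report tibble (`start`, `end`); entries with a
#'   missing bound are imputed first via [impute_bounds()].
#' @param impute_window_s Imputation window passed to [impute_bounds()].
#' @param n_nonsmoking_windows Optional false-positive denominator, e.g.
#'   from [nonsmoking_windows()]; carried into the report for
#'   [eval_rates()].
#' @return An `eval_report` object holding the counts and the match
#'   table; see [eval_rates()], [tidy.eval_report()].
#' @export
match_sessions <- function(detected, reported, impute_window_s = 480,
                           n_nonsmoking_windows = NA_integer_) {
  det <- as_tibble(detected)
  rep_full <- if (nrow(as_tibble(reported)) > 0) {
    impute_bounds(reported, window_s = impute_window_s)
  } else {
    tibble(start = numeric(0), end = numeric(0))
  }
  ord <- order(rep_full$start)
  consumed <- logical(nrow(det))
  matches <- vector("list", nrow(rep_full))
  for (j in ord) {
    hit <- which(!consumed &
                   det$start_s < rep_full$end[j] &
                   det$end_s > rep_full$start[j])
    if (length(hit) > 0) {
      k <- hit[which.min(det$start_s[hit])]
      consumed[k] <- TRUE
      matches[[j]] <- tibble(report_id = j, detection_id = k)
    }
  }
  matches <- dplyr::bind_rows(matches)
  if (nrow(matches) == 0) {
    matches <- tibble(report_id = integer(0), detection_id = integer(0))
  }
  eval_report(
    n_tp = nrow(matches),
    n_reported = nrow(rep_full),
    n_fp = nrow(det) - nrow(matches),
    n_nonsmoking_windows = n_nonsmoking_windows,
    matches = matches
  )
}

#' Construct an evaluation report from counts
#'
#' Assembles the session-level confusion counts directly, which is how
#' published count tables are re-analysed without re-running a detector.
#'
#' @param n_tp True positives (detections corroborated by a report).
#' @param n_reported Total reported sessions.
#' @param n_fp False positives (detections in nonsmoking time).
#' @param n_nonsmoking_windows False-positive denominator (count of
#'   contiguous nonsmoking windows), `NA` if not yet known.
#' @param matches Optional match table.
#' @return An `eval_report`.
#' @export
eval_report <- function(n_tp, n_reported, n_fp,
                        n_nonsmoking_windows = NA_integer_,
                        matches = NULL) {
  if (n_tp > n_reported) abort("true positives cannot exceed reported sessions")
  if (min(n_tp, n_reported, n_fp) < 0) abort("counts must be nonnegative")
  structure(
    list(
      n_reported = as.integer(n_reported),
      n_detected = as.integer(n_tp + n_fp),
      n_tp = as.integer(n_tp),
      n_fp = as.integer(n_fp),
      n_fn = as.integer(n_reported - n_tp),
      n_nonsmoking_windows = as.integer(n_nonsmoking_windows),
      matches = matches
    ),
    class = "eval_report"
  )
}

tpr_categories <- c("no_smoking", "improper_use", "abnormal_gesture",
                    "true_false_negative")
fpr_categories <- c("clearly_smoking", "true_false_positive")

#' Compute detection rates, optionally after excluding sessions
#'
#' The true positive rate is true positives over reported sessions; the
#' false positive rate is false positives over the count of contiguous
#' nonsmoking windows. Discrepancy categories established by inspection
#' may be excluded: categories that produce false negatives
#' (`no_smoking`, `improper_use`, `abnormal_gesture`,
#' `true_false_negative`) shrink the reported-session denominator;
#' `clearly_smoking` (unlogged but unmistakable smoking) removes false
#' positives together with their windows from the denominator.
#' Whole-percent TPR is truncated and FPR is half-up rounded to one
#' decimal, matching how such rates are conventionally printed; the raw
#' fractions are returned alongside.
#'
#' @param report An [eval_report()].
#' @param exclusions Optional tibble with columns `category` (one of the
#'   six labels above) and `n_excluded`.
#' @param n_nonsmoking_windows Overrides the denominator stored in
#'   `report`.
#' @return `report` augmented with `tpr`, `fpr` (fractions), `tpr_pct`,
#'   `fpr_pct`, and the corrected counts.
#' @export
eval_rates <- function(report, exclusions = NULL,
                       n_nonsmoking_windows = report$n_nonsmoking_windows) {
  excl_tpr <- 0L
  excl_fp <- 0L
  if (!is.null(exclusions)) {
    bad <- setdiff(exclusions$category, c(tpr_categories, fpr_categories))
    if (length(bad) > 0) {
      abort(sprintf("unknown exclusion categories: %s", paste(bad, collapse = ", ")))
    }
    if (any(exclusions$n_excluded < 0)) abort("n_excluded must be nonnegative")
    excl_tpr <- sum(exclusions$n_excluded[exclusions$category %in% tpr_categories])
    excl_fp <- sum(exclusions$n_excluded[exclusions$category == "clearly_smoking"])
  }
  corrected_reported <- report$n_reported - excl_tpr
  corrected_fp <- report$n_fp - excl_fp
  corrected_windows <- n_nonsmoking_windows - excl_fp
  if (corrected_reported < report$n_tp) {
    abort("exclusions leave fewer reported sessions than true positives")
  }
  if (corrected_fp < 0) abort("exclusions exceed available false positives")

  report$exclusions <- exclusions
  report$corrected_reported <- as.integer(corrected_reported)
  report$corrected_fp <- as.integer(corrected_fp)
  report$corrected_windows <- as.integer(corrected_windows)
  report$tpr <- report$n_tp / corrected_reported
  report$tpr_pct <- pct_trunc(report$tpr)
  if (!is.na(corrected_windows)) {
    report$fpr <- corrected_fp / corrected_windows
    report$fpr_pct <- round_half_up(100 * report$fpr, 1)
  } else {
    report$fpr <- report$fpr_pct <- NA_real_
  }
  report
}

#' Number of contiguous nonsmoking windows
#'
#' The false-positive denominator: total recorded minutes divided by the
#' window size, minus the number of reported smoking sessions (120 hours
#' with 123 reports gives 777 eight-minute windows; a 12-hour day with
#' 10 cigarettes gives 80). Floored at zero.
#'
#' @param total_minutes Total minutes of recording.
#' @param n_reported Reported smoking sessions in that time.
#' @param window_minutes Window size in minutes.
#' @return Integer window count.
#' @export
#' @examples
#' nonsmoking_windows(7200, 123) # 777
#' nonsmoking_windows(720, 10) # 80
nonsmoking_windows <- function(total_minutes, n_reported, window_minutes = 8) {
  if (window_minutes <= 0) abort("window_minutes must be positive")
  if (total_minutes < 0) abort("total_minutes must be nonnegative")
  as.integer(max(0, floor(total_minutes / window_minutes) - n_reported))
}

#' Count of rolling windows extractable from a sampled record
#'
#' The alternative, far larger false-positive denominator: how many
#' fixed-length windows a rolling window can cut from `n_samples`
#' samples. The default `"exclusive"` convention counts `n - w` windows
#' (12 hours at 20 Hz yields 854,400 eight-minute windows);
#' `"inclusive"` counts every distinct placement, `n - w + 1`.
#'
#' @param n_samples Total samples recorded.
#' @param window_samples Window length in samples.
#' @param convention `"exclusive"` (`n - w`) or `"inclusive"`
#'   (`n - w + 1`).
#' @return Integer window count (0 when the window exceeds the record).
#' @export
#' @examples
#' rolling_window_count(864000, 9600) # 854400
rolling_window_count <- function(n_samples, window_samples,
                                 convention = c("exclusive", "inclusive")) {
  convention <- match.arg(convention)
  if (window_samples <= 0) abort("window_samples must be positive")
  if (window_samples > n_samples) return(0L)
  extra <- if (convention == "inclusive") 1L else 0L
  as.integer(n_samples - window_samples + extra)
}

#' Progressive exclusion tables for detection rates
#'
#' Recomputes the true (or false) positive rate while cumulatively
#' excluding sessions category by category, reproducing the standard
#' progressive-exclusion accounting: each row shows the running corrected
#' denominator (or corrected false-positive count and window denominator)
#' and the resulting rate. The category labels are supplied by the
#' analyst — assigning sessions to categories is a visual-inspection
#' judgment, not something the package automates.
#'
#' @param n_tp True positives (constant across rows).
#' @param n_reported Initial reported-session count.
#' @param exclusions Tibble with `category` and `n_excluded`, in the
#'   order rows should be applied.
#' @return A tibble, one row for the ground assumption plus one per
#'   exclusion step.
#' @export
#' @examples
#' tpr_exclusion_table(100, 123,
#'   tibble::tibble(category = c("no_smoking", "improper_use"),
#'                  n_excluded = c(2, 9)))
tpr_exclusion_table <- function(n_tp, n_reported, exclusions) {
  bad <- setdiff(exclusions$category, tpr_categories)
  if (length(bad) > 0) {
    abort(sprintf("not a false-negative category: %s", paste(bad, collapse = ", ")))
  }
  corrected <- c(n_reported, n_reported - cumsum(exclusions$n_excluded))
  if (any(corrected < n_tp)) abort("exclusions exceed available sessions")
  tibble(
    category = c("ground_assumption", exclusions$category),
    n_detected = rep(as.integer(n_tp), length(corrected)),
    n_excluded = as.integer(c(0, exclusions$n_excluded)),
    corrected_reported = as.integer(corrected),
    tpr_pct = pct_trunc(n_tp / corrected)
  )
}

#' @rdname tpr_exclusion_table
#' @param n_fp Initial false-positive count.
#' @param n_windows Initial nonsmoking-window denominator; rows excluding
#'   `clearly_smoking` sessions remove their windows from it too.
#' @export
#' @examples
#' fpr_exclusion_table(22, 777,
#'   tibble::tibble(category = c("clearly_smoking", "true_false_positive"),
#'                  n_excluded = c(6, 0)))
fpr_exclusion_table <- function(n_fp, n_windows, exclusions) {
  bad <- setdiff(exclusions$category, fpr_categories)
  if (length(bad) > 0) {
    abort(sprintf("not a false-positive category: %s", paste(bad, collapse = ", ")))
  }
  removed <- ifelse(exclusions$category == "clearly_smoking",
                    exclusions$n_excluded, 0L)
  corrected_fp <- c(n_fp, n_fp - cumsum(removed))
  corrected_win <- c(n_windows, n_windows - cumsum(removed))
  if (any(corrected_fp < 0)) abort("exclusions exceed available false positives")
  tibble(
    category = c("ground_assumption", exclusions$category),
    n_fp = rep(as.integer(n_fp), length(corrected_fp)),
    n_excluded = as.integer(c(0, exclusions$n_excluded)),
    corrected_fp = as.integer(corrected_fp),
    n_windows = as.integer(corrected_win),
    fpr_pct = round_half_up(100 * corrected_fp / corrected_win, 1)
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  reported %d | detected %d | TP %d | FP %d | FN %d\n",
              x$n_reported, x$n_detected, x$n_tp, x$n_fp, x$n_fn))
  if (!is.null(x$tpr)) {
    cat(sprintf("  TPR %d%% (%d/%d)", x$tpr_pct, x$n_tp, x$corrected_reported))
    if (!is.na(x$fpr)) {
      cat(sprintf(" | FPR %.1f%% (%d/%d)", x$fpr_pct, x$corrected_fp,
                  x$corrected_windows))
    }
    cat("\n")
  }
  invisible(x)
}

#' Tidy and glance methods for evaluation reports
#'
#' `tidy()` returns the counts and rates in long form; `glance()` a
#' one-row summary.
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.eval_report <- function(x, ...) {
  vals <- c(
    n_reported = x$n_reported, n_detected = x$n_detected,
    n_true_positive = x$n_tp, n_false_positive = x$n_fp,
    n_false_negative = x$n_fn,
    n_nonsmoking_windows = x$n_nonsmoking_windows,
    tpr = x$tpr %||% NA_real_, fpr = x$fpr %||% NA_real_
  )
  tibble(metric = names(vals), value = as.numeric(vals))
}

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble(
    n_reported = x$n_reported, n_detected = x$n_detected,
    n_tp = x$n_tp, n_fp = x$n_fp, n_fn = x$n_fn,
    tpr = x$tpr %||% NA_real_, fpr = x$fpr %||% NA_real_
  )
}

#' Plot an evaluation report
#'
#' Bar chart of the session-level confusion counts.
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tibble(
    outcome = factor(c("true positive", "false positive", "false negative"),
                     levels = c("true positive", "false positive", "false negative")),
    n = c(object$n_tp, object$n_fp, object$n_fn)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$outcome, .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "sessions")
}
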