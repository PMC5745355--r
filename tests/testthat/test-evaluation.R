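test_that("partial log entries get an 8-minute imputed window", {
  log <- tibble::tibble(start = c(1000, NA, 1000), end = c(NA, 1480, 1300))
  out <- impute_bounds(log)
  expect_equal(out$start, c(1000, 1000, 1000))
  expect_equal(out$end, c(1480, 1480, 1300))

  expect_error(impute_bounds(tibble::tibble(start = NA_real_, end = NA_real_)),
               "at least one bound")
  expect_error(impute_bounds(log, window_s = 0), "positive")
})

test_that("overlap matching is greedy and one-to-one", {
  none <- tibble::tibble(start_s = numeric(0), end_s = numeric(0))
  three <- tibble::tibble(start = c(0, 1000, 2000), end = c(500, 1500, 2500))
  r <- match_sessions(none, three)
  expect_equal(r$n_tp, 0)
  expect_equal(r$n_fp, 0)
  expect_equal(r$n_fn, 3)

  det <- tibble::tibble(start_s = 100, end_s = 400)
  rep1 <- tibble::tibble(start = 90, end = 500)
  expect_equal(match_sessions(det, rep1)$n_tp, 1)

  # two detections inside one report: at most one can match
  det2 <- tibble::tibble(start_s = c(100, 300), end_s = c(200, 400))
  r2 <- match_sessions(det2, rep1)
  expect_equal(r2$n_tp, 1)
  expect_equal(r2$n_fp, 1)
  expect_equal(r2$matches$detection_id, 1) # earliest overlapping consumed

  # touching intervals do not overlap
  det3 <- tibble::tibble(start_s = 500, end_s = 600)
  expect_equal(match_sessions(det3, rep1)$n_tp, 0)
})

test_that("the nonsmoking-window formula matches its worked examples", {
  expect_identical(nonsmoking_windows(7200, 123), 777L)
  expect_identical(nonsmoking_windows(720, 10), 80L)
  expect_identical(nonsmoking_windows(0, 0), 0L)
  expect_identical(nonsmoking_windows(10, 5), 0L) # floored at zero
  expect_error(nonsmoking_windows(100, 0, 0), "positive")

  for (m in c(0, 7, 64, 720, 7200)) {
    expect_identical(nonsmoking_windows(m, 0), as.integer(floor(m / 8)))
  }
})

test_that("rolling window counts follow the exclusive convention", {
  expect_identical(rolling_window_count(864000, 9600), 854400L)
  expect_identical(rolling_window_count(9600, 9600), 0L)
  expect_identical(rolling_window_count(9700, 9600), 100L)
  expect_identical(rolling_window_count(100, 9600), 0L)
  expect_identical(rolling_window_count(9700, 9600, "inclusive"), 101L)
})

test_that("rates and exclusions reproduce the progressive accounting", {
  rep <- eval_report(n_tp = 100, n_reported = 123, n_fp = 22,
                     n_nonsmoking_windows = 777)
  base <- eval_rates(rep)
  expect_equal(base$tpr_pct, 81L)
  expect_equal(base$fpr_pct, 2.8)

  excl <- tibble::tibble(category = c("no_smoking", "improper_use"),
                         n_excluded = c(2L, 9L))
  adj <- eval_rates(rep, exclusions = excl)
  expect_equal(adj$corrected_reported, 112L)
  expect_equal(adj$tpr_pct, 89L)
  expect_equal(adj$tpr, 100 / 112)

  fpx <- eval_rates(rep, exclusions = tibble::tibble(
    category = "clearly_smoking", n_excluded = 6L))
  expect_equal(fpx$corrected_fp, 16L)
  expect_equal(fpx$corrected_windows, 771L)
  expect_equal(fpx$fpr_pct, 2.1)

  expect_error(
    eval_rates(rep, exclusions = tibble::tibble(
      category = "no_smoking", n_excluded = 30L)),
    "fewer reported"
  )
  expect_error(
    eval_rates(rep, exclusions = tibble::tibble(
      category = "clearly_smoking", n_excluded = 23L)),
    "exceed"
  )
  expect_error(
    eval_rates(rep, exclusions = tibble::tibble(
      category = "mystery", n_excluded = 1L)),
    "unknown"
  )
})

test_that("rates are scale-invariant in the counts", {
  a <- eval_rates(eval_report(50, 60, 11, n_nonsmoking_windows = 400))
  b <- eval_rates(eval_report(100, 120, 22, n_nonsmoking_windows = 800))
  expect_equal(a$tpr, b$tpr)
  expect_equal(a$fpr, b$fpr)
})

test_that("dropping reports from the log turns their detections into FPs", {
  withr::local_seed(81)
  starts <- seq(0, by = 2000, length.out = 10)
  det <- tibble::tibble(start_s = starts + 50, end_s = starts + 350)
  log <- tibble::tibble(start = starts, end = starts + 480)
  full <- match_sessions(det, log)
  expect_equal(full$n_tp, 10)
  expect_equal(full$n_fp, 0)
  for (k in c(1, 3, 5)) {
    thin <- log[-sample(10, k), ]
    r <- match_sessions(det, thin)
    expect_equal(r$n_fp, full$n_fp + k)
    expect_equal(r$n_tp, 10 - k)
  }
})

test_that("a perfect detector on error-free logs scores TPR 100%, FPR 0%", {
  cfg <- sim_config(report_slop_range_s = c(0, 0))
  rec <- simulate_recording(
    2, 45,
    log_errors = list(p_missing_bound = 0, p_unreported = 0, p_phantom = 0),
    config = cfg, seed = 82
  )
  # ground-truth stream stands in for a perfect classifier
  det <- puffs_to_sessions(stream_to_puffs(rec$stream, cfg$fs))
  r <- eval_rates(match_sessions(det, rec$log),
                  n_nonsmoking_windows = nonsmoking_windows(45, 2))
  expect_equal(r$tpr, 1)
  expect_equal(r$fpr, 0)
})

test_that("exclusion tables report the running corrected rates", {
  t1 <- tpr_exclusion_table(100, 123, tibble::tibble(
    category = c("no_smoking", "improper_use"), n_excluded = c(2L, 9L)))
  expect_equal(t1$corrected_reported, c(123L, 121L, 112L))
  expect_equal(t1$tpr_pct, c(81L, 82L, 89L))

  t2 <- fpr_exclusion_table(22, 777, tibble::tibble(
    category = c("clearly_smoking", "true_false_positive"),
    n_excluded = c(6L, 0L)))
  expect_equal(t2$corrected_fp, c(22L, 16L, 16L))
  expect_equal(t2$n_windows, c(777L, 771L, 771L))
  expect_equal(t2$fpr_pct, c(2.8, 2.1, 2.1))

  expect_error(tpr_exclusion_table(100, 123, tibble::tibble(
    category = "clearly_smoking", n_excluded = 1L)), "category")
})

test_that("eval reports tidy, glance and plot", {
  r <- eval_rates(eval_report(100, 123, 22, n_nonsmoking_windows = 777))
  td <- tidy(r)
  expect_true(all(c("n_true_positive", "tpr", "fpr") %in% td$metric))
  expect_equal(td$value[td$metric == "n_false_negative"], 23)
  gl <- glance(r)
  expect_equal(gl$n_tp, 100)
  p <- autoplot(r)
  expect_s3_class(p, "ggplot")
})
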