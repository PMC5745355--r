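test_that("the forward pass matches hand-computed sigmoid composition", {
  # 2-2-1 network small enough to evaluate by arithmetic
  w1 <- matrix(c(0.5, -1, 2, 0.25), 2, 2)
  b1 <- c(0.1, -0.2)
  w2 <- c(1.5, -0.75)
  b2 <- 0.3
  m <- toy_model(w1, b1, w2, b2)
  x <- matrix(c(0.4, -1.2), 1, 2)
  h <- 1 / (1 + exp(-(x %*% w1 + rep(b1, each = 1))))
  expected <- 1 / (1 + exp(-(sum(h * w2) + b2)))
  got <- score_windows(tibble::tibble(features = x), m)$score
  expect_equal(got, as.numeric(expected), tolerance = 1e-12)
})

test_that("degenerate weights pin the score where sigmoid says", {
  x <- tibble::tibble(features = matrix(rnorm(300), 1, 300))
  expect_equal(score_windows(x, constant_model(0))$score, 0.5)
  expect_lt(score_windows(x, constant_model(-1000))$score, 1e-6)
  expect_gt(score_windows(x, constant_model(1000))$score, 1 - 1e-6)
})

test_that("scores always lie in [0, 1] and reject wrong feature counts", {
  m <- full_model()
  w <- tibble::tibble(features = matrix(rnorm(20 * 300, sd = 30), 20, 300))
  s <- score_windows(w, m)$score
  expect_true(all(s >= 0 & s <= 1))
  expect_error(
    score_windows(tibble::tibble(features = matrix(0, 1, 299)), m),
    "features"
  )
})

test_that("training is deterministic given the seed", {
  corpus <- separable_corpus()
  m1 <- train_gesture_model(corpus, seed = 9, hidden = 4, max_iter = 60)
  m2 <- train_gesture_model(corpus, seed = 9, hidden = 4, max_iter = 60)
  expect_identical(m1$w1, m2$w1)
  expect_identical(m1$w2, m2$w2)
  expect_identical(m1$b1, m2$b1)
  expect_identical(m1$b2, m2$b2)
  m3 <- train_gesture_model(corpus, seed = 10, hidden = 4, max_iter = 60)
  expect_false(identical(m1$w1, m3$w1))
})

test_that("linearly separable clusters are learned perfectly", {
  corpus <- separable_corpus(n = 300)
  m <- train_gesture_model(corpus, seed = 2, hidden = 4, max_iter = 120)
  expect_equal(m$holdout_accuracy, 1)
  # independent linear classifier agrees the problem is separable
  df <- data.frame(y = corpus$label, corpus$features)
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial))
  expect_equal(mean((fitted(fit) > 0.5) == (corpus$label == 1)), 1)
})

test_that("degenerate training inputs are rejected", {
  corpus <- separable_corpus()
  expect_error(
    train_gesture_model(dplyr::filter(corpus, label == 1)),
    "both labels"
  )
  bad <- corpus
  bad$features <- bad$features[, 1:29]
  expect_error(train_gesture_model(bad), "multiple of 3")
})

test_that("an independent optimiser reaches the same separation", {
  skip_if_not_installed("nnet")
  corpus <- separable_corpus(n = 300)
  ours <- train_gesture_model(corpus, seed = 2, hidden = 4, max_iter = 120)
  fit <- withr::with_seed(2, nnet::nnet(
    corpus$features, corpus$label, size = 4, entropy = TRUE,
    maxit = 200, trace = FALSE
  ))
  nnet_acc <- mean((predict(fit) > 0.5) == (corpus$label == 1))
  expect_gte(nnet_acc, 0.99)
  expect_gte(ours$holdout_accuracy, 0.99)
})

test_that("raising the threshold never adds positive windows", {
  m <- full_model()
  w <- dplyr::slice_head(full_corpus(), n = 500)
  s <- score_windows(w, m)$score
  counts <- vapply(seq(0, 1, by = 0.05), function(th) sum(s > th), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("classify_stream equals the naive per-window loop", {
  m <- full_model()
  rec <- simulate_recording(0, 2, config = sim_config(), seed = 31)
  tr <- lowpass(rec$trace)
  stream <- classify_stream(tr, m, chunk = 97L) # odd chunk: exercise seams
  n <- nrow(tr)
  w <- 100L
  naive <- integer(n)
  decisions <- logical(n - w + 1)
  for (s in seq_len(n - w + 1)) {
    feat <- matrix(c(tr$x[s:(s + w - 1)], tr$y[s:(s + w - 1)],
                     tr$z[s:(s + w - 1)]), 1, 3 * w)
    decisions[s] <- score_windows(tibble::tibble(features = feat), m)$score >
      m$threshold
    naive[s + w %/% 2] <- as.integer(decisions[s])
  }
  naive[1:(w %/% 2)] <- naive[w %/% 2 + 1]
  last <- (n - w + 1) + w %/% 2
  if (last < n) naive[(last + 1):n] <- naive[last]
  expect_identical(stream, naive)
})

test_that("constant-scoring models produce constant streams", {
  tr <- accel_trace(rnorm(300), rnorm(300), 9.81 + rnorm(300))
  expect_identical(classify_stream(tr, constant_model(-1000)),
                   integer(300))
  expect_identical(classify_stream(tr, constant_model(1000)),
                   rep(1L, 300))
  empty <- accel_trace(numeric(0), numeric(0), numeric(0))
  expect_identical(classify_stream(empty, constant_model(0)), integer(0))
})

test_that("models serialise to JSON and back without loss", {
  m <- train_gesture_model(separable_corpus(), seed = 4, hidden = 3,
                           max_iter = 40)
  f <- withr::local_tempfile(fileext = ".json")
  write_gesture_model(m, f)
  back <- read_gesture_model(f)
  expect_equal(back$w1, m$w1, tolerance = 1e-14)
  expect_equal(back$w2, m$w2, tolerance = 1e-14)
  expect_equal(back$b1, m$b1, tolerance = 1e-14)
  expect_equal(back$b2, m$b2, tolerance = 1e-14)
  expect_equal(back$threshold, m$threshold)
  expect_equal(back$scaling$center, m$scaling$center, tolerance = 1e-14)
  x <- tibble::tibble(features = matrix(rnorm(5 * 30), 5, 30))
  expect_equal(score_windows(x, back)$score, score_windows(x, m)$score,
               tolerance = 1e-12)
})

test_that("tidy and glance summarise a fitted model", {
  m <- train_gesture_model(separable_corpus(), seed = 4, hidden = 3,
                           max_iter = 40)
  td <- tidy(m)
  expect_equal(nrow(td), (30 + 1) * 3 + 3 + 1)
  expect_named(td, c("layer", "unit", "term", "estimate"))
  gl <- glance(m)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_hidden, 3)
  expect_equal(gl$threshold, 0.85)
})
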